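#' Lineage tree as an ape phylogeny / Newick string
#'
#' Converts the genealogy of selected individuals into an `ape` `phylo`
#' object (tips are the childless individuals, edge lengths are generation
#' steps, labels are individual ids). Multiple founders are joined under a
#' virtual root named `ROOT`. `exportNewick` writes/returns the Newick
#' serialisation; single-child ancestors are collapsed onto their outgoing
#' edge (Newick has no singleton nodes), so pair it with the edge
#' annotation TSV from [writeRunOutputs()] for the per-edge mutations.
#'
#' @param tree a [LineageTree].
#' @param path optional file to write the Newick string to.
#' @return `lineagePhylo`: an `ape` `phylo`; `exportNewick`: the Newick
#'   string, invisibly when `path` is given.
#' @export
lineagePhylo <- function(tree) {
  nd <- tree@nodes
  ids <- nd$id
  parent <- ifelse(is.na(nd$parentId), "ROOT", nd$parentId)
  gen <- stats::setNames(c(nd$generation, -1L), c(ids, "ROOT"))
  nchild <- table(factor(parent, levels = c(ids, "ROOT")))
  ## singleton (one-child) ancestors are collapsed onto the edge: Newick has
  ## no place for them, the companion TSV keeps the full chain
  keep <- names(nchild)[nchild != 1L | names(nchild) == "ROOT"]
  parentOf <- stats::setNames(parent, ids)
  nearestKept <- function(x) {
    p <- parentOf[[x]]
    while (!(p %in% keep)) p <- parentOf[[p]]
    p
  }
  tipIds <- intersect(ids, names(nchild)[nchild == 0L])
  intIds <- c("ROOT", setdiff(keep, c(tipIds, "ROOT")))
  idx <- stats::setNames(seq_along(c(tipIds, intIds)), c(tipIds, intIds))
  nonroot <- setdiff(keep, "ROOT")
  anc <- vapply(nonroot, nearestKept, character(1))
  phy <- list(edge = cbind(unname(idx[anc]), unname(idx[nonroot])),
              edge.length = unname(gen[nonroot] - gen[anc]),
              tip.label = tipIds,
              node.label = intIds,
              Nnode = length(intIds))
  class(phy) <- "phylo"
  phy
}

#' @rdname lineagePhylo
#' @export
exportNewick <- function(tree, path = NULL) {
  phy <- lineagePhylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write all artefacts of a finished run
#'
#' Writes, under `outDir`: `records.tsv` (one row per pool member per
#' generation with the full fitness breakdown and a selected flag),
#' `final_population.fasta`, `lineage.nwk` plus `lineage_edges.tsv` (one
#' row per tree edge with its mutation annotation), and `manifest.json`
#' (configuration echo, seed, package and R versions).
#'
#' @param run an [EvolutionRun].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunOutputs <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(run@records, file.path(outDir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeFastaPopulation(run@population,
                       file.path(outDir, "final_population.fasta"))
  exportNewick(run@tree, file.path(outDir, "lineage.nwk"))
  nd <- run@tree@nodes
  edges <- nd[!is.na(nd$parentId),
              c("id", "parentId", "generation", "eventType", "eventPos",
                "eventPayload", "score")]
  utils::write.table(edges, file.path(outDir, "lineage_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- run@config
  manifest <- list(
    package = "foldevo",
    version = as.character(utils::packageVersion("foldevo")),
    r_version = R.version.string,
    seed = cfg@seed,
    pop_size = cfg@popSize,
    founder_mode = cfg@founderMode,
    founder_length = cfg@founderLength,
    selection_mode = cfg@selection@mode,
    beta = cfg@selection@beta,
    event_rates = as.list(cfg@dictionary@eventRates),
    indel_range = cfg@dictionary@indelRange,
    min_length = cfg@dictionary@minLength,
    max_length = cfg@dictionary@maxLength,
    plddt_stop = cfg@plddtStop,
    ptm_stop = cfg@ptmStop,
    max_generations = cfg@maxGenerations,
    generations_run = run@generations,
    stop_id = if (is.na(run@stopId)) NULL else run@stopId,
    dimer_mode = !is.null(cfg@partner))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}
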