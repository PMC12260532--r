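#' Radius of gyration of a chain
#'
#' Unweighted root-mean-square distance of the CA atoms to their centroid.
#'
#' @param model a [StructureModel].
#' @param chain chain label; defaults to the first chain.
#' @return radius of gyration in Angstrom.
#' @export
radiusOfGyration <- function(model, chain = NULL) {
  if (is.null(chain)) chain <- model@chain[1]
  ca <- atomCoords(model, "CA", chain = chain)
  if (nrow(ca) == 0L) stop("empty chain")
  cen <- colMeans(ca)
  sqrt(mean(rowSums(sweep(ca, 2, cen)^2)))
}

#' Extract the root-to-individual lineage
#'
#' Walks the lineage tree from the given individual back to its founder and
#' returns the path root-first. Event-free edges (survivor clones of an
#' unchanged parent) carry no mutation, so the number of distinct sequences
#' on a lineage is always smaller than the number of generations; the
#' `events` list keeps only the true mutation events, in order.
#'
#' @param tree a [LineageTree].
#' @param individualId id of any node in the tree.
#' @return list with `path` (data.frame of the node rows, root first) and
#'   `events` (list of [MutationEvent] on the path, in order).
#' @export
extractLineage <- function(tree, individualId) {
  nd <- tree@nodes
  i <- match(individualId, nd$id)
  if (is.na(i)) stop(sprintf("no individual '%s' in the tree", individualId))
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(i, path)
    i <- match(nd$parentId[i], nd$id)
  }
  rows <- nd[path, , drop = FALSE]
  rownames(rows) <- NULL
  has_ev <- !is.na(rows$eventType)
  events <- lapply(which(has_ev), function(j) {
    pos <- as.integer(strsplit(rows$eventPos[j], ":")[[1]])
    new("MutationEvent", type = rows$eventType[j],
        position = if (length(pos)) pos else integer(),
        payload = if (is.na(rows$eventPayload[j])) ""
                  else rows$eventPayload[j])
  })
  list(path = rows, events = events)
}

#' Summary statistics of a completed run
#'
#' Table-style accounting of one run: the total mutation load is exactly
#' N x generations (one mutation per individual per generation); the fixed
#' mutations are those on the nucleation lineage, i.e. the lineage of the
#' first individual to satisfy the stop condition (ties broken by higher
#' score, then stable order) or of the best-scoring final individual when
#' the run stopped on budget. Mutations per site divides the fixed count by
#' the mean final sequence length; for variable-length runs (dictionaries
#' allowing more than single-residue indels) that is an overestimate and is
#' flagged as such.
#'
#' @param run an [EvolutionRun], or `records` + `tree` given separately.
#' @param records per-generation records (when `run` is not given).
#' @param tree the [LineageTree] (when `run` is not given).
#' @param config the [RunConfig] (when `run` is not given).
#' @param stopId id of the stop individual, or `NA`.
#' @return a [SummaryStats].
#' @export
summarizeRun <- function(run = NULL, records = NULL, tree = NULL,
                         config = NULL, stopId = NA_character_) {
  if (!is.null(run)) {
    records <- run@records; tree <- run@tree; config <- run@config
    stopId <- run@stopId
  }
  if (is.null(records) || nrow(records) == 0L)
    stop("summarizeRun needs a non-empty run record")
  gens <- max(records$generation)
  if (gens < 1L) stop("run has no completed generation")
  n <- config@popSize
  total <- as.numeric(n) * gens
  ## nucleation individual: stop individual, else best-scoring final survivor
  if (is.na(stopId)) {
    fin <- records[records$generation == gens & records$selected, ]
    fin <- fin[order(-fin$score), ]
    focal <- fin$id[1]
    ## the id recorded in the final generation may be a pool id that was
    ## cloned; every selected individual is in the tree, fall back to the
    ## best tree node of the last generation
    if (!(focal %in% tree@nodes$id)) {
      cand <- tree@nodes[tree@nodes$generation == gens, ]
      focal <- cand$id[order(-cand$score)][1]
    }
  } else focal <- stopId
  lin <- extractLineage(tree, focal)
  fixed <- length(lin$events)
  finalPop <- records[records$generation == gens & records$selected, ]
  ## survivors selected several times (clones) count with multiplicity
  w <- if ("selected_n" %in% names(finalPop)) finalPop$selected_n
       else rep(1L, nrow(finalPop))
  meanLen <- sum(finalPop$length * w) / sum(w)
  rates <- config@dictionary@eventRates
  varlen <- any(rates[c("MULTI_DELETION", "RANDOM_INSERTION",
                        "PARTIAL_DUPLICATION", "COMPLETE_DUPLICATION")] > 0)
  perGen <- do.call(rbind, lapply(split(records, records$generation),
    function(d) data.frame(generation = d$generation[1],
                           meanRg = mean(d$rg), fracH = mean(d$frac_h),
                           fracE = mean(d$frac_e), fracC = mean(d$frac_c))))
  rownames(perGen) <- NULL
  new("SummaryStats", generations = gens, totalMutations = total,
      fixedMutations = fixed, fixationRate = fixed / total,
      meanFinalLength = meanLen, mutationsPerSite = fixed / meanLen,
      variableLength = varlen, perGeneration = perGen)
}

#' Aggregate summary statistics over replicate runs
#'
#' Means over replicates, the way multi-run tables are reported: the
#' aggregate fixation rate is the mean fixed count over the mean total
#' mutation load, and the aggregate mutations per site is the mean fixed
#' count over the mean final length.
#'
#' @param stats list of [SummaryStats] (or a data.frame with columns
#'   generations, totalMutations, fixedMutations, meanFinalLength).
#' @return one-row data.frame with the aggregated quantities.
#' @export
aggregateSummaries <- function(stats) {
  df <- if (is.data.frame(stats)) stats else
    do.call(rbind, lapply(stats, function(s)
      data.frame(generations = s@generations,
                 totalMutations = s@totalMutations,
                 fixedMutations = s@fixedMutations,
                 meanFinalLength = s@meanFinalLength)))
  data.frame(
    nRuns = nrow(df),
    meanGenerations = mean(df$generations),
    meanTotalMutations = mean(df$totalMutations),
    meanFixedMutations = mean(df$fixedMutations),
    fixationRate = mean(df$fixedMutations) / mean(df$totalMutations),
    meanFinalLength = mean(df$meanFinalLength),
    mutationsPerSite = mean(df$fixedMutations) / mean(df$meanFinalLength))
}

#' Secondary-structure composition per generation
#'
#' H/E/C fractions of the evolving chain, per generation, either from run
#' records (mean over pool members) or from a list of annotations.
#'
#' @param x an [EvolutionRun], a records data.frame, or a list of
#'   [SecondaryStructureAnnotation].
#' @return data.frame with columns generation (or index), fracH, fracE,
#'   fracC; the three fractions sum to 1 in every row.
#' @export
ssComposition <- function(x) {
  if (is(x, "EvolutionRun")) x <- x@records
  if (is.data.frame(x)) {
    out <- do.call(rbind, lapply(split(x, x$generation), function(d)
      data.frame(generation = d$generation[1], fracH = mean(d$frac_h),
                 fracE = mean(d$frac_e), fracC = mean(d$frac_c))))
    rownames(out) <- NULL
    return(out)
  }
  do.call(rbind, lapply(seq_along(x), function(i) {
    labs <- x[[i]]@labels
    data.frame(generation = i, fracH = mean(labs == "H"),
               fracE = mean(labs == "E"), fracC = mean(labs == "C"))
  }))
}
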