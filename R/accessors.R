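#' @describeIn ProteinSequence-class constructor.
#' @param residues residue string.
#' @param id unique token (a fresh one is generated when omitted).
#' @param generation non-negative integer.
#' @param parentId parent token or `NA`.
#' @export
proteinSequence <- function(residues, id = NULL, generation = 0L,
                            parentId = NA_character_) {
  if (is.null(id)) id <- .fresh_id("seq")
  new("ProteinSequence", id = id, residues = toupper(residues),
      generation = as.integer(generation), parentId = parentId)
}

.id_counter <- local({env <- new.env(); env$i <- 0L; env})

.fresh_id <- function(prefix) {
  .id_counter$i <- .id_counter$i + 1L
  sprintf("%s%06d", prefix, .id_counter$i)
}

#' @rdname ProteinSequence-class
#' @export
setMethod("seqId", "ProteinSequence", function(x) x@id)

#' @rdname ProteinSequence-class
#' @export
setMethod("residues", "ProteinSequence", function(x) x@residues)

#' @rdname ProteinSequence-class
#' @export
setMethod("residues", "character", function(x) x)

#' @rdname ProteinSequence-class
#' @export
setMethod("generation", "ProteinSequence", function(x) x@generation)

#' @rdname ProteinSequence-class
#' @export
setMethod("parentId", "ProteinSequence", function(x) x@parentId)

#' @rdname ProteinSequence-class
#' @export
setMethod("nchar", "ProteinSequence", function(x) nchar(x@residues))

setMethod("show", "ProteinSequence", function(object) {
  cat(sprintf("ProteinSequence %s (generation %d, length %d)\n",
              object@id, object@generation, nchar(object@residues)))
  cat(" ", object@residues, "\n")
})

#' @rdname StructureModel-class
#' @export
setMethod("plddt", "StructureModel", function(x) x@plddt)

#' @rdname StructureModel-class
#' @export
setMethod("ptm", "StructureModel", function(x) x@ptm)

#' @rdname StructureModel-class
#' @export
setMethod("chains", "StructureModel", function(x) unique(x@chain))

#' @describeIn StructureModel-class per-residue coordinates of one backbone
#'   atom (`"N"`, `"CA"`, `"C"`, or `"CB"`), optionally for one chain.
#' @param model a `StructureModel`.
#' @param atom backbone atom name.
#' @param chain chain label, or `NULL` for all residues.
#' @export
atomCoords <- function(model, atom = c("CA", "CB", "N", "C"), chain = NULL) {
  atom <- match.arg(atom)
  co <- slot(model, tolower(atom))
  if (!is.null(chain)) co <- co[model@chain == chain, , drop = FALSE]
  co
}

setMethod("show", "StructureModel", function(object) {
  ch <- chains(object)
  cat(sprintf("StructureModel: %d residue(s), %d chain(s) [%s]\n",
              length(object@residues), length(ch), paste(ch, collapse = ",")))
  cat(sprintf("  mean pLDDT %.3f, pTM %.3f\n", mean(object@plddt), object@ptm))
})

#' @rdname FitnessBreakdown-class
#' @export
setMethod("fitness", "FitnessBreakdown", function(x) x@score)

#' @describeIn FitnessBreakdown-class all terms as a one-row data.frame.
#' @param row.names,optional,... ignored; standard `as.data.frame` arguments.
#' @export
setMethod("as.data.frame", "FitnessBreakdown",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(plddt_mean = x@plddtMean, ptm = x@ptm, cd = x@cd,
               iplddt = x@iplddt, icd = x@icd, constr = x@constr,
               score = x@score)
  })

setMethod("show", "FitnessBreakdown", function(object) {
  cat("FitnessBreakdown\n")
  cat(sprintf("  plddt_mean %.4f  ptm %.4f  cd %.4f\n",
              object@plddtMean, object@ptm, object@cd))
  cat(sprintf("  iplddt %.4f  icd %.4f  constr %.4f\n",
              object@iplddt, object@icd, object@constr))
  cat(sprintf("  score = %.6g\n", object@score))
})

#' @rdname LineageTree-class
#' @export
setMethod("lineageNodes", "LineageTree", function(x) x@nodes)

setMethod("show", "LineageTree", function(object) {
  nd <- object@nodes
  cat(sprintf("LineageTree: %d node(s), %d founder root(s), generations 0..%d\n",
              nrow(nd), sum(is.na(nd$parentId)), max(nd$generation)))
})

setMethod("show", "SelectionConfig", function(object) {
  cat(sprintf("SelectionConfig: mode %s%s\n", object@mode,
              if (object@mode == "GIBBS")
                sprintf(" (beta = %g)", object@beta) else ""))
})

setMethod("show", "EvolutionRun", function(object) {
  cat(sprintf("EvolutionRun: N = %d, %d generation(s)%s\n",
              object@config@popSize, object@generations,
              if (is.na(object@stopId)) " (budget exhausted)"
              else sprintf(" (stopped by %s)", object@stopId)))
  sel <- object@records[object@records$selected, ]
  if (nrow(sel)) {
    last <- sel[sel$generation == max(sel$generation), ]
    cat(sprintf("  final best score %.6g, mean length %.1f\n",
                max(last$score), mean(last$length)))
  }
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats\n")
  cat(sprintf("  generations        %g\n", object@generations))
  cat(sprintf("  total mutations    %g\n", object@totalMutations))
  cat(sprintf("  fixed mutations    %g\n", object@fixedMutations))
  cat(sprintf("  fixation rate      %.5f\n", object@fixationRate))
  cat(sprintf("  mean final length  %.2f\n", object@meanFinalLength))
  cat(sprintf("  mutations per site %.3f%s\n", object@mutationsPerSite,
              if (object@variableLength) " (variable-length run: overestimate)"
              else ""))
})
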