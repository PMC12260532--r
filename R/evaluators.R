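#' Recorded-fixture structure backend
#'
#' Replays stored [StructureModel] objects keyed by residue string. Its main
#' use is proving that the engine is backend-agnostic: any code path
#' exercised with the surrogate can be exercised identically with recorded
#' models.
#'
#' @param models named list of [StructureModel]; names are residue strings.
#' @return a [FixtureEvaluator].
#' @export
fixtureEvaluator <- function(models) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be named by residue string")
  new("FixtureEvaluator", deterministic = TRUE, batchCapable = TRUE,
      models = models)
}

#' @rdname evaluateStructure
#' @export
setMethod("evaluateStructure", "FixtureEvaluator",
  function(evaluator, sequences, partner = NULL) {
    seqs <- if (is.list(sequences)) vapply(sequences, residues, character(1))
            else sequences
    miss <- setdiff(seqs, names(evaluator@models))
    if (length(miss))
      stop(sprintf("no recorded model for sequence(s): %s",
                   paste(substr(miss, 1, 20), collapse = ", ")))
    unname(evaluator@models[seqs])
  })

#' Evaluate a generation in batches
#'
#' Splits the sequences into batches of at most `batchSize` and concatenates
#' the results. Batching is purely a throughput contract: output order
#' always matches input order, and for deterministic backends the models are
#' identical to one-at-a-time evaluation.
#'
#' @param sequences character vector or list of [ProteinSequence]; must be
#'   non-empty.
#' @param evaluator a [StructureEvaluator].
#' @param partner optional fixed-partner [StructureModel].
#' @param batchSize maximum sequences per backend call.
#' @return list of [StructureModel] in input order.
#' @export
batchEvaluate <- function(sequences, evaluator, partner = NULL,
                          batchSize = 16L) {
  seqs <- if (is.list(sequences)) vapply(sequences, residues, character(1))
          else sequences
  if (length(seqs) == 0L) stop("batchEvaluate needs at least one sequence")
  ids <- if (is.list(sequences))
    vapply(sequences, function(s)
      if (is(s, "ProteinSequence")) seqId(s) else NA_character_,
      character(1))
    else rep(NA_character_, length(seqs))
  groups <- split(seq_along(seqs),
                  ceiling(seq_along(seqs) / max(1L, batchSize)))
  out <- vector("list", length(seqs))
  for (g in groups) {
    models <- tryCatch(
      evaluateStructure(evaluator, seqs[g], partner = partner),
      error = function(e) stop(sprintf(
        "structure evaluation failed for sequence(s) [%s]: %s",
        paste(ifelse(is.na(ids[g]), g, ids[g]), collapse = ", "),
        conditionMessage(e)), call. = FALSE))
    out[g] <- models
  }
  out
}
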