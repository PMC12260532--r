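#' Random amino acid string
#'
#' Uniform over the 20 canonical residues; uses the current RNG state.
#'
#' @param length number of residues.
#' @return a residue string.
#' @export
randomResidues <- function(length)
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")

#' Draw exactly one mutation event
#'
#' Samples an event type from the dictionary's rate table and the event's
#' position/payload from the sequence. Events that would push the chain
#' below `minLength` or above `maxLength` (deletions of a minimal chain,
#' duplications of a near-maximal one) are coerced to a substitution, so the
#' hard length guards can never be violated. Uses the current RNG state;
#' wrap calls in [withStream()] (or `set.seed()`) for reproducibility.
#'
#' @param seq a [ProteinSequence] or residue string.
#' @param dict an [EvolutionaryDictionary].
#' @return a [MutationEvent].
#' @export
drawMutation <- function(seq, dict) {
  res <- residues(seq)
  L <- nchar(res)
  if (L == 0L) stop("cannot mutate an empty sequence")
  r <- dict@eventRates
  type <- sample(names(r), 1L, prob = r)
  lo <- dict@indelRange[1]; hi <- dict@indelRange[2]
  klaw <- function() if (lo == hi) lo else sample(lo:hi, 1L)
  repeat {
    switch(type,
      SINGLE_DELETION = if (L - 1L < dict@minLength) type <- "SUBSTITUTION"
                        else return(new("MutationEvent", type = type,
                                        position = sample.int(L, 1L),
                                        payload = "")),
      MULTI_DELETION = {
        k <- klaw()
        if (L - k < dict@minLength || k >= L) type <- "SUBSTITUTION"
        else {
          start <- sample.int(L - k + 1L, 1L)
          return(new("MutationEvent", type = type,
                     position = c(start, start + k - 1L), payload = ""))
        }
      },
      SINGLE_INSERTION = if (L + 1L > dict@maxLength) type <- "SUBSTITUTION"
                         else return(new("MutationEvent", type = type,
                                         position = sample.int(L + 1L, 1L),
                                         payload = sample(AA_ALPHABET, 1L))),
      RANDOM_INSERTION = {
        k <- klaw()
        if (L + k > dict@maxLength) type <- "SUBSTITUTION"
        else return(new("MutationEvent", type = type,
                        position = sample.int(L + 1L, 1L),
                        payload = randomResidues(k)))
      },
      PARTIAL_DUPLICATION = {
        segmax <- L %/% 2L
        if (segmax < 2L) type <- "SUBSTITUTION"
        else {
          k <- if (segmax == 2L) 2L else sample(2L:segmax, 1L)
          if (L + k > dict@maxLength) type <- "SUBSTITUTION"
          else {
            start <- sample.int(L - k + 1L, 1L)
            return(new("MutationEvent", type = type,
                       position = c(start, start + k - 1L), payload = ""))
          }
        }
      },
      COMPLETE_DUPLICATION = if (2L * L > dict@maxLength) type <- "SUBSTITUTION"
                             else return(new("MutationEvent", type = type,
                                             position = integer(),
                                             payload = "")),
      CIRCULAR_PERMUTATION = if (L < 2L) type <- "SUBSTITUTION"
                             else return(new("MutationEvent", type = type,
                                             position = sample.int(L - 1L, 1L),
                                             payload = "")),
      SUBSTITUTION = {
        pos <- sample.int(L, 1L)
        orig <- substr(res, pos, pos)
        repl <- sample(AA_ALPHABET, 1L,
                       prob = dict@substitutionMatrix[orig, ])
        return(new("MutationEvent", type = "SUBSTITUTION",
                   position = pos, payload = repl))
      })
  }
}

#' Apply a mutation event to a sequence
#'
#' Pure string transformation; the result is a new [ProteinSequence] whose
#' `parentId` is the input's id and whose generation is one higher. Length
#' bookkeeping is exact: substitution and circular permutation preserve
#' length, single indels change it by one, a complete duplication doubles
#' it, a partial duplication adds the segment length, and multi-deletion /
#' random insertion change it by the event's k.
#'
#' @param seq a [ProteinSequence] (or residue string, in which case a bare
#'   string is returned).
#' @param ev a [MutationEvent] valid for `seq`.
#' @return mutated [ProteinSequence] (or string).
#' @examples
#' applyMutation("MKVW", new("MutationEvent", type = "SUBSTITUTION",
#'                           position = 2L, payload = "A"))
#' @export
applyMutation <- function(seq, ev) {
  res <- residues(seq)
  L <- nchar(res)
  p <- ev@position
  chk <- function(ok) if (!ok) stop(sprintf(
    "position [%s] out of range for %s on a sequence of length %d",
    paste(p, collapse = ","), ev@type, L))
  out <- switch(ev@type,
    SUBSTITUTION = {
      chk(length(p) == 1L && p >= 1L && p <= L && nchar(ev@payload) == 1L)
      paste0(substr(res, 1L, p - 1L), ev@payload, substr(res, p + 1L, L))
    },
    SINGLE_INSERTION = ,
    RANDOM_INSERTION = {
      chk(length(p) == 1L && p >= 1L && p <= L + 1L && nchar(ev@payload) >= 1L)
      paste0(substr(res, 1L, p - 1L), ev@payload, substr(res, p, L))
    },
    SINGLE_DELETION = {
      chk(length(p) == 1L && p >= 1L && p <= L)
      paste0(substr(res, 1L, p - 1L), substr(res, p + 1L, L))
    },
    MULTI_DELETION = {
      chk(length(p) == 2L && p[1] >= 1L && p[2] >= p[1] && p[2] <= L)
      paste0(substr(res, 1L, p[1] - 1L), substr(res, p[2] + 1L, L))
    },
    PARTIAL_DUPLICATION = {
      chk(length(p) == 2L && p[1] >= 1L && p[2] >= p[1] && p[2] <= L)
      seg <- substr(res, p[1], p[2])
      paste0(substr(res, 1L, p[2]), seg, substr(res, p[2] + 1L, L))
    },
    COMPLETE_DUPLICATION = paste0(res, res),
    CIRCULAR_PERMUTATION = {
      chk(length(p) == 1L && p >= 1L && p <= L - 1L)
      paste0(substr(res, p + 1L, L), substr(res, 1L, p))
    },
    stop(sprintf("unknown event type '%s'", ev@type)))
  if (is(seq, "ProteinSequence")) {
    proteinSequence(out, generation = seq@generation + 1L,
                    parentId = seq@id)
  } else out
}

#' Create the founder population
#'
#' Either `n` independent random sequences of the given length, or `n`
#' single-event mutants of one seed sequence (random unless supplied).
#' Founders sit at generation 0 with no parent. Uses the current RNG state.
#'
#' @param mode `"n_random"` or `"n_mutants_of_one"`.
#' @param length founder sequence length.
#' @param n population size (>= 2).
#' @param dict [EvolutionaryDictionary] used to draw the single events in
#'   `n_mutants_of_one` mode.
#' @param seedSequence optional predefined seed residue string for
#'   `n_mutants_of_one`.
#' @return list of `n` [ProteinSequence] founders.
#' @export
makeFounders <- function(mode = c("n_random", "n_mutants_of_one"),
                         length = 24L, n = 100L,
                         dict = evolutionaryDictionary(),
                         seedSequence = NULL) {
  mode <- match.arg(mode)
  if (n < 2L) stop("need a population of at least 2")
  if (length < dict@minLength)
    stop(sprintf("founder length %d below the minimum %d", length,
                 dict@minLength))
  if (mode == "n_random") {
    lapply(seq_len(n), function(i)
      proteinSequence(randomResidues(length), id = .fresh_id("f")))
  } else {
    seed <- if (is.null(seedSequence)) randomResidues(length)
            else toupper(seedSequence)
    lapply(seq_len(n), function(i) {
      ev <- drawMutation(seed, dict)
      proteinSequence(applyMutation(seed, ev), id = .fresh_id("f"))
    })
  }
}
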