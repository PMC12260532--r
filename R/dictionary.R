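## Default event-type rates: substitutions dominate, duplications and
## circular permutations are rare. All overridable via evolutionaryDictionary().
DEFAULT_EVENT_RATES <- c(
  SUBSTITUTION         = 0.88,
  SINGLE_INSERTION     = 0.04,
  SINGLE_DELETION      = 0.04,
  MULTI_DELETION       = 0.01,
  RANDOM_INSERTION     = 0.01,
  PARTIAL_DUPLICATION  = 0.01,
  COMPLETE_DUPLICATION = 0.005,
  CIRCULAR_PERMUTATION = 0.005)

## Event rates for the fixed-length regime: point mutations and single
## amino acid indels only, so chain length stays approximately constant.
FIXED_LENGTH_EVENT_RATES <- c(
  SUBSTITUTION     = 0.90,
  SINGLE_INSERTION = 0.05,
  SINGLE_DELETION  = 0.05)

.full_rates <- function(r) {
  out <- setNames(numeric(length(EVENT_TYPES)), EVENT_TYPES)
  out[names(r)] <- r
  out
}

#' Build an evolutionary dictionary
#'
#' An evolutionary dictionary holds everything the mutation operator needs:
#' the probabilities of the eight event types, the amino acid substitution
#' model, and the length law for multi-residue indels. Substitution models:
#' \describe{
#'   \item{flat}{uniform over the 19 alternative residues.}
#'   \item{frequency}{replacement probability proportional to user-supplied
#'     target amino acid frequencies (self-replacement excluded).}
#'   \item{matrix}{an explicit 20x20 row-stochastic replacement table, e.g.
#'     derived from PAM/BLOSUM-style matrices; the diagonal is zeroed and
#'     rows renormalised so a substitution never returns the original
#'     residue.}
#' }
#'
#' @param eventRates named numeric of event-type probabilities (must sum
#'   to 1). Missing event types get probability 0. `fixedLengthRates()`
#'   gives the preset that keeps chain length approximately constant.
#' @param substitution `"flat"`, `"frequency"`, or `"matrix"`.
#' @param targetFreqs named numeric of 20 amino acid frequencies
#'   (for `substitution = "frequency"`).
#' @param matrix 20x20 numeric matrix with amino acid dimnames
#'   (for `substitution = "matrix"`); rows need not be normalised.
#' @param indelRange inclusive bounds of the uniform length law for
#'   `MULTI_DELETION` / `RANDOM_INSERTION`.
#' @param minLength,maxLength hard guards on chain length; events that would
#'   cross either bound are resampled as substitutions.
#' @return an [EvolutionaryDictionary].
#' @examples
#' d <- evolutionaryDictionary()
#' d2 <- evolutionaryDictionary(fixedLengthRates())
#' @export
evolutionaryDictionary <- function(eventRates = DEFAULT_EVENT_RATES,
                                   substitution = c("flat", "frequency",
                                                    "matrix"),
                                   targetFreqs = NULL, matrix = NULL,
                                   indelRange = c(2L, 10L),
                                   minLength = 10L, maxLength = 500L) {
  substitution <- match.arg(substitution)
  sm <- switch(substitution,
    flat = flatSubstitutionMatrix(),
    frequency = frequencySubstitutionMatrix(targetFreqs),
    matrix = normalizeSubstitutionMatrix(matrix))
  new("EvolutionaryDictionary", eventRates = .full_rates(eventRates),
      substitutionMatrix = sm, indelRange = as.integer(indelRange),
      minLength = as.integer(minLength), maxLength = as.integer(maxLength))
}

#' @rdname evolutionaryDictionary
#' @export
fixedLengthRates <- function() FIXED_LENGTH_EVENT_RATES

#' @rdname evolutionaryDictionary
#' @export
flatSubstitutionMatrix <- function() {
  m <- matrix(1 / 19, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(m) <- 0
  m
}

#' @rdname evolutionaryDictionary
#' @export
frequencySubstitutionMatrix <- function(targetFreqs) {
  if (is.null(targetFreqs) || !all(AA_ALPHABET %in% names(targetFreqs)))
    stop("targetFreqs must be a named vector covering all 20 amino acids")
  f <- targetFreqs[AA_ALPHABET]
  if (any(f < 0) || sum(f) <= 0) stop("targetFreqs must be non-negative")
  m <- matrix(rep(f, each = 20), 20, 20,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  normalizeSubstitutionMatrix(m)
}

#' @rdname evolutionaryDictionary
#' @export
normalizeSubstitutionMatrix <- function(matrix) {
  if (is.null(matrix) || !all(dim(matrix) == c(20L, 20L)))
    stop("substitution matrix must be 20x20")
  m <- matrix[AA_ALPHABET, AA_ALPHABET]
  if (any(m < 0)) stop("substitution matrix entries must be non-negative")
  diag(m) <- 0
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("every row needs at least one allowed replacement")
  m / rs
}

#' Read a whitespace-delimited 20x20 substitution table
#'
#' The expected layout is a header row of one-letter codes followed by 20
#' rows, each beginning with its one-letter code. Rows are renormalised and
#' the diagonal zeroed, so count- or score-derived tables are accepted as
#' long as entries are non-negative.
#'
#' @param path file path.
#' @return a 20x20 row-stochastic matrix usable as the `matrix` argument of
#'   [evolutionaryDictionary()].
#' @export
readSubstitutionMatrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(AA_ALPHABET %in% rownames(m)) || !all(AA_ALPHABET %in% colnames(m)))
    stop("table must cover all 20 one-letter amino acid codes")
  normalizeSubstitutionMatrix(m)
}

#' Serialise / restore an evolutionary dictionary
#'
#' Dictionaries round-trip through YAML (or JSON, chosen by file
#' extension). The substitution matrix is stored row-wise.
#'
#' @param dict an [EvolutionaryDictionary].
#' @param path output (`writeDictionary`) or input (`readDictionary`) file;
#'   `.json` selects JSON, anything else YAML.
#' @return `readDictionary` returns the restored [EvolutionaryDictionary];
#'   `writeDictionary` returns `path` invisibly.
#' @export
writeDictionary <- function(dict, path) {
  obj <- list(
    event_rates = as.list(dict@eventRates),
    substitution_matrix = stats::setNames(
      lapply(seq_len(20), function(i) unname(dict@substitutionMatrix[i, ])),
      AA_ALPHABET),
    indel_range = dict@indelRange,
    min_length = dict@minLength,
    max_length = dict@maxLength)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path, precision = 12L)
  }
  invisible(path)
}

#' @rdname writeDictionary
#' @export
readDictionary <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  m <- do.call(rbind, lapply(obj$substitution_matrix[AA_ALPHABET], unlist))
  colnames(m) <- AA_ALPHABET
  new("EvolutionaryDictionary",
      eventRates = .full_rates(unlist(obj$event_rates)),
      substitutionMatrix = m / rowSums(m),
      indelRange = as.integer(unlist(obj$indel_range)),
      minLength = as.integer(obj$min_length),
      maxLength = as.integer(obj$max_length))
}
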