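#' @import methods
NULL

## Canonical one-letter amino acid alphabet (alphabetical by letter).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Mutation event types drawn from the evolutionary dictionary.
EVENT_TYPES <- c("SUBSTITUTION", "SINGLE_INSERTION", "SINGLE_DELETION",
                 "MULTI_DELETION", "RANDOM_INSERTION", "PARTIAL_DUPLICATION",
                 "COMPLETE_DUPLICATION", "CIRCULAR_PERMUTATION")

.valid_residues <- function(x) {
  nzchar(x) && !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), x)
}

#' One evolving protein chain
#'
#' A single member of the evolving population: an amino acid sequence with an
#' opaque identity and provenance (parent individual and the mutation event
#' that produced it, if any).
#'
#' @slot id opaque unique token.
#' @slot residues string over the 20 canonical one-letter amino acid codes.
#' @slot generation non-negative integer; founders are generation 0.
#' @slot parentId id of the parent individual, or `NA` for founders.
#'
#' @exportClass ProteinSequence
setClass("ProteinSequence",
  representation(id = "character", residues = "character",
                 generation = "integer", parentId = "character"),
  prototype(id = NA_character_, residues = "", generation = 0L,
            parentId = NA_character_))

setValidity("ProteinSequence", function(object) {
  msg <- character()
  if (length(object@residues) != 1L || !.valid_residues(object@residues))
    msg <- c(msg, "residues must be a single string over the 20 canonical amino acid codes")
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    msg <- c(msg, "generation must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' A single mutation event
#'
#' One event drawn from the evolutionary dictionary, describing how a parent
#' sequence is transformed into its offspring.
#'
#' @slot type one of `SUBSTITUTION`, `SINGLE_INSERTION`, `SINGLE_DELETION`,
#'   `MULTI_DELETION`, `RANDOM_INSERTION`, `PARTIAL_DUPLICATION`,
#'   `COMPLETE_DUPLICATION`, `CIRCULAR_PERMUTATION`.
#' @slot position 1-based position (or start/end range for segment events;
#'   the cut point for circular permutation). Empty for complete duplication.
#' @slot payload inserted or substituted residues, if any.
#'
#' @exportClass MutationEvent
setClass("MutationEvent",
  representation(type = "character", position = "integer",
                 payload = "character"),
  prototype(type = "SUBSTITUTION", position = integer(), payload = ""))

setValidity("MutationEvent", function(object) {
  if (!(object@type %in% EVENT_TYPES))
    return(sprintf("unknown event type '%s'", object@type))
  TRUE
})

#' Evolutionary dictionary of allowed mutations
#'
#' Holds the per-generation event-type rates, the amino acid substitution
#' model as a 20x20 row-stochastic replacement matrix with zero diagonal,
#' and the length law for multi-residue indels.
#'
#' @slot eventRates named numeric, probabilities over `EVENT_TYPES`, sum 1.
#' @slot substitutionMatrix 20x20 row-stochastic matrix; `[a, b]` is the
#'   probability that residue `a` is replaced by `b`; diagonal is zero.
#' @slot indelRange integer length-2, inclusive bounds of the (uniform)
#'   length law for `MULTI_DELETION` and `RANDOM_INSERTION`.
#' @slot minLength shortest sequence the dictionary will ever produce;
#'   events that would go below are resampled as substitutions.
#' @slot maxLength longest sequence allowed; events that would exceed it are
#'   resampled as substitutions.
#'
#' @exportClass EvolutionaryDictionary
setClass("EvolutionaryDictionary",
  representation(eventRates = "numeric", substitutionMatrix = "matrix",
                 indelRange = "integer", minLength = "integer",
                 maxLength = "integer"))

setValidity("EvolutionaryDictionary", function(object) {
  msg <- character()
  r <- object@eventRates
  if (!all(names(r) %in% EVENT_TYPES))
    msg <- c(msg, "eventRates has unknown event types")
  if (any(r < 0) || abs(sum(r) - 1) > 1e-9)
    msg <- c(msg, "eventRates must be non-negative and sum to 1 (tol 1e-9)")
  m <- object@substitutionMatrix
  if (!all(dim(m) == c(20L, 20L)) ||
      !identical(rownames(m), AA_ALPHABET) ||
      !identical(colnames(m), AA_ALPHABET)) {
    msg <- c(msg, "substitutionMatrix must be 20x20 with amino acid dimnames")
  } else {
    if (any(abs(rowSums(m) - 1) > 1e-9))
      msg <- c(msg, "substitutionMatrix rows must sum to 1 (tol 1e-9)")
    if (any(diag(m) != 0))
      msg <- c(msg, "substitutionMatrix diagonal must be zero (no self-replacement)")
    if (any(m < 0))
      msg <- c(msg, "substitutionMatrix entries must be non-negative")
  }
  if (length(object@indelRange) != 2L || object@indelRange[1] < 1L ||
      object@indelRange[2] < object@indelRange[1])
    msg <- c(msg, "indelRange must be two increasing positive integers")
  if (object@minLength < 1L || object@maxLength < object@minLength)
    msg <- c(msg, "need 1 <= minLength <= maxLength")
  if (length(msg)) msg else TRUE
})

#' Predicted structure of one or two chains
#'
#' Backbone coordinates (N, CA, C, CB; Angstrom) with per-residue and global
#' confidences. Confidences are held on the [0, 1] scale internally; the
#' 0-100 scale appears only at PDB I/O boundaries (B-factor column).
#' Glycine has no side chain: its CB slot carries the CA position.
#'
#' @slot residues one-letter code per residue (both chains concatenated).
#' @slot chain chain label per residue (1 or 2 distinct labels).
#' @slot n,ca,c,cb L x 3 coordinate matrices.
#' @slot plddt per-residue confidence in [0, 1].
#' @slot ptm global confidence in [0, 1].
#'
#' @exportClass StructureModel
setClass("StructureModel",
  representation(residues = "character", chain = "character",
                 n = "matrix", ca = "matrix", c = "matrix", cb = "matrix",
                 plddt = "numeric", ptm = "numeric"))

setValidity("StructureModel", function(object) {
  msg <- character()
  L <- length(object@residues)
  if (length(object@chain) != L)
    msg <- c(msg, "chain labels must match residue count")
  if (length(unique(object@chain)) > 2L)
    msg <- c(msg, "at most 2 chains supported")
  for (at in c("n", "ca", "c", "cb")) {
    co <- slot(object, at)
    if (!is.numeric(co) || nrow(co) != L || ncol(co) != 3L)
      msg <- c(msg, sprintf("%s coordinates must be an L x 3 numeric matrix", toupper(at)))
  }
  if (length(object@plddt) != L || any(object@plddt < 0 | object@plddt > 1))
    msg <- c(msg, "plddt must be per-residue in [0, 1]")
  if (length(object@ptm) != 1L || object@ptm < 0 || object@ptm > 1)
    msg <- c(msg, "ptm must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' All terms of the multiplicative fitness score
#'
#' The composite score of one individual and every factor entering it:
#' `score = plddtMean * ptm * cd * (iplddt * icd) * constr`. On the monomer
#' path the two interface terms are the identity 1.
#'
#' @slot plddtMean mean per-residue confidence of the evolving chain, [0, 1].
#' @slot ptm global confidence, [0, 1].
#' @slot cd long-range contact density, contacts per residue.
#' @slot iplddt mean confidence over interface residues (1 for monomers).
#' @slot icd inter-chain contacts per evolving-chain residue (1 for monomers).
#' @slot constr product of the logistic length-constraint factors, (0, 1].
#' @slot score the product of all terms.
#'
#' @exportClass FitnessBreakdown
setClass("FitnessBreakdown",
  representation(plddtMean = "numeric", ptm = "numeric", cd = "numeric",
                 iplddt = "numeric", icd = "numeric", constr = "numeric",
                 score = "numeric"))

setValidity("FitnessBreakdown", function(object) {
  p <- object@plddtMean * object@ptm * object@cd *
    object@iplddt * object@icd * object@constr
  if (!isTRUE(all.equal(p, object@score, tolerance = 1e-12)) &&
      p != object@score)
    return("score must equal the product of its terms")
  if (object@score < 0) return("score must be non-negative")
  TRUE
})

#' Logistic length-constraint parameters
#'
#' Each law is `P(L) = 1 - 1 / (1 + exp(C * (L0 - L)))`: strictly decreasing
#' in L, equal to 0.5 at the midpoint L0, approaching 1 for short and 0 for
#' long elements. One law penalises total chain length, one over-long helix
#' elements, and one over-long strand elements.
#'
#' @slot lengthC,lengthL0 chain-length law (defaults C = 0.2, L0 = 250).
#' @slot helixC,helixL0 helix-element law (defaults C = 0.5, L0 = 30).
#' @slot strandC,strandL0 strand-element law (defaults C = 0.5, L0 = 12).
#'
#' @exportClass ConstraintParams
setClass("ConstraintParams",
  representation(lengthC = "numeric", lengthL0 = "numeric",
                 helixC = "numeric", helixL0 = "numeric",
                 strandC = "numeric", strandL0 = "numeric"),
  prototype(lengthC = 0.2, lengthL0 = 250, helixC = 0.5, helixL0 = 30,
            strandC = 0.5, strandL0 = 12))

#' Selection mode configuration
#'
#' @slot mode `"STRONG"` (deterministic top half), `"PROPORTIONAL"`
#'   (survival probability proportional to fitness), or `"GIBBS"`
#'   (softmax with inverse temperature `beta`).
#' @slot beta inverse-temperature, >= 0; used by `GIBBS` only. `beta = 0`
#'   is neutral drift; large `beta` approaches strong selection.
#'
#' @exportClass SelectionConfig
setClass("SelectionConfig",
  representation(mode = "character", beta = "numeric"),
  prototype(mode = "PROPORTIONAL", beta = 1))

setValidity("SelectionConfig", function(object) {
  if (!(object@mode %in% c("STRONG", "PROPORTIONAL", "GIBBS")))
    return("mode must be STRONG, PROPORTIONAL or GIBBS")
  if (length(object@beta) != 1L || is.na(object@beta) || object@beta < 0)
    return("beta must be a single value >= 0")
  TRUE
})

## --- evaluator contract ----------------------------------------------------

#' Structure evaluation contract
#'
#' Virtual parent of every structure backend. A backend maps amino acid
#' sequences (plus an optional fixed binding partner) to [StructureModel]
#' objects via [evaluateStructure()]. Backends declare whether they are
#' deterministic (identical input implies bit-identical output) and whether
#' they can score several sequences per call.
#'
#' @slot deterministic logical flag of the determinism contract.
#' @slot batchCapable logical; whether the backend accepts batches.
#'
#' @exportClass StructureEvaluator
setClass("StructureEvaluator",
  representation("VIRTUAL", deterministic = "logical",
                 batchCapable = "logical"),
  prototype(deterministic = TRUE, batchCapable = TRUE))

#' Deterministic geometric surrogate backend
#'
#' A desk-scale stand-in for a neural structure predictor: a deterministic
#' function of the residue string built from sliding-window hydropathy
#' periodicity (see [surrogateEvaluator()]).
#'
#' @slot params list of surrogate constants (window, lags, logistic scales).
#'
#' @exportClass SurrogateEvaluator
setClass("SurrogateEvaluator",
  contains = "StructureEvaluator",
  representation(params = "list"))

#' Recorded-fixture backend
#'
#' Replays stored [StructureModel] objects keyed by sequence; used to prove
#' the engine is backend-agnostic and to test against hand-built models.
#'
#' @slot models named list of [StructureModel], names are residue strings.
#'
#' @exportClass FixtureEvaluator
setClass("FixtureEvaluator",
  contains = "StructureEvaluator",
  representation(models = "list"))

## --- engine-side containers ------------------------------------------------

#' Complete genealogy of selected individuals
#'
#' Every individual ever selected (plus the founders) as one node, with the
#' mutation event on the edge to its parent. A connected forest rooted at
#' the founders; survivor clones from with-replacement selection are
#' distinct nodes with an event-free edge, so the genealogy stays a tree.
#'
#' @slot nodes data.frame with columns id, parentId, generation, residues,
#'   eventType, eventPos, eventPayload, score.
#'
#' @exportClass LineageTree
setClass("LineageTree", representation(nodes = "data.frame"))

setValidity("LineageTree", function(object) {
  nd <- object@nodes
  need <- c("id", "parentId", "generation", "residues", "eventType",
            "eventPos", "eventPayload", "score")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  known <- !is.na(nd$parentId)
  if (any(known & !(nd$parentId %in% nd$id)))
    return("every non-root parentId must be a node id")
  TRUE
})

#' Full run configuration
#'
#' @slot popSize population size N (fixed throughout the run).
#' @slot founderMode `"n_random"` (N independent random sequences) or
#'   `"n_mutants_of_one"` (N single-event mutants of one random seed).
#' @slot founderLength founder sequence length.
#' @slot founderSeed optional predefined seed sequence (overrides length).
#' @slot dictionary the [EvolutionaryDictionary].
#' @slot selection the [SelectionConfig].
#' @slot constraints the [ConstraintParams].
#' @slot evaluator any [StructureEvaluator].
#' @slot partner optional fixed binding-partner [StructureModel] for dimer
#'   mode, or `NULL` for monomer runs.
#' @slot plddtStop,ptmStop stop thresholds on [0, 1]; the run halts when any
#'   selected individual reaches both (inclusive).
#' @slot maxGenerations generation budget.
#' @slot seed master seed; all randomness derives from it.
#' @slot snapshotEvery write a PDB snapshot of the best structure every this
#'   many generations (0 = never) when an output directory is given.
#'
#' @exportClass RunConfig
setClass("RunConfig",
  representation(popSize = "integer", founderMode = "character",
                 founderLength = "integer", founderSeed = "character",
                 dictionary = "EvolutionaryDictionary",
                 selection = "SelectionConfig",
                 constraints = "ConstraintParams",
                 evaluator = "StructureEvaluator",
                 partner = "ANY",
                 plddtStop = "numeric", ptmStop = "numeric",
                 maxGenerations = "integer", seed = "integer",
                 snapshotEvery = "integer"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@popSize < 2L) msg <- c(msg, "popSize must be >= 2")
  if (object@maxGenerations < 1L) msg <- c(msg, "maxGenerations must be >= 1")
  if (object@plddtStop < 0 || object@plddtStop > 1 ||
      object@ptmStop < 0 || object@ptmStop > 1)
    msg <- c(msg, "stop thresholds must be in [0, 1]")
  if (!(object@founderMode %in% c("n_random", "n_mutants_of_one")))
    msg <- c(msg, "founderMode must be n_random or n_mutants_of_one")
  if (!is.null(object@partner) && !is(object@partner, "StructureModel"))
    msg <- c(msg, "partner must be NULL or a StructureModel")
  if (length(msg)) msg else TRUE
})

#' A completed simulation
#'
#' Returned by [runSimulation()]: the final population, the lineage tree,
#' and the per-generation records of all 2N pool members.
#'
#' @slot population list of [ProteinSequence], the N survivors of the last
#'   generation.
#' @slot tree the [LineageTree].
#' @slot records data.frame with one row per pool member per generation:
#'   generation, id, parentId, event fields, every fitness term, structure
#'   descriptors (radius of gyration, H/E/C fractions), the selection
#'   multiplicity `selected_n` (with-replacement modes can pick a member
#'   more than once) and the derived `selected` flag.
#' @slot config the [RunConfig] the run was launched with.
#' @slot generations number of mutation rounds executed.
#' @slot stopId id of the first individual to satisfy the stop condition,
#'   or `NA` if the run exhausted its generation budget.
#'
#' @exportClass EvolutionRun
setClass("EvolutionRun",
  representation(population = "list", tree = "LineageTree",
                 records = "data.frame", config = "RunConfig",
                 generations = "integer", stopId = "character"))

#' Table-style summary statistics of one run
#'
#' @slot generations generations to stop (integer for a single run).
#' @slot totalMutations N x generations, exactly.
#' @slot fixedMutations mutation events on the nucleation lineage.
#' @slot fixationRate fixedMutations / totalMutations.
#' @slot meanFinalLength mean sequence length of the final population.
#' @slot mutationsPerSite fixedMutations / meanFinalLength.
#' @slot variableLength TRUE when the run allowed length-changing events
#'   beyond single indels (mutations per site is then an overestimate).
#' @slot perGeneration data.frame: generation, meanRg, fracH, fracE, fracC.
#'
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(generations = "numeric", totalMutations = "numeric",
                 fixedMutations = "numeric", fixationRate = "numeric",
                 meanFinalLength = "numeric", mutationsPerSite = "numeric",
                 variableLength = "logical", perGeneration = "data.frame"))

setValidity("SummaryStats", function(object) {
  if (object@fixationRate < 0 || object@fixationRate > 1)
    return("fixationRate must lie in [0, 1]")
  TRUE
})
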