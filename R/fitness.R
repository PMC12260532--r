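#' @describeIn ConstraintParams-class constructor with the default logistic
#'   length laws (chain C = 0.2, L0 = 250; helix C = 0.5, L0 = 30; strand
#'   C = 0.5, L0 = 12).
#' @param lengthC,lengthL0,helixC,helixL0,strandC,strandL0 law parameters.
#' @export
constraintParams <- function(lengthC = 0.2, lengthL0 = 250,
                             helixC = 0.5, helixL0 = 30,
                             strandC = 0.5, strandL0 = 12) {
  new("ConstraintParams", lengthC = lengthC, lengthL0 = lengthL0,
      helixC = helixC, helixL0 = helixL0, strandC = strandC,
      strandL0 = strandL0)
}

#' Logistic length-constraint sigmoid
#'
#' `P(L) = 1 - 1 / (1 + exp(C * (L0 - L)))`: strictly decreasing in `L`,
#' exactly 0.5 at `L = L0`, approaching 1 for short and 0 for long chains
#' or elements.
#'
#' @param L length (residues); vectorised.
#' @param C steepness.
#' @param L0 midpoint length at which the factor is 0.5.
#' @return the penalty factor in (0, 1).
#' @examples
#' constraintSigmoid(250, C = 0.2, L0 = 250)  # 0.5
#' @export
constraintSigmoid <- function(L, C, L0) 1 - 1 / (1 + exp(C * (L0 - L)))

#' Long-range contact density
#'
#' Number of unordered residue pairs (i, j) within one chain with
#' `|i - j| > 5`, CB-CB Euclidean distance strictly below 6 Angstrom, and
#' per-residue confidence strictly above 0.5 for both residues, divided by
#' the chain length. The sequence-separation filter excludes the local
#' (i, i+4)-type contacts of an alpha-helix, so the term measures tertiary
#' packing; the confidence filter ignores contacts in unreliable regions.
#'
#' @param model a [StructureModel].
#' @param chain chain label; defaults to the first chain.
#' @param distCutoff,sepCutoff,plddtCutoff filter parameters.
#' @return contacts per residue (>= 0).
#' @export
contactDensity <- function(model, chain = NULL, distCutoff = 6.0,
                           sepCutoff = 5L, plddtCutoff = 0.5) {
  if (is.null(chain)) chain <- model@chain[1]
  sel <- model@chain == chain
  cb <- model@cb[sel, , drop = FALSE]
  pl <- model@plddt[sel]
  l <- nrow(cb)
  if (l == 0L) stop("empty chain")
  if (l <= sepCutoff + 1L) return(0)
  d <- stats::dist(cb)              # pairs (i, j), i < j, column-major
  ij <- .pair_index(l)
  keep <- (ij$j - ij$i) > sepCutoff & d < distCutoff &
    pl[ij$i] > plddtCutoff & pl[ij$j] > plddtCutoff
  sum(keep) / l
}

## row/column indices of the dist() pair vector, cached per chain length
.pair_cache <- new.env(parent = emptyenv())
.pair_index <- function(l) {
  key <- as.character(l)
  if (!exists(key, envir = .pair_cache, inherits = FALSE)) {
    ## dist() orders pairs (i < j) by the first index
    ii <- unlist(lapply(seq_len(l - 1L), function(k) rep.int(k, l - k)))
    jj <- unlist(lapply(seq_len(l - 1L), function(k) (k + 1L):l))
    assign(key, list(i = ii, j = jj), envir = .pair_cache)
  }
  get(key, envir = .pair_cache)
}

#' Interface confidence and inter-chain contact density
#'
#' For a two-chain model: inter-chain CB pairs closer than 6 Angstrom with
#' both residues above the confidence cutoff qualify as interface contacts
#' (no sequence-separation filter across chains). The interface residue set
#' contains every residue, on either chain, that takes part in at least one
#' qualifying pair. `iplddt` is the mean confidence over that set (0 when
#' the chains do not touch, which drives a dimer-mode score to zero), and
#' `icd` is the number of qualifying pairs divided by the evolving chain's
#' length.
#'
#' @param model a two-chain [StructureModel].
#' @param evolvingChain label of the evolving chain (default `"A"`).
#' @param distCutoff,plddtCutoff filter parameters.
#' @return named list with `iplddt` and `icd`.
#' @export
interfaceTerms <- function(model, evolvingChain = "A", distCutoff = 6.0,
                           plddtCutoff = 0.5) {
  ch <- chains(model)
  if (length(ch) != 2L)
    stop("interfaceTerms needs a two-chain model; monomers use the identity terms")
  if (!(evolvingChain %in% ch))
    stop(sprintf("no chain '%s' in model", evolvingChain))
  a <- model@chain == evolvingChain
  b <- !a
  da <- model@cb[a, , drop = FALSE]
  db <- model@cb[b, , drop = FALSE]
  cross <- sqrt(outer(rowSums(da^2), rowSums(db^2), "+") -
                2 * tcrossprod(da, db))
  ok <- cross < distCutoff &
    outer(model@plddt[a] > plddtCutoff, model@plddt[b] > plddtCutoff, "&")
  npairs <- sum(ok)
  if (npairs == 0L) return(list(iplddt = 0, icd = 0))
  ia <- which(a)[unique(which(ok, arr.ind = TRUE)[, 1])]
  ib <- which(b)[unique(which(ok, arr.ind = TRUE)[, 2])]
  list(iplddt = mean(model@plddt[c(ia, ib)]), icd = npairs / sum(a))
}

#' Length-constraint factor
#'
#' The product of the chain-length law evaluated at the sequence length and
#' the helix / strand element laws evaluated at the length of every maximal
#' H and E element. A chain (or element) at its midpoint length L0
#' multiplies the score by exactly 0.5; short chains and elements leave the
#' score essentially unchanged.
#'
#' @param seqLen chain length in residues.
#' @param ss a [SecondaryStructureAnnotation] (or label vector) for the
#'   chain; `NULL` applies the chain-length law only.
#' @param params a [ConstraintParams].
#' @return the constraint factor in (0, 1].
#' @export
constraintFactor <- function(seqLen, ss = NULL,
                             params = constraintParams()) {
  if (is(ss, "SecondaryStructureAnnotation")) {
    if (length(ss@labels) != seqLen)
      stop("annotation length does not match seqLen")
    el <- ss@elements
  } else if (is.character(ss)) {
    if (length(ss) != seqLen)
      stop("annotation length does not match seqLen")
    el <- ssElements(ss)
  } else {
    el <- data.frame(label = character(0), length = integer(0))
  }
  f <- constraintSigmoid(seqLen, params@lengthC, params@lengthL0)
  h <- el$length[el$label == "H"]
  e <- el$length[el$label == "E"]
  if (length(h))
    f <- f * prod(constraintSigmoid(h, params@helixC, params@helixL0))
  if (length(e))
    f <- f * prod(constraintSigmoid(e, params@strandC, params@strandL0))
  f
}

## all fitness terms as a named numeric vector (engine hot path; the S4
## FitnessBreakdown wrapper is fitnessScore below)
.fitness_terms <- function(res, model, params, evolvingChain = "A",
                           labs = NULL) {
  sel <- model@chain == evolvingChain
  if (!any(sel)) {
    evolvingChain <- model@chain[1]
    sel <- model@chain == evolvingChain
  }
  if (sum(sel) != nchar(res))
    stop(sprintf("model chain %s has %d residues but the sequence has %d",
                 evolvingChain, sum(sel), nchar(res)))
  if (is.null(labs))
    labs <- .assign_ss_chain(model@ca[sel, , drop = FALSE])
  plddt_mean <- mean(model@plddt[sel])
  cd <- contactDensity(model, chain = evolvingChain)
  if (length(unique(model@chain)) == 2L) {
    it <- interfaceTerms(model, evolvingChain = evolvingChain)
  } else {
    it <- list(iplddt = 1, icd = 1)
  }
  constr <- constraintFactor(sum(sel), labs, params)
  c(plddt_mean = plddt_mean, ptm = model@ptm, cd = cd,
    iplddt = it$iplddt, icd = it$icd, constr = constr,
    score = plddt_mean * model@ptm * cd * it$iplddt * it$icd * constr)
}

#' Composite multiplicative fitness score
#'
#' `score = plddt_mean * ptm * cd * (iplddt * icd) * constr`. The mean
#' confidence, contact density, and constraint factor are computed on the
#' evolving chain; for monomers the two interface terms are the identity 1,
#' for two-chain models they come from [interfaceTerms()]. Because the
#' score is a product, any vanishing term (no long-range contacts, chains
#' that do not touch) zeroes the whole score.
#'
#' @param seq [ProteinSequence] or residue string of the evolving chain.
#' @param model the [StructureModel] for that sequence (one chain, or two
#'   with the evolving chain labelled `evolvingChain`).
#' @param params a [ConstraintParams].
#' @param evolvingChain label of the evolving chain.
#' @param ssAssigner function mapping a [StructureModel] to a
#'   [SecondaryStructureAnnotation]; pluggable, defaults to the geometric
#'   assigner [assignSecondaryStructure()].
#' @param ss optional precomputed annotation (whole model), to avoid
#'   assigning twice when the caller already has it.
#' @return a [FitnessBreakdown].
#' @export
fitnessScore <- function(seq, model, params = constraintParams(),
                         evolvingChain = "A",
                         ssAssigner = assignSecondaryStructure, ss = NULL) {
  res <- residues(seq)
  labs <- NULL
  if (!is.null(ss)) {
    sel <- model@chain == evolvingChain
    if (!any(sel)) sel <- model@chain == model@chain[1]
    labs <- ss@labels[sel]
  } else if (!identical(ssAssigner, assignSecondaryStructure)) {
    ss <- ssAssigner(model)
    sel <- model@chain == evolvingChain
    if (!any(sel)) sel <- model@chain == model@chain[1]
    labs <- ss@labels[sel]
  }
  v <- .fitness_terms(res, model, params, evolvingChain, labs)
  new("FitnessBreakdown", plddtMean = v[["plddt_mean"]], ptm = v[["ptm"]],
      cd = v[["cd"]], iplddt = v[["iplddt"]], icd = v[["icd"]],
      constr = v[["constr"]], score = v[["score"]])
}

#' Score a directory of PDB files
#'
#' Reads every `*.pdb` file, scores it against the given constraint
#' parameters, and returns one row per file with all fitness terms. Used by
#' the scoring command-line subcommand.
#'
#' @param dir directory containing PDB files.
#' @param params a [ConstraintParams].
#' @param evolvingChain chain scored as the evolving protein.
#' @return data.frame with columns id, plddt_mean, ptm, cd, iplddt, icd,
#'   constr, score.
#' @export
scoreStructureDir <- function(dir, params = constraintParams(),
                              evolvingChain = "A") {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (!length(files)) stop("no PDB files in ", dir)
  rows <- lapply(files, function(f) {
    model <- readStructure(f)
    sel <- model@chain == evolvingChain
    if (!any(sel)) sel <- model@chain == model@chain[1]
    seq <- paste(model@residues[sel], collapse = "")
    fb <- fitnessScore(seq, model, params, evolvingChain = evolvingChain)
    cbind(data.frame(id = sub("\\.pdb$", "", basename(f))),
          as.data.frame(fb))
  })
  do.call(rbind, rows)
}
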