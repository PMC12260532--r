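#' Per-residue secondary structure labels with derived elements
#'
#' @slot labels per-residue label in `{H, E, C}`.
#' @slot elements data.frame of maximal same-label runs: label, start, end,
#'   length. Elements tile the sequence; lengths sum to the chain length.
#'
#' @exportClass SecondaryStructureAnnotation
setClass("SecondaryStructureAnnotation",
  representation(labels = "character", elements = "data.frame"))

setValidity("SecondaryStructureAnnotation", function(object) {
  if (sum(object@elements$length) != length(object@labels))
    return("element lengths must sum to the chain length")
  TRUE
})

#' @describeIn SecondaryStructureAnnotation-class maximal same-label runs
#'   from a label vector.
#' @param labels character vector over `{H, E, C}`.
#' @export
ssElements <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(label = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

.ss_annotation <- function(labels)
  new("SecondaryStructureAnnotation", labels = labels,
      elements = ssElements(labels))

## geometric thresholds of the default CA-trace assigner
.ss_geom <- list(
  helixD13   = c(4.2, 6.2),   # CA(i)-CA(i+3) distance window (Angstrom)
  helixTau   = c(20, 100),    # CA virtual torsion window (degrees)
  strandD02  = 6.0,           # CA(i)-CA(i+2) distance floor (Angstrom)
  strandTau  = 130,           # |torsion| floor (degrees)
  minVotes   = 2,             # qualifying quadruplets covering a residue
  minHelixRun  = 4,
  minStrandRun = 3)

#' Assign secondary structure from backbone geometry
#'
#' The default assigner classifies each overlapping CA quadruplet by its
#' virtual torsion angle and CA(i)-CA(i+3) / CA(i)-CA(i+2) distances
#' (DSSP-style thresholds on the virtual-bond representation): compact
#' positive-torsion quadruplets vote helix, extended near-trans quadruplets
#' vote strand. A residue takes the label it receives at least two votes
#' for, short runs are demoted to coil, and chains under 4 residues are all
#' coil. Two-chain models are assigned per chain. The assigner is pluggable:
#' [fitnessScore()] accepts any function with this signature.
#'
#' @param model a [StructureModel].
#' @return a [SecondaryStructureAnnotation] covering all residues.
#' @export
assignSecondaryStructure <- function(model) {
  labs <- unlist(lapply(unique(model@chain), function(ch)
    .assign_ss_chain(atomCoords(model, "CA", chain = ch))))
  .ss_annotation(unname(labs))
}

.assign_ss_chain <- function(ca) {
  L <- nrow(ca)
  if (L < 4L) return(rep("C", L))
  g <- .ss_geom
  tau <- bio3d::torsion.xyz(as.vector(t(ca)), atm.inc = 1)
  nq <- L - 3L
  tau <- tau[seq_len(nq) + 1L]   # torsion.xyz aligns to the 2nd atom
  d13 <- sqrt(rowSums((ca[seq_len(nq), , drop = FALSE] -
                       ca[seq_len(nq) + 3L, , drop = FALSE])^2))
  d02 <- sqrt(rowSums((ca[seq_len(L - 2L), , drop = FALSE] -
                       ca[seq_len(L - 2L) + 2L, , drop = FALSE])^2))
  hq <- !is.na(tau) & tau >= g$helixTau[1] & tau <= g$helixTau[2] &
        d13 >= g$helixD13[1] & d13 <= g$helixD13[2]
  eq <- !is.na(tau) & abs(tau) >= g$strandTau &
        d02[seq_len(nq)] > g$strandD02 & d02[seq_len(nq) + 1L] > g$strandD02
  hv <- ev <- integer(L)
  for (i in which(hq)) hv[i:(i + 3L)] <- hv[i:(i + 3L)] + 1L
  for (i in which(eq)) ev[i:(i + 3L)] <- ev[i:(i + 3L)] + 1L
  lab <- rep("C", L)
  lab[ev >= g$minVotes] <- "E"
  lab[hv >= g$minVotes & hv >= ev] <- "H"
  r <- rle(lab)
  drop <- (r$values == "H" & r$lengths < g$minHelixRun) |
          (r$values == "E" & r$lengths < g$minStrandRun)
  r$values[drop] <- "C"
  inverse.rle(r)
}
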