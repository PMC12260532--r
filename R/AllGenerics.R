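#' Evaluate sequences with a structure backend
#'
#' Maps one or more amino acid sequences to [StructureModel] objects. With a
#' `partner` model, backends that support dimer mode return two-chain models
#' in which the partner chain is fixed and the evolving chain varies.
#'
#' @param evaluator a [StructureEvaluator].
#' @param sequences character vector of residue strings, or a list of
#'   [ProteinSequence] objects.
#' @param partner optional fixed-partner [StructureModel] (single chain).
#' @return list of [StructureModel], one per input sequence, input order.
#' @export
setGeneric("evaluateStructure",
           function(evaluator, sequences, partner = NULL)
             standardGeneric("evaluateStructure"))

#' @rdname ProteinSequence-class
#' @param object,x a `ProteinSequence` (or, for `residues`, any object with
#'   a residue string).
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("generation", function(x) standardGeneric("generation"))

#' @rdname ProteinSequence-class
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))

#' @rdname StructureModel-class
#' @export
setGeneric("plddt", function(x) standardGeneric("plddt"))

#' @rdname StructureModel-class
#' @export
setGeneric("ptm", function(x) standardGeneric("ptm"))

#' @rdname StructureModel-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname FitnessBreakdown-class
#' @param x a `FitnessBreakdown`.
#' @export
setGeneric("fitness", function(x) standardGeneric("fitness"))

#' @rdname LineageTree-class
#' @param x a `LineageTree`.
#' @export
setGeneric("lineageNodes", function(x) standardGeneric("lineageNodes"))
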