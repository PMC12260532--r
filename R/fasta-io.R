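#' Read / write populations as FASTA
#'
#' Thin wrappers over Biostrings. `readFastaPopulation` turns each record
#' into a [ProteinSequence] (id from the header, generation 0); sequences
#' may be wrapped at any column width. `writeFastaPopulation` writes
#' 60-column wrapped records named by sequence id.
#'
#' @param path FASTA file path.
#' @param population list of [ProteinSequence].
#' @return `readFastaPopulation`: list of [ProteinSequence];
#'   `writeFastaPopulation`: `path`, invisibly.
#' @export
readFastaPopulation <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  lapply(seq_along(aa), function(i)
    proteinSequence(as.character(aa[[i]]), id = ids[i]))
}

#' @rdname readFastaPopulation
#' @export
writeFastaPopulation <- function(population, path) {
  aa <- Biostrings::AAStringSet(vapply(population, residues, character(1)))
  names(aa) <- vapply(population, seqId, character(1))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
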