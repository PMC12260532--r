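#' Read / write structure models as PDB
#'
#' The B-factor column carries per-residue confidence on the conventional
#' 0-100 scale; internally the model always holds [0, 1] (files whose
#' B-factors never exceed 1 are taken to be on the fractional scale
#' already). The global confidence is kept in a `REMARK 99 PTM` header
#' line. Glycine is written without a CB atom; on reading, its CA position
#' is used as the CB proxy.
#'
#' @param model a [StructureModel].
#' @param path PDB file path.
#' @return `readStructure`: a [StructureModel]; `writeStructure`: `path`,
#'   invisibly.
#' @export
writeStructure <- function(model, path) {
  L <- length(model@residues)
  res3 <- bio3d::aa123(model@residues)
  ## residue numbering restarts per chain
  resno <- stats::ave(seq_len(L), model@chain, FUN = seq_along)
  elety <- character(0); xyz <- numeric(0)
  a_resno <- integer(0); a_resid <- character(0)
  a_chain <- character(0); a_b <- numeric(0)
  for (i in seq_len(L)) {
    ats <- c("N", "CA", "C", if (model@residues[i] != "G") "CB")
    for (at in ats) {
      elety <- c(elety, at)
      xyz <- c(xyz, slot(model, tolower(at))[i, ])
      a_resno <- c(a_resno, resno[i])
      a_resid <- c(a_resid, res3[i])
      a_chain <- c(a_chain, model@chain[i])
      a_b <- c(a_b, round(model@plddt[i] * 100, 2))
    }
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = a_resno, resid = a_resid,
                   eleno = seq_along(elety), elety = elety, chain = a_chain,
                   o = rep(1, length(elety)), b = a_b)
  body <- readLines(path)
  writeLines(c(sprintf("REMARK  99 PTM %.4f", model@ptm), body), path)
  invisible(path)
}

#' @rdname writeStructure
#' @export
readStructure <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  ukey <- unique(key)
  L <- length(ukey)
  res <- character(L); chain <- character(L)
  co <- lapply(c(n = "N", ca = "CA", c = "C", cb = "CB"),
               function(x) matrix(NA_real_, L, 3))
  plddt <- numeric(L)
  for (i in seq_len(L)) {
    rows <- at[key == ukey[i], , drop = FALSE]
    aa3 <- rows$resid[1]
    aa1 <- suppressWarnings(bio3d::aa321(aa3))
    if (is.na(aa1) || !(aa1 %in% AA_ALPHABET))
      stop(sprintf("unknown residue code '%s' at %s %s", aa3,
                   rows$chain[1], rows$resno[1]))
    res[i] <- aa1
    chain[i] <- rows$chain[1]
    for (atm in c("N", "CA", "C")) {
      j <- match(atm, rows$elety)
      if (is.na(j))
        stop(sprintf("missing backbone atom %s for residue %s %s%s", atm,
                     aa3, rows$chain[1], rows$resno[1]))
      co[[tolower(atm)]][i, ] <- as.numeric(rows[j, c("x", "y", "z")])
    }
    j <- match("CB", rows$elety)
    if (is.na(j)) {
      if (aa1 != "G")
        stop(sprintf("missing backbone atom CB for residue %s %s%s", aa3,
                     rows$chain[1], rows$resno[1]))
      co$cb[i, ] <- co$ca[i, ]
    } else {
      co$cb[i, ] <- as.numeric(rows[j, c("x", "y", "z")])
    }
    plddt[i] <- rows$b[match("CA", rows$elety)]
  }
  if (any(plddt > 1)) plddt <- plddt / 100
  plddt <- pmin(pmax(plddt, 0), 1)
  ptm <- mean(plddt)
  hdr <- grep("^REMARK  99 PTM ", readLines(path, n = 50L), value = TRUE)
  if (length(hdr))
    ptm <- min(max(as.numeric(sub("^REMARK  99 PTM ", "", hdr[1])), 0), 1)
  new("StructureModel", residues = res, chain = chain,
      n = co$n, ca = co$ca, c = co$c, cb = co$cb,
      plddt = plddt, ptm = ptm)
}
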