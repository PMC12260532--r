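test_that("dictionary validity enforces stochasticity and no self-replacement", {
  d <- evolutionaryDictionary()
  expect_true(validObject(d))
  expect_equal(sum(d@eventRates), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(d@substitutionMatrix) - 1) < 1e-9))
  expect_true(all(diag(d@substitutionMatrix) == 0))
  expect_error(evolutionaryDictionary(eventRates = c(SUBSTITUTION = 0.5)),
               "sum to 1")
})

test_that("a degenerate rate table always yields that event", {
  d <- evolutionaryDictionary(c(SUBSTITUTION = 1))
  set.seed(1)
  evs <- replicate(50, drawMutation("MKVILSEQWENCETRAPID", d)@type)
  expect_true(all(evs == "SUBSTITUTION"))
})

test_that("event-type frequencies converge to the rate table (3-sigma binomial)", {
  rates <- c(SUBSTITUTION = 0.9, SINGLE_INSERTION = 0.05,
             SINGLE_DELETION = 0.05)
  d <- evolutionaryDictionary(rates)
  seq <- paste(rep("MKVILSEQW", 4), collapse = "")   # far from length guards
  n <- 1e5
  set.seed(42)
  types <- character(n)
  for (i in seq_len(n)) types[i] <- drawMutation(seq, d)@type
  for (ty in names(rates)) {
    p <- rates[[ty]]
    expect_lt(abs(sum(types == ty) / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("deletions at the length floor are coerced to substitutions", {
  d <- evolutionaryDictionary(c(SINGLE_DELETION = 1), minLength = 10L)
  seq <- strrep("A", 10)   # exactly the floor
  set.seed(7)
  ev <- drawMutation(seq, d)
  expect_identical(ev@type, "SUBSTITUTION")
  d2 <- evolutionaryDictionary(c(MULTI_DELETION = 1), minLength = 10L,
                               indelRange = c(2L, 10L))
  set.seed(8)
  expect_identical(drawMutation(strrep("A", 11), d2)@type, "SUBSTITUTION")
})

test_that("duplications beyond the length ceiling are coerced to substitutions", {
  d <- evolutionaryDictionary(c(COMPLETE_DUPLICATION = 1), maxLength = 30L)
  set.seed(3)
  expect_identical(drawMutation(strrep("AC", 10), d)@type, "SUBSTITUTION")
})

test_that("mutating an empty sequence errors", {
  expect_error(drawMutation("", evolutionaryDictionary()), "empty")
})

test_that("applyMutation matches the event algebra on worked examples", {
  cp <- new("MutationEvent", type = "CIRCULAR_PERMUTATION", position = 2L,
            payload = "")
  expect_identical(applyMutation("ABCDEF", cp), "CDEFAB")
  dup <- new("MutationEvent", type = "COMPLETE_DUPLICATION",
             position = integer(), payload = "")
  expect_identical(applyMutation("MKV", dup), "MKVMKV")
  sub <- new("MutationEvent", type = "SUBSTITUTION", position = 2L,
             payload = "A")
  expect_identical(applyMutation("MKVW", sub), "MAVW")
  pd <- new("MutationEvent", type = "PARTIAL_DUPLICATION",
            position = c(2L, 3L), payload = "")
  expect_identical(applyMutation("MKVW", pd), "MKVKVW")
  md <- new("MutationEvent", type = "MULTI_DELETION", position = c(2L, 4L),
            payload = "")
  expect_identical(applyMutation("MKVWY", md), "MY")
  expect_error(applyMutation("MKV", new("MutationEvent",
    type = "SUBSTITUTION", position = 9L, payload = "A")), "out of range")
})

test_that("length deltas match the event algebra over random events", {
  d <- evolutionaryDictionary()
  set.seed(11)
  seq <- randomResidues(60)
  for (i in 1:10000) {
    ev <- drawMutation(seq, d)
    out <- applyMutation(seq, ev)
    L <- nchar(seq)
    expected <- switch(ev@type,
      SUBSTITUTION = L, CIRCULAR_PERMUTATION = L,
      SINGLE_INSERTION = L + 1L, SINGLE_DELETION = L - 1L,
      MULTI_DELETION = L - (ev@position[2] - ev@position[1] + 1L),
      RANDOM_INSERTION = L + nchar(ev@payload),
      PARTIAL_DUPLICATION = L + (ev@position[2] - ev@position[1] + 1L),
      COMPLETE_DUPLICATION = 2L * L)
    expect_identical(nchar(out), expected)
    seq <- if (nchar(out) <= 120) out else randomResidues(60)
  }
})

test_that("circular permutation preserves the residue multiset and fragment order", {
  set.seed(5)
  for (i in 1:50) {
    s <- randomResidues(30)
    cut <- sample(29, 1)
    out <- applyMutation(s, new("MutationEvent",
      type = "CIRCULAR_PERMUTATION", position = as.integer(cut),
      payload = ""))
    # string-rotation oracle
    expect_identical(out, paste0(substr(s, cut + 1, 30), substr(s, 1, cut)))
    expect_identical(sort(strsplit(out, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
})

test_that("matrix-derived substitutions follow the row distribution (chi-square)", {
  set.seed(21)
  raw <- matrix(runif(400, 0.1, 1), 20, 20,
                dimnames = list(AA, AA))
  d <- evolutionaryDictionary(c(SUBSTITUTION = 1), substitution = "matrix",
                              matrix = raw)
  seq <- strrep("L", 20)       # every draw replaces an L
  n <- 1e5
  set.seed(22)
  repl <- character(n)
  for (i in seq_len(n)) repl[i] <- drawMutation(seq, d)@payload
  expect_false(any(repl == "L"))   # never the original residue
  obs <- table(factor(repl, levels = AA))
  p <- d@substitutionMatrix["L", ]
  keep <- p > 0
  gof <- suppressWarnings(chisq.test(obs[keep], p = p[keep]))
  expect_gt(gof$p.value, 0.001)
})

test_that("founder construction respects mode, length and determinism", {
  set.seed(1)
  f <- makeFounders("n_random", length = 24L, n = 100L)
  expect_length(f, 100)
  expect_true(all(vapply(f, nchar, integer(1)) == 24L))
  expect_true(all(vapply(f, generation, integer(1)) == 0L))

  dsub <- evolutionaryDictionary(c(SUBSTITUTION = 1))
  set.seed(2)
  seed_seq <- randomResidues(24)
  f2 <- makeFounders("n_mutants_of_one", length = 24L, n = 20L, dict = dsub,
                     seedSequence = seed_seq)
  hd <- vapply(f2, function(x) {
    a <- strsplit(residues(x), "")[[1]]
    b <- strsplit(seed_seq, "")[[1]]
    sum(a != b)
  }, integer(1))
  expect_true(all(hd == 1L))

  set.seed(99); a <- makeFounders("n_random", 24L, 10L)
  set.seed(99); b <- makeFounders("n_random", 24L, 10L)
  expect_identical(vapply(a, residues, character(1)),
                   vapply(b, residues, character(1)))
  expect_error(makeFounders("n_random", 24L, n = 1L), "at least 2")
})

test_that("dictionaries round-trip through YAML/JSON and matrix tables through text", {
  d <- evolutionaryDictionary(substitution = "frequency",
    targetFreqs = setNames(runif(20, 0.5, 2), AA))
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    writeDictionary(d, f)
    d2 <- readDictionary(f)
    expect_equal(d2@eventRates, d@eventRates, tolerance = 1e-9)
    expect_equal(d2@substitutionMatrix, d@substitutionMatrix,
                 tolerance = 1e-9)
    expect_identical(d2@indelRange, d@indelRange)
  }
  tab <- tempfile(fileext = ".txt")
  m <- matrix(runif(400, 0.1, 1), 20, 20, dimnames = list(AA, AA))
  write.table(m, tab, quote = FALSE)
  m2 <- readSubstitutionMatrix(tab)
  expect_true(all(abs(rowSums(m2) - 1) < 1e-12))
  expect_true(all(diag(m2) == 0))
})

test_that("FASTA populations round-trip through Biostrings", {
  set.seed(4)
  pop <- makeFounders("n_random", 24L, 5L)
  f <- tempfile(fileext = ".fasta")
  writeFastaPopulation(pop, f)
  pop2 <- readFastaPopulation(f)
  expect_identical(vapply(pop2, residues, character(1)),
                   vapply(pop, residues, character(1)))
  expect_identical(vapply(pop2, seqId, character(1)),
                   vapply(pop, seqId, character(1)))
})
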