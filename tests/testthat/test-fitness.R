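test_that("constraint sigmoids are decreasing, half at L0, and symmetric", {
  p <- constraintParams()
  laws <- list(c(p@lengthC, p@lengthL0), c(p@helixC, p@helixL0),
               c(p@strandC, p@strandL0))
  for (cl in laws) {
    C <- cl[1]; L0 <- cl[2]
    expect_identical(constraintSigmoid(L0, C, L0), 0.5)
    grid <- seq(1, 2 * L0, by = 1)
    expect_true(all(diff(constraintSigmoid(grid, C, L0)) <= 0))
    # strictly decreasing wherever the law has not underflowed
    near <- seq(max(1, L0 - 40), L0 + 40, by = 1)
    expect_true(all(diff(constraintSigmoid(near, C, L0)) < 0))
    x <- seq(0, L0 - 1, by = 1)
    expect_equal(constraintSigmoid(L0 - x, C, L0) +
                 constraintSigmoid(L0 + x, C, L0),
                 rep(1, length(x)), tolerance = 1e-12)
  }
})

test_that("constraint factor matches the worked sigmoid values", {
  # chain at the midpoint length, no structured elements
  expect_equal(constraintFactor(250, rep("C", 250)), 0.5)
  # short chain: saturated to 1 within machine precision
  expect_equal(constraintFactor(50, rep("C", 50)), 1, tolerance = 1e-15)
  # one 36-residue helix element: direct evaluation of the helix law
  labs <- c(rep("C", 2), rep("H", 36), rep("C", 2))
  expect_equal(constraintFactor(40, labs),
               constraintSigmoid(40, 0.2, 250) * (1 - 1 / (1 + exp(-3))),
               tolerance = 1e-12)
  expect_equal(1 - 1 / (1 + exp(-3)), 0.04742587, tolerance = 1e-7)
  # multiple elements multiply
  labs2 <- c(rep("H", 10), rep("C", 3), rep("E", 5), rep("C", 2))
  expect_equal(constraintFactor(20, labs2),
               constraintSigmoid(20, 0.2, 250) *
               constraintSigmoid(10, 0.5, 30) *
               constraintSigmoid(5, 0.5, 12), tolerance = 1e-12)
})

test_that("contact density honours the separation and confidence filters", {
  # any chain of <= 6 residues has no eligible pair
  m <- model_from_ca(matrix(0, 6, 3) + ideal_helix_ca(6))
  expect_identical(contactDensity(m), 0)
  # low confidence kills all contacts regardless of geometry
  ca <- matrix(rnorm(120, sd = 2), 40, 3)
  m2 <- model_from_ca(ca, plddt = rep(0.4, 40))
  expect_identical(contactDensity(m2), 0)
  # the 0.5 cutoff is exclusive
  m3 <- model_from_ca(ca, plddt = rep(0.5, 40))
  expect_identical(contactDensity(m3), 0)
})

test_that("contact density equals the exhaustive pairwise oracle", {
  # a 40-residue hairpin: strand out, turn, strand back
  out <- cbind(seq_len(18) * 3.3, 0, 0)
  turn <- cbind(18 * 3.3 + c(2, 3, 3, 2), 2.5, c(0, 1, 3, 4))
  back <- cbind(rev(seq_len(18)) * 3.3, 0.5, 4.8)
  ca <- rbind(out, turn, back)
  m <- model_from_ca(ca, plddt = rep(0.9, 40))
  expect_gt(contactDensity(m), 0)
  expect_equal(contactDensity(m), cd_oracle(m@cb, m@plddt))
  # 200 random fixtures of length <= 80
  set.seed(77)
  for (i in 1:200) {
    n <- sample(10:80, 1)
    m <- random_model(n)
    expect_equal(contactDensity(m), cd_oracle(m@cb, m@plddt))
  }
})

test_that("interface terms match the inter-chain oracle and edge rules", {
  # chains farther than 6 A apart everywhere: empty interface
  ca1 <- ideal_helix_ca(12)
  ca2 <- sweep(ideal_helix_ca(12), 2, c(50, 0, 0), "+")
  m <- model_from_ca(rbind(ca1, ca2), plddt = rep(0.9, 24),
                     chain = rep(c("A", "B"), each = 12))
  it <- interfaceTerms(m)
  expect_identical(it$iplddt, 0)
  expect_identical(it$icd, 0)

  # a single qualifying pair over an evolving chain of 25: icd = 0.04
  ca1 <- cbind(seq_len(25) * 10, 0, 0)
  ca2 <- cbind(seq_len(5) * 10, 100, 0)   # chain B far away in y ...
  ca2[3, ] <- ca1[7, ] + c(0, 4, 0)       # ... except one CB within 6 A
  m2 <- model_from_ca(rbind(ca1, ca2), plddt = rep(0.8, 30),
                      chain = rep(c("A", "B"), c(25, 5)))
  it2 <- interfaceTerms(m2)
  expect_equal(it2$icd, 1 / 25)
  expect_equal(it2$iplddt, 0.8)

  # random two-chain fixtures vs the exhaustive oracle
  set.seed(13)
  for (i in 1:50) {
    na <- sample(8:30, 1); nb <- sample(8:30, 1)
    ca <- rbind(matrix(rnorm(3 * na, sd = 6), na, 3),
                matrix(rnorm(3 * nb, sd = 6), nb, 3))
    m3 <- model_from_ca(ca, plddt = runif(na + nb),
                        chain = rep(c("A", "B"), c(na, nb)))
    orc <- interface_oracle(m3)
    got <- interfaceTerms(m3)
    expect_equal(got$icd, orc$icd)
    expect_equal(got$iplddt, orc$iplddt)
  }
  expect_error(interfaceTerms(model_from_ca(ideal_helix_ca(10))),
               "two-chain")
})

test_that("the geometric assigner recovers ideal elements and leaves coil alone", {
  m <- model_from_ca(ideal_helix_ca(20))
  expect_gte(sum(assignSecondaryStructure(m)@labels == "H"), 18)
  ms <- model_from_ca(ideal_strand_ca(15))
  expect_gte(mean(assignSecondaryStructure(ms)@labels == "E"), 0.8)
  set.seed(31)
  fracC <- replicate(20, {
    mc <- model_from_ca(coil_ca(40))
    mean(assignSecondaryStructure(mc)@labels == "C")
  })
  expect_gte(mean(fracC), 0.8)
  m3 <- model_from_ca(matrix(rnorm(9), 3, 3))
  expect_identical(assignSecondaryStructure(m3)@labels, c("C", "C", "C"))
})

test_that("annotation elements tile the chain", {
  set.seed(41)
  for (i in 1:20) {
    m <- model_from_ca(rbind(ideal_helix_ca(sample(5:15, 1)),
                             coil_ca(sample(5:15, 1))))
    ann <- assignSecondaryStructure(m)
    expect_identical(sum(ann@elements$length), length(ann@labels))
    expect_identical(ann@elements$end[nrow(ann@elements)],
                     length(ann@labels))
  }
})

test_that("the fitness score is the exact product of its terms", {
  fb <- new("FitnessBreakdown", plddtMean = 0.8, ptm = 0.7, cd = 2.0,
            iplddt = 1, icd = 1, constr = 0.5, score = 0.56)
  expect_true(validObject(fb))
  expect_identical(fitness(fb), 0.56)
  expect_error(validObject(new("FitnessBreakdown", plddtMean = 0.8,
    ptm = 0.7, cd = 2.0, iplddt = 1, icd = 1, constr = 0.5, score = 0.9)),
    "product")

  # cd = 0 zeroes the whole score regardless of other terms
  ca <- cbind(seq_len(20) * 10, 0, 0)
  m <- model_from_ca(ca, plddt = rep(0.95, 20), ptm = 0.9)
  fb0 <- fitnessScore(paste(m@residues, collapse = ""), m)
  expect_identical(fb0@cd, 0)
  expect_identical(fitness(fb0), 0)

  # self-consistency over random fixtures: breakdown re-multiplies exactly
  set.seed(55)
  for (i in 1:1000) {
    m <- random_model(sample(10:40, 1))
    fb <- fitnessScore(paste(m@residues, collapse = ""), m)
    expect_identical(fb@score, fb@plddtMean * fb@ptm * fb@cd *
                     fb@iplddt * fb@icd * fb@constr)
  }
})

test_that("fitness scoring rejects sequence/model length mismatch", {
  m <- model_from_ca(ideal_helix_ca(12))
  expect_error(fitnessScore(strrep("A", 10), m), "residues")
})

test_that("monomer scoring uses identity interface terms; dimer scoring does not", {
  m <- model_from_ca(ideal_helix_ca(12))
  fb <- fitnessScore(paste(m@residues, collapse = ""), m)
  expect_identical(fb@iplddt, 1)
  expect_identical(fb@icd, 1)
  ca <- rbind(ideal_helix_ca(12), sweep(ideal_helix_ca(8), 2, c(4, 0, 0), "+"))
  md <- model_from_ca(ca, plddt = rep(0.9, 20),
                      chain = rep(c("A", "B"), c(12, 8)))
  fbd <- fitnessScore(paste(md@residues[1:12], collapse = ""), md)
  orc <- interface_oracle(md)
  expect_equal(fbd@icd, orc$icd)
  expect_equal(fbd@iplddt, orc$iplddt)
})

test_that("scoring a directory of PDB files yields one breakdown row per file", {
  dir <- tempfile(); dir.create(dir)
  ev <- surrogateEvaluator()
  seqs <- c(a = "LKKLEEKLKKLEEK", b = "VTVTVTVTVTVT")
  for (nm in names(seqs))
    writeStructure(evaluateStructure(ev, seqs[[nm]])[[1]],
                   file.path(dir, paste0(nm, ".pdb")))
  tab <- scoreStructureDir(dir)
  expect_identical(tab$id, c("a", "b"))
  expect_identical(names(tab), c("id", "plddt_mean", "ptm", "cd", "iplddt",
                                 "icd", "constr", "score"))
  expect_equal(tab$score, tab$plddt_mean * tab$ptm * tab$cd * tab$iplddt *
               tab$icd * tab$constr, tolerance = 1e-12)
})
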