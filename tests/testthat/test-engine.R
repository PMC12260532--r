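test_that("population size is conserved and the pool is exactly 2N", {
  run <- small_run(seed = 101, popSize = 6L, gens = 8L)
  recs <- run@records
  for (g in 1:8) {
    gr <- recs[recs$generation == g, ]
    expect_identical(nrow(gr), 12L)
    expect_identical(sum(gr$selected_n), 6L)  # survivors, with multiplicity
    expect_true(all(gr$selected == (gr$selected_n > 0L)))
  }
  expect_length(run@population, 6L)
})

test_that("under strong selection the elite scores never decrease", {
  run <- runSimulation(runConfig(popSize = 10L, founderLength = 24L,
                                 selection = selectionConfig("STRONG"),
                                 maxGenerations = 30L,
                                 plddtStop = 1, ptmStop = 1, seed = 5))
  sel <- run@records[run@records$selected & run@records$generation > 0, ]
  byGen <- split(sel$score, sel$generation)
  nthBest <- vapply(byGen, min, numeric(1))   # worst surviving score
  best <- vapply(byGen, max, numeric(1))
  expect_true(all(diff(nthBest) >= 0))
  expect_true(all(diff(best) >= 0))
})

test_that("vacuous stop thresholds halt the run at generation 1", {
  run <- runSimulation(runConfig(popSize = 4L, maxGenerations = 50L,
                                 plddtStop = 0, ptmStop = 0, seed = 2))
  expect_identical(run@generations, 1L)
  expect_false(is.na(run@stopId))
})

test_that("identical config and seed reproduce the run byte-for-byte", {
  cfg <- runConfig(popSize = 5L, maxGenerations = 6L, plddtStop = 1,
                   ptmStop = 1, seed = 77)
  a <- runSimulation(cfg)
  b <- runSimulation(cfg)
  expect_identical(a@records, b@records)
  expect_identical(lineageNodes(a@tree), lineageNodes(b@tree))
  fa <- tempfile(); fb <- tempfile()
  write.table(a@records, fa, sep = "\t", row.names = FALSE)
  write.table(b@records, fb, sep = "\t", row.names = FALSE)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("the memoization cache changes runtime only, never results", {
  cfg <- runConfig(popSize = 5L, maxGenerations = 6L, plddtStop = 1,
                   ptmStop = 1, seed = 31)
  plain <- runSimulation(cfg)
  cached <- runSimulation(cfg, memoize = TRUE)
  expect_equal(plain@records, cached@records)
})

test_that("the lineage is a forest rooted at the founders", {
  run <- small_run(seed = 13, popSize = 6L, gens = 12L)
  nd <- lineageNodes(run@tree)
  roots <- sum(is.na(nd$parentId))
  expect_identical(roots, 6L)              # the founders
  expect_identical(nrow(nd) - roots, sum(!is.na(nd$parentId)))
  expect_true(all(nd$parentId[!is.na(nd$parentId)] %in% nd$id))
  # every final individual reaches generation 0
  for (ind in run@population) {
    lin <- extractLineage(run@tree, seqId(ind))
    expect_identical(lin$path$generation[1], 0L)
    expect_lte(nrow(lin$path) - 1L, run@generations)
    # unique sequences on the lineage < generations + 1
    expect_lte(length(unique(lin$path$residues)), run@generations + 1L)
  }
})

test_that("checkpoint and resume continue the exact trajectory", {
  full <- runSimulation(runConfig(popSize = 5L, maxGenerations = 10L,
                                  plddtStop = 1, ptmStop = 1, seed = 19))
  ck <- tempfile(fileext = ".rds")
  half <- runSimulation(runConfig(popSize = 5L, maxGenerations = 5L,
                                  plddtStop = 1, ptmStop = 1, seed = 19),
                        checkpointPath = ck)
  resumed <- resumeSimulation(ck, maxGenerations = 10L)
  expect_identical(resumed@records, full@records)
  expect_identical(vapply(resumed@population, residues, character(1)),
                   vapply(full@population, residues, character(1)))
})

test_that("checkpointing twice without stepping writes identical files", {
  run <- small_run(seed = 3, popSize = 4L, gens = 3L)
  st <- attr(run, "engineState")
  f1 <- tempfile(); f2 <- tempfile()
  checkpointEngine(st, f1)
  checkpointEngine(st, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("resume rejects missing or corrupt checkpoints", {
  expect_error(resumeSimulation(tempfile()), "no checkpoint")
  bad <- tempfile()
  saveRDS(list(unrelated = TRUE), bad)
  expect_error(resumeSimulation(bad), "corrupt checkpoint")
})

test_that("evaluator failure aborts with the checkpoint preserved", {
  # replay evaluator that knows the founders but none of their mutants
  streams <- rngStreams(8L)
  founders <- withStream(streams, "founders",
                         makeFounders("n_random", 24L, 2L))
  fseqs <- vapply(founders, residues, character(1))
  fx <- fixtureEvaluator(setNames(
    evaluateStructure(surrogateEvaluator(), fseqs), fseqs))
  cfg <- runConfig(popSize = 2L, evaluator = fx, maxGenerations = 3L,
                   plddtStop = 1, ptmStop = 1, seed = 8)
  ck <- tempfile()
  expect_error(runSimulation(cfg, checkpointPath = ck),
               "evaluator failed at generation 1")
  expect_true(file.exists(ck))
  st <- readRDS(ck)
  expect_identical(st$generationIdx, 0L)   # last valid state
})

test_that("dimer mode runs end to end and records interface terms", {
  part <- evaluateStructure(surrogateEvaluator(), "VTVTVTVTVTVTVTVT")[[1]]
  cfg <- runConfig(popSize = 4L, maxGenerations = 3L, partner = part,
                   plddtStop = 1, ptmStop = 1, seed = 91)
  run <- runSimulation(cfg)
  expect_true(all(c("iplddt", "icd") %in% names(run@records)))
  # in dimer mode the interface terms are measured, not the identity
  expect_false(all(run@records$iplddt == 1))
})

test_that("run outputs land on disk in the documented formats", {
  od <- tempfile()
  run <- runSimulation(runConfig(popSize = 4L, maxGenerations = 4L,
                                 plddtStop = 1, ptmStop = 1, seed = 44,
                                 snapshotEvery = 2L), outDir = od)
  expect_true(all(file.exists(file.path(od,
    c("records.tsv", "final_population.fasta", "lineage.nwk",
      "lineage_edges.tsv", "manifest.json")))))
  expect_true(length(list.files(od, pattern = "^best_g.*\\.pdb$")) >= 1)
  recs <- read.delim(file.path(od, "records.tsv"))
  expect_identical(nrow(recs), nrow(run@records))
  man <- jsonlite::read_json(file.path(od, "manifest.json"))
  expect_identical(man$pop_size, 4L)
  expect_identical(man$seed, 44L)
  phy <- ape::read.tree(file.path(od, "lineage.nwk"))
  expect_s3_class(phy, "phylo")
})
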