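makeToySweep <- function(info, noiseNorm, keq = 10^-(5:(4 + length(info)))) {
  tab <- data.frame(Keq = keq, information = info,
                    noise = noiseNorm, outputRange = 1,
                    noiseNorm = noiseNorm)
  new("SweepResult", table = tab, type = "affinity",
      spec = bindingModel(), seed = 1L, replicates = 10L,
      nLevels = 3L, tSample = 1)
}

test_that("optimum search maximizes information, ties to weaker affinity", {
  sw <- makeToySweep(info = c(0.1, 0.9, 0.4),
                     noiseNorm = c(1.0, 0.5, 0.1))
  opt <- findOptimum(sw)
  expect_equal(opt$index, 2L)
  expect_equal(opt$information, 0.9)
  expect_equal(opt$noiseNorm, 0.5)

  flat <- makeToySweep(info = c(0.4, 0.4, 0.4),
                       noiseNorm = c(1.0, 0.5, 0.1))
  expect_equal(findOptimum(flat)$Keq, 1e-5)  # weakest affinity wins ties
  expect_error(findOptimum(makeToySweep(0.1, 1.0)), "at least 2")
})

test_that("sweeps are reproducible: same config and seed, same table", {
  grid <- c(1e-6, 1e-7)
  a <- affinitySweep(bindingModel(), grid, nLevels = 3, replicates = 60,
                     seed = 99)
  b <- affinitySweep(bindingModel(), grid, nLevels = 3, replicates = 60,
                     seed = 99)
  expect_identical(sweepTable(a), sweepTable(b))
  c <- affinitySweep(bindingModel(), grid, nLevels = 3, replicates = 60,
                     seed = 100)
  expect_false(identical(sweepTable(a), sweepTable(c)))
})

test_that("normalized series peak at 1 and stay within [0, 1]", {
  sw <- affinitySweep(bindingModel(), c(1e-5, 1e-7, 1e-9), nLevels = 4,
                      replicates = 80, seed = 2)
  tab <- sweepTable(sw)
  for (col in c("informationNorm", "noiseNorm", "outputRangeNorm")) {
    expect_true(all(tab[[col]] >= 0 & tab[[col]] <= 1))
    expect_equal(max(tab[[col]]), 1)
  }
})

test_that("single-cell ratio grid yields one flagged row", {
  sw <- ratioAffinityGrid(bindingModel(NSmax = 10L), ratioGrid = 10,
                          keqGrid = 1e-9, nLevels = 3, replicates = 40,
                          seed = 1)
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$NRT, 100L)
  expect_true(tab$perfectDetection)
})

test_that("cascade grid: silent upstream or saturated DNA kill the response", {
  spec <- cascadeModel()
  sw <- suppressWarnings(  # the weak edge sits beyond typical affinities
    dualAffinityGrid(spec, keqBindGrid = c(1e-3, 1e-5, 1e-7),
                     keqDnaGrid = c(1e-8, 1e-9),
                     nLevels = 4, replicates = 300, seed = 6))
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 6L)
  # weakest receptor-signal affinity: almost no complexes ever form, so
  # by data processing the DNA layer cannot recover the signal
  weak <- tab[tab$KeqBind == 1e-3, ]
  expect_true(all(weak$informationNorm <= 0.2))
  # the receptor-signal information maximum is interior, not at an edge
  best <- tab[which.max(tab$information), ]
  expect_equal(best$KeqBind, 1e-5)
  # strong DNA affinity under an occupied upstream: the site is bound for
  # every signal level, so the output range collapses
  sat <- tab[tab$KeqDna == 1e-9 & tab$KeqBind == 1e-7, ]
  expect_lt(sat$outputRange, 0.1)
  expect_gt(mean(simulateModel(setKeq(spec, 1e-10, "dna"), 1000,
                               replicates = 50, seed = 1)[, "RSD"]),
            0.95)
})

test_that("ten binding sites lead to the same qualitative conclusion", {
  spec <- cascadeModel(sites = 10L)
  sw <- suppressWarnings(
    dualAffinityGrid(spec, keqBindGrid = c(1e-3, 1e-5),
                     keqDnaGrid = 1e-9, nLevels = 4,
                     replicates = 200, seed = 8))
  tab <- sweepTable(sw)
  expect_true(all(tab$outputRange <= 10))
  expect_gt(tab$information[tab$KeqBind == 1e-5],
            tab$information[tab$KeqBind == 1e-3])
})

test_that("sweep tables round-trip through TSV with provenance", {
  sw <- affinitySweep(bindingModel(), c(1e-6, 1e-8), nLevels = 3,
                      replicates = 40, seed = 5)
  path <- tempfile(fileext = ".tsv")
  writeSweep(sw, path)
  lines <- readLines(path)
  expect_match(lines[1L], "^# signoise sweep type=affinity")
  back <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(back$information, sweepTable(sw)$information,
               tolerance = 1e-9)
  unlink(path)
})

test_that("a YAML configuration drives a full sweep run", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "model:",
    "  variant: binding",
    "  receptors: 10",
    "  NSmax: 100",
    "sweep:",
    "  type: affinity",
    "  keqGrid: [1.0e-6, 1.0e-8]",
    "  nLevels: 3",
    "  replicates: 40",
    "  seed: 11"), cfg)
  out <- tempfile()
  sw <- runSweepConfig(cfg, outDir = out)
  expect_s4_class(sw, "SweepResult")
  expect_true(file.exists(file.path(out, "sweep.tsv")))
  # identical to calling the sweep directly
  direct <- affinitySweep(bindingModel(NSmax = 100L), c(1e-6, 1e-8),
                          nLevels = 3, replicates = 40, seed = 11)
  expect_equal(sweepTable(sw), sweepTable(direct))
  unlink(c(cfg, out), recursive = TRUE)
})

test_that("extrinsic-noise experiment structure and determinism at toy scale", {
  spec <- genePolymeraseModel(NSmax = 50L)
  sw <- extrinsicNoiseExperiment(spec, keqGrid = c(1e-10, 1e-12),
                                 sdFractions = c(0, 0.3), nLevels = 3,
                                 replicates = 20, seed = 13,
                                 tSample = 3000)
  tab <- sweepTable(sw)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("sdFraction", "informationSE") %in% names(tab)))
  smry <- extrinsicSummary(sw)
  expect_equal(smry$sdFraction, c(0, 0.3))
  # sd 0: every replicate sees the identical polymerase count
  ep <- simulateModel(genePolymeraseModel(NSmax = 50L, sdFraction = 0),
                      50, replicates = 10, seed = 2, tSample = 500)
  expect_equal(length(unique(ep[, "Pol"] + ep[, "TFPD"])), 1L)
})
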