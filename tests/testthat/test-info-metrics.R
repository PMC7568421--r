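test_that("Shannon entropy: uniform, point mass, and a hand-computed case", {
  expect_equal(shannonEntropy(rep(1 / 8, 8)), 3)
  expect_equal(shannonEntropy(c(1, 0, 0)), 0)
  expect_equal(shannonEntropy(c(0.75, 0.25)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(shannonEntropy(c(0.75, 0.25)), 0.811278, tolerance = 1e-6)
  expect_error(shannonEntropy(c(0.5, 0.4)), "sum to 1")
})

test_that("mutual information: distinguishable, independent, and 2x2 cases", {
  perfect <- responseEnsemble(1:2, pmfs = list(c(`0` = 1), c(`1` = 1)))
  expect_equal(mutualInformation(perfect), 1)

  same <- responseEnsemble(1:4, pmfs = rep(list(c(`0` = 0.3, `3` = 0.7)), 4))
  expect_equal(mutualInformation(same), 0)

  cross <- responseEnsemble(1:2, pmfs = list(c(`0` = 0.75, `1` = 0.25),
                                             c(`0` = 0.25, `1` = 0.75)))
  # frozen from the brute-force joint: 1 - H(0.75)
  expect_equal(mutualInformation(cross), 0.1887219, tolerance = 1e-6)
  expect_equal(mutualInformation(cross), bruteForceMI(cross))
})

test_that("mutual information equals the brute-force joint sum and is bounded", {
  for (seed in 1:10) {
    ens <- randomEnsemble(nLevels = 4L, supportSize = 6L, seed = seed)
    mi <- mutualInformation(ens)
    expect_equal(mi, bruteForceMI(ens), tolerance = 1e-12)
    hs <- log2(4)
    ho <- shannonEntropy(colMeans(signoise:::.conditionalMatrix(ens)))
    expect_gte(mi, 0)
    expect_lte(mi, min(hs, ho) + 1e-12)
  }
})

test_that("merging output bins never increases mutual information", {
  mergeBins <- function(ens) {
    pmfs <- lapply(ens@pmfs, function(p) {
      o <- as.numeric(names(p)) %/% 2  # coarsen support 2-to-1
      tapply(p, o, sum)
    })
    responseEnsemble(ens@signalLevels,
                     pmfs = lapply(pmfs, function(p)
                       setNames(as.numeric(p), names(p))))
  }
  for (seed in 11:16) {
    ens <- randomEnsemble(nLevels = 3L, supportSize = 8L, seed = seed)
    expect_lte(mutualInformation(mergeBins(ens)),
               mutualInformation(ens) + 1e-12)
  }
})

test_that("average Fano factor: point masses, direct case, Poisson sampling", {
  pm <- responseEnsemble(1:3, pmfs = list(c(`2` = 1), c(`5` = 1),
                                          c(`9` = 1)))
  expect_equal(averageFano(pm), 0)

  # direct evaluation of the printed average: level 1 has mean 10 and
  # variance 25 (Fano 2.5), level 2 is a point mass (Fano 0)
  mixed <- responseEnsemble(1:2,
                            pmfs = list(c(`5` = 0.5, `15` = 0.5),
                                        c(`20` = 1)))
  expect_equal(averageFano(mixed), (25 / 10 + 0) / 2)

  set.seed(30)
  pois <- responseEnsemble(1:2,
                           samples = list(rpois(1e4, 20), rpois(1e4, 7)))
  expect_lt(abs(averageFano(pois) - 1), 3 * sqrt(2 / 1e4) * 2)

  allzero <- responseEnsemble(1:2, pmfs = list(c(`0` = 1), c(`0` = 1)))
  expect_equal(averageFano(allzero), 0)  # zero-mean convention
})

test_that("Fano factor depends only on each conditional pmf, not labels", {
  ens <- randomEnsemble(3L, 5L, seed = 77)
  relabeled <- new("ResponseEnsemble",
                   signalLevels = rev(ens@signalLevels),
                   pmfs = rev(ens@pmfs), samples = list(),
                   replicates = NA_integer_, output = "O")
  expect_equal(averageFano(ens), averageFano(relabeled))
})

test_that("output range is the spread of conditional means", {
  ens <- responseEnsemble(1:3, pmfs = list(c(`3` = 1), c(`10` = 1),
                                           c(`7` = 1)))
  expect_equal(outputRange(ens), 7)
  same <- responseEnsemble(1:3, pmfs = rep(list(c(`4` = 1)), 3))
  expect_equal(outputRange(same), 0)
  one <- responseEnsemble(5L, pmfs = list(c(`9` = 0.5, `11` = 0.5)))
  expect_equal(outputRange(one), 0)
})

test_that("series normalization divides by the maximum (zeros preserved)", {
  expect_equal(normalizeSeries(c(1, 2, 4)), c(0.25, 0.5, 1))
  expect_equal(normalizeSeries(5), 1)
  expect_equal(normalizeSeries(c(0, 0)), c(0, 0))
})

test_that("response ensembles round-trip through TSV", {
  ens <- randomEnsemble(3L, 4L, seed = 5)
  ens@replicates <- 100L
  path <- tempfile(fileext = ".tsv")
  writeEnsemble(ens, path)
  back <- readEnsemble(path)
  expect_equal(back@signalLevels, ens@signalLevels)
  expect_equal(ensembleMetrics(back), ensembleMetrics(ens),
               tolerance = 1e-12)
  unlink(path)
})
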