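test_that("molar-count conversion follows N = c * V * N_Avogadro", {
  expect_equal(molarToCount(1e-8, receptorVolume()), 10)
  expect_equal(molarToCount(1e-6, receptorVolume()), 1000)
  expect_equal(molarToCount(0, receptorVolume()), 0)
  expect_equal(molarToCount(1e-11, geneVolume()), 100)
  expect_error(molarToCount(-1e-9), ">= 0")
})

test_that("signal grid is the n rounded multiples of NSmax/n", {
  expect_equal(signalGrid(1000, 10), seq(100L, 1000L, by = 100L))
  expect_equal(signalGrid(8, 8), 1:8)
  expect_equal(signalGrid(1000, 1), 1000L)
  expect_error(signalGrid(5, 6), "1 <= n <= NSmax")
  # always strictly increasing for any admissible n
  for (nmax in c(10L, 37L, 1000L))
    for (n in c(1L, 3L, 7L, nmax))
      expect_true(all(diff(signalGrid(nmax, n)) > 0L) ||
                    n == 1L)
})

test_that("expected complexes: half occupancy, clamping, monotone limits", {
  expect_equal(expectedComplexes(10, 100, 100), 5)
  expect_equal(expectedComplexes(1, 100, 100), 0.5)
  expect_equal(expectedComplexes(10, 1000, 100), 10 * 1000 / 1100)
  # clamp: more binding sites than signal molecules at strong affinity
  expect_equal(expectedComplexes(100, 3, 1e-6), 3)
  # monotone increasing in signal, decreasing in Keq
  ns <- c(1, 5, 20, 100, 400)
  v <- vapply(ns, function(s) expectedComplexes(10, s, 50), numeric(1L))
  expect_true(all(diff(v) > 0))
  ks <- c(1e-3, 1, 50, 1e4)
  v <- vapply(ks, function(k) expectedComplexes(10, 100, k), numeric(1L))
  expect_true(all(diff(v) < 0))
  # limits: all receptors bound as Keq -> 0, none as Keq -> Inf
  expect_equal(expectedComplexes(10, 100, 1e-12), 10, tolerance = 1e-9)
  expect_lt(expectedComplexes(10, 100, 1e12), 1e-8)
  expect_equal(expectedComplexes(10, 0, 0), 0)
})

test_that("initial states implement the equilibrium-expectation formulas", {
  # receptor-signal: nearest integer to Nhat_C = 5
  st <- initialState(bindingModel(Keq = 1e-7), NS = 100)
  expect_identical(st, c(S = 95L, R = 5L, RS = 5L))
  # gene: mRNA/protein at Nhat * k1/d1 (k2/d2); Keq 1e-11 -> 100 counts
  spec <- geneModel(Keq = 1e-11, k1 = 0.02, k2 = 0.01,
                    d1 = 0.001, d2 = 0.0002)
  set.seed(1)
  st <- initialState(spec, NS = 100)  # occupancy p = 0.5
  expect_equal(unname(st[["mR"]]), round(0.5 * 20))
  expect_equal(unname(st[["P"]]), round(0.5 * 20 * 50))
  expect_true(st[["TFD"]] %in% 0:1)
  expect_equal(sum(st[c("TF", "TFD")]), 100L)
  # Bernoulli site occupancy has the right frequency
  set.seed(2)
  occ <- replicate(1e4, initialState(spec, 100)[["TFD"]])
  expect_lt(abs(mean(occ) - 0.5), 3 * sqrt(0.25 / 1e4))
  # no negative free molecules even when sites exceed signal
  spec2 <- geneModel(sites = 10L, NSmax = 1000L, Keq = 1e-13)
  set.seed(3)
  for (i in 1:50) expect_true(all(initialState(spec2, 3) >= 0L))
})

test_that("polymerase counts: deterministic at sd 0, moment-matched otherwise", {
  expect_identical(samplePolymeraseCount(10000, 0), 10000L)
  expect_identical(samplePolymeraseCount(10000, 0), 10000L)
  set.seed(8)
  draws <- replicate(1e5, samplePolymeraseCount(10000, 0.10))
  expect_lt(abs(mean(draws) - 10000), 3 * sd(draws) / sqrt(1e5))
  expect_lt(abs(sd(draws) - 1000) / 1000, 0.05)
  expect_error(samplePolymeraseCount(10, 0.10), "1/sqrt\\(mean\\)")
})

test_that("built models have the declared reactions and conserved sums", {
  b <- buildModel(bindingModel(), 100)
  expect_length(b@reactions, 2L)
  expect_equal(b@conserved, list(c("S", "RS"), c("R", "RS")))

  g <- buildModel(geneModel(), 100)
  expect_length(g@reactions, 6L)
  expect_equal(g@output, "P")

  gp <- buildModel(genePolymeraseModel(), 100)
  expect_length(gp@reactions, 9L)
  # transcription is gated on the TF-polymerase-DNA complex
  st <- setNames(rep(0, length(gp@species)), names(gp@species))
  st["TFD"] <- 1  # TF bound but no polymerase: no transcription
  k1row <- which(vapply(gp@reactions, function(r)
    r@kind == "conditional-synthesis", logical(1L)))
  expect_equal(propensities(st, gp)[k1row], 0)
  st["TFD"] <- 0; st["TFPD"] <- 1
  expect_equal(propensities(st, gp)[k1row], 0.02)

  cs <- buildModel(cascadeModel(sites = 3L), 100)
  expect_length(cs@reactions, 4L)
  expect_equal(unname(cs@species["D"]), 3L)
  expect_error(buildModel(fullPathwayModel(), -1), ">= 0")
})

test_that("multi-site gene models use mass-action transcription", {
  g <- buildModel(geneModel(sites = 3L), 100)
  st <- setNames(rep(0, length(g@species)), names(g@species))
  st["TFD"] <- 2
  i <- which(vapply(g@reactions, function(r)
    r@kind == "first-order-synthesis" &&
      r@reactants == "TFD", logical(1L)))
  expect_equal(propensities(st, g)[i], 0.02 * 2)
})

test_that("association rates derive from Keq as kd/Keq", {
  spec <- bindingModel(Keq = 1e-7, kd = 0.01)
  sys <- buildModel(spec, 100)
  expect_equal(sys@reactions[[1L]]@rate, 0.01 / 1e-7)
  # stationary behavior depends only on Keq, not on the kd split:
  # same Keq with a 5x faster kd gives the same stationary distribution
  fast <- bindingModel(Keq = 1e-7, kd = 0.05)
  epA <- simulateModel(spec, 100, replicates = 800, seed = 21)
  epB <- simulateModel(fast, 100, replicates = 800, seed = 22)
  pi <- bindingStationaryDist(10, 100, 100)
  m <- sum(0:10 * pi)
  expect_lt(abs(mean(epA[, "RS"]) - m), 0.25)
  expect_lt(abs(mean(epB[, "RS"]) - m), 0.25)
})

test_that("model validity rejects out-of-range parameters", {
  expect_error(geneModel(sites = 11L), "B must lie in")
  expect_error(bindingModel(Keq = -1e-7), "positive")
  expect_error(signoise:::.newModel("nope", NSmax = 10L,
                                    Keq = c(bind = 1e-7),
                                    kd = c(bind = 0.01),
                                    volume = 1e-15),
               "variant")
  expect_error(setKeq(bindingModel(), 1e-9, step = "dna"), "no binding step")
})
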