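#' Exact stationary distribution of reversible binding
#'
#' The complex count of the reversible-binding model is a birth--death
#' chain on `c = 0..min(N_RT, N_S)` with birth rate
#' `lambda_c = k_d (N_RT - c)(N_S - c)/Keq_count` and death rate
#' `mu_c = k_d c`.  Its stationary distribution follows from detailed
#' balance, `pi_c  proportional to  prod_{j=1..c} lambda_{j-1}/mu_j`
#' (`k_d` cancels, so the distribution depends on the affinity only
#' through `Keq_count`).  Computed in log space.
#'
#' @param NRT total receptor molecules.
#' @param NS total signal molecules.
#' @param KeqCount equilibrium constant in count units (> 0).
#' @return Named numeric of stationary probabilities over `0..min(NRT,
#'   NS)` (sums to 1).
#' @export
#' @examples
#' bindingStationaryDist(1, 1, 1)        # (0.5, 0.5)
#' sum(bindingStationaryDist(10, 100, 100) * 0:10)  # mean ~ 5
bindingStationaryDist <- function(NRT, NS, KeqCount) {
  if (KeqCount <= 0) stop("KeqCount must be > 0")
  cmax <- min(NRT, NS)
  logw <- c(0, cumsum(vapply(seq_len(cmax), function(j)
    log((NRT - j + 1) * (NS - j + 1)) - log(j * KeqCount), numeric(1L))))
  if (cmax == 0) logw <- 0
  w <- exp(logw - max(logw))
  setNames(w / sum(w), 0:cmax)
}

#' Brute-force stationary distribution of the binding chain
#'
#' Independent cross-check of [bindingStationaryDist()]: builds the full
#' generator matrix of the birth--death chain and solves the global
#' balance equations `pi Q = 0`, `sum pi = 1` as a linear system.
#' Intended for small state spaces.
#'
#' @inheritParams bindingStationaryDist
#' @param kd dissociation rate (cancels; kept to build the literal
#'   generator).
#' @return Named numeric of stationary probabilities over `0..min(NRT,
#'   NS)`.
#' @export
bindingStationaryBrute <- function(NRT, NS, KeqCount, kd = 1) {
  if (KeqCount <= 0) stop("KeqCount must be > 0")
  cmax <- min(NRT, NS)
  m <- cmax + 1L
  Q <- matrix(0, m, m)
  for (c in 0:cmax) {
    i <- c + 1L
    if (c < cmax) Q[i, i + 1L] <- kd * (NRT - c) * (NS - c) / KeqCount
    if (c > 0)    Q[i, i - 1L] <- kd * c
    Q[i, i] <- -sum(Q[i, -i])
  }
  A <- t(Q)
  A[m, ] <- 1                     # replace one balance eq by normalization
  b <- c(rep(0, m - 1L), 1)
  setNames(solve(A, b), 0:cmax)
}

#' Exact metrics of the binding model
#'
#' Computes mutual information, average Fano factor and output range of
#' the reversible-binding model directly from the `n` exact stationary
#' distributions (no sampling), one per signal level.
#'
#' @param NRT total receptor molecules.
#' @param grid integer vector of signal levels (see [signalGrid()]).
#' @param KeqCount equilibrium constant in count units.
#' @return Named numeric as in [ensembleMetrics()].
#' @export
#' @examples
#' exactBindingMetrics(10, signalGrid(1000, 8), 100)
exactBindingMetrics <- function(NRT, grid, KeqCount) {
  pmfs <- lapply(grid, function(ns) bindingStationaryDist(NRT, ns, KeqCount))
  ens <- responseEnsemble(grid, pmfs = pmfs, replicates = NA_integer_,
                          output = "RS")
  ensembleMetrics(ens)
}

#' Constitutive gene-expression moments
#'
#' Expected protein count and its standard deviation for an always-on
#' gene: `E(N_P) = (k1/d2)(k2/d1)` and
#' `E(sigma(N_P)) = sqrt((k1/d2)(k2/d1)^2)`.
#'
#' @param k1 transcription rate (s^-1).
#' @param k2 translation rate (s^-1).
#' @param d1 mRNA decay rate (s^-1).
#' @param d2 protein decay rate (s^-1).
#' @return Named numeric with `mean` and `sd` (counts).
#' @export
#' @examples
#' constitutiveMoments(0.02, 0.01, 0.001, 2e-4)  # mean 1000, sd 100
constitutiveMoments <- function(k1, k2, d1, d2) {
  if (any(c(k1, k2, d1, d2) <= 0)) stop("all rates must be > 0")
  c(mean = (k1 / d2) * (k2 / d1),
    sd = sqrt((k1 / d2) * (k2 / d1)^2))
}
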