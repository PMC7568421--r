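#' Shannon entropy of a discrete distribution
#'
#' `H = -sum p log2 p`, with `0 * log 0 = 0`.
#'
#' @param pmf numeric vector of probabilities summing to 1.
#' @return Entropy in bits (>= 0).
#' @export
#' @examples
#' shannonEntropy(rep(1/8, 8))     # 3 bits
#' shannonEntropy(c(0.75, 0.25))   # 0.8113 bits
shannonEntropy <- function(pmf) {
  if (any(pmf < 0)) stop("probabilities must be non-negative")
  if (abs(sum(pmf) - 1) > 1e-9) stop("pmf must sum to 1")
  p <- pmf[pmf > 0]
  -sum(p * log2(p))
}

#' Construct a ResponseEnsemble
#'
#' From either raw endpoint samples (a list of integer vectors, one per
#' signal level) or pre-computed probability mass functions (a list of
#' named numeric vectors whose names are the integer output counts).
#'
#' @param signalLevels integer vector of signal levels.
#' @param samples list of integer sample vectors, one per level.
#' @param pmfs list of named probability vectors, one per level
#'   (alternative to `samples`).
#' @param replicates replicates per level (inferred from `samples`).
#' @param output output species name.
#' @return A [ResponseEnsemble-class].
#' @export
#' @examples
#' responseEnsemble(c(1L, 2L),
#'                  pmfs = list(c(`0` = 0.75, `1` = 0.25),
#'                              c(`0` = 0.25, `1` = 0.75)))
responseEnsemble <- function(signalLevels, samples = NULL, pmfs = NULL,
                             replicates = NA_integer_, output = "O") {
  if (is.null(pmfs)) {
    if (is.null(samples)) stop("provide samples or pmfs")
    pmfs <- lapply(samples, function(x) {
      tab <- table(x)
      setNames(as.numeric(tab) / length(x), names(tab))
    })
    replicates <- unique(lengths(samples))
    if (length(replicates) != 1L)
      stop("all levels need the same number of replicates")
  }
  new("ResponseEnsemble", signalLevels = as.integer(signalLevels),
      pmfs = pmfs, samples = if (is.null(samples)) list() else samples,
      replicates = as.integer(replicates[1L]), output = output)
}

#' @rdname signalLevels
#' @param x a [ResponseEnsemble-class].
#' @return `signalLevels()`: the integer signal levels.
#' @export
setMethod("signalLevels", "ResponseEnsemble", function(x) x@signalLevels)

## Freedman-Diaconis width on the pooled response distribution, floored
## at 1 count.  For low-copy outputs (binding complexes: support ~ tens)
## this returns 1, i.e. no binning.  For protein-valued outputs whose
## observed support is comparable to the replicate count, the unbinned
## plug-in mutual information is dominated by finite-sample bias (almost
## every sample value is unique), so the conditional distributions are
## histogrammed at this width first.
.autoBinWidth <- function(ensemble) {
  if (is.na(ensemble@replicates)) return(1)
  n <- ensemble@replicates * length(ensemble@pmfs)
  ## pooled quantiles from the averaged pmf
  support <- sort(unique(as.numeric(unlist(lapply(ensemble@pmfs, names)))))
  pooled <- rep(0, length(support))
  for (p in ensemble@pmfs)
    pooled[match(as.numeric(names(p)), support)] <-
      pooled[match(as.numeric(names(p)), support)] +
      p / length(ensemble@pmfs)
  cdf <- cumsum(pooled)
  q <- function(u) support[which(cdf >= u)[1L]]
  iqr <- q(0.75) - q(0.25)
  max(1, floor(2 * iqr / n^(1 / 3)))
}

## Histogram a pmf at integer width w: support value o -> bin floor(o/w).
.binPmf <- function(pmf, w) {
  if (w <= 1) return(pmf)
  bins <- floor(as.numeric(names(pmf)) / w)
  out <- tapply(as.numeric(pmf), bins, sum)
  setNames(as.numeric(out), names(out))
}

## Common-support conditional probability matrix p(o | s): n x m.
.conditionalMatrix <- function(ensemble) {
  support <- sort(unique(as.numeric(unlist(lapply(ensemble@pmfs, names)))))
  n <- length(ensemble@pmfs)
  M <- matrix(0, nrow = n, ncol = length(support),
              dimnames = list(ensemble@signalLevels, support))
  for (i in seq_len(n)) {
    p <- ensemble@pmfs[[i]]
    M[i, as.character(as.numeric(names(p)))] <- p
  }
  M
}

#' Mutual information between signal and output
#'
#' Plug-in estimate for a uniform signal prior over the `n` levels:
#' the joint is `p(s, o) = p(o | s)/n` and
#' `I(S;O) = H(Pr(S)) - H(Pr(S|O)) = sum p(s,o) log2( p(o|s) / p(o) )`,
#' computed from the joint table (never from re-normalized sparse
#' columns).  The result lies in `[0, log2 n]`.
#'
#' For high-copy outputs (protein counts) whose observed support is
#' comparable to the number of replicates, the raw plug-in estimate is
#' dominated by finite-sample bias, so the conditional distributions are
#' first histogrammed: `binWidth = "auto"` uses the Freedman--Diaconis
#' width of the pooled response distribution, floored at one count (so
#' low-copy outputs such as bound-complex counts, and all exact
#' probability inputs, are never binned).
#'
#' @param ensemble a [ResponseEnsemble-class].
#' @param binWidth `"auto"`, or a positive integer histogram width for
#'   the output counts (1 = no binning).
#' @param ... unused.
#' @return Mutual information in bits.
#' @export
#' @examples
#' ens <- responseEnsemble(c(1L, 2L),
#'                         pmfs = list(c(`0` = 0.75, `1` = 0.25),
#'                                     c(`0` = 0.25, `1` = 0.75)))
#' mutualInformation(ens)  # 1 - H(0.75) = 0.1887 bits
#' @rdname mutualInformation
setMethod("mutualInformation", "ResponseEnsemble",
          function(ensemble, binWidth = "auto", ...) {
  w <- if (identical(binWidth, "auto")) .autoBinWidth(ensemble)
       else as.numeric(binWidth)
  if (w > 1) {
    ensemble <- new("ResponseEnsemble",
                    signalLevels = ensemble@signalLevels,
                    pmfs = lapply(ensemble@pmfs, .binPmf, w = w),
                    samples = list(), replicates = ensemble@replicates,
                    output = ensemble@output)
  }
  M <- .conditionalMatrix(ensemble)
  n <- nrow(M)
  if (n < 1L) stop("empty ensemble")
  po <- colMeans(M)                       # marginal under the uniform prior
  I <- 0
  for (i in seq_len(n)) {
    nz <- M[i, ] > 0
    I <- I + sum(M[i, nz] / n * log2(M[i, nz] / po[nz]))
  }
  max(I, 0)
})

## Mean and variance of each conditional pmf.
.pmfMoments <- function(pmf) {
  o <- as.numeric(names(pmf))
  m <- sum(o * pmf)
  c(mean = m, var = sum(o^2 * pmf) - m^2)
}

#' Average Fano-factor noise
#'
#' The variance over mean of each conditional response distribution,
#' averaged over the `n` signal levels.  A level whose output is exactly
#' zero in every replicate (mean 0, variance 0) contributes 0; a zero
#' mean with non-zero variance is impossible for non-negative counts and
#' raises an error.
#'
#' @param ensemble a [ResponseEnsemble-class].
#' @param ... unused.
#' @return Dimensionless average Fano factor (>= 0).
#' @rdname averageFano
#' @export
setMethod("averageFano", "ResponseEnsemble", function(ensemble, ...) {
  terms <- vapply(ensemble@pmfs, function(p) {
    mo <- .pmfMoments(p)
    if (mo["mean"] == 0) {
      if (mo["var"] > 1e-12)
        stop("zero conditional mean with non-zero variance")
      return(0)
    }
    unname(mo["var"] / mo["mean"])
  }, numeric(1L))
  mean(terms)
})

#' Output range
#'
#' Difference between the largest and smallest conditional mean response
#' across signal levels.
#'
#' @param ensemble a [ResponseEnsemble-class].
#' @param ... unused.
#' @return Output range in counts (>= 0; 0 for a single level).
#' @rdname outputRange
#' @export
setMethod("outputRange", "ResponseEnsemble", function(ensemble, ...) {
  means <- vapply(ensemble@pmfs,
                  function(p) unname(.pmfMoments(p)["mean"]), numeric(1L))
  max(means) - min(means)
})

#' All three summary metrics of an ensemble
#'
#' @param ensemble a [ResponseEnsemble-class].
#' @param ... unused.
#' @return Named numeric: `information` (bits), `noise` (average Fano
#'   factor), `outputRange` (counts).
#' @rdname ensembleMetrics
#' @param binWidth passed to [mutualInformation()]; the Fano factor and
#'   output range always use the unbinned counts.
#' @export
setMethod("ensembleMetrics", "ResponseEnsemble",
          function(ensemble, binWidth = "auto", ...) {
  c(information = mutualInformation(ensemble, binWidth = binWidth),
    noise = averageFano(ensemble),
    outputRange = outputRange(ensemble))
})

#' Normalize a series by its maximum
#'
#' @param values numeric vector (>= 0).
#' @return `values / max(values)`, or all zeros when the series is all
#'   zero (documented convention).
#' @export
#' @examples
#' normalizeSeries(c(1, 2, 4))  # 0.25 0.50 1.00
normalizeSeries <- function(values) {
  m <- max(values)
  if (m <= 0) return(rep(0, length(values)))
  values / m
}

#' Write / read a ResponseEnsemble as TSV
#'
#' Columns: `signal_level`, `output_count`, `probability`, `replicates`.
#'
#' @param ensemble a [ResponseEnsemble-class].
#' @param path file path.
#' @return `writeEnsemble()` returns `path` invisibly; `readEnsemble()`
#'   returns the [ResponseEnsemble-class] (raw samples are not stored in
#'   the TSV).
#' @export
writeEnsemble <- function(ensemble, path) {
  rows <- do.call(rbind, lapply(seq_along(ensemble@pmfs), function(i) {
    p <- ensemble@pmfs[[i]]
    data.frame(signal_level = ensemble@signalLevels[i],
               output_count = as.integer(as.numeric(names(p))),
               probability = as.numeric(p),
               replicates = ensemble@replicates)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  levels <- sort(unique(tab$signal_level))
  pmfs <- lapply(levels, function(s) {
    sub <- tab[tab$signal_level == s, ]
    setNames(sub$probability, sub$output_count)
  })
  responseEnsemble(levels, pmfs = pmfs,
                   replicates = tab$replicates[1L])
}

#' @describeIn ResponseEnsemble-class compact display.
#' @param object a `ResponseEnsemble`.
#' @export
setMethod("show", "ResponseEnsemble", function(object) {
  cat(sprintf("ResponseEnsemble: %d signal levels, %d replicates each, output '%s'\n",
              length(object@signalLevels), object@replicates,
              object@output))
  m <- ensembleMetrics(object)
  cat(sprintf("  I = %.3f bits, noise = %.3f, output range = %.2f\n",
              m["information"], m["noise"], m["outputRange"]))
})
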