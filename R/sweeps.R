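## Orchestration of the affinity and concentration sweeps.

.BIO_KEQ_RANGE <- c(1e-13, 1e-4)  # sanity envelope around the printed
                                  # receptor-signal and TF-DNA rectangles

.warnKeqRange <- function(keqGrid) {
  if (any(keqGrid < .BIO_KEQ_RANGE[1L] | keqGrid > .BIO_KEQ_RANGE[2L]))
    warning("Keq grid extends beyond biologically typical affinities (",
            sprintf("%.0e..%.0e M)", .BIO_KEQ_RANGE[1L],
                    .BIO_KEQ_RANGE[2L]), call. = FALSE)
}

## Block-wise mutual-information standard error: split the replicates of
## every level into `blocks` interleaved groups, compute the plug-in MI of
## each group, and take sd/sqrt(blocks).
.blockInfoSE <- function(ensemble, blocks = 5L) {
  if (!length(ensemble@samples)) return(NA_real_)
  reps <- ensemble@replicates
  w <- .autoBinWidth(ensemble)  # one width for all blocks
  mi <- vapply(seq_len(blocks), function(b) {
    idx <- seq(b, reps, by = blocks)
    sub <- responseEnsemble(ensemble@signalLevels,
                            lapply(ensemble@samples, `[`, idx),
                            output = ensemble@output)
    mutualInformation(sub, binWidth = w)
  }, numeric(1L))
  sd(mi) / sqrt(blocks)
}

.normalizeColumns <- function(tab, group = NULL) {
  for (col in c("information", "noise", "outputRange")) {
    norm <- paste0(col, "Norm")
    if (is.null(group)) {
      tab[[norm]] <- normalizeSeries(tab[[col]])
    } else {
      tab[[norm]] <- NA_real_
      for (g in unique(tab[[group]])) {
        sel <- tab[[group]] == g
        tab[[norm]][sel] <- normalizeSeries(tab[[col]][sel])
      }
    }
  }
  tab
}

.newSweep <- function(tab, type, spec, seed, replicates, nLevels, tSample)
  new("SweepResult", table = tab, type = type, spec = spec,
      seed = as.integer(seed), replicates = as.integer(replicates),
      nLevels = as.integer(nLevels), tSample = tSample)

#' Affinity sweep
#'
#' Simulates the response ensemble of a model at every equilibrium
#' constant of `keqGrid` and records mutual information, average
#' Fano-factor noise and output range, raw and normalized by their
#' maxima over the grid.
#'
#' @param spec a [PathwayModel-class] template.
#' @param keqGrid equilibrium constants in molar (strictly monotone).
#' @param nLevels number of signal levels `n`.
#' @param replicates replicate simulations per level.
#' @param seed master seed; per-point seeds are derived from it.
#' @param step which binding step the grid applies to (default the
#'   first, `"bind"`).
#' @param tSample sampling horizon (seconds); `NA` = variant default.
#' @param blocks when > 0, also estimate a block-wise standard error of
#'   the information at every grid point (`informationSE` column).
#' @return A [SweepResult-class] with one row per grid point.
#' @export
#' @examples
#' sw <- affinitySweep(bindingModel(), keqGrid = c(1e-5, 1e-7, 1e-9),
#'                     nLevels = 4, replicates = 100, seed = 1)
#' sweepTable(sw)
affinitySweep <- function(spec, keqGrid, nLevels = 10L,
                          replicates = 1000L, seed = 1L, step = "bind",
                          tSample = NA_real_, blocks = 0L) {
  if (is.unsorted(keqGrid) && is.unsorted(rev(keqGrid)))
    stop("keqGrid must be monotone")
  .warnKeqRange(keqGrid)
  if (is.na(tSample)) tSample <- .defaultTSample(spec)
  seeds <- .deriveSeeds(seed, length(keqGrid))
  rows <- lapply(seq_along(keqGrid), function(i) {
    ens <- simulateResponse(setKeq(spec, keqGrid[i], step), nLevels,
                            replicates, seeds[i], tSample)
    m <- ensembleMetrics(ens)
    data.frame(Keq = keqGrid[i], information = m[["information"]],
               noise = m[["noise"]], outputRange = m[["outputRange"]],
               informationSE = if (blocks > 0L)
                 .blockInfoSE(ens, blocks) else NA_real_)
  })
  tab <- .normalizeColumns(do.call(rbind, rows))
  .newSweep(tab, "affinity", spec, seed, replicates, nLevels, tSample)
}

#' Receptor/signal-ratio by affinity grid
#'
#' Full factorial sweep of the binding model over receptor-to-signal
#' ratios `N_RT / N_Smax` and affinities.  For each ratio the receptor
#' total is `round(ratio * NSmax)` with `NSmax` fixed by the template.
#' Metrics are normalized over the whole grid.  Cells in which detection
#' can be perfect -- signal molecules not exceeding receptors at the
#' strongest affinity of the grid -- are flagged.
#'
#' @inheritParams affinitySweep
#' @param ratioGrid ratios `N_RT / N_Smax` (> 0).
#' @return A [SweepResult-class] with one row per `(ratio, Keq)` cell
#'   and a logical `perfectDetection` column.
#' @export
ratioAffinityGrid <- function(spec, ratioGrid, keqGrid, nLevels = 10L,
                              replicates = 1000L, seed = 1L,
                              tSample = NA_real_) {
  stopifnot(length(ratioGrid) >= 1L, length(keqGrid) >= 1L)
  .warnKeqRange(keqGrid)
  if (is.na(tSample)) tSample <- .defaultTSample(spec)
  cells <- expand.grid(ratio = ratioGrid, Keq = keqGrid,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- .deriveSeeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    nrt <- max(1L, as.integer(round(cells$ratio[i] * spec@NSmax)))
    sp <- spec; sp@receptors <- nrt
    sp <- setKeq(sp, cells$Keq[i], "bind")
    ens <- simulateResponse(sp, nLevels, replicates, seeds[i], tSample)
    m <- ensembleMetrics(ens)
    data.frame(ratio = cells$ratio[i], Keq = cells$Keq[i],
               NRT = nrt, information = m[["information"]],
               noise = m[["noise"]], outputRange = m[["outputRange"]])
  })
  tab <- .normalizeColumns(do.call(rbind, rows))
  tab$perfectDetection <- tab$NRT >= spec@NSmax & tab$Keq == min(keqGrid)
  .newSweep(tab, "ratioAffinity", spec, seed, replicates, nLevels, tSample)
}

#' Dual-affinity grid of the binding cascade
#'
#' Full factorial sweep of a cascade model over the receptor--signal
#' affinity (`Keq_RS`) and the complex--DNA affinity (`Keq_RSD`), with
#' the receptor-signal-DNA complex count as the output.  Metrics are
#' normalized over the whole grid.
#'
#' @inheritParams affinitySweep
#' @param keqBindGrid receptor--signal equilibrium constants (M).
#' @param keqDnaGrid complex--DNA equilibrium constants (M).
#' @return A [SweepResult-class] with one row per `(KeqBind, KeqDna)`
#'   cell.
#' @export
dualAffinityGrid <- function(spec, keqBindGrid, keqDnaGrid,
                             nLevels = 10L, replicates = 1000L,
                             seed = 1L, tSample = NA_real_) {
  if (spec@variant != "cascade")
    stop("dualAffinityGrid requires a cascade model")
  if (is.na(tSample)) tSample <- .defaultTSample(spec)
  cells <- expand.grid(KeqBind = keqBindGrid, KeqDna = keqDnaGrid,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- .deriveSeeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- setKeq(setKeq(spec, cells$KeqBind[i], "bind"),
                 cells$KeqDna[i], "dna")
    ens <- simulateResponse(sp, nLevels, replicates, seeds[i], tSample)
    m <- ensembleMetrics(ens)
    data.frame(KeqBind = cells$KeqBind[i], KeqDna = cells$KeqDna[i],
               information = m[["information"]], noise = m[["noise"]],
               outputRange = m[["outputRange"]])
  })
  tab <- .normalizeColumns(do.call(rbind, rows))
  .newSweep(tab, "dualAffinity", spec, seed, replicates, nLevels, tSample)
}

#' Extrinsic-noise experiment
#'
#' One affinity sweep of the polymerase gene-expression model per
#' extrinsic-noise level (the sd of the polymerase copy-number
#' distribution as a fraction of its mean; the copy number is redrawn
#' every replicate).  Metrics are normalized within each noise level's
#' sweep; a block-wise standard error of the information accompanies
#' every point.
#'
#' @inheritParams affinitySweep
#' @param sdFractions extrinsic-noise levels to compare.
#' @return A [SweepResult-class] with one row per `(sdFraction, Keq)`
#'   point; see [extrinsicSummary()] for the per-level maxima.
#' @export
extrinsicNoiseExperiment <- function(spec, keqGrid,
                                     sdFractions = c(0, 0.10, 0.30),
                                     nLevels = 10L, replicates = 1000L,
                                     seed = 1L, tSample = NA_real_) {
  if (spec@variant != "genePolymerase")
    stop("extrinsicNoiseExperiment requires a genePolymerase model")
  seeds <- .deriveSeeds(seed, length(sdFractions))
  tabs <- lapply(seq_along(sdFractions), function(i) {
    sw <- affinitySweep(setSdFraction(spec, sdFractions[i]), keqGrid,
                        nLevels, replicates, seeds[i],
                        tSample = tSample, blocks = 5L)
    cbind(sdFraction = sdFractions[i], sw@table)
  })
  tab <- do.call(rbind, tabs)
  tab <- .normalizeColumns(tab[setdiff(names(tab),
                                       grep("Norm$", names(tab),
                                            value = TRUE))],
                           group = "sdFraction")
  if (is.na(tSample)) tSample <- .defaultTSample(spec)
  .newSweep(tab, "extrinsicNoise", spec, seed, replicates, nLevels,
            tSample)
}

#' Maximal information per extrinsic-noise level
#'
#' @param sweep a [SweepResult-class] from [extrinsicNoiseExperiment()].
#' @return data.frame with one row per `sdFraction`: the
#'   information-maximizing `Keq`, the information there (bits) and its
#'   block-wise standard error.
#' @export
extrinsicSummary <- function(sweep) {
  if (sweep@type != "extrinsicNoise")
    stop("extrinsicSummary expects an extrinsicNoise sweep")
  tab <- sweep@table
  do.call(rbind, lapply(sort(unique(tab$sdFraction)), function(f) {
    sub <- tab[tab$sdFraction == f, ]
    i <- .argmaxWeakest(sub$information, sub$Keq)
    data.frame(sdFraction = f, Keq = sub$Keq[i],
               maxInformation = sub$information[i],
               informationSE = sub$informationSE[i])
  }))
}

## Index of the maximum; ties broken toward weaker affinity (larger Keq).
.argmaxWeakest <- function(values, keq) {
  idx <- which(values == max(values))
  idx[which.max(keq[idx])]
}

#' Information-maximizing grid point of a sweep
#'
#' Returns the grid point with maximal information; ties are broken
#' toward weaker affinity (larger `Keq`).
#'
#' @param sweep a [SweepResult-class] with a `Keq` column (an affinity
#'   sweep, or one noise level of an extrinsic-noise sweep).
#' @param sdFraction for extrinsic-noise sweeps, which noise level to
#'   inspect.
#' @param ... unused.
#' @return List with `index`, `Keq`, `information` (bits) and
#'   `noiseNorm` (normalized noise at the optimum).
#' @rdname findOptimum
#' @export
setMethod("findOptimum", "SweepResult",
  function(sweep, sdFraction = NULL, ...) {
    tab <- sweep@table
    if (!is.null(sdFraction)) tab <- tab[tab$sdFraction == sdFraction, ]
    if (!"Keq" %in% names(tab))
      stop("sweep has no Keq axis")
    if (nrow(tab) < 2L)
      stop("findOptimum needs at least 2 grid points")
    i <- .argmaxWeakest(tab$information, tab$Keq)
    list(index = i, Keq = tab$Keq[i], information = tab$information[i],
         noiseNorm = tab$noiseNorm[i])
  })

#' @rdname sweepTable
#' @param x a [SweepResult-class].
#' @return `sweepTable()`: the underlying data.frame.
#' @export
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' Write a sweep as TSV
#'
#' Provenance (variant, seed, replicates, levels, horizon) is written as
#' `#`-prefixed header lines above the table.
#'
#' @param x a [SweepResult-class].
#' @param path file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @rdname writeSweep
#' @export
setMethod("writeSweep", "SweepResult", function(x, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# signoise sweep type=%s variant=%s seed=%d replicates=%d nLevels=%d tSample=%g",
    x@type, x@spec@variant, x@seed, x@replicates, x@nLevels, x@tSample),
    con)
  write.table(format(x@table, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' @describeIn SweepResult-class compact display.
#' @param object a `SweepResult`.
#' @export
setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult '%s' (%s model): %d grid points\n",
              object@type, object@spec@variant, nrow(object@table)))
  cat(sprintf("  n = %d levels, %d replicates, tSample = %.5g s, seed = %d\n",
              object@nLevels, object@replicates, object@tSample,
              object@seed))
  print(head(object@table, 6L), digits = 4)
  if (nrow(object@table) > 6L) cat("  ...\n")
})

#' Run a sweep from a configuration file
#'
#' Executes one sweep described by a YAML (or pre-parsed list)
#' configuration with two blocks: `model` (a variant name plus any
#' constructor arguments of [bindingModel()] and friends) and `sweep`
#' (`type` among `affinity`, `ratioAffinity`, `dualAffinity`,
#' `extrinsicNoise`, plus the matching grid arguments, `nLevels`,
#' `replicates`, `seed`).  When `outDir` is given, the sweep table is
#' written to `<outDir>/sweep.tsv`.
#'
#' @param config path to a YAML file, or an equivalent list.
#' @param outDir optional output directory.
#' @param seed optional master-seed override.
#' @param replicates optional replicate-count override.
#' @return The [SweepResult-class], invisibly when `outDir` is given.
#' @export
runSweepConfig <- function(config, outDir = NULL, seed = NULL,
                           replicates = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mc <- config$model
  ctor <- switch(mc$variant,
                 binding = bindingModel, cascade = cascadeModel,
                 gene = geneModel, genePolymerase = genePolymeraseModel,
                 fullPathway = fullPathwayModel,
                 stop(sprintf("unknown model variant '%s'", mc$variant)))
  spec <- do.call(ctor, mc[setdiff(names(mc), "variant")])
  sc <- config$sweep
  sc$seed <- seed %||% sc$seed %||% 1L
  sc$replicates <- replicates %||% sc$replicates %||% 1000L
  sc$nLevels <- sc$nLevels %||% 10L
  sweep <- switch(sc$type,
    affinity = affinitySweep(spec, as.numeric(sc$keqGrid),
                             sc$nLevels, sc$replicates, sc$seed),
    ratioAffinity = ratioAffinityGrid(spec, as.numeric(sc$ratioGrid),
                                      as.numeric(sc$keqGrid),
                                      sc$nLevels, sc$replicates, sc$seed),
    dualAffinity = dualAffinityGrid(spec, as.numeric(sc$keqBindGrid),
                                    as.numeric(sc$keqDnaGrid),
                                    sc$nLevels, sc$replicates, sc$seed),
    extrinsicNoise = extrinsicNoiseExperiment(
      spec, as.numeric(sc$keqGrid),
      as.numeric(sc$sdFractions %||% c(0, 0.10, 0.30)),
      sc$nLevels, sc$replicates, sc$seed),
    stop(sprintf("unknown sweep type '%s'", sc$type)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSweep(sweep, file.path(outDir, "sweep.tsv"))
    return(invisible(sweep))
  }
  sweep
}
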