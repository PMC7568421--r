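#' Convert a molar concentration to a molecule count
#'
#' `N = c * V * N_Avogadro`.  The result is a real number; callers round
#' where an integer count is required.
#'
#' @param concentration concentration in molar (>= 0).
#' @param volume reaction volume in liters.
#' @return Real-valued molecule count.
#' @export
#' @examples
#' molarToCount(1e-8, receptorVolume())  # 10
#' molarToCount(1e-6, receptorVolume())  # 1000
molarToCount <- function(concentration, volume = receptorVolume()) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  concentration * volume * .AVOGADRO
}

#' Evenly spaced signal levels
#'
#' The `n` integer signal levels `round(i * NSmax / n)`, `i = 1..n`,
#' evenly distributed within `[NSmax/n, NSmax]`.
#'
#' @param NSmax maximal number of signal molecules.
#' @param n number of levels (`1 <= n <= NSmax`).
#' @return Strictly increasing integer vector of length `n`.
#' @export
#' @examples
#' signalGrid(1000, 10)
#' signalGrid(8, 8)
signalGrid <- function(NSmax, n) {
  NSmax <- as.integer(NSmax); n <- as.integer(n)
  if (n < 1L || n > NSmax)
    stop("n must satisfy 1 <= n <= NSmax")
  g <- as.integer(round(seq_len(n) * NSmax / n))
  if (any(diff(g) <= 0L))
    stop("signal grid is not strictly increasing")  # unreachable for n <= NSmax
  g
}

#' Expected number of complexes at equilibrium
#'
#' `Nhat_C = N_BT * N_signal / (Keq_count + N_signal)`, clamped so that
#' the expected complex count never exceeds the available signal
#' molecules.  For a single binding site (`N_BT = 1`) this is the
#' occupancy probability of the site.
#'
#' @param NBT total receptors or DNA binding sites.
#' @param Nsignal number of signal (or TF) molecules.
#' @param KeqCount equilibrium constant in count units (see
#'   [molarToCount()]).
#' @return Real-valued expected complex count.
#' @export
#' @examples
#' expectedComplexes(10, 100, 100)   # 5: half occupancy at N_S = Keq
#' expectedComplexes(1, 100, 100)    # 0.5: site occupancy probability
expectedComplexes <- function(NBT, Nsignal, KeqCount) {
  if (any(c(NBT, Nsignal, KeqCount) < 0))
    stop("all arguments must be >= 0")
  if (KeqCount + Nsignal == 0) return(0)
  min(NBT * Nsignal / (KeqCount + Nsignal), Nsignal)
}

#' Draw a polymerase copy number
#'
#' With `sdFraction = 0` the draw is deterministic (`round(mean)`, no
#' extrinsic noise).  Otherwise the count is negative binomial with the
#' given mean `m` and variance `(sdFraction * m)^2`, parameterized by
#' `size = m^2 / (var - m)`; over-dispersion (`var > m`) is required.
#'
#' @param mean mean polymerase copy number (> 0).
#' @param sdFraction standard deviation as a fraction of the mean.
#' @return A single integer count.
#' @export
#' @examples
#' samplePolymeraseCount(10000, 0)      # always 10000
#' set.seed(1); samplePolymeraseCount(10000, 0.1)
samplePolymeraseCount <- function(mean, sdFraction) {
  if (mean <= 0) stop("mean must be > 0")
  if (sdFraction < 0) stop("sdFraction must be >= 0")
  if (sdFraction == 0) return(as.integer(round(mean)))
  v <- (sdFraction * mean)^2
  if (v <= mean)
    stop(sprintf(paste0("negative binomial requires variance > mean: ",
                        "sdFraction must exceed 1/sqrt(mean) = %.4g"),
                 1 / sqrt(mean)))
  size <- mean^2 / (v - mean)
  as.integer(rnbinom(1L, size = size, mu = mean))
}

## ---- model constructors -------------------------------------------------

.defaultRates <- function(k1 = 0.02, k2 = 0.1,
                          d1 = log(2) / 600, d2 = log(2) / 3600)
  c(k1 = k1, k2 = k2, d1 = d1, d2 = d2)

.newModel <- function(variant, receptors = 0L, sites = 0L, NSmax,
                      Keq, kd, rates = numeric(), polymerase = list(),
                      volume, tSample = NA_real_) {
  new("PathwayModel", variant = variant,
      receptors = as.integer(receptors), sites = as.integer(sites),
      NSmax = as.integer(NSmax), Keq = Keq, kd = kd, rates = rates,
      polymerase = polymerase, volume = volume, tSample = tSample)
}

#' Model constructors
#'
#' Build a [PathwayModel-class] for one of the five variants with
#' field-typical defaults: receptor concentration `1e-8` M (10 molecules),
#' maximal signal `1e-6` M (1000 molecules), dissociation rates fixed
#' (`0.01` s^-1 receptor--signal, `0.001` s^-1 for DNA-binding steps, a
#' residence time inside the 10 s -- 2 h interval typical of TF--DNA
#' binding) so that the association rate of each step is `kd/Keq`;
#' transcription `k1 = 0.02` s^-1, translation `k2 = 0.1` s^-1
#' (`k2/k1 = 5`), mRNA half-life 10 min and protein half-life 1 h.
#'
#' @param receptors total receptor molecules `N_RT`.
#' @param sites number of DNA binding sites `B` (1--10).
#' @param NSmax maximal signal (or TF) copy number.
#' @param Keq equilibrium constant(s) in molar; for multi-step models a
#'   named vector with entries `bind` (first step) and `dna` or `pol`.
#' @param kd dissociation rate(s) in s^-1, named like `Keq`.
#' @param k1,k2,d1,d2 transcription, translation, mRNA- and protein-decay
#'   rates (s^-1).
#' @param meanFactor polymerase mean copy number as a multiple of `NSmax`.
#' @param sdFraction polymerase extrinsic-noise level: the sd of the
#'   negative binomial copy-number distribution as a fraction of its mean
#'   (0 = no extrinsic noise).
#' @param volume reaction volume in liters ([receptorVolume()] for
#'   receptor-ligand models, [geneVolume()] for TF--DNA models).
#' @param tSample sampling horizon in seconds; `NA` selects the variant
#'   default (20/kd for pure binding, 10/min(d1, d2) for gene expression).
#' @return A validated [PathwayModel-class].
#' @seealso [buildModel()], [initialState()], [simulateResponse()]
#' @export
#' @examples
#' bindingModel(Keq = 1e-7)
#' geneModel(Keq = 1e-11)
bindingModel <- function(receptors = 10L, NSmax = 1000L, Keq = 1e-7,
                         kd = 0.01, volume = receptorVolume(),
                         tSample = NA_real_) {
  .newModel("binding", receptors = receptors, NSmax = NSmax,
            Keq = c(bind = unname(Keq)), kd = c(bind = unname(kd)),
            volume = volume, tSample = tSample)
}

#' @rdname bindingModel
#' @param KeqDna,kdDna equilibrium constant (M) and dissociation rate
#'   (s^-1) of the complex--DNA binding step.
#' @export
cascadeModel <- function(receptors = 10L, sites = 1L, NSmax = 1000L,
                         Keq = 1e-7, kd = 0.01,
                         KeqDna = 1e-9, kdDna = 0.001,
                         volume = receptorVolume(), tSample = NA_real_) {
  .newModel("cascade", receptors = receptors, sites = sites, NSmax = NSmax,
            Keq = c(bind = unname(Keq), dna = unname(KeqDna)),
            kd = c(bind = unname(kd), dna = unname(kdDna)),
            volume = volume, tSample = tSample)
}

#' @rdname bindingModel
#' @export
geneModel <- function(sites = 1L, NSmax = 1000L, Keq = 1e-11, kd = 0.001,
                      k1 = 0.02, k2 = 0.1,
                      d1 = log(2) / 600, d2 = log(2) / 3600,
                      volume = geneVolume(), tSample = NA_real_) {
  .newModel("gene", sites = sites, NSmax = NSmax,
            Keq = c(bind = unname(Keq)), kd = c(bind = unname(kd)),
            rates = .defaultRates(k1, k2, d1, d2),
            volume = volume, tSample = tSample)
}

#' @rdname bindingModel
#' @param KeqPol,kdPol equilibrium constant (M) and dissociation rate
#'   (s^-1) of polymerase--DNA binding: affinity `1e-9` M, and a
#'   seconds-scale residence time (`kdPol = 0.1` s^-1, i.e. 10 s) --
#'   polymerase turns over at a promoter far faster than a TF does.
#' @export
genePolymeraseModel <- function(sites = 1L, NSmax = 1000L,
                                Keq = 1e-11, kd = 0.001,
                                KeqPol = 1e-9, kdPol = 0.1,
                                k1 = 0.02, k2 = 0.1,
                                d1 = log(2) / 600, d2 = log(2) / 3600,
                                meanFactor = 10, sdFraction = 0,
                                volume = geneVolume(),
                                tSample = NA_real_) {
  .newModel("genePolymerase", sites = sites, NSmax = NSmax,
            Keq = c(bind = unname(Keq), pol = unname(KeqPol)),
            kd = c(bind = unname(kd), pol = unname(kdPol)),
            rates = .defaultRates(k1, k2, d1, d2),
            polymerase = list(meanFactor = meanFactor,
                              sdFraction = sdFraction),
            volume = volume, tSample = tSample)
}

#' @rdname bindingModel
#' @export
fullPathwayModel <- function(receptors = 10L, sites = 1L, NSmax = 1000L,
                             Keq = 1e-7, kd = 0.01,
                             KeqDna = 1e-9, kdDna = 0.001,
                             k1 = 0.02, k2 = 0.1,
                             d1 = log(2) / 600, d2 = log(2) / 3600,
                             volume = receptorVolume(),
                             tSample = NA_real_) {
  .newModel("fullPathway", receptors = receptors, sites = sites,
            NSmax = NSmax,
            Keq = c(bind = unname(Keq), dna = unname(KeqDna)),
            kd = c(bind = unname(kd), dna = unname(kdDna)),
            rates = .defaultRates(k1, k2, d1, d2),
            volume = volume, tSample = tSample)
}

#' Replace an equilibrium constant of a model
#'
#' @param spec a [PathwayModel-class].
#' @param Keq new equilibrium constant in molar.
#' @param step which binding step to modify (`"bind"`, `"dna"` or
#'   `"pol"`).
#' @return The modified model.
#' @export
setKeq <- function(spec, Keq, step = "bind") {
  if (!step %in% names(spec@Keq))
    stop(sprintf("model has no binding step '%s'", step))
  spec@Keq[step] <- Keq
  validObject(spec)
  spec
}

#' @rdname setKeq
#' @param sdFraction new polymerase extrinsic-noise level.
#' @export
setSdFraction <- function(spec, sdFraction) {
  if (spec@variant != "genePolymerase")
    stop("sdFraction applies only to genePolymerase models")
  spec@polymerase$sdFraction <- sdFraction
  validObject(spec)
  spec
}

## Default sampling horizon: >= 20 relaxation times of the slowest process.
.defaultTSample <- function(spec) {
  if (!is.na(spec@tSample)) return(spec@tSample)
  switch(spec@variant,
    binding = , cascade = 20 / min(spec@kd),
    10 / min(spec@rates[c("d1", "d2")]))
}

## Association rate (M^-1 s^-1) of a named binding step.
.ka <- function(spec, step) unname(spec@kd[step] / spec@Keq[step])

## Keq in count units for a named step.
.keqCount <- function(spec, step)
  molarToCount(unname(spec@Keq[step]), spec@volume)

#' Build the reaction system of a model at a signal level
#'
#' Instantiates the [ReactionSystem-class] of a [PathwayModel-class] for a
#' given number of signal (or TF) molecules `NS`, including the declared
#' conserved sums.  For a single DNA binding site the transcription
#' propensity uses the indicator form (`k1` while the site is bound, 0
#' otherwise); for `B > 1` sites, the `B` sites are an indistinguishable
#' count species and transcription is proportional to the bound-site
#' count.
#'
#' @param spec a [PathwayModel-class].
#' @param NS number of signal (or TF) molecules for this system.
#' @param ... unused.
#' @return A [ReactionSystem-class]; species counts are the deterministic
#'   skeleton (free molecules at their totals) -- use [initialState()] for
#'   near-equilibrium starting states.
#' @export
#' @rdname buildModel
#' @examples
#' buildModel(bindingModel(), NS = 100)
setMethod("buildModel", "PathwayModel", function(spec, NS, ...) {
  NS <- as.integer(NS)
  if (NS < 0L) stop("NS must be >= 0")
  B <- spec@sites
  r <- spec@rates
  condOrLinear <- function(gate, rate)
    if (B == 1L) reaction("conditional-synthesis", rate, gate, "mR",
                          change = c(mR = 1))
    else reaction("first-order-synthesis", rate, gate, "mR",
                  change = c(mR = 1))
  geneReactions <- function(gate) list(
    condOrLinear(gate, r[["k1"]]),
    reaction("first-order-decay", r[["d1"]], "mR", character()),
    reaction("first-order-synthesis", r[["k2"]], "mR", "P",
             change = c(P = 1)),
    reaction("first-order-decay", r[["d2"]], "P", character()))

  switch(spec@variant,
    binding = reactionSystem(
      c(S = NS, R = spec@receptors, RS = 0L),
      list(reaction("association", .ka(spec, "bind"), c("S", "R"), "RS"),
           reaction("dissociation", spec@kd[["bind"]], "RS", c("S", "R"))),
      volume = spec@volume,
      conserved = list(c("S", "RS"), c("R", "RS")),
      output = "RS"),
    cascade = reactionSystem(
      c(S = NS, R = spec@receptors, RS = 0L, D = B, RSD = 0L),
      list(reaction("association", .ka(spec, "bind"), c("S", "R"), "RS"),
           reaction("dissociation", spec@kd[["bind"]], "RS", c("S", "R")),
           reaction("association", .ka(spec, "dna"), c("RS", "D"), "RSD"),
           reaction("dissociation", spec@kd[["dna"]], "RSD", c("RS", "D"))),
      volume = spec@volume,
      conserved = list(c("S", "RS", "RSD"), c("R", "RS", "RSD"),
                       c("D", "RSD")),
      output = "RSD"),
    gene = reactionSystem(
      c(TF = NS, DNAbs = B, TFD = 0L, mR = 0L, P = 0L),
      c(list(reaction("association", .ka(spec, "bind"), c("TF", "DNAbs"),
                      "TFD"),
             reaction("dissociation", spec@kd[["bind"]], "TFD",
                      c("TF", "DNAbs"))),
        geneReactions("TFD")),
      volume = spec@volume,
      conserved = list(c("TF", "TFD"), c("DNAbs", "TFD")),
      output = "P"),
    genePolymerase = {
      npol <- as.integer(round(spec@polymerase$meanFactor * spec@NSmax))
      reactionSystem(
        c(TF = NS, DNAbs = B, TFD = 0L, Pol = npol, TFPD = 0L,
          mR = 0L, P = 0L),
        c(list(
          reaction("association", .ka(spec, "bind"), c("TF", "DNAbs"),
                   "TFD"),
          reaction("dissociation", spec@kd[["bind"]], "TFD",
                   c("TF", "DNAbs")),
          reaction("association", .ka(spec, "pol"), c("Pol", "TFD"),
                   "TFPD"),
          reaction("dissociation", spec@kd[["pol"]], "TFPD",
                   c("TFD", "Pol")),
          ## TF unbinding evicts the polymerase as well
          reaction("dissociation", spec@kd[["bind"]], "TFPD",
                   c("TF", "DNAbs", "Pol"))),
          geneReactions("TFPD")),
        volume = spec@volume,
        conserved = list(c("TF", "TFD", "TFPD"),
                         c("DNAbs", "TFD", "TFPD"),
                         c("Pol", "TFPD")),
        output = "P")
    },
    fullPathway = reactionSystem(
      c(S = NS, R = spec@receptors, RS = 0L, DNAbs = B, RSD = 0L,
        mR = 0L, P = 0L),
      c(list(reaction("association", .ka(spec, "bind"), c("S", "R"), "RS"),
             reaction("dissociation", spec@kd[["bind"]], "RS",
                      c("S", "R")),
             reaction("association", .ka(spec, "dna"), c("RS", "DNAbs"),
                      "RSD"),
             reaction("dissociation", spec@kd[["dna"]], "RSD",
                      c("RS", "DNAbs"))),
        geneReactions("RSD")),
      volume = spec@volume,
      conserved = list(c("S", "RS", "RSD"), c("R", "RS", "RSD"),
                       c("DNAbs", "RSD")),
      output = "P"),
    stop(sprintf("unknown variant '%s'", spec@variant)))
})

#' Near-equilibrium initial state of a model
#'
#' Implements the equilibrium-expectation initialization: the expected
#' complex count `Nhat_C` (see [expectedComplexes()]) determines the
#' starting complexes -- the nearest integer for receptor--signal binding,
#' a Bernoulli draw per DNA binding site -- and free molecules are the
#' totals minus the complexes.  mRNA and protein start at the nearest
#' integers of `Nhat_C * k1/d1` and `Nhat_C * (k1/d1) * (k2/d2)`.  For the
#' polymerase model the polymerase copy number is drawn via
#' [samplePolymeraseCount()] (redraw per replicate = extrinsic noise) and
#' polymerase occupancy of TF-bound sites is initialized at its
#' conditional equilibrium.
#'
#' The returned state is stochastic for all DNA-site variants; callers
#' re-invoke it per replicate under their own RNG stream.
#'
#' @param spec a [PathwayModel-class].
#' @param NS number of signal (or TF) molecules.
#' @param ... unused.
#' @return Named integer vector matching the species of
#'   `buildModel(spec, NS)`.
#' @export
#' @rdname initialState
#' @examples
#' initialState(bindingModel(Keq = 1e-7), NS = 100)  # Nhat_C = 5
setMethod("initialState", "PathwayModel", function(spec, NS, ...) {
  NS <- as.integer(NS)
  B <- spec@sites
  r <- spec@rates
  mrnaProtein <- function(nhat) {
    c(mR = as.integer(round(nhat * r[["k1"]] / r[["d1"]])),
      P = as.integer(round(nhat * r[["k1"]] / r[["d1"]] *
                             r[["k2"]] / r[["d2"]])))
  }
  switch(spec@variant,
    binding = {
      nhat <- expectedComplexes(spec@receptors, NS, .keqCount(spec, "bind"))
      nc <- as.integer(round(nhat))
      c(S = NS - nc, R = spec@receptors - nc, RS = nc)
    },
    cascade = {
      nhat1 <- expectedComplexes(spec@receptors, NS,
                                 .keqCount(spec, "bind"))
      nc1 <- as.integer(round(nhat1))
      p2 <- if (nhat1 > 0)
        expectedComplexes(1, nhat1, .keqCount(spec, "dna")) else 0
      nc2 <- min(rbinom(1L, B, p2), nc1)
      c(S = NS - nc1, R = spec@receptors - nc1, RS = nc1 - nc2,
        D = B - nc2, RSD = nc2)
    },
    gene = {
      p <- expectedComplexes(1, NS, .keqCount(spec, "bind"))
      nc <- min(rbinom(1L, B, p), NS)  # bound sites cannot exceed TFs
      c(c(TF = NS - nc, DNAbs = B - nc, TFD = nc),
        mrnaProtein(min(B * p, NS)))
    },
    genePolymerase = {
      p <- expectedComplexes(1, NS, .keqCount(spec, "bind"))
      nc <- min(rbinom(1L, B, p), NS)
      npol <- samplePolymeraseCount(
        spec@polymerase$meanFactor * spec@NSmax,
        spec@polymerase$sdFraction)
      pP <- expectedComplexes(1, npol, .keqCount(spec, "pol"))
      ncp <- min(rbinom(1L, nc, pP), npol)
      c(c(TF = NS - nc, DNAbs = B - nc, TFD = nc - ncp,
          Pol = npol - ncp, TFPD = ncp),
        mrnaProtein(min(B * p, NS) * pP))
    },
    fullPathway = {
      nhat1 <- expectedComplexes(spec@receptors, NS,
                                 .keqCount(spec, "bind"))
      nc1 <- as.integer(round(nhat1))
      p2 <- if (nhat1 > 0)
        expectedComplexes(1, nhat1, .keqCount(spec, "dna")) else 0
      nc2 <- min(rbinom(1L, B, p2), nc1)
      c(c(S = NS - nc1, R = spec@receptors - nc1, RS = nc1 - nc2,
          DNAbs = B - nc2, RSD = nc2),
        mrnaProtein(min(B * p2, nhat1)))
    },
    stop(sprintf("unknown variant '%s'", spec@variant)))
})

#' The output species of a model
#'
#' @param spec a [PathwayModel-class].
#' @return Species name read out as the response (`RS`, `RSD` or `P`).
#' @export
outputSpecies <- function(spec) {
  switch(spec@variant, binding = "RS", cascade = "RSD", "P")
}

#' @describeIn PathwayModel-class compact display.
#' @param object a `PathwayModel`.
#' @export
setMethod("show", "PathwayModel", function(object) {
  cat(sprintf("PathwayModel '%s'\n", object@variant))
  if (object@variant %in% c("binding", "cascade", "fullPathway"))
    cat(sprintf("  receptors N_RT = %d\n", object@receptors))
  if (object@sites > 0L)
    cat(sprintf("  DNA binding sites B = %d\n", object@sites))
  cat(sprintf("  NSmax = %d molecules; V = %.4g L\n", object@NSmax,
              object@volume))
  cat(sprintf("  Keq (M): %s\n",
              paste(sprintf("%s = %.3g", names(object@Keq), object@Keq),
                    collapse = ", ")))
  if (length(object@rates))
    cat(sprintf("  rates (s^-1): %s\n",
                paste(sprintf("%s = %.3g", names(object@rates),
                              object@rates), collapse = ", ")))
  if (length(object@polymerase))
    cat(sprintf("  polymerase: mean = %g x NSmax, sdFraction = %g\n",
                object@polymerase$meanFactor,
                object@polymerase$sdFraction))
  cat(sprintf("  output: %s; tSample = %.5g s\n", outputSpecies(object),
              .defaultTSample(object)))
})
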