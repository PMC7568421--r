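## S4 classes.  Counts are stored as named integer vectors; rates carry the
## units of their reaction kind (association M^-1 s^-1, all others s^-1).

.REACTION_KINDS <- c("association", "dissociation", "conditional-synthesis",
                     "first-order-synthesis", "first-order-decay")

#' Reaction: one elementary reaction channel
#'
#' A single reaction of a [ReactionSystem-class].  `kind` selects the
#' propensity form:
#' \describe{
#'   \item{`association`}{two reactants, propensity
#'     `rate/(V*N_Avogadro) * N_a * N_b` (rate in M^-1 s^-1);}
#'   \item{`dissociation`, `first-order-decay`}{one reactant, propensity
#'     `rate * N` (rate in s^-1);}
#'   \item{`first-order-synthesis`}{one template species (not consumed),
#'     propensity `rate * N_template`;}
#'   \item{`conditional-synthesis`}{propensity `rate` while the gating
#'     complex count is at least 1, and 0 otherwise (the single
#'     binding-site reduction of occupancy-driven transcription).}
#' }
#' `change` is the (sparse, named) stoichiometric change applied when the
#' reaction fires.
#'
#' @slot kind character, one of the kinds above.
#' @slot rate non-negative rate constant.
#' @slot reactants character vector of reactant species names.
#' @slot products character vector of product species names.
#' @slot change named numeric of integer-valued stoichiometry changes.
#' @export
setClass("Reaction",
  representation(kind = "character", rate = "numeric",
                 reactants = "character", products = "character",
                 change = "numeric"))

setValidity("Reaction", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .REACTION_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.REACTION_KINDS, collapse = ", ")))
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate < 0)
    msg <- c(msg, "rate must be a single finite non-negative number")
  if (identical(object@kind, "association") && length(object@reactants) != 2L)
    msg <- c(msg, "association reactions need exactly two reactant species")
  if (object@kind %in% c("dissociation", "first-order-decay",
                         "first-order-synthesis", "conditional-synthesis") &&
      length(object@reactants) != 1L)
    msg <- c(msg, "first-order reactions need exactly one reactant species")
  if (is.null(names(object@change)) || any(names(object@change) == ""))
    msg <- c(msg, "change must be a fully named vector")
  if (any(object@change != round(object@change)))
    msg <- c(msg, "change entries must be integer-valued")
  if (length(msg)) msg else TRUE
})

#' ReactionSystem: a discrete-count reaction network
#'
#' A well-stirred, constant-volume system of named integer species counts
#' and [Reaction-class] channels, with declared conserved sums (e.g. free
#' receptor + complex = total receptors) that must hold after every event.
#'
#' @slot species named integer vector of initial/reference counts.
#' @slot reactions list of [Reaction-class] objects.
#' @slot volume reaction volume in liters.
#' @slot conserved list of character vectors; each names a set of species
#'   whose summed count is invariant under every reaction.
#' @slot output name of the species read out as the system response.
#' @seealso [reactionSystem()], [propensities()], [gillespieStep()],
#'   [sampleEndpoints()]
#' @export
setClass("ReactionSystem",
  representation(species = "integer", reactions = "list",
                 volume = "numeric", conserved = "list",
                 output = "character"))

setValidity("ReactionSystem", function(object) {
  msg <- character()
  sp <- object@species
  if (is.null(names(sp)) || anyDuplicated(names(sp)))
    msg <- c(msg, "species must be uniquely named")
  if (any(is.na(sp)) || any(sp < 0L))
    msg <- c(msg, "species counts must be non-negative integers")
  if (length(object@volume) != 1L || !is.finite(object@volume) ||
      object@volume <= 0)
    msg <- c(msg, "volume must be a single positive number (liters)")
  for (r in object@reactions) {
    if (!is(r, "Reaction")) { msg <- c(msg, "reactions must be Reaction objects"); break }
    bad <- setdiff(c(r@reactants, names(r@change)), names(sp))
    if (length(bad)) msg <- c(msg, sprintf("unknown species: %s",
                                           paste(bad, collapse = ", ")))
    dz <- r@change
    for (grp in object@conserved)
      if (sum(dz[intersect(names(dz), grp)]) != 0)
        msg <- c(msg, sprintf("reaction '%s' breaks conserved sum {%s}",
                              r@kind, paste(grp, collapse = "+")))
  }
  if (length(object@output) != 1L || !object@output %in% names(sp))
    msg <- c(msg, "output must name one species")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: replicate-sampling settings
#'
#' @slot tSample horizon (seconds) at which the endpoint state is recorded.
#' @slot seed master integer seed; per-replicate streams are derived from
#'   it deterministically.
#' @slot replicates number of replicate simulations.
#' @export
setClass("SimulationConfig",
  representation(tSample = "numeric", seed = "integer",
                 replicates = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@tSample) != 1L || !is.finite(object@tSample) ||
      object@tSample <= 0)
    msg <- c(msg, "tSample must be a single positive number of seconds")
  if (length(object@replicates) != 1L || is.na(object@replicates) ||
      object@replicates < 1L)
    msg <- c(msg, "replicates must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' PathwayModel: one of the five signaling model variants
#'
#' A parameterized model specification from which a concrete
#' [ReactionSystem-class] is built per signal level.  Variants:
#' \describe{
#'   \item{`binding`}{reversible receptor--signal binding, output `RS`;}
#'   \item{`cascade`}{receptor--signal binding followed by binding of the
#'     complex to a downstream DNA site, output `RSD`;}
#'   \item{`gene`}{TF--DNA binding driving mRNA transcription and protein
#'     translation with first-order decay, output `P`;}
#'   \item{`genePolymerase`}{the gene model with an explicit polymerase
#'     that binds only TF-bound DNA; the polymerase copy number is redrawn
#'     per replicate from a negative binomial (extrinsic noise), output `P`;}
#'   \item{`fullPathway`}{signal, receptor, DNA site and gene expression
#'     assembled into one linear pathway, output `P`.}
#' }
#'
#' @slot variant model variant name.
#' @slot receptors total receptors `N_RT` (used by `binding`, `cascade`
#'   and `fullPathway`).
#' @slot sites number of DNA binding sites `B` (used by `cascade`, `gene`,
#'   `genePolymerase` and `fullPathway`; 0 when unused).
#' @slot NSmax maximal number of signal (or TF) molecules.
#' @slot Keq named numeric of equilibrium constants in molar; names among
#'   `bind` (first/only binding step), `dna` (complex--DNA step) and
#'   `pol` (polymerase--DNA step).
#' @slot kd named numeric of dissociation rates (s^-1) matching `Keq`;
#'   the association rate of each step is `kd/Keq`.
#' @slot rates named numeric with `k1` (transcription), `d1` (mRNA decay),
#'   `k2` (translation), `d2` (protein decay), all s^-1, where applicable.
#' @slot polymerase list with `meanFactor` (mean polymerase copies as a
#'   multiple of `NSmax`) and `sdFraction` (sd of the negative binomial as
#'   a fraction of its mean; 0 disables extrinsic noise).
#' @slot volume reaction volume in liters.
#' @slot tSample sampling horizon (seconds); `NA` means the variant
#'   default (20/kd for pure binding models, 10/min(d1, d2) for
#'   gene-expression models).
#' @seealso [bindingModel()], [cascadeModel()], [geneModel()],
#'   [genePolymeraseModel()], [fullPathwayModel()], [buildModel()],
#'   [initialState()]
#' @export
setClass("PathwayModel",
  representation(variant = "character", receptors = "integer",
                 sites = "integer", NSmax = "integer",
                 Keq = "numeric", kd = "numeric",
                 rates = "numeric", polymerase = "list",
                 volume = "numeric", tSample = "numeric"))

.MODEL_VARIANTS <- c("binding", "cascade", "gene", "genePolymerase",
                     "fullPathway")

setValidity("PathwayModel", function(object) {
  msg <- character()
  if (length(object@variant) != 1L || !object@variant %in% .MODEL_VARIANTS)
    msg <- c(msg, sprintf("variant must be one of: %s",
                          paste(.MODEL_VARIANTS, collapse = ", ")))
  if (object@variant %in% c("binding", "cascade", "fullPathway") &&
      object@receptors < 1L)
    msg <- c(msg, "receptors (N_RT) must be >= 1")
  if (object@variant %in% c("cascade", "gene", "genePolymerase",
                            "fullPathway") &&
      !(object@sites >= 1L && object@sites <= 10L))
    msg <- c(msg, "number of DNA binding sites B must lie in [1, 10]")
  if (object@NSmax < 1L)
    msg <- c(msg, "NSmax must be >= 1")
  if (any(object@Keq <= 0) || any(!is.finite(object@Keq)))
    msg <- c(msg, "Keq values must be positive and finite (molar)")
  if (any(object@kd <= 0))
    msg <- c(msg, "kd values must be positive (s^-1)")
  if (!all(names(object@Keq) %in% names(object@kd)))
    msg <- c(msg, "every Keq entry needs a matching kd entry")
  if (length(object@rates) && any(object@rates < 0))
    msg <- c(msg, "rates must be non-negative")
  if (length(object@polymerase)) {
    sdf <- object@polymerase$sdFraction
    if (is.null(sdf) || sdf < 0)
      msg <- c(msg, "polymerase$sdFraction must be >= 0")
  }
  if (length(object@volume) != 1L || object@volume <= 0)
    msg <- c(msg, "volume must be positive (liters)")
  if (length(msg)) msg else TRUE
})

#' ResponseEnsemble: per-signal-level response distributions
#'
#' Empirical conditional distributions `Pr(N_O | S = N_S)` of the output
#' count for each simulated signal level, the raw endpoint samples they
#' were estimated from, and the replicate count.
#'
#' @slot signalLevels integer vector of the `n` signal levels.
#' @slot pmfs list of named numeric vectors, one per level; names are the
#'   integer output counts, values the empirical probabilities (sum 1).
#' @slot samples list of integer vectors of raw per-replicate endpoint
#'   output counts (may be empty lists if constructed from probabilities).
#' @slot replicates replicates per level.
#' @slot output name of the output species.
#' @seealso [responseEnsemble()], [mutualInformation()], [averageFano()],
#'   [outputRange()]
#' @export
setClass("ResponseEnsemble",
  representation(signalLevels = "integer", pmfs = "list",
                 samples = "list", replicates = "integer",
                 output = "character"))

setValidity("ResponseEnsemble", function(object) {
  msg <- character()
  n <- length(object@signalLevels)
  if (n < 1L) msg <- c(msg, "at least one signal level is required")
  if (length(object@pmfs) != n)
    msg <- c(msg, "one pmf per signal level is required")
  for (p in object@pmfs) {
    if (abs(sum(p) - 1) > 1e-12)
      msg <- c(msg, "each pmf must sum to 1 (within 1e-12)")
    o <- suppressWarnings(as.numeric(names(p)))
    if (any(is.na(o)) || any(o < 0) || any(o != round(o)))
      msg <- c(msg, "pmf support values must be non-negative integers")
    if (any(p < 0)) msg <- c(msg, "probabilities must be non-negative")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' SweepResult: metrics over a parameter grid
#'
#' One row per grid point with raw and max-normalized mutual information,
#' average Fano-factor noise, and output range, plus provenance (the model
#' specification, master seed, replicates, sampling horizon).
#'
#' @slot table data.frame of grid coordinates and metrics.
#' @slot type sweep type (`"affinity"`, `"ratioAffinity"`,
#'   `"dualAffinity"`, `"extrinsicNoise"`).
#' @slot spec the [PathwayModel-class] template that was swept.
#' @slot seed master seed.
#' @slot replicates replicates per signal level.
#' @slot nLevels number of signal levels.
#' @slot tSample sampling horizon used (seconds).
#' @seealso [affinitySweep()], [findOptimum()], [writeSweep()]
#' @export
setClass("SweepResult",
  representation(table = "data.frame", type = "character",
                 spec = "PathwayModel", seed = "integer",
                 replicates = "integer", nLevels = "integer",
                 tSample = "numeric"))

setValidity("SweepResult", function(object) {
  msg <- character()
  need <- c("information", "noise", "outputRange")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must contain information, noise and outputRange")
  if (length(msg)) msg else TRUE
})
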