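#' Construct a Reaction
#'
#' @param kind reaction kind; see [Reaction-class].
#' @param rate rate constant (M^-1 s^-1 for `association`, s^-1 otherwise).
#' @param reactants character vector of reactant species (two for
#'   `association`, one otherwise).
#' @param products character vector of product species.
#' @param change named numeric of stoichiometric changes; defaults to
#'   -1 per reactant and +1 per product (synthesis kinds consume nothing).
#' @return A [Reaction-class] object.
#' @export
#' @examples
#' reaction("association", 1e6, c("S", "R"), "RS")
#' reaction("first-order-decay", 0.01, "mR", character())
reaction <- function(kind, rate, reactants, products, change = NULL) {
  if (is.null(change)) {
    change <- numeric()
    if (!kind %in% c("conditional-synthesis", "first-order-synthesis"))
      for (sp in reactants) change[sp] <- (change[sp] %||% 0) - 1
    for (sp in products) change[sp] <- (change[sp] %||% 0) + 1
  }
  new("Reaction", kind = kind, rate = rate,
      reactants = as.character(reactants),
      products = as.character(products), change = change)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Construct a ReactionSystem
#'
#' @param species named integer-valued vector of counts.
#' @param reactions list of [Reaction-class] objects.
#' @param volume reaction volume in liters (default [receptorVolume()]).
#' @param conserved list of character vectors naming species groups whose
#'   summed count every reaction must leave unchanged.
#' @param output name of the output species (defaults to the last species).
#' @return A validated [ReactionSystem-class].
#' @export
#' @examples
#' sys <- reactionSystem(
#'   c(S = 100L, R = 10L, RS = 0L),
#'   list(reaction("association", 1e6, c("S", "R"), "RS"),
#'        reaction("dissociation", 0.01, "RS", c("S", "R"))),
#'   conserved = list(c("S", "RS"), c("R", "RS")), output = "RS")
#' propensities(c(S = 100, R = 10, RS = 0), sys)
reactionSystem <- function(species, reactions,
                           volume = receptorVolume(),
                           conserved = list(), output = NULL) {
  sp <- setNames(as.integer(round(species)), names(species))
  new("ReactionSystem", species = sp, reactions = reactions,
      volume = volume, conserved = conserved,
      output = output %||% names(sp)[length(sp)])
}

#' Reaction propensities in a given state
#'
#' Evaluates the instantaneous firing rate of every reaction: association
#' reactions use `k_a/(V*N_Avogadro) * N_a * N_b`, first-order reactions
#' `rate * N`, and conditional synthesis `rate * 1(N_complex >= 1)`.
#'
#' @param state named numeric of non-negative species counts.
#' @param system a [ReactionSystem-class].
#' @return Numeric vector of non-negative propensities (s^-1), one per
#'   reaction, in declared reaction order.
#' @export
propensities <- function(state, system) {
  if (any(is.na(state)) || any(state < 0))
    stop("invalid state: species counts must be non-negative")
  vna <- system@volume * .AVOGADRO
  vapply(system@reactions, function(r) {
    switch(r@kind,
      "association" = r@rate / vna * state[[r@reactants[1L]]] *
        state[[r@reactants[2L]]],
      "conditional-synthesis" =
        if (state[[r@reactants[1L]]] >= 1) r@rate else 0,
      ## dissociation, first-order decay/synthesis: rate times count
      r@rate * state[[r@reactants[1L]]])
  }, numeric(1L))
}

#' One step of the Gillespie direct method
#'
#' Draws an exponential waiting time with rate equal to the total
#' propensity, selects a reaction with probability proportional to its
#' propensity (cumulative sums in declared order), and applies its
#' stoichiometric change.  A state in which no reaction can fire is
#' reported as absorbed, not as an error.
#'
#' @inheritParams propensities
#' @return A list with `state` (the updated counts), `tau` (the waiting
#'   time in seconds; `Inf` when absorbed) and `absorbed` (logical).
#' @export
#' @examples
#' sys <- reactionSystem(
#'   c(S = 100L, R = 10L, RS = 0L),
#'   list(reaction("association", 1e6, c("S", "R"), "RS"),
#'        reaction("dissociation", 0.01, "RS", c("S", "R"))),
#'   conserved = list(c("S", "RS"), c("R", "RS")), output = "RS")
#' set.seed(1)
#' gillespieStep(c(S = 100, R = 10, RS = 0), sys)
gillespieStep <- function(state, system) {
  a <- propensities(state, system)
  a0 <- sum(a)
  if (a0 <= 0)
    return(list(state = state, tau = Inf, absorbed = TRUE))
  tau <- rexp(1L, rate = a0)
  j <- findInterval(runif(1L) * a0, cumsum(a)) + 1L
  dz <- system@reactions[[j]]@change
  state[names(dz)] <- state[names(dz)] + dz
  if (any(state < 0))
    stop("reaction drove a species count negative; check the model")
  list(state = state, tau = tau, absorbed = FALSE)
}

## Lower the reaction list to the flat arrays the C++ kernel consumes.
## type codes: 0 = association, 1 = linear first-order, 2 = conditional
## (indicator) synthesis.  Association rates are pre-divided by V*N_A.
.compileSystem <- function(system) {
  spn <- names(system@species)
  nr <- length(system@reactions)
  rtype <- integer(nr); rrate <- numeric(nr)
  ri1 <- integer(nr); ri2 <- integer(nr)
  stoich <- matrix(0L, nrow = length(spn), ncol = nr,
                   dimnames = list(spn, NULL))
  vna <- system@volume * .AVOGADRO
  for (j in seq_len(nr)) {
    r <- system@reactions[[j]]
    if (r@kind == "association") {
      rtype[j] <- 0L
      rrate[j] <- r@rate / vna
      ri1[j] <- match(r@reactants[1L], spn) - 1L
      ri2[j] <- match(r@reactants[2L], spn) - 1L
    } else if (r@kind == "conditional-synthesis") {
      rtype[j] <- 2L
      rrate[j] <- r@rate
      ri1[j] <- match(r@reactants[1L], spn) - 1L
    } else {
      rtype[j] <- 1L
      rrate[j] <- r@rate
      ri1[j] <- match(r@reactants[1L], spn) - 1L
    }
    stoich[names(r@change), j] <- as.integer(r@change)
  }
  list(rtype = rtype, rate = rrate, ri1 = ri1, ri2 = ri2, stoich = stoich)
}

.checkConserved <- function(system, x0, xT) {
  for (grp in system@conserved)
    if (sum(x0[grp]) != sum(xT[grp]))
      stop(sprintf("conserved sum {%s} violated during simulation",
                   paste(grp, collapse = "+")))
  invisible(TRUE)
}

#' @describeIn ReactionSystem-class compact display.
#' @param object a `ReactionSystem`.
#' @export
setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf("ReactionSystem: %d species, %d reactions, V = %.4g L\n",
              length(object@species), length(object@reactions),
              object@volume))
  cat("  species:", paste(sprintf("%s=%d", names(object@species),
                                  object@species), collapse = ", "), "\n")
  cat(sprintf("  output: %s; conserved sums: %d\n", object@output,
              length(object@conserved)))
})
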