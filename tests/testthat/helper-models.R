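# Shared fixtures: tiny reaction systems built in code.

# Reversible binding S + R <-> RS with explicit rates.
tinyBindingSystem <- function(NS = 100L, NR = 10L, ka = 1e6, kd = 0.01) {
  reactionSystem(
    c(S = NS, R = NR, RS = 0L),
    list(reaction("association", ka, c("S", "R"), "RS"),
         reaction("dissociation", kd, "RS", c("S", "R"))),
    conserved = list(c("S", "RS"), c("R", "RS")),
    output = "RS")
}

# A frozen system: every rate zero, nothing can ever fire.
frozenSystem <- function() {
  reactionSystem(
    c(A = 5L, B = 3L, AB = 2L),
    list(reaction("association", 0, c("A", "B"), "AB"),
         reaction("dissociation", 0, "AB", c("A", "B"))),
    conserved = list(c("A", "AB"), c("B", "AB")),
    output = "AB")
}

# Random small ensemble for metric property tests.
randomEnsemble <- function(nLevels, supportSize, seed) {
  set.seed(seed)
  pmfs <- lapply(seq_len(nLevels), function(i) {
    p <- runif(supportSize)
    setNames(p / sum(p), 0:(supportSize - 1L))
  })
  responseEnsemble(seq_len(nLevels), pmfs = pmfs)
}

# Brute-force mutual information from the explicit joint table, written
# independently of the package implementation.
bruteForceMI <- function(ensemble) {
  support <- sort(unique(as.numeric(unlist(lapply(ensemble@pmfs, names)))))
  n <- length(ensemble@pmfs)
  joint <- matrix(0, n, length(support))
  for (i in seq_len(n)) {
    p <- ensemble@pmfs[[i]]
    joint[i, match(as.numeric(names(p)), support)] <- p / n
  }
  ps <- rowSums(joint); po <- colSums(joint)
  total <- 0
  for (i in seq_len(n))
    for (j in seq_along(support))
      if (joint[i, j] > 0)
        total <- total + joint[i, j] *
          log2(joint[i, j] / (ps[i] * po[j]))
  total
}
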