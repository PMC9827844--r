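# Independent oracles used across tests.  The enumeration oracle computes
# the tip-state likelihood by brute force over all internal-node state
# assignments, with transition probabilities from expm::expm -- a fully
# separate code path from the package's pruning/eigendecomposition kernel.

enum_loglik <- function(tree, tip_states, Q, rootw = rep(0.25, nrow(Q))) {
  k <- nrow(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  Ps <- lapply(tr$edge.length, function(t) expm::expm(Q * t))
  s <- integer(ntip + nint)
  s[seq_len(ntip)] <- tip_states[tr$tip.label]
  root <- tr$edge[nrow(tr$edge), 1]
  total <- 0
  for (idx in 0:(k^nint - 1)) {
    rem <- idx
    for (j in seq_len(nint)) {
      s[ntip + j] <- rem %% k + 1
      rem <- rem %/% k
    }
    p <- rootw[s[root]]
    for (e in seq_len(nrow(tr$edge)))
      p <- p * Ps[[e]][s[tr$edge[e, 1]], s[tr$edge[e, 2]]]
    total <- total + p
  }
  log(total)
}

# random strictly positive dependent rate set
rand_rates <- function() rate_set(runif(8, 0.05, 3))

# random small tree with branch lengths
rand_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- pmax(tr$edge.length, 0.01)
  tr
}

# tip state vectors (4-state) from integer states 1..4
tv_from_states <- function(states) {
  tv <- tip_state_vectors((states - 1L) %/% 2L, (states - 1L) %% 2L)
  colnames(tv) <- names(states)
  tv
}

# 2-state generator from gain/loss rates
gen2 <- function(alpha, beta)
  matrix(c(-alpha, alpha, beta, -beta), 2, 2, byrow = TRUE)

# analytic CDF of the rate prior: Exponential(mean m), m ~ Uniform(0, hi)
prior_mixture_cdf <- function(hi = 20) {
  Vectorize(function(z) {
    if (z <= 0) return(0)
    integrate(function(m) (1 - exp(-z / m)) / hi, 0, hi,
              rel.tol = 1e-9)$value
  })
}

make_ambiguous_pair <- function() {
  tree <- read_phylogeny("(A:0.1,B:0.1);")
  tv <- tip_state_vectors(c(A = NA, B = NA), c(A = NA, B = NA))
  colnames(tv) <- c("A", "B")
  list(tree = tree, tv = tv)
}
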