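#' Construct a dependent-model transition rate set
#'
#' The 4-state model of two binary traits has eight permitted transitions,
#' one per single-trait change; dual transitions (both traits changing in
#' one instant) are excluded. States are indexed `1=(0,0)`, `2=(0,1)`,
#' `3=(1,0)`, `4=(1,1)` with the first position the ecology trait (A) and
#' the second the care trait (B), i.e. index `= 2*A + B + 1`.
#'
#' @param q12,q13,q21,q24,q31,q34,q42,q43 Non-negative rates per unit of
#'   (scaled) branch length, or pass a single named vector as `q12`.
#' @return A named numeric vector of class `rate_set`.
#' @export
rate_set <- function(q12, q13, q21, q24, q31, q34, q42, q43) {
  if (length(q12) == 8L && !missing(q12) && missing(q13)) {
    x <- q12
    if (is.null(names(x))) names(x) <- RATE_NAMES
    x <- x[RATE_NAMES]
  } else {
    x <- c(q12 = q12, q13 = q13, q21 = q21, q24 = q24,
           q31 = q31, q34 = q34, q42 = q42, q43 = q43)
  }
  if (anyNA(x)) stop("rate set has missing entries")
  if (any(x < 0)) stop("transition rates must be non-negative")
  structure(as.numeric(x), names = RATE_NAMES, class = "rate_set")
}

#' Construct an independent-model rate set
#'
#' Under the independent model each trait gains and loses at rates that do
#' not depend on the other trait's state, which constrains the eight
#' dependent rates to four free parameters.
#'
#' @param alpha_A,beta_A Gain and loss rate of the ecology trait (A).
#' @param alpha_B,beta_B Gain and loss rate of the care trait (B).
#' @return A named numeric vector of class `indep_rates`.
#' @export
independent_rates <- function(alpha_A, beta_A, alpha_B, beta_B) {
  x <- c(alpha_A = alpha_A, beta_A = beta_A,
         alpha_B = alpha_B, beta_B = beta_B)
  if (anyNA(x) || any(x < 0)) stop("rates must be non-negative")
  structure(as.numeric(x), names = names(x), class = "indep_rates")
}

#' Expand independent rates to the 8-rate parameterization
#'
#' Applies the equality constraints `q13 = q24 = alpha_A`,
#' `q31 = q42 = beta_A`, `q12 = q34 = alpha_B`, `q21 = q43 = beta_B`.
#'
#' @param ind An `indep_rates` object.
#' @return A `rate_set`.
#' @export
expand_independent <- function(ind) {
  stopifnot(inherits(ind, "indep_rates"))
  rate_set(q12 = ind[["alpha_B"]], q13 = ind[["alpha_A"]],
           q21 = ind[["beta_B"]], q24 = ind[["alpha_A"]],
           q31 = ind[["beta_A"]], q34 = ind[["alpha_B"]],
           q42 = ind[["beta_A"]], q43 = ind[["beta_B"]])
}

as_rate_set <- function(rates) {
  if (inherits(rates, "indep_rates")) return(expand_independent(rates))
  if (inherits(rates, "rate_set")) return(rates)
  if (is.numeric(rates) && length(rates) == 8L) return(rate_set(rates))
  stop("cannot interpret `rates` as a rate set")
}

#' Build the 4x4 generator matrix
#'
#' Places the eight permitted rates off-diagonal, zeros the four forbidden
#' (dual-transition) cells, and sets the diagonal to minus the row sums.
#'
#' @param rates A `rate_set`, `indep_rates`, or named 8-vector.
#' @return A 4x4 generator matrix with zero row sums.
#' @export
build_generator <- function(rates) {
  q <- as_rate_set(rates)
  Q <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  from <- c(1, 1, 2, 2, 3, 3, 4, 4)
  to   <- c(2, 3, 1, 4, 1, 4, 2, 3)
  Q[cbind(from, to)] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition with an automatic scaling-and-squaring
#' fallback when the generator is defective; round-off below `-1e-12` is
#' clamped to zero. A zero elapsed time returns the identity exactly.
#'
#' @param Q A generator matrix (any dimension with zero row sums).
#' @param t Non-negative elapsed (scaled) branch length.
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("elapsed time must be non-negative")
  P <- cpp_transition_matrix(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1`; returns the uniform distribution when
#' the chain is reducible or the solve fails.
#'
#' @param Q A generator matrix.
#' @return A probability vector.
#' @export
stationary_distribution <- function(Q) {
  as.numeric(cpp_stationary(Q))
}

#' Build per-tip partial likelihood vectors for the 4-state model
#'
#' An observed joint state becomes an indicator vector over the four
#' states; a missing value in either trait yields ones over all compatible
#' states (a fully missing tip is all-ones, i.e. ambiguous).
#'
#' @param trait_A,trait_B Vectors of 0/1 (or NA for ambiguity), named by
#'   species or aligned positionally.
#' @return A 4 x n matrix of partial likelihood vectors, columns named by
#'   species when names are available.
#' @export
tip_state_vectors <- function(trait_A, trait_B) {
  n <- length(trait_A)
  stopifnot(length(trait_B) == n)
  out <- matrix(0, 4, n)
  a_states <- c(0, 0, 1, 1)
  b_states <- c(0, 1, 0, 1)
  for (i in seq_len(n)) {
    ok_a <- if (is.na(trait_A[i])) rep(TRUE, 4) else a_states == trait_A[i]
    ok_b <- if (is.na(trait_B[i])) rep(TRUE, 4) else b_states == trait_B[i]
    out[, i] <- as.numeric(ok_a & ok_b)
  }
  colnames(out) <- names(trait_A) %||% names(trait_B)
  out
}

postorder_arrays <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = t(tr$edge) - 1L, elen = tr$edge.length)
}

#' Pruning (post-order) log-likelihood of tip states under a CTMC
#'
#' Felsenstein's pruning algorithm over the tree, propagating per-tip
#' partial likelihood vectors to the root, where they are weighted
#' uniformly or by the stationary distribution of the generator.
#'
#' @param tree A `phylo` object.
#' @param tipvec A k x ntip matrix of partial likelihood vectors with
#'   columns named by tip label (see [tip_state_vectors()]), or unnamed and
#'   already in `tree$tip.label` order.
#' @param rates A `rate_set`/`indep_rates` (4-state), or a k x k generator
#'   matrix for other state spaces (e.g. a single binary trait, k = 2).
#' @param root_mode `"uniform"` (default) or `"stationary"`.
#' @return The log-likelihood (a scalar).
#' @export
pruning_log_likelihood <- function(tree, tipvec, rates,
                                   root_mode = c("uniform", "stationary")) {
  root_mode <- match.arg(root_mode)
  Q <- if (is.matrix(rates)) rates else build_generator(rates)
  ntip <- length(tree$tip.label)
  if (ncol(tipvec) != ntip)
    stop("tip vector count does not match number of tips")
  if (!is.null(colnames(tipvec))) {
    if (!setequal(colnames(tipvec), tree$tip.label))
      stop("tip vector names do not match tree tip labels")
    tipvec <- tipvec[, tree$tip.label, drop = FALSE]
  }
  if (any(colSums(tipvec) <= 0))
    stop("each tip vector must be non-negative and not all-zero")
  po <- postorder_arrays(tree)
  cpp_pruning_loglik(po$edge, po$elen, tipvec, Q,
                     if (root_mode == "uniform") 0L else 1L,
                     numeric(nrow(Q)))
}

#' Simulate a trait history on a tree (exact Gillespie simulation)
#'
#' Evolves the 4-state joint character from the root towards the tips with
#' exponential waiting times given each state's total exit rate; no event
#' ever changes both traits at once, by construction of the generator.
#'
#' @param tree A `phylo` object.
#' @param rates A `rate_set`, `indep_rates` or generator matrix.
#' @param root_state Integer state 1..4, or `"stationary"` to draw the root
#'   from the stationary distribution (uniform fallback if reducible).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `tip_states` (named integer vector, 1..4), `events`
#'   (data.frame: edge, time, from, to) and `root_state`.
#' @export
simulate_history <- function(tree, rates, root_state = "stationary",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- if (is.matrix(rates)) rates else build_generator(rates)
  k <- nrow(Q)
  if (identical(root_state, "stationary")) {
    pi0 <- stationary_distribution(Q)
    root_state <- sample.int(k, 1L, prob = pi0)
  }
  stopifnot(root_state %in% seq_len(k))

  tr <- ape::reorder.phylo(tree, "postorder")
  nedge <- nrow(tr$edge)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  state <- integer(nnode)
  root <- tr$edge[nedge, 1]
  state[root] <- root_state

  cap <- 256L
  ev_edge <- integer(cap); ev_time <- numeric(cap)
  ev_from <- integer(cap); ev_to <- integer(cap)
  nev <- 0L
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nedge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- state[par]
    len <- tr$edge.length[e]
    t <- 0
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      dt <- rexp(1, out_rate)
      if (t + dt > len) break
      t <- t + dt
      p <- Q[s, ]
      p[s] <- 0
      s_new <- sample.int(k, 1L, prob = p)
      nev <- nev + 1L
      if (nev > cap) {         # grow geometrically
        cap <- cap * 2L
        length(ev_edge) <- cap; length(ev_time) <- cap
        length(ev_from) <- cap; length(ev_to) <- cap
      }
      ev_edge[nev] <- e; ev_time[nev] <- t
      ev_from[nev] <- s; ev_to[nev] <- s_new
      s <- s_new
    }
    state[ch] <- s
  }
  keep <- seq_len(nev)
  ev_edge <- ev_edge[keep]; ev_time <- ev_time[keep]
  ev_from <- ev_from[keep]; ev_to <- ev_to[keep]
  tips <- state[seq_len(ntip)]
  names(tips) <- tr$tip.label
  list(tip_states = tips,
       events = data.frame(edge = ev_edge, time = ev_time,
                           from = ev_from, to = ev_to),
       root_state = root_state)
}
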