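test_that("generator construction places rates and forbids dual transitions", {
  Q0 <- build_generator(rate_set(rep(0, 8)))
  expect_equal(Q0, matrix(0, 4, 4, dimnames = list(1:4, 1:4)))

  Q1 <- build_generator(rate_set(q12 = 1, q13 = 0, q21 = 0, q24 = 0,
                                 q31 = 0, q34 = 0, q42 = 0, q43 = 0))
  expect_equal(unname(Q1[1, ]), c(-1, 1, 0, 0))
  expect_equal(unname(Q1[2:4, ]), matrix(0, 3, 4))

  set.seed(1)
  for (i in 1:5) {
    Q <- build_generator(rand_rates())
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(unname(c(Q[1, 4], Q[4, 1], Q[2, 3], Q[3, 2])), rep(0, 4))
  }
  expect_error(rate_set(q12 = -1, q13 = 0, q21 = 0, q24 = 0,
                        q31 = 0, q34 = 0, q42 = 0, q43 = 0),
               "non-negative")
})

test_that("independent expansion obeys its constraints and the Kronecker sum", {
  r <- expand_independent(independent_rates(1, 2, 3, 4))
  expect_equal(unname(r[c("q13", "q24")]), c(1, 1))
  expect_equal(unname(r[c("q31", "q42")]), c(2, 2))
  expect_equal(unname(r[c("q12", "q34")]), c(3, 3))
  expect_equal(unname(r[c("q21", "q43")]), c(4, 4))

  expect_equal(as.numeric(expand_independent(independent_rates(0, 0, 0, 0))),
               rep(0, 8))

  # generator equals the Kronecker sum of the two 2-state generators
  ind <- independent_rates(0.7, 1.3, 0.4, 2.1)
  G <- build_generator(ind)
  G2 <- kronecker(gen2(0.7, 1.3), diag(2)) + kronecker(diag(2), gen2(0.4, 2.1))
  expect_equal(unname(G), G2, tolerance = 1e-14)
})

test_that("transition matrices are stochastic and match closed forms", {
  Q <- build_generator(rate_set(runif(8, 0.1, 2)))
  expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE)
  expect_error(transition_matrix(Q, -1), "non-negative")

  P <- transition_matrix(Q, 0.7)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0 & P <= 1))

  # independent model: joint P(t) factorizes into the 2-state closed forms
  a <- 0.9; b <- 0.4
  p2 <- function(t) {
    e <- exp(-(a + b) * t)
    matrix(c(b + a * e, a - a * e, b - b * e, a + b * e), 2, 2,
           byrow = TRUE) / (a + b)
  }
  ind <- independent_rates(a, b, 0.3, 1.1)
  Pj <- transition_matrix(build_generator(ind), 0.6)
  PA <- p2(0.6)
  e2 <- exp(-(0.3 + 1.1) * 0.6)
  PB <- matrix(c(1.1 + 0.3 * e2, 0.3 - 0.3 * e2,
                 1.1 - 1.1 * e2, 0.3 + 1.1 * e2), 2, 2,
               byrow = TRUE) / 1.4
  expect_equal(unname(Pj), kronecker(PA, PB), tolerance = 1e-10)

  # long-time limit: every row at the stationary distribution
  Qe <- build_generator(rate_set(runif(8, 0.5, 2)))
  pi0 <- stationary_distribution(Qe)
  Pinf <- transition_matrix(Qe, 1e6)
  expect_lt(max(abs(sweep(Pinf, 2, pi0))), 1e-6)

  # Chapman-Kolmogorov
  expect_lt(max(abs(transition_matrix(Qe, 0.3) %*% transition_matrix(Qe, 0.7) -
                    transition_matrix(Qe, 1))), 1e-9)
})

test_that("pruning likelihood matches trivial cases and the enumeration oracle", {
  tr0 <- read_phylogeny("(A:0,B:0);")
  tv <- tv_from_states(c(A = 1L, B = 1L))
  expect_equal(pruning_log_likelihood(tr0, tv, rate_set(rep(0.5, 8))),
               log(0.25), tolerance = 1e-12)

  amb <- make_ambiguous_pair()
  expect_equal(pruning_log_likelihood(amb$tree, amb$tv,
                                      rate_set(rep(1.3, 8))), 0,
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:12) {
    n <- sample(3:4, 1)
    tree <- rand_tree(n)
    q <- rand_rates()
    states <- setNames(sample(1:4, n, replace = TRUE), tree$tip.label)
    ll <- pruning_log_likelihood(tree, tv_from_states(states), q)
    expect_equal(ll, enum_loglik(tree, states, build_generator(q)),
                 tolerance = 1e-10)
  }
})

test_that("likelihood invariances hold: rescaling, factorization, tip order", {
  set.seed(11)
  tree <- rand_tree(6)
  q <- rand_rates()
  states <- setNames(sample(1:4, 6, replace = TRUE), tree$tip.label)
  tv <- tv_from_states(states)
  ll <- pruning_log_likelihood(tree, tv, q)

  for (cc in c(0.1, 10)) {
    tr_c <- tree
    tr_c$edge.length <- tr_c$edge.length * cc
    q_c <- rate_set(as.numeric(q) * cc)
    expect_equal(pruning_log_likelihood(tr_c, tv, q),
                 pruning_log_likelihood(tree, tv, q_c), tolerance = 1e-10)
  }

  ind <- independent_rates(0.8, 1.1, 0.5, 1.7)
  A <- (states - 1L) %/% 2L
  B <- (states - 1L) %% 2L
  tvA <- rbind(1 - A, A); tvB <- rbind(1 - B, B)
  colnames(tvA) <- colnames(tvB) <- names(states)
  expect_equal(pruning_log_likelihood(tree, tv, ind),
               pruning_log_likelihood(tree, tvA, gen2(0.8, 1.1)) +
                 pruning_log_likelihood(tree, tvB, gen2(0.5, 1.7)),
               tolerance = 1e-10)

  perm <- sample(ncol(tv))
  expect_equal(pruning_log_likelihood(tree, tv[, perm], q), ll,
               tolerance = 1e-12)
})

test_that("exact zero rates forbid transitions through unreachable states", {
  tree <- read_phylogeny("(A:0.5,B:0.5);")
  tv <- tv_from_states(c(A = 1L, B = 4L))
  # care trait immutable: tips differing in care are impossible
  q <- rate_set(q12 = 0, q13 = 0.7, q21 = 0, q24 = 0.7,
                q31 = 0.6, q34 = 0, q42 = 0.6, q43 = 0)
  expect_identical(pruning_log_likelihood(tree, tv, q), -Inf)
  P <- transition_matrix(build_generator(q), 0.5)
  expect_identical(unname(P[1, c(2, 4)]), c(0, 0))
})

test_that("simulate_history is exact: no dual transitions, correct statistics", {
  tree <- simulate_tree(15, seed = 2)
  h0 <- simulate_history(tree, rate_set(rep(0, 8)), root_state = 3, seed = 1)
  expect_true(all(h0$tip_states == 3))
  expect_equal(nrow(h0$events), 0)

  h <- simulate_history(tree, regime_rates("ecology_first")$rates,
                        root_state = 1, seed = 5)
  if (nrow(h$events)) {
    a_from <- (h$events$from - 1) %/% 2; a_to <- (h$events$to - 1) %/% 2
    b_from <- (h$events$from - 1) %% 2;  b_to <- (h$events$to - 1) %% 2
    expect_true(all((a_from != a_to) + (b_from != b_to) == 1))
  }

  # single long branch with q12 = q21 = 1: events ~ alternating renewal;
  # expected count = branch length * stationary flux = 1000 * 1
  long <- read_phylogeny("(A:1000,B:0);")
  q <- rate_set(q12 = 1, q13 = 0, q21 = 1, q24 = 0,
                q31 = 0, q34 = 0, q42 = 0, q43 = 0)
  set.seed(9)
  n_ev <- replicate(40, {
    h1 <- simulate_history(long, q, root_state = 1)
    nrow(h1$events)
  })
  # total rate alternates between 1 and 1; E[events] = 1000, SE ~ sqrt(1000)
  expect_lt(abs(mean(n_ev) - 1000), 5 * sqrt(1000 / 40))

  set.seed(10)
  tips2 <- replicate(1000, simulate_history(long, q, root_state = 1)$tip_states[["A"]])
  expect_lt(abs(mean(tips2 == 2) - 0.5), 5 * sqrt(0.25 / 1000))
})
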