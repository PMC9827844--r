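test_that("chain_config validates its settings", {
  expect_error(chain_config(iterations = 100, burnin = 100), "burnin")
  cfg <- chain_config(preset = "rapid")
  expect_lt(cfg$burnin, cfg$iterations)
  expect_identical(chain_config(seed = 2)$hyper, c(0, 20))
})

test_that("prior-only sampling recovers the exponential/uniform mixture", {
  amb <- make_ambiguous_pair()
  fixed <- setNames(rep(0.5, 7), setdiff(names(rate_set(rep(1, 8))), "q12"))
  cfg <- chain_config(iterations = 6e4, burnin = 5e3, thinning = 5,
                      seed = 7, rj = FALSE)
  tr <- sample_posterior(amb$tree, amb$tv, "dependent", cfg,
                         fixed_rates = fixed)
  x <- tr$samples[, "q12"]
  expect_gte(length(x), 1e4)
  # E[rate] = E[m] = 10 under m ~ Uniform(0, 20)
  expect_lt(abs(mean(x) - 10), 0.5)
  ks <- suppressWarnings(stats::ks.test(x, prior_mixture_cdf()))
  expect_lt(unname(ks$statistic), 0.05)
  # hyperprior mean itself explores (0, 20)
  expect_lt(abs(mean(tr$m) - 10), 0.6)
})

test_that("RJ structure moves leave the uniform partition prior invariant", {
  amb <- make_ambiguous_pair()
  cfg <- chain_config(iterations = 1.5e5, burnin = 1e4, thinning = 10,
                      seed = 11, rj = TRUE)
  tr <- sample_posterior(amb$tree, amb$tv, "dependent", cfg)
  nbins <- apply(tr$assign, 1, function(a) length(unique(a[a >= 0])))
  obs <- table(factor(nbins, levels = 0:8))
  # analytic marginal of the number of value bins under the uniform prior
  # over structures: count(z zeroed, k bins) = C(8,z) * Stirling2(8-z, k)
  S2 <- function(n, k) {
    if (k == 0) return(as.numeric(n == 0))
    if (n == 0) return(0)
    sum((-1)^(k - 0:k) * choose(k, 0:k) * (0:k)^n) / factorial(k)
  }
  cnt <- sapply(0:8, function(k)
    sum(sapply(0:8, function(z) choose(8, z) * S2(8 - z, k))))
  p <- cnt / sum(cnt)
  ess <- as.numeric(coda::effectiveSize(coda::mcmc(nbins)))
  chi <- sum((as.numeric(obs) / sum(obs) - p)^2 / p) * ess
  expect_lt(chi, qchisq(0.99, df = 8))
})

test_that("traces are bit-reproducible under a fixed seed", {
  study <- generate_study(30, c(T = "ecology_first"), seed = 5)
  tv <- tip_state_vectors(study$traits[, "T"], study$traits[, "attendance"])
  colnames(tv) <- rownames(study$traits)
  cfg <- chain_config(iterations = 2000, burnin = 500, thinning = 5, seed = 3)
  t1 <- sample_posterior(study$tree, tv, "dependent", cfg)
  t2 <- sample_posterior(study$tree, tv, "dependent", cfg)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$logl, t2$logl)
  cfg2 <- cfg; cfg2$seed <- 4L
  t3 <- sample_posterior(study$tree, tv, "dependent", cfg2)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("plain MH (RJ off, all rates free) agrees with RJ conditional means", {
  study <- generate_study(100, c(T = "ecology_first"), seed = 21)
  tv <- tip_state_vectors(study$traits[, "T"], study$traits[, "attendance"])
  colnames(tv) <- rownames(study$traits)
  cfg_mh <- chain_config(iterations = 1.5e4, burnin = 3e3, thinning = 10,
                         seed = 1, rj = FALSE)
  cfg_rj <- chain_config(iterations = 1.5e4, burnin = 3e3, thinning = 10,
                         seed = 2, rj = TRUE)
  mh <- sample_posterior(study$tree, tv, "dependent", cfg_mh)
  rj <- sample_posterior(study$tree, tv, "dependent", cfg_rj)
  # strongly identified rates should agree within generous MC error
  for (r in c("q13", "q34")) {
    se <- sd(mh$samples[, r]) / sqrt(coda::effectiveSize(coda::mcmc(mh$samples[, r])))
    expect_lt(abs(mean(mh$samples[, r]) - mean(rj$samples[, r])),
              8 * se + 0.15)
  }
})

test_that("rate summaries report mean/median/mode/CI/pct_zero as specified", {
  m <- matrix(rep(c(0, 0, 0, 4), each = 25), ncol = 1)
  colnames(m) <- "q12"
  s <- summarize_rates(m)
  expect_equal(s["q12", "pct_zero"], 75)
  expect_equal(s["q12", "median"], 0)
  expect_equal(s["q12", "mean"], 1)
  expect_equal(s["q12", "mode"], 0)   # zero bin holds the majority

  m2 <- matrix(2, 150, 1, dimnames = list(NULL, "q34"))
  s2 <- summarize_rates(m2)
  expect_equal(unname(unlist(s2["q34", c("mean", "median", "ci_lower",
                                         "ci_upper")])),
               c(2, 2, 2, 2))
  expect_equal(s2["q34", "pct_zero"], 0)

  # KDE mode of log-normal samples near the analytic mode
  set.seed(4)
  x <- matrix(rlnorm(20000, meanlog = 0.5, sdlog = 0.4), ncol = 1,
              dimnames = list(NULL, "q21"))
  s3 <- summarize_rates(x)
  analytic_mode <- exp(0.5 - 0.4^2)
  expect_lt(abs(s3["q21", "mode"] - analytic_mode) / analytic_mode, 0.1)

  expect_error(summarize_rates(m2[1:10, , drop = FALSE]), "too few")
})

test_that("diagnostics report ESS, autocorrelation and multi-chain PSRF", {
  set.seed(8)
  iid <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  d <- mcmc_diagnostics(iid)
  expect_lt(abs(d$ess["x", "ess"] - 5000) / 5000, 0.1)
  expect_false(d$ess["x", "low_ess"])

  const <- matrix(1, 500, 1, dimnames = list(NULL, "x"))
  dc <- mcmc_diagnostics(const)
  expect_true(dc$ess["x", "degenerate"])
  expect_true(is.na(dc$ess["x", "ess"]))

  two <- list(cbind(iid, y = rnorm(5000)), cbind(iid, y = rnorm(5000)))
  d2 <- mcmc_diagnostics(two)
  expect_lt(abs(d2$psrf["x", 1] - 1), 0.05)
})

test_that("stepping stone gives 0 for flat likelihood and matches quadrature", {
  amb <- make_ambiguous_pair()
  cfg <- chain_config(preset = "rapid", seed = 5)
  ss <- stepping_stone_log_marginal(amb$tree, amb$tv, "dependent", cfg)
  expect_lt(abs(ss$logml), max(2 * ss$se, 1e-8))

  # 1 free rate, RJ off: marginal likelihood by 2-D quadrature
  tree <- read_phylogeny("(A:0.1,B:0.1);")
  tv2 <- tv_from_states(c(A = 1L, B = 2L))
  fixed <- setNames(rep(0.5, 7), setdiff(names(rate_set(rep(1, 8))), "q12"))
  lik <- function(qv) vapply(qv, function(q) exp(pruning_log_likelihood(
    tree, tv2, rate_set(c(q, rep(0.5, 7))))), numeric(1))
  inner <- Vectorize(function(m)
    integrate(function(q) lik(q) * exp(-q / m) / m, 0, Inf,
              rel.tol = 1e-9)$value)
  ml_quad <- log(integrate(function(m) inner(m) / 20, 1e-6, 20,
                           rel.tol = 1e-7)$value)
  cfg2 <- chain_config(iterations = 2e4, burnin = 2e3, thinning = 5,
                       seed = 9, rj = FALSE, n_stones = 12,
                       stone_iterations = 3000, stone_burnin = 500)
  ss2 <- stepping_stone_log_marginal(tree, tv2, "dependent", cfg2,
                                     fixed_rates = fixed)
  expect_lt(abs(ss2$logml - ml_quad), 2 * ss2$se + 0.02)
})
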