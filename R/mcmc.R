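#' Chain configuration for the rate samplers
#'
#' Bundles iteration counts, the hyperprior bounds, proposal scales and
#' stepping-stone settings. Presets: `"paper"` mirrors the published run
#' lengths (4e8 iterations, burnin 5e5, thinning 2e5), `"desk"` is the
#' package default for interactive work (1e6 / 1e5 / 100), and `"rapid"`
#' is the short preset used by the test-suite and calibration scripts
#' (3e4 / 5e3 / 25, 8 stepping stones of 1500 draws).
#'
#' @param iterations,burnin,thinning MCMC chain settings.
#' @param seed Integer seed; every source of randomness derives from it.
#' @param rj Enable reversible-jump moves over rate-class partitions with a
#'   zero bin (default TRUE).
#' @param root_mode `"uniform"` (default) or `"stationary"` root weighting.
#' @param hyper Bounds of the uniform hyperprior on the exponential prior
#'   mean (default `c(0, 20)`).
#' @param prop_scale Initial scale of the multiplicative log-normal rate
#'   proposal (auto-tuned to 20--40 percent acceptance during burnin, then frozen).
#' @param m_prop_sd Standard deviation of the reflective walk on the
#'   hyperprior mean.
#' @param n_stones,stone_iterations,stone_burnin Stepping-stone ladder
#'   settings (power ladder from quantiles of Beta(0.3, 1)).
#' @param tune Auto-tune the rate proposal during burnin.
#' @param preset One of `"paper"`, `"desk"`, `"rapid"`; overrides the
#'   iteration arguments.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(iterations = 1e6, burnin = 1e5, thinning = 100,
                         seed = 1L, rj = TRUE,
                         root_mode = c("uniform", "stationary"),
                         hyper = c(0, 20), prop_scale = 0.8, m_prop_sd = 2,
                         n_stones = 8, stone_iterations = 2500,
                         stone_burnin = 500, tune = TRUE, preset = NULL) {
  root_mode <- match.arg(root_mode)
  if (!is.null(preset)) {
    p <- switch(preset,
      paper = list(4e8, 5e5, 2e5, 32, 10000, 2000),
      desk  = list(1e6, 1e5, 100, 16, 4000, 1000),
      rapid = list(3e4, 5e3, 25, 8, 1500, 300),
      stop("unknown preset: ", preset))
    iterations <- p[[1]]; burnin <- p[[2]]; thinning <- p[[3]]
    n_stones <- p[[4]]; stone_iterations <- p[[5]]; stone_burnin <- p[[6]]
  }
  stopifnot(burnin < iterations, thinning >= 1, hyper[1] >= 0,
            hyper[2] > hyper[1])
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed), rj = isTRUE(rj),
                 root_mode = root_mode, hyper = hyper,
                 prop_scale = prop_scale, m_prop_sd = m_prop_sd,
                 n_stones = as.integer(n_stones),
                 stone_iterations = as.integer(stone_iterations),
                 stone_burnin = as.integer(stone_burnin),
                 tune = isTRUE(tune)),
            class = "chain_config")
}

# Model plumbing: map the 8 generator slots to free labels (0-based for the
# C++ sampler) or to fixed constants.  `fixed_rates` is a named vector of
# slots pinned to constants (removed from the free labels).
model_spec <- function(model = c("dependent", "independent"),
                       fixed_rates = NULL) {
  if (is.list(model)) return(model)   # pre-built spec (internal/testing use)
  model <- match.arg(model)
  if (model == "dependent") {
    labmap <- 0:7
    lab_names <- RATE_NAMES
  } else {
    # alpha_A -> q13,q24; beta_A -> q31,q42; alpha_B -> q12,q34; beta_B -> q21,q43
    labmap <- c(2L, 0L, 3L, 0L, 1L, 2L, 1L, 3L)
    lab_names <- c("alpha_A", "beta_A", "alpha_B", "beta_B")
  }
  fixedvals <- rep(0, 8)
  if (!is.null(fixed_rates)) {
    stopifnot(all(names(fixed_rates) %in% RATE_NAMES))
    idx <- match(names(fixed_rates), RATE_NAMES)
    labmap[idx] <- -9L
    fixedvals[idx] <- fixed_rates
    kept <- sort(unique(labmap[labmap >= 0]))
    labmap[labmap >= 0] <- match(labmap[labmap >= 0], kept) - 1L
    lab_names <- lab_names[kept + 1L]
  }
  list(name = model, labmap = as.integer(labmap), fixedvals = fixedvals,
       nlab = length(lab_names), lab_names = lab_names)
}

prepare_tipvec <- function(tree, tipvec) {
  if (!is.null(colnames(tipvec))) {
    if (!setequal(colnames(tipvec), tree$tip.label))
      stop("tip vector names do not match tree tip labels")
    tipvec <- tipvec[, tree$tip.label, drop = FALSE]
  }
  if (ncol(tipvec) != length(tree$tip.label))
    stop("tip vector count does not match number of tips")
  tipvec
}

run_chain <- function(tree, tipvec, spec, config, beta_power = 1,
                      init = NULL, seed = NULL) {
  po <- postorder_arrays(tree)
  tipvec <- prepare_tipvec(tree, tipvec)
  set.seed(seed %||% config$seed)
  for (try in seq_len(100)) {
    if (is.null(init)) {
      # start the hyperprior mean low: on a mean-0.1-scaled tree the
      # data-supported rates sit well below the hyperprior's upper bound,
      # and the m walk reaches the rest of (lo, hi) within burnin
      m0 <- runif(1, max(0.5, config$hyper[1] + 1e-6),
                  min(2, config$hyper[2]))
      assign0 <- seq_len(spec$nlab) - 1L   # every label its own bin
      vals0 <- rexp(spec$nlab, rate = 1 / m0)
      vals0[vals0 <= 0] <- 1e-6
    } else {
      m0 <- init$m; assign0 <- init$assign; vals0 <- init$vals
    }
    res <- tryCatch(
      cpp_rj_sampler(po$edge, po$elen, tipvec,
                     spec$labmap, spec$fixedvals, spec$nlab,
                     config$iterations, config$burnin, config$thinning,
                     config$rj,
                     if (config$root_mode == "uniform") 0L else 1L,
                     beta_power, config$hyper[1], config$hyper[2],
                     config$prop_scale, config$m_prop_sd,
                     as.integer(assign0), as.numeric(vals0), m0,
                     config$tune),
      error = function(e) e)
    if (!inherits(res, "error")) {
      colnames(res$samples) <- RATE_NAMES
      return(res)
    }
    if (!is.null(init)) stop(conditionMessage(res))
  }
  stop("non-finite likelihood at initialization after 100 retries")
}

#' Sample the posterior of the transition rates by (RJ-)MCMC
#'
#' Metropolis--Hastings over rate values and the hyperprior mean, plus
#' reversible-jump moves over rate-class partitions including a zero bin.
#' Each value-bin rate has prior Exponential(mean m) with
#' m ~ Uniform(`config$hyper`); the partition prior is uniform over
#' partition structures, so structure moves accept on the likelihood ratio
#' times the ratio of available-move counts.
#'
#' @param tree A `phylo` object (branch lengths already scaled, see
#'   [scale_branch_lengths()]).
#' @param tipvec 4 x ntip tip state vectors ([tip_state_vectors()]).
#' @param model `"dependent"` (8 free rates) or `"independent"` (4).
#' @param config A [chain_config()].
#' @param fixed_rates Optional named vector pinning some rates to constants.
#' @return A `posterior_trace`: retained samples of the eight rates (zeros
#'   materialized for zero-bin rates), partition assignments, hyperprior
#'   mean, log-likelihood, acceptance rates and a config echo.
#' @export
sample_posterior <- function(tree, tipvec, model = c("dependent", "independent"),
                             config = chain_config(), fixed_rates = NULL) {
  spec <- model_spec(model, fixed_rates)
  res <- run_chain(tree, tipvec, spec, config)
  structure(list(samples = res$samples, logl = as.numeric(res$logl),
                 m = as.numeric(res$m), assign = res$assign,
                 accept = res$accept, model = spec$name %||% "custom",
                 lab_names = spec$lab_names, config = config,
                 seed = config$seed),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("posterior_trace:", nrow(x$samples), "retained samples,",
      x$model, "model, seed", x$seed, "\n")
  print(summarize_rates(x))
  invisible(x)
}

#' Summarize posterior transition rates
#'
#' Per rate: posterior mean and median over all retained samples (zeros
#' included), the central 95 percent credible interval, the percentage of samples
#' with the rate in the zero bin (`pct_zero`), and a mode --- reported as 0
#' when the zero bin holds the majority, otherwise the kernel-density mode
#' of the positive samples.
#'
#' @param trace A `posterior_trace`, or a samples matrix with rate columns.
#' @param min_samples Minimum retained sample count (default 100).
#' @return A data.frame with one row per rate.
#' @export
summarize_rates <- function(trace, min_samples = 100) {
  samples <- if (inherits(trace, "posterior_trace")) trace$samples else trace
  if (nrow(samples) < min_samples)
    stop("too few retained samples (", nrow(samples), " < ", min_samples, ")")
  out <- do.call(rbind, lapply(colnames(samples), function(nm) {
    x <- samples[, nm]
    pz <- 100 * mean(x == 0)
    pos <- x[x > 0]
    mode <- if (pz > 50 || length(pos) < 2) 0 else {
      d <- density(pos)
      d$x[which.max(d$y)]
    }
    ci <- unname(quantile(x, c(0.025, 0.975)))
    data.frame(rate = nm, mean = mean(x), median = median(x), mode = mode,
               ci_lower = ci[1], ci_upper = ci[2], pct_zero = pz)
  }))
  rownames(out) <- out$rate
  out
}

#' Convergence and mixing diagnostics for posterior traces
#'
#' Effective sample sizes (spectral estimate), lag-k autocorrelations, and,
#' given two or more chains, the between/within-chain potential scale
#' reduction factor. Parameters with ESS below `ess_floor` are flagged;
#' constant traces are reported as degenerate.
#'
#' @param trace A `posterior_trace`, a numeric matrix, or a list of either
#'   (multiple chains).
#' @param lags Lags at which to report autocorrelation.
#' @param ess_floor Flag threshold for ESS (default 200).
#' @return List with `ess` table and, for multiple chains, `psrf`.
#' @export
mcmc_diagnostics <- function(trace, lags = c(1, 5, 10), ess_floor = 200) {
  as_mat <- function(x) if (inherits(x, "posterior_trace"))
    cbind(x$samples, m = x$m, logl = x$logl) else as.matrix(x)
  chains <- if (is.list(trace) && !inherits(trace, "posterior_trace"))
    lapply(trace, as_mat) else list(as_mat(trace))

  mat <- chains[[1]]
  ess_tab <- do.call(rbind, lapply(colnames(mat) %||%
                                     paste0("V", seq_len(ncol(mat))),
                                   function(nm) {
    x <- mat[, nm]
    if (sd(x) == 0) {
      return(data.frame(param = nm, ess = NA_real_,
                        t(setNames(rep(NA_real_, length(lags)),
                                   paste0("acf", lags))),
                        degenerate = TRUE, low_ess = TRUE))
    }
    ess <- as.numeric(coda::effectiveSize(coda::mcmc(x)))
    ac <- acf(x, lag.max = max(lags), plot = FALSE)$acf[lags + 1]
    data.frame(param = nm, ess = ess,
               t(setNames(ac, paste0("acf", lags))),
               degenerate = FALSE, low_ess = ess < ess_floor)
  }))
  rownames(ess_tab) <- ess_tab$param
  out <- list(ess = ess_tab)
  if (length(chains) >= 2) {
    keep <- colnames(mat)[apply(mat, 2, sd) > 0]
    ml <- coda::mcmc.list(lapply(chains, function(m)
      coda::mcmc(m[, keep, drop = FALSE])))
    psrf <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE,
                                       multivariate = FALSE)$psrf,
                     error = function(e) NULL)
    # identical chains give 0/0; zero between-chain variance means exact
    # agreement, so report the statistic at its ideal value
    if (!is.null(psrf)) psrf[is.nan(psrf)] <- 1
    out$psrf <- psrf
  }
  out
}

#' Log marginal likelihood by stepping-stone sampling
#'
#' Runs a ladder of power posteriors with inverse temperatures placed at
#' quantiles of Beta(0.3, 1) and accumulates importance-weighted ratio
#' estimates between adjacent stones, warm-starting each stone from the
#' previous one. Reports a Monte-Carlo standard error from the effective
#' sample size of the per-stone weights and flags stones whose weight
#' distribution is dominated by a single draw (non-overlapping stones).
#'
#' @inheritParams sample_posterior
#' @return List with `logml`, `se`, per-stone table, and `overlap_warning`.
#' @export
stepping_stone_log_marginal <- function(tree, tipvec,
                                        model = c("dependent", "independent"),
                                        config = chain_config(),
                                        fixed_rates = NULL) {
  spec <- model_spec(model, fixed_rates)
  K <- config$n_stones
  stopifnot(K >= 8)
  betas <- ((0:K) / K)^(1 / 0.3)
  stone_cfg <- config
  stone_cfg$iterations <- config$stone_burnin + config$stone_iterations
  stone_cfg$burnin <- config$stone_burnin
  stone_cfg$thinning <- 1L

  # anneal from the posterior down to the prior (hot to cold), warm-starting
  # every stone from the one above: chains then never have to recover from
  # the diffuse-prior region, which is where cold-started ladders stall
  pilot <- run_chain(tree, tipvec, spec, stone_cfg, beta_power = 1,
                     seed = derive_seed(config$seed, 999))
  init <- list(assign = pilot$final_assign, vals = pilot$final_vals,
               m = pilot$final_m)
  log_r <- se2 <- numeric(K)
  overlap <- logical(K)
  for (k in rev(seq_len(K))) {
    res <- run_chain(tree, tipvec, spec, stone_cfg,
                     beta_power = betas[k],
                     init = init, seed = derive_seed(config$seed, k))
    init <- list(assign = res$final_assign, vals = res$final_vals,
                 m = res$final_m)
    w <- (betas[k + 1] - betas[k]) * res$logl
    log_r[k] <- log_sum_exp(w) - log(length(w))
    a <- exp(w - max(w))
    ess_w <- max(1, as.numeric(coda::effectiveSize(coda::mcmc(a))))
    se2[k] <- var(a) / (ess_w * mean(a)^2)
    overlap[k] <- max(a) / sum(a) > 0.5
  }
  if (any(overlap))
    warning("stepping-stone stones with poorly overlapping power posteriors: ",
            paste(which(overlap), collapse = ", "))
  list(logml = sum(log_r), se = sqrt(sum(se2)),
       stones = data.frame(stone = seq_len(K), beta_from = betas[1:K],
                           beta_to = betas[-1], log_ratio = log_r,
                           se = sqrt(se2), dominated = overlap),
       overlap_warning = any(overlap), model = spec$name %||% "custom")
}
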