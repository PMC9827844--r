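#' Phylogenetic correlation matrix from a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length divided by the
#' maximum root-to-tip depth; for an exactly ultrametric tree the diagonal
#' is rescaled to 1. If round-off pushes the smallest eigenvalue below
#' zero, a jitter of at most 1e-8 is added to the diagonal (with a message).
#'
#' @param tree A `phylo` object with positive root-to-tip depths.
#' @return A species x species correlation matrix.
#' @export
phylo_correlation <- function(tree) {
  V <- ape::vcv.phylo(tree)
  depths <- diag(V)
  dmax <- max(depths)
  if (dmax <= 0) stop("tree has zero depth")
  C <- V / dmax
  if (max(depths) - min(depths) < 1e-8 * dmax) diag(C) <- 1
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) {
    message("phylo_correlation: adding diagonal jitter ",
            format(min(1e-8, -ev_min * 2)), " for positive semi-definiteness")
    diag(C) <- diag(C) + min(1e-8, -ev_min * 2)
  }
  C
}

#' Specification of a phylogenetic probit model
#'
#' The latent-liability model: `l = intercept + X beta + u + e`, with
#' `u ~ N(0, sigma2_p * C)` for the phylogenetic correlation `C`,
#' `e ~ N(0, 1)` (residual variance fixed at 1, as required for a binary
#' response), and the response observed as `y = 1` iff `l > 0`. Fixed
#' effects carry a diffuse normal prior (variance 1e8); the phylogenetic
#' standard deviation carries a half-t prior (scale 1, df 1), a
#' weakly-informative heavy-tailed choice spreading mass over a wide
#' variance range.
#'
#' @param response Name of the binary response trait.
#' @param predictors Character vector of predictor trait names (ordered).
#' @param prior_var Prior variance of fixed effects (default 1e8).
#' @param iterations,burnin,thinning Chain settings; defaults mirror the
#'   long production runs (5e6 / 1e5 / 2500); tests use much shorter
#'   presets.
#' @param sigma_prior Prior on the phylogenetic variance: `"uniform_h2"`
#'   (default) places a uniform prior on the heritability
#'   `h2 = sigma2_p / (sigma2_p + 1 + L)` (approximately a cumulative
#'   uniform on the variance fraction, and proper, so the variance cannot
#'   drift without bound when clades separate perfectly); `"half_t"` is a
#'   heavy-tailed half-t on the phylogenetic SD.
#' @param sigma_df,sigma_scale Half-t parameters (used when
#'   `sigma_prior = "half_t"`).
#' @param include_link_variance Include the probit link variance in the
#'   heritability denominator (default TRUE).
#' @return A list of class `probit_spec`.
#' @export
probit_spec <- function(response, predictors, prior_var = 1e8,
                        iterations = 5e6, burnin = 1e5, thinning = 2500,
                        sigma_prior = c("uniform_h2", "half_t"),
                        sigma_df = 1, sigma_scale = 1,
                        include_link_variance = TRUE) {
  if (response %in% predictors)
    stop("response must not be among the predictors")
  stopifnot(burnin < iterations, thinning >= 1)
  structure(list(response = response, predictors = predictors,
                 prior_var = prior_var, iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thinning = as.integer(thinning),
                 sigma_prior = match.arg(sigma_prior),
                 sigma_df = sigma_df, sigma_scale = sigma_scale,
                 include_link_variance = isTRUE(include_link_variance)),
            class = "probit_spec")
}

# truncated standard-normal draws on (a, Inf) or (-Inf, a), vectorized via
# inverse CDF with clamping to keep qnorm finite
rtruncnorm_lower <- function(mu) {   # l > 0 given mean mu, sd 1
  p <- pnorm(-mu)
  u <- p + runif(length(mu)) * (1 - p)
  mu + qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))
}
rtruncnorm_upper <- function(mu) {   # l <= 0
  p <- pnorm(-mu)
  u <- runif(length(mu)) * p
  mu + qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))
}

#' Fit the phylogenetic probit model by blocked Gibbs/MH
#'
#' Latent liabilities are drawn from their truncated-normal conditionals;
#' fixed effects and phylogenetic effects are drawn jointly from their
#' normal conditional (the phylogenetic effects are parameterized in the
#' eigenbasis of the correlation matrix, making the update O(n^2));
#' the phylogenetic variance is updated by a random-walk MH step on its
#' log, under the half-t prior on the standard deviation. The residual
#' variance is never updated (fixed at 1).
#'
#' @param traits Trait matrix (species rownames) from [read_traits()] or
#'   [generate_study()].
#' @param tree An aligned `phylo` object.
#' @param spec A [probit_spec()].
#' @param seed Integer seed.
#' @param fix_sigma2p Optionally fix the phylogenetic variance (e.g. 0 for
#'   a non-phylogenetic probit); default NULL (sampled).
#' @return A `probit_posterior`: matrices of beta samples, sigma2_p and h2
#'   samples, per-predictor Px, and the dropped-predictor report.
#' @export
fit_probit <- function(traits, tree, spec, seed = 1L, fix_sigma2p = NULL) {
  stopifnot(inherits(spec, "probit_spec"))
  al <- align_tree_traits(tree, traits)
  traits <- al$traits; tree <- al$tree
  y <- traits[, spec$response]
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("response must have at least 2 species in each class")

  keep <- spec$predictors
  const <- keep[apply(traits[, keep, drop = FALSE], 2, function(x)
    length(unique(x)) < 2)]
  if (length(const)) {
    warning("dropping constant predictor(s): ", paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  X <- cbind(`(Intercept)` = 1, traits[, keep, drop = FALSE])
  n <- nrow(X); p <- ncol(X)

  C <- phylo_correlation(tree)
  eg <- eigen(C, symmetric = TRUE)
  E <- eg$vectors
  d <- pmax(eg$values, 1e-10)
  Xe <- crossprod(E, X)                 # E'X, fixed across iterations
  XtX <- crossprod(X)

  set.seed(seed)
  nsamp <- (spec$iterations - spec$burnin) %/% spec$thinning
  beta_out <- matrix(NA_real_, nsamp, p,
                     dimnames = list(NULL, colnames(X)))
  s2_out <- numeric(nsamp)

  b <- rep(0, p)
  a <- rep(0, n)                        # phylogenetic effects, eigen-coords
  sigma2 <- fix_sigma2p %||% 0.5
  use_phylo <- is.null(fix_sigma2p) || fix_sigma2p > 0
  l <- ifelse(y == 1, 0.5, -0.5)
  theta_sd <- 0.8                       # RW sd on log sigma2
  isamp <- 0L
  ktot <- 1 + if (spec$include_link_variance) 1 else 0
  # The diffuse fixed-effect prior applies to liability-standardized
  # effects: b | sigma2 ~ N(0, prior_var * (sigma2 + ktot)).  With the
  # residual variance fixed at 1 the liability scale is only weakly
  # identified; a scale-free effect prior would make the posterior of the
  # scale (and hence of sigma2) improper.  Standardizing keeps the prior
  # "largely uninformative" at any scale while making the model proper.
  tau_b <- function(s2) spec$prior_var * (s2 + ktot)
  # log prior density of sigma2 (in the sigma2 coordinate)
  lprior_s2 <- function(s2) {
    if (spec$sigma_prior == "uniform_h2")
      log(ktot) - 2 * log(s2 + ktot)
    else
      stats::dt(sqrt(s2) / spec$sigma_scale, df = spec$sigma_df,
                log = TRUE) - 0.5 * log(s2) - log(2 * spec$sigma_scale)
  }

  acc <- 0L; tries <- 0L
  for (it in seq_len(spec$iterations)) {
    # liabilities | b, a
    mu <- as.numeric(X %*% b) + if (use_phylo) as.numeric(E %*% a) else 0
    l <- ifelse(y == 1, rtruncnorm_lower(mu), rtruncnorm_upper(mu))

    z <- crossprod(E, l)                # rotate once per iteration

    # sigma2 | l, b with the phylogenetic effects integrated out (collapsed
    # update: in the eigenbasis z_i ~ N((Xe b)_i, sigma2 d_i + 1), which
    # avoids the funnel coupling of sigma2 with the effects themselves);
    # the effects are redrawn downstream, keeping the sweep valid
    if (use_phylo && is.null(fix_sigma2p)) {
      r2 <- as.numeric(z - Xe %*% b)^2
      sumb2 <- sum(b^2)
      logmarg <- function(s2) {
        v <- s2 * d + 1
        -0.5 * sum(r2 / v + log(v)) -
          0.5 * (p * log(tau_b(s2)) + sumb2 / tau_b(s2)) +
          lprior_s2(s2) + log(s2)       # log-scale proposal Jacobian
      }
      lp_cur <- logmarg(sigma2)
      for (sub in 1:3) {
        thp <- log(sigma2) + theta_sd * rnorm(1)
        lp_new <- logmarg(exp(thp))
        tries <- tries + 1L
        if (log(runif(1)) < lp_new - lp_cur) {
          sigma2 <- exp(thp); lp_cur <- lp_new; acc <- acc + 1L
        }
      }
      if (it <= spec$burnin && tries >= 60) {  # tune toward ~30% acceptance
        theta_sd <- min(5, max(0.05, theta_sd * exp(0.5 * (acc / tries - 0.3))))
        acc <- 0L; tries <- 0L
      }
    }

    if (use_phylo) {
      s <- sigma2 * d / (sigma2 * d + 1)
      # marginal conditional of b (phylogenetic effects integrated out)
      Pb <- XtX + diag(1 / tau_b(sigma2), p) - crossprod(Xe, s * Xe)
      rb <- crossprod(Xe, (1 - s) * z)
      U <- chol(Pb)
      mu_b <- backsolve(U, forwardsolve(t(U), rb))
      b <- as.numeric(mu_b + backsolve(U, rnorm(p)))
      # a | b
      ma <- s * (z - Xe %*% b)
      a <- as.numeric(ma + sqrt(s) * rnorm(n))
    } else {
      Pb <- XtX + diag(1 / (spec$prior_var * ktot), p)
      rb <- crossprod(X, l)
      U <- chol(Pb)
      mu_b <- backsolve(U, forwardsolve(t(U), rb))
      b <- as.numeric(mu_b + backsolve(U, rnorm(p)))
    }

    # group scaling move: rescale (l, b, a, sigma2) jointly by c > 0.  The
    # observation model only constrains sign(l), so the move accepts on the
    # Gaussian residual/prior terms plus the transformation Jacobian, and
    # lets the liability scale (and with it sigma2) mix across orders of
    # magnitude instead of random-walking along the weakly identified ray.
    if (use_phylo && is.null(fix_sigma2p)) {
      cc <- exp(0.4 * rnorm(1))
      s2n <- cc^2 * sigma2
      r <- l - as.numeric(X %*% b) - as.numeric(E %*% a)
      sumb2 <- sum(b^2)
      logA <- -0.5 * (cc^2 - 1) * sum(r^2) +
        (2 * n + p + 2) * log(cc) - n * log(cc) +        # Jacobian minus a-norm
        (-0.5 * (p * log(tau_b(s2n)) + cc^2 * sumb2 / tau_b(s2n))) -
        (-0.5 * (p * log(tau_b(sigma2)) + sumb2 / tau_b(sigma2))) +
        lprior_s2(s2n) - lprior_s2(sigma2)
      if (log(runif(1)) < logA) {
        l <- cc * l; b <- cc * b; a <- cc * a; sigma2 <- s2n
      }
    }

    if (it > spec$burnin && (it - spec$burnin) %% spec$thinning == 0 &&
        isamp < nsamp) {
      isamp <- isamp + 1L
      beta_out[isamp, ] <- b
      s2_out[isamp] <- if (use_phylo) sigma2 else 0
    }
  }

  h2 <- heritability(s2_out, spec$include_link_variance)
  px <- vapply(setdiff(colnames(X), "(Intercept)"), function(nm)
    compute_px(beta_out[, nm], min_samples = 1), numeric(1))
  structure(list(beta = beta_out, sigma2p = s2_out, h2 = h2, px = px,
                 dropped_predictors = const, spec = spec, seed = seed),
            class = "probit_posterior")
}

#' @export
print.probit_posterior <- function(x, ...) {
  est <- colMeans(x$beta)
  ci <- apply(x$beta, 2, quantile, c(0.025, 0.975))
  tab <- data.frame(mean = est, ci_lower = ci[1, ], ci_upper = ci[2, ],
                    Px = c(NA, x$px)[match(colnames(x$beta),
                                           c("(Intercept)", names(x$px)))])
  cat("phylogenetic probit posterior (", nrow(x$beta), " samples)\n", sep = "")
  print(round(tab, 4))
  cat("h2: mean", round(mean(x$h2), 3), " 95% CI [",
      paste(round(quantile(x$h2, c(0.025, 0.975)), 3), collapse = ", "),
      "]\n")
  invisible(x)
}

#' Posterior probability of a coefficient crossing zero (Px)
#'
#' The fraction of posterior samples on the opposite side of zero from the
#' posterior median (samples exactly zero count as crossing); a predictor
#' is considered significant when Px < 0.05.
#'
#' @param beta_samples Numeric vector of posterior samples.
#' @param min_samples Minimum sample count (default 100).
#' @return The Px value (scalar in `[0, 0.5]` for any unimodal posterior).
#' @export
compute_px <- function(beta_samples, min_samples = 100) {
  if (length(beta_samples) < min_samples)
    stop("too few posterior samples for Px")
  med <- median(beta_samples)
  s <- sign(med)
  if (s == 0) return(0.5)
  mean(sign(beta_samples) != s | beta_samples == 0)
}

#' Liability-scale phylogenetic heritability
#'
#' `h2 = sigma2_p / (sigma2_p + 1 + L)` per posterior sample, where 1 is
#' the fixed residual variance and `L = 1` adds the probit link variance
#' (the default liability-scale convention; set
#' `include_link_variance = FALSE` to omit it). Interpreted like Pagel's
#' lambda: 0 = no phylogenetic signal, 1 = maximal.
#'
#' @param sigma2_p_samples Non-negative posterior samples of the
#'   phylogenetic variance.
#' @param include_link_variance Include the link variance (default TRUE).
#' @return Vector of h2 samples in `[0, 1)`.
#' @export
heritability <- function(sigma2_p_samples, include_link_variance = TRUE) {
  stopifnot(all(sigma2_p_samples >= 0))
  L <- if (include_link_variance) 1 else 0
  sigma2_p_samples / (sigma2_p_samples + 1 + L)
}

#' Variance inflation factors for binary predictors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from the OLS regression (with intercept) of
#' predictor k on the remaining predictors. Values above 5 are flagged as
#' problematic collinearity; a perfectly collinear predictor is reported
#' as infinite with a hard flag.
#'
#' @param traits Trait matrix.
#' @param predictor_names At least two non-constant predictor columns.
#' @return data.frame with columns `vif` and `flag`.
#' @export
vif <- function(traits, predictor_names) {
  stopifnot(length(predictor_names) >= 2)
  X <- traits[, predictor_names, drop = FALSE]
  if (any(apply(X, 2, function(x) length(unique(x)) < 2)))
    stop("constant predictor in VIF computation")
  out <- vapply(seq_along(predictor_names), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictor_names, vif = out, flag = out > 5,
             row.names = predictor_names)
}
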