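#' Compare dependent and independent models by log Bayes factor
#'
#' `logBF = 2 * (lnML_dep - lnML_indep)` on the conventional 2*delta-lnML
#' scale, graded as `"independent-supported"` (logBF < -positive),
#' `"inconclusive"` (|logBF| <= positive), `"dependent-positive"`
#' (positive < logBF <= strong) or `"dependent-strong"` (logBF > strong).
#'
#' @param ml_dep,ml_indep Log marginal likelihoods (scalars or the lists
#'   returned by [stepping_stone_log_marginal()]).
#' @param thresholds Named vector with `positive` (default 2) and `strong`
#'   (default 10).
#' @return List of class `model_comparison`.
#' @export
compare_models <- function(ml_dep, ml_indep,
                           thresholds = c(positive = 2, strong = 10)) {
  get <- function(x) if (is.list(x)) c(x$logml, x$se %||% NA_real_)
                     else c(x, NA_real_)
  d <- get(ml_dep); i <- get(ml_indep)
  stopifnot(is.finite(d[1]), is.finite(i[1]))
  logbf <- 2 * (d[1] - i[1])
  grade <- if (logbf < -thresholds[["positive"]]) "independent-supported"
    else if (abs(logbf) <= thresholds[["positive"]]) "inconclusive"
    else if (logbf <= thresholds[["strong"]]) "dependent-positive"
    else "dependent-strong"
  structure(list(logml_dep = d[1], se_dep = d[2],
                 logml_indep = i[1], se_indep = i[2],
                 logbf = logbf, grade = grade, thresholds = thresholds),
            class = "model_comparison")
}

#' Posterior support for a transition-rate inequality
#'
#' Computes `P(left > right)` sample-wise over paired posterior draws
#' (preserving within-sample dependence); exact ties are counted
#' separately.
#'
#' @param trace A `posterior_trace` (or samples matrix with rate columns).
#' @param left,right Rate labels, e.g. `"q34"`, `"q12"`.
#' @return List of class `inequality_claim` with `support`, `ties`, labels.
#' @export
inequality_support <- function(trace, left, right) {
  samples <- if (inherits(trace, "posterior_trace")) trace$samples else trace
  if (!all(c(left, right) %in% colnames(samples)))
    stop("unknown rate label(s): ",
         paste(setdiff(c(left, right), colnames(samples)), collapse = ", "))
  a <- samples[, left]; b <- samples[, right]
  structure(list(left = left, right = right,
                 support = mean(a > b), ties = mean(a == b),
                 n = length(a)),
            class = "inequality_claim")
}

# the eight directional claims the hypothesis rules consume
standard_claims <- function(trace) {
  pairs <- list(c("q34", "q12"), c("q13", "q12"),
                c("q24", "q13"), c("q12", "q13"),
                c("q12", "q21"), c("q42", "q24"),
                c("q13", "q31"), c("q43", "q34"))
  cl <- lapply(pairs, function(p) inequality_support(trace, p[1], p[2]))
  names(cl) <- vapply(pairs, function(p) paste0(p[1], ">", p[2]),
                      character(1))
  cl
}

#' Per-state evolutionary stability profile
#'
#' For each joint state, tabulates posterior support that each rate
#' entering the state exceeds the corresponding exiting rate (the paired
#' comparisons q12/q21, q13/q31, q24/q42, q34/q43), in both directions. A
#' state gained faster than it is lost is evolutionarily stable; the
#' both-present state being lost faster than gained is the signature of
#' the alternative-solutions hypothesis.
#'
#' @param summary A rate summary ([summarize_rates()]), used for reporting.
#' @param trace A dependent-model `posterior_trace`.
#' @return data.frame, one row per entering/exiting rate pair.
#' @export
stability_profile <- function(summary, trace) {
  pairs <- rbind(
    c("2 (care alone)",      "q12", "q21"),
    c("3 (ecology alone)",   "q13", "q31"),
    c("4 (both, via care)",  "q24", "q42"),
    c("4 (both, via ecol)",  "q34", "q43"))
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    gain <- inequality_support(trace, pairs[i, 2], pairs[i, 3])
    loss <- inequality_support(trace, pairs[i, 3], pairs[i, 2])
    data.frame(state = pairs[i, 1],
               gain_rate = pairs[i, 2], loss_rate = pairs[i, 3],
               support_gain_gt_loss = gain$support,
               support_loss_gt_gain = loss$support,
               ties = gain$ties,
               stable = gain$support > 0.5)
  }))
  out
}

#' Classify the evolutionary pathway for a trait pair
#'
#' Maps the model comparison, the posterior inequality supports, and the
#' zero-bin percentages onto one of five verdicts:
#' \describe{
#'   \item{unrelated}{the independent model is the supported model;}
#'   \item{ecology_first}{support(q34 > q12) >= theta, or
#'     support(q13 > q12) >= theta with pct_zero(q34) < 25 (the ecological
#'     trait is gained first and care follows at a meaningfully positive
#'     rate);}
#'   \item{care_first}{the mirrored conditions (q24 > q13; q12 > q13 with
#'     pct_zero(q24) < 25);}
#'   \item{alternative_solutions}{each single-trait state is gained faster
#'     than lost while the both-present state is lost faster than gained
#'     (q12 > q21, q42 > q24, q13 > q31, q43 > q34, each at >= theta);}
#'   \item{unresolved}{no rule fires, or conflicting rules fire.}
#' }
#' All fired/failed conditions are reported in the evidence table; the
#' verdict is a pure function of its inputs.
#'
#' @param comparison A `model_comparison`.
#' @param claims Named list of `inequality_claim`s (see
#'   [inequality_support()]); the standard set is built by
#'   [run_full_analysis()].
#' @param summary A rate summary with `pct_zero` column.
#' @param theta Posterior support threshold for a clear claim
#'   (default 0.95); 0.75 is reported as a suggestive tier in the evidence.
#' @return List of class `pathway_verdict`.
#' @export
classify_pathway <- function(comparison, claims, summary, theta = 0.95) {
  sup <- function(nm) {
    if (!nm %in% names(claims)) stop("missing claim: ", nm)
    claims[[nm]]$support
  }
  pz <- function(rate) summary[rate, "pct_zero"]

  if (comparison$grade == "independent-supported") {
    return(structure(list(label = "unrelated", comparison = comparison,
                          evidence = data.frame(
                            condition = "independent model supported",
                            value = comparison$logbf, fired = TRUE),
                          theta = theta),
                     class = "pathway_verdict"))
  }

  ev <- data.frame(
    condition = c("support(q34>q12) >= theta",
                  "support(q13>q12) >= theta & pct_zero(q34) < 25",
                  "support(q24>q13) >= theta",
                  "support(q12>q13) >= theta & pct_zero(q24) < 25",
                  "stability: q12>q21, q42>q24, q13>q31, q43>q34 all >= theta"),
    value = c(sup("q34>q12"), sup("q13>q12"), sup("q24>q13"),
              sup("q12>q13"),
              min(sup("q12>q21"), sup("q42>q24"),
                  sup("q13>q31"), sup("q43>q34"))),
    fired = c(sup("q34>q12") >= theta,
              sup("q13>q12") >= theta && pz("q34") < 25,
              sup("q24>q13") >= theta,
              sup("q12>q13") >= theta && pz("q24") < 25,
              all(c(sup("q12>q21"), sup("q42>q24"),
                    sup("q13>q31"), sup("q43>q34")) >= theta)))
  ev$suggestive <- ev$value >= 0.75

  eco <- ev$fired[1] || ev$fired[2]
  care <- ev$fired[3] || ev$fired[4]
  alt <- ev$fired[5]
  fired <- c(ecology_first = eco, care_first = care,
             alternative_solutions = alt)
  label <- if (sum(fired) == 1) names(fired)[fired] else "unresolved"
  structure(list(label = label, comparison = comparison, evidence = ev,
                 fired = fired, theta = theta),
            class = "pathway_verdict")
}

#' @export
print.pathway_verdict <- function(x, ...) {
  cat("pathway verdict:", x$label,
      sprintf("(model grade: %s, logBF = %.2f)\n",
              x$comparison$grade, x$comparison$logbf))
  print(x$evidence)
  invisible(x)
}

#' Run the full two-stage comparative analysis
#'
#' Stage 1: VIF collinearity screen (predictors with VIF > 5 are excluded,
#' last-listed first) and a joint phylogenetic probit of the response on
#' all surviving predictors. Stage 2: for each predictor with Px < 0.05,
#' dependent and independent 4-state models are fitted to the (predictor,
#' response) pair by RJ-MCMC (in `n_seeds` replicate chains; chain 1 is
#' reported, all chains feed the convergence diagnostics) on the
#' branch-scaled tree, with stepping-stone marginal likelihoods for both
#' models. Stage 3: model comparison, rate summaries, inequality claims
#' and a pathway verdict per significant predictor. A failed stage marks
#' the affected trait pair only.
#'
#' @param tree A `phylo` object (unscaled; the discrete stage scales a
#'   copy to mean branch length `scale_mean`).
#' @param traits Trait matrix including response and predictors.
#' @param response Binary response trait name.
#' @param predictors Character vector of predictor names.
#' @param pspec A [probit_spec()] (defaults to one over `predictors`).
#' @param config A [chain_config()] for the discrete stage.
#' @param theta Support threshold for [classify_pathway()].
#' @param thresholds Bayes-factor grading thresholds.
#' @param n_seeds Number of replicate discrete chains (default 3).
#' @param scale_mean Target mean branch length before the discrete stage
#'   (default 0.1).
#' @param seed Master seed.
#' @return List of class `study_report`.
#' @export
run_full_analysis <- function(tree, traits, response, predictors,
                              pspec = NULL, config = chain_config(),
                              theta = 0.95,
                              thresholds = c(positive = 2, strong = 10),
                              n_seeds = 3, scale_mean = 0.1, seed = 1L) {
  al <- align_tree_traits(tree, traits)
  tree <- al$tree; traits <- al$traits

  # stage 1: collinearity screen, then the joint probit
  preds <- predictors
  vif_tab <- NULL
  while (length(preds) >= 2) {
    vif_tab <- vif(traits, preds)
    if (!any(vif_tab$flag)) break
    worst <- preds[vif_tab$vif == max(vif_tab$vif)]
    drop <- worst[length(worst)]       # last-listed among the worst
    message("run_full_analysis: excluding collinear predictor '", drop,
            "' (VIF = ", format(vif_tab[drop, "vif"], digits = 3), ")")
    preds <- setdiff(preds, drop)
  }
  pspec <- pspec %||% probit_spec(response, preds)
  pspec$predictors <- preds
  probit_fit <- fit_probit(traits, tree, pspec,
                           seed = derive_seed(seed, 1))
  significant <- names(probit_fit$px)[probit_fit$px < 0.05]

  # stage 2 + 3 per significant predictor
  stree <- scale_branch_lengths(tree, scale_mean)
  pairs <- list()
  for (pred in significant) {
    pairs[[pred]] <- tryCatch({
      tv <- tip_state_vectors(traits[, pred], traits[, response])
      colnames(tv) <- rownames(traits)
      traces <- lapply(seq_len(n_seeds), function(s) {
        cfg <- config; cfg$seed <- derive_seed(seed, 10 * match(pred, significant) + s)
        sample_posterior(stree, tv, "dependent", cfg)
      })
      trace <- traces[[1]]
      ml_dep <- stepping_stone_log_marginal(stree, tv, "dependent", {
        cfg <- config; cfg$seed <- derive_seed(seed, 100 + match(pred, significant)); cfg })
      ml_ind <- stepping_stone_log_marginal(stree, tv, "independent", {
        cfg <- config; cfg$seed <- derive_seed(seed, 200 + match(pred, significant)); cfg })
      comparison <- compare_models(ml_dep, ml_ind, thresholds)
      rsum <- summarize_rates(trace)
      claims <- standard_claims(trace)
      verdict <- classify_pathway(comparison, claims, rsum, theta)
      list(trace = trace, diagnostics = mcmc_diagnostics(traces),
           ml_dep = ml_dep, ml_indep = ml_ind, comparison = comparison,
           summary = rsum, claims = claims,
           stability = stability_profile(rsum, trace), verdict = verdict,
           error = NULL)
    }, error = function(e) list(error = conditionMessage(e)))
  }

  structure(list(probit = probit_fit, vif = vif_tab,
                 predictors_screened = preds, significant = significant,
                 pairs = pairs, response = response, seed = seed,
                 config = config, theta = theta, thresholds = thresholds,
                 stage2_skipped = length(significant) == 0),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== study report (response:", x$response, ") ==\n")
  cat("VIF screen:\n"); print(x$vif)
  cat("significant predictors (Px < 0.05):",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "none (discrete stage skipped)", "\n")
  for (nm in names(x$pairs)) {
    cat("\n--", nm, "--\n")
    if (!is.null(x$pairs[[nm]]$error))
      cat("stage failed:", x$pairs[[nm]]$error, "\n")
    else
      print(x$pairs[[nm]]$verdict)
  }
  invisible(x)
}
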