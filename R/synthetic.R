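#' Simulate a pure-birth (Yule) tree grown to a fixed tip count
#'
#' Starts with two lineages at the root; while fewer than `n_tips`
#' lineages are active, waits an Exponential(k * birth_rate) time and
#' splits one lineage uniformly at random; after the n-th lineage appears
#' a final Exponential(n * birth_rate) stretch runs to the present, so all
#' tips are contemporaneous and the expected root-to-tip depth is
#' `sum_{k=2..n} 1 / (k * birth_rate)`. By default branch lengths are then
#' rescaled so the all-branch mean is 0.1, matching the convention applied
#' before the discrete analyses.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Positive speciation rate.
#' @param seed Optional integer seed.
#' @param scale Rescale to mean branch length `target_mean` (default TRUE).
#' @param target_mean Target mean branch length when scaling.
#' @return A `phylo` object; attribute `"depth_raw"` records the unscaled
#'   root-to-tip depth.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                          scale = TRUE, target_mean = 0.1) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  root <- n + 1L
  next_internal <- n + 2L
  # active lineages: parent node id and the time its branch started
  act_parent <- c(root, root)
  act_start <- c(0, 0)
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  t <- 0
  k <- 2L
  while (k < n) {
    t <- t + rexp(1, k * birth_rate)
    i <- sample.int(k, 1L)
    node <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(act_parent[i], node))
    lens <- c(lens, t - act_start[i])
    act_parent[i] <- node; act_start[i] <- t
    act_parent <- c(act_parent, node); act_start <- c(act_start, t)
    k <- k + 1L
  }
  t <- t + rexp(1, n * birth_rate)     # final stretch to the present
  tip_ids <- sample.int(n)             # randomize tip placement
  edges <- rbind(edges, cbind(act_parent, tip_ids))
  lens <- c(lens, t - act_start)

  tree <- structure(list(edge = edges, edge.length = lens,
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = n - 1L),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "depth_raw") <- t
  if (scale) {
    depth <- t
    tree <- scale_branch_lengths(tree, target_mean)
    attr(tree, "depth_raw") <- depth
  }
  tree
}

#' Named regime presets for the synthetic generator
#'
#' Each preset is a documented rate set realizing the inequality pattern
#' of one hypothesis, together with the verdict the pipeline should
#' recover:
#' \describe{
#'   \item{ecology_first}{care cannot arise without the ecology trait
#'     (q12 = 0) and arises quickly with it (q34 = 3 > q12); the ecology
#'     trait is gained readily from the double-absence state (q13 = 1.5)
#'     and care without it is shed fast (q21 = 3).}
#'   \item{care_first}{the exact mirror (traits A and B swapped).}
#'   \item{alternative_solutions}{each single trait is stable
#'     (q12 > q21, q13 > q31) but the both-present state decays quickly
#'     (q43, q42 high; q34, q24 low).}
#'   \item{independent}{the two traits evolve independently, all gain and
#'     loss rates 1.}
#'   \item{null_care}{the care trait barely evolves (gain and loss 0.1)
#'     and is independent of the ecology trait.}
#' }
#'
#' @param name One of the preset names above.
#' @param scale Positive multiplier applied to every rate (default 1).
#' @return List of class `regime_preset` with `name`, `rates`, `verdict`.
#' @export
regime_rates <- function(name, scale = 1) {
  stopifnot(scale > 0)
  preset <- switch(name,
    ecology_first = list(
      rates = rate_set(q12 = 0, q13 = 1.5, q21 = 3, q24 = 0.5,
                       q31 = 2, q34 = 3, q42 = 0.3, q43 = 1.2),
      verdict = "ecology_first"),
    care_first = list(
      rates = rate_set(q12 = 1.5, q13 = 0, q21 = 2, q24 = 3,
                       q31 = 3, q34 = 0.5, q42 = 1.2, q43 = 0.3),
      verdict = "care_first"),
    alternative_solutions = list(
      rates = rate_set(q12 = 1.5, q13 = 1.5, q21 = 0.5, q24 = 0.3,
                       q31 = 0.5, q34 = 0.3, q42 = 2.5, q43 = 2.5),
      verdict = "alternative_solutions"),
    independent = list(
      rates = independent_rates(1, 1, 1, 1),
      verdict = "unrelated"),
    null_care = list(
      rates = independent_rates(1, 1, 0.1, 0.1),
      verdict = "unrelated"),
    stop("unknown regime: ", name))
  rates <- if (inherits(preset$rates, "indep_rates")) preset$rates
           else rate_set(as.numeric(preset$rates) * scale)
  if (inherits(preset$rates, "indep_rates"))
    rates <- independent_rates(preset$rates[["alpha_A"]] * scale,
                               preset$rates[["beta_A"]] * scale,
                               preset$rates[["alpha_B"]] * scale,
                               preset$rates[["beta_B"]] * scale)
  structure(list(name = name, rates = rates, verdict = preset$verdict,
                 scale = scale),
            class = "regime_preset")
}

# defining inequalities of each regime; used by tests and sanity checks
check_regime <- function(preset) {
  q <- as_rate_set(preset$rates)
  ok <- switch(preset$name,
    ecology_first = q[["q12"]] == 0 && q[["q13"]] > q[["q12"]] &&
      q[["q34"]] > q[["q12"]] && q[["q34"]] > 0,
    care_first = q[["q13"]] == 0 && q[["q12"]] > q[["q13"]] &&
      q[["q24"]] > q[["q13"]] && q[["q24"]] > 0,
    alternative_solutions = q[["q43"]] > q[["q34"]] &&
      q[["q42"]] > q[["q24"]] && q[["q12"]] > q[["q21"]] &&
      q[["q13"]] > q[["q31"]],
    independent = inherits(preset$rates, "indep_rates"),
    null_care = inherits(preset$rates, "indep_rates") &&
      preset$rates[["alpha_B"]] < 0.5 * preset$rates[["alpha_A"]],
    FALSE)
  isTRUE(ok)
}

#' Generate one paired-trait dataset under a regime preset
#'
#' Draws the root state from the stationary distribution of the preset's
#' generator (state 1 with a warning when the chain is reducible) and runs
#' the exact Gillespie simulation of [simulate_history()].
#'
#' @param tree A `phylo` object.
#' @param preset A [regime_rates()] preset.
#' @param seed Optional integer seed.
#' @return List with `traits` (matrix with columns `trait_A`, `trait_B`),
#'   `history` (the event list) and `preset`.
#' @export
generate_dataset <- function(tree, preset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- build_generator(preset$rates)
  pi0 <- stationary_distribution(Q)
  # irreducible iff every state reaches every other through positive rates
  reach <- (Q > 0) | diag(4) > 0
  for (m in 1:4) reach <- reach | (reach[, m] %o% reach[m, ])
  reducible <- !all(reach) || any(pi0 < 1e-12) || any(!is.finite(pi0))
  root_state <- if (reducible) {
    warning("reducible generator; rooting history in state 1")
    1L
  } else sample.int(4, 1L, prob = pi0)
  hist <- simulate_history(tree, preset$rates, root_state = root_state)
  st <- hist$tip_states
  traits <- cbind(trait_A = (st - 1L) %/% 2L, trait_B = (st - 1L) %% 2L)
  rownames(traits) <- names(st)
  list(traits = traits[tree$tip.label, , drop = FALSE], history = hist,
       preset = preset)
}

#' Generate a full synthetic study (tree + response + predictors)
#'
#' One Yule tree; each predictor evolves under its named regime. The
#' response (care) trait is taken from the pair simulated under the first
#' coupled regime (any preset other than `independent`/`null_care`); all
#' other predictors get their own independent histories, so they are
#' statistically unrelated to the response. At most one coupled regime is
#' supported per study. Full provenance (seeds, presets) is embedded for
#' exact replay.
#'
#' @param n_tips Number of tips.
#' @param regimes Named character vector: predictor name -> regime name.
#' @param seed Master integer seed.
#' @param response_name Column name of the response trait.
#' @param birth_rate Yule speciation rate.
#' @param scale Rate-scale multiplier passed to [regime_rates()].
#' @return List of class `synthetic_study` with `tree`, `traits` (response
#'   plus one column per predictor), `histories`, `regimes`, `seeds`.
#' @export
generate_study <- function(n_tips, regimes, seed = 1L,
                           response_name = "attendance", birth_rate = 1,
                           scale = 1) {
  stopifnot(length(regimes) >= 1, !is.null(names(regimes)))
  coupled <- names(regimes)[!regimes %in% c("independent", "null_care")]
  if (length(coupled) > 1)
    stop("at most one regime may couple a predictor to the response; got: ",
         paste(coupled, collapse = ", "))
  tree <- simulate_tree(n_tips, birth_rate, seed = derive_seed(seed, 0))
  response_from <- if (length(coupled)) coupled else names(regimes)[1]

  traits <- matrix(NA_integer_, length(tree$tip.label),
                   1 + length(regimes),
                   dimnames = list(tree$tip.label,
                                   c(response_name, names(regimes))))
  histories <- list()
  presets <- list()
  seeds <- c(tree = derive_seed(seed, 0))
  for (i in seq_along(regimes)) {
    nm <- names(regimes)[i]
    presets[[nm]] <- regime_rates(regimes[[i]], scale)
    s <- derive_seed(seed, i)
    seeds[nm] <- s
    ds <- generate_dataset(tree, presets[[nm]], seed = s)
    histories[[nm]] <- ds$history
    traits[, nm] <- ds$traits[, "trait_A"]
    if (nm == response_from)
      traits[, response_name] <- ds$traits[, "trait_B"]
  }
  structure(list(tree = tree, traits = traits, histories = histories,
                 presets = presets, regimes = regimes, seeds = seeds,
                 response = response_name, response_from = response_from,
                 seed = seed),
            class = "synthetic_study")
}

#' Serialize a synthetic study to a directory
#'
#' Writes `tree.nwk` (Newick), `traits.csv` and `truth.json` (rates,
#' seeds, regime labels, event counts) for replay outside R.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  df <- data.frame(species = rownames(study$traits), study$traits,
                   check.names = FALSE)
  utils::write.csv(df, file.path(dir, "traits.csv"), row.names = FALSE)
  truth <- list(
    seed = study$seed, seeds = as.list(study$seeds),
    regimes = as.list(study$regimes),
    response = study$response, response_from = study$response_from,
    rates = lapply(study$presets, function(p)
      as.list(setNames(as.numeric(as_rate_set(p$rates)), RATE_NAMES))),
    event_counts = lapply(study$histories, function(h) nrow(h$events)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
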