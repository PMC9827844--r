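# small synthetic trace helper: constant matrices as posterior samples
fake_trace <- function(..., n = 200) {
  vals <- list(...)
  m <- matrix(0, n, 8, dimnames = list(NULL, names(rate_set(rep(0, 8)))))
  for (nm in colnames(m)) m[, nm] <- if (nm %in% names(vals)) vals[[nm]] else 1
  m
}

test_that("model comparison grades the log Bayes factor as stated", {
  cm <- compare_models(-100, -110)
  expect_equal(cm$logbf, 20)
  expect_equal(cm$grade, "dependent-strong")

  expect_equal(compare_models(-50, -50)$grade, "inconclusive")
  expect_equal(compare_models(-50, -53)$grade, "dependent-positive")
  expect_equal(compare_models(-53, -50)$grade, "independent-supported")
  # accepts stepping-stone result lists
  cm2 <- compare_models(list(logml = -10, se = 0.1),
                        list(logml = -12, se = 0.1))
  expect_equal(cm2$logbf, 4)
})

test_that("inequality support is computed on paired samples with ties", {
  m <- fake_trace(q34 = c(2, 3, 1), q12 = c(1, 1, 2), n = 3)
  cl <- inequality_support(m, "q34", "q12")
  expect_equal(cl$support, 2 / 3)
  expect_equal(cl$ties, 0)

  m2 <- fake_trace(n = 10)         # identical columns
  cl2 <- inequality_support(m2, "q34", "q12")
  expect_equal(cl2$support, 0)
  expect_equal(cl2$ties, 1)
  expect_error(inequality_support(m2, "q34", "q99"), "unknown")
  # P(a>b) + P(b>a) + ties = 1
  set.seed(1)
  m3 <- fake_trace(q34 = rpois(50, 2), q12 = rpois(50, 2), n = 50)
  s1 <- inequality_support(m3, "q34", "q12")
  s2 <- inequality_support(m3, "q12", "q34")
  expect_equal(s1$support + s2$support + s1$ties, 1)
})

test_that("stability profile flags states lost faster than gained", {
  m <- fake_trace(q43 = 5, q34 = 1, q42 = 5, q24 = 1)
  st <- stability_profile(summarize_rates(m), m)
  both <- st[grepl("^4", st$state), ]
  expect_true(all(both$support_loss_gt_gain == 1))
  expect_true(all(!both$stable))

  m2 <- fake_trace(n = 150)        # all rates equal
  st2 <- stability_profile(summarize_rates(m2), m2)
  expect_true(all(st2$support_gain_gt_loss == 0))
  expect_true(all(st2$ties == 1))
})

test_that("pathway classification maps evidence to the verdict table", {
  mk <- function(m) {
    list(claims = evopath:::standard_claims(m), summary = summarize_rates(m))
  }
  cm_dep <- compare_models(-100, -130)

  # ecology first: care evolves faster with the ecological trait present
  eco <- mk(fake_trace(q34 = 3, q12 = 0.01, q13 = 2, n = 200))
  v <- classify_pathway(cm_dep, eco$claims, eco$summary)
  expect_equal(v$label, "ecology_first")

  # care first: mirrored conditions
  care <- mk(fake_trace(q24 = 3, q13 = 0.01, q12 = 2, n = 200))
  v2 <- classify_pathway(cm_dep, care$claims, care$summary)
  expect_equal(v2$label, "care_first")

  # all supports ~0.5 with the dependent model supported -> unresolved
  set.seed(9)
  jit <- function() 1 + abs(rnorm(200, 0, 1e-3))
  flat <- fake_trace(q12 = jit(), q13 = jit(), q21 = jit(), q24 = jit(),
                     q31 = jit(), q34 = jit(), q42 = jit(), q43 = jit())
  v3 <- classify_pathway(cm_dep, evopath:::standard_claims(flat),
                         summarize_rates(flat))
  expect_equal(v3$label, "unresolved")

  # independent supported -> unrelated regardless of rates
  cm_ind <- compare_models(-130, -100)
  v4 <- classify_pathway(cm_ind, eco$claims, eco$summary)
  expect_equal(v4$label, "unrelated")

  # alternative solutions: single-trait states stable, both-present unstable
  alt <- mk(fake_trace(q12 = 2, q21 = 0.3, q13 = 2, q31 = 0.3,
                       q43 = 3, q34 = 0.5, q42 = 3, q24 = 0.5))
  v5 <- classify_pathway(cm_dep, alt$claims, alt$summary)
  expect_equal(v5$label, "alternative_solutions")

  # conflicting rules -> unresolved, both evidence rows present
  confl <- mk(fake_trace(q34 = 3, q12 = 2, q24 = 3, q13 = 0.01, n = 200))
  v6 <- classify_pathway(cm_dep, confl$claims, confl$summary)
  expect_true(v6$label %in% c("unresolved"))
})

test_that("verdicts are deterministic and respect the trait-swap symmetry", {
  m <- fake_trace(q34 = 3, q12 = 0.01, q13 = 2, n = 200)
  cm <- compare_models(-100, -130)
  cl <- evopath:::standard_claims(m); su <- summarize_rates(m)
  expect_identical(classify_pathway(cm, cl, su)$label,
                   classify_pathway(cm, cl, su)$label)

  # swap traits A and B: state 2 <-> 3 relabels rates
  # q12<->q13, q21<->q31, q24<->q34, q42<->q43
  swap <- m[, c("q13", "q12", "q31", "q34", "q21", "q24", "q43", "q42")]
  colnames(swap) <- colnames(m)
  vs <- classify_pathway(cm, evopath:::standard_claims(swap), summarize_rates(swap))
  expect_equal(vs$label, "care_first")
})

test_that("the full pipeline handles collinear and null screens gracefully", {
  study <- generate_study(80, c(T = "independent"), seed = 55)
  traits <- cbind(study$traits, T2 = study$traits[, "T"])
  sp <- probit_spec("attendance", c("T", "T2"), iterations = 1500,
                    burnin = 300, thinning = 3)
  expect_message(
    rep <- run_full_analysis(study$tree, traits, "attendance", c("T", "T2"),
                             pspec = sp,
                             config = chain_config(iterations = 2000,
                                                   burnin = 500,
                                                   thinning = 5),
                             n_seeds = 1, seed = 1),
    "collinear")
  expect_false("T2" %in% rep$predictors_screened)
  expect_true("T" %in% rep$predictors_screened)
  # with no significant predictor, stage 2 is skipped and the report says so
  if (length(rep$significant) == 0) expect_true(rep$stage2_skipped)
})
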