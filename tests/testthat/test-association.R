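test_that("BH flags match the step-up rule on hand examples", {
  expect_identical(bh_fdr(c(0.01, 0.04, 0.9), q = 0.1), c(TRUE, TRUE, FALSE))
  # step-up: a larger p can be rescued by a smaller one below it
  expect_identical(bh_fdr(c(0.01, 0.02, 0.9, 0.9), q = 0.1),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(0.05, 10), q = 0.1), rep(TRUE, 10))
  expect_identical(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "lie in")
  # agrees with p.adjust thresholding for random p
  set.seed(8)
  p <- runif(50)^2
  expect_identical(bh_fdr(p, 0.1), p.adjust(p, "BH") <= 0.1)
})

test_that("BH flags are rare under the complete null", {
  set.seed(123)
  flags <- replicate(50, mean(bh_fdr(runif(100), q = 0.1)))
  expect_lt(mean(flags), 0.02)
})

test_that("modified Poisson reproduces the closed-form 2x2 risk ratio", {
  set.seed(14)
  for (i in 1:10) {
    n1 <- sample(60:90, 1); k1 <- sample(3:12, 1)
    n2 <- sample(20:50, 1); k2 <- sample(5:15, 1)
    d <- replicated_covariate_frame(list(n1 = n1, k1 = k1, n2 = n2, k2 = k2))
    res <- fit_binary_outcome(d, "y", model = "basic")
    # covariates are balanced by construction, so the adjusted fit collapses
    # to the crude model: RR and robust SE equal the 2x2 closed forms
    N1 <- 8 * n1; K1 <- 8 * k1; N2 <- 8 * n2; K2 <- 8 * k2
    p1 <- K1 / N1; p2 <- K2 / N2
    expect_equal(res$effect, (K2 / N2) / (K1 / N1), tolerance = 1e-7)
    expect_equal(res$se, sqrt((1 - p1) / (N1 * p1) + (1 - p2) / (N2 * p2)),
                 tolerance = 1e-7)
    expect_identical(res$contrast_class, "2")
    expect_identical(attr(res, "reference"), "1")
    expect_identical(res$n_complete, nrow(d))
    expect_false(res$degenerate)
  }
})

test_that("g-computation agrees with modified Poisson on the crude design", {
  d <- replicated_covariate_frame(list(n1 = 80, k1 = 8, n2 = 40, k2 = 12))
  mp <- fit_binary_outcome(d, "y", model = "basic")
  gc <- fit_binary_outcome(d, "y", model = "basic", estimator = "gcomp")
  expect_equal(gc$effect, mp$effect, tolerance = 1e-6)
})

test_that("binary outcome edge cases are flagged, not fatal", {
  d <- replicated_covariate_frame(list(n1 = 40, k1 = 5, n2 = 30, k2 = 0))
  res <- suppressWarnings(fit_binary_outcome(d, "y", model = "basic"))
  expect_true(all(res$degenerate))
  d2 <- replicated_covariate_frame(list(n1 = 40, k1 = 5, n2 = 30, k2 = 3))
  d2$y <- d2$y * 2L
  expect_error(fit_binary_outcome(d2, "y", model = "basic"), "not binary")
  expect_error(fit_binary_outcome(d2[, -2], "y", model = "basic"),
               "missing column")
})

test_that("continuous outcomes reproduce the OLS oracle", {
  set.seed(15)
  d <- replicated_covariate_frame(list(n1 = 50, k1 = 5, n2 = 30, k2 = 5))
  d$z <- rnorm(nrow(d)) + 0.8 * (d$traj_class == 2)
  res <- fit_continuous_outcome(d, "z", model = "basic")
  ref <- lm(z ~ relevel(factor(traj_class), "1") + sex + maternal_education +
              social_class, data = d)
  sm <- summary(ref)$coefficients[2, ]
  expect_equal(res$effect, unname(sm[1]))
  expect_equal(res$se, unname(sm[2]))
  expect_equal(res$p_value, unname(sm[4]))
})

test_that("associate_outcomes pools the FDR correction across outcomes", {
  set.seed(16)
  d <- replicated_covariate_frame(list(n1 = 60, k1 = 6, n2 = 40, k2 = 14))
  d$z <- rnorm(nrow(d))
  out <- associate_outcomes(d, binary_outcomes = "y",
                            continuous_outcomes = "z", model = "basic")
  expect_identical(nrow(out), 2L)
  expect_identical(out$fdr_significant, bh_fdr(out$p_value, 0.1))
  out2 <- associate_outcomes(d, binary_outcomes = "y",
                             continuous_outcomes = "z", model = "basic",
                             pool_fdr = FALSE)
  expect_identical(out2$fdr_significant[out2$outcome == "y"],
                   as.vector(bh_fdr(out2$p_value[out2$outcome == "y"], 0.1)))
})

test_that("adjusted risk ratios recover a planted effect on synthetic data", {
  cfg <- cohort_config(n_subjects = 4000, seed = 61)
  coh <- generate_cohort(cfg, occasions = FALSE)
  out <- generate_outcomes(coh, default_outcome_configs(4), seed = 62)
  d <- cbind(coh$subjects, out[-1])
  d$traj_class <- d$true_class
  res <- fit_binary_outcome(d, "depressive_episode")
  expect_identical(attr(res, "reference"), "1")
  rr <- res$effect[match(c("2", "3", "4"), res$contrast_class)]
  expect_equal(rr, c(3.65, 13.11, 6.25), tolerance = 0.35)
})

test_that("sensitivity modes restrict or augment as documented", {
  cfg <- cohort_config(n_subjects = 500, seed = 71)
  coh <- generate_cohort(cfg)
  fl <- filter_eligible(score_smfq(coh$occasions))
  fit <- fit_trajectory(trajectory_spec(4), fl$fitting, n_starts = 20,
                        seed = 72)
  post <- predict_class(fit, score_smfq(coh$occasions),
                        subject_ids = coh$subjects$subject_id)
  out <- generate_outcomes(coh, default_outcome_configs(4), seed = 73)
  d <- cbind(coh$subjects, out[-1])
  d$traj_class <- post$modal_class[match(d$subject_id, post$subject_id)]

  full <- fit_binary_outcome(d, "depressive_episode")
  restricted <- fit_binary_outcome(d, "depressive_episode",
                                   mode = "modal_p_ge_0.7", posterior = post)
  expect_lte(restricted$n_complete[1], full$n_complete[1])
  expect_identical(unique(restricted$sensitivity_mode), "modal_p_ge_0.7")

  # apply_sensitivity mirrors the internal restriction
  kept <- apply_sensitivity("modal_p_ge_0.7", d, post)
  expect_identical(nrow(kept), sum(post$modal_probability[
    match(d$subject_id, post$subject_id)] >= 0.7))
  aug <- apply_sensitivity("posterior_terms", d, post)
  expect_true(all(paste0("p_class", 1:4) %in% names(aug)))

  pt <- fit_binary_outcome(d, "depressive_episode", mode = "posterior_terms",
                           posterior = post)
  expect_identical(nrow(pt), 3L)   # G - 1 posterior terms
  expect_true(all(grepl("^[0-9]+$", pt$contrast_class)))

  # with crisp (one-hot) posteriors the posterior-terms model matches the
  # class-factor model coefficients
  P <- diag(4)[d$traj_class, ]
  crisp <- symptraj:::new_posterior_matrix(P, d$subject_id)
  pt2 <- fit_binary_outcome(d, "depressive_episode", mode = "posterior_terms",
                            posterior = crisp)
  expect_equal(sort(pt2$effect), sort(full$effect), tolerance = 1e-6)

  # modes need the posterior matrix
  expect_error(fit_binary_outcome(d, "depressive_episode",
                                  mode = "modal_p_ge_0.7"),
               "needs a posterior")
})
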