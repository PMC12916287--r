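test_that("marginal_loglik matches a brute-force MVN oracle (GBTM and GMM)", {
  data <- data.frame(
    subject_id = c("a", "a", "a", "b", "b", "c"),
    age = c(10, 16, 25, 12, 22, 17),
    score = c(3, 5, 4, 12, 15, 8))
  params <- list(logits = 0.4,
                 beta = rbind(c(2, 1, 0.2), c(-3, 9, -1)),
                 sigma = 1.7, tau = 1.1, omega = c(1, 1.6))
  for (re in c("none", "common_intercept", "class_proportional_intercept")) {
    spec <- trajectory_spec(2, fp_basis(c(1, 2)), re)
    expect_equal(as.numeric(marginal_loglik(spec, params, data)),
                 oracle_loglik(spec, params, data), tolerance = 1e-10,
                 info = re)
  }
  # G = 1 with a degree-1 basis
  spec1 <- trajectory_spec(1, fp_basis(0))
  p1 <- list(logits = numeric(0), beta = matrix(c(4, 2), 1), sigma = 2,
             tau = 0, omega = 1)
  expect_equal(as.numeric(marginal_loglik(spec1, p1, data)),
               oracle_loglik(spec1, p1, data), tolerance = 1e-10)
})

test_that("subjects with only missing scores are excluded and counted", {
  data <- data.frame(subject_id = c("a", "a", "a", "b"),
                     age = c(10, 12, 14, 10),
                     score = c(1, 2, 3, NA))
  spec <- trajectory_spec(1)
  p <- list(logits = numeric(0), beta = matrix(c(2, 0, 0), 1), sigma = 1,
            tau = 0, omega = 1)
  ll <- marginal_loglik(spec, p, data)
  expect_identical(attr(ll, "n_excluded"), 1L)
})

test_that("a G = 1 fit reproduces the pooled least-squares solution", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(1), data, n_starts = 3, seed = 1)
  X <- build_fp_basis(data$age, fit$spec$basis)
  ols <- stats::lm.fit(X, data$score)
  expect_equal(as.vector(fit$params$beta), unname(ols$coefficients),
               tolerance = 1e-8)
  sigma2 <- mean(ols$residuals^2)
  expect_equal(fit$params$sigma^2, sigma2, tolerance = 1e-8)
  expect_equal(fit$loglik,
               sum(stats::dnorm(ols$residuals, 0, sqrt(sigma2), log = TRUE)),
               tolerance = 1e-8)
  expect_identical(fit$n_parameters, 4L)  # 3 curve coefficients + sigma
})

test_that("EM keeps the likelihood monotone and the fit is deterministic", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 10, seed = 4)
  expect_true(fit$converged)
  expect_true(all(diff(fit$em_loglik_path) >= -1e-8))
  fit2 <- fit_trajectory(trajectory_spec(2), data, n_starts = 10, seed = 4)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$pi, fit2$pi)
  expect_identical(fit$params$beta, fit2$params$beta)
})

test_that("well-separated classes are recovered with canonical ordering", {
  data <- tiny_two_class_scores(n_per_class = 60)
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 10, seed = 2)
  expect_equal(fit$pi, c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(diff(fit$pi) <= 0))     # descending mixing proportions
  post <- posterior_probs(fit, data)
  # crisp classification of planted groups
  expect_gt(mean(post$modal_probability), 0.99)
  cls <- split(post$modal_class, substr(post$subject_id, 1, 1))
  expect_identical(length(unique(cls$A)), 1L)
  expect_identical(length(unique(cls$B)), 1L)
  expect_false(unique(cls$A) == unique(cls$B))
})

test_that("4-class generator fits recover the planted structure", {
  cfg <- cohort_config(n_subjects = 700, seed = 31)
  coh <- generate_cohort(cfg)
  fl <- filter_eligible(score_smfq(coh$occasions))
  fit <- fit_trajectory(trajectory_spec(4), fl$fitting, n_starts = 30,
                        seed = 77)
  expect_true(fit$converged)
  expect_equal(fit$pi, sort(cfg$class_proportions, decreasing = TRUE),
               tolerance = 0.25)
  # the multistart solution is at least as good as an EM run started at the
  # planted truth (local-optimum guard)
  dat <- symptraj:::traj_data(fl$fitting, fit$spec$basis)
  truth <- symptraj:::em_gbtm(dat, 4, t(cfg$class_trajectories),
                              cfg$residual_sd^2, cfg$class_proportions,
                              max_iter = 500, tol = 1e-6)
  # allow a sliver of convergence slack on either side
  expect_gte(fit$loglik, truth$loglik - 0.05)
})

test_that("posterior matrices are well-formed probability rows", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 5, seed = 3)
  post <- posterior_probs(fit, data)
  expect_equal(rowSums(post$probabilities), rep(1, nrow(post$probabilities)))
  expect_true(all(post$probabilities >= 0))
  expect_identical(post$modal_class,
                   max.col(post$probabilities, ties.method = "first"))
  # modal ties break to the lowest class index
  tied <- symptraj:::new_posterior_matrix(
    matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2, byrow = TRUE), c("x", "y"))
  expect_identical(tied$modal_class, c(1L, 2L))
})

test_that("predict_class covers subjects outside the fitting subsample", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 5, seed = 3)
  newdata <- data.frame(subject_id = c("n1", "n1", "n2"),
                        age = c(10, 25, 16),
                        score = c(2, 3, 22))
  post <- predict_class(fit, newdata, subject_ids = c("n1", "n2", "n3"))
  expect_identical(post$subject_id, c("n1", "n2", "n3"))
  expect_identical(post$prior_only, c(FALSE, FALSE, TRUE))
  # a subject with no data gets the prior as posterior
  expect_equal(as.vector(post$probabilities[3, ]), fit$pi)
  # single-occasion subjects are classified from that one observation
  expect_true(all(rowSums(post$probabilities) == 1))
})

test_that("unconverged fits refuse posterior computation unless overridden", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 3,
                        final_iters = 1, seed = 5)
  expect_false(fit$converged)
  expect_error(posterior_probs(fit, data), "did not converge")
  expect_s3_class(posterior_probs(fit, data, allow_unconverged = TRUE),
                  "posterior_matrix")
})

test_that("trajectory_curves evaluates class means with uncertainty bands", {
  data <- tiny_two_class_scores()
  fit <- fit_trajectory(trajectory_spec(2), data, n_starts = 5, seed = 3)
  cur <- trajectory_curves(fit, data, ages = c(10, 20, 25))
  expect_identical(nrow(cur), 6L)
  X <- build_fp_basis(c(10, 20, 25), fit$spec$basis)
  expect_equal(cur$mean, as.vector(X %*% t(fit$params$beta)))
  expect_true(all(cur$lower <= cur$mean & cur$mean <= cur$upper))
  # without data, no bands
  cur0 <- trajectory_curves(fit, ages = c(10, 20))
  expect_true(all(is.na(cur0$lower)))
})

test_that("growth-mixture structures estimate the intercept variance", {
  set.seed(12)
  ages <- c(10, 13, 16, 19, 22, 25)
  n <- 150
  b <- rnorm(n, 0, 2)
  data <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = sprintf("s%03d", i), age = ages,
               score = 5 + 2 * (ages / 10) + b[i] + rnorm(length(ages), 0, 1))))
  spec <- trajectory_spec(1, fp_basis(1), "common_intercept")
  fit <- fit_trajectory(spec, data, n_starts = 4, seed = 6)
  expect_true(fit$converged)
  expect_equal(fit$params$tau, 2, tolerance = 0.35)
  expect_equal(fit$params$sigma, 1, tolerance = 0.15)
  # the GMM marginal loglik beats a GBTM forced on the same data
  gb <- fit_trajectory(trajectory_spec(1, fp_basis(1)), data,
                       n_starts = 4, seed = 6)
  expect_gt(fit$loglik, gb$loglik)
})

test_that("fit inputs are validated", {
  data <- tiny_two_class_scores(n_per_class = 3)
  expect_error(fit_trajectory(trajectory_spec(20), data, seed = 1),
               "exceeds the number of subjects")
  expect_error(trajectory_spec(0), "G must be >= 1")
  expect_error(fit_trajectory(trajectory_spec(1),
                              data.frame(subject_id = "a", age = 10),
                              seed = 1),
               "missing column")
})
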