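test_that("the LOD filter keeps 67 of 92 proteins and is boundary-inclusive", {
  cfg <- cohort_config(n_subjects = 300, seed = 81)
  coh <- generate_cohort(cfg, occasions = FALSE)
  panel <- generate_biomarker_panel(coh, protein_catalogue(), seed = 82)
  kept <- lod_filter(panel)
  expect_identical(ncol(kept$values), 67L)
  # a fraction of exactly 0.5 is excluded (>= is inclusive)
  v <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  p <- make_panel(v, below_lod_fraction = c(0.5, 0.499))
  expect_identical(lod_filter(p)$metadata$analyte, "b")
  # non-protein families pass through untouched
  pm <- make_panel(v, family = "metabolomic", category = "glycolysis",
                   below_lod_fraction = c(0.9, 0.9))
  expect_identical(ncol(lod_filter(pm)$values), 2L)
})

test_that("the metabolomic feature filter drops subclasses to 57 features", {
  cfg <- cohort_config(n_subjects = 100, seed = 83)
  coh <- generate_cohort(cfg, occasions = FALSE)
  panel <- generate_biomarker_panel(coh, metabolomic_catalogue(), seed = 84)
  expect_identical(ncol(panel$values), 71L)
  kept <- select_metabolomic_features(panel)
  expect_identical(ncol(kept$values), 57L)
  expect_false("lipoprotein_subclass" %in% kept$metadata$category)
  # unknown categories are a validation error
  v <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  bad <- make_panel(v, family = "metabolomic", category = "mystery")
  expect_error(select_metabolomic_features(bad), "unknown metabolomic")
  # an all-subclass panel empties with a warning
  sub <- make_panel(v, family = "metabolomic",
                    category = "lipoprotein_subclass")
  expect_warning(out <- select_metabolomic_features(sub), "every analyte")
  expect_identical(ncol(out$values), 0L)
})

test_that("per-analyte linear fits reproduce lm coefficient by coefficient", {
  set.seed(31)
  n <- 60L
  design <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       traj_class = factor(sample(1:3, n, TRUE)),
                       sex = sample(c("f", "m"), n, TRUE),
                       bmi10 = rnorm(n, 17.5, 2))
  v <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(design$subject_id, paste0("A", 1:4)))
  afit <- fit_analyte_models(v, design, ~ traj_class + sex + bmi10)
  for (j in 1:4) {
    ref <- lm(v[, j] ~ traj_class + sex + bmi10, data = design)
    expect_equal(unname(afit$coefficients[, j]), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(unname(afit$sigma2[j]), summary(ref)$sigma^2,
                 tolerance = 1e-10)
    expect_identical(afit$df_residual[j], unname(ref$df.residual))
  }
  # complete-case handling on the covariates
  design$bmi10[1] <- NA
  afit2 <- fit_analyte_models(v, design, ~ traj_class + sex + bmi10)
  expect_identical(length(afit2$subject_id), n - 1L)
  # rank-deficient designs name the aliased column
  design$dup <- design$bmi10
  expect_error(fit_analyte_models(v, design, ~ bmi10 + dup), "aliased.*dup")
})

test_that("empirical-Bayes moderation recovers planted hyperparameters", {
  set.seed(32)
  m <- 2000; d0 <- 4; s02 <- 2; d <- 20
  sigma2_true <- d0 * s02 / rchisq(m, d0)
  s2 <- sigma2_true * rchisq(m, d) / d
  mod <- ebayes_moderate(s2, d)
  expect_equal(mod$d0, 4, tolerance = 0.5)
  expect_equal(mod$s02, 2, tolerance = 0.1)
  # moderated variances lie between the observed value and the prior
  expect_true(all(mod$s2_post >= pmin(s2, mod$s02) - 1e-12 &
                    mod$s2_post <= pmax(s2, mod$s02) + 1e-12))
  # shrinkage is the precision-weighted blend
  expect_equal(mod$s2_post, (mod$d0 * mod$s02 + d * s2) / (mod$d0 + d))
})

test_that("moderation agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  set.seed(33)
  s2 <- 1.5 * rchisq(500, 15) / 15
  mod <- ebayes_moderate(s2, 15)
  sq <- limma::squeezeVar(s2, df = 15)
  expect_equal(mod$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(mod$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("homogeneous variances give an infinite prior df", {
  mod <- ebayes_moderate(rep(2, 50), 10)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(mod$s02, 50))
  expect_error(ebayes_moderate(2, 10), ">= 2 analytes")
  expect_error(ebayes_moderate(c(1, 0), 10), "positive")
})

test_that("unmoderated contrasts equal the ordinary per-analyte t-tests", {
  set.seed(34)
  n <- 50
  design <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       traj_class = factor(sample(1:2, n, TRUE)),
                       sex = sample(c("f", "m"), n, TRUE))
  v <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(design$subject_id, paste0("A", 1:6)))
  afit <- fit_analyte_models(v, design, ~ traj_class + sex)
  C <- trajectory_contrasts(afit)
  plain <- planned_contrasts(afit, C, moderate = FALSE)
  expect_identical(plain$d0, 0)
  for (j in 1:6) {
    sm <- summary(lm(v[, j] ~ traj_class + sex,
                     data = design))$coefficients["traj_class2", ]
    row <- plain$table[plain$table$analyte == paste0("A", j), ]
    expect_equal(row$estimate, unname(sm[1]), tolerance = 1e-10)
    expect_equal(row$se, unname(sm[2]), tolerance = 1e-10)
    expect_equal(row$t, unname(sm[3]), tolerance = 1e-10)
    expect_equal(row$p, unname(sm[4]), tolerance = 1e-10)
  }
  # moderation changes se/t/p but never the estimates
  modded <- planned_contrasts(afit, C, moderate = TRUE)
  expect_equal(modded$table$estimate, plain$table$estimate)
  expect_false(isTRUE(all.equal(modded$table$t, plain$table$t)))
})

test_that("contrast FDR flags are calibrated under the null", {
  cfg <- cohort_config(n_subjects = 250, seed = 85)
  coh <- generate_cohort(cfg, occasions = FALSE)
  panel <- generate_biomarker_panel(coh, protein_catalogue(), seed = 86)
  design <- coh$subjects
  design$traj_class <- design$true_class  # class has no planted analyte shift
  res <- analyze_biomarkers(panel, design, family = "protein")
  expect_identical(nrow(res$table), 67L * 3L)
  expect_lt(mean(res$table$fdr_significant), 0.02)
})

test_that("planted analyte shifts are detected with moderation", {
  cfg <- cohort_config(n_subjects = 400, seed = 87)
  coh <- generate_cohort(cfg, occasions = FALSE)
  shifts <- data.frame(analyte = c("IL6", "TNF", "CCL11"),
                       class = 3, shift = 1.2)
  panel <- generate_biomarker_panel(coh, protein_catalogue(),
                                    class_shifts = shifts, seed = 88)
  design <- coh$subjects
  design$traj_class <- design$true_class
  res <- analyze_biomarkers(panel, design, family = "protein")
  hits <- res$table[res$table$fdr_significant & res$table$contrast == "3", ]
  expect_true(all(c("IL6", "TNF", "CCL11") %in% hits$analyte))
  expect_true(is.finite(res$d0) || is.infinite(res$d0))
})

test_that("contrast matrices extract the class coefficients", {
  set.seed(36)
  design <- data.frame(subject_id = sprintf("s%02d", 1:30),
                       traj_class = factor(rep(1:3, each = 10)))
  v <- matrix(rnorm(60), 30, 2, dimnames = list(design$subject_id, c("a", "b")))
  afit <- fit_analyte_models(v, design, ~ traj_class)
  C <- trajectory_contrasts(afit)
  expect_identical(dim(C), c(3L, 2L))
  expect_identical(colnames(C), c("2", "3"))
  expect_equal(colSums(C), c(`2` = 1, `3` = 1))
  expect_error(trajectory_contrasts(afit, class_prefix = "nope"),
               "no class coefficients")
})
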