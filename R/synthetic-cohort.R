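#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the statistical structure of a simulated cohort of repeated
#' 13-item depressive-symptom (SMFQ) measurements: latent trajectory
#' classes, a measurement schedule, subject-level random intercepts,
#' occasion-level missingness, and marginal covariate distributions.
#'
#' Defaults emulate the study design the package targets: 10 occasions at
#' ages 10, 12, 13, 16, 17, 18, 21, 22, 23 and 25; four latent classes with
#' mixing proportions proportional to 69.6/13.3/7.0/10.0 percent
#' (low-stable, adolescent-limited, adolescent-persistent, adulthood-onset)
#' and quadratic trajectory shapes on t = age/10 encoding those qualitative
#' patterns; per-occasion response rates declining with age so the
#' at-least-three-measurements eligibility filter binds. The default has no
#' within-class random intercept, matching the group-based trajectory model
#' class that the selection framework identifies as final for this design;
#' set \code{random_intercept_sd > 0} (and optionally per-class variance
#' multipliers) to emulate growth-mixture-model data.
#'
#' @param n_subjects number of subjects.
#' @param occasion_ages strictly increasing measurement ages (years).
#' @param class_proportions mixing proportions over the G classes (must sum
#'   to 1 within 1e-12, all positive).
#' @param class_trajectories G x 3 matrix of quadratic coefficients on the
#'   basis (1, t, t^2) with t = (age - offset)/divisor of \code{basis}.
#' @param basis [fp_basis()] on which \code{class_trajectories} is expressed.
#' @param random_intercept_sd subject random-intercept SD (score units, >= 0).
#' @param class_variance_multipliers per-class positive scale on the random
#'   intercept SD (reference convention: multiplier 1 in class 1).
#' @param residual_sd occasion-level residual SD (score units, >= 0; 0 gives
#'   the noise-free limit).
#' @param response_prob per-occasion probability of responding (length 1 or
#'   length(occasion_ages)).
#' @param dropout_hazard per-interval hazard of permanent dropout (default 0,
#'   i.e. purely occasion-wise missingness-completely-at-random).
#' @param mar_class_effect optional per-class multiplier on response_prob
#'   (missingness-at-random on class; default NULL = off).
#' @param covariate_model list of marginal covariate distributions; see
#'   [default_covariate_model()].
#' @param seed integer seed (required).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 2000L,
                          occasion_ages = c(10, 12, 13, 16, 17, 18, 21, 22, 23, 25),
                          class_proportions = c(0.696, 0.133, 0.070, 0.100) /
                            sum(c(0.696, 0.133, 0.070, 0.100)),
                          class_trajectories = default_class_trajectories(),
                          basis = fp_basis(c(1, 2)),
                          random_intercept_sd = 0,
                          class_variance_multipliers = NULL,
                          residual_sd = 3,
                          response_prob = c(0.90, 0.85, 0.80, 0.75, 0.70,
                                            0.65, 0.55, 0.50, 0.50, 0.45),
                          dropout_hazard = 0,
                          mar_class_effect = NULL,
                          covariate_model = default_covariate_model(),
                          seed = NULL) {
  seed <- check_seed(seed %||% stop_config("cohort_config: 'seed' is required"))
  G <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-12 || any(class_proportions <= 0))
    stop_config("class_proportions must be positive and sum to 1 (got sum %.15f)",
                sum(class_proportions))
  if (is.unsorted(occasion_ages, strictly = TRUE))
    stop_config("occasion_ages must be strictly increasing")
  class_trajectories <- as.matrix(class_trajectories)
  if (nrow(class_trajectories) != G || ncol(class_trajectories) != 3L)
    stop_config("class_trajectories must be a %d x 3 coefficient matrix", G)
  if (random_intercept_sd < 0 || residual_sd < 0)
    stop_config("random_intercept_sd and residual_sd must be >= 0")
  class_variance_multipliers <- class_variance_multipliers %||% rep(1, G)
  if (length(class_variance_multipliers) != G || any(class_variance_multipliers <= 0))
    stop_config("class_variance_multipliers must be %d positive scalars", G)
  response_prob <- rep(response_prob, length.out = length(occasion_ages))
  if (any(response_prob < 0 | response_prob > 1))
    stop_config("response_prob entries must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 occasion_ages = occasion_ages,
                 class_proportions = class_proportions,
                 class_trajectories = class_trajectories,
                 basis = basis,
                 random_intercept_sd = random_intercept_sd,
                 class_variance_multipliers = class_variance_multipliers,
                 residual_sd = residual_sd,
                 response_prob = response_prob,
                 dropout_hazard = dropout_hazard,
                 mar_class_effect = mar_class_effect,
                 covariate_model = covariate_model,
                 seed = seed),
            class = "cohort_config")
}

#' Default quadratic trajectory shapes
#'
#' Coefficients on (1, t, t^2), t = age/10, for the four canonical shapes:
#' low-stable (flat near 2 points), adolescent-limited (rising to a
#' mid-adolescent peak near 10 then falling), adolescent-persistent (early
#' rise to a sustained high plateau near 13), and adulthood-onset (low
#' through adolescence, rising after about age 17). Shapes are illustrative
#' defaults on the 0-26 score scale; recovery tests use whatever is planted.
#'
#' @return 4 x 3 numeric matrix.
#' @export
default_class_trajectories <- function() {
  m <- rbind(low_stable            = c(2.00,   0.0,  0),
             adolescent_limited    = c(-10.25, 27.0, -9),
             adolescent_persistent = c(-16.04, 26.4, -6),
             adulthood_onset       = c(17.25, -21.0,  7))
  colnames(m) <- c("(Intercept)", "t", "t^2")
  m
}

#' Default marginal covariate model
#'
#' Marginal distributions for the subject-level covariates: sex (female
#' probability), maternal education (5 ordered levels), maternal
#' occupational social class (5 levels), BMI at age 10 (log-normal,
#' right-skewed) and a family-adversity index (ordinal noise covariate, not
#' linked to class).
#'
#' @return list of distribution parameters.
#' @export
default_covariate_model <- function() {
  list(p_female = 0.53,
       maternal_education_levels = c("CSE_or_none", "Vocational", "O_level",
                                     "A_level", "Degree"),
       maternal_education_probs = c(0.15, 0.09, 0.35, 0.26, 0.15),
       social_class_levels = c("I", "II", "III_nonmanual", "III_manual", "IV_V"),
       social_class_probs = c(0.07, 0.34, 0.42, 0.07, 0.10),
       bmi10_meanlog = log(17.5), bmi10_sdlog = 0.15,
       adversity_probs = c(0.30, 0.25, 0.20, 0.12, 0.08, 0.05))
}

# allocate an integer total S in 0..26 over 13 items each in {0,1,2},
# summing exactly to S; the +1 remainders land on randomly chosen items
allocate_items <- function(S) {
  base <- S %/% 13L
  rem <- S %% 13L
  items <- rep(base, 13L)
  if (rem > 0L) items[sample.int(13L, rem)] <- base + 1L
  items
}

#' Generate a synthetic longitudinal cohort
#'
#' Samples latent classes from the mixing proportions, builds each subject's
#' occasion-level latent mean as the class trajectory evaluated at age plus
#' a class-scaled subject random intercept, adds Gaussian residual noise,
#' rounds half-up and truncates the occasion sum score to [0, 26], and then
#' allocates that exact sum over the 13 items (each in \{0,1,2\}).
#' Occasions are deleted independently according to the per-occasion
#' response probabilities (optionally with permanent dropout). Deterministic
#' given the config seed.
#'
#' @param config a [cohort_config()].
#' @param occasions logical; set FALSE to generate only the subject table
#'   (classes + covariates), e.g. for outcome-recovery simulations.
#' @return object of class \code{ltraj_cohort}: a list with \code{subjects}
#'   (subject_id, true_class, sex, maternal_education, social_class, bmi10,
#'   family_adversity), \code{occasions} (subject_id, age, item01..item13)
#'   and the generating \code{config}.
#' @export
generate_cohort <- function(config, occasions = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_subjects
    G <- length(config$class_proportions)
    true_class <- sample.int(G, n, replace = TRUE, prob = config$class_proportions)
    cm <- config$covariate_model
    subjects <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      true_class = true_class,
      sex = ifelse(stats::runif(n) < cm$p_female, "female", "male"),
      maternal_education = sample(cm$maternal_education_levels, n, TRUE,
                                  cm$maternal_education_probs),
      social_class = sample(cm$social_class_levels, n, TRUE, cm$social_class_probs),
      bmi10 = stats::rlnorm(n, cm$bmi10_meanlog, cm$bmi10_sdlog),
      family_adversity = sample(seq_along(cm$adversity_probs) - 1L, n, TRUE,
                                cm$adversity_probs),
      stringsAsFactors = FALSE)
    out <- list(subjects = subjects, occasions = NULL, config = config)
    class(out) <- "ltraj_cohort"
    if (!occasions) return(out)

    ages <- config$occasion_ages
    J <- length(ages)
    X <- build_fp_basis(ages, config$basis)  # J x 3
    mu_class <- X %*% t(config$class_trajectories)  # J x G
    b <- stats::rnorm(n, 0, config$random_intercept_sd) *
      config$class_variance_multipliers[true_class]

    # response indicators: occasion-wise MCAR, optional class MAR, dropout
    rp <- matrix(config$response_prob, n, J, byrow = TRUE)
    if (!is.null(config$mar_class_effect))
      rp <- pmin(rp * config$mar_class_effect[true_class], 1)
    resp <- matrix(stats::runif(n * J), n, J) < rp
    if (config$dropout_hazard > 0) {
      drop_at <- 1L + stats::rgeom(n, config$dropout_hazard)
      resp <- resp & outer(drop_at, seq_len(J), ">=")
    }

    latent <- mu_class[, true_class]            # J x n
    latent <- t(latent) + b                     # n x J
    if (config$residual_sd > 0)
      latent <- latent + matrix(stats::rnorm(n * J, 0, config$residual_sd), n, J)
    S <- pmin(pmax(round_half_up(latent), 0L), 26L)

    keep <- which(resp, arr.ind = TRUE)
    keep <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
    n_occ <- nrow(keep)
    items <- matrix(0L, n_occ, 13L)
    Svec <- S[keep]
    for (k in seq_len(n_occ)) items[k, ] <- allocate_items(Svec[k])
    colnames(items) <- sprintf("item%02d", 1:13)
    out$occasions <- data.frame(subject_id = subjects$subject_id[keep[, 1L]],
                                age = ages[keep[, 2L]],
                                items, stringsAsFactors = FALSE)
    out
  })
}

#' @export
print.ltraj_cohort <- function(x, ...) {
  cat(sprintf("Synthetic longitudinal cohort: %d subjects, %s occasion rows, %d classes\n",
              nrow(x$subjects),
              if (is.null(x$occasions)) "no" else format(nrow(x$occasions)),
              length(x$config$class_proportions)))
  invisible(x)
}

#' Outcome effect configuration
#'
#' Describes how a synthetic outcome depends on latent class and covariates.
#' For binary outcomes, per-subject risk is
#' baseline_risk x RR(class) x exp(covariate terms), which must stay within
#' [0, 1]; for continuous outcomes, a Gaussian with per-class means.
#'
#' @param outcome_name label for the outcome column.
#' @param type "binary" or "continuous".
#' @param baseline_risk risk in the reference class (class 1) at covariate
#'   reference values (binary outcomes).
#' @param class_risk_ratios length-G vector of risk ratios; entry 1 is the
#'   reference and must equal 1.
#' @param covariate_effects named list of log-scale coefficients; supported
#'   names: \code{sex_female}, \code{bmi10_per_sd} (BMI at 10 standardized
#'   as (bmi10 - 17.5)/2.6).
#' @param class_means,sd per-class means and residual SD (continuous
#'   outcomes).
#' @return object of class \code{outcome_effect_config}.
#' @export
outcome_effect_config <- function(outcome_name, type = c("binary", "continuous"),
                                  baseline_risk = NULL, class_risk_ratios = NULL,
                                  covariate_effects = list(),
                                  class_means = NULL, sd = 1) {
  type <- match.arg(type)
  if (type == "binary") {
    if (is.null(baseline_risk) || baseline_risk < 0 || baseline_risk > 1)
      stop_config("baseline_risk must be a probability")
    if (is.null(class_risk_ratios) || any(class_risk_ratios <= 0))
      stop_config("class_risk_ratios must be positive")
    if (abs(class_risk_ratios[1L] - 1) > 1e-12)
      stop_config("the reference (first) class risk ratio must be 1")
    if (baseline_risk * max(class_risk_ratios) > 1)
      stop_config("baseline_risk x max(class_risk_ratios) exceeds 1")
  } else if (is.null(class_means)) {
    stop_config("continuous outcomes need class_means")
  }
  structure(list(outcome_name = outcome_name, type = type,
                 baseline_risk = baseline_risk,
                 class_risk_ratios = class_risk_ratios,
                 covariate_effects = covariate_effects,
                 class_means = class_means, sd = sd),
            class = "outcome_effect_config")
}

# linear predictor contribution of the supported covariate effects
covariate_log_terms <- function(subjects, effects) {
  lp <- numeric(nrow(subjects))
  for (nm in names(effects)) {
    lp <- lp + switch(nm,
      sex_female = effects[[nm]] * (subjects$sex == "female"),
      bmi10_per_sd = effects[[nm]] * (subjects$bmi10 - 17.5) / 2.6,
      stop_config("unknown covariate effect '%s'", nm))
  }
  lp
}

#' Generate synthetic outcomes with planted class effects
#'
#' @param cohort an \code{ltraj_cohort} with true classes.
#' @param effect_configs a single [outcome_effect_config()] or a list of them.
#' @param seed integer seed. Use a value distinct from the cohort's own seed:
#'   reusing it replays the uniform stream that assigned the latent classes,
#'   coupling the outcome draws to class membership.
#' @return data frame: subject_id plus one column per outcome.
#' @export
generate_outcomes <- function(cohort, effect_configs, seed) {
  stopifnot(inherits(cohort, "ltraj_cohort"))
  if (inherits(effect_configs, "outcome_effect_config"))
    effect_configs <- list(effect_configs)
  subj <- cohort$subjects
  if (is.null(subj$true_class)) stop_config("cohort lacks true_class")
  G <- length(cohort$config$class_proportions)
  with_seed(seed, {
    out <- data.frame(subject_id = subj$subject_id, stringsAsFactors = FALSE)
    for (ec in effect_configs) {
      if (ec$type == "binary") {
        if (length(ec$class_risk_ratios) != G)
          stop_config("class_risk_ratios must have length %d", G)
        risk <- ec$baseline_risk * ec$class_risk_ratios[subj$true_class] *
          exp(covariate_log_terms(subj, ec$covariate_effects))
        n_over <- sum(risk > 1)
        if (n_over > 0)
          stop_config("outcome '%s': risk exceeds 1 for %d subject(s)",
                      ec$outcome_name, n_over)
        out[[ec$outcome_name]] <- as.integer(stats::runif(nrow(subj)) < risk)
      } else {
        mu <- ec$class_means[subj$true_class] +
          covariate_log_terms(subj, ec$covariate_effects)
        out[[ec$outcome_name]] <- stats::rnorm(nrow(subj), mu, ec$sd)
      }
    }
    out
  })
}

#' Generate a synthetic biomarker panel with planted class shifts
#'
#' Log-scale analyte values are Gaussian around a per-analyte baseline with
#' optional planted per-class shifts. Each analyte's limit of detection
#' (LOD) is placed at the empirical quantile matching its configured
#' below-LOD fraction; values below it are flagged and left-censored at the
#' LOD.
#'
#' @param cohort an \code{ltraj_cohort}.
#' @param catalogue analyte metadata, e.g. [protein_catalogue()]; must have
#'   columns analyte, family, category, baseline_level, below_lod_target.
#' @param class_shifts optional data frame (analyte, class, shift) of
#'   planted log-scale group shifts.
#' @param analyte_sd log-scale residual SD (default 1).
#' @param seed integer seed.
#' @return object of class \code{biomarker_panel}: values matrix (subjects x
#'   analytes), logical \code{censored} matrix, and \code{metadata} with the
#'   realised LOD and below-LOD fraction per analyte.
#' @export
generate_biomarker_panel <- function(cohort, catalogue = protein_catalogue(),
                                     class_shifts = NULL, analyte_sd = 1,
                                     seed) {
  stopifnot(inherits(cohort, "ltraj_cohort"))
  subj <- cohort$subjects
  G <- length(cohort$config$class_proportions)
  n <- nrow(subj)
  m <- nrow(catalogue)
  if (anyDuplicated(catalogue$analyte))
    stop_config("duplicate analyte names in catalogue")
  shift_mat <- matrix(0, m, G, dimnames = list(catalogue$analyte, NULL))
  if (!is.null(class_shifts)) {
    bad <- setdiff(class_shifts$analyte, catalogue$analyte)
    if (length(bad))
      stop_config("planted shift refers to unknown analyte '%s'", bad[1L])
    if (any(class_shifts$class < 1 | class_shifts$class > G))
      stop_config("planted shift refers to a class outside 1..%d", G)
    for (k in seq_len(nrow(class_shifts)))
      shift_mat[class_shifts$analyte[k], class_shifts$class[k]] <-
        class_shifts$shift[k]
  }
  if (any(catalogue$below_lod_target < 0 | catalogue$below_lod_target > 1))
    stop_config("below_lod_target fractions must lie in [0, 1]")
  with_seed(seed, {
    values <- matrix(stats::rnorm(n * m, 0, analyte_sd), n, m,
                     dimnames = list(subj$subject_id, catalogue$analyte))
    values <- sweep(values, 2L, catalogue$baseline_level, `+`)
    values <- values + t(shift_mat[, subj$true_class])
    censored <- matrix(FALSE, n, m, dimnames = dimnames(values))
    lod <- numeric(m)
    for (j in seq_len(m)) {
      f <- catalogue$below_lod_target[j]
      if (f <= 0) { lod[j] <- -Inf; next }
      lod[j] <- stats::quantile(values[, j], probs = f, type = 1, names = FALSE)
      censored[, j] <- values[, j] <= lod[j]
      values[censored[, j], j] <- lod[j]
    }
    metadata <- data.frame(analyte = catalogue$analyte,
                           family = catalogue$family,
                           category = catalogue$category,
                           lod = lod,
                           below_lod_fraction = colMeans(censored),
                           stringsAsFactors = FALSE)
    structure(list(values = values, censored = censored, metadata = metadata),
              class = "biomarker_panel")
  })
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("Biomarker panel: %d subjects x %d analytes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$metadata$family), collapse = ", ")))
  invisible(x)
}

#' Write cohort tables to CSV
#'
#' Writes the long-format occasions table (subject_id, age, item01..item13)
#' and the subject covariates table.
#'
#' @param cohort an \code{ltraj_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(occasions = file.path(dir, "occasions.csv"),
             covariates = file.path(dir, "covariates.csv"))
  utils::write.csv(cohort$occasions, paths["occasions"], row.names = FALSE)
  utils::write.csv(cohort$subjects, paths["covariates"], row.names = FALSE)
  invisible(paths)
}

#' Write a biomarker panel to CSV (values matrix + metadata sidecar)
#'
#' @param panel a \code{biomarker_panel}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_biomarker_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(values = file.path(dir, "biomarkers.csv"),
             metadata = file.path(dir, "analyte_metadata.csv"))
  vals <- data.frame(subject_id = rownames(panel$values), panel$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(vals, paths["values"], row.names = FALSE)
  utils::write.csv(panel$metadata, paths["metadata"], row.names = FALSE)
  invisible(paths)
}
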