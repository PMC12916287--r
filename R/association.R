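#' Benjamini-Hochberg FDR significance flags
#'
#' Standard step-up procedure at rate \code{q}: flags every hypothesis whose
#' BH-adjusted p-value is at most \code{q} (equivalently, all with rank up
#' to the largest k such that p_(k) <= k q / m).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param q false discovery rate (default 0.1).
#' @return logical vector of flags (empty input gives empty output).
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

adjustment_sets <- function(model = c("adjusted", "basic")) {
  model <- match.arg(model)
  base <- c("sex", "maternal_education", "social_class")
  if (model == "adjusted") c(base, "bmi10") else base
}

# assemble the complete-case model frame: outcome, class factor (reference
# = largest class), covariates; optionally posterior-term columns
association_frame <- function(data, outcome, class_col, covariates, mode,
                              posterior = NULL) {
  need <- c(outcome, class_col, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop_config("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (mode != "none" && is.null(posterior))
    stop_config("sensitivity mode '%s' needs a posterior matrix", mode)
  if (mode != "none" && is.null(data$subject_id))
    stop_config("sensitivity modes need a subject_id column")
  df <- data[, need, drop = FALSE]
  names(df)[1:2] <- c(".outcome", ".class")
  if (mode != "none") df$.subject <- data$subject_id
  if (mode == "modal_p_ge_0.7") {
    keep_ids <- posterior$subject_id[posterior$modal_probability >= 0.7]
    df <- df[df$.subject %in% keep_ids, , drop = FALSE]
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (!nrow(df)) return(df)
  tabcl <- table(df$.class)
  ref <- names(tabcl)[which.max(tabcl)]
  df$.class <- stats::relevel(factor(df$.class), ref = ref)
  if (mode == "posterior_terms") {
    P <- posterior$probabilities[match(df$.subject, posterior$subject_id), ,
                                 drop = FALSE]
    # class labels are the posterior column indices 1..G
    ref_idx <- suppressWarnings(as.integer(ref))
    if (is.na(ref_idx) || ref_idx < 1L || ref_idx > ncol(P))
      stop_config("posterior_terms mode requires integer class labels 1..G")
    Pterms <- P[, -ref_idx, drop = FALSE]
    colnames(Pterms) <- paste0(".p_class", setdiff(seq_len(ncol(P)), ref_idx))
    df <- cbind(df, Pterms)
  }
  df$.subject <- NULL
  attr(df, "reference") <- ref
  df
}

check_aliased <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop_config("collinear model column(s): %s",
                paste(names(co)[is.na(co)], collapse = ", "))
}

association_formula <- function(df, mode, covariates) {
  rhs <- c(if (mode == "posterior_terms")
    grep("^\\.p_class", names(df), value = TRUE) else ".class",
    intersect(covariates, names(df)))
  stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
}

result_row <- function(outcome, contrast, effect, se, p, model, n, mode,
                       degenerate = FALSE, scale = c("rr", "coef")) {
  scale <- match.arg(scale)
  if (scale == "rr") {
    ci_low <- exp(log(effect) - 1.96 * se)
    ci_high <- exp(log(effect) + 1.96 * se)
  } else {
    ci_low <- effect - 1.96 * se
    ci_high <- effect + 1.96 * se
  }
  data.frame(outcome = outcome, contrast_class = contrast, effect = effect,
             se = se, ci_low = ci_low, ci_high = ci_high, p_value = p,
             fdr_significant = NA, model = model, n_complete = n,
             sensitivity_mode = mode, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Risk ratios for a binary outcome by trajectory class
#'
#' Modified-Poisson regression: a log-link Poisson GLM on the binary
#' outcome with heteroskedasticity-robust (sandwich, HC0) standard errors,
#' yielding adjusted risk ratios per non-reference class directly. The
#' reference class is the largest class in the complete-case sample; the
#' adjusted model controls for sex, maternal education, maternal
#' occupational social class and BMI at age 10 (the basic model drops BMI).
#' 95 percent CIs are exp(logRR +/- 1.96 robust SE).
#'
#' Outcomes with zero events in some class are returned flagged degenerate
#' (separation) rather than raising.
#'
#' @param data subject-level data frame containing the outcome, class and
#'   covariate columns (plus \code{subject_id} when a sensitivity mode is
#'   used).
#' @param outcome name of the binary (0/1) outcome column.
#' @param class_col name of the assigned-class column.
#' @param model "adjusted" (default) or "basic".
#' @param mode sensitivity mode: "none", "modal_p_ge_0.7" (restrict to
#'   subjects with modal posterior >= 0.7) or "posterior_terms" (replace the
#'   class factor with posterior-probability terms).
#' @param posterior \code{posterior_matrix} (required for sensitivity modes).
#' @param estimator "modified_poisson" (default) or "gcomp" (logistic
#'   g-computation: average predicted risks under each class assignment).
#' @return data frame of association results, one row per non-reference
#'   class (or posterior term).
#' @export
fit_binary_outcome <- function(data, outcome, class_col = "traj_class",
                               model = c("adjusted", "basic"),
                               mode = c("none", "modal_p_ge_0.7", "posterior_terms"),
                               posterior = NULL,
                               estimator = c("modified_poisson", "gcomp")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  covars <- adjustment_sets(model)
  df <- association_frame(data, outcome, class_col, covars, mode, posterior)
  if (!nrow(df))
    return(result_row(outcome, NA_character_, NA_real_, NA_real_, NA_real_,
                      model, 0L, mode, degenerate = TRUE, scale = "coef"))
  if (!all(df$.outcome %in% c(0, 1)))
    stop_config("'%s' is not binary 0/1", outcome)
  fml <- association_formula(df, mode, covars)
  degenerate <- mode != "posterior_terms" &&
    any(tapply(df$.outcome, df$.class, sum) == 0) || sum(df$.outcome) == 0

  fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::poisson()))
  check_aliased(fit)
  vc <- sandwich::vcovHC(fit, type = "HC0")
  terms_keep <- grep(if (mode == "posterior_terms") "^\\.p_class" else "^\\.class",
                     names(stats::coef(fit)), value = TRUE)
  out <- do.call(rbind, lapply(terms_keep, function(tm) {
    b <- stats::coef(fit)[tm]
    se <- sqrt(vc[tm, tm])
    rr <- exp(b)
    if (estimator == "gcomp" && mode != "posterior_terms") {
      lfit <- stats::glm(fml, data = df, family = stats::binomial())
      lev <- sub("^\\.class", "", tm)
      d1 <- df; d1$.class <- factor(lev, levels = levels(df$.class))
      d0 <- df; d0$.class <- factor(levels(df$.class)[1L],
                                    levels = levels(df$.class))
      rr <- mean(stats::predict(lfit, d1, type = "response")) /
        mean(stats::predict(lfit, d0, type = "response"))
    }
    p <- 2 * stats::pnorm(-abs(b / se))
    result_row(outcome, sub("^\\.(class|p_class)", "", tm), rr, se, p,
               model, nrow(df), mode, degenerate = degenerate, scale = "rr")
  }))
  attr(out, "reference") <- attr(df, "reference")
  out
}

#' Adjusted mean differences for a continuous outcome by trajectory class
#'
#' Ordinary least squares with the same adjustment sets as
#' [fit_binary_outcome()]; effects are unstandardised mean differences
#' versus the reference (largest) class.
#'
#' @inheritParams fit_binary_outcome
#' @return data frame of association results.
#' @export
fit_continuous_outcome <- function(data, outcome, class_col = "traj_class",
                                   model = c("adjusted", "basic"),
                                   mode = c("none", "modal_p_ge_0.7",
                                            "posterior_terms"),
                                   posterior = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  covars <- adjustment_sets(model)
  df <- association_frame(data, outcome, class_col, covars, mode, posterior)
  if (!nrow(df))
    return(result_row(outcome, NA_character_, NA_real_, NA_real_, NA_real_,
                      model, 0L, mode, degenerate = TRUE, scale = "coef"))
  degenerate <- stats::var(df$.outcome) == 0
  fml <- association_formula(df, mode, covars)
  fit <- stats::lm(fml, data = df)
  check_aliased(fit)
  sm <- summary(fit)$coefficients
  terms_keep <- grep(if (mode == "posterior_terms") "^\\.p_class" else "^\\.class",
                     rownames(sm), value = TRUE)
  out <- do.call(rbind, lapply(terms_keep, function(tm)
    result_row(outcome, sub("^\\.(class|p_class)", "", tm), sm[tm, 1L],
               sm[tm, 2L], sm[tm, 4L], model, nrow(df), mode,
               degenerate = degenerate, scale = "coef")))
  attr(out, "reference") <- attr(df, "reference")
  out
}

#' Run an outcome table and apply FDR flags
#'
#' Fits every listed outcome (binary via modified Poisson, continuous via
#' OLS) against the assigned class, pools the p-values across the whole
#' table, and sets \code{fdr_significant} by the Benjamini-Hochberg
#' procedure at rate \code{q} (set \code{pool_fdr = FALSE} to correct within
#' each outcome instead).
#'
#' @param data subject-level data frame (class assignments + covariates +
#'   outcome columns).
#' @param binary_outcomes,continuous_outcomes character vectors of column
#'   names.
#' @param q FDR threshold (default 0.1).
#' @param pool_fdr pool the correction across all outcomes (default TRUE).
#' @inheritParams fit_binary_outcome
#' @return combined association results data frame.
#' @export
associate_outcomes <- function(data, binary_outcomes = character(0),
                               continuous_outcomes = character(0),
                               class_col = "traj_class",
                               model = "adjusted", mode = "none",
                               posterior = NULL, q = 0.1, pool_fdr = TRUE) {
  res <- list()
  for (oc in binary_outcomes)
    res[[oc]] <- fit_binary_outcome(data, oc, class_col, model, mode, posterior)
  for (oc in continuous_outcomes)
    res[[oc]] <- fit_continuous_outcome(data, oc, class_col, model, mode,
                                        posterior)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (nrow(out)) {
    if (pool_fdr) out$fdr_significant <- bh_fdr(out$p_value, q)
    else for (oc in unique(out$outcome)) {
      i <- out$outcome == oc
      out$fdr_significant[i] <- bh_fdr(out$p_value[i], q)
    }
  }
  out
}

#' Apply a classification-uncertainty sensitivity mode to model inputs
#'
#' Mode \code{"modal_p_ge_0.7"} restricts the data to subjects whose modal
#' posterior probability is at least 0.7 (flagging, via a warning, any class
#' emptied by the filter); mode \code{"posterior_terms"} returns the data
#' augmented with the G-1 non-reference posterior-probability columns to be
#' used in place of the class factor.
#'
#' @param mode "modal_p_ge_0.7" or "posterior_terms".
#' @param data subject-level data frame with \code{subject_id} and the
#'   assigned-class column.
#' @param posterior a \code{posterior_matrix}.
#' @param class_col assigned-class column name.
#' @return the restricted or augmented data frame.
#' @export
apply_sensitivity <- function(mode = c("modal_p_ge_0.7", "posterior_terms"),
                              data, posterior, class_col = "traj_class") {
  mode <- match.arg(mode)
  m <- match(data$subject_id, posterior$subject_id)
  if (anyNA(m)) stop_config("posterior matrix lacks %d subject(s)", sum(is.na(m)))
  if (mode == "modal_p_ge_0.7") {
    keep <- posterior$modal_probability[m] >= 0.7
    out <- data[keep, , drop = FALSE]
    remaining <- table(factor(out[[class_col]],
                              levels = sort(unique(data[[class_col]]))))
    if (any(remaining == 0))
      warning(sprintf("sensitivity filter emptied class(es): %s",
                      paste(names(remaining)[remaining == 0], collapse = ", ")))
    out
  } else {
    P <- posterior$probabilities[m, , drop = FALSE]
    colnames(P) <- paste0("p_class", seq_len(ncol(P)))
    cbind(data, P)
  }
}
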