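#' Limit-of-detection filter for protein panels
#'
#' Removes protein analytes whose below-LOD fraction is at or above
#' \code{max_below_lod} (the >= is inclusive: a fraction of exactly 0.5 is
#' excluded at the default threshold). Analytes of other families pass
#' through untouched, and retained below-LOD values are kept as delivered
#' (no re-censoring or substitution).
#'
#' @param panel a \code{biomarker_panel}.
#' @param max_below_lod exclusion threshold on the below-LOD fraction
#'   (default 0.5).
#' @return the filtered \code{biomarker_panel}.
#' @export
lod_filter <- function(panel, max_below_lod = 0.5) {
  stopifnot(inherits(panel, "biomarker_panel"))
  drop <- panel$metadata$family == "protein" &
    panel$metadata$below_lod_fraction >= max_below_lod
  subset_panel(panel, !drop)
}

metabolomic_categories <- function() {
  c("cholesterol", "apolipoproteins/lipids", "particle_size", "fatty_acids",
    "glycolysis", "amino_acids", "ketone_bodies", "fluid_balance",
    "inflammation", "lipoprotein_subclass")
}

#' Drop redundant lipoprotein-subclass metabolomic features
#'
#' Removes metabolomic analytes with category \code{lipoprotein_subclass},
#' keeping the non-redundant feature subset. With the packaged
#' [metabolomic_catalogue()] this leaves 57 features. Unknown metabolomic
#' categories raise a validation error; an all-subclass panel returns an
#' empty panel with a warning.
#'
#' @param panel a \code{biomarker_panel}.
#' @return the filtered \code{biomarker_panel}.
#' @export
select_metabolomic_features <- function(panel) {
  stopifnot(inherits(panel, "biomarker_panel"))
  metab <- panel$metadata$family == "metabolomic"
  bad <- setdiff(unique(panel$metadata$category[metab]),
                 metabolomic_categories())
  if (length(bad))
    stop_config("unknown metabolomic category: %s", paste(bad, collapse = ", "))
  keep <- !(metab & panel$metadata$category == "lipoprotein_subclass")
  if (!any(keep)) warning("feature filter removed every analyte")
  subset_panel(panel, keep)
}

subset_panel <- function(panel, keep) {
  structure(list(values = panel$values[, keep, drop = FALSE],
                 censored = panel$censored[, keep, drop = FALSE],
                 metadata = panel$metadata[keep, , drop = FALSE]),
            class = "biomarker_panel")
}

#' Per-analyte linear models on a shared design
#'
#' Fits the same design matrix to every analyte by least squares
#' (complete cases on the covariates), returning per-analyte coefficients,
#' residual variances s_g^2 and residual degrees of freedom
#' d_g = n - rank(design). Analytes with zero residual variance are flagged
#' and excluded from variance moderation.
#'
#' @param panel a \code{biomarker_panel} (or a subjects x analytes matrix).
#' @param design data frame of subject-level variables (rownames or a
#'   \code{subject_id} column matching the panel's subjects).
#' @param formula model formula over \code{design} columns, e.g.
#'   \code{~ traj_class + sex + maternal_education + social_class + bmi10}.
#' @return object of class \code{analyte_fit}: coefficients (p x m),
#'   unscaled coefficient variances, sigma2 (length m), df_residual, the
#'   design matrix, and the complete-case subject ids.
#' @export
fit_analyte_models <- function(panel, design, formula) {
  values <- if (inherits(panel, "biomarker_panel")) panel$values else as.matrix(panel)
  ids <- design$subject_id %||% rownames(design)
  if (is.null(ids)) stop_config("design needs a subject_id column or rownames")
  m <- match(rownames(values), ids)
  if (anyNA(m)) stop_config("design lacks %d panel subject(s)", sum(is.na(m)))
  design <- design[m, , drop = FALSE]
  mf <- stats::model.frame(formula, design, na.action = stats::na.pass)
  cc <- stats::complete.cases(mf)
  X <- stats::model.matrix(formula, mf[cc, , drop = FALSE])
  Y <- values[cc, , drop = FALSE]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop_config("rank-deficient design; aliased column(s): %s",
                paste(aliased, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, Y)                    # p x m
  res <- Y - X %*% coefs
  d <- nrow(X) - qr_x$rank
  s2 <- colSums(res^2) / d
  xtx_inv <- chol2inv(qr.R(qr_x))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coefs,
                 cov_unscaled = xtx_inv,
                 sigma2 = s2,
                 df_residual = rep(d, ncol(Y)),
                 zero_variance = s2 <= 0,
                 design = X,
                 subject_id = rownames(values)[cc],
                 analytes = colnames(Y)),
            class = "analyte_fit")
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the hyperparameters (d0, s0^2) of a scaled inverse-chi-square
#' prior on the per-analyte residual variances by the method of moments on
#' e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2): d0 solves
#' trigamma(d0/2) = max(0, var(e) - mean trigamma(d_g/2)) (d0 = +Inf when
#' the right-hand side is 0) and s0^2 = exp(mean(e) + digamma(d0/2) -
#' log(d0/2)). Posterior (moderated) variances are the precision-weighted
#' blend (d0 s0^2 + d_g s_g^2) / (d0 + d_g).
#'
#' @param s2 per-analyte residual variances (all positive; >= 2 analytes).
#' @param df per-analyte residual degrees of freedom.
#' @return list with \code{d0}, \code{s02} and \code{s2_post}.
#' @export
ebayes_moderate <- function(s2, df) {
  if (length(s2) < 2L) stop_config("variance moderation needs >= 2 analytes")
  if (any(s2 <= 0)) stop_config("all residual variances must be positive")
  df <- rep(df, length.out = length(s2))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  rhs <- max(0, stats::var(e) - mean(trigamma(df / 2)))
  if (rhs <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    # trigamma(d0/2) is strictly decreasing in d0; solve on the log scale
    f <- function(log_half_d0) trigamma(exp(log_half_d0)) - rhs
    root <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
    d0 <- 2 * exp(root)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + df * s2) / (d0 + df)
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Class contrasts against the reference trajectory
#'
#' Builds the contrast matrix extracting each non-reference class
#' coefficient from an [fit_analyte_models()] design whose class factor was
#' entered with the reference (largest) class as baseline.
#'
#' @param afit an \code{analyte_fit}.
#' @param class_prefix coefficient-name prefix of the class factor.
#' @return p x (number of contrasts) matrix.
#' @export
trajectory_contrasts <- function(afit, class_prefix = "traj_class") {
  cn <- colnames(afit$design)
  keep <- grep(paste0("^", class_prefix), cn, value = TRUE)
  if (!length(keep)) stop_config("no class coefficients matching prefix '%s'",
                                 class_prefix)
  C <- matrix(0, length(cn), length(keep),
              dimnames = list(cn, sub(paste0("^", class_prefix), "", keep)))
  C[cbind(match(keep, cn), seq_along(keep))] <- 1
  C
}

#' Moderated-t planned contrasts
#'
#' Applies a contrast matrix to per-analyte linear-model fits, with
#' (optionally) empirical-Bayes moderated standard errors: moderated
#' t = estimate / (s_tilde * c) on d0 + d_g degrees of freedom (the normal
#' reference when d0 is infinite), two-sided p-values and
#' Benjamini-Hochberg FDR flags at rate \code{q} within each contrast.
#' Setting \code{moderate = FALSE} (equivalently d0 = 0) reproduces the
#' ordinary per-analyte t-tests, the convention used for the blood count
#' and clinical chemistry family. Contrast estimates are untouched by
#' moderation.
#'
#' @param afit an \code{analyte_fit}.
#' @param contrasts p x k contrast matrix (rows = design columns), e.g. from
#'   [trajectory_contrasts()].
#' @param q FDR rate within each contrast set (default 0.1).
#' @param moderate moderate variances across analytes (default TRUE).
#' @return object of class \code{ebayes_fit}: a results table (analyte,
#'   contrast, estimate, se, t, p, neg_log10_p, fdr_significant) plus the
#'   hyperparameters d0 and s02 and the moderated variances.
#' @export
planned_contrasts <- function(afit, contrasts, q = 0.1, moderate = TRUE) {
  stopifnot(inherits(afit, "analyte_fit"))
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != nrow(afit$coefficients))
    stop_config("contrast matrix has %d rows but the design has %d columns",
                nrow(contrasts), nrow(afit$coefficients))
  usable <- !afit$zero_variance
  if (moderate && sum(usable) >= 2L) {
    mod <- ebayes_moderate(afit$sigma2[usable], afit$df_residual[usable])
    d0 <- mod$d0
    s2_tilde <- afit$sigma2
    s2_tilde[usable] <- mod$s2_post
    s02 <- mod$s02
  } else {
    d0 <- 0
    s2_tilde <- afit$sigma2
    s02 <- NA_real_
  }
  est <- t(contrasts) %*% afit$coefficients          # k x m
  cvar <- diag(t(contrasts) %*% afit$cov_unscaled %*% contrasts)  # k
  k <- ncol(contrasts)
  rows <- lapply(seq_len(k), function(j) {
    se <- sqrt(cvar[j] * s2_tilde)
    tt <- ifelse(se > 0, est[j, ] / se, 0)
    dft <- d0 + afit$df_residual
    p <- if (cvar[j] == 0) rep(1, length(tt))
    else 2 * stats::pt(-abs(tt), df = dft)
    data.frame(analyte = afit$analytes,
               contrast = colnames(contrasts)[j] %||% paste0("C", j),
               estimate = est[j, ], se = se, t = tt, p = p,
               neg_log10_p = -log10(p),
               fdr_significant = bh_fdr(p, q),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, d0 = d0, s02 = s02, s2_post = s2_tilde,
                 q = q, moderated = moderate),
            class = "ebayes_fit")
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat(sprintf("Moderated contrasts: %d rows | d0 = %s, s0^2 = %s | %d FDR hits at q = %g\n",
              nrow(x$table), format(x$d0, digits = 4),
              format(x$s02, digits = 4), sum(x$table$fdr_significant), x$q))
  invisible(x)
}

#' Full biomarker association pass for one omics family
#'
#' Convenience wrapper: applies the family's feature filter (LOD filter for
#' proteins, subclass removal for metabolomics), fits the per-analyte
#' linear models, and runs the reference-class planned contrasts with
#' moderation (plain regressions for the blood count/chemistry family by
#' default).
#'
#' @param panel a \code{biomarker_panel}.
#' @param design subject-level data frame including the class column.
#' @param formula model formula; default uses the adjusted covariate set.
#' @param family analyte family to analyse.
#' @param q FDR rate.
#' @param moderate override the family default for variance moderation.
#' @return an \code{ebayes_fit}.
#' @export
analyze_biomarkers <- function(panel, design,
                               formula = ~ traj_class + sex +
                                 maternal_education + social_class + bmi10,
                               family = c("protein", "metabolomic",
                                          "blood_count_chemistry"),
                               q = 0.1, moderate = NULL) {
  family <- match.arg(family)
  keep <- panel$metadata$family == family
  fam_panel <- subset_panel(panel, keep)
  fam_panel <- switch(family,
                      protein = lod_filter(fam_panel),
                      metabolomic = select_metabolomic_features(fam_panel),
                      blood_count_chemistry = fam_panel)
  moderate <- moderate %||% (family != "blood_count_chemistry")
  if ("traj_class" %in% names(design)) {
    tabcl <- table(design$traj_class)
    design$traj_class <- stats::relevel(factor(design$traj_class),
                                        ref = names(tabcl)[which.max(tabcl)])
  }
  afit <- fit_analyte_models(fam_panel, design, formula)
  planned_contrasts(afit, trajectory_contrasts(afit), q = q,
                    moderate = moderate)
}
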