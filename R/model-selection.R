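#' Bayesian information criterion
#'
#' BIC = -2 loglik + k log(N), with N the number of subjects (the
#' independent sampling units of the mixture), not observations.
#'
#' @param loglik maximised log-likelihood.
#' @param n_parameters number of free parameters k.
#' @param n_subjects number of subjects N (>= 2).
#' @return numeric scalar.
#' @export
bic <- function(loglik, n_parameters, n_subjects) {
  if (n_subjects < 2) stop_config("n_subjects must be >= 2")
  -2 * loglik + n_parameters * log(n_subjects)
}

# total classification entropy EN = sum_i sum_g -p log p, with 0 log 0 = 0
entropy_total <- function(P) {
  pl <- P * log(P)
  pl[P == 0] <- 0
  -sum(pl)
}

#' Relative entropy of a posterior classification
#'
#' 1 - EN / (N log G), where EN is the total classification entropy; 1 means
#' perfectly crisp assignment, 0 uniform posteriors. For G = 1 the statistic
#' is undefined; 1 is returned with a warning.
#'
#' @param posteriors a \code{posterior_matrix} or an N x G probability
#'   matrix.
#' @return numeric in [0, 1].
#' @export
relative_entropy <- function(posteriors) {
  P <- if (inherits(posteriors, "posterior_matrix")) posteriors$probabilities
  else as.matrix(posteriors)
  G <- ncol(P)
  if (G == 1L) {
    warning("relative entropy is undefined for G = 1; returning 1")
    return(1)
  }
  1 - entropy_total(P) / (nrow(P) * log(G))
}

#' Integrated completed likelihood (ICL-BIC convention)
#'
#' ICL = BIC + 2 EN, where EN is the total classification entropy of the
#' posterior matrix; equal to the BIC when the classification is crisp.
#'
#' @param bic_value the model's BIC.
#' @param posteriors a \code{posterior_matrix} or probability matrix.
#' @return numeric scalar.
#' @export
icl <- function(bic_value, posteriors) {
  P <- if (inherits(posteriors, "posterior_matrix")) posteriors$probabilities
  else as.matrix(posteriors)
  bic_value + 2 * entropy_total(P)
}

#' Average posterior probability of assignment (APP) per class
#'
#' APP_g is the mean posterior probability of class g among subjects whose
#' modal class is g; the conventional adequacy gate requires APP >= 0.7 for
#' every class. Classes with no assigned member get NA.
#'
#' @param posteriors a \code{posterior_matrix}.
#' @return numeric vector of length G.
#' @export
average_posterior_prob <- function(posteriors) {
  stopifnot(inherits(posteriors, "posterior_matrix"))
  P <- posteriors$probabilities
  vapply(seq_len(ncol(P)), function(g) {
    in_g <- posteriors$modal_class == g
    if (!any(in_g)) NA_real_ else mean(P[in_g, g])
  }, numeric(1L))
}

#' Odds of correct classification (OCC) per class
#'
#' OCC_g = [APP_g / (1 - APP_g)] / [pi_g / (1 - pi_g)], the assignment odds
#' relative to the model-estimated prior odds; the conventional adequacy
#' gate requires OCC >= 5 for every class. APP_g = 1 yields +Inf.
#'
#' @param app per-class average posterior probabilities.
#' @param pi_hat model-estimated mixing proportions (all strictly in (0,1)).
#' @return numeric vector.
#' @export
odds_correct_classification <- function(app, pi_hat) {
  if (any(pi_hat <= 0 | pi_hat >= 1))
    stop_config("mixing proportions must lie strictly in (0, 1)")
  ifelse(app >= 1, Inf, (app / (1 - app)) / (pi_hat / (1 - pi_hat)))
}

#' Fit indices and adequacy statistics for one candidate
#'
#' @param fit a \code{trajectory_fit}.
#' @param data the score table used for fitting.
#' @return one-row data frame: G, structure, powers, loglik, n_parameters,
#'   BIC, ICL, relative entropy, smallest class share, min APP, min OCC,
#'   converged.
#' @export
fit_indices <- function(fit, data) {
  post <- posterior_probs(fit, data, allow_unconverged = TRUE)
  b <- bic(fit$loglik, fit$n_parameters, fit$n_subjects)
  ent <- if (fit$spec$G == 1L) 1 else relative_entropy(post)
  app <- average_posterior_prob(post)
  occ <- if (fit$spec$G == 1L) Inf
  else suppressWarnings(odds_correct_classification(
    app, pmin(pmax(fit$pi, 1e-12), 1 - 1e-12)))
  share <- as.vector(table(factor(post$modal_class, levels = seq_len(fit$spec$G)))) /
    length(post$modal_class)
  data.frame(G = fit$spec$G, structure = fit$spec$random_effects,
             powers = paste(fit$spec$basis$powers, collapse = ","),
             loglik = fit$loglik, n_parameters = fit$n_parameters,
             BIC = b, ICL = icl(b, post), relative_entropy = ent,
             smallest_class_share = min(fit$pi),
             smallest_assigned_share = min(share),
             min_APP = min(app), min_OCC = min(occ),
             converged = fit$converged, stringsAsFactors = FALSE)
}

gate_candidates <- function(tab, gates, adequacy = FALSE) {
  pass <- tab$converged & tab$smallest_class_share >= gates$min_class_share
  if (adequacy)
    pass <- pass & !is.na(tab$min_APP) & tab$min_APP >= gates$min_app &
      !is.na(tab$min_OCC) & tab$min_OCC >= gates$min_occ
  pass
}

#' Multi-step latent-class model selection
#'
#' Applies the four-step selection framework to a list of candidate fits:
#' (i) choose the number of classes k by BIC among candidates of the
#' class-number-sweep structure that converge and keep every class share at
#' or above \code{min_class_share}; (ii) at fixed k, compare random-effect
#' structures under the additional adequacy gates (average posterior
#' probability and odds of correct classification), choosing by BIC;
#' (iii) at fixed k and structure, refine the fractional-polynomial basis by
#' BIC. Every gate outcome is recorded in the decision trail; when BIC and
#' ICL disagree, BIC decides and the disagreement is logged. Visual
#' inspection is supported by [trajectory_curves()] output, never applied as
#' an automatic rule.
#'
#' The function is a pure function of its candidate list: candidates for the
#' steps are distinguished by their spec (structure for step (i) via
#' \code{sweep_structure}, G for step (ii), basis for step (iii)); steps
#' with no eligible candidates are skipped with a trail entry.
#'
#' @param candidates list of \code{trajectory_fit} objects.
#' @param data the score table the candidates were fitted to.
#' @param gates list with \code{min_class_share} (default 0.05),
#'   \code{min_app} (0.7) and \code{min_occ} (5).
#' @param sweep_structure the random-effect structure used for the
#'   class-number sweep; defaults to the structure of the first candidate.
#' @return object of class \code{model_selection_report}: the candidate
#'   index table, the ordered decision trail, the chosen candidate index
#'   (NA when no candidate passes) and the chosen fit.
#' @export
select_model <- function(candidates, data,
                         gates = list(min_class_share = 0.05, min_app = 0.7,
                                      min_occ = 5),
                         sweep_structure = NULL) {
  if (!length(candidates)) stop_config("no candidates supplied")
  tab <- do.call(rbind, lapply(candidates, fit_indices, data = data))
  tab$candidate <- seq_len(nrow(tab))
  sweep_structure <- sweep_structure %||% tab$structure[1L]
  trail <- character(0)
  note <- function(...) trail <<- c(trail, sprintf(...))

  # step (i): class number under the sweep structure
  s1 <- tab[tab$structure == sweep_structure, , drop = FALSE]
  pass1 <- gate_candidates(s1, gates)
  note("step 1: %d/%d candidates with structure '%s' pass convergence and class-share >= %g gates",
       sum(pass1), nrow(s1), sweep_structure, gates$min_class_share)
  if (!any(pass1)) {
    note("step 1: no candidate passes; selection fails")
    return(structure(list(candidates = tab, decision_trail = trail,
                          chosen = NA_integer_, chosen_fit = NULL),
                     class = "model_selection_report"))
  }
  s1p <- s1[pass1, , drop = FALSE]
  k <- s1p$G[which.min(s1p$BIC)]
  if (s1p$G[which.min(s1p$ICL)] != k)
    note("step 1: BIC chooses k = %d but ICL prefers k = %d; BIC decides",
         k, s1p$G[which.min(s1p$ICL)])
  note("step 1: k = %d selected by BIC (%.2f)", k, min(s1p$BIC))

  # step (ii): structure comparison at fixed k with adequacy gates
  s2 <- tab[tab$G == k, , drop = FALSE]
  pass2 <- gate_candidates(s2, gates, adequacy = TRUE)
  note("step 2: %d/%d candidates at k = %d pass adequacy gates (APP >= %g, OCC >= %g)",
       sum(pass2), nrow(s2), k, gates$min_app, gates$min_occ)
  if (!any(pass2)) {
    note("step 2: adequacy gates relaxed (no candidate passed); falling back to convergence + class-share gates")
    pass2 <- gate_candidates(s2, gates)
  }
  if (!any(pass2)) {
    note("step 2: no candidate passes; selection fails")
    return(structure(list(candidates = tab, decision_trail = trail,
                          chosen = NA_integer_, chosen_fit = NULL),
                     class = "model_selection_report"))
  }
  s2p <- s2[pass2, , drop = FALSE]
  # compare one representative (best BIC) per structure
  best_by_structure <- do.call(rbind, lapply(split(s2p, s2p$structure),
                                             function(d) d[which.min(d$BIC), ]))
  structure_chosen <- best_by_structure$structure[which.min(best_by_structure$BIC)]
  note("step 2: structure '%s' selected by BIC (%.2f)", structure_chosen,
       min(best_by_structure$BIC))

  # step (iii): FP refinement at fixed k and structure
  s3 <- tab[tab$G == k & tab$structure == structure_chosen, , drop = FALSE]
  pass3 <- gate_candidates(s3, gates)
  s3p <- s3[pass3, , drop = FALSE]
  chosen <- s3p$candidate[which.min(s3p$BIC)]
  note("step 3: basis (%s) selected by BIC (%.2f) among %d converged bases",
       s3p$powers[which.min(s3p$BIC)], min(s3p$BIC), nrow(s3p))

  structure(list(candidates = tab, decision_trail = trail,
                 chosen = chosen, chosen_fit = candidates[[chosen]]),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("Model selection report\n")
  cat(paste0("  - ", x$decision_trail, collapse = "\n"), "\n")
  if (!is.na(x$chosen)) {
    cat("chosen candidate:", x$chosen, "\n")
    print(x$chosen_fit)
  } else cat("no candidate passed the gates\n")
  invisible(x)
}

#' Write a selection report to JSON and its index table to CSV
#'
#' @param report a \code{model_selection_report}.
#' @param json_path,csv_path output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_selection_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$candidates, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    obj <- list(decision_trail = report$decision_trail, chosen = report$chosen,
                candidates = report$candidates)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(json = json_path, csv = csv_path))
}
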