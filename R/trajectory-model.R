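#' Latent-class trajectory model specification
#'
#' Defines a finite-mixture model for longitudinal sum scores: G latent
#' classes, a fractional-polynomial basis of age for the class mean curves,
#' and the random-effect structure. \code{"none"} gives a group-based
#' trajectory model (GBTM: fixed-effect class curves plus i.i.d. residual);
#' \code{"common_intercept"} a growth mixture model with one random
#' intercept variance shared by all classes; and
#' \code{"class_proportional_intercept"} a growth mixture model where each
#' class scales the random-intercept SD by a positive multiplier (reference
#' class fixed at 1 for identifiability). Residual variance is common
#' across classes.
#'
#' @param G number of latent classes (>= 1).
#' @param basis an [fp_basis()] for the class mean curves.
#' @param random_effects one of "none", "common_intercept",
#'   "class_proportional_intercept".
#' @return object of class \code{trajectory_spec}.
#' @export
trajectory_spec <- function(G, basis = fp_basis(c(1, 2)),
                            random_effects = c("none", "common_intercept",
                                               "class_proportional_intercept")) {
  random_effects <- match.arg(random_effects)
  if (G < 1) stop_config("G must be >= 1")
  structure(list(G = as.integer(G), basis = basis,
                 random_effects = random_effects),
            class = "trajectory_spec")
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat(sprintf("Trajectory model: G = %d, random effects = %s, powers (%s)\n",
              x$G, x$random_effects, paste(x$basis$powers, collapse = ", ")))
  invisible(x)
}

# grouped design: observations sorted by subject, with subject index
traj_data <- function(score_table, basis) {
  need <- c("subject_id", "age", "score")
  missing_cols <- setdiff(need, names(score_table))
  if (length(missing_cols))
    stop_config("score table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  obs <- score_table[!is.na(score_table$score), , drop = FALSE]
  n_dropped <- length(setdiff(unique(score_table$subject_id),
                              unique(obs$subject_id)))
  if (!nrow(obs)) stop_config("no non-missing scores to model")
  ids <- unique(obs$subject_id)
  idx <- match(obs$subject_id, ids)
  ord <- order(idx)
  obs <- obs[ord, , drop = FALSE]
  idx <- idx[ord]
  list(y = as.numeric(obs$score), X = build_fp_basis(obs$age, basis),
       age = obs$age,
       idx = idx, n_i = tabulate(idx, nbins = length(ids)),
       subject_ids = ids, N = length(ids), n_dropped_empty = n_dropped)
}

# N x G matrix of per-subject class log-densities under a random-intercept
# covariance V_ig = c_g 1 1' + sigma2 I (c_g = omega_g^2 tau^2; 0 for GBTM),
# using the Sherman-Morrison identity for the determinant and quadratic form
class_logdens <- function(dat, beta, sigma2, c_g) {
  G <- ncol(beta)
  if (sigma2 <= 0) stop_config("residual variance must be positive")
  R <- dat$y - dat$X %*% beta                  # n_obs x G residuals
  A <- rowsum(R * R, dat$idx)                  # sum r^2 per subject
  B <- rowsum(R, dat$idx)                      # sum r  per subject
  n_i <- dat$n_i
  logf <- matrix(0, dat$N, G)
  for (g in seq_len(G)) {
    cg <- c_g[g]
    logdet <- n_i * log(sigma2) + log1p(n_i * cg / sigma2)
    quad <- A[, g] / sigma2 -
      cg * B[, g]^2 / (sigma2 * (sigma2 + n_i * cg))
    logf[, g] <- -0.5 * (n_i * log(2 * pi) + logdet + quad)
  }
  logf
}

softmax0 <- function(logits) {
  e <- exp(c(0, logits) - max(0, logits))
  e / sum(e)
}

params_c_g <- function(spec, params) {
  switch(spec$random_effects,
         none = rep(0, spec$G),
         common_intercept = rep(params$tau^2, spec$G),
         class_proportional_intercept = (params$omega * params$tau)^2)
}

#' Marginal log-likelihood of a latent-class trajectory model
#'
#' Evaluates sum over subjects of log sum_g pi_g phi(y_i; X_i beta_g, V_ig),
#' with V_ig = omega_g^2 tau^2 1 1' + sigma^2 I under random-intercept
#' structures and sigma^2 I for the GBTM. Subjects contribute whatever
#' non-missing occasions they have (row deletion, no imputation); subjects
#' with zero non-missing occasions are excluded with a count recorded in the
#' \code{"n_excluded"} attribute.
#'
#' @param spec a [trajectory_spec()].
#' @param params list with elements \code{logits} (G-1 mixing logits,
#'   reference class 1 at 0), \code{beta} (G x p class coefficient matrix),
#'   \code{sigma} (residual SD), and for random-intercept structures
#'   \code{tau} (random-intercept SD) and \code{omega} (length-G class
#'   multipliers, omega[1] = 1).
#' @param data score table with columns subject_id, age, score.
#' @return the log-likelihood (numeric scalar).
#' @export
marginal_loglik <- function(spec, params, data) {
  dat <- traj_data(data, spec$basis)
  ll <- loglik_internal(spec, params, dat)
  attr(ll, "n_excluded") <- dat$n_dropped_empty
  ll
}

loglik_internal <- function(spec, params, dat) {
  pi_g <- softmax0(params$logits %||% numeric(0))
  beta <- t(params$beta)                        # p x G
  logf <- class_logdens(dat, beta, params$sigma^2, params_c_g(spec, params))
  lw <- sweep(logf, 2L, log(pmax(pi_g, 1e-300)), `+`)
  sum(logsumexp_rows(lw))
}

# one EM pass structure for the GBTM: E-step posteriors, M-step WLS + pooled
# residual variance; returns the loglik path and final parameters
em_gbtm <- function(dat, G, beta, sigma2, pi_g, max_iter, tol,
                    monitor_monotone = TRUE) {
  ll_old <- -Inf
  path <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logf <- class_logdens(dat, beta, sigma2, rep(0, G))
    lw <- sweep(logf, 2L, log(pmax(pi_g, 1e-300)), `+`)
    lse <- logsumexp_rows(lw)
    ll <- sum(lse)
    if (monitor_monotone && ll < ll_old - 1e-8)
      stop_config("EM log-likelihood decreased by %g at iteration %d",
                  ll_old - ll, it)
    path <- c(path, ll)
    if (it > 1L && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    P <- exp(lw - lse)
    pi_g <- colMeans(P)
    w_obs <- P[dat$idx, , drop = FALSE]
    ssr <- 0
    for (g in seq_len(G)) {
      w <- w_obs[, g]
      if (sum(w) > 1e-8) {
        fit <- stats::lm.wfit(dat$X, dat$y, w)
        beta[, g] <- fit$coefficients
        ssr <- ssr + sum(w * fit$residuals^2)
      } else {
        ssr <- ssr + sum(w * (dat$y - dat$X %*% beta[, g])^2)
      }
    }
    sigma2 <- ssr / length(dat$y)
  }
  if (!converged) {
    # loglik at the post-M-step parameters actually returned
    logf <- class_logdens(dat, beta, sigma2, rep(0, G))
    lw <- sweep(logf, 2L, log(pmax(pi_g, 1e-300)), `+`)
    ll <- sum(logsumexp_rows(lw))
  }
  list(beta = beta, sigma2 = sigma2, pi = pi_g, loglik = ll, path = path,
       converged = converged, iters = it)
}

# pack/unpack the unconstrained parameter vector for quasi-Newton GMM fits
pack_theta <- function(spec, logits, beta, sigma, tau, omega) {
  th <- c(logits, as.vector(beta))
  th <- c(th, log(sigma))
  if (spec$random_effects != "none") th <- c(th, log(tau))
  if (spec$random_effects == "class_proportional_intercept")
    th <- c(th, log(omega[-1L]))
  th
}

unpack_theta <- function(spec, theta, p) {
  G <- spec$G
  k <- G - 1L
  logits <- if (k > 0) theta[seq_len(k)] else numeric(0)
  beta <- matrix(theta[k + seq_len(p * G)], p, G)
  pos <- k + p * G
  sigma <- exp(theta[pos + 1L]); pos <- pos + 1L
  tau <- 0; omega <- rep(1, G)
  if (spec$random_effects != "none") { tau <- exp(theta[pos + 1L]); pos <- pos + 1L }
  if (spec$random_effects == "class_proportional_intercept" && G > 1L)
    omega <- c(1, exp(theta[pos + seq_len(G - 1L)]))
  list(logits = logits, beta = beta, sigma = sigma, tau = tau, omega = omega)
}

# random multistart initial values: each start seeds class curves from a
# one-step cluster assignment of the subjects' coarse age-profile features
# (mean score in early / mid / late age bands) around G randomly chosen
# anchor subjects, with per-cluster least-squares curves. This disperses the
# starts over qualitatively different trajectory configurations, which
# perturbing the pooled fit by coefficient standard errors does not.
make_starts <- function(dat, G, n_starts, beta0, sigma0) {
  p <- nrow(as.matrix(beta0))
  if (G == 1L)
    return(replicate(n_starts,
                     list(beta = matrix(beta0, p, 1L), sigma = sigma0, pi = 1),
                     simplify = FALSE))
  br <- stats::quantile(dat$age, c(1 / 3, 2 / 3))
  band <- 1L + (dat$age > br[1L]) + (dat$age > br[2L])
  sums <- rowsum(cbind(dat$y * (band == 1L), dat$y * (band == 2L),
                       dat$y * (band == 3L)), dat$idx)
  cnts <- rowsum(cbind(band == 1L, band == 2L, band == 3L) + 0, dat$idx)
  feat <- sums / cnts
  overall <- rowsum(dat$y, dat$idx) / dat$n_i
  for (b in 1:3) feat[cnts[, b] == 0, b] <- overall[cnts[, b] == 0]
  lapply(seq_len(n_starts), function(s) {
    anchors <- feat[sample.int(dat$N, G), , drop = FALSE]
    d2 <- vapply(seq_len(G),
                 function(g) rowSums((feat - matrix(anchors[g, ], dat$N, 3,
                                                    byrow = TRUE))^2),
                 numeric(dat$N))
    cl <- max.col(-d2, ties.method = "first")
    beta <- matrix(beta0, p, G)
    for (g in seq_len(G)) {
      rows <- cl[dat$idx] == g
      if (sum(rows) > 2L * p) {
        fit <- stats::lm.fit(dat$X[rows, , drop = FALSE], dat$y[rows])
        if (!anyNA(fit$coefficients)) beta[, g] <- fit$coefficients
      }
    }
    pi_g <- pmax(tabulate(cl, nbins = G) / dat$N, 0.01)
    list(beta = beta, sigma = sigma0, pi = pi_g / sum(pi_g))
  })
}

negll_theta <- function(theta, spec, dat, n_coef) {
  # line-search proposals can over/underflow the log-variance components;
  # return a large finite value so the optimiser backtracks
  if (any(!is.finite(theta))) return(1e10)
  u <- unpack_theta(spec, theta, n_coef)
  if (!is.finite(u$sigma) || u$sigma^2 <= 0 || !is.finite(u$tau^2) ||
      any(!is.finite(u$omega)))
    return(1e10)
  pi_g <- softmax0(u$logits)
  c_g <- switch(spec$random_effects,
                none = rep(0, spec$G),
                common_intercept = rep(u$tau^2, spec$G),
                class_proportional_intercept = (u$omega * u$tau)^2)
  logf <- class_logdens(dat, u$beta, u$sigma^2, c_g)
  lw <- sweep(logf, 2L, log(pmax(pi_g, 1e-300)), `+`)
  val <- -sum(logsumexp_rows(lw))
  if (is.finite(val)) val else 1e10
}

n_traj_parameters <- function(spec, p) {
  spec$G - 1L + spec$G * p + 1L +
    (spec$random_effects != "none") +
    (spec$random_effects == "class_proportional_intercept") * (spec$G - 1L)
}

#' Fit a latent-class trajectory model by maximum likelihood
#'
#' Multistart estimation: \code{n_starts} random initial values (class
#' curves seeded from cluster assignments of the subjects' coarse
#' age-profile features around randomly chosen anchor subjects) are each
#' advanced for \code{burn_iters} iterations, and the best is continued to
#' convergence (relative log-likelihood change below \code{tol}) or
#' \code{final_iters} iterations. GBTM fits use EM with an analytic
#' weighted-least-squares M-step (monotone likelihood is monitored); growth
#' mixture structures maximise the marginal likelihood by quasi-Newton
#' (BFGS) with log-parameterised variance components. Classes are returned
#' in canonical order of decreasing mixing proportion.
#'
#' @param spec a [trajectory_spec()].
#' @param data score table (subject_id, age, score); should already have
#'   passed the minimum-measurements eligibility filter.
#' @param n_starts,burn_iters,final_iters multistart schedule (defaults 50,
#'   10, 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param seed integer seed controlling the random starts.
#' @return object of class \code{trajectory_fit}: mixing proportions and
#'   logits, class coefficients, variance components, log-likelihood,
#'   parameter count, convergence flag and the multistart trace.
#' @export
fit_trajectory <- function(spec, data, n_starts = 50L, burn_iters = 10L,
                           final_iters = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  dat <- traj_data(data, spec$basis)
  G <- spec$G
  p <- ncol(dat$X)
  if (G > dat$N)
    stop_config("G = %d exceeds the number of subjects (%d)", G, dat$N)

  ols <- stats::lm.fit(dat$X, dat$y)
  beta0 <- ols$coefficients
  sigma0 <- sqrt(mean(ols$residuals^2))

  with_seed(seed, {
    starts <- make_starts(dat, G, max(1L, n_starts), beta0, sigma0)

    if (spec$random_effects == "none") {
      burns <- lapply(starts, function(st)
        em_gbtm(dat, G, st$beta, st$sigma^2, st$pi, burn_iters, tol = 0))
      trace <- vapply(burns, `[[`, numeric(1), "loglik")
      best <- burns[[which.max(trace)]]
      fin <- em_gbtm(dat, G, best$beta, best$sigma2, best$pi,
                     final_iters, tol = tol)
      pi_g <- fin$pi
      beta <- fin$beta
      params <- list(beta = t(beta), sigma = sqrt(fin$sigma2),
                     tau = 0, omega = rep(1, G))
      loglik <- fin$loglik
      converged <- fin$converged
      em_path <- fin$path
    } else {
      thetas <- lapply(starts, function(st)
        pack_theta(spec, rep(0, G - 1L), st$beta, st$sigma,
                   tau = st$sigma / 2, omega = rep(1, G)))
      burns <- lapply(thetas, function(th)
        stats::optim(th, negll_theta, spec = spec, dat = dat, n_coef = p,
                     method = "BFGS", control = list(maxit = burn_iters)))
      trace <- -vapply(burns, `[[`, numeric(1), "value")
      bi <- which.max(trace)
      fin <- stats::optim(burns[[bi]]$par, negll_theta, spec = spec, dat = dat,
                          n_coef = p, method = "BFGS",
                          control = list(maxit = final_iters, reltol = tol))
      u <- unpack_theta(spec, fin$par, p)
      pi_g <- softmax0(u$logits)
      beta <- u$beta
      params <- list(beta = t(beta), sigma = u$sigma, tau = u$tau,
                     omega = u$omega)
      loglik <- -fin$value
      converged <- fin$convergence == 0L
      em_path <- NULL
    }

    # canonical ordering: descending mixing proportion; re-reference the
    # class multipliers so omega[1] = 1 (fold the scale into tau)
    perm <- order(pi_g, decreasing = TRUE)
    pi_g <- pi_g[perm]
    beta <- beta[, perm, drop = FALSE]
    omega <- params$omega[perm]
    tau <- params$tau
    if (spec$random_effects == "class_proportional_intercept") {
      tau <- tau * omega[1L]
      omega <- omega / omega[1L]
    }
    logits <- log(pi_g[-1L] / pi_g[1L])
    params <- list(logits = logits, beta = t(beta), sigma = params$sigma,
                   tau = tau, omega = omega)

    fit <- structure(list(spec = spec, pi = pi_g, params = params,
                          loglik = loglik,
                          n_parameters = n_traj_parameters(spec, p),
                          n_subjects = dat$N, converged = converged,
                          multistart_trace = trace, em_loglik_path = em_path,
                          basis_columns = colnames(dat$X)),
                     class = "trajectory_fit")
    check <- loglik_internal(spec, params, dat)
    if (abs(check - loglik) > 1e-6 * (abs(loglik) + 1))
      stop_config("internal error: stored loglik %.8f != recomputed %.8f",
                  loglik, check)
    fit
  })
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Fitted %d-class %s | loglik %.3f | %d subjects | converged: %s\n",
              x$spec$G,
              switch(x$spec$random_effects, none = "GBTM",
                     common_intercept = "GMM (common intercept variance)",
                     class_proportional_intercept = "GMM (class-proportional intercept variance)"),
              x$loglik, x$n_subjects, x$converged))
  cat("mixing proportions:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

posterior_internal <- function(fit, dat) {
  G <- fit$spec$G
  beta <- t(fit$params$beta)
  logf <- class_logdens(dat, beta, fit$params$sigma^2,
                        params_c_g(fit$spec, fit$params))
  lw <- sweep(logf, 2L, log(pmax(fit$pi, 1e-300)), `+`)
  lse <- logsumexp_rows(lw)
  P <- exp(lw - lse)
  P / rowSums(P)
}

new_posterior_matrix <- function(P, subject_ids, prior_only = NULL) {
  modal <- max.col(P, ties.method = "first")
  structure(list(probabilities = P,
                 subject_id = subject_ids,
                 modal_class = modal,
                 modal_probability = P[cbind(seq_len(nrow(P)), modal)],
                 prior_only = prior_only %||% rep(FALSE, nrow(P))),
            class = "posterior_matrix")
}

#' Posterior class-membership probabilities
#'
#' p_ig = pi_g f_g(y_i) / sum_h pi_h f_h(y_i), computed with log-sum-exp
#' stabilisation and renormalised rows. Modal class ties break to the lowest
#' class index.
#'
#' @param fit a \code{trajectory_fit}.
#' @param data score table (subject_id, age, score).
#' @param allow_unconverged evaluate even if the fit did not converge.
#' @return object of class \code{posterior_matrix} with fields
#'   \code{probabilities} (N x G), \code{subject_id}, \code{modal_class},
#'   \code{modal_probability}.
#' @export
posterior_probs <- function(fit, data, allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!fit$converged && !allow_unconverged)
    stop_config("fit did not converge; pass allow_unconverged = TRUE to override")
  dat <- traj_data(data, fit$spec$basis)
  new_posterior_matrix(posterior_internal(fit, dat), dat$subject_ids)
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("Posterior matrix: %d subjects x %d classes (mean modal p = %.3f)\n",
              nrow(x$probabilities), ncol(x$probabilities),
              mean(x$modal_probability)))
  invisible(x)
}

#' Predict class membership for new subjects
#'
#' Applies the fitted model's posterior computation to subjects outside the
#' fitting subsample, including those with only one or two measurements.
#' Subjects listed in \code{subject_ids} but with no non-missing occasion
#' receive the prior mixing proportions as their posterior row and are
#' flagged \code{prior_only}.
#'
#' @param fit a \code{trajectory_fit}.
#' @param data score table for the subjects to classify.
#' @param subject_ids optional full roster; defaults to the subjects present
#'   in \code{data}.
#' @inheritParams posterior_probs
#' @return a \code{posterior_matrix} with a \code{prior_only} flag.
#' @export
predict_class <- function(fit, data, subject_ids = NULL,
                          allow_unconverged = FALSE) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!fit$converged && !allow_unconverged)
    stop_config("fit did not converge; pass allow_unconverged = TRUE to override")
  obs <- data[!is.na(data$score), , drop = FALSE]
  subject_ids <- subject_ids %||% unique(data$subject_id)
  with_obs <- intersect(subject_ids, unique(obs$subject_id))
  without_obs <- setdiff(subject_ids, with_obs)
  P_obs <- if (length(with_obs)) {
    dat <- traj_data(obs[obs$subject_id %in% with_obs, , drop = FALSE],
                     fit$spec$basis)
    P <- posterior_internal(fit, dat)
    rownames(P) <- dat$subject_ids
    P[match(with_obs, dat$subject_ids), , drop = FALSE]
  } else matrix(0, 0, fit$spec$G)
  P_prior <- if (length(without_obs))
    matrix(fit$pi, length(without_obs), fit$spec$G, byrow = TRUE)
  else matrix(0, 0, fit$spec$G)
  P <- rbind(P_obs, P_prior)
  ids <- c(with_obs, without_obs)
  ord <- match(subject_ids, ids)
  new_posterior_matrix(P[ord, , drop = FALSE], subject_ids,
                       prior_only = c(rep(FALSE, length(with_obs)),
                                      rep(TRUE, length(without_obs)))[ord])
}

#' Predicted class mean trajectory curves
#'
#' Evaluates each class's mean curve over an age grid, with an approximate
#' 95 percent band from the observed-information covariance of the class
#' coefficients (numerical Hessian of the marginal log-likelihood with
#' mixing and variance parameters held at their estimates).
#'
#' @param fit a \code{trajectory_fit}.
#' @param data the score table the model was fitted to (needed for the
#'   information matrix); omit for curves without bands.
#' @param ages age grid (default 10 to 25 by 0.5).
#' @return data frame: class, age, mean, lower, upper.
#' @export
trajectory_curves <- function(fit, data = NULL, ages = seq(10, 25, by = 0.5)) {
  X <- build_fp_basis(ages, fit$spec$basis)
  G <- fit$spec$G
  p <- ncol(X)
  se <- NULL
  if (!is.null(data)) {
    dat <- traj_data(data, fit$spec$basis)
    f <- function(b) {
      pars <- fit$params
      pars$beta <- matrix(b, G, p, byrow = FALSE)
      loglik_internal(fit$spec, pars, dat)
    }
    H <- tryCatch(stats::optimHess(as.vector(fit$params$beta), f),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(-H), error = function(e) NULL)
      if (!is.null(V)) {
        se <- matrix(NA_real_, length(ages), G)
        for (g in seq_len(G)) {
          rows <- g + G * (seq_len(p) - 1L)  # beta stored G x p, column-major
          Vg <- V[rows, rows, drop = FALSE]
          se[, g] <- sqrt(pmax(rowSums((X %*% Vg) * X), 0))
        }
      }
    }
  }
  mu <- X %*% t(fit$params$beta)
  out <- data.frame(class = rep(seq_len(G), each = length(ages)),
                    age = rep(ages, G),
                    mean = as.vector(mu))
  if (!is.null(se)) {
    out$lower <- out$mean - 1.96 * as.vector(se)
    out$upper <- out$mean + 1.96 * as.vector(se)
  } else {
    out$lower <- NA_real_
    out$upper <- NA_real_
  }
  out
}

#' Write a fitted model to JSON
#'
#' @param fit a \code{trajectory_fit}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(G = fit$spec$G, random_effects = fit$spec$random_effects,
              powers = fit$spec$basis$powers,
              age_transform = list(offset = fit$spec$basis$offset,
                                   divisor = fit$spec$basis$divisor),
              pi = fit$pi, beta = fit$params$beta, sigma = fit$params$sigma,
              tau = fit$params$tau, omega = fit$params$omega,
              loglik = fit$loglik, n_parameters = fit$n_parameters,
              n_subjects = fit$n_subjects, converged = fit$converged,
              multistart_trace = fit$multistart_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a posterior matrix to CSV
#'
#' Columns: subject_id, p_1..p_G, modal_class, modal_probability.
#'
#' @param post a \code{posterior_matrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_posteriors_csv <- function(post, path) {
  P <- post$probabilities
  colnames(P) <- paste0("p_", seq_len(ncol(P)))
  df <- data.frame(subject_id = post$subject_id, P,
                   modal_class = post$modal_class,
                   modal_probability = post$modal_probability,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
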