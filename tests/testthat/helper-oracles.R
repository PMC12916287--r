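# shared helpers for the test suite: brute-force oracles and tiny fixtures

# brute-force marginal log-likelihood of a latent-class trajectory model via
# explicit per-subject multivariate-normal densities (solve/det, no
# Sherman-Morrison), for oracle comparisons on small instances
oracle_loglik <- function(spec, params, data) {
  pi_g <- symptraj:::softmax0(params$logits %||% numeric(0))
  c_g <- switch(spec$random_effects,
                none = rep(0, spec$G),
                common_intercept = rep(params$tau^2, spec$G),
                class_proportional_intercept = (params$omega * params$tau)^2)
  obs <- data[!is.na(data$score), , drop = FALSE]
  total <- 0
  for (id in unique(obs$subject_id)) {
    rows <- obs[obs$subject_id == id, , drop = FALSE]
    X <- build_fp_basis(rows$age, spec$basis)
    y <- rows$score
    n <- length(y)
    logf <- numeric(spec$G)
    for (g in seq_len(spec$G)) {
      V <- c_g[g] * matrix(1, n, n) + params$sigma^2 * diag(n)
      r <- y - as.vector(X %*% params$beta[g, ])
      logf[g] <- -0.5 * (n * log(2 * pi) + log(det(V)) +
                           as.numeric(t(r) %*% solve(V) %*% r))
    }
    total <- total + log(sum(pi_g * exp(logf)))
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small complete-data score table with well-separated linear classes
tiny_two_class_scores <- function(n_per_class = 40, seed = 7) {
  set.seed(seed)
  ages <- c(10, 13, 16, 19, 22, 25)
  mk <- function(prefix, intercept, slope)
    do.call(rbind, lapply(seq_len(n_per_class), function(i)
      data.frame(subject_id = sprintf("%s%03d", prefix, i), age = ages,
                 score = intercept + slope * (ages / 10) +
                   rnorm(length(ages), 0, 0.8),
                 stringsAsFactors = FALSE)))
  rbind(mk("A", 2, 0.5), mk("B", 14, 2))
}

# minimal biomarker_panel constructor for unit tests
make_panel <- function(values, family = "protein",
                       category = "inflammation",
                       below_lod_fraction = 0) {
  m <- ncol(values)
  structure(list(values = values,
                 censored = matrix(FALSE, nrow(values), m,
                                   dimnames = dimnames(values)),
                 metadata = data.frame(
                   analyte = colnames(values),
                   family = rep(family, length.out = m),
                   category = rep(category, length.out = m),
                   lod = rep(-Inf, m),
                   below_lod_fraction = rep(below_lod_fraction,
                                            length.out = m),
                   stringsAsFactors = FALSE)),
            class = "biomarker_panel")
}

# covariate block replicated so each covariate level sees the same
# class-by-outcome table; makes the adjusted fit collapse to the crude model
replicated_covariate_frame <- function(counts) {
  # counts: list(n1, k1, n2, k2) for classes 1 and 2
  cell <- function(cl, y, n) if (n > 0)
    data.frame(traj_class = cl, y = y, n = n) else NULL
  base <- rbind(cell(1L, 1L, counts$k1), cell(1L, 0L, counts$n1 - counts$k1),
                cell(2L, 1L, counts$k2), cell(2L, 0L, counts$n2 - counts$k2))
  base <- base[rep(seq_len(nrow(base)), base$n), c("traj_class", "y")]
  levs <- expand.grid(sex = c("female", "male"),
                      maternal_education = c("low", "high"),
                      social_class = c("I", "II"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(levs)), function(i)
    cbind(base, levs[rep(i, nrow(base)), , drop = FALSE])))
  out$bmi10 <- 17.5
  rownames(out) <- NULL
  out$subject_id <- sprintf("S%05d", seq_len(nrow(out)))
  out
}
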