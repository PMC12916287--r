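#' Score one SMFQ occasion
#'
#' Computes the 13-item Short Mood and Feelings Questionnaire (SMFQ) sum
#' score (0-26) for a single measurement occasion. Items are scored
#' 0 = "not true", 1 = "sometimes true", 2 = "always true". Occasions with
#' one or two missing items have each missing item imputed to the median of
#' the answered items before summing; occasions with more missing items are
#' scored as missing.
#'
#' The median of an even number of answered items is the mean of the two
#' central values; the imputed total is rounded half-up to an integer
#' (disable with \code{round_total = FALSE}) and clamped to [0, 26].
#'
#' @param items numeric vector of exactly 13 entries, each 0, 1, 2 or NA.
#' @param max_missing maximum number of missing items that may be imputed;
#'   occasions with more missing items score NA. Default 2: an occasion with
#'   exactly three missing items is conservatively scored missing.
#' @param round_total logical; round the imputed total half-up to an integer.
#' @return list with elements \code{score} (integer 0-26 or NA),
#'   \code{n_imputed} (0-2 when the score is present) and
#'   \code{imputation_value} (per-item imputed value, or NA when nothing was
#'   imputed).
#' @examples
#' score_occasion(rep(2, 13))$score              # 26
#' score_occasion(c(rep(1, 11), NA, NA))$score   # 13
#' @export
score_occasion <- function(items, max_missing = 2L, round_total = TRUE) {
  if (length(items) != 13L)
    stop_config("an SMFQ record must have exactly 13 items, got %d", length(items))
  bad <- which(!is.na(items) & !(items %in% c(0, 1, 2)))
  if (length(bad))
    stop_config("illegal SMFQ item value %s at index %d (must be 0, 1, 2 or NA)",
                format(items[bad[1L]]), bad[1L])
  miss <- is.na(items)
  n_miss <- sum(miss)
  if (n_miss > max_missing)
    return(list(score = NA_integer_, n_imputed = n_miss, imputation_value = NA_real_))
  answered <- items[!miss]
  if (n_miss == 0L)
    return(list(score = as.integer(sum(answered)), n_imputed = 0L,
                imputation_value = NA_real_))
  med <- stats::median(answered)
  total <- sum(answered) + n_miss * med
  if (round_total) total <- round_half_up(total)
  total <- min(max(total, 0), 26)
  list(score = if (round_total) as.integer(total) else total,
       n_imputed = n_miss, imputation_value = med)
}

#' Score a long-format occasions table
#'
#' Applies [score_occasion()] to every row of a long-format table with one
#' row per subject-occasion and columns \code{item01}..\code{item13}.
#'
#' @param occasions data frame with columns \code{subject_id}, \code{age},
#'   and \code{item01} .. \code{item13}.
#' @inheritParams score_occasion
#' @return data frame with columns \code{subject_id}, \code{age},
#'   \code{score}, \code{n_imputed}.
#' @export
score_smfq <- function(occasions, max_missing = 2L, round_total = TRUE) {
  item_cols <- sprintf("item%02d", 1:13)
  missing_cols <- setdiff(c("subject_id", "age", item_cols), names(occasions))
  if (length(missing_cols))
    stop_config("occasions table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  it <- as.matrix(occasions[item_cols])
  scored <- apply(it, 1L, function(r) {
    s <- score_occasion(r, max_missing = max_missing, round_total = round_total)
    c(s$score, s$n_imputed)
  })
  data.frame(subject_id = occasions$subject_id,
             age = occasions$age,
             score = scored[1L, ],
             n_imputed = as.integer(scored[2L, ]))
}

#' Eligibility filter for trajectory model fitting
#'
#' A subject enters the model-fitting subsample only with at least
#' \code{min_measurements} non-missing occasion scores; subjects with fewer
#' (including none) are retained for posterior class prediction only.
#'
#' @param scores vector of occasion scores (NA = missing) for one subject.
#' @param min_measurements minimum number of non-missing scores (default 3).
#' @return logical.
#' @export
eligible_for_fitting <- function(scores, min_measurements = 3L) {
  sum(!is.na(scores)) >= min_measurements
}

#' Split a score table into fitting and prediction-only subsamples
#'
#' @param score_table output of [score_smfq()].
#' @inheritParams eligible_for_fitting
#' @return list with \code{fitting} and \code{prediction_only} score tables
#'   (both restricted to non-missing scores) and the eligible subject ids.
#' @export
filter_eligible <- function(score_table, min_measurements = 3L) {
  obs <- score_table[!is.na(score_table$score), , drop = FALSE]
  n_by_subj <- table(obs$subject_id)
  eligible <- names(n_by_subj)[n_by_subj >= min_measurements]
  list(fitting = obs[obs$subject_id %in% eligible, , drop = FALSE],
       prediction_only = obs[!(obs$subject_id %in% eligible), , drop = FALSE],
       eligible_ids = eligible)
}
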