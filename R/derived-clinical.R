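#' Homeostatic Model Assessment of Insulin Resistance (HOMA-IR)
#'
#' Standard Matthews formula: fasting glucose (mmol/L) x fasting insulin
#' (uU/mL) / 22.5. Nonpositive inputs yield NA.
#'
#' @param glucose_mmol_l fasting glucose in mmol/L.
#' @param insulin_uu_ml fasting insulin in uU/mL.
#' @return numeric vector.
#' @examples
#' homa_ir(5.6, 10)   # 2.4889
#' @export
homa_ir <- function(glucose_mmol_l, insulin_uu_ml) {
  out <- glucose_mmol_l * insulin_uu_ml / 22.5
  out[!is.na(glucose_mmol_l) & glucose_mmol_l <= 0] <- NA_real_
  out[!is.na(insulin_uu_ml) & insulin_uu_ml <= 0] <- NA_real_
  out
}

#' AST/ALT ratio
#'
#' Aspartate over alanine aminotransferase; NA when ALT is nonpositive.
#'
#' @param ast,alt aminotransferase levels (same units).
#' @return numeric vector.
#' @export
ast_alt_ratio <- function(ast, alt) {
  out <- ast / alt
  out[!is.na(alt) & alt <= 0] <- NA_real_
  out
}

#' Metabolic-syndrome component thresholds
#'
#' The 2009 harmonised consensus thresholds: elevated waist circumference
#' (>= 94 cm for white men, >= 90 cm for non-white men, >= 80 cm for women),
#' triglycerides >= 1.7 mmol/L, HDL cholesterol < 1.0 mmol/L, blood pressure
#' systolic >= 130 or diastolic >= 85 mmHg, fasting glucose >= 5.6 mmol/L.
#'
#' @return named list of thresholds, suitable for the \code{thresholds}
#'   argument of [metabolic_syndrome()].
#' @export
metsyn_thresholds <- function() {
  list(waist_white_male = 94, waist_nonwhite_male = 90, waist_female = 80,
       triglycerides = 1.7, hdl = 1.0, sbp = 130, dbp = 85, glucose = 5.6)
}

# one subject's five risk-factor indicators; NA where undetermined
metsyn_factors <- function(waist_cm, triglycerides_mmol_l, hdl_mmol_l,
                           sbp_mmhg, dbp_mmhg, fasting_glucose_mmol_l,
                           sex, ethnicity_white, th) {
  waist_cut <- if (is.na(sex)) NA_real_
  else if (sex == "female") th$waist_female
  else if (sex == "male") {
    if (is.na(ethnicity_white)) NA_real_
    else if (ethnicity_white) th$waist_white_male else th$waist_nonwhite_male
  } else NA_real_
  bp <- if (is.na(sbp_mmhg) && is.na(dbp_mmhg)) NA
  else if (isTRUE(sbp_mmhg >= th$sbp) || isTRUE(dbp_mmhg >= th$dbp)) TRUE
  else if (is.na(sbp_mmhg) || is.na(dbp_mmhg)) NA  # both needed to rule out
  else FALSE
  c(waist = if (is.na(waist_cut)) NA else waist_cm >= waist_cut,
    tg = triglycerides_mmol_l >= th$triglycerides,
    hdl = hdl_mmol_l < th$hdl,
    bp = bp,
    glucose = fasting_glucose_mmol_l >= th$glucose)
}

#' Metabolic-syndrome classification
#'
#' Classifies subjects as metabolic-syndrome positive when at least three of
#' the five harmonised risk factors are present (see [metsyn_thresholds()]
#' for the inclusive/exclusive boundaries). The blood-pressure factor is the
#' OR of the systolic and diastolic criteria. A subject with undetermined
#' components is classified only when the decision is invariant to them:
#' positive when the determined factors already number >= 3, negative when
#' even counting every undetermined factor the total stays < 3, and missing
#' otherwise. Unknown sex (or unknown ethnicity for men) leaves the waist
#' factor undetermined.
#'
#' @param components data frame with columns \code{waist_cm},
#'   \code{triglycerides_mmol_l}, \code{hdl_mmol_l}, \code{sbp_mmhg},
#'   \code{dbp_mmhg}, \code{fasting_glucose_mmol_l}, \code{sex}
#'   ("male"/"female") and \code{ethnicity_white} (logical).
#' @param thresholds threshold list, by default [metsyn_thresholds()].
#' @return character vector: "positive", "negative" or NA (missing).
#' @export
metabolic_syndrome <- function(components, thresholds = metsyn_thresholds()) {
  need <- c("waist_cm", "triglycerides_mmol_l", "hdl_mmol_l", "sbp_mmhg",
            "dbp_mmhg", "fasting_glucose_mmol_l", "sex", "ethnicity_white")
  missing_cols <- setdiff(need, names(components))
  if (length(missing_cols))
    stop_config("metabolic_syndrome: missing component column(s): %s",
                paste(missing_cols, collapse = ", "))
  vapply(seq_len(nrow(components)), function(i) {
    f <- metsyn_factors(components$waist_cm[i],
                        components$triglycerides_mmol_l[i],
                        components$hdl_mmol_l[i],
                        components$sbp_mmhg[i], components$dbp_mmhg[i],
                        components$fasting_glucose_mmol_l[i],
                        as.character(components$sex[i]),
                        components$ethnicity_white[i], thresholds)
    n_pos <- sum(f, na.rm = TRUE)
    n_unk <- sum(is.na(f))
    if (n_pos >= 3) "positive"
    else if (n_pos + n_unk < 3) "negative"
    else NA_character_
  }, character(1L))
}
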