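#' Synthetic inflammation protein panel catalogue
#'
#' A 92-analyte inflammation protein panel emulating the structure of a
#' targeted proximity-extension assay (values on a log2 NPX-like scale).
#' By construction, \code{n_high_lod} analytes (default 25) carry a target
#' below-detection fraction of 0.6, so the standard >= 50 percent
#' below-LOD exclusion retains 67 of 92 analytes. The catalogue is
#' synthetic: analyte names echo common inflammation markers but the
#' baseline levels and detectability are simulation parameters, not assay
#' data.
#'
#' @param n_high_lod number of analytes configured to exceed the 50 percent
#'   below-LOD threshold.
#' @return data frame: analyte, family, category, baseline_level,
#'   below_lod_target.
#' @export
protein_catalogue <- function(n_high_lod = 25L) {
  named <- c("IL6", "CXCL8", "TNF", "IFNG", "IL10", "IL18", "CCL2", "CCL3",
             "CCL4", "CCL11", "CCL19", "CCL20", "CCL23", "CCL25", "CCL28",
             "CXCL1", "CXCL5", "CXCL6", "CXCL9", "CXCL10", "CXCL11", "CDCP1",
             "FGF19", "FGF21", "FGF23", "HGF", "EIF4EBP1", "VEGFA", "OSM",
             "MMP1", "MMP10", "TGFA", "LIF", "SCF", "TRAIL", "TRANCE",
             "FLT3LG", "CSF1", "CD40", "CD5", "CD6", "CD244", "IL7", "IL12B",
             "IL15RA", "IL10RB", "IL18R1", "TNFRSF9", "TNFSF14", "PDL1",
             "ADA", "AXIN1", "CASP8", "CST5", "DNER", "GDNF", "NTF3", "NT3",
             "SIRT2", "STAMBP", "SULT1A1", "UPA", "SLAMF1", "OPG", "LAPTGFB1",
             "LTA", "NRTN")
  n_total <- 92L
  extra <- sprintf("INFP%02d", seq_len(n_total - length(named)))
  analyte <- c(named, extra)[seq_len(n_total)]
  if (n_high_lod < 0L || n_high_lod > n_total)
    stop_config("n_high_lod must be in 0..%d", n_total)
  # low-abundance analytes (the tail of the panel) carry high censoring
  below <- rep(0.05, n_total)
  if (n_high_lod > 0L)
    below[(n_total - n_high_lod + 1L):n_total] <- 0.60
  data.frame(analyte = analyte,
             family = "protein",
             category = "inflammation",
             baseline_level = 3 + 5 * (seq_len(n_total) - 1) / (n_total - 1),
             below_lod_target = below,
             stringsAsFactors = FALSE)
}

#' Synthetic metabolomic feature catalogue
#'
#' A serum NMR-style metabolomic catalogue: 57 non-redundant features in the
#' standard composition (9 cholesterol measures, 12 apolipoprotein/lipid
#' measures, 3 lipoprotein particle sizes, 16 fatty-acid and saturation
#' measures, 3 glycolysis-related metabolites, 8 amino acids, 3 ketone
#' bodies, 2 fluid-balance measures, 1 inflammation measure), optionally
#' together with lipoprotein-subclass features, which the feature filter
#' [select_metabolomic_features()] removes to minimise redundancy.
#'
#' @param include_subclasses include 14 lipoprotein-subclass features.
#' @return data frame: analyte, family, category, baseline_level,
#'   below_lod_target.
#' @export
metabolomic_catalogue <- function(include_subclasses = TRUE) {
  feats <- list(
    cholesterol = c("Total_C", "non_HDL_C", "Remnant_C", "VLDL_C",
                    "Clinical_LDL_C", "LDL_C", "HDL_C", "Esterified_C",
                    "Free_C"),
    `apolipoproteins/lipids` = c("ApoA1", "ApoB", "ApoB_by_ApoA1", "Total_TG",
                                 "VLDL_TG", "LDL_TG", "HDL_TG",
                                 "Phosphoglycerides", "Total_Cholines",
                                 "Phosphatidylcholines", "Sphingomyelins",
                                 "Total_Lipids"),
    particle_size = c("VLDL_size", "LDL_size", "HDL_size"),
    fatty_acids = c("Total_FA", "Unsaturation", "Omega3", "Omega6", "PUFA",
                    "MUFA", "SFA", "LA", "DHA", "Omega3_by_FA", "Omega6_by_FA",
                    "PUFA_by_FA", "MUFA_by_FA", "SFA_by_FA", "LA_by_FA",
                    "DHA_by_FA"),
    glycolysis = c("Glucose", "Lactate", "Citrate"),
    amino_acids = c("Ala", "Gln", "Gly", "His", "Ile", "Leu", "Val", "Phe"),
    ketone_bodies = c("Acetate", "Acetoacetate", "bOHbutyrate"),
    fluid_balance = c("Albumin", "Creatinine"),
    inflammation = "GlycA")
  cat_df <- data.frame(analyte = unlist(feats, use.names = FALSE),
                       category = rep(names(feats), lengths(feats)),
                       stringsAsFactors = FALSE)
  if (include_subclasses) {
    sub <- c("XXL_VLDL_L", "XL_VLDL_L", "L_VLDL_L", "M_VLDL_L", "S_VLDL_L",
             "XS_VLDL_L", "IDL_L", "L_LDL_L", "M_LDL_L", "S_LDL_L",
             "XL_HDL_L", "L_HDL_L", "M_HDL_L", "S_HDL_L")
    cat_df <- rbind(cat_df, data.frame(analyte = sub,
                                       category = "lipoprotein_subclass",
                                       stringsAsFactors = FALSE))
  }
  data.frame(analyte = cat_df$analyte,
             family = "metabolomic",
             category = cat_df$category,
             baseline_level = 0,
             below_lod_target = 0,
             stringsAsFactors = FALSE)
}

#' Synthetic blood count and clinical chemistry catalogue
#'
#' 26 routine haematology and biochemistry measures plus the two derived
#' indices (AST/ALT ratio and HOMA-IR), analysed on the natural-log scale so
#' exponentiated effects read as percentage differences.
#'
#' @return data frame: analyte, family, category, baseline_level,
#'   below_lod_target.
#' @export
blood_chemistry_catalogue <- function() {
  haem <- c("WBC", "RBC", "Hb", "Hct", "MCV", "MCH", "MCHC", "Platelets",
            "Neutrophils", "Lymphocytes", "Monocytes", "Eosinophils",
            "Basophils")
  chem <- c("CRP", "Glucose", "Insulin", "Total_cholesterol", "HDL_chol",
            "LDL_chol", "VLDL_chol", "Triglycerides", "GGT", "ALT", "AST",
            "P3NP", "Urea")
  derived <- c("AST_ALT_ratio", "HOMA_IR")
  data.frame(analyte = c(haem, chem, derived),
             family = "blood_count_chemistry",
             category = c(rep("haematology", length(haem)),
                          rep("biochemistry", length(chem)),
                          rep("derived_index", length(derived))),
             baseline_level = 1,
             below_lod_target = 0,
             stringsAsFactors = FALSE)
}
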