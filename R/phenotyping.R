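#' Fatty liver index (FLI)
#'
#' Logistic-scale steatosis score in \[0, 100\] from triglycerides, BMI,
#' gamma-glutamyl transferase and waist circumference (Bedogni et al. 2006):
#' linear predictor
#' `0.953 ln(TG mg/dL) + 0.139 BMI + 0.718 ln(GGT) + 0.053 waist - 15.745`,
#' logistic-transformed and scaled by 100. FLI >= 60 proxies hepatic
#' steatosis (87% sensitivity / 86% specificity in the source cohort).
#'
#' Canonical triglyceride unit here is mmol/L (as in the metabolic criteria);
#' the conversion to the mg/dL used inside the formula (x 88.57) is internal.
#'
#' @param triglycerides serum triglycerides; unit per `tg_unit`.
#' @param bmi body-mass index, kg/m^2.
#' @param ggt gamma-glutamyl transferase, U/L.
#' @param waist waist circumference, cm.
#' @param tg_unit `"mmol/L"` (default) or `"mg/dL"`.
#' @return numeric vector of FLI scores in \[0, 100\].
#' @export
compute_fli <- function(triglycerides, bmi, ggt, waist, tg_unit = c("mmol/L", "mg/dL")) {
  tg_unit <- match.arg(tg_unit)
  for (nm in c("triglycerides", "ggt")) {
    v <- get(nm)
    if (any(!is.na(v) & v <= 0)) {
      stop(sprintf("compute_fli: '%s' must be strictly positive (log transform)", nm),
           call. = FALSE)
    }
  }
  if (any(!is.na(bmi) & bmi <= 0) || any(!is.na(waist) & waist <= 0)) {
    stop("compute_fli: 'bmi' and 'waist' must be positive", call. = FALSE)
  }
  tg_mgdl <- if (tg_unit == "mmol/L") triglycerides * 88.57 else triglycerides
  lp <- 0.953 * log(tg_mgdl) + 0.139 * bmi + 0.718 * log(ggt) +
    0.053 * waist - 15.745
  100 * plogis(lp)
}

#' NAFLD fibrosis score (NFS)
#'
#' Linear score for advanced liver fibrosis:
#' `-1.675 + 0.037 age + 0.094 BMI + 1.13 T2D + 0.99 AST/ALT
#'  - 0.013 platelets - 0.66 albumin`
#' with age in years, BMI in kg/m^2, platelets in 10^9/L and albumin in g/dL.
#'
#' @param age years.
#' @param bmi kg/m^2.
#' @param t2d type-2 diabetes indicator (0/1 or logical).
#' @param ast,alt aminotransferases, U/L; `alt` must be strictly positive.
#' @param platelets platelet count, 10^9/L.
#' @param albumin g/dL.
#' @return numeric NFS values.
#' @export
compute_nfs <- function(age, bmi, t2d, ast, alt, platelets, albumin) {
  if (any(!is.na(alt) & alt <= 0)) {
    stop("compute_nfs: 'alt' must be strictly positive (AST/ALT ratio)", call. = FALSE)
  }
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(t2d) +
    0.99 * (ast / alt) - 0.013 * platelets - 0.66 * albumin
}

#' Advanced-fibrosis flag from NFS
#'
#' The published cutoff is -1.455 (negative predictive value 93%). The
#' boundary is exclusive by default: a score exactly at the cutoff is not
#' flagged; set `inclusive = TRUE` for `>=`.
#'
#' @param nfs NFS values.
#' @param cutoff decision threshold (default -1.455).
#' @param inclusive whether the boundary itself flags.
#' @export
flag_advanced_fibrosis <- function(nfs, cutoff = -1.455, inclusive = FALSE) {
  if (inclusive) nfs >= cutoff else nfs > cutoff
}

#' MAFLD classification
#'
#' MAFLD = hepatic steatosis plus one of: type-2 diabetes; overweight/obesity
#' (BMI >= 25 kg/m^2); or at least two metabolic abnormalities among
#' prediabetes (fasting glucose >= 100 mg/dL or HbA1c >= 5.7%), low HDL
#' (< 1.03 mmol/L males / < 1.29 females), hypertriglyceridemia
#' (TG >= 1.7 mmol/L), hypertension (>= 130/85 mmHg or antihypertensive
#' medication), and increased waist circumference (>= 102 cm males / >= 88
#' females). Insulin resistance is not evaluable without serum insulin and is
#' omitted, leaving six usable criteria of which two are required.
#'
#' Missing fields make the result `NA` ("undetermined") only when the
#' decision actually depends on them; participants with undetermined status
#' are meant to be excluded upstream.
#'
#' @param steatosis logical, hepatic steatosis (e.g. FLI >= 60).
#' @param t2d logical/0-1, type-2 diabetes.
#' @param bmi kg/m^2.
#' @param glucose fasting glucose, mg/dL.
#' @param hba1c HbA1c, percent.
#' @param hdl HDL cholesterol, mmol/L.
#' @param triglycerides mmol/L.
#' @param sbp,dbp blood pressure, mmHg.
#' @param bp_med antihypertensive medication flag.
#' @param waist cm.
#' @param sex `"male"`/`"female"` (or `1`/`0`).
#' @return logical vector (TRUE / FALSE / NA-undetermined).
#' @export
classify_mafld <- function(steatosis, t2d, bmi, glucose, hba1c, hdl,
                           triglycerides, sbp, dbp, bp_med, waist, sex) {
  male <- is_male(sex)
  t2d <- as.logical(t2d)
  # three-valued logic: pmax/pmin-style OR/AND keeping NA only when decisive
  or3 <- function(a, b) ifelse(!is.na(a) & a, TRUE,
                        ifelse(!is.na(b) & b, TRUE,
                        ifelse(is.na(a) | is.na(b), NA, FALSE)))
  prediab <- or3(glucose >= 100, hba1c >= 5.7)
  low_hdl <- ifelse(male, hdl < 1.03, hdl < 1.29)
  high_tg <- triglycerides >= 1.7
  htn <- or3(or3(sbp >= 130, dbp >= 85), as.logical(bp_med))
  big_waist <- ifelse(male, waist >= 102, waist >= 88)
  abn <- cbind(prediab, low_hdl, high_tg, htn, big_waist)
  n_known <- rowSums(abn, na.rm = TRUE)
  n_na <- rowSums(is.na(abn))
  two_plus <- ifelse(n_known >= 2, TRUE, ifelse(n_known + n_na >= 2, NA, FALSE))
  overweight <- bmi >= 25
  crit <- or3(or3(t2d, overweight), two_plus)
  ifelse(!is.na(steatosis) & !steatosis, FALSE,
         ifelse(is.na(steatosis), NA,
                crit))
}

is_male <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    s <- tolower(as.character(sex))
    ifelse(s %in% c("male", "m", "1"), TRUE,
           ifelse(s %in% c("female", "f", "0"), FALSE, NA))
  } else {
    as.numeric(sex) == 1
  }
}

#' Polygenic risk score for MAFLD
#'
#' Weighted allele-dosage score over the four MAFLD risk variants
#' (MBOAT7 rs641738, GCKR rs1260326, TM6SF2 rs58542926, PNPLA3 rs738409),
#' normalized so the attainable range is \[0, 2 x nSNPs\] regardless of the
#' weights: `(sum beta_i x dosage_i) x (nSNPs / sum beta_i)`. With four SNPs
#' the score runs 0 to 8.
#'
#' @param dosages matrix (participants x SNPs) of risk-allele dosages in
#'   \{0, 1, 2\}.
#' @param betas positive per-SNP weights from the source GWAS.
#' @return numeric score vector.
#' @export
compute_prs <- function(dosages, betas) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(betas)) {
    stop("compute_prs: one beta per SNP column required", call. = FALSE)
  }
  if (any(betas <= 0)) stop("compute_prs: betas must be positive", call. = FALSE)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("compute_prs: dosages must be 0, 1 or 2", call. = FALSE)
  as.numeric(dosages %*% betas) * (length(betas) / sum(betas))
}

#' Genetic-risk tertile from the PRS
#'
#' Default fixed cutoffs are those of the source cohort: low < 0.76,
#' intermediate 0.76-2.35, high > 2.35. `method = "empirical"` instead
#' splits at the cohort's own tertile boundaries, for synthetic cohorts
#' whose PRS distribution differs.
#'
#' @param prs score vector.
#' @param method `"fixed"` or `"empirical"`.
#' @param cutoffs length-2 boundaries for the fixed method.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
prs_tertile <- function(prs, method = c("fixed", "empirical"),
                        cutoffs = c(0.76, 2.35)) {
  method <- match.arg(method)
  if (method == "empirical") {
    cutoffs <- stats::quantile(prs, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
  }
  # low < c1; intermediate c1..c2 inclusive; high > c2
  factor(ifelse(prs < cutoffs[1], "low",
         ifelse(prs <= cutoffs[2], "intermediate", "high")),
         levels = c("low", "intermediate", "high"))
}

#' Subgroup flags (overweight, heavy drinker)
#'
#' Overweight/obese is BMI >= 25 kg/m^2 (inclusive). Excessive daily alcohol
#' is sex-specific: >= 20 g/day for women, >= 30 g/day for men.
#'
#' @param bmi kg/m^2.
#' @param alcohol g/day.
#' @param sex see [classify_mafld()].
#' @return data.frame with logical `overweight` and `heavy_drinker`.
#' @export
subgroup_flags <- function(bmi, alcohol, sex) {
  male <- is_male(sex)
  data.frame(overweight = bmi >= 25,
             heavy_drinker = ifelse(male, alcohol >= 30, alcohol >= 20))
}

#' Phenotype a participant table
#'
#' Computes every derived phenotype column (FLI, steatosis, NFS, advanced
#' fibrosis, MAFLD, PRS, genetic tertile, subgroup flags) from a participant
#' table in the canonical dialect written by [simulate_cohort()].
#'
#' @param participants participant table (see package README for columns).
#' @param snp_cols names of the four dosage columns.
#' @param snp_betas positive weights, one per SNP column.
#' @param fli_cutoff steatosis threshold on the FLI (default 60).
#' @param nfs_cutoff advanced-fibrosis threshold (default -1.455).
#' @param tertile_method passed to [prs_tertile()].
#' @return data.table: `participant_id` plus all phenotype columns.
#' @export
phenotype_cohort <- function(participants,
                             snp_cols = c("snp_mboat7", "snp_gckr",
                                          "snp_tm6sf2", "snp_pnpla3"),
                             snp_betas = c(0.17, 0.21, 0.36, 0.46),
                             fli_cutoff = 60, nfs_cutoff = -1.455,
                             tertile_method = "fixed") {
  p <- participants
  assert_cols(p, c("participant_id", "age", "sex", "bmi", "waist", "tg", "hdl",
                   "ggt", "ast", "alt", "platelets", "albumin", "glucose",
                   "hba1c", "sbp", "dbp", "bp_med", "t2d", "alcohol"),
              "participant table")
  fli <- compute_fli(p$tg, p$bmi, p$ggt, p$waist)
  steat <- fli >= fli_cutoff
  nfs <- compute_nfs(p$age, p$bmi, p$t2d, p$ast, p$alt, p$platelets, p$albumin)
  mafld <- classify_mafld(steat, p$t2d, p$bmi, p$glucose, p$hba1c, p$hdl,
                          p$tg, p$sbp, p$dbp, p$bp_med, p$waist, p$sex)
  sub <- subgroup_flags(p$bmi, p$alcohol, p$sex)
  out <- data.table::data.table(
    participant_id = as.character(p$participant_id),
    fli = fli, steatosis = steat, nfs = nfs,
    advanced_fibrosis = flag_advanced_fibrosis(nfs, nfs_cutoff),
    mafld = mafld,
    overweight = sub$overweight, heavy_drinker = sub$heavy_drinker)
  if (all(snp_cols %in% names(p))) {
    prs <- compute_prs(as.matrix(as.data.frame(p)[, snp_cols]), snp_betas)
    out$prs <- prs
    out$genetic_tertile <- prs_tertile(prs, method = tertile_method)
  }
  out
}
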