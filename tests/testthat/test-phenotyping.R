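test_that("FLI matches direct evaluation of the published formula", {
  # frozen from independent hand evaluation:
  # 0.953 ln 150 + 0.139*30 + 0.718 ln 50 + 0.053*100 - 15.745 = 1.308968
  expect_equal(compute_fli(150, 30, 50, 100, tg_unit = "mg/dL"),
               78.734040585390, tolerance = 1e-9)
  # logistic midpoint: TG solved so the linear predictor is exactly 0
  tg_mid <- exp((15.745 - 0.139 * 30 - 0.718 * log(50) - 0.053 * 100) / 0.953)
  expect_equal(compute_fli(tg_mid, 30, 50, 100, tg_unit = "mg/dL"), 50,
               tolerance = 1e-9)
  # mmol/L canonical unit converts through x 88.57
  expect_equal(compute_fli(150 / 88.57, 30, 50, 100),
               compute_fli(150, 30, 50, 100, tg_unit = "mg/dL"))
})

test_that("FLI is bounded and strictly monotone in each input", {
  set.seed(1)
  base <- list(tg = runif(50, 0.4, 5), bmi = runif(50, 18, 45),
               ggt = runif(50, 8, 200), waist = runif(50, 60, 140))
  f0 <- compute_fli(base$tg, base$bmi, base$ggt, base$waist)
  expect_true(all(f0 > 0 & f0 < 100))
  expect_true(all(compute_fli(base$tg * 1.1, base$bmi, base$ggt, base$waist) > f0))
  expect_true(all(compute_fli(base$tg, base$bmi + 1, base$ggt, base$waist) > f0))
  expect_true(all(compute_fli(base$tg, base$bmi, base$ggt * 1.1, base$waist) > f0))
  expect_true(all(compute_fli(base$tg, base$bmi, base$ggt, base$waist + 1) > f0))
  expect_error(compute_fli(0, 30, 50, 100), "triglycerides")
  expect_error(compute_fli(1.5, 30, -1, 100), "ggt")
})

test_that("NFS evaluates the printed formula and flags above -1.455", {
  # worked input: hand evaluation gives exactly -0.405
  nfs <- compute_nfs(age = 60, bmi = 30, t2d = 1, ast = 25, alt = 25,
                     platelets = 250, albumin = 4.0)
  expect_equal(nfs, -0.405, tolerance = 1e-9)
  expect_true(flag_advanced_fibrosis(nfs))
  # intercept-only case
  expect_equal(compute_nfs(0, 0, 0, 0, 1, 0, 0), -1.675, tolerance = 1e-12)
  expect_false(flag_advanced_fibrosis(-1.675))
  # boundary is exclusive by default, configurable
  expect_false(flag_advanced_fibrosis(-1.455))
  expect_true(flag_advanced_fibrosis(-1.455, inclusive = TRUE))
  expect_error(compute_nfs(60, 30, 1, 25, 0, 250, 4), "alt")
})

test_that("MAFLD classification implements the consensus criteria", {
  cm <- function(...) classify_mafld(...)
  # steatosis + overweight alone suffices
  expect_true(cm(TRUE, t2d = FALSE, bmi = 27, glucose = 90, hba1c = 5.0,
                 hdl = 1.5, triglycerides = 1.0, sbp = 120, dbp = 70,
                 bp_med = FALSE, waist = 80, sex = "male"))
  # no steatosis: never MAFLD, however many abnormalities
  expect_false(cm(FALSE, t2d = TRUE, bmi = 35, glucose = 150, hba1c = 7,
                  hdl = 0.5, triglycerides = 3, sbp = 160, dbp = 100,
                  bp_med = TRUE, waist = 120, sex = "male"))
  # lean steatosis with two abnormalities (TG 1.8, SBP 135)
  expect_true(cm(TRUE, t2d = FALSE, bmi = 23, glucose = 90, hba1c = 5.0,
                 hdl = 1.5, triglycerides = 1.8, sbp = 135, dbp = 70,
                 bp_med = FALSE, waist = 80, sex = "male"))
  # one abnormality only: not MAFLD
  expect_false(cm(TRUE, t2d = FALSE, bmi = 23, glucose = 90, hba1c = 5.0,
                  hdl = 1.5, triglycerides = 1.8, sbp = 120, dbp = 70,
                  bp_med = FALSE, waist = 80, sex = "male"))
  # sex-specific HDL and waist cutoffs
  expect_true(cm(TRUE, FALSE, 23, 90, 5.0, hdl = 1.2, triglycerides = 1.8,
                 sbp = 120, dbp = 70, bp_med = FALSE, waist = 80,
                 sex = "female"))  # HDL < 1.29 (F) + TG
  expect_false(cm(TRUE, FALSE, 23, 90, 5.0, hdl = 1.2, triglycerides = 1.8,
                  sbp = 120, dbp = 70, bp_med = FALSE, waist = 80,
                  sex = "male"))  # HDL 1.2 normal for males: only TG
  # undetermined when a decisive field is missing
  expect_true(is.na(cm(TRUE, t2d = NA, bmi = NA, glucose = 90, hba1c = 5.0,
                       hdl = 1.5, triglycerides = 1.0, sbp = 120, dbp = 70,
                       bp_med = FALSE, waist = 80, sex = "male")))
})

test_that("MAFLD classification is monotone in metabolic abnormalities", {
  set.seed(7)
  for (i in 1:50) {
    panel <- list(steatosis = TRUE, t2d = runif(1) < 0.2,
                  bmi = runif(1, 19, 35), glucose = runif(1, 80, 130),
                  hba1c = runif(1, 5, 7), hdl = runif(1, 0.8, 2),
                  triglycerides = runif(1, 0.8, 3), sbp = runif(1, 110, 160),
                  dbp = runif(1, 65, 100), bp_med = runif(1) < 0.2,
                  waist = runif(1, 70, 120), sex = sample(c("male", "female"), 1))
    before <- do.call(classify_mafld, panel)
    panel$triglycerides <- 2.5  # add an abnormality
    panel$sbp <- 150
    after <- do.call(classify_mafld, panel)
    if (isTRUE(before)) expect_true(after)
  }
})

test_that("PRS normalization spans 0 to 2 x nSNPs for any positive weights", {
  betas <- c(0.17, 0.21, 0.36, 0.46)
  expect_equal(compute_prs(matrix(0, 1, 4), betas), 0)
  expect_equal(compute_prs(matrix(2, 1, 4), betas), 8)
  # equal weights: score reduces to the dosage sum
  expect_equal(compute_prs(matrix(c(2, 1, 0, 1), 1), rep(0.3, 4)), 4)
  expect_error(compute_prs(matrix(c(3, 0, 0, 0), 1), betas), "dosages")
  expect_error(compute_prs(matrix(0, 1, 4), c(0.1, -0.2, 0.3, 0.4)), "positive")
})

test_that("PRS tertile boundaries follow the study convention", {
  t <- prs_tertile(c(0.5, 0.76, 2.35, 2.36, 0.75))
  expect_equal(as.character(t),
               c("low", "intermediate", "intermediate", "high", "low"))
  # empirical mode splits a uniform sample roughly into thirds
  set.seed(3)
  te <- prs_tertile(runif(3000, 0, 8), method = "empirical")
  expect_true(all(abs(table(te) / 3000 - 1 / 3) < 0.02))
})

test_that("subgroup flags use the sex-specific alcohol and BMI cutoffs", {
  f <- subgroup_flags(bmi = c(25, 24.9, 30), alcohol = c(25, 25, 31),
                      sex = c("female", "male", "male"))
  expect_equal(f$overweight, c(TRUE, FALSE, TRUE))  # BMI 25 inclusive
  expect_equal(f$heavy_drinker, c(TRUE, FALSE, TRUE))  # 20 g F / 30 g M
})
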