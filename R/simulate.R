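#' Default simulated disease catalog
#'
#' Combined disease categories (codes are keys of the bundled mapping) with
#' baseline annual first-diagnosis hazards chosen to mimic common-condition
#' incidence in a middle-aged cohort over ~13 years of follow-up.
#' @export
default_disease_catalog <- function() {
  data.table::data.table(
    code = c("E11", "I10", "I20", "I21", "I25", "I48", "I50", "J18", "J44",
             "J45", "J96", "K29", "K57", "K76", "K80", "N17", "N18", "C18",
             "C50", "D50", "F32", "G47", "M10", "A41", "A09", "E87"),
    rate = c(0.010, 0.012, 0.004, 0.004, 0.006, 0.005, 0.004, 0.006, 0.004,
             0.005, 0.002, 0.005, 0.008, 0.003, 0.005, 0.003, 0.004, 0.002,
             0.002, 0.004, 0.006, 0.003, 0.003, 0.002, 0.003, 0.003))
}

#' Simulation configuration
#'
#' Declares the synthetic world: cohort size, follow-up, the latent
#' steatosis process driving the fatty-liver biomarkers, per-SNP risk-allele
#' frequencies and weights, a disease catalog with baseline annual hazards,
#' planted multiplicative exposure effects, directed pair amplification
#' (psi >= 1, multiplying D2's hazard once D1 has occurred, effective from
#' the day after D1), and cause-specific death hazards with
#' disease-conditional multipliers. One master seed drives deterministic
#' per-stream child seeds.
#'
#' @param n_participants cohort size (0 allowed: empty tables).
#' @param seed master seed.
#' @param follow_up_years follow-up length, years.
#' @param steatosis_prevalence probability of the latent steatosis state;
#'   exactly the expected FLI >= 60 fraction by construction.
#' @param disease_catalog data.frame `code`, `rate` (annual hazard >= 0).
#' @param exposure_hr named per-category hazard ratios for MAFLD-exposed
#'   participants (unnamed categories default to 1).
#' @param pair_amplification data.frame `d1`, `d2`, `psi` (psi >= 1).
#' @param death_causes data.frame `code` (ICD-10 cause code), `rate`
#'   (annual).
#' @param death_multipliers data.frame `disease`, `cause`, `mult`:
#'   multiplier on a cause-specific death hazard after the disease occurs.
#' @param allele_freqs,snp_betas per-SNP risk-allele frequencies in \[0, 1\]
#'   and positive weights (MBOAT7, GCKR, TM6SF2, PNPLA3).
#' @param prs_hr named per-category hazard ratios expressing genetic risk:
#'   the category hazard is multiplied by `hr^(prs / 8)`.
#' @param p_male male fraction.
#' @param study_start first possible assessment date (ISO-8601).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants, seed = 1L, follow_up_years = 12.9,
                       steatosis_prevalence = 0.5,
                       disease_catalog = default_disease_catalog(),
                       exposure_hr = c(E11 = 4.2, G47 = 3.7, F32 = 1.6,
                                       I21 = 1.55, J96 = 1.6, K57 = 1.4,
                                       D50 = 1.38, C18 = 1.27, A41 = 1.5,
                                       K76 = 2.1),
                       pair_amplification = data.frame(
                         d1 = c("I25", "E11", "I21"),
                         d2 = c("I21", "N18", "I50"),
                         psi = c(3, 2.5, 3)),
                       death_causes = data.frame(
                         code = c("I21", "C50", "J44", "K70", "A41"),
                         rate = c(0.0015, 0.0012, 0.0008, 0.0004, 0.0006)),
                       death_multipliers = data.frame(
                         disease = c("I50", "N17"),
                         cause = c("I21", "I21"),
                         mult = c(3, 2)),
                       allele_freqs = c(0.44, 0.39, 0.07, 0.22),
                       snp_betas = c(0.17, 0.21, 0.36, 0.46),
                       prs_hr = numeric(),
                       p_male = 0.5,
                       study_start = "2006-01-01") {
  stopifnot(n_participants >= 0, follow_up_years > 0,
            steatosis_prevalence >= 0, steatosis_prevalence <= 1,
            p_male >= 0, p_male <= 1)
  if (any(disease_catalog$rate < 0)) {
    stop("sim_config: negative baseline hazard rejected", call. = FALSE)
  }
  if (any(exposure_hr <= 0)) {
    stop("sim_config: exposure hazard ratios must be strictly positive",
         call. = FALSE)
  }
  if (nrow(as.data.frame(pair_amplification))) {
    pa <- as.data.frame(pair_amplification)
    if (any(pa$psi < 1)) stop("sim_config: pair psi must be >= 1", call. = FALSE)
    if (any(pa$d1 == pa$d2)) stop("sim_config: pair with d1 == d2", call. = FALSE)
    if (!all(c(pa$d1, pa$d2) %in% disease_catalog$code)) {
      stop("sim_config: pair endpoints must be catalog categories", call. = FALSE)
    }
  }
  if (any(as.data.frame(death_causes)$rate < 0)) {
    stop("sim_config: negative death hazard rejected", call. = FALSE)
  }
  if (nrow(as.data.frame(death_multipliers)) &&
      any(as.data.frame(death_multipliers)$mult <= 0)) {
    stop("sim_config: death multipliers must be strictly positive", call. = FALSE)
  }
  stopifnot(all(allele_freqs >= 0 & allele_freqs <= 1),
            all(snp_betas > 0), length(allele_freqs) == length(snp_betas))
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    follow_up_years = follow_up_years,
    steatosis_prevalence = steatosis_prevalence,
    disease_catalog = data.table::as.data.table(disease_catalog),
    exposure_hr = exposure_hr,
    pair_amplification = data.table::as.data.table(as.data.frame(pair_amplification)),
    death_causes = data.table::as.data.table(as.data.frame(death_causes)),
    death_multipliers = data.table::as.data.table(as.data.frame(death_multipliers)),
    allele_freqs = allele_freqs, snp_betas = snp_betas, prs_hr = prs_hr,
    p_male = p_male, study_start = as.Date(study_start)),
    class = "sim_config")
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

#' Simulate the participant table
#'
#' Biomarkers are tied together by a latent steatosis state S ~
#' Bernoulli(steatosis_prevalence): the FLI linear predictor is drawn on the
#' correct side of the FLI = 60 boundary given S, then decomposed exactly
#' into BMI, waist, GGT and triglycerides, so the emitted biomarkers
#' reproduce the intended steatosis status and the FLI >= 60 fraction equals
#' the prevalence knob up to binomial noise. Remaining biomarkers are drawn
#' from realistic sex- and S-conditional distributions; genotypes are
#' per-SNP Binomial(2, allele frequency).
#'
#' @param config a [sim_config()].
#' @return data.table participant table (one row per participant).
#' @export
simulate_biomarkers <- function(config) {
  n <- config$n_participants
  cols <- c("participant_id", "age", "sex", "townsend", "bmi", "waist", "tg",
            "hdl", "ggt", "ast", "alt", "platelets", "albumin", "glucose",
            "hba1c", "sbp", "dbp", "bp_med", "t2d", "alcohol",
            "snp_mboat7", "snp_gckr", "snp_tm6sf2", "snp_pnpla3",
            "assessment_date", "censor_date", "latent_steatosis")
  if (n == 0L) {
    out <- data.table::as.data.table(
      setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  set.seed(child_seed(config$seed, "biomarkers"))
  s <- runif(n) < config$steatosis_prevalence
  sex <- ifelse(runif(n) < config$p_male, "male", "female")
  age <- sample(40:69, n, replace = TRUE)
  townsend <- rnorm(n, -1.5, 2.8)
  bmi <- clamp(rnorm(n, ifelse(s, 31, 25), ifelse(s, 3.2, 3.0)), 17, 55)
  waist <- clamp(ifelse(sex == "male", 84, 78) + 2.2 * (bmi - 25) + rnorm(n, 0, 5),
                 55, 160)
  # FLI linear predictor: strictly >= logit(0.6) under steatosis, < otherwise
  thr <- qlogis(0.6)
  lp <- ifelse(s, thr + rexp(n, 1 / 1.2), thr - 0.02 - rexp(n, 1 / 1.5))
  ggt <- clamp(exp(rnorm(n, log(30 + 15 * s), 0.4)), 5, 400)
  ln_tg_mgdl <- (lp + 15.745 - 0.139 * bmi - 0.718 * log(ggt) - 0.053 * waist) / 0.953
  tg <- exp(ln_tg_mgdl) / 88.57
  hdl <- exp(rnorm(n, log(ifelse(sex == "male", 1.25, 1.55)) - 0.1 * s, 0.18))
  glucose <- clamp(rnorm(n, 95 + 8 * s, 12), 55, 350)
  hba1c <- clamp(rnorm(n, 5.5 + 0.2 * s, 0.45), 3.5, 15)
  sbp <- clamp(rnorm(n, 133 + 3 * s, 15), 80, 230)
  dbp <- clamp(rnorm(n, 80 + 1 * s, 10), 45, 140)
  bp_med <- runif(n) < (0.12 + 0.08 * s)
  t2d <- runif(n) < plogis(-3.2 + 1.3 * s + 0.05 * (bmi - 25))
  ast <- clamp(exp(rnorm(n, log(26), 0.30)), 5, 400)
  alt <- clamp(exp(rnorm(n, log(28 + 6 * s), 0.35)), 5, 400)
  platelets <- clamp(rnorm(n, 252, 60), 50, 600)
  albumin <- clamp(rnorm(n, 4.47, 0.28), 2.5, 6)
  alcohol <- rgamma(n, shape = 1.2, scale = 12)
  geno <- vapply(config$allele_freqs,
                 function(af) rbinom(n, 2L, af), integer(n))
  if (n == 1L) geno <- matrix(geno, nrow = 1L)
  assessment <- config$study_start + floor(runif(n, 0, 1461))
  censor <- assessment + round(config$follow_up_years * 365.25)
  data.table::data.table(
    participant_id = sprintf("P%06d", seq_len(n)),
    age = age, sex = sex, townsend = townsend, bmi = bmi, waist = waist,
    tg = tg, hdl = hdl, ggt = ggt, ast = ast, alt = alt,
    platelets = platelets, albumin = albumin, glucose = glucose,
    hba1c = hba1c, sbp = sbp, dbp = dbp, bp_med = bp_med, t2d = t2d,
    alcohol = alcohol,
    snp_mboat7 = geno[, 1], snp_gckr = geno[, 2],
    snp_tm6sf2 = geno[, 3], snp_pnpla3 = geno[, 4],
    assessment_date = assessment, censor_date = censor,
    latent_steatosis = s)
}

#' Simulate a full synthetic cohort
#'
#' Draws the participant table ([simulate_biomarkers()]), derives the
#' exposure truth (MAFLD status computed from the emitted biomarkers), then
#' simulates diagnosis and death events as competing piecewise-exponential
#' processes: the hazard of category D at time t is
#' `baseline(D) x exposure_hr(D)^exposed x prod(psi(D1, D))` over categories
#' D1 already diagnosed, with genetic modifiers `prs_hr(D)^(PRS/8)` when
#' configured. Death (cause-specific competing hazards, disease-conditional
#' multipliers) truncates further diagnoses. Dates are emitted as ISO
#' calendar dates; an amplified event never shares its amplifier's day, so
#' planted directions are strictly ordered. Diagnoses are emitted as
#' four-character ICD-10 child codes of the category (exercising the
#' three-character truncation downstream). Fixed seed implies byte-identical
#' tables.
#'
#' @param config a [sim_config()].
#' @return list with `participants`, `diagnoses`
#'   (`participant_id`, `icd10_code`, `date`), `deaths` (`participant_id`,
#'   `date`, `cause_codes` semicolon-joined), and `truth` (class
#'   `ground_truth`: `exposed_flags`, `planted_hr`, `planted_pairs`,
#'   `prs`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  participants <- simulate_biomarkers(config)
  n <- nrow(participants)
  empty_diag <- data.table::data.table(participant_id = character(),
                                       icd10_code = character(),
                                       date = as.Date(character()))
  empty_death <- data.table::data.table(participant_id = character(),
                                        date = as.Date(character()),
                                        cause_codes = character())
  prs <- compute_prs(as.matrix(participants[, c("snp_mboat7", "snp_gckr",
                                                "snp_tm6sf2", "snp_pnpla3"),
                                            with = FALSE]),
                     config$snp_betas)
  exposed <- if (n) {
    m <- classify_mafld(
      steatosis = compute_fli(participants$tg, participants$bmi,
                              participants$ggt, participants$waist) >= 60,
      t2d = participants$t2d, bmi = participants$bmi,
      glucose = participants$glucose, hba1c = participants$hba1c,
      hdl = participants$hdl, triglycerides = participants$tg,
      sbp = participants$sbp, dbp = participants$dbp,
      bp_med = participants$bp_med, waist = participants$waist,
      sex = participants$sex)
    !is.na(m) & m
  } else logical(0)
  truth <- structure(list(
    exposed_flags = setNames(exposed, participants$participant_id),
    planted_hr = config$exposure_hr,
    planted_pairs = config$pair_amplification,
    prs = setNames(prs, participants$participant_id)), class = "ground_truth")
  if (n == 0L) {
    return(list(participants = participants, diagnoses = empty_diag,
                deaths = empty_death, truth = truth))
  }

  cat_codes <- config$disease_catalog$code
  K <- length(cat_codes)
  causes <- config$death_causes$code
  C <- length(causes)
  day_rate <- function(annual) annual / 365.25
  # n x K disease rates per day (time-invariant baseline part)
  R <- matrix(rep(day_rate(config$disease_catalog$rate), each = n), n, K,
              dimnames = list(NULL, cat_codes))
  hr <- setNames(rep(1, K), cat_codes)
  hr[names(config$exposure_hr)[names(config$exposure_hr) %in% cat_codes]] <-
    config$exposure_hr[names(config$exposure_hr) %in% cat_codes]
  R <- R * vapply(seq_len(K), function(k) hr[k]^exposed, numeric(n))
  if (length(config$prs_hr)) {
    for (nm in intersect(names(config$prs_hr), cat_codes)) {
      R[, nm] <- R[, nm] * config$prs_hr[[nm]]^(prs / 8)
    }
  }
  Dth <- if (C) matrix(rep(day_rate(config$death_causes$rate), each = n), n, C,
                       dimnames = list(NULL, causes))
         else matrix(0, n, 0)

  horizon <- as.numeric(participants$censor_date - participants$assessment_date)
  had <- matrix(FALSE, n, K, dimnames = list(NULL, cat_codes))
  day_of <- matrix(NA_real_, n, K, dimnames = list(NULL, cat_codes))
  cur <- rep(0, n)
  alive <- rep(TRUE, n)
  active <- horizon > 0 & rowSums(cbind(R, Dth)) > 0
  pa <- as.data.frame(config$pair_amplification)
  dm <- as.data.frame(config$death_multipliers)
  diag_i <- integer(); diag_k <- integer(); diag_day <- numeric()
  death_i <- integer(); death_day <- numeric(); death_cause <- character()

  set.seed(child_seed(config$seed, "events"))
  # per round each active participant experiences at most one event, so all
  # state updates within a round are independent and vectorize
  while (any(active)) {
    idx <- which(active)
    m <- length(idx)
    rates <- cbind(R[idx, , drop = FALSE] * !had[idx, , drop = FALSE],
                   Dth[idx, , drop = FALSE])
    # competing exponentials: waiting times stream-by-stream, take the min
    # (a zero rate divides a positive exponential draw to Inf: never fires)
    draws <- matrix(rexp(m * ncol(rates)), m, ncol(rates)) / rates
    j <- max.col(-draws, ties.method = "first")
    dt <- draws[cbind(seq_len(m), j)]
    newt <- cur[idx] + dt
    done <- !is.finite(newt) | newt > horizon[idx]
    active[idx[done]] <- FALSE
    hit <- idx[!done]
    if (!length(hit)) next
    jh <- j[!done]
    cur[hit] <- newt[!done]

    is_diag <- jh <= K
    di <- hit[is_diag]; dk <- jh[is_diag]
    if (length(di)) {
      day <- floor(cur[di])
      # amplified events start strictly after their amplifier's day
      for (r in seq_len(nrow(pa))) {
        sel <- cat_codes[dk] == pa$d2[r] & had[cbind(di, match(pa$d1[r], cat_codes))]
        if (any(sel)) {
          a <- match(pa$d1[r], cat_codes)
          day[sel] <- pmax(day[sel], day_of[cbind(di[sel], rep(a, sum(sel)))] + 1)
        }
      }
      day <- pmin(day, horizon[di])  # never past the censor date
      had[cbind(di, dk)] <- TRUE
      day_of[cbind(di, dk)] <- day
      diag_i <- c(diag_i, di); diag_k <- c(diag_k, dk)
      diag_day <- c(diag_day, day)
      for (r in seq_len(nrow(pa))) {
        sel <- di[cat_codes[dk] == pa$d1[r]]
        if (length(sel)) {
          t <- match(pa$d2[r], cat_codes)
          R[cbind(sel, rep(t, length(sel)))] <-
            R[cbind(sel, rep(t, length(sel)))] * pa$psi[r]
        }
      }
      for (r in seq_len(nrow(dm))) {
        sel <- di[cat_codes[dk] == dm$disease[r]]
        if (length(sel)) {
          t <- match(dm$cause[r], causes)
          Dth[cbind(sel, rep(t, length(sel)))] <-
            Dth[cbind(sel, rep(t, length(sel)))] * dm$mult[r]
        }
      }
      exhausted <- di[rowSums((!had[di, , drop = FALSE]) *
                                R[di, , drop = FALSE]) == 0 &
                        rowSums(Dth[di, , drop = FALSE]) == 0]
      active[exhausted] <- FALSE
    }
    mi <- hit[!is_diag]; mc <- jh[!is_diag] - K
    if (length(mi)) {
      death_i <- c(death_i, mi)
      death_day <- c(death_day, floor(cur[mi]))
      death_cause <- c(death_cause, causes[mc])
      alive[mi] <- FALSE
      active[mi] <- FALSE
    }
  }
  diag_pid <- as.list(participants$participant_id[diag_i])
  diag_cat <- as.list(cat_codes[diag_k])
  diag_day <- as.list(diag_day)
  death_pid <- participants$participant_id[death_i]

  diagnoses <- if (length(diag_pid)) {
    dd <- data.table::data.table(
      participant_id = unlist(diag_pid),
      category = unlist(diag_cat),
      day = unlist(diag_day))
    # death truncates diagnoses recorded on a later day than death
    if (length(death_pid)) {
      dday <- setNames(death_day, death_pid)
      keep <- is.na(dday[dd$participant_id]) | dd$day <= dday[dd$participant_id]
      keep[is.na(keep)] <- TRUE
      dd <- dd[which(unname(keep))]
    }
    sub <- sample(0:9, nrow(dd), replace = TRUE)  # 4th character of the code
    assess <- participants$assessment_date[
      match(dd$participant_id, participants$participant_id)]
    out <- data.table::data.table(
      participant_id = dd$participant_id,
      icd10_code = paste0(dd$category, sub),
      date = assess + dd$day)
    data.table::setorderv(out, c("participant_id", "icd10_code"))[]
  } else empty_diag

  deaths <- if (length(death_pid)) {
    assess <- participants$assessment_date[
      match(death_pid, participants$participant_id)]
    secondary <- vapply(seq_along(death_pid), function(v) {
      i <- match(death_pid[v], participants$participant_id)
      prior <- cat_codes[had[i, ]]
      if (length(prior) && runif(1) < 0.3) sample(prior, 1) else NA_character_
    }, character(1))
    out <- data.table::data.table(
      participant_id = death_pid,
      date = assess + death_day,
      cause_codes = ifelse(is.na(secondary), death_cause,
                           paste(death_cause, secondary, sep = ";")))
    data.table::setorderv(out, "participant_id")[]
  } else empty_death

  list(participants = participants, diagnoses = diagnoses, deaths = deaths,
       truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the exact dialects consumed by the pipeline: `participants.csv`,
#' `diagnoses.csv`, `deaths.csv`, `ground_truth.json`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory.
#' @return invisible vector of files written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- file.path(dir, "participants.csv")
  fd <- file.path(dir, "diagnoses.csv")
  fm <- file.path(dir, "deaths.csv")
  fg <- file.path(dir, "ground_truth.json")
  data.table::fwrite(sim$participants, fp, eol = "\n")
  data.table::fwrite(sim$diagnoses, fd, eol = "\n")
  data.table::fwrite(sim$deaths, fm, eol = "\n")
  jsonlite::write_json(
    list(exposed_ids = names(sim$truth$exposed_flags)[sim$truth$exposed_flags],
         planted_hr = as.list(sim$truth$planted_hr),
         planted_pairs = as.data.frame(sim$truth$planted_pairs)),
    fg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fp, fd, fm, fg))
}
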