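test_that("incidence threshold reproduces the study arithmetic", {
  expect_equal(incidence_threshold(163303, 0.01), 1633)
  expect_equal(incidence_threshold(163303, 0.005), 816)
  expect_equal(incidence_threshold(100, 0.01), 1)
  expect_error(incidence_threshold(0, 0.01))
})

test_that("build_subcohort applies the prevalence and censoring rules", {
  p <- toy_participants(4, seed = 1)
  p$exposed <- c(TRUE, TRUE, FALSE, FALSE)
  p$death_date <- as.Date(c(NA, NA, "2012-06-01", NA))
  ev <- toy_events(
    list("T0001", "K76", "2005-01-01"),  # before baseline: prevalent
    list("T0002", "K76", "2010-06-01"),  # incident
    list("T0003", "K76", "2015-06-01"))  # after own death: censored at death
  sub <- build_subcohort(p, ev, "K76", "exposed")
  expect_false("T0001" %in% sub$participant_id)
  r2 <- sub[sub$participant_id == "T0002"]
  expect_equal(r2$event, 1L)
  expect_equal(r2$time, as.numeric(as.Date("2010-06-01") - as.Date("2006-06-01")))
  r3 <- sub[sub$participant_id == "T0003"]
  expect_equal(r3$event, 0L)
  expect_equal(r3$time, as.numeric(as.Date("2012-06-01") - as.Date("2006-06-01")))
  # censored participant carries the full follow-up
  r4 <- sub[sub$participant_id == "T0004"]
  expect_equal(r4$time, as.numeric(as.Date("2019-06-01") - as.Date("2006-06-01")))
  # diagnosis exactly on the assessment date counts as prevalent
  ev2 <- toy_events(list("T0004", "K76", "2006-06-01"))
  expect_false("T0004" %in% build_subcohort(p, ev2, "K76", "exposed")$participant_id)
  expect_error(build_subcohort(p, ev, "XXX", "exposed",
                               known_categories = "K76"), "unknown outcome")
})

test_that("Cox fit recovers a known rate ratio and the permutation null", {
  covered <- 0L
  null_sig <- 0L
  for (s in 1:20) {
    set.seed(2000 + s)
    n <- 5000
    exposed <- rep(c(TRUE, FALSE), each = n / 2)
    time <- rexp(n, rate = ifelse(exposed, 2, 1) * 0.1)
    sub <- data.table::data.table(participant_id = as.character(1:n),
                                  exposed = exposed,
                                  time = time, event = 1L)
    f <- fit_time_to_event(sub)
    expect_true(f$estimable)
    if (f$ci_low <= 2 && 2 <= f$ci_high) covered <- covered + 1L
    # permutation null: same times, shuffled labels
    sub$exposed <- sample(sub$exposed)
    f0 <- fit_time_to_event(sub)
    if (f0$p < 0.05 / 490) null_sig <- null_sig + 1L
  }
  expect_gte(covered, 18L)
  expect_equal(null_sig, 0L)
})

test_that("degenerate inputs are flagged non-estimable", {
  sub <- data.table::data.table(participant_id = as.character(1:100),
                                exposed = rep(c(TRUE, FALSE), 50),
                                time = runif(100, 1, 10), event = 0L)
  expect_false(fit_time_to_event(sub)$estimable)  # all censored
  sub$event[sub$exposed] <- 1L  # no control events
  expect_false(fit_time_to_event(sub)$estimable)
})

test_that("run_phewas applies the incidence filter and Bonferroni rule", {
  sim <- simulate_cohort(sim_config(
    6000, seed = 31,
    disease_catalog = data.frame(code = c("E11", "I21", "K57", "F32", "G47"),
                                 rate = c(0.01, 0.004, 0.01, 0.0002, 0.01)),
    exposure_hr = c(E11 = 4),
    pair_amplification = data.frame(d1 = character(), d2 = character(),
                                    psi = numeric()),
    death_causes = data.frame(code = "I21", rate = 0.001),
    death_multipliers = data.frame(disease = character(), cause = character(),
                                   mult = numeric())))
  p <- merge(sim$participants, phenotype_cohort(sim$participants),
             by = "participant_id")
  p <- p[!is.na(p$mafld)]
  ev <- collapse_events(sim$diagnoses, default_mapping())
  res <- run_phewas(p, ev, c("E11", "I21", "K57", "F32", "G47"), "mafld",
                    bonferroni_n = 490)
  expect_equal(attr(res, "p_cut"), 0.05 / 490, tolerance = 1e-12)
  expect_true(res$significant[res$outcome == "E11"])
  # rare outcome (rate 2e-4) cannot clear the 1% filter at this n
  expect_equal(res$skip_reason[res$outcome == "F32"], "incidence_filter")
  expect_false(res$significant[res$outcome == "F32"])
  # subcohort exclusivity: no analysis row with a baseline-dated outcome
  for (oc in c("E11", "K57")) {
    sub <- build_subcohort(p, ev, oc, "mafld")
    onset <- ev[ev$category == oc]
    m <- merge(sub, onset, by = "participant_id")
    assess <- p$assessment_date[match(m$participant_id, p$participant_id)]
    expect_true(all(m$date > assess))
  }
})

test_that("sensitivity exclusion removes same-system baseline disease", {
  p <- toy_participants(3, seed = 4)
  p$exposed <- c(TRUE, FALSE, TRUE)
  ev <- toy_events(
    list("T0001", "I48", "2005-01-01"),  # baseline atrial fibrillation
    list("T0001", "I50", "2012-01-01"),
    list("T0002", "I50", "2013-01-01"))
  sub <- sensitivity_exclusion(p, ev, "I50", "exposed")
  # heart-failure outcome: baseline cardiovascular disease excludes T0001
  expect_false("T0001" %in% sub$participant_id)
  expect_equal(attr(sub, "n_system_excluded"), 1L)
  # outcome in a chapter without baseline disease: identical to build_subcohort
  ev2 <- toy_events(list("T0001", "K76", "2012-01-01"))
  expect_equal(sensitivity_exclusion(p, ev2, "K76", "exposed"),
               build_subcohort(p, ev2, "K76", "exposed"),
               ignore_attr = TRUE)
  # all participants carrying baseline disease in the chapter: empty table
  ev3 <- toy_events(list("T0001", "I48", "2005-01-01"),
                    list("T0002", "I21", "2005-02-01"),
                    list("T0003", "I50", "2005-03-01"))
  expect_equal(nrow(sensitivity_exclusion(p, ev3, "I50", "exposed")), 0L)
})
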