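#' Minimum exposed-case count from an incidence fraction
#'
#' Outcomes are only analyzed when they occur in more than `fraction` of the
#' exposed participants: the threshold is `floor(fraction x n_exposed)` and
#' outcomes must *exceed* it. With the study's 163,303 exposed participants
#' the 1% and 0.5% thresholds are 1633 and 816.
#'
#' @param n_exposed number of exposed participants (> 0).
#' @param fraction incidence fraction in (0, 1).
#' @export
incidence_threshold <- function(n_exposed, fraction) {
  stopifnot(n_exposed > 0, fraction > 0, fraction < 1)
  floor(fraction * n_exposed)
}

#' Build the per-outcome analysis subcohort
#'
#' Excludes participants with a history of the outcome at baseline
#' (diagnosis dated on or before the assessment date counts as prevalent)
#' and attaches, per remaining participant, the event indicator and the
#' follow-up time in days from assessment to first outcome, death or censor
#' date, whichever comes first. Death acts as censoring for disease
#' outcomes; death-cause outcomes use [build_death_subcohort()].
#'
#' @param participants table with `participant_id`, `assessment_date`,
#'   `censor_date`, optional `death_date`, and the exposure column.
#' @param events collapsed diagnosis events ([collapse_events()]).
#' @param outcome combined category code.
#' @param exposure name of the logical exposure column in `participants`.
#' @param known_categories optional catalog of valid outcome codes; an
#'   outcome outside it is a hard error.
#' @return data.table: `participant_id`, `exposed`, `time` (days), `event`.
#' @export
build_subcohort <- function(participants, events, outcome, exposure,
                            known_categories = NULL) {
  assert_cols(participants, c("participant_id", "assessment_date",
                              "censor_date", exposure), "participant table")
  if (!is.null(known_categories) && !outcome %in% known_categories) {
    stop("build_subcohort: unknown outcome category '", outcome, "'",
         call. = FALSE)
  }
  p <- data.table::as.data.table(participants)
  p[, `:=`(assessment_date = as_date_strict(assessment_date),
           censor_date = as_date_strict(censor_date))]
  dd <- if ("death_date" %in% names(p)) as_date_strict(p$death_date)
        else as.Date(rep(NA, nrow(p)))
  ev <- events[events$category == outcome,
               c("participant_id", "date"), with = FALSE]
  onset <- ev$date[match(as.character(p$participant_id), ev$participant_id)]
  prevalent <- !is.na(onset) & onset <= p$assessment_date
  end <- pmin(p$censor_date, dd, na.rm = TRUE)
  event <- !is.na(onset) & onset <= end & !prevalent
  stop_num <- ifelse(event, as.numeric(onset), as.numeric(end))
  time <- stop_num - as.numeric(p$assessment_date)
  out <- data.table::data.table(
    participant_id = as.character(p$participant_id),
    exposed = as.logical(p[[exposure]]),
    time = time, event = as.integer(event))[!prevalent]
  out[out$time >= 0]
}

#' Cox fit of exposure on one outcome
#'
#' Proportional-hazards partial likelihood with Efron tie handling; the
#' hazard ratio is the exponentiated exposure coefficient with Wald CI and
#' p-value. Requires at least one event in each exposure arm; otherwise the
#' result is flagged non-estimable rather than erroring.
#'
#' @param subcohort output of [build_subcohort()].
#' @return list: `hr`, `ci_low`, `ci_high`, `p`, `n_cases`,
#'   `n_cases_exposed`, `estimable`.
#' @export
fit_time_to_event <- function(subcohort) {
  n_cases <- sum(subcohort$event)
  n_exp <- sum(subcohort$event[subcohort$exposed])
  n_ctl <- n_cases - n_exp
  base <- list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, n_cases = n_cases, n_cases_exposed = n_exp,
               estimable = FALSE)
  if (n_exp == 0L || n_ctl == 0L) return(base)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ exposed,
                                     data = subcohort, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(coef(fit)[1])) return(base)
  b <- coef(fit)[1]
  se <- sqrt(vcov(fit)[1, 1])
  if (!is.finite(se) || se > 50) return(base)  # monotone likelihood
  z <- b / se
  list(hr = exp(b), ci_low = exp(b - 1.959964 * se),
       ci_high = exp(b + 1.959964 * se),
       p = 2 * pnorm(-abs(z)), n_cases = n_cases, n_cases_exposed = n_exp,
       estimable = TRUE)
}

#' Phenome-wide association sweep
#'
#' One Cox regression per outcome category on the (matched) cohort. Outcomes
#' are skipped unless their exposed-case count exceeds the incidence
#' threshold; per-outcome failures are flagged, never aborting the sweep.
#' Significance is the conjunction `HR > 1` and `p < alpha / bonferroni_n`.
#'
#' @inheritParams build_subcohort
#' @param outcomes character vector of outcome category codes.
#' @param alpha familywise level (default 0.05).
#' @param bonferroni_n Bonferroni denominator. Default `NULL` uses
#'   `length(outcomes)` (the catalog size, matching the study's "number of
#'   disease categories"); set explicitly to use a different convention.
#' @param min_case_fraction incidence filter fraction (default 0.01).
#' @param log optional run logger.
#' @return data.table, one row per outcome: `outcome`, `n_cases`,
#'   `n_cases_exposed`, `hr`, `ci_low`, `ci_high`, `p`, `tested`,
#'   `significant`, `skip_reason`.
#' @export
run_phewas <- function(participants, events, outcomes, exposure,
                       alpha = 0.05, bonferroni_n = NULL,
                       min_case_fraction = 0.01, log = null_logger()) {
  if (!length(outcomes)) stop("run_phewas: no outcomes supplied", call. = FALSE)
  bonferroni_n <- bonferroni_n %||% length(outcomes)
  n_exposed <- sum(as.logical(as.data.frame(participants)[[exposure]]))
  thr <- incidence_threshold(n_exposed, min_case_fraction)
  cut <- alpha / bonferroni_n
  log("run_phewas", n_outcomes = length(outcomes), n_exposed = n_exposed,
      incidence_threshold = thr, alpha = alpha, bonferroni_n = bonferroni_n,
      p_cut = cut)
  rows <- lapply(outcomes, function(oc) {
    sub <- build_subcohort(participants, events, oc, exposure)
    f <- fit_time_to_event(sub)
    skip <- if (f$n_cases_exposed <= thr) "incidence_filter"
            else if (!f$estimable) "non_estimable" else NA_character_
    log("phewas_outcome", outcome = oc, n_cases = f$n_cases,
        n_cases_exposed = f$n_cases_exposed, skipped = skip)
    data.table::data.table(
      outcome = oc, n_cases = f$n_cases, n_cases_exposed = f$n_cases_exposed,
      hr = f$hr, ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
      tested = is.na(skip),
      significant = is.na(skip) & !is.na(f$hr) & f$hr > 1 & f$p < cut,
      skip_reason = skip)
  })
  res <- data.table::rbindlist(rows)
  attr(res, "p_cut") <- cut
  attr(res, "incidence_threshold") <- thr
  res
}

#' Sensitivity analysis table: exclude same-system baseline disease
#'
#' Builds the analysis subcohort for `outcome` after additionally removing
#' participants with *any* baseline disease in the outcome's chapter-level
#' system group (the same 16 groups as the causes of death). E.g. for a
#' heart-failure outcome, anyone with any baseline cardiovascular disease is
#' excluded.
#'
#' @inheritParams build_subcohort
#' @param scheme system-group scheme ([load_death_scheme()]).
#' @return as [build_subcohort()]; attribute `n_system_excluded` reports the
#'   extra exclusions.
#' @export
sensitivity_exclusion <- function(participants, events, outcome, exposure,
                                  scheme = load_death_scheme()) {
  grp <- category_system_group(outcome, scheme)
  p <- data.table::as.data.table(participants)
  assess <- as_date_strict(p$assessment_date)
  same_sys <- events[!is.na(category_system_group(events$category, scheme)) &
                     category_system_group(events$category, scheme) == grp]
  base_idx <- match(same_sys$participant_id, as.character(p$participant_id))
  at_base <- same_sys[!is.na(base_idx) & same_sys$date <= assess[base_idx]]
  drop_ids <- unique(at_base$participant_id)
  out <- build_subcohort(p[!as.character(p$participant_id) %in% drop_ids],
                         events, outcome, exposure)
  data.table::setattr(out, "n_system_excluded", length(drop_ids))
  out
}
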