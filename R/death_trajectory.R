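#' Parse a death table into per-participant cause categories
#'
#' `cause_codes` holds primary and secondary ICD-10 causes joined by
#' semicolons; primary and secondary are treated alike when assigning the 16
#' cause-of-death categories.
#'
#' @param deaths table with `participant_id`, `date`, `cause_codes`.
#' @param scheme a `death_scheme`.
#' @return data.table `participant_id`, `death_date`, `cause` (one row per
#'   participant x cause category).
#' @export
parse_deaths <- function(deaths, scheme = load_death_scheme()) {
  if (!nrow(deaths)) {
    return(data.table::data.table(participant_id = character(),
                                  death_date = as.Date(character()),
                                  cause = character()))
  }
  assert_cols(deaths, c("participant_id", "date", "cause_codes"), "death table")
  rows <- lapply(seq_len(nrow(deaths)), function(i) {
    codes <- strsplit(as.character(deaths$cause_codes[i]), ";", fixed = TRUE)[[1]]
    cats <- group_death_causes(codes, scheme)
    if (!length(cats)) return(NULL)
    data.table::data.table(
      participant_id = as.character(deaths$participant_id[i]),
      death_date = as_date_strict(deaths$date[i], "death date"),
      cause = cats)
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    return(data.table::data.table(participant_id = character(),
                                  death_date = as.Date(character()),
                                  cause = character()))
  }
  unique(out)
}

#' Analysis table for a cause-of-death outcome
#'
#' Event = death with the given cause among the primary or secondary causes;
#' everyone else is censored at death from other causes or study end.
#'
#' @param participants participant table with the exposure column.
#' @param parsed_deaths output of [parse_deaths()].
#' @param cause cause category.
#' @param exposure exposure column name.
#' @return data.table as [build_subcohort()].
#' @export
build_death_subcohort <- function(participants, parsed_deaths, cause, exposure) {
  p <- data.table::as.data.table(participants)
  assess <- as_date_strict(p$assessment_date)
  censor <- as_date_strict(p$censor_date)
  dd <- parsed_deaths[!duplicated(parsed_deaths$participant_id),
                      c("participant_id", "death_date"), with = FALSE]
  death_date <- dd$death_date[match(as.character(p$participant_id),
                                    dd$participant_id)]
  cause_ids <- unique(parsed_deaths$participant_id[parsed_deaths$cause == cause])
  event <- as.character(p$participant_id) %in% cause_ids
  end <- pmin(censor, death_date, na.rm = TRUE)
  out <- data.table::data.table(
    participant_id = as.character(p$participant_id),
    exposed = as.logical(p[[exposure]]),
    time = as.numeric(end) - as.numeric(assess),
    event = as.integer(event))
  out[out$time >= 0]
}

#' Cause-of-death PheWAS
#'
#' One Cox fit per cause-of-death category (default: all 16) with the given
#' exposure; same incidence filter and Bonferroni rule as [run_phewas()],
#' with denominator = number of causes.
#'
#' @inheritParams build_death_subcohort
#' @param causes cause categories to sweep (default: all in the scheme).
#' @param alpha,min_case_fraction,log as in [run_phewas()].
#' @param scheme a `death_scheme`.
#' @export
run_death_phewas <- function(participants, parsed_deaths, exposure,
                             causes = NULL, scheme = load_death_scheme(),
                             alpha = 0.05, min_case_fraction = 0.01,
                             log = null_logger()) {
  causes <- causes %||% sort(unique(scheme$cause_category))
  n_exposed <- sum(as.logical(as.data.frame(participants)[[exposure]]))
  thr <- incidence_threshold(n_exposed, min_case_fraction)
  cut <- alpha / length(causes)
  rows <- lapply(causes, function(cs) {
    sub <- build_death_subcohort(participants, parsed_deaths, cs, exposure)
    f <- fit_time_to_event(sub)
    skip <- if (f$n_cases == 0L) "no_decedents"
            else if (f$n_cases_exposed <= thr) "incidence_filter"
            else if (!f$estimable) "non_estimable" else NA_character_
    log("death_phewas_cause", cause = cs, n_cases = f$n_cases, skipped = skip)
    data.table::data.table(
      outcome = cs, n_cases = f$n_cases, n_cases_exposed = f$n_cases_exposed,
      hr = f$hr, ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
      tested = is.na(skip),
      significant = is.na(skip) & !is.na(f$hr) & f$hr > 1 & f$p < cut,
      skip_reason = skip)
  })
  res <- data.table::rbindlist(rows)
  attr(res, "p_cut") <- cut
  res
}

#' Disease-to-death association sweep for one cause
#'
#' Among the matched decedent/survivor cohort (all MAFLD-exposed), each
#' candidate disease in turn is the exposure and death from the given cause
#' the outcome. Default model is Cox time-to-death with the disease
#' (diagnosed before the end of follow-up) as exposure; `model =
#' "logistic"` fits a logistic fallback on the same risk indicator.
#'
#' @param participants matched decedent/survivor participant table.
#' @param events collapsed diagnosis events.
#' @param parsed_deaths output of [parse_deaths()].
#' @param cause cause category.
#' @param diseases candidate disease categories.
#' @param alpha familywise level; Bonferroni denominator =
#'   `length(diseases)`.
#' @param model `"cox"` (default) or `"logistic"`.
#' @param log optional run logger.
#' @return data.table, one row per disease, same shape as [run_phewas()].
#' @export
run_disease_death_phewas <- function(participants, events, parsed_deaths,
                                     cause, diseases, alpha = 0.05,
                                     model = c("cox", "logistic"),
                                     log = null_logger()) {
  model <- match.arg(model)
  cut <- alpha / length(diseases)
  p <- data.table::as.data.table(participants)
  base <- build_death_subcohort(p, parsed_deaths, cause, exposure = names(p)[1])
  # exposure column above is a placeholder; disease flags replace it below
  rows <- lapply(diseases, function(ds) {
    ev <- events[events$category == ds]
    onset <- ev$date[match(base$participant_id, ev$participant_id)]
    assess <- as_date_strict(p$assessment_date)[
      match(base$participant_id, as.character(p$participant_id))]
    sub <- data.table::copy(base)
    sub$exposed <- !is.na(onset) &
      (as.numeric(onset) - as.numeric(assess)) <= sub$time
    f <- if (model == "cox") {
      fit_time_to_event(sub)
    } else {
      lt <- tryCatch(suppressWarnings(
        glm(event ~ exposed, data = sub, family = binomial())),
        error = function(e) NULL)
      if (is.null(lt) || !is.finite(coef(lt)["exposedTRUE"])) {
        list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
             p = NA_real_, n_cases = sum(sub$event),
             n_cases_exposed = sum(sub$event[sub$exposed]), estimable = FALSE)
      } else {
        b <- coef(lt)["exposedTRUE"]; se <- sqrt(vcov(lt)["exposedTRUE", "exposedTRUE"])
        list(hr = unname(exp(b)), ci_low = unname(exp(b - 1.959964 * se)),
             ci_high = unname(exp(b + 1.959964 * se)),
             p = unname(2 * pnorm(-abs(b / se))), n_cases = sum(sub$event),
             n_cases_exposed = sum(sub$event[sub$exposed]),
             estimable = is.finite(se) && se < 50)
      }
    }
    log("disease_death", cause = cause, disease = ds, model = model,
        n_cases = f$n_cases)
    data.table::data.table(
      outcome = ds, n_cases = f$n_cases, n_cases_exposed = f$n_cases_exposed,
      hr = f$hr, ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
      tested = f$estimable,
      significant = f$estimable & !is.na(f$hr) & f$hr > 1 & f$p < cut,
      skip_reason = ifelse(f$estimable, NA_character_, "non_estimable"))
  })
  res <- data.table::rbindlist(rows)
  attr(res, "p_cut") <- cut
  res
}

#' Death-trajectory workflow
#'
#' The cause-specific variant of the trajectory pipeline:
#' (1) exposure -> cause-of-death PheWAS over the 16 causes on the matched
#' MAFLD cohort; (2) decedents matched to survivors *within the exposed
#' group* (1:ratio on age, sex, deprivation); (3) for each retained cause, a
#' disease -> death sweep over the supplied disease categories; (4) pair
#' inference among that cause's significant diseases, restricted to its
#' decedents; (5) a per-cause pruned trajectory graph terminating in the
#' death node `death:<cause>`.
#'
#' @param participants matched-cohort participant table (must contain the
#'   `exposure` column, `age`, `sex`, `townsend`, dates, and `death_date`
#'   where applicable).
#' @param events collapsed diagnosis events.
#' @param deaths raw death table.
#' @param exposure exposure column (e.g. `"mafld"`).
#' @param disease_categories candidate diseases (typically the significant
#'   set of the main disease PheWAS).
#' @param scheme a `death_scheme`.
#' @param match_ratio survivors matched per decedent (default 1).
#' @param alpha familywise level.
#' @param min_case_fraction incidence filter for the cause sweep.
#' @param cooccurrence_fraction pair filter among decedents.
#' @param model disease -> death model, `"cox"` or `"logistic"`.
#' @param seed integer.
#' @param log optional run logger.
#' @return list: `cause_phewas`, and per retained cause a list with
#'   `disease_phewas`, `pairs`, `graph`.
#' @export
run_death_workflow <- function(participants, events, deaths, exposure,
                               disease_categories,
                               scheme = load_death_scheme(),
                               match_ratio = 1L, alpha = 0.05,
                               min_case_fraction = 0.01,
                               cooccurrence_fraction = 0.005,
                               model = "cox", seed = 1L,
                               log = null_logger()) {
  parsed <- parse_deaths(deaths, scheme)
  cause_res <- run_death_phewas(participants, parsed, exposure,
                                scheme = scheme, alpha = alpha,
                                min_case_fraction = min_case_fraction,
                                log = log)
  retained <- cause_res$outcome[cause_res$significant]
  log("death_workflow", n_causes_retained = length(retained))
  out <- list(cause_phewas = cause_res, per_cause = list())
  if (!length(retained)) return(out)

  p <- data.table::as.data.table(participants)
  expo <- p[as.logical(p[[exposure]])]
  expo$died <- as.character(expo$participant_id) %in%
    unique(parsed$participant_id)
  if (!any(expo$died)) return(out)
  ps <- estimate_propensity(expo, "died")
  mc <- match_pairs(expo, ps, "died", ratio = match_ratio,
                    seed = child_seed(seed, "death_match"), log = log)
  stopifnot(length(intersect(mc$pairs$exposed_id, mc$pairs$control_id)) == 0)
  msub <- expo[as.character(expo$participant_id) %in% matched_ids(mc)]

  for (cs in retained) {
    dres <- run_disease_death_phewas(msub, events, parsed, cs,
                                     disease_categories, alpha = alpha,
                                     model = model, log = log)
    sig <- dres$outcome[dres$significant]
    dec_ids <- intersect(
      unique(parsed$participant_id[parsed$cause == cs]),
      as.character(expo$participant_id))
    pres <- if (length(sig) >= 2 && length(dec_ids)) {
      run_pair_inference(msub, events, sig, dec_ids,
                         n_exposed = length(dec_ids), alpha = alpha,
                         cooccurrence_fraction = cooccurrence_fraction,
                         log = log)
    } else NULL
    death_node <- paste0("death:", cs)
    nodes_tbl <- data.table::rbindlist(list(
      dres[, c("outcome", "hr", "ci_low", "ci_high", "p", "n_cases",
               "n_cases_exposed", "tested", "significant", "skip_reason")],
      data.table::data.table(outcome = death_node,
                             hr = cause_res$hr[cause_res$outcome == cs],
                             ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                             n_cases = cause_res$n_cases[cause_res$outcome == cs],
                             n_cases_exposed =
                               cause_res$n_cases_exposed[cause_res$outcome == cs],
                             tested = TRUE, significant = TRUE,
                             skip_reason = NA_character_)))
    conf <- if (!is.null(pres)) pres[pres$confirmed] else
      data.table::data.table(d1 = character(), d2 = character(),
                             or = numeric(), n_both = integer(),
                             binom_p = numeric(), logit_p = numeric())
    dd_edges <- data.table::data.table(
      d1 = sig, d2 = rep(death_node, length(sig)),
      or = dres$hr[match(sig, dres$outcome)],
      n_both = dres$n_cases_exposed[match(sig, dres$outcome)],
      binom_p = NA_real_, logit_p = dres$p[match(sig, dres$outcome)])
    all_edges <- data.table::rbindlist(list(
      conf[, c("d1", "d2", "or", "n_both", "binom_p", "logit_p")], dd_edges))
    graph <- if (nrow(all_edges)) {
      transitive_prune(assemble_graph(nodes_tbl, all_edges))
    } else NULL
    stopifnot(is.null(graph) ||
                all(c(graph$edges$d1, graph$edges$d2) %in%
                      c(disease_categories, death_node)))
    out$per_cause[[cs]] <- list(disease_phewas = dres, pairs = pres,
                                graph = graph)
  }
  out
}

#' Genetic-susceptibility trajectory workflow
#'
#' Identical pipeline with exposure = highest vs lowest PRS tertile (the
#' intermediate tertile is dropped): propensity matching on age, sex and
#' deprivation, disease PheWAS, pair inference, pruned graph.
#'
#' @param participants participant table containing `genetic_tertile`
#'   (factor from [prs_tertile()]) plus matching covariates and dates.
#' @param events collapsed diagnosis events.
#' @param outcomes disease categories to sweep.
#' @param alpha,min_case_fraction,cooccurrence_fraction stage thresholds.
#' @param bonferroni_n see [run_phewas()].
#' @param seed integer.
#' @param log optional run logger.
#' @return list: `cohort` (kept rows), `matches`, `phewas`, `pairs`,
#'   `graph`.
#' @export
run_genetic_workflow <- function(participants, events, outcomes,
                                 alpha = 0.05, min_case_fraction = 0.01,
                                 cooccurrence_fraction = 0.005,
                                 bonferroni_n = NULL, seed = 1L,
                                 log = null_logger()) {
  p <- data.table::as.data.table(participants)
  assert_cols(p, "genetic_tertile", "participant table")
  tert <- as.character(p$genetic_tertile)
  if (!any(tert == "high") || !any(tert == "low")) {
    stop("run_genetic_workflow: empty PRS tertile (degenerate PRS distribution)",
         call. = FALSE)
  }
  keep <- p[tert %in% c("high", "low")]
  keep$prs_exposed <- as.character(keep$genetic_tertile) == "high"
  ps <- estimate_propensity(keep, "prs_exposed")
  mc <- match_pairs(keep, ps, "prs_exposed",
                    seed = child_seed(seed, "genetic_match"), log = log)
  msub <- keep[as.character(keep$participant_id) %in% matched_ids(mc)]
  phe <- run_phewas(msub, events, outcomes, "prs_exposed", alpha = alpha,
                    bonferroni_n = bonferroni_n,
                    min_case_fraction = min_case_fraction, log = log)
  sig <- phe$outcome[phe$significant]
  exp_ids <- as.character(msub$participant_id)[msub$prs_exposed]
  pres <- if (length(sig) >= 2) {
    run_pair_inference(msub, events, sig, exp_ids, alpha = alpha,
                       cooccurrence_fraction = cooccurrence_fraction,
                       log = log)
  } else NULL
  graph <- if (!is.null(pres) && any(pres$confirmed)) {
    transitive_prune(assemble_graph(phe, pres[pres$confirmed]))
  } else NULL
  list(cohort = msub, matches = mc, phewas = phe, pairs = pres, graph = graph)
}
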