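#' Default pipeline configuration
#'
#' Every stage parameter defaults to the study's stated value where one
#' exists: incidence fraction 0.01, pair co-occurrence fraction 0.005,
#' alpha = 0.05 with Bonferroni correction, FLI steatosis cutoff 60, NFS
#' fibrosis cutoff -1.455, fixed PRS tertile cutoffs 0.76 / 2.35, 1:1
#' matching on age, sex and deprivation with a 0.2-SD logit caliper.
#'
#' @param ... overrides (partial matching not performed; unknown keys
#'   rejected).
#' @return a named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    participants = NULL, diagnoses = NULL, deaths = NULL,
    mapping = NULL, death_scheme = NULL,
    seed = 1L, outdir = NULL,
    fli_cutoff = 60, nfs_cutoff = -1.455,
    tertile_method = "fixed",
    exposure = "mafld",
    covariates = c("age", "sex", "townsend"),
    caliper = "default", match_ratio = 1L,
    alpha = 0.05, bonferroni_n = NULL,
    min_case_fraction = 0.01, cooccurrence_fraction = 0.005,
    unmapped = "drop",
    subgroup = NULL, sensitivity = FALSE,
    death_workflow = FALSE, genetic_workflow = FALSE,
    death_match_ratio = 1L, death_model = "cox")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("run_config: unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys are [run_config()] parameters.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path, simplifyVector = TRUE))
}

write_tsv <- function(x, path) data.table::fwrite(x, path, sep = "\t", eol = "\n")

#' Run the end-to-end trajectory pipeline
#'
#' taxonomy -> phenotyping -> matching -> PheWAS -> pair inference -> graph,
#' with optional death and genetic workflows. Every stage's parameters,
#' in/out counts and thresholds are appended to `run_log.jsonl` in the
#' output directory; identical config and seed give byte-identical outputs.
#'
#' Subgroup analyses are row filters applied *before* matching (each
#' subgroup gets its own matched cohort): `subgroup` is an R expression over
#' participant/phenotype columns, e.g. `"sex == 'female'"` or
#' `"overweight"`.
#'
#' @param config a [run_config()] (paths to `participants`, `diagnoses`,
#'   `deaths` CSVs are required; `mapping` defaults to the bundled file).
#' @param until last stage to run: one of `"phenotype"`, `"match"`,
#'   `"phewas"`, `"pairs"`, `"graph"` (default, also runs the optional
#'   workflows).
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, until = "graph") {
  stopifnot(inherits(config, "run_config"))
  stages <- c("phenotype", "match", "phewas", "pairs", "graph")
  until <- match.arg(until, stages)
  outdir <- config$outdir %||% stop_stage("config", "outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- run_logger(file.path(outdir, "run_log.jsonl"))
  log("config", parameters = config[!vapply(config, is.null, logical(1))])
  seed <- config$seed

  # ---- taxonomy ----
  mapping <- if (is.null(config$mapping)) default_mapping()
             else load_mapping(config$mapping)
  scheme <- load_death_scheme(config$death_scheme)
  log("taxonomy", n_codes = nrow(mapping), n_categories = n_categories(mapping))
  participants <- data.table::fread(config$participants, colClasses = list(
    character = "participant_id"))
  diagnoses <- data.table::fread(config$diagnoses, colClasses = list(
    character = c("participant_id", "icd10_code")))
  deaths <- data.table::fread(config$deaths, colClasses = list(
    character = c("participant_id", "cause_codes")))
  events <- collapse_events(diagnoses, mapping, unmapped = config$unmapped,
                            log = log)
  log("events", n_raw = nrow(diagnoses), n_collapsed = nrow(events))

  # ---- phenotype ----
  phen <- phenotype_cohort(participants, fli_cutoff = config$fli_cutoff,
                           nfs_cutoff = config$nfs_cutoff,
                           tertile_method = config$tertile_method)
  write_tsv(phen, file.path(outdir, "phenotypes.tsv"))
  p <- merge(data.table::as.data.table(participants), phen,
             by = "participant_id")
  if (nrow(deaths)) {
    dd <- deaths[!duplicated(deaths$participant_id)]
    p$death_date <- as_date_strict(dd$date)[
      match(p$participant_id, as.character(dd$participant_id))]
  } else {
    p$death_date <- as.Date(NA)
  }
  n0 <- nrow(p)
  p <- p[!is.na(p[[config$exposure]])]  # undetermined phenotype excluded
  log("phenotype", n_in = n0, n_determined = nrow(p),
      n_exposed = sum(p[[config$exposure]]))
  if (!is.null(config$subgroup)) {
    keep <- eval(parse(text = config$subgroup), envir = p, enclos = baseenv())
    p <- p[!is.na(keep) & keep]
    log("subgroup", filter = config$subgroup, n_kept = nrow(p))
  }
  res <- list(participants = p, events = events, phenotypes = phen,
              mapping = mapping)
  if (until == "phenotype") return(invisible(res))

  # ---- match ----
  ps <- estimate_propensity(p, config$exposure, config$covariates)
  mc <- match_pairs(p, ps, config$exposure, covariates = config$covariates,
                    caliper = config$caliper, ratio = config$match_ratio,
                    seed = child_seed(seed, "match"), log = log)
  write_tsv(mc$pairs, file.path(outdir, "matched_pairs.tsv"))
  write_tsv(mc$balance, file.path(outdir, "balance_report.tsv"))
  cohort <- p[p$participant_id %in% matched_ids(mc)]
  res$matches <- mc
  res$cohort <- cohort
  if (until == "match") return(invisible(res))

  # ---- phewas ----
  outcomes <- sort(unique(mapping$combined_code))
  bonf <- config$bonferroni_n %||% n_categories(mapping)
  phe <- run_phewas(cohort, events, outcomes, config$exposure,
                    alpha = config$alpha, bonferroni_n = bonf,
                    min_case_fraction = config$min_case_fraction, log = log)
  write_tsv(phe, file.path(outdir, "phewas_results.tsv"))
  if (isTRUE(config$sensitivity)) {
    sens <- data.table::rbindlist(lapply(outcomes, function(oc) {
      sub <- sensitivity_exclusion(cohort, events, oc, config$exposure, scheme)
      f <- fit_time_to_event(sub)
      data.table::data.table(outcome = oc, n_cases = f$n_cases,
                             n_cases_exposed = f$n_cases_exposed, hr = f$hr,
                             ci_low = f$ci_low, ci_high = f$ci_high, p = f$p,
                             n_system_excluded = attr(sub, "n_system_excluded"))
    }))
    write_tsv(sens, file.path(outdir, "phewas_sensitivity.tsv"))
    res$sensitivity <- sens
  }
  res$phewas <- phe
  if (until == "phewas") return(invisible(res))

  # ---- pairs ----
  sig <- phe$outcome[phe$significant]
  exp_ids <- cohort$participant_id[as.logical(cohort[[config$exposure]])]
  pres <- run_pair_inference(cohort, events, sig, exp_ids,
                             alpha = config$alpha,
                             cooccurrence_fraction = config$cooccurrence_fraction,
                             log = log)
  write_tsv(pres, file.path(outdir, "pairs.tsv"))
  res$pairs <- pres
  if (until == "pairs") return(invisible(res))

  # ---- graph ----
  conf <- pres[pres$confirmed]
  graph <- if (nrow(conf)) transitive_prune(assemble_graph(phe, conf)) else {
    structure(list(nodes = data.table::data.table(category = character(),
                                                  hr = numeric(),
                                                  n_cases = integer()),
                   edges = data.table::data.table(d1 = character(),
                                                  d2 = character(),
                                                  or = numeric(),
                                                  n_both = integer(),
                                                  binom_p = numeric(),
                                                  logit_p = numeric(),
                                                  pruned = logical())),
              class = "trajectory_graph")
  }
  export_graph(graph, outdir)
  if (nrow(graph$nodes)) {
    write_tsv(layer_nodes(graph), file.path(outdir, "layers.tsv"))
  }
  res$graph <- graph
  log("graph", n_nodes = nrow(graph$nodes), n_edges = nrow(graph$edges),
      n_pruned = sum(graph$edges$pruned))

  # ---- optional workflows ----
  if (isTRUE(config$death_workflow)) {
    dw <- run_death_workflow(cohort, events, deaths, config$exposure,
                             disease_categories = if (length(sig)) sig else outcomes,
                             scheme = scheme,
                             match_ratio = config$death_match_ratio,
                             alpha = config$alpha,
                             min_case_fraction = config$min_case_fraction,
                             cooccurrence_fraction = config$cooccurrence_fraction,
                             model = config$death_model,
                             seed = child_seed(seed, "death"), log = log)
    ddir <- file.path(outdir, "death")
    dir.create(ddir, showWarnings = FALSE)
    write_tsv(dw$cause_phewas, file.path(ddir, "cause_phewas.tsv"))
    for (cs in names(dw$per_cause)) {
      cdir <- file.path(ddir, cs)
      dir.create(cdir, showWarnings = FALSE)
      write_tsv(dw$per_cause[[cs]]$disease_phewas,
                file.path(cdir, "phewas_results.tsv"))
      if (!is.null(dw$per_cause[[cs]]$pairs)) {
        write_tsv(dw$per_cause[[cs]]$pairs, file.path(cdir, "pairs.tsv"))
      }
      if (!is.null(dw$per_cause[[cs]]$graph)) {
        export_graph(dw$per_cause[[cs]]$graph, cdir)
      }
    }
    res$death <- dw
  }
  if (isTRUE(config$genetic_workflow)) {
    gw <- run_genetic_workflow(p, events, outcomes, alpha = config$alpha,
                               min_case_fraction = config$min_case_fraction,
                               cooccurrence_fraction = config$cooccurrence_fraction,
                               bonferroni_n = bonf,
                               seed = child_seed(seed, "genetic"), log = log)
    gdir <- file.path(outdir, "genetic")
    dir.create(gdir, showWarnings = FALSE)
    write_tsv(gw$phewas, file.path(gdir, "phewas_results.tsv"))
    if (!is.null(gw$pairs)) write_tsv(gw$pairs, file.path(gdir, "pairs.tsv"))
    if (!is.null(gw$graph)) export_graph(gw$graph, gdir)
    res$genetic <- gw
  }
  log("done", outdir = outdir)
  invisible(res)
}
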