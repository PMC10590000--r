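#' Estimate propensity scores
#'
#' Additive logistic model of exposure on the matching covariates (default:
#' age, sex, Townsend deprivation index). Perfect or quasi-perfect separation
#' is detected and surfaced as a classed warning (`mafldtraj_separation`)
#' advising exact matching without a propensity caliper; the fitted values
#' are still returned.
#'
#' @param data participant table.
#' @param exposure name of the logical/0-1 exposure column.
#' @param covariates character vector of covariate column names.
#' @return numeric vector of propensities in (0, 1), aligned with `data` rows.
#' @export
estimate_propensity <- function(data, exposure,
                                covariates = c("age", "sex", "townsend")) {
  assert_cols(data, c(exposure, covariates), "matching input")
  df <- as.data.frame(data)[, c(exposure, covariates)]
  if (any(!complete.cases(df))) {
    stop("estimate_propensity: missing covariate or exposure values; ",
         "exclude incomplete participants first", call. = FALSE)
  }
  df[[exposure]] <- as.numeric(df[[exposure]])
  # constant covariates (e.g. sex inside a single-sex subgroup) carry no
  # information and would break the factor contrasts: drop them
  constant <- vapply(covariates, function(v)
    length(unique(df[[v]])) < 2L, logical(1))
  if (all(constant)) {
    stop("estimate_propensity: every covariate is constant", call. = FALSE)
  }
  if (any(constant)) {
    message("estimate_propensity: dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  form <- stats::as.formula(paste(exposure, "~",
                                  paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  p <- as.numeric(stats::fitted(fit))
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps)) {
    warning(structure(class = c("mafldtraj_separation", "warning", "condition"),
                      list(message = paste0(
                        "estimate_propensity: (quasi-)separation detected; ",
                        "fitted propensities reach 0/1. Consider exact matching ",
                        "on the separating covariate with caliper = 'none'."),
                        call = NULL)))
  }
  p
}

logit <- function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))

#' Standardized mean difference
#'
#' `(mean_1 - mean_0) / sqrt((var_1 + var_0) / 2)`; binary variables are
#' coerced to 0/1. Returns 0 when both groups are constant and equal.
#'
#' @param x covariate values.
#' @param g exposure grouping (logical/0-1).
#' @export
smd <- function(x, g) {
  x <- as.numeric(if (is.character(x) || is.factor(x)) x == x[order(x)][1] else x)
  g <- as.logical(g)
  m1 <- mean(x[g]); m0 <- mean(x[!g])
  s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
  if (!is.finite(s) || s == 0) {
    if (isTRUE(all.equal(m1, m0))) 0 else Inf
  } else {
    (m1 - m0) / s
  }
}

#' 1:k propensity matching without replacement
#'
#' Greedy nearest-neighbor matching on the logit propensity, without
#' replacement, processing exposed participants in an order randomized by
#' `seed`. Sex is matched exactly (stratified matching) when present in
#' `exact`; continuous covariates act through the propensity. The default
#' caliper is 0.2 standard deviations of the logit propensity; pass
#' `caliper = "none"` to disable or a number for an absolute logit-scale
#' caliper. Unmatched exposed participants are dropped with a logged count.
#'
#' @param data participant table containing `id_col` and the covariates.
#' @param propensity propensities from [estimate_propensity()], aligned with
#'   `data`.
#' @param exposure name of the exposure column.
#' @param covariates covariates for the balance table.
#' @param exact columns matched exactly (default `"sex"` when present).
#' @param caliper `"default"` (0.2 SD of logit propensity), `"none"`, or a
#'   non-negative number on the logit scale.
#' @param ratio controls matched per exposed (integer >= 1; default 1).
#' @param id_col participant identifier column.
#' @param seed integer; fixes the processing order.
#' @param log optional run logger.
#' @return a `matched_cohort`: list with `pairs` (data.table
#'   `exposed_id`, `control_id`, `pair_id`), `balance` (per-covariate SMD
#'   before/after), `n_unmatched`, and the matching parameters.
#' @export
match_pairs <- function(data, propensity, exposure,
                        covariates = c("age", "sex", "townsend"),
                        exact = intersect("sex", names(data)),
                        caliper = "default", ratio = 1L,
                        id_col = "participant_id", seed = 1L,
                        log = null_logger()) {
  assert_cols(data, c(id_col, exposure), "matching input")
  stopifnot(length(propensity) == nrow(data), ratio >= 1)
  expo <- as.logical(as.data.frame(data)[[exposure]])
  if (!any(expo) || all(expo)) {
    stop("match_pairs: need both exposed and control participants", call. = FALSE)
  }
  lp <- logit(propensity)
  cal <- if (identical(caliper, "default")) {
    0.2 * sd(lp)
  } else if (identical(caliper, "none")) {
    Inf
  } else {
    stopifnot(is.numeric(caliper), caliper >= 0)
    as.numeric(caliper)
  }
  ids <- as.character(as.data.frame(data)[[id_col]])
  strata <- if (length(exact)) {
    do.call(paste, c(as.data.frame(data)[, exact, drop = FALSE], sep = "|"))
  } else {
    rep("all", nrow(data))
  }

  set.seed(seed)
  pairs <- list()
  for (st in sort(unique(strata))) {
    in_st <- strata == st
    t_idx <- which(in_st & expo)
    c_idx <- which(in_st & !expo)
    if (!length(t_idx) || !length(c_idx)) next
    t_idx <- t_idx[sample.int(length(t_idx))]
    # controls kept sorted by logit propensity for O(log n) neighbor lookup
    ord <- order(lp[c_idx], c_idx)
    pool_lp <- lp[c_idx][ord]
    pool_id <- c_idx[ord]
    alive <- rep(TRUE, length(pool_id))
    n_alive <- length(pool_id)
    for (ti in t_idx) {
      take <- integer(0)
      for (r in seq_len(ratio)) {
        if (n_alive == 0L) break
        j <- findInterval(lp[ti], pool_lp[alive])
        cand <- which(alive)
        pick <- if (j <= 0) cand[1] else if (j >= n_alive) cand[n_alive] else {
          lo <- cand[j]; hi <- cand[j + 1]
          if (lp[ti] - pool_lp[lo] <= pool_lp[hi] - lp[ti]) lo else hi
        }
        if (abs(pool_lp[pick] - lp[ti]) > cal) break
        take <- c(take, pick)
        alive[pick] <- FALSE
        n_alive <- n_alive - 1L
      }
      if (length(take) == ratio) {
        pairs[[length(pairs) + 1L]] <-
          data.table::data.table(exposed_id = ids[ti],
                                 control_id = ids[pool_id[take]])
      } else if (length(take)) {
        alive[take] <- TRUE  # incomplete set: release controls
        n_alive <- n_alive + length(take)
      }
    }
  }
  pairs <- if (length(pairs)) data.table::rbindlist(pairs, idcol = "pair_id")
           else data.table::data.table(pair_id = integer(),
                                       exposed_id = character(),
                                       control_id = character())
  matched_ids <- c(unique(pairs$exposed_id), pairs$control_id)
  stopifnot(!anyDuplicated(matched_ids))  # without-replacement contract
  n_unmatched <- sum(expo) - length(unique(pairs$exposed_id))
  keep <- ids %in% matched_ids
  balance <- data.table::data.table(
    covariate = covariates,
    smd_before = vapply(covariates, function(v)
      smd(as.data.frame(data)[[v]], expo), numeric(1)),
    smd_after = vapply(covariates, function(v) {
      if (!nrow(pairs)) return(NA_real_)
      smd(as.data.frame(data)[[v]][keep], expo[keep])
    }, numeric(1)))
  log("match_pairs", exposure = exposure, caliper = cal, ratio = ratio,
      seed = seed, n_exposed = sum(expo), n_matched = length(unique(pairs$exposed_id)),
      n_unmatched = n_unmatched)
  structure(list(pairs = pairs, balance = balance, n_unmatched = n_unmatched,
                 caliper = cal, ratio = as.integer(ratio), seed = seed,
                 exposure = exposure),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d exposed matched 1:%d (%d unmatched dropped)\n",
              length(unique(x$pairs$exposed_id)), x$ratio, x$n_unmatched))
  print(x$balance)
  invisible(x)
}

#' Participant ids retained by a matching
#' @param m a `matched_cohort`.
#' @export
matched_ids <- function(m) unique(c(m$pairs$exposed_id, m$pairs$control_id))
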