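#' Enumerate ordered disease pairs
#'
#' All ordered (D1, D2) pairs from the PheWAS-significant category set:
#' n(n-1) pairs for n categories. Fewer than two categories yields an empty
#' list.
#'
#' @param categories character vector of category codes.
#' @param log optional run logger.
#' @return data.table with columns `d1`, `d2`.
#' @export
enumerate_pairs <- function(categories, log = null_logger()) {
  categories <- unique(categories)
  n <- length(categories)
  if (n < 2L) {
    log("enumerate_pairs", n_categories = n, n_pairs = 0,
        note = "fewer than two categories")
    return(data.table::data.table(d1 = character(), d2 = character()))
  }
  g <- expand.grid(d2 = categories, d1 = categories,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- data.table::as.data.table(g[g$d1 != g$d2, c("d1", "d2")])
  log("enumerate_pairs", n_categories = n, n_pairs = nrow(out))
  data.table::setorderv(out, c("d1", "d2"))[]
}

#' Per-pair temporal co-occurrence counts
#'
#' For each ordered pair, among the given (exposed) participants: the number
#' holding both diagnoses (`n_both`), the number with D2 dated strictly
#' after D1 (`n_d2_after`), and same-day counts (`n_ties`).
#'
#' @param pairs data.table from [enumerate_pairs()].
#' @param events collapsed events restricted as desired.
#' @param participant_ids participants forming the risk population
#'   (typically the exposed arm).
#' @return `pairs` with `n_both`, `n_d2_after`, `n_ties` appended.
#' @export
pair_cooccurrence <- function(pairs, events, participant_ids) {
  ev <- events[events$participant_id %in% as.character(participant_ids)]
  if (!nrow(pairs)) {
    return(data.table::data.table(d1 = character(), d2 = character(),
                                  n_both = integer(), n_d2_after = integer(),
                                  n_ties = integer()))
  }
  out <- data.table::copy(pairs)
  out$n_both <- 0L
  out$n_d2_after <- 0L
  out$n_ties <- 0L
  for (i in seq_len(nrow(out))) {
    e1 <- ev[ev$category == out$d1[i]]
    e2 <- ev[ev$category == out$d2[i]]
    m <- merge(e1[, c("participant_id", "date")],
               e2[, c("participant_id", "date")],
               by = "participant_id", suffixes = c("_1", "_2"))
    out$n_both[i] <- nrow(m)
    out$n_d2_after[i] <- sum(m$date_2 > m$date_1)
    out$n_ties[i] <- sum(m$date_2 == m$date_1)
  }
  out
}

#' Co-occurrence filter
#'
#' Keeps pairs held by strictly more than `floor(fraction x n_exposed)`
#' exposed participants (default fraction 0.5%, i.e. 816 of 163,303).
#'
#' @param pairs output of [pair_cooccurrence()].
#' @param n_exposed exposed-cohort size.
#' @param fraction co-occurrence fraction (default 0.005).
#' @export
cooccurrence_filter <- function(pairs, n_exposed, fraction = 0.005) {
  pairs[pairs$n_both > incidence_threshold(n_exposed, fraction)]
}

#' Exact binomial test of temporal direction
#'
#' Tests whether more than 50% of co-affected participants had D2 diagnosed
#' later than D1. Same-day ties carry no direction evidence and are removed
#' from the trial count. The one-sided p-value is the exact upper binomial
#' tail `P(X >= n_d2_after | n_trials, 1/2)`, accumulated by the
#' multiplicative recurrence over tail terms (no distribution-function
#' shortcut, so the test is checkable against order enumeration). For large
#' counts a normal approximation with continuity correction is available.
#'
#' @param n_d2_after participants with D2 strictly after D1.
#' @param n_both participants with both diagnoses.
#' @param n_ties same-day diagnoses among them.
#' @param method `"exact"` (default), `"approx"`, or `"auto"` (approximate
#'   above 500 trials).
#' @return list: `n_trials`, `fraction` (share D2-later among non-tied),
#'   `p` (one-sided), `testable` (FALSE when every co-occurrence is tied).
#' @export
binomial_direction_test <- function(n_d2_after, n_both, n_ties = 0L,
                                    method = c("exact", "approx", "auto")) {
  method <- match.arg(method)
  stopifnot(n_both >= 0, n_d2_after >= 0, n_ties >= 0,
            n_d2_after + n_ties <= n_both)
  n <- n_both - n_ties
  if (n == 0L) {
    return(list(n_trials = 0L, fraction = NA_real_, p = NA_real_,
                testable = FALSE))
  }
  k <- n_d2_after
  if (method == "auto") method <- if (n > 500) "approx" else "exact"
  p <- if (method == "approx") {
    pnorm((k - 0.5 - n / 2) / sqrt(n / 4), lower.tail = FALSE)
  } else {
    # P(X >= k) = 2^-n * sum_{j=k}^{n} C(n, j), terms by recurrence
    # C(n, j+1) = C(n, j) * (n - j) / (j + 1), accumulated in log space
    if (k <= 0) 1 else {
      lterm <- lchoose(n, k)
      acc <- 1
      term <- 1
      if (k < n) for (j in k:(n - 1L)) {
        term <- term * (n - j) / (j + 1)
        acc <- acc + term
      }
      exp(lterm + log(acc) - n * log(2))
    }
  }
  list(n_trials = n, fraction = k / n, p = min(p, 1), testable = TRUE)
}

#' Logistic confirmation of a disease pair
#'
#' Among exposed participants free of D2 at baseline, a univariate logistic
#' regression of incident D2 on D1 status. Without covariates the odds
#' ratio equals the 2x2 cross-product ratio. A zero cell makes the pair
#' non-estimable (no continuity correction).
#'
#' `anchoring` controls the exposure definition. The default `"ever"` codes
#' D1 as diagnosed at any point during follow-up: this stage tests plain
#' association, with temporal order already enforced by the binomial
#' direction gate. `"temporal"` additionally requires D1 strictly before D2
#' for cases (before end of follow-up for non-cases); note that this gives
#' cases a shorter exposure window than non-cases and so biases the OR of a
#' genuinely amplified pair toward (or below) 1 — it is provided for
#' sensitivity analysis, not as the default.
#'
#' @param participants participant table (needs `assessment_date`,
#'   `censor_date`, optional `death_date`).
#' @param events collapsed events.
#' @param d1,d2 category codes.
#' @param participant_ids risk population (exposed arm).
#' @param adjust optional covariate column names (default none).
#' @param anchoring `"ever"` (default) or `"temporal"`, see Details.
#' @return list: `or`, `ci_low`, `ci_high`, `p`, `n`, `estimable`.
#' @export
logistic_pair_test <- function(participants, events, d1, d2, participant_ids,
                               adjust = character(),
                               anchoring = c("ever", "temporal")) {
  anchoring <- match.arg(anchoring)
  p <- data.table::as.data.table(participants)
  p <- p[as.character(p$participant_id) %in% as.character(participant_ids)]
  assess <- as_date_strict(p$assessment_date)
  end <- pmin(as_date_strict(p$censor_date),
              if ("death_date" %in% names(p)) as_date_strict(p$death_date)
              else as.Date(rep(NA, nrow(p))), na.rm = TRUE)
  t1 <- events$date[events$category == d1][
    match(as.character(p$participant_id),
          events$participant_id[events$category == d1])]
  t2 <- events$date[events$category == d2][
    match(as.character(p$participant_id),
          events$participant_id[events$category == d2])]
  keep <- is.na(t2) | t2 > assess  # D2-free at baseline
  t1 <- t1[keep]; t2 <- t2[keep]; endk <- end[keep]
  y <- as.integer(!is.na(t2))
  x <- if (anchoring == "ever") {
    as.integer(!is.na(t1))
  } else {
    as.integer(ifelse(!is.na(t2),
                      !is.na(t1) & t1 < t2,
                      !is.na(t1) & t1 <= endk))
  }
  base <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, n = length(y), estimable = FALSE)
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  if (any(tab == 0)) return(base)
  df <- data.frame(y = y, x = x, as.data.frame(p)[keep, adjust, drop = FALSE])
  form <- stats::as.formula(paste("y ~ x",
                                  if (length(adjust))
                                    paste("+", paste(adjust, collapse = " + "))
                                  else ""))
  fit <- tryCatch(suppressWarnings(glm(form, data = df, family = binomial())),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(coef(fit)["x"])) return(base)
  b <- coef(fit)["x"]
  se <- sqrt(vcov(fit)["x", "x"])
  if (!is.finite(se) || se > 50) return(base)
  list(or = unname(exp(b)), ci_low = unname(exp(b - 1.959964 * se)),
       ci_high = unname(exp(b + 1.959964 * se)),
       p = unname(2 * pnorm(-abs(b / se))), n = length(y), estimable = TRUE)
}

#' Staged temporal pair inference
#'
#' Runs the full pair pipeline over the PheWAS-significant categories:
#' (1) ordered-pair enumeration, (2) co-occurrence filter among the exposed,
#' (3) exact binomial direction test (Bonferroni denominator = pairs passing
#' the co-occurrence filter), (4) logistic confirmation (denominator = pairs
#' passing direction). A pair is confirmed when the D2-later fraction
#' exceeds 1/2 with a significant binomial test, and OR > 1 with a
#' significant logistic test.
#'
#' @inheritParams logistic_pair_test
#' @param categories significant category codes.
#' @param n_exposed exposed-cohort size for the filters.
#' @param alpha familywise level (default 0.05).
#' @param cooccurrence_fraction default 0.005.
#' @param binom_method passed to [binomial_direction_test()].
#' @param anchoring passed to [logistic_pair_test()].
#' @param log optional run logger.
#' @return data.table with one row per enumerated pair: counts, test
#'   results, `direction_ok`, `association_ok`, `confirmed`, and
#'   `stage_exited` in `cooccurrence`, `direction`, `association`,
#'   `confirmed`.
#' @export
run_pair_inference <- function(participants, events, categories,
                               participant_ids, n_exposed = length(participant_ids),
                               alpha = 0.05, cooccurrence_fraction = 0.005,
                               binom_method = "exact", adjust = character(),
                               anchoring = "ever", log = null_logger()) {
  pairs <- enumerate_pairs(categories, log = log)
  res <- pair_cooccurrence(pairs, events, participant_ids)
  res$fraction_d2_after <- NA_real_
  res$binom_p <- NA_real_
  res$or <- NA_real_; res$or_ci_low <- NA_real_; res$or_ci_high <- NA_real_
  res$logit_p <- NA_real_
  res$direction_ok <- FALSE
  res$association_ok <- FALSE
  thr <- if (nrow(res)) incidence_threshold(n_exposed, cooccurrence_fraction) else 0
  res$passed_cooccurrence <- res$n_both > thr
  n_dir_tests <- sum(res$passed_cooccurrence)
  dir_cut <- if (n_dir_tests) alpha / n_dir_tests else NA_real_
  log("pair_direction_stage", n_pairs = nrow(res), cooccurrence_threshold = thr,
      n_tested = n_dir_tests, bonferroni_cut = dir_cut)
  for (i in which(res$passed_cooccurrence)) {
    bt <- binomial_direction_test(res$n_d2_after[i], res$n_both[i],
                                  res$n_ties[i], method = binom_method)
    res$fraction_d2_after[i] <- bt$fraction
    res$binom_p[i] <- bt$p
    res$direction_ok[i] <- isTRUE(bt$testable) && !is.na(bt$fraction) &&
      bt$fraction > 0.5 && bt$p < dir_cut
  }
  n_assoc_tests <- sum(res$direction_ok)
  assoc_cut <- if (n_assoc_tests) alpha / n_assoc_tests else NA_real_
  log("pair_association_stage", n_tested = n_assoc_tests,
      bonferroni_cut = assoc_cut)
  for (i in which(res$direction_ok)) {
    lt <- logistic_pair_test(participants, events, res$d1[i], res$d2[i],
                             participant_ids, adjust = adjust,
                             anchoring = anchoring)
    res$or[i] <- lt$or
    res$or_ci_low[i] <- lt$ci_low
    res$or_ci_high[i] <- lt$ci_high
    res$logit_p[i] <- lt$p
    res$association_ok[i] <- isTRUE(lt$estimable) && !is.na(lt$or) &&
      lt$or > 1 && lt$p < assoc_cut
  }
  res$confirmed <- res$passed_cooccurrence & res$direction_ok & res$association_ok
  res$stage_exited <- ifelse(res$confirmed, "confirmed",
                      ifelse(!res$passed_cooccurrence, "cooccurrence",
                      ifelse(!res$direction_ok, "direction", "association")))
  attr(res, "direction_cut") <- dir_cut
  attr(res, "association_cut") <- assoc_cut
  res
}
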