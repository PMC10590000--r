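# Small in-code fixtures shared across test files.

# minimal participant table: ids, matching covariates, follow-up window
toy_participants <- function(n, seed = 1, p_exposed = 0.5,
                             exposure_col = "exposed") {
  set.seed(seed)
  p <- data.table::data.table(
    participant_id = sprintf("T%04d", seq_len(n)),
    age = sample(40:69, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    townsend = rnorm(n),
    assessment_date = as.Date("2006-06-01"),
    censor_date = as.Date("2019-06-01"))
  p[[exposure_col]] <- runif(n) < p_exposed
  p
}

# event table in collapsed form (participant_id, category, date)
toy_events <- function(...) {
  rows <- list(...)
  data.table::data.table(
    participant_id = vapply(rows, `[[`, "", 1),
    category = vapply(rows, `[[`, "", 2),
    date = as.Date(vapply(rows, `[[`, "", 3)))
}

# write a two-column mapping file and load it
tmp_mapping <- function(lines, excluded_chapters = c("O", "R")) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(c("icd10_code\tcombined_code\tdescription", lines), f)
  load_mapping(f, excluded_chapters = excluded_chapters)
}

# reachability closure by boolean matrix powers (oracle, independent of igraph)
closure_oracle <- function(adj) {
  n <- nrow(adj)
  r <- adj
  repeat {
    r2 <- (r | (r %*% adj) > 0)
    if (identical(r2, r)) return(r)
    r <- r2
  }
}

# brute-force transitive reduction of a DAG from the closure
transitive_reduction_oracle <- function(adj) {
  r <- closure_oracle(adj)
  keep <- adj
  n <- nrow(adj)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (adj[u, v]) {
      # redundant iff a length >= 2 path u -> w -> v exists
      if (any(adj[u, ] & r[, v] & seq_len(n) != v & seq_len(n) != u)) {
        keep[u, v] <- FALSE
      }
    }
  }
  keep
}

# random DAG adjacency over k nodes (edges only low -> high index);
# isolated nodes dropped since trajectory graphs are built from pairs
random_dag <- function(k, p = 0.35) {
  adj <- matrix(FALSE, k, k)
  for (u in seq_len(k - 1)) for (v in (u + 1):k) {
    if (runif(1) < p) adj[u, v] <- TRUE
  }
  dimnames(adj) <- list(LETTERS[seq_len(k)], LETTERS[seq_len(k)])
  used <- rowSums(adj) > 0 | colSums(adj) > 0
  adj[used, used, drop = FALSE]
}

graph_from_adj <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  cats <- rownames(adj)
  phe <- data.table::data.table(outcome = cats, hr = 2,
                                n_cases_exposed = 10L, n_cases = 10L)
  pairs <- data.table::data.table(d1 = cats[idx[, 1]], d2 = cats[idx[, 2]],
                                  or = 2, n_both = 5L, binom_p = 0.001,
                                  logit_p = 0.001)
  assemble_graph(phe, pairs)
}

adj_from_graph <- function(g, active_only = TRUE) {
  cats <- sort(g$nodes$category)
  adj <- matrix(FALSE, length(cats), length(cats),
                dimnames = list(cats, cats))
  e <- if (active_only) active_edges(g) else g$edges
  if (nrow(e)) adj[cbind(e$d1, e$d2)] <- TRUE
  adj
}
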