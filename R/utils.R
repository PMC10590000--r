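#' @importFrom stats glm binomial coef vcov plogis qlogis rexp rbinom rnorm
#'   runif rgamma sd setNames qnorm pnorm median complete.cases
#' @importFrom utils head modifyList
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage draws
#' its own stream via a deterministic child seed so partial reruns reproduce.
#' Children stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param stream stream label (character) or index.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(paste0(stream)) * seq_along(utf8ToInt(paste0(stream))))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% 2147483647)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_cols <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row %d: '%s' (expected ISO-8601 YYYY-MM-DD)",
                 what, bad[1], as.character(x)[bad[1]]), call. = FALSE)
  }
  out
}

#' Open a JSON-lines run log
#'
#' @param path file path, or `NULL` for a silent sink.
#' @return a logger closure taking `stage` and named fields.
#' @export
run_logger <- function(path = NULL) {
  if (!is.null(path) && !file.exists(path)) file.create(path)
  function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    if (!is.null(path)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
          "\n", sep = "", file = path, append = TRUE)
    }
    invisible(rec)
  }
}

null_logger <- function() function(stage, ...) invisible(NULL)
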