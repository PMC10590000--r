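#' ICD-10 code-to-category mapping
#'
#' Loads the mapping that collapses three-character ICD-10 codes into combined
#' disease categories (diagnoses with high clinical or biological similarity
#' are pooled; the full study mapping reduces 1645 codes to 490 categories).
#' The package ships a small synthetic mapping for testing; analyses of real
#' data supply their own file in the same dialect.
#'
#' @param path tab-separated UTF-8 file with header columns
#'   `icd10_code`, `combined_code` and optionally `description`.
#' @param excluded_chapters chapter letters dropped wholesale from diagnosis
#'   tables. Defaults to `O` (pregnancy/childbirth) and `R` (symptoms and
#'   signs not elsewhere classified).
#' @return an object of class `code_mapping`: a data.table with columns
#'   `icd10_code`, `combined_code`, `description`, carrying the excluded
#'   chapters and the distinct category count as attributes.
#' @export
load_mapping <- function(path, excluded_chapters = c("O", "R")) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", encoding = "UTF-8")
  if (nrow(raw) == 0L) {
    m <- data.table::data.table(icd10_code = character(),
                                combined_code = character(),
                                description = character())
    return(new_code_mapping(m, excluded_chapters))
  }
  assert_cols(raw, c("icd10_code", "combined_code"), "mapping file")
  if (!"description" %in% names(raw)) raw$description <- NA_character_
  bad <- which(!grepl("^[A-Z][0-9]{2}$", raw$icd10_code))
  if (length(bad)) {
    stop(sprintf("malformed ICD-10 code '%s' at mapping line %d (want letter + two digits)",
                 raw$icd10_code[bad[1]], bad[1] + 1L), call. = FALSE)
  }
  # a code listed twice with the same category is deduplicated silently;
  # two different categories for one code is a hard error
  m <- unique(raw[, c("icd10_code", "combined_code", "description")])
  dup <- m$icd10_code[duplicated(m$icd10_code)]
  if (length(dup)) {
    stop(sprintf("ICD-10 code %s maps to more than one combined category",
                 dup[1]), call. = FALSE)
  }
  new_code_mapping(m, excluded_chapters)
}

new_code_mapping <- function(m, excluded_chapters) {
  data.table::setDT(m)
  data.table::setkeyv(m, "icd10_code")
  structure(m, class = c("code_mapping", class(m)),
            excluded_chapters = toupper(excluded_chapters))
}

#' @export
print.code_mapping <- function(x, ...) {
  cat(sprintf("<code_mapping> %d ICD-10 codes -> %d combined categories (chapters %s excluded)\n",
              nrow(x), n_categories(x),
              paste(attr(x, "excluded_chapters"), collapse = ", ")))
  invisible(x)
}

#' Number of distinct combined categories in a mapping
#' @param mapping a `code_mapping`.
#' @export
n_categories <- function(mapping) length(unique(mapping$combined_code))

#' Bundled synthetic code mapping
#'
#' A small stand-in for the study-scale mapping file, used by the simulator
#' and tests. Synthetic: covers only the disease categories of the bundled
#' simulation catalog.
#' @inheritParams load_mapping
#' @export
default_mapping <- function(excluded_chapters = c("O", "R")) {
  load_mapping(system.file("extdata", "icd10_combined_map.tsv",
                           package = "mafldtraj", mustWork = TRUE),
               excluded_chapters = excluded_chapters)
}

#' Collapse raw diagnoses into first-occurrence category events
#'
#' Codes are truncated to their three-character stem, excluded chapters are
#' dropped, codes are collapsed to combined categories, and for participants
#' with multiple records of one category only the first record and the date
#' of the first hospital visit are kept.
#'
#' @param raw data.frame with columns `participant_id`, `icd10_code`,
#'   `date` (ISO-8601 or Date).
#' @param mapping a `code_mapping`.
#' @param unmapped policy for codes absent from the mapping: `"drop"` (skip
#'   with a warning, the default, mirroring restriction to the mapped
#'   category set) or `"strict"` (hard error).
#' @param log optional run logger (see [run_logger()]).
#' @return data.table of events: `participant_id`, `category`, `date`,
#'   at most one row per (participant, category).
#' @export
collapse_events <- function(raw, mapping, unmapped = c("drop", "strict"),
                            log = null_logger()) {
  unmapped <- match.arg(unmapped)
  empty <- data.table::data.table(participant_id = character(),
                                  category = character(), date = as.Date(character()))
  if (nrow(raw) == 0L) return(empty)
  assert_cols(raw, c("participant_id", "icd10_code", "date"), "diagnosis table")
  dt <- data.table::data.table(
    participant_id = as.character(raw$participant_id),
    code = toupper(substr(as.character(raw$icd10_code), 1L, 3L)),
    date = as_date_strict(raw$date, "diagnosis date"))
  excl <- attr(mapping, "excluded_chapters") %||% c("O", "R")
  n0 <- nrow(dt)
  dt <- dt[!substr(dt$code, 1L, 1L) %in% excl, ]
  log("collapse_events", n_in = n0, n_after_chapter_exclusion = nrow(dt),
      excluded_chapters = excl)
  if (nrow(dt) == 0L) return(empty)
  idx <- match(dt$code, mapping$icd10_code)
  if (anyNA(idx)) {
    missing_codes <- sort(unique(dt$code[is.na(idx)]))
    if (unmapped == "strict") {
      stop("unmapped ICD-10 code(s): ", paste(missing_codes, collapse = ", "),
           call. = FALSE)
    }
    warning(sprintf("dropping %d record(s) with unmapped ICD-10 code(s): %s",
                    sum(is.na(idx)), paste(missing_codes, collapse = ", ")),
            call. = FALSE)
    log("collapse_events", dropped_unmapped = sum(is.na(idx)),
        unmapped_codes = missing_codes)
    dt <- dt[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(dt) == 0L) return(empty)
  dt$category <- mapping$combined_code[idx]
  date <- NULL # appease R CMD check
  ev <- dt[, list(date = min(date)), by = c("participant_id", "category")]
  data.table::setkeyv(ev, c("participant_id", "category"))
  ev[]
}

#' Cause-of-death grouping scheme
#'
#' Loads the chapter-level scheme grouping ICD-10 death codes into the 16
#' cause-of-death categories used throughout the death-trajectory workflow.
#' @param path tab-separated file with columns `chapter_prefix`,
#'   `cause_category`, `description`; `NULL` loads the bundled default.
#' @return a `death_scheme` data.table keyed by chapter letter.
#' @export
load_death_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "death_cause_scheme.tsv",
                        package = "mafldtraj", mustWork = TRUE)
  }
  s <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character", encoding = "UTF-8")
  assert_cols(s, c("chapter_prefix", "cause_category"), "death scheme")
  structure(s, class = c("death_scheme", class(s)))
}

#' Map death-certificate ICD-10 codes to cause-of-death categories
#'
#' Primary and secondary causes are treated alike; duplicate categories merge.
#' Codes whose chapter is outside the scheme (e.g. O, U, Z) are dropped.
#'
#' @param codes character vector of ICD-10 codes (3+ characters).
#' @param scheme a `death_scheme` (default: bundled 16-category scheme).
#' @return sorted character vector of distinct cause categories.
#' @export
group_death_causes <- function(codes, scheme = load_death_scheme()) {
  codes <- toupper(codes[!is.na(codes) & nzchar(codes)])
  if (length(codes) == 0L) return(character())
  idx <- match(substr(codes, 1L, 1L), scheme$chapter_prefix)
  sort(unique(scheme$cause_category[idx[!is.na(idx)]]))
}

#' Chapter group of a combined disease category
#'
#' Used by the sensitivity exclusion: disease categories are assigned to the
#' same chapter-level groups as the 16 causes of death, via the first letter
#' of the combined category code.
#' @param categories character vector of combined category codes.
#' @inheritParams group_death_causes
#' @return character vector of group labels (`NA` for unknown chapters).
#' @export
category_system_group <- function(categories, scheme = load_death_scheme()) {
  idx <- match(substr(toupper(categories), 1L, 1L), scheme$chapter_prefix)
  scheme$cause_category[idx]
}
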