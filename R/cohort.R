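#' Read a registry case listing
#'
#' Parses a SEER*Stat-style case-listing CSV into a cohort data frame with one
#' row per case. Rows that cannot be parsed (non-numeric survival months,
#' sex or vital status outside the vocabulary) are collected into a
#' `"parse_errors"` attribute, never silently dropped.
#'
#' Logical columns (map file columns to these via `schema`):
#' `id`, `sex`, `race`, `age_dx`, `dx_year`, `dx_month`, `survival_months`,
#' `vital_status`, `histology`, `site`, `nodal`, `area`, `autopsy_dco`,
#' `sequence`. Only the demographic/follow-up columns are required; tumour
#' and flag columns default to missing/benign values when absent.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping logical column names to file
#'   column names (identity by default).
#' @return A data.frame of class `cohort`, with attribute `parse_errors`
#'   (data.frame of row numbers and reasons; zero rows when clean).
#' @export
read_case_listing <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("case listing not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sex", "race", "age_dx", "dx_year", "survival_months",
                "vital_status")
  optional <- c("id", "dx_month", "histology", "site", "nodal", "area",
                "autopsy_dco", "sequence")
  if (is.null(schema)) schema <- character(0)
  schema <- unlist(schema)
  have <- function(col) {
    fc <- if (col %in% names(schema)) unname(schema[col]) else col
    if (fc %in% names(raw)) fc else NA_character_
  }
  absent <- required[is.na(vapply(required, have, character(1)))]
  if (length(absent)) {
    stop("case listing: required column(s) not found: ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(raw)
  get <- function(col, default) {
    fc <- have(col)
    if (is.na(fc)) rep(default, n) else raw[[fc]]
  }
  df <- data.frame(
    id = as.character(get("id", NA_character_)),
    sex = tolower(trimws(as.character(raw[[have("sex")]]))),
    race = as.character(raw[[have("race")]]),
    age_dx = suppressWarnings(as.integer(raw[[have("age_dx")]])),
    dx_year = suppressWarnings(as.integer(raw[[have("dx_year")]])),
    dx_month = suppressWarnings(as.integer(get("dx_month", NA_integer_))),
    survival_months = suppressWarnings(as.integer(raw[[have("survival_months")]])),
    vital_status = tolower(trimws(as.character(raw[[have("vital_status")]]))),
    histology = as.character(get("histology", NA_character_)),
    site = as.character(get("site", NA_character_)),
    nodal = as.character(get("nodal", NA_character_)),
    area = as.character(get("area", NA_character_)),
    autopsy_dco = as.logical(get("autopsy_dco", FALSE)),
    sequence = suppressWarnings(as.integer(get("sequence", 0L))),
    stringsAsFactors = FALSE
  )
  if (n > 0 && all(is.na(df$id))) df$id <- sprintf("case%06d", seq_len(n))

  errs <- list()
  note <- function(rows, reason) {
    if (length(rows)) errs[[length(errs) + 1L]] <<-
        data.frame(row = rows, reason = reason)
  }
  surv_raw <- as.character(raw[[have("survival_months")]])
  note(which(is.na(df$survival_months) & !is.na(surv_raw) &
               trimws(surv_raw) != "" & tolower(trimws(surv_raw)) != "na"),
       "unparseable survival_months")
  note(which(!df$sex %in% c("male", "female", NA)), "sex outside vocabulary")
  note(which(!df$vital_status %in% c("alive", "dead", NA)),
       "vital status outside vocabulary")
  parse_errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), reason = character(0))
  bad_rows <- unique(parse_errors$row)
  out <- df[setdiff(seq_len(n), bad_rows), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  attr(out, "parse_errors") <- parse_errors
  out
}

#' Inclusion and exclusion filtering of registry cases
#'
#' Keeps cases that are older than 15 years at diagnosis, are a first or only
#' primary tumour, are not known only through autopsy or a death certificate,
#' have complete required fields, and are not alive without a survival time.
#' When several criteria fire for one record it is counted once, under the
#' highest-precedence reason: `autopsy_dco` > `age_15_or_under` >
#' `multiple_primary` > `incomplete_data` > `alive_no_survival_time`.
#'
#' @param records a `cohort` data frame ([read_case_listing()]).
#' @param config list of options: `min_age` (default 16, i.e. "age > 15"),
#'   `keep_sequence` (sequence codes kept, default `c(0, 1)`: only/first
#'   primary).
#' @return list with elements `kept` (the filtered cohort) and `report`
#'   (a `filter_report`: input/kept counts, per-reason exclusion counts,
#'   per-record reason log).
#' @export
apply_inclusion_filters <- function(records, config = list()) {
  min_age <- config$min_age %||% 16L
  keep_seq <- config$keep_sequence %||% c(0L, 1L)
  required_fields <- c("sex", "race", "age_dx", "dx_year", "vital_status")

  n <- nrow(records)
  reason <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)

  dco <- isTRUE_vec(records$autopsy_dco)
  young <- !is.na(records$age_dx) & records$age_dx < min_age
  multi <- !is.na(records$sequence) & !(records$sequence %in% keep_seq)
  inc_field <- apply(is.na(records[required_fields]), 1L, function(z) {
    if (any(z)) required_fields[which(z)[1]] else NA_character_
  })
  dead <- !is.na(records$vital_status) & records$vital_status == "dead"
  inc_field[is.na(inc_field) & dead & is.na(records$survival_months)] <-
    "survival_months"
  incomplete <- !is.na(inc_field)
  alive <- !is.na(records$vital_status) & records$vital_status == "alive"
  no_surv <- alive & (is.na(records$survival_months) | records$survival_months < 0)

  # fixed precedence; each record counted once
  set <- function(mask, r) {
    hit <- mask & is.na(reason)
    reason[hit] <<- r
    hit
  }
  set(dco, "autopsy_dco")
  set(young, "age_15_or_under")
  set(multi, "multiple_primary")
  hit <- set(incomplete, "incomplete_data")
  detail[hit] <- inc_field[hit]
  set(no_surv, "alive_no_survival_time")

  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("cohort", "data.frame")
  excl <- table(reason[!is.na(reason)])
  report <- structure(
    list(n_input = n, n_kept = nrow(kept),
         exclusions = stats::setNames(as.integer(excl), names(excl)),
         log = data.frame(id = records$id, reason = reason,
                          missing_field = detail, stringsAsFactors = FALSE)),
    class = "filter_report"
  )
  stopifnot(report$n_input == report$n_kept + sum(report$exclusions))
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d kept, %d excluded\n",
              x$n_input, x$n_kept, x$n_input - x$n_kept))
  if (length(x$exclusions)) {
    for (r in names(x$exclusions)) cat(sprintf("  %-24s %d\n", r, x$exclusions[[r]]))
  }
  invisible(x)
}

#' Serialize a filter report to JSON
#' @param report a `filter_report`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
filter_report_json <- function(report, path = NULL) {
  obj <- list(n_input = report$n_input, n_kept = report$n_kept,
              exclusions = as.list(report$exclusions))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Default histology-code map for the six major NHL subtypes
#'
#' Loads the shipped morphology-code table mapping ICD-O-3 codes to subtype
#' labels (CLL/SLL, DLBCL, FL, MCL, MZL, PTCL). The mapping is configuration
#' data, not code: edit the CSV (columns `morph_low`, `morph_high`, `label`)
#' or pass your own data frame to [classify_subtype()] to track revisions of
#' the lymphoma classification.
#'
#' @return data.frame with columns `morph_low`, `morph_high`, `label`.
#' @export
default_subtype_map <- function() {
  utils::read.csv(system.file("extdata", "subtype_map.csv",
                              package = "periodsurv"),
                  stringsAsFactors = FALSE)
}

#' Classify histology codes into subtype labels
#'
#' @param histology character vector of ICD-O-3 morphology codes with
#'   behaviour digit, e.g. `"9680/3"`.
#' @param subtype_map data.frame with `morph_low`, `morph_high`, `label`
#'   (inclusive code ranges); default [default_subtype_map()].
#' @return character vector of labels; codes outside the map become
#'   `"other"`. A behaviour digit other than 3 (malignant) is an error.
#' @export
classify_subtype <- function(histology, subtype_map = default_subtype_map()) {
  m <- regmatches(histology, regexec("^([0-9]{4})/([0-9])$", histology))
  bad <- which(!is.na(histology) & lengths(m) != 3L)
  if (length(bad)) stop("malformed histology code: ", histology[bad[1]])
  morph <- vapply(m, function(z) if (length(z) == 3L) as.integer(z[2]) else NA_integer_,
                  integer(1))
  behav <- vapply(m, function(z) if (length(z) == 3L) as.integer(z[3]) else NA_integer_,
                  integer(1))
  nonmal <- which(!is.na(behav) & behav != 3L)
  if (length(nonmal)) {
    stop("non-malignant behavior digit in histology code: ",
         histology[nonmal[1]])
  }
  out <- rep(NA_character_, length(histology))
  known <- !is.na(morph)
  out[known] <- "other"
  for (i in seq_len(nrow(subtype_map))) {
    hit <- known & morph >= subtype_map$morph_low[i] &
      morph <= subtype_map$morph_high[i]
    out[hit] <- subtype_map$label[i]
  }
  out
}

#' Assign diagnosis ages to age groups
#'
#' Half-open bins `[lo, hi)`; the default bins are 15-44, 45-54, 55-64,
#' 65-74 and 75+ years.
#'
#' @param age_dx integer ages at diagnosis.
#' @param breaks lower bin edges plus `Inf`, default
#'   `c(15, 45, 55, 65, 75, Inf)`.
#' @param labels bin labels, default `c("15-44","45-54","55-64","65-74","75+")`.
#' @return factor of age-group labels.
#' @export
assign_age_group <- function(age_dx,
                             breaks = c(15, 45, 55, 65, 75, Inf),
                             labels = c("15-44", "45-54", "55-64", "65-74", "75+")) {
  if (any(!is.na(age_dx) & age_dx < breaks[1])) {
    stop("age below the first age-group bin (", breaks[1], ")")
  }
  cut(age_dx, breaks = breaks, labels = labels, right = FALSE)
}

#' Partition a cohort into analysis strata
#'
#' @param records a `cohort` data frame.
#' @param by character vector of stratifiers from `sex`, `race`, `age_group`,
#'   `subtype`, `nodal`, `area`, `overall`. `age_group` and `subtype` are
#'   derived on the fly when not already columns. `"overall"` (or an empty
#'   `by`) yields a single stratum.
#' @return named list of cohort data frames; the names are stratum keys
#'   (levels joined by `" | "` across stratifiers). The strata partition the
#'   input.
#' @export
stratify_cohort <- function(records, by = "overall") {
  allowed <- c("sex", "race", "age_group", "subtype", "nodal", "area", "overall")
  bad <- setdiff(by, allowed)
  if (length(bad)) stop("unknown stratifier(s): ", paste(bad, collapse = ", "))
  if (length(by) == 0L || identical(by, "overall")) {
    return(stats::setNames(list(records), "overall"))
  }
  by <- setdiff(by, "overall")
  cols <- lapply(by, function(b) {
    if (b %in% names(records)) return(as.character(records[[b]]))
    switch(b,
      age_group = as.character(assign_age_group(records$age_dx)),
      subtype = classify_subtype(records$histology),
      stop("stratifier not derivable: ", b)
    )
  })
  key <- do.call(paste, c(cols, sep = " | "))
  idx <- split(seq_len(nrow(records)), key)
  lapply(idx, function(i) {
    out <- records[i, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("cohort", "data.frame")
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
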