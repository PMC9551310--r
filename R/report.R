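#' Run configuration
#'
#' Builds (and validates) the configuration object driving [run_analysis()].
#' Round-trippable through JSON; every run writes its resolved configuration
#' next to its outputs.
#'
#' @param cases path to a case-listing CSV, or an in-memory `cohort`.
#' @param lifetable path to a life-table CSV, or a [lifetable] object.
#' @param output_dir directory for rendered outputs (`NULL` = don't write).
#' @param windows list of window definitions, each
#'   `list(mode, start, end, k)`; defaults to the three 5-year period
#'   windows 2004-2008, 2009-2013, 2014-2018 with k = 5.
#' @param stratifiers character vector for [stratify_cohort()].
#' @param weights named age-standardization weights ([icss_weights()]).
#' @param projection list: `enabled`, `link`, `target_label`,
#'   `target_p` (default one period past the fitted ones).
#' @param case_schema,lifetable_schema column-name maps for the readers.
#' @param filter_config options for [apply_inclusion_filters()].
#' @param seed integer seed (used by the optional projection bootstrap).
#' @return list of class `run_config`.
#' @export
run_config <- function(cases, lifetable, output_dir = NULL,
                       windows = NULL,
                       stratifiers = "overall",
                       weights = icss_weights(),
                       projection = list(enabled = TRUE, link = "cloglog",
                                         target_label = "2019-2023",
                                         target_p = NULL),
                       case_schema = NULL, lifetable_schema = NULL,
                       filter_config = list(), seed = 1L) {
  if (is.null(windows)) {
    windows <- list(list(mode = "period", start = 2004, end = 2008, k = 5),
                    list(mode = "period", start = 2009, end = 2013, k = 5),
                    list(mode = "period", start = 2014, end = 2018, k = 5))
  }
  cfg <- list(cases = cases, lifetable = lifetable, output_dir = output_dir,
              windows = windows, stratifiers = stratifiers,
              weights = weights, projection = projection,
              case_schema = case_schema, lifetable_schema = lifetable_schema,
              filter_config = filter_config, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  for (w in cfg$windows) {
    if (!all(c("mode", "start", "end") %in% names(w))) {
      stop("run config: each window needs mode, start, end")
    }
    if (!w$mode %in% c("period", "cohort")) {
      stop("run config: unknown window mode ", w$mode)
    }
  }
  allowed <- c("sex", "race", "age_group", "subtype", "nodal", "area", "overall")
  bad <- setdiff(cfg$stratifiers, allowed)
  if (length(bad)) stop("run config: unknown stratifier(s): ",
                        paste(bad, collapse = ", "))
  if (is.character(cfg$cases) && !file.exists(cfg$cases)) {
    stop("run config: case listing not found: ", cfg$cases)
  }
  if (is.character(cfg$lifetable) && !file.exists(cfg$lifetable)) {
    stop("run config: life table not found: ", cfg$lifetable)
  }
  invisible(cfg)
}

#' Read / write a run configuration as JSON
#'
#' Only path-valued `cases`/`lifetable` entries survive serialization;
#' in-memory objects are recorded as `"<in-memory>"`.
#'
#' @param path JSON path.
#' @return [read_run_config()]: a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$windows <- if (is.data.frame(obj$windows)) {
    lapply(seq_len(nrow(obj$windows)), function(i) as.list(obj$windows[i, ]))
  } else obj$windows
  obj$weights <- unlist(obj$weights)
  do.call(run_config, obj)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  if (!is.character(obj$cases)) obj$cases <- "<in-memory>"
  if (!is.character(obj$lifetable)) obj$lifetable <- "<in-memory>"
  obj$weights <- as.list(obj$weights)  # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run a full period-analysis from a configuration
#'
#' Reads (or accepts) the cohort and life table, applies the inclusion
#' filters, and for every stratum and analysis window estimates the k-year
#' relative survival with its Greenwood standard error; adds an
#' age-standardized row per stratum when age groups are estimable; fits the
#' projection model per stratum over the windows and appends the projected
#' target period. Also assembles a descriptive-counts table (cases per
#' window by stratum). When `config$output_dir` is set, writes tidy and
#' formatted tables, the filter report, the projection metadata and the
#' resolved configuration there.
#'
#' @param config a [run_config()] (or a path to its JSON form).
#' @return list of class `period_analysis`: `estimates` (tidy data.frame),
#'   `wide` (formatted table), `counts`, `filter_report`, `projections`
#'   (per-stratum `projection_result`s), `config`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)

  lt <- if (inherits(config$lifetable, "lifetable")) config$lifetable else
    load_lifetable(config$lifetable, config$lifetable_schema)
  cohort <- if (is.character(config$cases)) {
    read_case_listing(config$cases, config$case_schema)
  } else config$cases

  flt <- apply_inclusion_filters(cohort, config$filter_config)
  kept <- flt$kept
  strata <- stratify_cohort(kept, config$stratifiers)
  if (!identical(config$stratifiers, "overall") &&
      length(config$stratifiers) > 0) {
    strata <- c(stats::setNames(list(kept), "overall"), strata)
  }
  windows <- lapply(config$windows, function(w) {
    analysis_window(w$mode, w$start, w$end, w$k %||% 5L)
  })
  win_labels <- vapply(windows, function(w) sprintf("%d-%d", w$start, w$end),
                       character(1))

  rows <- list(); projections <- list()
  for (s in names(strata)) {
    sub <- strata[[s]]
    ests <- lapply(windows, function(w) relative_survival(sub, w, lt))
    for (i in seq_along(ests)) {
      k <- windows[[i]]$k
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, window = win_labels[i], standardized = FALSE,
        n_cases = attr(attr(ests[[i]], "riskset"), "n_contributing"),
        R = ests[[i]]$R[k], se_R = ests[[i]]$se_R[k],
        stringsAsFactors = FALSE
      )
      std <- standardized_rs_for(sub, windows[[i]], lt, config$weights)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, window = win_labels[i], standardized = TRUE,
        n_cases = NA_integer_, R = std[["R_std"]], se_R = std[["se_std"]],
        stringsAsFactors = FALSE
      )
    }
    if (isTRUE(config$projection$enabled) && length(windows) >= 2L) {
      proj <- tryCatch({
        grid <- build_conditional_grid(ests, period_labels = win_labels)
        link <- config$projection$link
        if (length(link) == 0) link <- "cloglog"
        fit <- fit_projection_model(grid, link)
        target_p <- config$projection$target_p
        if (length(target_p) == 0) target_p <- length(windows) + 1L
        predict_future_period(fit, target_p)
      }, error = function(e) structure(list(error = conditionMessage(e)),
                                       class = "projection_failure"))
      projections[[s]] <- proj
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s,
        window = paste0("projected:",
                        config$projection$target_label %||% "next period"),
        standardized = FALSE, n_cases = NA_integer_,
        R = if (inherits(proj, "projection_result")) proj$R_hat else NA_real_,
        se_R = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  estimates <- do.call(rbind, rows)

  counts <- descriptive_counts(kept, windows, win_labels)
  wide <- format_wide(estimates)

  out <- structure(
    list(estimates = estimates, wide = wide, counts = counts,
         filter_report = flt$report, projections = projections,
         config = config),
    class = "period_analysis"
  )
  if (!is.null(config$output_dir)) render_tables(out, dir = config$output_dir)
  out
}

# age-standardized R_k for one stratum x window (NA when any weighted age
# group is inestimable)
standardized_rs_for <- function(sub, window, lt, weights) {
  by_age <- split(sub, assign_age_group(sub$age_dx))
  est <- lapply(names(weights), function(g) {
    if (is.null(by_age[[g]]) || nrow(by_age[[g]]) == 0L) {
      return(c(R = NA_real_, se_R = NA_real_))
    }
    e <- relative_survival(by_age[[g]], window, lt)
    c(R = e$R[window$k], se_R = e$se_R[window$k])
  })
  age_standardized_rs(
    data.frame(age_group = names(weights),
               R = vapply(est, `[[`, numeric(1), "R"),
               se_R = vapply(est, `[[`, numeric(1), "se_R")),
    weights
  )
}

descriptive_counts <- function(kept, windows, win_labels) {
  do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    inw <- kept[kept$dx_year >= w$start & kept$dx_year <= w$end, ]
    data.frame(window = win_labels[i], n = nrow(inw),
               n_male = sum(inw$sex == "male"),
               n_female = sum(inw$sex == "female"),
               median_age = stats::median(inw$age_dx),
               stringsAsFactors = FALSE)
  }))
}

#' Format a relative-survival value as a percentage string
#'
#' `"73.3 ± 0.3"` style: `100 * R` rounded half-even to one decimal, an
#' em-dash for undefined values.
#'
#' @param R,se_R numeric vectors on the probability scale.
#' @return character vector.
#' @export
format_rs <- function(R, se_R = NA) {
  n <- max(length(R), length(se_R))
  R <- rep_len(R, n); se_R <- rep_len(se_R, n)
  out <- ifelse(
    is.na(R), "—",
    ifelse(is.na(se_R),
           trimws(format(round(100 * R, 1), nsmall = 1)),
           paste0(trimws(format(round(100 * R, 1), nsmall = 1)), " ± ",
                  trimws(format(round(100 * se_R, 1), nsmall = 1))))
  )
  out
}

format_wide <- function(estimates) {
  crude <- estimates[!estimates$standardized, ]
  crude$cell <- format_rs(crude$R, crude$se_R)
  wins <- unique(crude$window)
  strata <- unique(crude$stratum)
  wide <- data.frame(stratum = strata, stringsAsFactors = FALSE)
  for (w in wins) {
    col <- crude$cell[match(paste(strata, w),
                            paste(crude$stratum, crude$window))]
    wide[[w]] <- ifelse(is.na(col), "—", col)
  }
  wide
}

#' Render analysis tables to files
#'
#' Writes, into `dir`: `estimates.csv` (tidy, raw unrounded values),
#' `estimates_wide.csv` and `estimates_wide.md` (formatted percentages,
#' identical numbers), `counts.csv`, `filter_report.json`,
#' `projection.json` (per-stratum model metadata) and `run_config.json`.
#' Column order is deterministic and re-running the same configuration
#' byte-reproduces every file.
#'
#' @param x a `period_analysis` from [run_analysis()].
#' @param format subset of `c("csv", "markdown")`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(x, format = c("csv", "markdown"), dir = ".") {
  stopifnot(inherits(x, "period_analysis"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
    paths <<- c(paths, p)
  }
  if ("csv" %in% format) {
    wr(x$estimates, "estimates.csv")
    wr(x$wide, "estimates_wide.csv")
    wr(x$counts, "counts.csv")
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "estimates_wide.md")
    writeLines(markdown_table(x$wide), p)
    paths <- c(paths, p)
  }
  filter_report_json(x$filter_report, file.path(dir, "filter_report.json"))
  proj_meta <- lapply(x$projections, function(pr) {
    if (inherits(pr, "projection_result")) {
      jsonlite::fromJSON(projection_json(pr))
    } else list(error = pr$error)
  })
  jsonlite::write_json(proj_meta, file.path(dir, "projection.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_run_config(x$config, file.path(dir, "run_config.json"))
  paths <- c(paths, file.path(dir, c("filter_report.json", "projection.json",
                                     "run_config.json")))
  invisible(paths)
}

markdown_table <- function(df) {
  esc <- function(v) gsub("\\|", "\\\\|", as.character(v))
  header <- paste0("| ", paste(esc(names(df)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(esc(r), collapse = " | "), " |"))
  c(header, sep, body)
}

#' @export
print.period_analysis <- function(x, ...) {
  cat("Period-analysis relative survival\n\n")
  print.data.frame(x$wide, row.names = FALSE)
  cat("\n")
  print(x$filter_report)
  invisible(x)
}
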