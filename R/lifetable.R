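#' Population expected-survival life tables
#'
#' A `lifetable` stores annual probabilities of surviving one further year for
#' the general population, indexed by single year of age (0--99), calendar
#' year, sex and race. It is the background mortality source for the
#' Ederer II expected-survival estimator: for every patient still at risk at
#' the start of a follow-up interval, the matching population probability is
#' looked up at the patient's attained age and calendar year.
#'
#' @section Clamping:
#' Registry follow-up routinely extends past the last published life-table
#' year, and attained ages can exceed 99. Lookups clamp age to 99 and the
#' calendar year to the table's range; the number of clamped lookups is
#' returned as an attribute so analyses stay auditable. Sex and race must
#' match a stored stratum exactly -- there is no silent fallback.
#'
#' @name lifetable
NULL

#' Construct a life table from a data frame
#'
#' @param df data.frame with columns `age`, `year`, `sex`, `race`,
#'   `surv_prob` (annual probability of surviving one year, in (0, 1]).
#' @return An object of class `lifetable`.
#' @export
lifetable <- function(df) {
  req <- c("age", "year", "sex", "race", "surv_prob")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("life table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$age <- as.integer(df$age)
  df$year <- as.integer(df$year)
  df$sex <- as.character(df$sex)
  df$race <- as.character(df$race)
  df$surv_prob <- as.numeric(df$surv_prob)

  bad <- which(!is.finite(df$surv_prob) | df$surv_prob <= 0 | df$surv_prob > 1)
  if (length(bad)) {
    stop(sprintf(
      "life table: surv_prob outside (0,1] at row %d (age=%d, year=%d, sex=%s, race=%s, surv_prob=%g)",
      bad[1], df$age[bad[1]], df$year[bad[1]], df$sex[bad[1]], df$race[bad[1]],
      df$surv_prob[bad[1]]
    ))
  }
  if (anyNA(df[req])) stop("life table contains missing values")

  ages <- 0:99
  years <- sort(unique(df$year))
  if (!identical(years, min(years):max(years))) {
    stop("life table calendar years are not contiguous: ",
         paste(setdiff(min(years):max(years), years), collapse = ", "),
         " missing")
  }
  sexes <- sort(unique(df$sex))
  races <- sort(unique(df$race))

  key <- paste(df$age, df$year, df$sex, df$race)
  if (anyDuplicated(key)) {
    stop("life table has duplicate (age, year, sex, race) rows, e.g. ",
         key[which(duplicated(key))[1]])
  }

  # dense array [age 0..99, year, sex, race]; any gap stays NA and is rejected
  arr <- array(NA_real_,
               dim = c(length(ages), length(years), length(sexes), length(races)),
               dimnames = list(age = ages, year = years, sex = sexes, race = races))
  idx <- cbind(df$age + 1L,
               match(df$year, years),
               match(df$sex, sexes),
               match(df$race, races))
  if (any(df$age < 0 | df$age > 99)) stop("life table ages must lie in 0..99")
  arr[idx] <- df$surv_prob
  if (anyNA(arr)) {
    hole <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "life table has a gap: age %s missing for year=%s, sex=%s, race=%s",
      ages[hole[1]], years[hole[2]], sexes[hole[3]], races[hole[4]]
    ))
  }

  structure(
    list(prob = arr, year_range = c(min(years), max(years)),
         sexes = sexes, races = races),
    class = "lifetable"
  )
}

#' Read a population life table from CSV
#'
#' Reads a CSV export of annual expected-survival probabilities and validates
#' it: probabilities in (0, 1], the full 0--99 age range in every
#' (year, sex, race) stratum, contiguous calendar years, no duplicates.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named character vector mapping the logical column names
#'   `age`, `year`, `sex`, `race`, `surv_prob` to the file's column names.
#'   Defaults to the identity mapping.
#' @return A `lifetable` object.
#' @examples
#' tab <- simulate_lifetable(simulation_spec(seed = 1))
#' tf <- tempfile(fileext = ".csv")
#' write_lifetable(tab, tf)
#' tab2 <- load_lifetable(tf)
#' annual_expected_survival(tab2, age = 70, year = 2014,
#'                          sex = "male", race = "white")
#' @export
load_lifetable <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- remap_schema(raw, schema,
                     required = c("age", "year", "sex", "race", "surv_prob"),
                     what = "life table")
  lifetable(df)
}

#' Write a life table to CSV
#'
#' Inverse of [load_lifetable()] with the default schema.
#'
#' @param table a `lifetable`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.lifetable <- function(x, ...) {
  d <- dimnames(x$prob)
  grid <- expand.grid(age = as.integer(d$age), year = as.integer(d$year),
                      sex = d$sex, race = d$race,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$surv_prob <- as.vector(x$prob)
  grid
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Population life table\n")
  cat(sprintf("  ages 0-99, years %d-%d\n", x$year_range[1], x$year_range[2]))
  cat("  sexes:", paste(x$sexes, collapse = ", "), "\n")
  cat("  races:", paste(x$races, collapse = ", "), "\n")
  invisible(x)
}

#' Annual expected survival probability lookup
#'
#' Returns the population probability of surviving one further year at the
#' given attained age and calendar year. Vectorised over `age`, `year`, `sex`
#' and `race` (recycled to a common length). Ages above 99 are clamped to 99
#' and years outside the table's range are clamped to its edges; the number
#' of clamped lookups is attached as attribute `"clamped"`.
#'
#' @param table a `lifetable`.
#' @param age attained age(s) in years.
#' @param year attained calendar year(s).
#' @param sex,race stratum labels; must exist in the table.
#' @return Numeric vector of probabilities with attribute `clamped`.
#' @export
annual_expected_survival <- function(table, age, year, sex, race) {
  stopifnot(inherits(table, "lifetable"))
  n <- max(length(age), length(year), length(sex), length(race))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  sex <- rep_len(as.character(sex), n)
  race <- rep_len(as.character(race), n)

  si <- match(sex, table$sexes)
  ri <- match(race, table$races)
  if (anyNA(si)) stop("unknown sex stratum: ", sex[which(is.na(si))[1]])
  if (anyNA(ri)) stop("unknown race stratum: ", race[which(is.na(ri))[1]])
  if (any(age < 0)) stop("negative age in life-table lookup")

  a <- pmin(floor(age), 99)
  y <- pmin(pmax(floor(year), table$year_range[1]), table$year_range[2])
  clamped <- sum(a != floor(age) | y != floor(year))

  yi <- y - table$year_range[1] + 1L
  p <- table$prob[cbind(a + 1L, yi, si, ri)]
  attr(p, "clamped") <- clamped
  p
}

# Rename file columns to logical names according to a schema map.
remap_schema <- function(df, schema, required, what) {
  if (is.null(schema)) schema <- stats::setNames(required, required)
  schema <- unlist(schema)
  miss_map <- setdiff(required, names(schema))
  if (length(miss_map)) {
    schema[miss_map] <- miss_map
  }
  absent <- setdiff(unname(schema[required]), names(df))
  if (length(absent)) {
    stop(what, ": required column(s) not found in file: ",
         paste(absent, collapse = ", "))
  }
  out <- df[unname(schema[required])]
  names(out) <- required
  extra <- setdiff(names(df), unname(schema[required]))
  if (length(extra)) out <- cbind(out, df[extra])
  out
}
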