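#' Specification of a synthetic registry study
#'
#' Bundles everything needed to generate a population life table and a
#' registry cohort with known excess-hazard structure: diagnosis-period
#' layout, cohort sizes, demographic mixes, a Gompertz-Makeham background
#' mortality hazard `mu(age) = a + b * c^age` with sex multipliers, a
#' piecewise-constant excess hazard `lambda[j, p]` per follow-up year j and
#' diagnosis period p, administrative censoring at a cutoff date, optional
#' uniform loss to follow-up, and a seed. Because the excess hazard acts
#' additively on the annual hazard scale, the implied k-year relative
#' survival has the exact closed form `prod(exp(-lambda[1:k, p]))`
#' ([true_relative_survival()]), independent of the demographic mix.
#'
#' The defaults emulate the study conditions of a US registry NHL cohort:
#' four diagnosis blocks 2000-2003, 2004-2008, 2009-2013 and 2014-2018,
#' follow-up through December 2019, the age/sex/race mix of a typical NHL
#' case series, and an excess hazard of 0.10/yr in the earliest periods
#' declining by a factor `exp(-0.1)` per later 5-year period.
#'
#' @param n_per_period cohort size(s) per diagnosis period (recycled).
#' @param periods list of integer vectors of diagnosis years.
#' @param lambda k x P matrix of annual excess hazards (rows: follow-up
#'   years, recycled downward past the last row; columns: periods).
#' @param age_bands data.frame with `low`, `high`, `prob`: diagnosis-age mix
#'   (uniform over integer ages within each band).
#' @param sex_probs,race_probs named probability vectors.
#' @param background list `a`, `b`, `c`: Gompertz-Makeham parameters of the
#'   annual background hazard.
#' @param sex_mult named multipliers on the background hazard by sex.
#' @param year_drift proportional change of the background hazard per
#'   calendar year (0 = time-constant life table).
#' @param cutoff list `year`, `month`: administrative censoring date
#'   (follow-up known through the end of that month).
#' @param loss_rate annual hazard of uniform loss to follow-up (0 = none).
#' @param dco_rate,multi_primary_rate,under_age_rate fractions of records
#'   flagged autopsy/DCO, given a later tumour-sequence number, or aged below
#'   16 -- all 0 by default so the generated cohort passes the inclusion
#'   filters unchanged; raise them to exercise the filters.
#' @param seed integer seed; a fixed seed gives byte-identical output, and
#'   per-patient draw blocks keep early patients stable when only the cohort
#'   size grows.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(
    n_per_period = c(12000, 15000, 15000, 15000),
    periods = list(2000:2003, 2004:2008, 2009:2013, 2014:2018),
    lambda = NULL,
    age_bands = data.frame(low = c(16, 45, 55, 65, 75),
                           high = c(44, 54, 64, 74, 95),
                           prob = c(0.12, 0.13, 0.23, 0.26, 0.26)),
    sex_probs = c(male = 0.55, female = 0.45),
    race_probs = c(white = 0.66, black = 0.08, api = 0.085,
                   aian = 0.005, hispanic = 0.17),
    background = list(a = 0.001, b = 5e-5, c = 1.09),
    sex_mult = c(male = 1.25, female = 0.80),
    year_drift = 0,
    cutoff = list(year = 2019, month = 12),
    loss_rate = 0,
    dco_rate = 0, multi_primary_rate = 0, under_age_rate = 0,
    seed = 1L) {
  P <- length(periods)
  if (is.null(lambda)) {
    # 0.10/yr in the two earliest blocks, then exp(-0.1) improvement per period
    trend <- c(1, seq_len(P - 1))
    lambda <- matrix(rep(0.10 * exp(-0.1 * (trend - 1)), each = 5),
                     nrow = 5, ncol = P)
  }
  lambda <- as.matrix(lambda)
  if (ncol(lambda) != P) stop("lambda must have one column per period")
  if (any(lambda < 0)) stop("excess hazards must be >= 0")
  for (nm in c("a", "b")) {
    if (background[[nm]] < 0) stop("background hazard parameters must be >= 0")
  }
  chk <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8) stop(what, " probabilities must sum to 1")
  }
  chk(sex_probs, "sex"); chk(race_probs, "race"); chk(age_bands$prob, "age band")
  structure(
    list(n_per_period = rep_len(n_per_period, P), periods = periods,
         lambda = lambda, age_bands = age_bands, sex_probs = sex_probs,
         race_probs = race_probs, background = background,
         sex_mult = sex_mult, year_drift = year_drift, cutoff = cutoff,
         loss_rate = loss_rate, dco_rate = dco_rate,
         multi_primary_rate = multi_primary_rate,
         under_age_rate = under_age_rate, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Read a simulation spec from JSON
#' @param path JSON file produced by [write_simulation_spec()].
#' @return a `simulation_spec`.
#' @export
read_simulation_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  per <- obj$periods
  if (is.matrix(per)) per <- lapply(seq_len(nrow(per)), function(i) per[i, ])
  obj$periods <- lapply(per, function(p) p[1]:p[2])
  obj$lambda <- as.matrix(obj$lambda)
  obj$age_bands <- as.data.frame(obj$age_bands)
  obj$cutoff <- as.list(obj$cutoff)
  obj$background <- as.list(obj$background)
  for (nm in c("sex_probs", "race_probs", "sex_mult")) {
    obj[[nm]] <- unlist(obj[[nm]])
  }
  do.call(simulation_spec, obj)
}

#' Write a simulation spec to JSON
#' @param spec a `simulation_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulation_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$periods <- lapply(obj$periods, range)
  for (nm in c("sex_probs", "race_probs", "sex_mult")) {
    obj[[nm]] <- as.list(obj[[nm]])  # keep names in JSON
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

# annual background hazard at integer age, by sex and calendar year
background_hazard <- function(spec, age, sex, year = NULL) {
  b <- spec$background
  mu <- (b$a + b$b * b$c^pmin(age, 99)) * spec$sex_mult[sex]
  if (!is.null(year) && spec$year_drift != 0) {
    y0 <- min(unlist(spec$periods))
    mu <- mu * (1 + spec$year_drift)^(year - y0)
  }
  unname(mu)
}

#' Generate the population life table implied by a simulation spec
#'
#' `p_pop(age, year, sex, race) = exp(-mu(age, sex, year))` over ages 0-99
#' and calendar years from the first diagnosis year through the cutoff year.
#' Deterministic: no randomness enters life tables.
#'
#' @param spec a `simulation_spec`.
#' @return a [lifetable].
#' @export
simulate_lifetable <- function(spec) {
  years <- min(unlist(spec$periods)):spec$cutoff$year
  grid <- expand.grid(age = 0:99, year = years,
                      sex = names(spec$sex_probs),
                      race = names(spec$race_probs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- background_hazard(spec, grid$age, grid$sex, grid$year)
  grid$surv_prob <- exp(-mu)
  if (any(grid$surv_prob <= 0 | grid$surv_prob > 1)) {
    stop("hazard parameters yield survival probabilities outside (0,1]")
  }
  lifetable(grid)
}

#' Simulate a registry cohort with known excess hazard
#'
#' Each patient's death probability in follow-up year j is
#' `1 - exp(-(mu_i + lambda[j, p]))`, where `mu_i = -log p_pop` is taken from
#' the supplied life table at the patient's attained age and calendar year --
#' so with `lambda = 0` the cohort's mortality matches the life table by
#' construction. Death months are uniform within the fatal year; recorded
#' survival months are the completed months (`floor`). Administrative
#' censoring applies at the spec's cutoff date, plus optional exponential
#' loss to follow-up.
#'
#' @param spec a `simulation_spec`.
#' @param lifetable the background [lifetable] (normally
#'   `simulate_lifetable(spec)`).
#' @return a `cohort` data frame ready for [apply_inclusion_filters()] /
#'   [build_risk_sets()], with a `period` column recording the diagnosis
#'   period index.
#' @export
simulate_cohort <- function(spec, lifetable) {
  P <- length(spec$periods)
  n_p <- spec$n_per_period
  n <- sum(n_p)
  period <- rep(seq_len(P), n_p)

  cutoff_dec <- spec$cutoff$year + spec$cutoff$month / 12
  jmax <- ceiling(cutoff_dec - min(unlist(spec$periods))) + 1L

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister")
  # fixed-size per-patient draw block, patient-major: early patients are
  # unchanged when only n grows
  B <- 12L + jmax
  U <- matrix(stats::runif(as.double(n) * B), nrow = B)

  pick <- function(u, probs) {
    findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  }
  dx_year <- integer(n)
  for (p in seq_len(P)) {
    idx <- period == p
    yrs <- spec$periods[[p]]
    dx_year[idx] <- yrs[pmin(floor(U[1L, idx] * length(yrs)) + 1L,
                             length(yrs))]
  }
  dx_month <- pmin(floor(U[2L, ] * 12) + 1L, 12L)
  sex <- names(spec$sex_probs)[pick(U[3L, ], spec$sex_probs)]
  race <- names(spec$race_probs)[pick(U[4L, ], spec$race_probs)]
  band <- pick(U[5L, ], spec$age_bands$prob)
  lo <- spec$age_bands$low[band]; hi <- spec$age_bands$high[band]
  age_dx <- lo + pmin(floor(U[6L, ] * (hi - lo + 1)), hi - lo)
  under <- U[9L, ] < spec$under_age_rate
  age_dx[under] <- pmin(floor(U[6L, under] * 14) + 1L, 15L)

  dx_date <- dx_year + (dx_month - 1) / 12  # month-start dating
  cens_months <- floor(12 * (cutoff_dec - dx_date))
  if (spec$loss_rate > 0) {
    loss_months <- floor(12 * (-log(U[8L, ]) / spec$loss_rate))
    cens_months <- pmin(cens_months, loss_months)
  }

  # annual death probabilities: background (from the life table) + excess
  lam_rows <- pmin(seq_len(jmax), nrow(spec$lambda))
  Q <- matrix(0, nrow = n, ncol = jmax)
  for (j in seq_len(jmax)) {
    p_bg <- annual_expected_survival(lifetable, age_dx + (j - 1L),
                                     dx_year + (j - 1L), sex, race)
    Q[, j] <- 1 - exp(-(-log(p_bg) + spec$lambda[lam_rows[j], period]))
  }
  Ud <- t(U[12L + seq_len(jmax), , drop = FALSE])
  hit <- Ud < Q
  any_hit <- rowSums(hit) > 0
  death_year <- ifelse(any_hit, max.col(hit, ties.method = "first"), NA_integer_)
  death_month <- (death_year - 1L) * 12L + pmin(floor(U[7L, ] * 12), 11L)

  dead <- any_hit & !is.na(death_month) & death_month < cens_months
  survival_months <- ifelse(dead, death_month, cens_months)

  subtype_codes <- c("9680/3", "9690/3", "9699/3", "9702/3", "9823/3",
                     "9673/3", "9591/3")
  subtype_probs <- c(0.375, 0.19, 0.10, 0.06, 0.045, 0.045, 0.185)
  histology <- subtype_codes[pick(U[10L, ], subtype_probs)]
  nodal <- ifelse(U[11L, ] < 0.65, "nodal", "extranodal")
  area <- ifelse(U[12L, ] < 0.85, "urban", "rural")

  out <- data.frame(
    id = sprintf("sim%07d", seq_len(n)),
    sex = sex, race = race, age_dx = as.integer(age_dx),
    dx_year = as.integer(dx_year), dx_month = as.integer(dx_month),
    survival_months = as.integer(survival_months),
    vital_status = ifelse(dead, "dead", "alive"),
    histology = histology, site = NA_character_,
    nodal = nodal, area = area,
    autopsy_dco = U[9L, ] >= 1 - spec$dco_rate,
    sequence = ifelse(U[9L, ] >= 0.5 &
                        U[9L, ] < 0.5 + spec$multi_primary_rate, 2L, 0L),
    period = period,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cohort", "data.frame")
  out
}

#' Write a cohort to a case-listing CSV
#'
#' Writes the CSV dialect that [read_case_listing()] reads back (identity
#' schema). Deterministic: a fixed simulation seed gives a byte-identical
#' file.
#'
#' @param cohort a `cohort` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$period <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Closed-form true relative survival of a simulated period
#'
#' Because the excess hazard is additive on the annual hazard scale, the
#' k-year relative survival implied by the spec is exactly
#' `prod(exp(-lambda[1:k, p]))`, independent of the age/sex/race mix.
#'
#' @param spec a `simulation_spec`.
#' @param p period index.
#' @param k follow-up depth in years.
#' @return probability.
#' @export
true_relative_survival <- function(spec, p, k = 5L) {
  rows <- pmin(seq_len(k), nrow(spec$lambda))
  prod(exp(-spec$lambda[rows, p]))
}
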