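#' Analysis window
#'
#' Defines the calendar window and follow-up depth of a survival analysis.
#' In `cohort` mode, patients diagnosed within the window contribute from
#' diagnosis. In `period` mode each patient's person-time is intersected
#' with the window `[start-01-01, (end+1)-01-01)`: patients diagnosed earlier
#' enter late (left truncation / delayed entry), deaths count only when the
#' death date falls inside the window, and follow-up is truncated when the
#' window closes. Follow-up is always capped at `k` annual intervals.
#'
#' @param mode `"period"` or `"cohort"`.
#' @param start,end first and last calendar year of the window (inclusive).
#' @param k number of annual follow-up intervals (default 5).
#' @return list of class `analysis_window`.
#' @export
analysis_window <- function(mode = c("period", "cohort"), start, end, k = 5L) {
  mode <- match.arg(mode)
  start <- as.integer(start); end <- as.integer(end); k <- as.integer(k)
  if (start > end) stop("analysis window: start year after end year")
  if (k < 1L) stop("analysis window: k must be >= 1")
  structure(list(mode = mode, start = start, end = end, k = k),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("%s analysis window %d-%d, k = %d annual intervals\n",
              x$mode, x$start, x$end, x$k))
  invisible(x)
}

# Per-patient follow-up segments under a window.
#
# Dating conventions: diagnosis is dated at the start of its month
# (year + (month - 1)/12; month 7, i.e. mid-year, when unrecorded), which
# keeps calendar-window boundaries on the follow-up month grid. Death times
# are mid-month dated within the recorded survival month,
# (survival_months + 0.5)/12 years of follow-up -- the unbiased inverse of
# the floor that produced the month count; with month-start diagnosis dates
# this classifies every death relative to a calendar-year window boundary
# exactly. Censoring times are survival_months/12 (last month known alive).
# Deaths at exactly an interval boundary belong to the earlier interval;
# withdrawals at exactly a boundary completed that interval and carry full
# actuarial weight; entrants at exactly a boundary are at risk only from the
# next interval and carry zero weight in the interval they nominally enter.
patient_segments <- function(patients, window) {
  dxm <- ifelse(is.na(patients$dx_month), 7L, patients$dx_month)
  dx_date <- patients$dx_year + (dxm - 1) / 12
  dead <- patients$vital_status == "dead"
  t_fu <- ifelse(dead,
                 (patients$survival_months + 0.5) / 12,
                 patients$survival_months / 12)
  k <- window$k
  if (window$mode == "period") {
    entry <- pmax(0, window$start - dx_date)
    exit_cal <- (window$end + 1) - dx_date
    event <- dead & (t_fu < exit_cal)
    exit <- pmin(t_fu, exit_cal)
  } else {
    inw <- patients$dx_year >= window$start & patients$dx_year <= window$end
    entry <- rep(0, nrow(patients))
    event <- dead
    exit <- t_fu
    exit[!inw] <- -Inf  # diagnosed outside the window: contributes nothing
  }
  over <- exit > k + 1e-9
  event[over] <- FALSE
  exit[over] <- k
  keep <- exit > entry + 1e-12 & is.finite(exit)
  data.frame(
    idx = which(keep),
    entry = entry[keep], exit = exit[keep], event = event[keep]
  )
}

#' Build annual-interval risk sets
#'
#' Constructs the actuarial life table of a cohort under an analysis window:
#' per annual follow-up interval j = 1..k the number at risk at the interval
#' start (`n`), late entrants during the interval (`e`, period mode, with
#' `e_interior` the strictly mid-interval ones that receive half-weight),
#' deaths (`d`), withdrawals (`c`, with `c_interior` the strictly
#' mid-interval ones that receive half-weight), the effective denominator
#' `n_eff = n + e_interior/2 - c_interior/2`, and the Ederer II conditional expected
#' survival `pstar` (the `n_eff`-weighted mean of population annual survival
#' at each at-risk patient's attained age and calendar year).
#'
#' @param patients a `cohort` data frame (filtered cases).
#' @param window an [analysis_window()].
#' @param lifetable a [lifetable] for the Ederer II expectation; `NULL`
#'   skips the expected-survival column.
#' @return data.frame of class `riskset_table` with one row per interval and
#'   attributes `window`, `n_contributing` and `clamped` (life-table lookup
#'   clamps). An empty contributing set yields an all-zero table flagged via
#'   attribute `empty = TRUE` rather than an error.
#' @export
build_risk_sets <- function(patients, window, lifetable = NULL) {
  stopifnot(inherits(window, "analysis_window"))
  seg <- patient_segments(patients, window)
  k <- window$k
  eps <- 1e-9
  n <- e <- ew <- d <- cw <- cb <- integer(k)
  pstar <- rep(NA_real_, k)
  clamped <- 0L

  c_bound <- !seg$event & abs(seg$exit - round(seg$exit)) < eps
  e_bound <- abs(seg$entry - round(seg$entry)) < eps
  for (j in seq_len(k)) {
    lo <- j - 1; hi <- j
    in_n <- seg$entry <= lo + eps & seg$exit > lo + eps
    in_e <- seg$entry > lo + eps & seg$entry <= hi + eps
    ends <- seg$exit > lo + eps & seg$exit <= hi + eps
    in_d <- seg$event & ends
    in_c <- !seg$event & ends
    n[j] <- sum(in_n); e[j] <- sum(in_e); ew[j] <- sum(in_e & !e_bound)
    d[j] <- sum(in_d); cw[j] <- sum(in_c & !c_bound); cb[j] <- sum(in_c & c_bound)
    if (!is.null(lifetable)) {
      at_risk <- in_n | in_e
      if (any(at_risk)) {
        w <- ifelse(in_e[at_risk], ifelse(e_bound[at_risk], 0, 0.5), 1) -
          ifelse((in_c & !c_bound)[at_risk], 0.5, 0)
        rows <- seg$idx[at_risk]
        p <- annual_expected_survival(
          lifetable,
          age = patients$age_dx[rows] + (j - 1L),
          year = patients$dx_year[rows] + (j - 1L),
          sex = patients$sex[rows], race = patients$race[rows]
        )
        clamped <- clamped + attr(p, "clamped")
        if (sum(w) > 0) pstar[j] <- sum(w * p) / sum(w)
      }
    }
  }
  out <- data.frame(
    interval = seq_len(k), n = n, e = e, e_interior = ew, d = d,
    c = cw + cb, c_interior = cw,
    n_eff = n + ew / 2 - cw / 2, pstar = pstar
  )
  class(out) <- c("riskset_table", "data.frame")
  attr(out, "window") <- window
  attr(out, "n_contributing") <- nrow(seg)
  attr(out, "clamped") <- clamped
  attr(out, "empty") <- nrow(seg) == 0L
  out
}

#' Conditional observed survival of one interval
#'
#' Actuarial estimator `p_j = 1 - d_j / n'_j` with effective denominator
#' `n'_j = n_j + e_j/2 - c_j/2` (half-weight for late entrants and for
#' mid-interval withdrawals).
#'
#' @param rs a `riskset_table`.
#' @param j interval index.
#' @return probability, or `NA` with attribute `reason` when the effective
#'   denominator is not positive.
#' @export
conditional_observed_survival <- function(rs, j) {
  ne <- rs$n_eff[j]
  if (!length(ne) || is.na(ne) || ne <= 0) {
    return(structure(NA_real_, reason = "effective denominator <= 0"))
  }
  1 - rs$d[j] / ne
}

#' Ederer II conditional expected survival
#'
#' Mean population annual survival probability over the patients at risk at
#' the start of a follow-up interval, looked up at each patient's attained
#' age and calendar year; patients entering or withdrawing mid-interval get
#' half-weight, mirroring the observed-survival denominator.
#'
#' @param at_risk data.frame with columns `age`, `year`, `sex`, `race` and
#'   optionally `weight` (default 1; use 0.5 for mid-interval entrants and
#'   withdrawers).
#' @param lifetable a [lifetable].
#' @return probability, or `NA` with a `reason` attribute for an empty set.
#' @export
ederer2_conditional_expected <- function(at_risk, lifetable) {
  if (is.null(at_risk) || nrow(at_risk) == 0L) {
    return(structure(NA_real_, reason = "empty at-risk set"))
  }
  w <- at_risk$weight %||% rep(1, nrow(at_risk))
  if (sum(w) <= 0) return(structure(NA_real_, reason = "zero total weight"))
  p <- annual_expected_survival(lifetable, at_risk$age, at_risk$year,
                                at_risk$sex, at_risk$race)
  sum(w * p) / sum(w)
}

#' Observed, expected and relative survival from a risk-set table
#'
#' Computes per-interval conditional observed survival `p`, conditional
#' relative survival `r = p/pstar`, cumulative observed `S`, cumulative
#' expected `Sstar`, cumulative relative `R = S/Sstar`, and Greenwood
#' standard errors `se_S` and `se_R = se_S/Sstar`. Relative survival is not
#' capped at 1. Intervals with a non-positive effective denominator are
#' undefined (`NA`) and propagate.
#'
#' @param rs a `riskset_table` from [build_risk_sets()].
#' @return data.frame of class `survival_estimate` with one row per interval;
#'   attribute `undefined` lists undefined intervals with reasons.
#' @export
survival_estimate <- function(rs) {
  k <- nrow(rs)
  undef <- character(0)
  p <- ifelse(rs$n_eff > 0, 1 - rs$d / rs$n_eff, NA_real_)
  if (any(rs$n_eff <= 0)) {
    undef <- c(undef, sprintf("interval %d: effective denominator <= 0",
                              rs$interval[rs$n_eff <= 0]))
  }
  pstar <- rs$pstar
  r <- p / pstar
  S <- cumprod(p)
  Sstar <- cumprod(pstar)
  R <- S / Sstar
  gw_term <- ifelse(rs$d == 0, 0,
                    ifelse(rs$n_eff - rs$d > 0,
                           rs$d / (rs$n_eff * (rs$n_eff - rs$d)), NA_real_))
  if (any(rs$d > 0 & rs$n_eff - rs$d <= 0)) {
    undef <- c(undef, sprintf("interval %d: Greenwood variance undefined",
                              rs$interval[rs$d > 0 & rs$n_eff - rs$d <= 0]))
  }
  se_S <- S * sqrt(cumsum(gw_term))
  se_R <- se_S / Sstar
  out <- data.frame(interval = rs$interval, p = p, pstar = pstar, r = r,
                    S = S, Sstar = Sstar, R = R, se_S = se_S, se_R = se_R)
  class(out) <- c("survival_estimate", "data.frame")
  attr(out, "window") <- attr(rs, "window")
  attr(out, "undefined") <- undef
  out
}

#' Cumulative relative survival at k years
#'
#' `R_k = prod(p_j) / prod(pstar_j)` over intervals 1..k, equal to the
#' product of the conditional relative survival ratios. Not capped at 1.
#'
#' @param est a `survival_estimate`.
#' @param k follow-up depth in years.
#' @return the ratio, or `NA` with a `reason` attribute when any contributing
#'   interval is undefined.
#' @export
cumulative_relative_survival <- function(est, k = nrow(est)) {
  if (k > nrow(est)) stop("k exceeds the number of estimated intervals")
  if (anyNA(est$p[seq_len(k)]) || anyNA(est$pstar[seq_len(k)])) {
    return(structure(NA_real_, reason = paste(attr(est, "undefined"),
                                              collapse = "; ")))
  }
  prod(est$p[seq_len(k)]) / prod(est$pstar[seq_len(k)])
}

#' Greenwood standard errors at k years
#'
#' `Var(S_k) = S_k^2 * sum_j d_j / (n'_j (n'_j - d_j))`;
#' `se_R_k = se_S_k / Sstar_k`.
#'
#' @param rs a `riskset_table`.
#' @param est the matching `survival_estimate`.
#' @param k follow-up depth in years.
#' @return named numeric vector `c(se_S, se_R)`; `NA`s with a `reason`
#'   attribute when the variance is undefined.
#' @export
greenwood_se <- function(rs, est, k = nrow(rs)) {
  idx <- seq_len(k)
  if (any(rs$d[idx] > 0 & rs$n_eff[idx] - rs$d[idx] <= 0)) {
    return(structure(c(se_S = NA_real_, se_R = NA_real_),
                     reason = "n'_j - d_j = 0 with d_j > 0"))
  }
  c(se_S = est$se_S[k], se_R = est$se_R[k])
}

#' One-call relative-survival estimation
#'
#' Convenience wrapper: builds the risk sets and returns the
#' `survival_estimate` for a cohort under a window.
#'
#' @inheritParams build_risk_sets
#' @return a `survival_estimate` (attribute `riskset` holds the table).
#' @examples
#' spec <- simulation_spec(n_per_period = 2000, seed = 7)
#' lt <- simulate_lifetable(spec)
#' coh <- simulate_cohort(spec, lt)
#' w <- analysis_window("period", 2014, 2018, k = 5)
#' est <- relative_survival(coh, w, lt)
#' est$R[5]  # 5-year relative survival
#' @export
relative_survival <- function(patients, window, lifetable) {
  rs <- build_risk_sets(patients, window, lifetable)
  est <- survival_estimate(rs)
  attr(est, "riskset") <- rs
  est
}

#' @export
print.survival_estimate <- function(x, digits = 4, ...) {
  w <- attr(x, "window")
  if (!is.null(w)) {
    cat(sprintf("Relative survival (%s analysis, %d-%d)\n", w$mode, w$start, w$end))
  }
  print.data.frame(round_df(x, digits), row.names = FALSE)
  u <- attr(x, "undefined")
  if (length(u)) cat("undefined:", paste(u, collapse = "; "), "\n")
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}
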