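# Shared fixtures and the brute-force risk-set oracle. The oracle enumerates
# each patient's (entry, exit, event) triple with scalar if-chains and
# buckets events interval by interval -- written independently of the
# engine's vectorised construction so the two can be compared exactly.

make_test_lifetable <- function(years = 2000:2019, sexes = c("male", "female"),
                                races = "all",
                                a = 0.001, b = 5e-5, cc = 1.09) {
  grid <- expand.grid(age = 0:99, year = years, sex = sexes, race = races,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$surv_prob <- exp(-(a + b * cc^grid$age))
  lifetable(grid)
}

# a patient data.frame with cohort-required columns and benign defaults
make_patients <- function(dx_year, dx_month, survival_months, vital_status,
                          age_dx = 65, sex = "male", race = "all", ...) {
  n <- max(lengths(list(dx_year, survival_months)))
  df <- data.frame(
    id = sprintf("p%03d", seq_len(n)),
    sex = rep_len(sex, n), race = rep_len(race, n),
    age_dx = rep_len(age_dx, n),
    dx_year = rep_len(dx_year, n), dx_month = rep_len(dx_month, n),
    survival_months = rep_len(survival_months, n),
    vital_status = rep_len(vital_status, n),
    histology = "9680/3", site = NA_character_,
    nodal = "nodal", area = "urban",
    autopsy_dco = FALSE, sequence = 0L,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  class(df) <- c("cohort", "data.frame")
  df
}

# exercises each exclusion rule exactly once; record 5 is fully valid
five_record_fixture <- function() {
  make_patients(
    dx_year = 2010, dx_month = 5,
    survival_months = c(12L, 12L, NA, 12L, 40L),
    vital_status = c("dead", "dead", "alive", "alive", "alive"),
    age_dx = c(14L, 60L, 60L, 60L, 60L),
    autopsy_dco = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    sequence = c(0L, 0L, 0L, 2L, 0L)
  )
}

random_mini_cohort <- function(n = sample(1:20, 1)) {
  make_patients(
    dx_year = sample(2000:2018, n, replace = TRUE),
    dx_month = sample(1:12, n, replace = TRUE),
    survival_months = sample(0:240, n, replace = TRUE),
    vital_status = sample(c("alive", "dead"), n, replace = TRUE),
    age_dx = sample(16:95, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
}

# independent per-patient triple enumeration
oracle_segments <- function(pat, window) {
  out <- list()
  for (i in seq_len(nrow(pat))) {
    m <- pat$dx_month[i]
    if (is.na(m)) m <- 7
    dx <- pat$dx_year[i] + (m - 1) / 12
    dead <- pat$vital_status[i] == "dead"
    tfu <- if (dead) (pat$survival_months[i] + 0.5) / 12 else
      pat$survival_months[i] / 12
    if (window$mode == "period") {
      entry <- max(0, window$start - dx)
      wclose <- (window$end + 1) - dx
      if (dead && tfu < wclose) {
        exit <- tfu; ev <- TRUE
      } else {
        exit <- min(tfu, wclose); ev <- FALSE
      }
    } else {
      if (pat$dx_year[i] < window$start || pat$dx_year[i] > window$end) next
      entry <- 0; exit <- tfu; ev <- dead
    }
    if (exit > window$k + 1e-9) {
      exit <- window$k; ev <- FALSE
    }
    if (exit <= entry + 1e-12) next
    out[[length(out) + 1L]] <- list(i = i, entry = entry, exit = exit, ev = ev)
  }
  out
}

oracle_risk_sets <- function(pat, window, lt = NULL) {
  segs <- oracle_segments(pat, window)
  k <- window$k
  tab <- data.frame(interval = 1:k, n = 0L, e = 0L, e_interior = 0L, d = 0L,
                    c = 0L, c_interior = 0L, n_eff = 0, pstar = NA_real_)
  eps <- 1e-9
  for (j in 1:k) {
    wsum <- 0; psum <- 0
    for (s in segs) {
      w <- 1
      if (s$entry <= j - 1 + eps && s$exit > j - 1 + eps) {
        tab$n[j] <- tab$n[j] + 1L
      } else if (s$entry > j - 1 + eps && s$entry <= j + eps) {
        tab$e[j] <- tab$e[j] + 1L
        if (abs(s$entry - round(s$entry)) >= eps) {
          tab$e_interior[j] <- tab$e_interior[j] + 1L
          w <- 0.5   # interior entrant: half the interval observed
        } else {
          w <- 0     # boundary entrant: at risk only from the next interval
        }
      } else {
        next
      }
      if (s$exit > j - 1 + eps && s$exit <= j + eps) {
        if (s$ev) {
          tab$d[j] <- tab$d[j] + 1L
        } else {
          tab$c[j] <- tab$c[j] + 1L
          if (abs(s$exit - round(s$exit)) >= eps) {
            tab$c_interior[j] <- tab$c_interior[j] + 1L
            w <- w - 0.5  # interior withdrawal: half the interval observed
          }
        }
      }
      if (!is.null(lt)) {
        p <- annual_expected_survival(lt, pat$age_dx[s$i] + (j - 1),
                                      pat$dx_year[s$i] + (j - 1),
                                      pat$sex[s$i], pat$race[s$i])
        wsum <- wsum + w; psum <- psum + w * as.numeric(p)
      }
    }
    tab$n_eff[j] <- tab$n[j] + tab$e_interior[j] / 2 - tab$c_interior[j] / 2
    if (!is.null(lt) && wsum > 0) tab$pstar[j] <- psum / wsum
  }
  tab
}

# hand-built riskset table for the operation-level tests
fake_riskset <- function(n, e = 0, d = 0, c_int = 0, c_bnd = 0, pstar = NA) {
  k <- length(n)
  out <- data.frame(interval = seq_len(k), n = n, e = rep_len(e, k),
                    e_interior = rep_len(e, k),
                    d = rep_len(d, k), c = rep_len(c_int, k) + rep_len(c_bnd, k),
                    c_interior = rep_len(c_int, k),
                    pstar = rep_len(pstar, k))
  out$n_eff <- out$n + out$e_interior / 2 - out$c_interior / 2
  class(out) <- c("riskset_table", "data.frame")
  out
}

# fabricate a survival_estimate + riskset pair from given conditional ratios
fake_period_estimate <- function(r, w = 1000, pstar = 0.95, label_years = NULL) {
  k <- length(r)
  rs <- fake_riskset(n = rep(w, k), pstar = pstar)
  est <- data.frame(interval = 1:k, p = r * pstar, pstar = pstar, r = r,
                    S = cumprod(r * pstar), Sstar = cumprod(rep(pstar, k)),
                    R = cumprod(r), se_S = NA_real_, se_R = NA_real_)
  class(est) <- c("survival_estimate", "data.frame")
  if (!is.null(label_years)) {
    attr(est, "window") <- analysis_window("period", label_years[1],
                                           label_years[2], k)
  }
  attr(est, "riskset") <- rs
  est
}
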