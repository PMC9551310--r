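test_that("period-mode risk sets match the hand-worked three-patient case", {
  lt <- make_test_lifetable()
  # P1 dx 2010-01 dead at 30 mo; P2 dx 2007-01 alive throughout;
  # P3 dx 2013-07 alive with follow-up past the window close
  pat <- make_patients(dx_year = c(2010, 2007, 2013),
                       dx_month = c(1, 1, 7),
                       survival_months = c(30, 150, 100),
                       vital_status = c("dead", "alive", "alive"))
  w <- analysis_window("period", 2010, 2014, k = 5)
  rs <- build_risk_sets(pat, w, lt)
  # P1 enters at 0, dies at 30.5 mo (interval 3); P2 enters at exactly 3.0 y
  # of follow-up (boundary entrant of interval 3, at risk from interval 4),
  # k-capped at 5 y; P3 enters at 0 and is censored at the window close,
  # 1.5 y into follow-up (interval 2)
  expect_equal(rs$n, c(2L, 2L, 1L, 1L, 1L))
  expect_equal(rs$e, c(0L, 0L, 1L, 0L, 0L))
  expect_equal(rs$e_interior, rep(0L, 5))
  expect_equal(rs$d, c(0L, 0L, 1L, 0L, 0L))
  expect_equal(rs$c, c(0L, 1L, 0L, 0L, 1L))
  expect_equal(rs$c_interior, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(rs$n_eff, c(2, 1.5, 1, 1, 1))
  expect_equal(rs, oracle_risk_sets(pat, w, lt), ignore_attr = TRUE)
})

test_that("patients outside the window contribute nothing", {
  lt <- make_test_lifetable()
  pat <- make_patients(dx_year = 2014, dx_month = 12, survival_months = 60,
                       vital_status = "alive")
  rs <- build_risk_sets(pat, analysis_window("period", 2004, 2008, 5), lt)
  expect_true(attr(rs, "empty"))
  expect_equal(sum(rs$n + rs$e), 0)
  est <- survival_estimate(rs)
  expect_true(all(is.na(est$R)))
  expect_true(is.na(cumulative_relative_survival(est, 5)))
  expect_match(attr(cumulative_relative_survival(est, 5), "reason"),
               "denominator")
})

test_that("cohort mode with full follow-up has no late entry and counts deaths", {
  pat <- make_patients(dx_year = rep(2004:2008, each = 4), dx_month = 6,
                       survival_months = rep(c(10, 30, 200, 200), 5),
                       vital_status = rep(c("dead", "dead", "alive", "alive"), 5))
  rs <- build_risk_sets(pat, analysis_window("cohort", 2004, 2008, 5))
  expect_equal(rs$e, rep(0L, 5))
  expect_equal(sum(rs$d), 10L)
  # flow conservation
  for (j in 1:4) {
    expect_equal(rs$n[j + 1], rs$n[j] + rs$e[j] - rs$d[j] - rs$c[j])
  }
})

test_that("actuarial conditional survival uses the effective denominator", {
  expect_equal(conditional_observed_survival(fake_riskset(100, d = 10), 1), 0.9)
  expect_equal(conditional_observed_survival(
    fake_riskset(100, d = 10, c_int = 20), 1), 1 - 10 / 90)
  expect_equal(conditional_observed_survival(
    fake_riskset(0, e = 2, d = 1), 1), 0)
  und <- conditional_observed_survival(fake_riskset(0), 1)
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "denominator")
})

test_that("Ederer II expectation is the weighted mean over the at-risk set", {
  # table with distinct values by age so lookups are controllable
  df <- expand.grid(age = 0:99, year = 2010, sex = "male", race = "all",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$surv_prob <- 1 - df$age / 200
  lt <- lifetable(df)
  ar <- function(ages, w = NULL) {
    n <- length(ages)
    out <- data.frame(age = ages, year = rep(2010, n),
                      sex = rep("male", n), race = rep("all", n))
    if (!is.null(w)) out$weight <- w
    out
  }
  # ages 8 and 20 store 0.96 and 0.90
  expect_equal(ederer2_conditional_expected(ar(c(8, 20)), lt), 0.93)
  expect_equal(ederer2_conditional_expected(ar(rep(30, 4)), lt), 0.85)
  # three full-interval patients (0.96, 0.94, 0.90) + one half-weight
  # withdrawer (0.80): (0.96 + 0.94 + 0.90 + 0.5*0.80) / 3.5
  expect_equal(ederer2_conditional_expected(ar(c(8, 12, 20, 40),
                                               w = c(1, 1, 1, 0.5)), lt),
               3.2 / 3.5)
  expect_true(is.na(ederer2_conditional_expected(ar(integer(0)), lt)))
})

test_that("cumulative relative survival multiplies conditionals, uncapped", {
  rs <- fake_riskset(c(100, 90), d = c(10, 9), pstar = 0.95)
  est <- survival_estimate(rs)
  expect_equal(cumulative_relative_survival(est, 2), (0.9 / 0.95)^2)
  expect_equal(est$R[2], est$S[2] / est$Sstar[2])
  expect_equal(est$r, est$p / est$pstar)

  rs2 <- fake_riskset(c(100, 100), d = 1, pstar = 0.95)
  est2 <- survival_estimate(rs2)
  expect_gt(cumulative_relative_survival(est2, 2), 1)  # never capped

  rs3 <- fake_riskset(100, d = 10, pstar = 0.9)
  est3 <- survival_estimate(rs3)
  expect_equal(cumulative_relative_survival(est3, 1), 1)  # p == pstar
})

test_that("Greenwood standard errors follow the closed form", {
  rs1 <- fake_riskset(100, d = 10, pstar = 0.95)
  est1 <- survival_estimate(rs1)
  se1 <- greenwood_se(rs1, est1, 1)
  expect_equal(unname(se1["se_S"]), 0.03)
  expect_equal(unname(se1["se_R"]), 0.03 / 0.95)

  rs0 <- fake_riskset(c(50, 50), d = 0, pstar = 0.95)
  expect_equal(unname(greenwood_se(rs0, survival_estimate(rs0), 2)["se_S"]), 0)

  rs2 <- fake_riskset(c(100, 90), d = c(10, 9), pstar = 0.95)
  est2 <- survival_estimate(rs2)
  expect_equal(unname(greenwood_se(rs2, est2, 2)["se_S"]),
               0.81 * sqrt(10 / 9000 + 9 / 7290))
  expect_equal(est2$se_R[2], est2$se_S[2] / est2$Sstar[2])

  rs_bad <- fake_riskset(10, d = 10, pstar = 0.95)
  se_bad <- greenwood_se(rs_bad, survival_estimate(rs_bad), 1)
  expect_true(all(is.na(se_bad)))
  expect_match(attr(se_bad, "reason"), "d_j")
})

test_that("flow conservation and count sanity hold on random cohorts", {
  set.seed(2024)
  lt <- make_test_lifetable()
  for (rep in 1:25) {
    pat <- random_mini_cohort(sample(5:20, 1))
    mode <- sample(c("period", "cohort"), 1)
    start <- sample(2004:2016, 1)
    w <- analysis_window(mode, start, start + sample(0:4, 1),
                         k = sample(1:6, 1))
    rs <- build_risk_sets(pat, w, lt)
    if (w$k > 1) {
      for (j in seq_len(w$k - 1)) {
        expect_equal(rs$n[j + 1], rs$n[j] + rs$e[j] - rs$d[j] - rs$c[j])
      }
    }
    expect_true(all(rs$d + rs$c <= rs$n + rs$e))
    expect_true(all(rs[c("n", "e", "d", "c")] >= 0))
  }
})

test_that("cohort mode without censoring reproduces direct counting exactly", {
  # everyone followed at least k years; deaths before k, survivors beyond
  set.seed(7)
  n <- 400
  dead <- runif(n) < 0.45
  pat <- make_patients(
    dx_year = sample(2004:2006, n, replace = TRUE),
    dx_month = sample(1:12, n, replace = TRUE),
    survival_months = ifelse(dead, sample(0:59, n, replace = TRUE), 90L),
    vital_status = ifelse(dead, "dead", "alive")
  )
  rs <- build_risk_sets(pat, analysis_window("cohort", 2004, 2006, 5))
  est <- survival_estimate(rs)
  expect_equal(est$S[5], mean(!dead), tolerance = 1e-14)
})

test_that("period mode with an all-covering window equals cohort mode", {
  set.seed(11)
  lt <- make_test_lifetable(years = 2000:2019)
  pat <- random_mini_cohort(20)
  wc <- analysis_window("cohort", 2000, 2018, 5)
  wp <- analysis_window("period", 1995, 2060, 5)
  rs_c <- build_risk_sets(pat, wc, lt)
  rs_p <- build_risk_sets(pat, wp, lt)
  expect_equal(rs_c[c("n", "e", "d", "c", "c_interior", "n_eff", "pstar")],
               rs_p[c("n", "e", "d", "c", "c_interior", "n_eff", "pstar")])
})
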