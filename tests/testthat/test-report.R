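tiny_run <- function(stratifiers = "sex", output_dir = NULL,
                     windows = NULL, projection_enabled = TRUE) {
  spec <- simulation_spec(
    n_per_period = c(400, 500, 500, 500),
    cutoff = list(year = 2019, month = 12), seed = 17
  )
  lt <- simulate_lifetable(spec)
  coh <- simulate_cohort(spec, lt)
  cfg <- run_config(cases = coh, lifetable = lt, output_dir = output_dir,
                    windows = windows, stratifiers = stratifiers,
                    projection = list(enabled = projection_enabled,
                                      link = "cloglog",
                                      target_label = "2019-2023"),
                    seed = 17)
  run_analysis(cfg)
}

test_that("a stratified run yields the Overall/Male/Female x window table", {
  res <- tiny_run("sex")
  expect_s3_class(res, "period_analysis")
  expect_setequal(res$wide$stratum, c("overall", "male", "female"))
  expect_equal(names(res$wide),
               c("stratum", "2004-2008", "2009-2013", "2014-2018",
                 "projected:2019-2023"))
  # crude and standardized rows exist for every stratum x window
  crude <- res$estimates[!res$estimates$standardized &
                           !grepl("^projected", res$estimates$window), ]
  expect_equal(nrow(crude), 3L * 3L)
  std <- res$estimates[res$estimates$standardized, ]
  expect_equal(nrow(std), 9L)
  expect_length(res$projections, 3L)
})

test_that("an empty stratifier list collapses to an overall-only table", {
  res <- tiny_run(character(0), projection_enabled = FALSE)
  expect_equal(unique(res$estimates$stratum), "overall")
})

test_that("windows with no cases render as missing, not as failures", {
  res <- tiny_run("overall", windows = list(
    list(mode = "cohort", start = 1990, end = 1995, k = 5),
    list(mode = "period", start = 2014, end = 2018, k = 5)
  ), projection_enabled = FALSE)
  expect_equal(res$wide[["1990-1995"]], "—")
  expect_false(res$wide[["2014-2018"]] == "—")
})

test_that("percent formatting is one-decimal, half-even, with em-dash for NA", {
  expect_equal(format_rs(0.733, 0.003), "73.3 ± 0.3")
  expect_equal(format_rs(NA), "—")
  expect_equal(format_rs(0.5, NA), "50.0")
  # clearly-off-midpoint values round to the nearest decimal
  expect_equal(format_rs(0.7334, 0.0006), "73.3 ± 0.1")
  expect_equal(format_rs(0.7336, NA), "73.4")
})

test_that("rendered csv and markdown carry identical numbers, byte-stable", {
  d1 <- tempfile(); d2 <- tempfile()
  res <- tiny_run("sex", output_dir = d1)
  expect_true(all(file.exists(file.path(
    d1, c("estimates.csv", "estimates_wide.csv", "estimates_wide.md",
          "counts.csv", "filter_report.json", "projection.json",
          "run_config.json")))))
  wide_csv <- utils::read.csv(file.path(d1, "estimates_wide.csv"),
                              check.names = FALSE)
  md <- readLines(file.path(d1, "estimates_wide.md"))
  for (i in seq_len(nrow(wide_csv))) {
    cells <- trimws(strsplit(md[i + 2], "\\|")[[1]][-1])
    expect_equal(cells, trimws(unname(unlist(wide_csv[i, ]))))
  }
  render_tables(res, dir = d2)
  for (f in c("estimates.csv", "estimates_wide.md", "projection.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("run configurations round-trip through JSON", {
  f_cases <- tempfile(fileext = ".csv")
  f_lt <- tempfile(fileext = ".csv")
  spec <- simulation_spec(n_per_period = 50, periods = list(2004:2008),
                          cutoff = list(year = 2012, month = 12), seed = 2)
  lt <- simulate_lifetable(spec)
  write_lifetable(lt, f_lt)
  write_cohort(simulate_cohort(spec, lt), f_cases)
  cfg <- run_config(cases = f_cases, lifetable = f_lt,
                    stratifiers = c("sex", "age_group"), seed = 5)
  f <- tempfile(fileext = ".json")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back$stratifiers, cfg$stratifiers)
  expect_equal(back$weights, cfg$weights)
  expect_equal(length(back$windows), length(cfg$windows))
  expect_equal(back$seed, cfg$seed)
})

test_that("a JSON config drives the full pipeline including projection", {
  dir <- tempfile()
  dir.create(dir)
  spec <- simulation_spec(n_per_period = c(300, 400, 400, 400), seed = 23)
  lt <- simulate_lifetable(spec)
  write_lifetable(lt, file.path(dir, "lt.csv"))
  write_cohort(simulate_cohort(spec, lt), file.path(dir, "cases.csv"))
  cfg <- run_config(cases = file.path(dir, "cases.csv"),
                    lifetable = file.path(dir, "lt.csv"),
                    output_dir = file.path(dir, "out"),
                    stratifiers = "overall", seed = 23)
  write_run_config(cfg, file.path(dir, "config.json"))
  res <- run_analysis(file.path(dir, "config.json"))
  expect_s3_class(res$projections$overall, "projection_result")
  expect_true(is.finite(res$projections$overall$R_hat))
  expect_true(file.exists(file.path(dir, "out", "projection.json")))
  pj <- jsonlite::read_json(file.path(dir, "out", "projection.json"))
  expect_null(pj$overall$error)
  expect_equal(pj$overall$R_hat, res$projections$overall$R_hat)
})

test_that("invalid configurations fail before any computation", {
  expect_error(run_config(cases = "nope.csv", lifetable = "nope.csv"),
               "not found")
  spec <- simulation_spec(n_per_period = 10, periods = list(2004:2008),
                          cutoff = list(year = 2010, month = 12), seed = 3)
  lt <- simulate_lifetable(spec)
  coh <- simulate_cohort(spec, lt)
  expect_error(run_config(cases = coh, lifetable = lt,
                          stratifiers = "shoe_size"), "unknown stratifier")
  expect_error(run_config(cases = coh, lifetable = lt,
                          windows = list(list(mode = "hybrid", start = 2004,
                                              end = 2008))),
               "unknown window mode")
})
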