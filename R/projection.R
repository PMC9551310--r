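#' Conditional 1-year relative-survival grid
#'
#' Assembles the input of the model-based projection: for each follow-up year
#' j = 1..k and each calendar period p = 1..P, the conditional 1-year
#' relative survival `r = p_j/pstar_j` and its effective denominator
#' `w = n'_j` from the period-specific risk-set tables. Ratios at or above 1
#' are clamped to `1 - eps` on the failure scale for link-scale fitting
#' (ratios at or below 0 to `eps`); the clamp count is recorded. Cells with
#' positive weight but an undefined ratio are flagged and skipped by the fit.
#'
#' @param estimates list of `survival_estimate` objects, one per period, all
#'   with the same number of intervals. Each must carry its `riskset`
#'   attribute (as returned by [relative_survival()]).
#' @param period_labels character labels, e.g. `"2004-2008"`; defaults to the
#'   window years of each estimate.
#' @param eps clamp distance on the failure scale (default 1e-6).
#' @return data.frame of class `conditional_grid` with columns `fu_year`,
#'   `period`, `period_label`, `r`, `w`, `flagged`; attributes `n_clamped`,
#'   `k`, `n_periods`.
#' @export
build_conditional_grid <- function(estimates, period_labels = NULL, eps = 1e-6) {
  P <- length(estimates)
  if (P < 2L) stop("projection needs at least 2 periods")
  ks <- vapply(estimates, nrow, integer(1))
  if (length(unique(ks)) != 1L) stop("all periods must share the same k")
  k <- ks[1]
  if (is.null(period_labels)) {
    period_labels <- vapply(estimates, function(e) {
      w <- attr(e, "window")
      if (is.null(w)) NA_character_ else sprintf("%d-%d", w$start, w$end)
    }, character(1))
  }
  cells <- do.call(rbind, lapply(seq_len(P), function(p) {
    est <- estimates[[p]]
    rs <- attr(est, "riskset")
    if (is.null(rs)) stop("estimate ", p, " lacks its riskset attribute")
    data.frame(fu_year = est$interval, period = p,
               period_label = period_labels[p],
               r = est$r, w = rs$n_eff, stringsAsFactors = FALSE)
  }))
  cells$flagged <- cells$w > 0 & (is.na(cells$r) | !is.finite(cells$r))
  usable <- !cells$flagged & cells$w > 0
  n_clamped <- sum(usable & (cells$r >= 1 | cells$r <= 0))
  cells$r[usable] <- pmin(pmax(cells$r[usable], eps), 1 - eps)
  class(cells) <- c("conditional_grid", "data.frame")
  attr(cells, "n_clamped") <- n_clamped
  attr(cells, "k") <- k
  attr(cells, "n_periods") <- P
  cells
}

#' Fit the period-trend projection model
#'
#' Fits a generalized linear model to the conditional 1-year failure
#' probabilities `q = 1 - r`: on the link scale (complementary log-log by
#' default), `link(q_{jp}) = alpha_j + gamma * p`, with a separate intercept
#' `alpha_j` per follow-up year and a linear trend `gamma` over the numeric
#' period index, each cell weighted by its effective denominator. Under the
#' cloglog link the linear predictor equals `log(-log r)`, the established
#' model-based period-analysis formulation; `gamma < 0` means improving
#' conditional survival over calendar periods.
#'
#' @param grid a `conditional_grid`.
#' @param link `"cloglog"` (default) or `"logit"`.
#' @return object of class `projection_fit`: coefficients `alpha` (length k)
#'   and `gamma`, the fitted [stats::glm] in `$fit`, `deviance`, `df`,
#'   `link`, `n_clamped`.
#' @export
fit_projection_model <- function(grid, link = c("cloglog", "logit")) {
  link <- match.arg(link)
  stopifnot(inherits(grid, "conditional_grid"))
  P <- attr(grid, "n_periods")
  k <- attr(grid, "k")
  if (P < 2L) stop("projection needs at least 2 periods")
  dat <- grid[!grid$flagged & grid$w > 0, , drop = FALSE]
  per_fy <- tapply(dat$period, dat$fu_year, function(p) length(unique(p)))
  if (any(per_fy < 2L)) {
    stop("fewer than 2 periods with usable cells at follow-up year(s): ",
         paste(names(per_fy)[per_fy < 2L], collapse = ", "))
  }
  dat$q <- 1 - dat$r
  dat$fy <- factor(dat$fu_year, levels = sort(unique(grid$fu_year)))
  # quasibinomial: same point estimates as binomial, tolerates the
  # non-integer effective denominators used as weights
  fit <- stats::glm(q ~ 0 + fy + period, data = dat,
                    family = stats::quasibinomial(link = link),
                    weights = dat$w)
  if (!fit$converged) {
    stop("projection model did not converge; deviance ",
         format(fit$deviance), " after ", fit$iter, " iterations")
  }
  cf <- stats::coef(fit)
  alpha <- cf[grep("^fy", names(cf))]
  names(alpha) <- sub("^fy", "", names(alpha))
  structure(
    list(alpha = alpha, gamma = unname(cf["period"]), link = link,
         fit = fit, deviance = stats::deviance(fit),
         df = stats::df.residual(fit),
         n_periods = P, k = k, n_clamped = attr(grid, "n_clamped")),
    class = "projection_fit"
  )
}

#' Project relative survival to a target period
#'
#' Inverts the fitted link at the target period index: per follow-up year,
#' `r_hat_j = 1 - linkinv(alpha_j + gamma * target_p)` (capped at 1), and
#' the projected cumulative k-year relative survival is the product
#' `R_hat_k = prod(r_hat_j)`. A target index beyond the fitted periods
#' extrapolates the period trend; an in-sample index reproduces the model's
#' fitted values.
#'
#' @param model a `projection_fit`.
#' @param target_p numeric period index (the fitted periods are 1..P).
#' @param k follow-up depth; default the model's k.
#' @return list of class `projection_result`: `r_hat` (per follow-up year),
#'   `R_hat` (cumulative at k), `target_p`, plus the model's coefficients
#'   and diagnostics.
#' @export
predict_future_period <- function(model, target_p, k = model$k) {
  stopifnot(inherits(model, "projection_fit"))
  if (k > length(model$alpha)) stop("k exceeds the fitted follow-up depth")
  eta <- model$alpha[seq_len(k)] + model$gamma * target_p
  linkinv <- stats::quasibinomial(link = model$link)$linkinv
  r_hat <- pmin(1 - linkinv(eta), 1)
  structure(
    list(r_hat = r_hat, R_hat = prod(r_hat), target_p = target_p, k = k,
         alpha = model$alpha, gamma = model$gamma, link = model$link,
         deviance = model$deviance, df = model$df,
         n_clamped = model$n_clamped),
    class = "projection_result"
  )
}

#' @export
print.projection_fit <- function(x, ...) {
  cat(sprintf("Projection GLM (%s link): %d follow-up years x %d periods\n",
              x$link, x$k, x$n_periods))
  cat(sprintf("  gamma (period trend) = %.6g; deviance %.4g on %d df; %d clamped cell(s)\n",
              x$gamma, x$deviance, x$df, x$n_clamped))
  invisible(x)
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projected %d-year relative survival at period index %g: %.4f\n",
              x$k, x$target_p, x$R_hat))
  cat("  conditional r_hat:", paste(sprintf("%.4f", x$r_hat), collapse = " "), "\n")
  invisible(x)
}

#' Parametric bootstrap of a projection
#'
#' Optional uncertainty for point projections: resamples each grid cell's
#' failure count as Binomial(round(w), q_hat) / round(w) under the fitted
#' model, refits, and re-projects. Seeded and reproducible.
#'
#' @param grid a `conditional_grid`.
#' @param target_p target period index.
#' @param n_boot number of bootstrap replicates.
#' @param link model link.
#' @param seed integer seed.
#' @return list: `R_hat` point projection, `se` bootstrap standard error,
#'   `quantiles` (2.5/97.5%), `replicates`.
#' @export
projection_bootstrap <- function(grid, target_p, n_boot = 200,
                                 link = "cloglog", seed = 1L) {
  fit <- fit_projection_model(grid, link)
  point <- predict_future_period(fit, target_p)
  usable <- !grid$flagged & grid$w > 0
  q_hat <- stats::fitted(fit$fit)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  w <- pmax(round(grid$w[usable]), 1)
  reps <- vapply(seq_len(n_boot), function(b) {
    g <- grid
    g$r[usable] <- 1 - stats::rbinom(length(w), w, q_hat) / w
    g$r[usable] <- pmin(pmax(g$r[usable], 1e-6), 1 - 1e-6)
    f <- fit_projection_model(g, link)
    predict_future_period(f, target_p)$R_hat
  }, numeric(1))
  list(R_hat = point$R_hat, se = stats::sd(reps),
       quantiles = stats::quantile(reps, c(0.025, 0.975)),
       replicates = reps)
}

#' Model metadata as JSON
#'
#' @param x a `projection_fit` or `projection_result`.
#' @param path optional output path.
#' @return JSON string, invisibly when written.
#' @export
projection_json <- function(x, path = NULL) {
  obj <- list(link = x$link, alpha = as.list(x$alpha), gamma = x$gamma,
              deviance = x$deviance, df = x$df, n_clamped = x$n_clamped)
  if (inherits(x, "projection_result")) {
    obj$target_p <- x$target_p
    obj$r_hat <- as.numeric(x$r_hat)
    obj$R_hat <- x$R_hat
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
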