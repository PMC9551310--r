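#' ICSS-style standard age weights
#'
#' Returns the shipped default weights for the five age bands 15-44, 45-54,
#' 55-64, 65-74 and 75+ (the ICSS standard-1 distribution: 0.07, 0.12, 0.23,
#' 0.29, 0.29). Weights are configuration, not code: supply your own named
#' vector to [age_standardized_rs()] for other standards or bands.
#'
#' @return named numeric vector summing to 1.
#' @export
icss_weights <- function() {
  c("15-44" = 0.07, "45-54" = 0.12, "55-64" = 0.23,
    "65-74" = 0.29, "75+" = 0.29)
}

#' Age-standardized relative survival
#'
#' Weighted average of age-group-specific relative survival,
#' `R_std = sum(w_a * R_a)`, with standard error combined in quadrature,
#' `se_std = sqrt(sum(w_a^2 * se_a^2))`.
#'
#' @param by_age data.frame with columns `age_group`, `R`, `se_R` (one row
#'   per age group), or a named list mapping group labels to `c(R, se_R)`.
#' @param weights named numeric vector of non-negative weights summing to 1
#'   (within 1e-12); names must be a subset of the estimate's age groups.
#' @return named numeric vector `c(R_std, se_std)`, or `NA`s with a `reason`
#'   attribute when a positively-weighted group is missing or undefined.
#' @export
age_standardized_rs <- function(by_age, weights = icss_weights()) {
  if (is.list(by_age) && !is.data.frame(by_age)) {
    by_age <- data.frame(
      age_group = names(by_age),
      R = vapply(by_age, `[`, numeric(1), 1L),
      se_R = vapply(by_age, `[`, numeric(1), 2L)
    )
  }
  if (any(weights < 0)) stop("standard weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-12) stop("standard weights must sum to 1")
  pos <- names(weights)[weights > 0]
  miss <- setdiff(pos, by_age$age_group)
  idx <- match(pos, by_age$age_group)
  bad <- pos[!is.na(idx) & (is.na(by_age$R[idx]) | is.na(by_age$se_R[idx]))]
  if (length(miss) || length(bad)) {
    return(structure(c(R_std = NA_real_, se_std = NA_real_),
                     reason = paste0("missing or undefined age group(s): ",
                                     paste(c(miss, bad), collapse = ", "))))
  }
  w <- weights[pos]
  c(R_std = sum(w * by_age$R[idx]),
    se_std = sqrt(sum(w^2 * by_age$se_R[idx]^2)))
}
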