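#' Pearson correlation between expected and observed abundances
#'
#' Standard product-moment correlation with the two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (delegated to
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return Named numeric vector `c(r, p_value)`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Ordinary least-squares fit with adjusted R-squared
#'
#' Simple linear regression `y ~ x` via [stats::lm()];
#' `adj_r2 = 1 - (1 - R^2)(n - 1)/(n - 2)`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` non-degenerate.
#' @return Named numeric vector `c(slope, intercept, adj_r2)`.
#' @export
linfit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("degenerate x: fit undefined")
  n <- length(x)
  if (stats::sd(y) == 0) {
    # flat response: R^2 = 0 by convention, adjusted form goes negative
    return(c(slope = 0, intercept = mean(y),
             adj_r2 = 1 - (n - 1) / (n - 2)))
  }
  fit <- stats::lm(y ~ x)
  # exact lines are legitimate input here; silence the perfect-fit notice
  s <- suppressWarnings(summary(fit))
  c(slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    adj_r2 = s$adj.r.squared)
}

#' Expected-vs-observed abundance concordance
#'
#' Joins an expected and an observed relative-abundance table by taxon
#' (normalized label comparison), filling taxa absent from the observation
#' with zero — undetected mock members count against concordance — and
#' reports the Pearson correlation and the least-squares fit, both on the
#' percentage scale.
#'
#' @param expected data.frame with columns `taxon` and `expected_ra`
#'   (fractions or percentages; see `percent`). [collapse_profile()] output
#'   works directly; an `expected_profile` is accepted and its `species`
#'   column used as taxon.
#' @param observed data.frame with columns `taxon` and `observed_ra`.
#' @param percent If `TRUE` (default) inputs that sum to ~1 are rescaled to
#'   percentages before comparison.
#' @return Object of class `concordance`: list with `r`, `p_value`, `slope`,
#'   `intercept`, `adj_r2`, `n` and the joined `data`.
#' @export
concordance <- function(expected, observed, percent = TRUE) {
  if (inherits(expected, "expected_profile")) {
    expected <- data.frame(taxon = expected$species,
                           expected_ra = expected$expected_ra)
  }
  stopifnot(all(c("taxon", "expected_ra") %in% names(expected)),
            all(c("taxon", "observed_ra") %in% names(observed)))
  key_e <- normalize_taxon(expected$taxon)
  key_o <- normalize_taxon(observed$taxon)
  if (anyDuplicated(key_e)) stop("duplicate taxa in expected table")
  obs <- observed$observed_ra[match(key_e, key_o)]
  obs[is.na(obs)] <- 0
  exp_v <- expected$expected_ra
  scale_to_pct <- function(v) {
    if (percent && abs(sum(v) - 1) < 0.01) v * 100 else v
  }
  exp_v <- scale_to_pct(exp_v)
  obs <- scale_to_pct(obs)
  pr <- pearson(exp_v, obs)
  lf <- linfit(exp_v, obs)
  out <- list(r = pr[["r"]], p_value = pr[["p_value"]],
              slope = lf[["slope"]], intercept = lf[["intercept"]],
              adj_r2 = lf[["adj_r2"]], n = length(exp_v),
              data = data.frame(taxon = expected$taxon, expected_pct = exp_v,
                                observed_pct = obs, stringsAsFactors = FALSE))
  class(out) <- "concordance"
  out
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(
    "Expected-vs-observed concordance over %d taxa\n  Pearson r = %.3f (p = %.3g)\n  OLS slope = %.3f, intercept = %.3f, adj R2 = %.3f\n",
    x$n, x$r, x$p_value, x$slope, x$intercept, x$adj_r2))
  invisible(x)
}
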