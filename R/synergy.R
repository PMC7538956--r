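#' Fit the median-effect model to single-agent dose-response data
#'
#' Ordinary least squares on the linearized median-effect plot
#' `log(fa / (1 - fa)) = m * log(D) - m * log(Dm)`, where the fraction
#' affected is `fa = 1 - viability`. Only points with `fa` strictly inside
#' (0, 1) and positive dose carry information; others are excluded with a
#' logged count.
#'
#' @param dose positive doses.
#' @param viability viabilities as fractions of the untreated control (see
#'   [normalize_viability()]).
#' @return object of class `median_effect_fit`: `m` (slope), `Dm`
#'   (median-effect dose), `r_squared`, `n_points`.
#' @export
fit_median_effect <- function(dose, viability) {
  if (length(dose) != length(viability))
    .stopf("'dose' and 'viability' must have equal length")
  fa <- 1 - viability
  usable <- is.finite(dose) & is.finite(fa) & dose > 0 & fa > 0 & fa < 1
  if (sum(!usable) > 0)
    .msgf("excluding %d point(s) with fa outside (0, 1) or dose <= 0",
          sum(!usable))
  if (sum(usable) < 2L || length(unique(dose[usable])) < 2L)
    .stopf("no information in (0, 1): need >= 2 usable points with distinct doses")
  x <- log(dose[usable])
  y <- log(fa[usable] / (1 - fa[usable]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m <= 0)
    .warnf("fitted slope m = %.3g is not positive; dose-response is not increasing", m)
  dm <- exp(-unname(stats::coef(fit)[1L]) / m)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(m = m, Dm = dm, r_squared = r2, n_points = sum(usable)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit: m = %.4g, Dm = %.4g (r^2 = %.4f, n = %d)\n",
              x$m, x$Dm, x$r_squared, x$n_points))
  invisible(x)
}

#' Normalize raw viability readings to the untreated control
#'
#' @param raw raw readings (e.g. MTT absorbances) for treated wells.
#' @param control raw readings of the untreated control wells.
#' @return viability fractions `raw / mean(control)`.
#' @export
normalize_viability <- function(raw, control) {
  if (!length(control) || mean(control) <= 0)
    .stopf("control readings must be nonempty with positive mean")
  raw / mean(control)
}

#' Effective dose for a target fraction affected
#'
#' Inverts the median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`; strictly increasing in `fa`.
#'
#' @param fit `median_effect_fit`.
#' @param fa fraction affected, strictly in (0, 1).
#' @return the dose producing the stated effect.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0) || any(fa >= 1))
    .stopf("'fa' must lie strictly in (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index at observed combination points
#'
#' For each combination point with observed fraction affected `fa`,
#' `CI = D1 / Dx1(fa) + D2 / Dx2(fa)` where `Dx` is each single agent's
#' effective dose for that `fa`. CI = 1 is additive, < 1 synergistic,
#' > 1 antagonistic (classified with a small numerical tolerance around 1).
#' Points whose `fa` falls outside (0, 1) are skipped with a log entry.
#'
#' @param fit_a,fit_b single-agent `median_effect_fit` objects.
#' @param combo data.frame with columns `dose_a`, `dose_b`, `viability`.
#' @param tol classification tolerance around CI = 1 (default 1e-8).
#' @return data.frame `dose_a`, `dose_b`, `fa`, `ci`, `classification`.
#' @export
combination_index <- function(fit_a, fit_b, combo, tol = 1e-8) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"))
  need <- c("dose_a", "dose_b", "viability")
  if (!all(need %in% names(combo)))
    .stopf("combo needs columns %s", paste(need, collapse = ", "))
  fa <- 1 - combo$viability
  ok <- fa > 0 & fa < 1
  if (any(!ok))
    .msgf("skipping %d combo point(s) with fa outside (0, 1)", sum(!ok))
  combo <- combo[ok, , drop = FALSE]
  fa <- fa[ok]
  ci <- combo$dose_a / dose_for_effect(fit_a, fa) +
        combo$dose_b / dose_for_effect(fit_b, fa)
  classification <- ifelse(abs(ci - 1) <= tol, "additive",
                    ifelse(ci < 1, "synergistic", "antagonistic"))
  data.frame(dose_a = combo$dose_a, dose_b = combo$dose_b, fa = fa,
             ci = ci, classification = classification, row.names = NULL)
}
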