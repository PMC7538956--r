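# Closed-form assay scores. All four are pure functions of their inputs.

#' T7 endonuclease 1 mutation frequency
#'
#' `100 * (1 - sqrt(1 - fraction_cleaved))`: converts the cleaved band
#' fraction of a heteroduplex digest into a percent editing frequency.
#' Monotone increasing; 0 at 0 and 100 at 1.
#'
#' @param fraction_cleaved fraction of cleaved band intensity, in [0, 1].
#' @return mutation frequency in percent.
#' @examples
#' t7e1_mutation_frequency(0.19)  # 10
#' @export
t7e1_mutation_frequency <- function(fraction_cleaved) {
  if (any(fraction_cleaved < 0) || any(fraction_cleaved > 1))
    .stopf("'fraction_cleaved' must lie in [0, 1]")
  100 * (1 - sqrt(1 - fraction_cleaved))
}

#' Immunohistochemistry H-index (Hirsch index)
#'
#' `1 * weak + 2 * moderate + 3 * strong` over the percentages of cells
#' staining weakly (1+), moderately (2+), and strongly (3+); ranges from 0
#' (no staining) to 300 (all cells 3+).
#'
#' @param weak,moderate,strong staining percentages in [0, 100], summing
#'   to at most 100.
#' @return H-index in [0, 300].
#' @export
h_index <- function(weak, moderate, strong) {
  for (v in list(weak, moderate, strong))
    if (any(v < 0) || any(v > 100))
      .stopf("staining percentages must lie in [0, 100]")
  if (any(weak + moderate + strong > 100))
    .stopf("staining percentages sum to more than 100")
  1 * weak + 2 * moderate + 3 * strong
}

#' Fold change from the 2^-ddCt method
#'
#' @param delta_delta_ct finite ddCt value(s).
#' @return `2^(-ddCt)` fold change relative to the calibrator.
#' @export
fold_change_ddct <- function(delta_delta_ct) {
  if (any(!is.finite(delta_delta_ct)))
    .stopf("'delta_delta_ct' must be finite")
  2^(-delta_delta_ct)
}

#' Caliper tumor volume
#'
#' `(length * width^2) / 2` in cubic millimeters. Warns (does not fail)
#' when width exceeds length, since caliper axis naming is a convention.
#'
#' @param length,width caliper measurements in mm, nonnegative.
#' @return tumor volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    .stopf("measurements must be nonnegative")
  if (any(width > length))
    .warnf("width exceeds length; check caliper axis assignment")
  (length * width^2) / 2
}
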