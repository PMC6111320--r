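#' Reference statistics of the ten-subject validation study
#'
#' Loads the printed summary statistics of the original ten-subject
#' validation study, shipped with the package as plain-text tables:
#' the pairwise Pearson correlations between grand-averaged markers with
#' their 95% CIs, and the per-participant classification accuracies (integer
#' percent with +-95% CI half-width) for every marker subset under
#' leave-one-epoch-out and leave-one-subject-out cross-validation. In the
#' accuracy table, `participant = "mean"` rows carry the column mean and the
#' sample standard deviation across participants.
#'
#' @return List with data.frames `pcc` (`pair`, `pcc`, `ci_low`, `ci_up`)
#'   and `accuracy` (`cv`, `features`, `participant`, `p_pct`, `pm_pct`).
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", "reference_tables", package = "stressmark")
  list(
    pcc = utils::read.delim(file.path(dir, "pcc_reference.tsv")),
    accuracy = utils::read.delim(file.path(dir, "accuracy_reference.tsv"),
                                 colClasses = c("character", "character",
                                                "character", "integer",
                                                "integer")))
}

#' Reconstruct Fisher confidence bounds from a correlation coefficient
#'
#' @param r Pearson coefficient(s).
#' @param n Number of paired epochs (630 for the reference curves).
#' @param z Normal quantile (1.96).
#' @return data.frame with `ci_low`, `ci_up`.
#' @export
reconstruct_fisher_ci <- function(r, n = 630, z = 1.96) {
  data.frame(ci_low = tanh(atanh(r) - z / sqrt(n - 3)),
             ci_up = tanh(atanh(r) + z / sqrt(n - 3)))
}

#' Reconstruct the integer-percent accuracy CI half-width
#'
#' Applies the binomial half-width `1.96 sqrt(p(1-p)/n)` to an accuracy
#' given in integer percent and rounds half-up to integer percent, the
#' convention of the reference accuracy tables.
#'
#' @param p_pct Accuracy in percent (vectorized).
#' @param n Number of observations (180 in the reference design).
#' @return Integer percent half-width(s).
#' @export
reconstruct_accuracy_halfwidth <- function(p_pct, n = 180) {
  round_half_up(100 * accuracy_ci(p_pct / 100, n))
}

#' Is a printed accuracy cell consistent with the binomial CI formula?
#'
#' The reference tables print the accuracy rounded to integer percent, so
#' the half-width they print may correspond to any true accuracy within
#' +-0.5 percentage points of the printed one. A cell is consistent when
#' some accuracy in that interval reproduces the printed half-width under
#' the binomial formula (half-up rounding).
#'
#' @param p_pct Printed accuracy, integer percent (vectorized).
#' @param pm_pct Printed CI half-width, integer percent.
#' @param n Number of observations.
#' @return Logical vector.
#' @export
accuracy_cell_consistent <- function(p_pct, pm_pct, n = 180) {
  mapply(function(p, pm) {
    grid <- seq(max(0, p - 0.5), min(100, p + 0.5), by = 0.01)
    any(reconstruct_accuracy_halfwidth(grid, n) == pm)
  }, p_pct, pm_pct)
}
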