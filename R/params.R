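#' Global model parameters
#'
#' Bundles the population and selection parameters of the two-sex stabilizing
#' selection model: population size `N`, per-gamete mutation rate `U`, the
#' width `VS` of the Gaussian fitness function, the sex-specific selection
#' shares `gamma_f`, `gamma_m` (with \eqn{\gamma_f^2 + \gamma_m^2 = 1}), and
#' the sex-specific optima `O_f`, `O_m`.
#'
#' Traits are measured in units of \eqn{\delta = \sqrt{V_S/(2N)}}, the typical
#' equilibrium fluctuation of the population mean about the optimum. The
#' default `VS = 2N` makes \eqn{\delta = 1}, in which units an allele's
#' squared overall magnitude \eqn{a^2} equals its scaled stabilizing-selection
#' coefficient \eqn{2Ns_e}.
#'
#' @param N Population size (individuals, both sexes combined).
#' @param U Expected number of new mutations per gamete per generation.
#'   May be left `NA` and filled in later via [calibrate_U()].
#' @param VS Width of the Gaussian fitness function (trait squared units).
#'   Default `2 * N`, i.e. delta units.
#' @param gamma_f,gamma_m Sex-specific selection-share factors, both positive
#'   with `gamma_f^2 + gamma_m^2 == 1`. Defaults give equal selection in the
#'   two sexes.
#' @param O_f,O_m Sex-specific optima (trait units).
#'
#' @return An object of class `"model_params"`: a list with the fields above
#'   plus the derived `delta` (\eqn{\sqrt{V_S/(2N)}}) and the sex-specific
#'   fitness widths `VS_f = VS / (2 gamma_f^2)`, `VS_m = VS / (2 gamma_m^2)`.
#' @examples
#' p <- model_params(N = 1000)
#' p$delta      # 1 under the default VS = 2N
#' p$VS_f       # equals VS with equal selection shares
#' @export
model_params <- function(N, U = NA_real_, VS = 2 * N,
                         gamma_f = 1 / sqrt(2), gamma_m = 1 / sqrt(2),
                         O_f = 0, O_m = 0) {
  stopifnot(N >= 2, VS > 0, is.na(U) || U >= 0)
  if (gamma_f <= 0 || gamma_m <= 0)
    stop("gamma_f and gamma_m must be positive (neither sex evolves neutrally)")
  if (abs(gamma_f^2 + gamma_m^2 - 1) > 1e-8)
    stop("gamma_f^2 + gamma_m^2 must equal 1")
  if (!is.na(U) && 2 * N * U <= 1)
    warning("2NU <= 1: outside the high-polygenicity regime the theory assumes")
  structure(list(
    N = N, U = U, VS = VS,
    gamma_f = gamma_f, gamma_m = gamma_m,
    O_f = O_f, O_m = O_m,
    delta = sqrt(VS / (2 * N)),
    VS_f = VS / (2 * gamma_f^2),
    VS_m = VS / (2 * gamma_m^2)
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-sex stabilizing selection model parameters\n")
  cat(sprintf("  N = %g, U = %s, VS = %g (delta = %g)\n",
              x$N, format(x$U), x$VS, x$delta))
  cat(sprintf("  gamma_f = %.4f, gamma_m = %.4f  (VS_f = %g, VS_m = %g)\n",
              x$gamma_f, x$gamma_m, x$VS_f, x$VS_m))
  cat(sprintf("  optima: O_f = %g, O_m = %g\n", x$O_f, x$O_m))
  invisible(x)
}

#' Average / average-difference coordinates
#'
#' Transforms a (female, male) pair of any quantity into its "average" and
#' "average difference" coordinates, \eqn{k_a = (k_f + k_m)/2} and
#' \eqn{k_d = (k_f - k_m)/2}, and back. Changes in the average coordinate
#' capture concordant evolution of the population as a whole; changes in the
#' difference coordinate capture the evolution of (half the) signed sexual
#' dimorphism.
#'
#' @param kf,km Female and male values (vectors of equal length).
#' @param ka,kd Average and half-difference values.
#' @return `to_avg_diff()` returns a list with components `a` and `d`;
#'   `from_avg_diff()` returns a list with components `f` and `m`. The two are
#'   exact inverses.
#' @examples
#' to_avg_diff(3, 1)            # a = 2, d = 1
#' from_avg_diff(2, 1)          # f = 3, m = 1
#' @export
to_avg_diff <- function(kf, km) {
  list(a = (kf + km) / 2, d = (kf - km) / 2)
}

#' @rdname to_avg_diff
#' @export
from_avg_diff <- function(ka, kd) {
  list(f = ka + kd, m = ka - kd)
}
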