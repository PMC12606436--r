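#' Dawson's integral
#'
#' Evaluates Dawson's function \eqn{D_+(x) = e^{-x^2} \int_0^x e^{t^2} dt},
#' which gives the expected per-unit-mutational-input contribution of an
#' allele of magnitude \eqn{a} to equilibrium genetic variance through
#' \eqn{v(a) = 4 a D_+(a/2)}.
#'
#' Computed through the substitution \eqn{t = x - u}, which turns the defining
#' integral into \eqn{D_+(x) = \int_0^x e^{u(u - 2x)} du} with an integrand
#' bounded by 1 for x > 0; this is numerically stable for all magnitudes that
#' arise here (no overflow, no cancellation).
#'
#' @param x Numeric vector.
#' @return `D_+(x)`, same length as `x`.
#' @examples
#' dawson(1)   # 0.53808
#' @export
dawson <- function(x) {
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    s <- sign(xi); xi <- abs(xi)  # odd function
    s * stats::integrate(function(u) exp(u * (u - 2 * xi)), 0, xi,
                         rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

#' Sojourn variance function v(a)
#'
#' Expected contribution to equilibrium genetic variance per unit mutational
#' input of an allele with overall magnitude `a` (delta units),
#' \eqn{v(a) = 4a D_+(a/2)}. Behaves as \eqn{2a^2} for small `a` (nearly
#' neutral alleles) and saturates at 4 for strongly selected alleles.
#'
#' @param a Overall allelic magnitude (non-negative, delta units).
#' @return `v(a)`, same length as `a`.
#' @export
sojourn_variance <- function(a) 4 * a * dawson(a / 2)

#' Mutation model: magnitudes and sex-bias angles
#'
#' Describes the distribution of incoming mutations. Squared overall
#' magnitudes \eqn{a^2} (equal to the scaled selection coefficient
#' \eqn{2Ns_e} in delta units) are exponential with mean `mean_sq`. The
#' sex-bias angle \eqn{\phi_a}, which sets the fraction of stabilizing
#' selection acting through each sex
#' (\eqn{\cos^2\phi_a} via females, \eqn{\sin^2\phi_a} via males), is drawn
#' independently of the magnitude, either from the simplified shared /
#' sex-specific mixture `h_r` or from a user-supplied discrete density.
#'
#' Under `h_r`, a fraction `r` of mutations are shared (equal effects in the
#' two sexes, \eqn{\phi_a = \pi/4} or \eqn{5\pi/4}) and the remaining
#' `1 - r` are sex-specific, half female-specific (\eqn{\phi_a = 0, \pi}) and
#' half male-specific (\eqn{\phi_a = \pi/2, 3\pi/2}); each mutation is equally
#' likely to increase or decrease the trait. The expected intersex
#' correlation at equilibrium then equals `r` exactly.
#'
#' @param mean_sq Mean of the exponential distribution of squared magnitudes
#'   \eqn{E(a^2)}, in delta-squared units. `mean_sq = 1` gives an
#'   approximately infinitesimal architecture; `mean_sq = 16` a multigenic one.
#' @param r Fraction of shared mutations under the `h_r` angle distribution.
#'   Ignored when `angles` is supplied.
#' @param angles Optional data frame with columns `angle` (radians) and
#'   `weight` defining a discrete angle density h(phi). Weights are
#'   normalised; the density is symmetrised so that h(phi) = h(phi + pi)
#'   (mutations equally likely to increase or decrease the trait).
#' @return An object of class `"mutation_model"` with elements `mean_sq`,
#'   `r` (or `NA` for custom angles), and `angles` (data frame of angle,
#'   weight covering the full circle).
#' @examples
#' mm <- mutation_model(mean_sq = 1, r = 0.5)
#' equilibrium_sex_moments(mm, model_params(N = 1000, U = 0.0134))$rfm  # 0.5
#' @export
mutation_model <- function(mean_sq = 1, r = 0.5, angles = NULL) {
  stopifnot(mean_sq > 0)
  if (is.null(angles)) {
    if (r < 0 || r > 1) stop("r must lie in [0, 1]")
    s2 <- sqrt(0.5)
    # direction cosines written out exactly so shared mutations get af == am
    # and sex-specific mutations an effect of exactly 0 in the other sex
    angles <- data.frame(
      angle  = c(pi / 4, 0, pi / 2, 5 * pi / 4, pi, 3 * pi / 2),
      weight = c(r / 2, (1 - r) / 4, (1 - r) / 4,
                 r / 2, (1 - r) / 4, (1 - r) / 4),
      cosphi = c(s2, 1, 0, -s2, -1, 0),
      sinphi = c(s2, 0, 1, -s2, 0, -1)
    )
  } else {
    stopifnot(all(c("angle", "weight") %in% names(angles)),
              all(angles$weight >= 0), sum(angles$weight) > 0)
    r <- NA_real_
    # enforce h(phi) = h(phi + pi): split every weight over the two signs
    angles <- data.frame(
      angle  = c(angles$angle, angles$angle + pi) %% (2 * pi),
      weight = rep(angles$weight / 2, 2)
    )
    angles$weight <- angles$weight / sum(angles$weight)
  }
  angles <- angles[angles$weight > 0, , drop = FALSE]
  if (is.null(angles$cosphi)) {
    angles$cosphi <- zap_tiny(cos(angles$angle))
    angles$sinphi <- zap_tiny(sin(angles$angle))
  }
  structure(list(mean_sq = mean_sq, r = r, angles = angles),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("Mutation model: a^2 ~ Exponential(mean %g)", x$mean_sq))
  if (!is.na(x$r)) cat(sprintf(", h_r angle mixture with r = %g\n", x$r))
  else cat(sprintf(", custom angle density on %d atoms\n", nrow(x$angles)))
  invisible(x)
}

#' Draw sex-specific effects for new mutations
#'
#' Samples `n` new mutations: overall magnitude \eqn{a} with
#' \eqn{a^2 \sim} Exponential(`mean_sq`), angle \eqn{\phi_a} from the model's
#' angle density (independent of `a`), then sex-specific per-copy effects
#' \eqn{a_f = a\cos(\phi_a)/\gamma_f}, \eqn{a_m = a\sin(\phi_a)/\gamma_m}.
#'
#' @param n Number of mutations to draw.
#' @param model A [mutation_model()].
#' @param params A [model_params()]; supplies `gamma_f`, `gamma_m`.
#' @return A list with numeric vectors `af`, `am` of length `n`.
#' @export
draw_mutations <- function(n, model, params) {
  if (n == 0) return(list(af = numeric(0), am = numeric(0)))
  a   <- sqrt(stats::rexp(n, rate = 1 / model$mean_sq))
  idx <- sample.int(nrow(model$angles), n, replace = TRUE,
                    prob = model$angles$weight)
  list(af = a * model$angles$cosphi[idx] / params$gamma_f,
       am = a * model$angles$sinphi[idx] / params$gamma_m)
}

#' Equilibrium overall genetic variance
#'
#' The expected overall genic variance at mutation-selection-drift balance,
#' \eqn{V_{A,O} = 2NU \int_0^\infty v(a) g(a) da} with
#' \eqn{v(a) = 4a D_+(a/2)} and g(a) the magnitude density induced by
#' \eqn{a^2 \sim} Exponential(`mean_sq`). The quadrature is performed on the
#' exponential scale (over \eqn{s = a^2}), which handles the heavy-tailed
#' multigenic architecture accurately.
#'
#' @param model A [mutation_model()].
#' @param params A [model_params()] with a non-missing `U`.
#' @param U Optional override of `params$U`.
#' @return Overall variance \eqn{V_{A,O}} in delta-squared units.
#' @examples
#' p <- model_params(N = 1000, U = 0.0134)
#' equilibrium_overall_variance(mutation_model(mean_sq = 1), p)  # ~ 40
#' @export
equilibrium_overall_variance <- function(model, params, U = params$U) {
  if (is.na(U)) stop("U is not set; supply U or use calibrate_U()")
  2 * params$N * U * mean_sojourn_variance(model)
}

zap_tiny <- function(x, eps = 1e-12) {
  x[abs(x) < eps] <- 0
  x
}

# E[v(a)] under a^2 ~ Exponential(mean_sq); integral over s = a^2
mean_sojourn_variance <- function(model) {
  m <- model$mean_sq
  stats::integrate(function(s) sojourn_variance(sqrt(s)) * exp(-s / m) / m,
                   0, Inf, rel.tol = 1e-10)$value
}

#' Calibrate the mutation rate to a target equilibrium variance
#'
#' Inverts the equilibrium-variance integral (which is linear in `U`) to find
#' the per-gamete mutation rate giving a target overall variance
#' \eqn{V_{A,*}} at mutation-selection-drift balance.
#'
#' @param model A [mutation_model()].
#' @param params A [model_params()].
#' @param target_VA Target overall genetic variance (delta-squared units).
#' @return The mutation rate `U` (mutations per gamete per generation).
#' @examples
#' p <- model_params(N = 1000)
#' calibrate_U(mutation_model(mean_sq = 1), p, 40)   # 0.0134
#' calibrate_U(mutation_model(mean_sq = 16), p, 40)  # 0.0047
#' @export
calibrate_U <- function(model, params, target_VA) {
  if (target_VA < 0) stop("target_VA must be non-negative")
  target_VA / (2 * params$N * mean_sojourn_variance(model))
}

#' Equilibrium sex-specific variances, covariance, and intersex correlation
#'
#' Combines the overall equilibrium variance with the three angle integrals
#' \deqn{V_{A,f}/V_{A,O} = \gamma_f^{-2} \int \cos^2\phi\, h(\phi) d\phi,\quad
#'       V_{A,m}/V_{A,O} = \gamma_m^{-2} \int \sin^2\phi\, h(\phi) d\phi,}
#' \deqn{B/V_{A,O} = (\gamma_f\gamma_m)^{-1} \int \cos\phi \sin\phi\,
#'       h(\phi) d\phi,}
#' and returns the implied intersex correlation
#' \eqn{r_{fm} = B/\sqrt{V_{A,f} V_{A,m}}}. Under the `h_r` mixture with equal
#' selection shares this yields \eqn{V_{A,f} = V_{A,m} = V_{A,O}} and
#' \eqn{r_{fm} = r}.
#'
#' @param model A [mutation_model()].
#' @param params A [model_params()].
#' @param U Optional override of `params$U`; when neither is available the
#'   moments are returned relative to `VA_O = 1`.
#' @return A list with `VA_f`, `VA_m`, `B`, `rfm`, and `VA_O`. `rfm` is `NA`
#'   if either sex has zero variance.
#' @export
equilibrium_sex_moments <- function(model, params, U = params$U) {
  VA_O <- if (is.na(U)) 1 else equilibrium_overall_variance(model, params, U)
  w  <- model$angles$weight / sum(model$angles$weight)
  cp <- model$angles$cosphi
  sp <- model$angles$sinphi
  cf <- sum(cp^2 * w)
  cm <- sum(sp^2 * w)
  cb <- sum(cp * sp * w)
  VA_f <- VA_O * cf / params$gamma_f^2
  VA_m <- VA_O * cm / params$gamma_m^2
  B    <- VA_O * cb / (params$gamma_f * params$gamma_m)
  rfm  <- if (VA_f > 0 && VA_m > 0) B / sqrt(VA_f * VA_m) else NA_real_
  list(VA_f = VA_f, VA_m = VA_m, B = B, rfm = rfm, VA_O = VA_O)
}
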