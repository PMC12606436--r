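#' Drift-induced sexual dimorphism at equilibrium
#'
#' Closed-form predictions for the stationary fluctuations at
#' mutation-selection-drift balance with coinciding sex-specific optima and
#' imperfect intersex correlation (`rfm < 1`): the population mean fluctuates
#' with variance \eqn{V[\bar z] = \delta^2}, each sex-specific mean with
#' \eqn{V[\bar z_{f/m}] = 2\delta^2} (the sexes' means are uncorrelated), the
#' signed dimorphism with \eqn{V[SD_\pm] = 4\delta^2}, and - because
#' \eqn{SD_\pm} is approximately Gaussian - the expected absolute dimorphism
#' is \eqn{E[SD] = 2\sqrt{2/\pi}\,\delta \approx 1.6\,\delta}.
#'
#' @param params A [model_params()] (only `delta` is used).
#' @return A list with `E_SD`, `V_SD`, `V_zfm`, and `V_zbar`.
#' @examples
#' drift_sd_prediction(model_params(N = 1000, U = 0.01))$E_SD  # ~1.596
#' @export
drift_sd_prediction <- function(params) {
  d <- params$delta
  list(E_SD = 2 * sqrt(2 / pi) * d,
       V_SD = 4 * d^2,
       V_zfm = 2 * d^2,
       V_zbar = d^2)
}

#' Dimorphism scaled by the phenotypic standard deviation
#'
#' The unitless significance ratio \eqn{E[SD]/\sqrt{V_A}}: how large the
#' expected dimorphism is relative to the standard deviation of the
#' (sex-specific) trait distribution. Drift-induced dimorphism is negligible
#' for high-variance traits and substantial when \eqn{V_A} is within an order
#' of magnitude of \eqn{\delta^2}.
#'
#' @param E_SD Expected sexual dimorphism (trait units).
#' @param VA Additive genetic variance (trait squared units), positive.
#' @return `E_SD / sqrt(VA)`.
#' @export
scaled_sd <- function(E_SD, VA) {
  if (any(VA <= 0)) stop("VA must be positive")
  E_SD / sqrt(VA)
}

#' Infinitesimal (constant-moments) trajectories after a shift in optima
#'
#' Solves the two-sex breeder's equation with constant genetic (co)variances,
#' in average / difference coordinates. With equal sex-specific variances
#' (`VA_d = 0`) the system decouples into
#' \deqn{D_a(t) = \Lambda_a e^{-t (V_{A,a} + B)/(2 V_S)}, \qquad
#'       D_d(t) = \Lambda_d e^{-t (V_{A,a} - B)/(2 V_S)},}
#' and the signed dimorphism, relative to its pre-shift value, follows
#' \eqn{SD_\pm(t) = 2\Lambda_d (1 - e^{-t (V_{A,a} - B)/(2V_S)})}. With
#' `VA_d != 0` the coupled linear system is solved exactly through the
#' eigendecomposition of the G' matrix.
#'
#' @param VA_a Average additive variance at the shift, \eqn{(V_{A,f} +
#'   V_{A,m})/2}.
#' @param B Intersex covariance at the shift.
#' @param shift A [shift_spec()].
#' @param params A [model_params()].
#' @param times Numeric vector of generations since the shift.
#' @param VA_d Half-difference of sex-specific variances (default 0).
#' @return A data frame with columns `generation`, `Da`, `Dd`, and `SDpm`
#'   (signed dimorphism gained since the shift, \eqn{2(\Lambda_d - D_d)}).
#' @export
lande_trajectories <- function(VA_a, B, shift, params, times, VA_d = 0) {
  G <- matrix(c(VA_a + B, VA_d, VA_d, VA_a - B), 2, 2) / (2 * params$VS)
  D0 <- c(shift$Lambda_a, shift$Lambda_d)
  if (VA_d == 0) {
    Da <- D0[1] * exp(-times * G[1, 1])
    Dd <- D0[2] * exp(-times * G[2, 2])
  } else {
    e <- eigen(G, symmetric = TRUE)
    w <- crossprod(e$vectors, D0)
    Dt <- e$vectors %*% (exp(outer(-e$values, times)) * as.vector(w))
    Da <- Dt[1, ]; Dd <- Dt[2, ]
  }
  data.frame(generation = times, Da = Da, Dd = Dd,
             SDpm = 2 * (shift$Lambda_d - Dd))
}

#' Lengths of the rapid phases of concordant and discordant adaptation
#'
#' The rapid phase ends when the distance from the (new) optimum falls to the
#' typical equilibrium fluctuation \eqn{\delta}:
#' \deqn{t_a = \frac{2V_S}{V_{A,a} + B} \ln(\Lambda_a/\delta), \qquad
#'       t_d = \frac{2V_S}{V_{A,a} - B} \ln(\Lambda_d/\delta).}
#' At equal shift sizes their ratio is
#' \eqn{t_d/t_a = (V_{A,a}+B)/(V_{A,a}-B) = (1+r_{fm})/(1-r_{fm})}: high
#' intersex correlation speeds concordant adaptation but delays discordant
#' adaptation, without limit as \eqn{r_{fm} \to 1}.
#'
#' @param VA_a Average additive variance.
#' @param B Intersex covariance.
#' @param Lambda_a,Lambda_d Shift sizes (must exceed `delta` for a positive
#'   phase length; a shift of exactly `delta` gives 0).
#' @param params A [model_params()].
#' @return A list with `ta`, `td`, and `ratio` (the equal-shift ratio
#'   \eqn{(V_{A,a}+B)/(V_{A,a}-B)}, `Inf` when `B == VA_a`).
#' @export
adaptation_timescales <- function(VA_a, B, Lambda_a, Lambda_d, params) {
  d <- params$delta
  ta <- 2 * params$VS / (VA_a + B) * log(Lambda_a / d)
  td <- if (B >= VA_a) Inf else
    2 * params$VS / (VA_a - B) * log(Lambda_d / d)
  ratio <- if (B >= VA_a) Inf else (VA_a + B) / (VA_a - B)
  list(ta = ta, td = td, ratio = ratio)
}

#' One step of the moment-driven two-sex breeder's equation
#'
#' Expected one-generation change in the distances of the sex-specific means
#' from their optima, given the current second and third central moments of
#' the joint phenotype distribution:
#' \deqn{E[\Delta D] = \frac{1}{2 V_S}\,\Gamma\,(\mu_3 - G D),}
#' with \eqn{\Gamma = diag(2\gamma_f^2, 2\gamma_m^2)},
#' \eqn{G = [[V_{A,f}, B], [B, V_{A,m}]]} and
#' \eqn{\mu_3 = (\mu_{3,f}, \mu_{3,m})}. The first (directional) term pulls
#' means toward the optima; the second reflects stabilizing selection acting
#' on a skewed distribution. `breeder_step()` is the same operation in
#' average / difference coordinates (valid for equal selection shares,
#' \eqn{\gamma_f = \gamma_m = 1/\sqrt 2}), with
#' \eqn{G' = [[V_{A,a}+B, V_{A,d}], [V_{A,d}, V_{A,a}-B]]}; with `mu3 = 0`
#' and constant moments it reduces to the constant-G recursion underlying
#' [lande_trajectories()].
#'
#' @param D Length-2 vector of distances: `c(Df, Dm)` for
#'   `breeder_step_fm()`, `c(Da, Dd)` for `breeder_step()`.
#' @param moments Named list/row: `VA_f`, `VA_m`, `B`, `mu3_f`, `mu3_m` for
#'   the sex-specific form; `VA_a`, `VA_d`, `B`, `mu3_a`, `mu3_d` for the
#'   average/difference form.
#' @param params A [model_params()].
#' @return Length-2 vector of expected changes `c(dDf, dDm)` (or
#'   `c(dDa, dDd)`).
#' @export
breeder_step_fm <- function(D, moments, params) {
  G <- matrix(c(moments$VA_f, moments$B, moments$B, moments$VA_m), 2, 2)
  mu3 <- c(moments$mu3_f, moments$mu3_m)
  gam <- c(2 * params$gamma_f^2, 2 * params$gamma_m^2)
  as.vector(gam * (mu3 - G %*% D)) / (2 * params$VS)
}

#' @rdname breeder_step_fm
#' @export
breeder_step <- function(D, moments, params) {
  if (abs(params$gamma_f^2 - 0.5) > 1e-8)
    stop("average/difference form requires equal selection shares; use breeder_step_fm()")
  G <- matrix(c(moments$VA_a + moments$B, moments$VA_d,
                moments$VA_d, moments$VA_a - moments$B), 2, 2)
  mu3 <- c(moments$mu3_a, moments$mu3_d)
  as.vector(mu3 - G %*% D) / (2 * params$VS)
}

#' Integrate the breeder's equation along a simulated moment series
#'
#' Drives the moment-dependent breeder's equation ([breeder_step()]) with a
#' time series of second and third central moments (typically
#' across-replicate means from simulation), producing the predicted mean
#' trajectories of `Da` and `Dd` after a shift. Moments are interpolated
#' linearly onto integer generations between recorded time points; the
#' recursion is applied one generation at a time.
#'
#' @param moment_series Data frame with columns `generation`, `VA_a`, `VA_d`,
#'   `B`, `mu3_a`, `mu3_d` spanning the prediction horizon (generations since
#'   the shift, starting at 0).
#' @param shift A [shift_spec()]; sets the initial distances
#'   `Da(0) = Lambda_a`, `Dd(0) = Lambda_d`.
#' @param params A [model_params()].
#' @return A data frame with `generation`, `Da`, `Dd`, and `SDpm` (signed
#'   dimorphism gained since the shift).
#' @export
predict_breeder_trajectory <- function(moment_series, shift, params) {
  gmax <- max(moment_series$generation)
  gg <- 0:gmax
  interp <- function(col)
    stats::approx(moment_series$generation, moment_series[[col]],
                  xout = gg, rule = 2)$y
  VA_a <- interp("VA_a"); VA_d <- interp("VA_d"); B <- interp("B")
  m3a <- interp("mu3_a"); m3d <- interp("mu3_d")
  D <- c(shift$Lambda_a, shift$Lambda_d)
  out <- matrix(NA_real_, length(gg), 2)
  out[1, ] <- D
  for (i in seq_len(gmax)) {
    D <- D + breeder_step(D, list(VA_a = VA_a[i], VA_d = VA_d[i], B = B[i],
                                  mu3_a = m3a[i], mu3_d = m3d[i]), params)
    out[i + 1L, ] <- D
  }
  data.frame(generation = gg, Da = out[, 1], Dd = out[, 2],
             SDpm = 2 * (shift$Lambda_d - out[, 2]))
}

#' Exponential equilibration of the fixed backgrounds
#'
#' After a shift, the component of each mean phenotype maintained by
#' fixations approaches the new optimum approximately exponentially at rate
#' `1/(2N)`:
#' \eqn{F_a(t) \approx \Lambda_a e^{-t/(2N)}},
#' \eqn{F_d(t) \approx \Lambda_d e^{-t/(2N)}}.
#' The `F_d` approximation degrades when the intersex correlation is high,
#' and a multigenic architecture shows mild deviations from exponential
#' decay; both approximations remain accurate on the 2N-generation scale.
#'
#' @param shift A [shift_spec()].
#' @param params A [model_params()].
#' @param times Generations since the shift.
#' @return A data frame with `generation`, `Fa`, `Fd`.
#' @export
equilibration_decay <- function(shift, params, times) {
  e <- exp(-times / (2 * params$N))
  data.frame(generation = times,
             Fa = shift$Lambda_a * e,
             Fd = shift$Lambda_d * e)
}
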