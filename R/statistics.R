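#' All phenotypic moments of a population state
#'
#' Evaluates, by direct summation over segregating alleles, the full set of
#' phenotypic summaries at one generation: sex-specific means, additive
#' variances \eqn{V_{A,f} = \sum_i 2 a_{i,f}^2 x_i (1 - x_i)} (and likewise
#' for males), intersex covariance
#' \eqn{B = \sum_i 2 a_{i,f} a_{i,m} x_i (1 - x_i)}, intersex correlation
#' \eqn{r_{fm} = B / \sqrt{V_{A,f} V_{A,m}}}, signed and absolute sexual
#' dimorphism, third central moments
#' \eqn{\mu_{3,\alpha\beta\gamma} = \sum_i 2 a_{i,\alpha} a_{i,\beta}
#' a_{i,\gamma} x_i (1-x_i)(1-2x_i)}, overall variance
#' \eqn{V_{A,O} = \sum_i 2 a_i^2 x_i(1-x_i)} with
#' \eqn{a_i^2 = a_{i,f}^2\gamma_f^2 + a_{i,m}^2\gamma_m^2},
#' the within/between/total variance decomposition, distances of the means
#' and of the fixed backgrounds from the optima, and everything in
#' average / difference coordinates.
#'
#' With no segregating variation all variance and third-moment fields are 0
#' and `rfm` is `NA` (undefined, not zero).
#'
#' @param state A [population_state()].
#' @param params A [model_params()].
#' @param optima Current optima `c(O_f, O_m)`; defaults to those in `params`.
#' @return A one-row data frame.
#' @export
compute_moments <- function(state, params,
                            optima = c(params$O_f, params$O_m)) {
  af <- state$af; am <- state$am; x <- state$x
  h  <- 2 * x * (1 - x)
  t3 <- x * (1 - x) * (1 - 2 * x)
  zf <- state$Ff + sum(2 * af * x)
  zm <- state$Fm + sum(2 * am * x)
  VA_f <- sum(af^2 * h)
  VA_m <- sum(am^2 * h)
  B    <- sum(af * am * h)
  VA_O <- sum((af^2 * params$gamma_f^2 + am^2 * params$gamma_m^2) * h)
  rfm  <- if (VA_f > 0 && VA_m > 0) B / sqrt(VA_f * VA_m) else NA_real_
  mu3_fff <- sum(2 * af^3 * t3)
  mu3_ffm <- sum(2 * af^2 * am * t3)
  mu3_fmm <- sum(2 * af * am^2 * t3)
  mu3_mmm <- sum(2 * am^3 * t3)
  mu3_f <- (mu3_fff + mu3_fmm) / 2
  mu3_m <- (mu3_mmm + mu3_ffm) / 2
  SDpm <- zf - zm
  VA_a <- (VA_f + VA_m) / 2
  VA_b <- (SDpm / 2)^2
  Oad <- to_avg_diff(optima[1L], optima[2L])
  Fad <- to_avg_diff(state$Ff, state$Fm)
  data.frame(
    generation = state$generation, n_seg = length(x),
    zf = zf, zm = zm, za = (zf + zm) / 2, zd = (zf - zm) / 2,
    SDpm = SDpm, SD = abs(SDpm),
    VA_f = VA_f, VA_m = VA_m, B = B, rfm = rfm, VA_O = VA_O,
    VA_a = VA_a, VA_d = (VA_f - VA_m) / 2,
    VA_w = VA_a, VA_b = VA_b, VA_t = VA_a + VA_b,
    mu3_fff = mu3_fff, mu3_ffm = mu3_ffm,
    mu3_fmm = mu3_fmm, mu3_mmm = mu3_mmm,
    mu3_f = mu3_f, mu3_m = mu3_m,
    mu3_a = (mu3_f + mu3_m) / 2, mu3_d = (mu3_f - mu3_m) / 2,
    Df = optima[1L] - zf, Dm = optima[2L] - zm,
    Da = Oad$a - (zf + zm) / 2, Dd = Oad$d - (zf - zm) / 2,
    Ff = state$Ff, Fm = state$Fm,
    Fa = Oad$a - Fad$a, Fd = Oad$d - Fad$d
  )
}

#' Within-sex, between-sex, and total additive variance
#'
#' Decomposes the total additive variance across both sexes as
#' \eqn{V_{A,t} = V_{A,w} + V_{A,b}}, where the within-sex variance is the
#' average of the sex-specific variances, \eqn{V_{A,w} = (V_{A,f} +
#' V_{A,m})/2}, and the between-sex variance is the variance of the two sex
#' means about the grand mean of two equal-sized groups,
#' \eqn{V_{A,b} = (SD_\pm / 2)^2}.
#'
#' @param state A [population_state()].
#' @return A list with `VA_w`, `VA_b`, `VA_t`.
#' @export
within_between_variance <- function(state) {
  h <- 2 * state$x * (1 - state$x)
  VA_w <- (sum(state$af^2 * h) + sum(state$am^2 * h)) / 2
  z <- phenotypic_means(state)
  VA_b <- ((z[["zf"]] - z[["zm"]]) / 2)^2
  list(VA_w = VA_w, VA_b = VA_b, VA_t = VA_w + VA_b)
}

#' Aggregate replicate trajectories
#'
#' Given per-replicate moment trajectories on the same time grid, returns per
#' time point the across-replicate mean and a 95% confidence half-width
#' computed as 1.96 times the standard error of the mean. Because the `SD`
#' column holds the per-replicate absolute difference in sex-specific means,
#' its aggregate is the mean of absolute values (E[SD]), which differs from
#' the absolute value of the aggregated signed difference `SDpm`.
#'
#' @param trajectories List of data frames as returned by [run_replicate()];
#'   all must share an identical `generation` grid.
#' @return A data frame with `generation` and `phase`, plus `<field>_mean` and
#'   `<field>_ci` for every numeric moment field, and `n_reps`.
#' @export
aggregate_replicates <- function(trajectories) {
  stopifnot(length(trajectories) >= 2)
  g0 <- trajectories[[1]]$generation
  for (tr in trajectories)
    if (!identical(tr$generation, g0))
      stop("replicate time grids are not aligned")
  n <- length(trajectories)
  num <- names(trajectories[[1]])[vapply(trajectories[[1]], is.numeric,
                                         logical(1))]
  num <- setdiff(num, "generation")
  out <- data.frame(generation = g0, phase = trajectories[[1]]$phase,
                    n_reps = n)
  for (f in num) {
    m <- vapply(trajectories, function(tr) tr[[f]], numeric(length(g0)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    mu <- rowMeans(m)
    se <- apply(m, 1, stats::sd) / sqrt(n)
    out[[paste0(f, "_mean")]] <- mu
    out[[paste0(f, "_ci")]]   <- 1.96 * se
  }
  out
}

#' Stationary fluctuation statistics at equilibrium
#'
#' From equilibrium (post-burn-in) samples of the sex-specific means,
#' estimates the stationary variance of the population mean
#' \eqn{V[\bar z]}, the sex-specific variances \eqn{V[\bar z_{f/m}]}, the
#' covariance \eqn{Cov[\bar z_f, \bar z_m]}, the variance of signed sexual
#' dimorphism \eqn{V[SD_\pm]}, and the mean absolute dimorphism
#' \eqn{E[SD]}. Also reports the identity check
#' \eqn{V[SD_\pm] = V[\bar z_f] + V[\bar z_m] - 2 Cov[\bar z_f, \bar z_m]}
#' (exact up to floating point on the same samples).
#'
#' Samples may be pooled across replicates and/or thinned in time; thinning
#' every N/10 generations roughly decorrelates successive samples for the
#' parameter regimes used here.
#'
#' @param trajectories A single moment data frame, or a list of them, holding
#'   only equilibrium records.
#' @param min_samples Minimum number of pooled samples required.
#' @return A list with `V_zbar`, `V_zf`, `V_zm`, `Cov_zfzm`, `V_SDpm`,
#'   `E_SD`, `E_SDpm`, `one_minus_cov_ratio` (\eqn{1 - Cov/V[\bar z]}),
#'   `consistency`, and `n_samples`.
#' @export
equilibrium_fluctuation_stats <- function(trajectories, min_samples = 10) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  zf <- unlist(lapply(trajectories, `[[`, "zf"))
  zm <- unlist(lapply(trajectories, `[[`, "zm"))
  n <- length(zf)
  if (n < min_samples)
    stop(sprintf("only %d equilibrium samples; need at least %d",
                 n, min_samples))
  za <- (zf + zm) / 2
  sdpm <- zf - zm
  V_zf <- stats::var(zf); V_zm <- stats::var(zm)
  Cov  <- stats::cov(zf, zm)
  V_zbar <- stats::var(za)
  V_SDpm <- stats::var(sdpm)
  list(V_zbar = V_zbar, V_zf = V_zf, V_zm = V_zm, Cov_zfzm = Cov,
       V_SDpm = V_SDpm, E_SD = mean(abs(sdpm)), E_SDpm = mean(sdpm),
       one_minus_cov_ratio = 1 - Cov / V_zbar,
       consistency = V_zf + V_zm - 2 * Cov - V_SDpm,
       n_samples = n)
}
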