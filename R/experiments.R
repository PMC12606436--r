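#' Shift size in phenotypic standard deviations
#'
#' Shift magnitudes are specified as multiples of \eqn{\sqrt{V_S}}; this
#' converts such a coefficient into multiples of the phenotypic standard
#' deviation \eqn{\sqrt{V_{A,*}}}:
#' `coeff * sqrt(VS) / sqrt(target_VA)`. With `VS = 2000` and
#' `target_VA = 40`, coefficients 0.15 / 0.25 / 0.5 give 1.06 / 1.77 / 3.54
#' standard deviations.
#'
#' @param coeff Dimensionless shift coefficient (multiple of `sqrt(VS)`).
#' @param params A [model_params()] (supplies `VS`).
#' @param target_VA Equilibrium additive variance of the trait.
#' @return Shift size in units of the phenotypic standard deviation.
#' @export
relative_shift_in_sd_units <- function(coeff, params, target_VA) {
  stopifnot(target_VA > 0)
  coeff * sqrt(params$VS) / sqrt(target_VA)
}

#' Time for the mean dimorphism to reach a fraction of its final value
#'
#' Scans an (aggregated) post-shift trajectory for the first time at which
#' the mean signed dimorphism gained since the shift reaches
#' `fraction * 2 * Lambda_d`, interpolating linearly between recorded
#' generations. Returns `NA` (censored) if the fraction is never reached
#' within the recorded horizon.
#'
#' The infinitesimal closed form for the same quantity is
#' \eqn{t_p = -2 V_S \ln(1 - p) / (V_{A,a} (1 - r_{fm}))}, available as
#' [time_to_fraction_sd_inf()].
#'
#' @param times Generations since the shift (increasing).
#' @param sdpm Signed dimorphism gained since the shift at those times (e.g.
#'   the `SDpm_mean` column of [aggregate_replicates()] output, minus its
#'   pre-shift value).
#' @param fraction Target fraction in (0, 1).
#' @param Lambda_d Half-difference shift; the asymptote of `sdpm` is
#'   `2 * Lambda_d`.
#' @return First crossing time in generations, or `NA` if censored.
#' @export
time_to_fraction_sd <- function(times, sdpm, fraction, Lambda_d) {
  stopifnot(fraction > 0, fraction < 1, length(times) == length(sdpm))
  target <- fraction * 2 * Lambda_d
  hit <- which(sdpm >= target)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(times[1L])
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- sdpm[i - 1L]; y1 <- sdpm[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' @rdname time_to_fraction_sd
#' @param VA_a Average additive variance at the shift.
#' @param rfm Intersex correlation at the shift.
#' @param params A [model_params()].
#' @export
time_to_fraction_sd_inf <- function(fraction, VA_a, rfm, params) {
  -2 * params$VS * log(1 - fraction) / (VA_a * (1 - rfm))
}

#' Run a named scenario end-to-end
#'
#' Config-driven driver for the study's figure-level experiments. Each
#' scenario burns replicate populations in to equilibrium, optionally applies
#' shifts in sex-specific optima, aggregates the replicate trajectories, and
#' attaches the matching analytic prediction:
#'
#' * `"equilibrium_sd"`: coinciding optima; post-burn-in sampling of the
#'   stationary fluctuations, compared against [drift_sd_prediction()].
#' * `"concordant_shift"`: both optima shift by `shift_coeff * sqrt(VS)` in
#'   the same direction (`Lambda_d = 0`).
#' * `"discordant_shift"`: optima shift by `shift_coeff * sqrt(VS)` in
#'   opposite directions (`Lambda_a = 0`, divergent).
#' * `"divergent_then_convergent"`: a divergent shift followed, after
#'   `post_shift` generations, by a convergent shift of the same magnitude.
#' * `"transient_rfm"`: a discordant shift; additionally reports the time
#'   averages of `VA_a`, `B`, and `rfm` over the first `5N` post-shift
#'   generations, where the transient dip of `rfm` below its equilibrium
#'   value appears under a multigenic architecture.
#'
#' Shifted scenarios carry a [lande_trajectories()] prediction (from the
#' calibrated equilibrium moments) and a [predict_breeder_trajectory()]
#' prediction (driven by the simulated moment series).
#'
#' @param name Scenario name (see above).
#' @param architecture `"infinitesimal"` (`E(a^2) = 1`) or `"multigenic"`
#'   (`E(a^2) = 16`).
#' @param r Fraction of shared mutations (target intersex correlation).
#' @param shift_coeff Shift magnitude as a multiple of `sqrt(VS)` (0.15,
#'   0.25, or 0.5 in the study design; ignored for `"equilibrium_sd"`).
#' @param N Population size.
#' @param target_VA Equilibrium overall variance the mutation rate is
#'   calibrated to.
#' @param burn_in Burn-in generations; default 10N for `target_VA = 40`,
#'   100N for `target_VA = 9`, 500N below that (slower equilibration for
#'   lower-variance traits).
#' @param post_shift Generations recorded after each shift (or sampling
#'   period for `"equilibrium_sd"`).
#' @param replicates Number of replicates (scaled-down default 25).
#' @param record_every Recording interval in generations; defaults to `N/10`
#'   for `"equilibrium_sd"` (approximately decorrelated samples) and 10
#'   otherwise.
#' @param seed Master seed.
#' @param out_dir Optional output directory; when given, writes per-replicate
#'   trajectories, the aggregate, the predictions, and a JSON manifest.
#' @param max_total_generations Resource guard: abort before running if
#'   `replicates * (burn_in + phases * post_shift)` exceeds this.
#' @return A list with `config`, `aggregate`, `prediction` (where defined),
#'   `stats` (equilibrium scenario), `post_shift_averages` (transient_rfm
#'   scenario: time-averaged `VA_a`, `B`, `rfm` over 5N generations), and
#'   `manifest`. Per-replicate trajectories are included as `trajectories`.
#' @export
run_scenario <- function(name = c("equilibrium_sd", "concordant_shift",
                                  "discordant_shift",
                                  "divergent_then_convergent",
                                  "transient_rfm"),
                         architecture = c("infinitesimal", "multigenic"),
                         r = 0.5, shift_coeff = 0.25,
                         N = 1000, target_VA = 40,
                         burn_in = NULL, post_shift = NULL,
                         replicates = 25, record_every = NULL, seed = 1,
                         out_dir = NULL, max_total_generations = 5e7) {
  name <- match.arg(name)
  architecture <- match.arg(architecture)
  mean_sq <- if (architecture == "infinitesimal") 1 else 16
  params <- model_params(N = N)
  model <- mutation_model(mean_sq = mean_sq, r = r)
  params$U <- calibrate_U(model, params, target_VA)
  if (is.null(burn_in))
    burn_in <- if (target_VA >= 40) 10 * N else if (target_VA >= 9) 100 * N
               else 500 * N

  Lam <- shift_coeff * sqrt(params$VS)
  shifts <- switch(name,
    equilibrium_sd = list(),
    concordant_shift = list(shift_spec(Lambda_a = Lam, Lambda_d = 0,
                                       label = "concordant")),
    discordant_shift = list(shift_spec(Lambda_a = 0, Lambda_d = Lam,
                                       label = "divergent")),
    transient_rfm = list(shift_spec(Lambda_a = 0, Lambda_d = Lam,
                                    label = "divergent")),
    divergent_then_convergent = list(
      shift_spec(Lambda_a = 0, Lambda_d = Lam, label = "divergent"),
      shift_spec(Lambda_a = 0, Lambda_d = -Lam, label = "convergent")))
  if (is.null(post_shift))
    post_shift <- if (name == "equilibrium_sd") 100 * N else 10 * N
  if (is.null(record_every))
    record_every <- if (name == "equilibrium_sd") max(1L, N %/% 10L) else 10L

  n_phases <- max(length(shifts), 1L)
  total <- as.numeric(replicates) * (burn_in + n_phases * as.numeric(post_shift))
  if (total > max_total_generations)
    stop(sprintf(
      "projected workload (%.3g replicate-generations) exceeds the budget (%.3g)",
      total, max_total_generations))

  cfg <- run_config(params = params, mutation = model, burn_in = burn_in,
                    post_shift = post_shift, shifts = shifts,
                    replicates = replicates, seed = seed,
                    record_every = record_every)
  trajs <- run_replicates(cfg)
  agg <- if (replicates >= 2) aggregate_replicates(trajs) else trajs[[1]]
  # time since the most recent shift, per phase
  agg$t <- agg$generation -
    ave(agg$generation, agg$phase, FUN = min)

  out <- list(config = cfg, trajectories = trajs, aggregate = agg)

  eqm <- equilibrium_sex_moments(model, params)
  if (name == "equilibrium_sd") {
    out$stats <- equilibrium_fluctuation_stats(trajs)
    out$prediction <- drift_sd_prediction(params)
  } else {
    sh <- shifts[[1]]
    tt <- sort(unique(agg$t[agg$phase == sh$label]))
    out$prediction <- lande_trajectories(VA_a = eqm$VA_O, B = eqm$B,
                                         shift = sh, params = params,
                                         times = tt)
    ms <- agg[agg$phase == sh$label,
              c("t", "VA_a_mean", "VA_d_mean", "B_mean",
                "mu3_a_mean", "mu3_d_mean")]
    names(ms) <- c("generation", "VA_a", "VA_d", "B", "mu3_a", "mu3_d")
    out$prediction_breeder <- predict_breeder_trajectory(ms, sh, params)
  }
  if (name == "transient_rfm") {
    win <- agg$phase == shifts[[1]]$label & agg$t > 0 & agg$t <= 5 * N
    out$post_shift_averages <- list(
      VA_a = mean(agg$VA_a_mean[win]),
      B = mean(agg$B_mean[win]),
      rfm = mean(agg$rfm_mean[win]),
      rfm_equilibrium = eqm$rfm)
  }

  out$manifest <- list(
    scenario = name, architecture = architecture, mean_sq = mean_sq, r = r,
    shift_coeff = shift_coeff, N = N, VS = params$VS, U = params$U,
    target_VA = target_VA, burn_in = burn_in, post_shift = post_shift,
    replicates = replicates, record_every = record_every, seed = seed,
    replicate_seeds = vapply(seq_len(replicates), replicate_seed,
                             integer(1), seed = seed),
    package_version = as.character(utils::packageVersion("twosexsel")))

  if (!is.null(out_dir)) write_scenario(out, out_dir)
  invisible(out)
}

# write trajectories, aggregate, prediction TSVs and a JSON manifest
write_scenario <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f)
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  for (i in seq_along(result$trajectories))
    wt(result$trajectories[[i]], sprintf("replicate_%03d.tsv", i))
  wt(result$aggregate, "aggregate.tsv")
  if (is.data.frame(result$prediction)) wt(result$prediction, "prediction.tsv")
  if (!is.null(result$prediction_breeder))
    wt(result$prediction_breeder, "prediction_breeder.tsv")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
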