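#' Expected one-generation allele-frequency change
#'
#' First moment of the change in frequency of an allele with per-copy effects
#' `af`, `am` segregating at frequency `x`, when the sex-specific trait means
#' sit at distances `Df`, `Dm` from their optima:
#' \deqn{E[\Delta x] = \left(\frac{a_f D_f \gamma_f^2}{V_S} +
#'   \frac{a_m D_m \gamma_m^2}{V_S}\right) x(1-x)
#'   - \left(\frac{a_f^2 \gamma_f^2}{V_S} +
#'   \frac{a_m^2 \gamma_m^2}{V_S}\right)\left(\tfrac12 - x\right) x(1-x).}
#' The first term is directional selection (pushing means toward optima); the
#' second is stabilizing selection (eroding minor-allele frequencies). At the
#' optimum (`Df = Dm = 0`) it reduces to
#' \eqn{-a^2/V_S (1/2 - x) x(1-x)} with \eqn{a^2 = a_f^2\gamma_f^2 +
#' a_m^2\gamma_m^2}.
#'
#' @param af,am Per-copy effects (vectors).
#' @param x Frequencies, strictly in (0, 1).
#' @param Df,Dm Distances of the sex-specific means from their optima.
#' @param params A [model_params()].
#' @return Expected frequency changes, same length as `x`.
#' @export
expected_delta_x <- function(af, am, x, Df, Dm, params) {
  if (length(x) && (any(x <= 0) || any(x >= 1)))
    stop("x must lie strictly in (0, 1)")
  gf2 <- params$gamma_f^2; gm2 <- params$gamma_m^2
  ((af * Df * gf2 + am * Dm * gm2) -
     (af^2 * gf2 + am^2 * gm2) * (0.5 - x)) * x * (1 - x) / params$VS
}

#' Advance the population one generation
#'
#' One step of the Wright-Fisher Hardy-Weinberg scheme: each allele's
#' frequency is updated by binomial sampling of `2N` gene copies around
#' `x + E[dx]` (so the drift variance is `x(1-x)/(2N)`), alleles reaching
#' frequency 0 or 1 are removed (fixations are folded into the fixed
#' backgrounds), and a Poisson(`2NU`) number of new mutations enters at
#' frequency `1/(2N)`. The expected-change term is clamped into [0, 1] before
#' sampling to guard against overshoot for large-effect alleles.
#'
#' @param state A [population_state()].
#' @param params A [model_params()] (must have `U` set).
#' @param model A [mutation_model()].
#' @param optima Length-2 vector of current optima `c(O_f, O_m)`; defaults to
#'   the optima stored in `params`.
#' @return The updated [population_state()].
#' @export
step_generation <- function(state, params, model,
                            optima = c(params$O_f, params$O_m)) {
  N <- params$N
  af <- state$af; am <- state$am; x <- state$x
  Ff <- state$Ff; Fm <- state$Fm
  if (length(x)) {
    Df <- optima[1L] - (Ff + sum(2 * af * x))
    Dm <- optima[2L] - (Fm + sum(2 * am * x))
    p <- x + expected_delta_x(af, am, x, Df, Dm, params)
    p[p < 0] <- 0
    p[p > 1] <- 1
    xn <- stats::rbinom(length(p), 2L * N, p) / (2 * N)
    fixed <- xn >= 1
    if (any(fixed)) {
      Ff <- Ff + sum(2 * af[fixed])
      Fm <- Fm + sum(2 * am[fixed])
    }
    keep <- xn > 0 & !fixed
    af <- af[keep]; am <- am[keep]; x <- xn[keep]
  }
  k <- stats::rpois(1L, 2 * N * params$U)
  if (k > 0L) {
    mu <- draw_mutations(k, model, params)
    af <- c(af, mu$af)
    am <- c(am, mu$am)
    x  <- c(x, rep.int(1 / (2 * N), k))
  }
  state$af <- af; state$am <- am; state$x <- x
  state$Ff <- Ff; state$Fm <- Fm
  state$generation <- state$generation + 1L
  state
}

#' Shift in sex-specific optima
#'
#' Specifies a shift applied to the two optima, either per sex
#' (`Lambda_f`, `Lambda_m`) or in average / difference coordinates
#' (`Lambda_a`, `Lambda_d`); the other pair is filled in. A purely concordant
#' shift has `Lambda_d = 0`; a purely discordant shift has `Lambda_a = 0`
#' (divergent if it moves optima apart, convergent if together).
#'
#' @param Lambda_f,Lambda_m Shifts of the sex-specific optima (delta units).
#' @param Lambda_a,Lambda_d Shifts of the average optimum and half-difference.
#' @param label Optional label carried through to outputs.
#' @return An object of class `"shift_spec"` with all four shift fields.
#' @export
shift_spec <- function(Lambda_f = NULL, Lambda_m = NULL,
                       Lambda_a = NULL, Lambda_d = NULL, label = "") {
  if (is.null(Lambda_f) != is.null(Lambda_m) ||
      is.null(Lambda_a) != is.null(Lambda_d))
    stop("supply both members of a coordinate pair")
  if (!is.null(Lambda_f) && !is.null(Lambda_a))
    stop("supply either sex-specific or average/difference shifts, not both")
  if (is.null(Lambda_f) && is.null(Lambda_a))
    Lambda_a <- Lambda_d <- 0
  if (is.null(Lambda_f)) {
    fm <- from_avg_diff(Lambda_a, Lambda_d)
    Lambda_f <- fm$f; Lambda_m <- fm$m
  } else {
    ad <- to_avg_diff(Lambda_f, Lambda_m)
    Lambda_a <- ad$a; Lambda_d <- ad$d
  }
  structure(list(Lambda_f = Lambda_f, Lambda_m = Lambda_m,
                 Lambda_a = Lambda_a, Lambda_d = Lambda_d, label = label),
            class = "shift_spec")
}

#' Simulation run configuration
#'
#' @param params A [model_params()] with `U` set (or use `target_VA` to
#'   calibrate it).
#' @param mutation A [mutation_model()].
#' @param burn_in Burn-in length in generations (conventionally a multiple of
#'   `N`: 10N, 100N, or 500N depending on how slowly the architecture
#'   equilibrates).
#' @param post_shift Generations simulated (and recorded) after each shift;
#'   with no shifts, an equilibrium recording period of this length follows
#'   the burn-in.
#' @param shifts List of [shift_spec()] applied in order, each followed by
#'   `post_shift` generations.
#' @param replicates Number of replicates.
#' @param seed Master seed; replicate `i` uses a deterministic child seed.
#' @param record_every Recording interval (generations) after the burn-in.
#' @param record_burn_in Optional recording interval during the burn-in
#'   (`NA` = do not record the burn-in).
#' @param target_VA If supplied, `params$U` is set by [calibrate_U()] to hit
#'   this equilibrium overall variance.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(params, mutation, burn_in, post_shift = 0,
                       shifts = list(), replicates = 1, seed = 1,
                       record_every = 10, record_burn_in = NA,
                       target_VA = NULL) {
  if (!is.null(target_VA))
    params$U <- calibrate_U(mutation, params, target_VA)
  if (is.na(params$U)) stop("params$U is not set and no target_VA given")
  if (2 * params$N * params$U <= 1)
    warning("2NU <= 1: outside the high-polygenicity regime")
  if (length(shifts)) {
    stopifnot(all(vapply(shifts, inherits, logical(1), "shift_spec")))
    lim <- 0.5 * sqrt(params$VS)
    big <- vapply(shifts, function(s)
      max(abs(s$Lambda_f), abs(s$Lambda_m)) > lim, logical(1))
    if (any(big))
      warning("shift magnitude exceeds 0.5*sqrt(VS); analytic approximations degrade")
  }
  structure(list(params = params, mutation = mutation,
                 burn_in = as.integer(burn_in),
                 post_shift = as.integer(post_shift), shifts = shifts,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 record_burn_in = record_burn_in),
            class = "run_config")
}

#' Deterministic per-replicate child seed
#'
#' Derives the seed used for replicate `replicate` of a run with master seed
#' `seed` (the values recorded in run manifests), kept below 2^31.
#'
#' @param seed Master seed (integer).
#' @param replicate Replicate index (1-based).
#' @return An integer seed.
#' @export
replicate_seed <- function(seed, replicate) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(replicate) * 9973) %%
               2147483647)
}

#' Run one replicate
#'
#' Burns the population in to mutation-selection-drift balance, applies each
#' shift in order (adding its Lambdas to the current optima), and records the
#' full set of phenotypic moments on the configured time grid. Deterministic
#' given `(config$seed, replicate)`.
#'
#' @param config A [run_config()].
#' @param replicate Replicate index (used to derive the child seed).
#' @param return_state If `TRUE`, the final [population_state()] is attached
#'   as attribute `"state"`.
#' @return A data frame of moment records (one row per recorded generation;
#'   see [compute_moments()] for columns, plus `generation` and `phase`).
#' @export
run_replicate <- function(config, replicate = 1, return_state = FALSE) {
  set.seed(replicate_seed(config$seed, replicate))
  params <- config$params
  state  <- population_state()
  optima <- c(params$O_f, params$O_m)
  rows <- list()

  rec <- function(phase) {
    rows[[length(rows) + 1L]] <<-
      cbind(compute_moments(state, params, optima), phase = phase)
  }

  rb <- config$record_burn_in
  for (g in seq_len(config$burn_in)) {
    state <- step_generation(state, params, config$mutation, optima)
    if (!is.na(rb) && g %% rb == 0L) rec("burn_in")
  }

  phases <- config$shifts
  if (!length(phases)) phases <- list(shift_spec(Lambda_a = 0, Lambda_d = 0))
  for (i in seq_along(phases)) {
    sh <- phases[[i]]
    optima <- optima + c(sh$Lambda_f, sh$Lambda_m)
    lab <- if (nzchar(sh$label)) sh$label else paste0("phase", i)
    rec(lab)  # t = 0 snapshot right after the shift
    for (g in seq_len(config$post_shift)) {
      state <- step_generation(state, params, config$mutation, optima)
      if (g %% config$record_every == 0L) rec(lab)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicate") <- replicate
  attr(out, "seed") <- replicate_seed(config$seed, replicate)
  if (return_state) attr(out, "state") <- state
  out
}

#' Run all replicates of a configuration
#'
#' @param config A [run_config()].
#' @return A list of per-replicate moment data frames (see [run_replicate()]).
#' @export
run_replicates <- function(config) {
  lapply(seq_len(config$replicates), function(i) run_replicate(config, i))
}
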