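test_that("shift coefficients convert to the published phenotypic-SD multiples", {
  p <- test_params()
  expect_equal(relative_shift_in_sd_units(0.15, p, 40), 1.06, tolerance = 0.005)
  expect_equal(relative_shift_in_sd_units(0.25, p, 40), 1.77, tolerance = 0.005)
  expect_equal(relative_shift_in_sd_units(0.5, p, 40), 3.54, tolerance = 0.005)
  expect_error(relative_shift_in_sd_units(0.25, p, 0))
})

test_that("time to a fraction of final dimorphism interpolates and inverts the closed form", {
  p <- test_params()
  # closed form: t_p = -2 VS ln(1 - p) / (VA_a (1 - rfm))
  expect_equal(time_to_fraction_sd_inf(0.8, 40, 0.8, p),
               -2 * p$VS * log(0.2) / (40 * 0.2))
  # on a densely evaluated exponential trajectory, the interpolated crossing
  # matches the closed form
  sh <- shift_spec(Lambda_a = 0, Lambda_d = 8)
  tr <- lande_trajectories(40, 32, sh, p, times = seq(0, 20000, by = 10))
  for (f in c(0.5, 0.8, 0.9)) {
    t_hat <- time_to_fraction_sd(tr$generation, tr$SDpm, f, 8)
    expect_equal(t_hat, time_to_fraction_sd_inf(f, 40, 0.8, p),
                 tolerance = 1e-3)
  }
  # small fractions are reached immediately; unreached fractions are censored
  expect_lt(time_to_fraction_sd(tr$generation, tr$SDpm, 1e-6, 8), 1)
  expect_true(is.na(time_to_fraction_sd(tr$generation[1:5], tr$SDpm[1:5],
                                        0.9, 8)))
})

test_that("the scenario driver runs end-to-end and writes a complete results directory", {
  out_dir <- withr::local_tempdir()
  res <- run_scenario("discordant_shift", architecture = "multigenic",
                      r = 0.8, shift_coeff = 0.25, N = 200, target_VA = 10,
                      burn_in = 1500, post_shift = 400, replicates = 2,
                      record_every = 50, seed = 42, out_dir = out_dir)
  expect_s3_class(res$aggregate, "data.frame")
  expect_true(all(c("SDpm_mean", "SDpm_ci", "rfm_mean", "t") %in%
                    names(res$aggregate)))
  # prediction shares the post-shift time grid
  post_t <- sort(unique(res$aggregate$t[res$aggregate$phase == "divergent"]))
  expect_equal(res$prediction$generation, post_t)
  expect_equal(res$prediction_breeder$Dd[1], 0.25 * sqrt(res$config$params$VS))
  # manifest records everything needed to re-run
  expect_equal(res$manifest$seed, 42)
  expect_equal(length(res$manifest$replicate_seeds), 2)
  expect_true(file.exists(file.path(out_dir, "aggregate.tsv")))
  expect_true(file.exists(file.path(out_dir, "prediction.tsv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  expect_true(file.exists(file.path(out_dir, "replicate_002.tsv")))
  # re-running with the same seed is bit-identical
  res2 <- run_scenario("discordant_shift", architecture = "multigenic",
                       r = 0.8, shift_coeff = 0.25, N = 200, target_VA = 10,
                       burn_in = 1500, post_shift = 400, replicates = 2,
                       record_every = 50, seed = 42)
  expect_equal(res2$aggregate, res$aggregate)
})

test_that("the resource guard refuses oversized workloads", {
  expect_error(
    run_scenario("equilibrium_sd", replicates = 1e6, N = 1000,
                 max_total_generations = 1e6),
    "budget")
})

test_that("divergent-then-convergent runs both phases in order", {
  res <- run_scenario("divergent_then_convergent", architecture = "multigenic",
                      r = 0.5, shift_coeff = 0.2, N = 200, target_VA = 10,
                      burn_in = 1000, post_shift = 300, replicates = 2,
                      record_every = 50, seed = 7)
  ph <- unique(res$aggregate$phase)
  expect_equal(ph, c("divergent", "convergent"))
  div <- res$aggregate[res$aggregate$phase == "divergent", ]
  conv <- res$aggregate[res$aggregate$phase == "convergent", ]
  # optima separate and then come back together
  expect_gt(tail(div$SDpm_mean, 1), 0.5 * tail(div$SD_mean, 1))
  expect_lt(tail(conv$SDpm_mean, 1), tail(div$SDpm_mean, 1))
})

test_that("the command-line front end round-trips simulate -> stats -> theory", {
  skip_if_not_installed("yaml")
  exec <- system.file("exec", "twosexsel", package = "twosexsel")
  skip_if(exec == "", "installed exec script not found")
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.yaml")
  writeLines(c("N: 200", "target_VA: 10", "mean_sq: 16", "r: 0.8",
               "burn_in: 800", "post_shift: 200", "replicates: 2",
               "record_every: 50", "seed: 5", "shifts:",
               "  - Lambda_a: 0", "    Lambda_d: 5",
               "    label: divergent"), cfg)
  run <- function(...) system2(rscript, c(exec, ...), stdout = TRUE,
                               stderr = TRUE)
  run("simulate", "--config", cfg, "--out", file.path(dir, "sim"))
  expect_true(file.exists(file.path(dir, "sim", "replicate_002.tsv")))
  man <- jsonlite::read_json(file.path(dir, "sim", "manifest.json"))
  expect_equal(man$N, 200)  # YAML `N:` key survives boolean resolution
  expect_equal(length(man$replicate_seeds), 2)
  run("stats", "--in", file.path(dir, "sim"), "--out", file.path(dir, "st"))
  agg <- read.table(file.path(dir, "st", "aggregate.tsv"), header = TRUE,
                    sep = "\t")
  expect_true(all(c("SDpm_mean", "SDpm_ci") %in% names(agg)))
  run("theory", "--config", cfg, "--out", file.path(dir, "pred.tsv"),
      "--moments", file.path(dir, "st", "aggregate.tsv"))
  pred <- read.table(file.path(dir, "pred.tsv"), header = TRUE, sep = "\t")
  expect_equal(pred$Dd[1], 5)
  expect_true(file.exists(file.path(dir, "pred_breeder.tsv")))
})
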