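test_that("drift predictions scale with delta", {
  p1 <- test_params()
  d1 <- drift_sd_prediction(p1)
  expect_equal(d1$E_SD, 2 * sqrt(2 / pi))
  expect_equal(d1$E_SD, 1.596, tolerance = 1e-3)
  expect_equal(d1$V_SD, 4)
  expect_equal(d1$V_zfm, 2)
  expect_equal(d1$V_zbar, 1)
  # delta = 2: E[SD] doubles, variances quadruple
  p2 <- suppressWarnings(model_params(N = 1000, VS = 8000))
  d2 <- drift_sd_prediction(p2)
  expect_equal(p2$delta, 2)
  expect_equal(d2$E_SD, 2 * d1$E_SD)
  expect_equal(d2$V_SD, 16)
})

test_that("scaled dimorphism gives the published significance ratios", {
  e_sd <- 2 * sqrt(2 / pi)
  expect_equal(scaled_sd(e_sd, 4), 0.8, tolerance = 0.003)
  expect_equal(scaled_sd(e_sd, 9), 0.53, tolerance = 0.01)
  expect_lt(scaled_sd(e_sd, 1e8), 1e-3)
  expect_error(scaled_sd(1, 0), "positive")
})

test_that("constant-moment trajectories have the right boundary behaviour", {
  p <- test_params()
  sh <- shift_spec(Lambda_a = 5, Lambda_d = 3)
  tr <- lande_trajectories(VA_a = 40, B = 20, shift = sh, params = p,
                           times = c(0, 100, 1e6))
  expect_equal(tr$Da[1], 5)   # D(0) = Lambda
  expect_equal(tr$Dd[1], 3)
  expect_equal(tr$SDpm[1], 0) # dimorphism gained starts at zero
  expect_equal(tr$Da[3], 0, tolerance = 1e-10)  # decays to the optimum
  expect_equal(tr$SDpm[3], 6, tolerance = 1e-10)
  # perfect correlation (B = VA_a): no discordant response at all
  tr1 <- lande_trajectories(VA_a = 40, B = 40, shift = sh, params = p,
                            times = c(0, 500, 5000))
  expect_equal(tr1$Dd, rep(3, 3))
})

test_that("coupled-variance trajectories agree with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- test_params()
  sh <- shift_spec(Lambda_a = 5, Lambda_d = 3)
  VA_a <- 40; B <- 20; VA_d <- 7
  G <- matrix(c(VA_a + B, VA_d, VA_d, VA_a - B), 2, 2) / (2 * p$VS)
  times <- seq(0, 800, by = 50)
  sol <- deSolve::ode(y = c(5, 3), times = times,
                      func = function(t, y, parms) list(-G %*% y),
                      rtol = 1e-12, atol = 1e-14)
  tr <- lande_trajectories(VA_a, B, sh, p, times, VA_d = VA_d)
  expect_equal(tr$Da, unname(sol[, 2]), tolerance = 1e-10)
  expect_equal(tr$Dd, unname(sol[, 3]), tolerance = 1e-10)
  # and the decoupled closed form agrees with the solver too (VA_d = 0)
  G0 <- matrix(c(VA_a + B, 0, 0, VA_a - B), 2, 2) / (2 * p$VS)
  sol0 <- deSolve::ode(y = c(5, 3), times = times,
                       func = function(t, y, parms) list(-G0 %*% y),
                       rtol = 1e-12, atol = 1e-14)
  tr0 <- lande_trajectories(VA_a, B, sh, p, times)
  expect_equal(tr0$Da, unname(sol0[, 2]), tolerance = 1e-10)
  expect_equal(tr0$Dd, unname(sol0[, 3]), tolerance = 1e-10)
})

test_that("rapid-phase lengths follow the (1 + rfm)/(1 - rfm) law", {
  p <- test_params()
  # rfm = 0.5 at equal shift sizes: discordant takes 3 times longer
  ts <- adaptation_timescales(VA_a = 40, B = 20, Lambda_a = 10,
                              Lambda_d = 10, params = p)
  expect_equal(ts$ratio, 3)
  expect_equal(ts$td / ts$ta, 3)
  # rfm = 0: equal phase lengths
  ts0 <- adaptation_timescales(40, 0, 10, 10, p)
  expect_equal(ts0$ratio, 1)
  # shift of exactly delta: zero-length rapid phase
  expect_equal(adaptation_timescales(40, 0, p$delta, p$delta, p)$ta, 0)
  # rfm = 1: discordant adaptation never completes
  ts1 <- adaptation_timescales(40, 40, 10, 10, p)
  expect_equal(ts1$td, Inf)
  # monotonicity in rfm: ta decreases, td increases
  rr <- seq(0, 0.95, by = 0.05)
  tas <- sapply(rr, function(r) adaptation_timescales(40, 40 * r, 10, 10, p)$ta)
  tds <- sapply(rr, function(r) adaptation_timescales(40, 40 * r, 10, 10, p)$td)
  expect_true(all(diff(tas) < 0))
  expect_true(all(diff(tds) > 0))
})

test_that("the moment-driven breeder step has the documented fixed points", {
  p <- test_params()
  eqm <- list(VA_a = 40, VA_d = 0, B = 20, mu3_a = 0, mu3_d = 0)
  # at the optima with a symmetric distribution nothing moves
  expect_equal(breeder_step(c(0, 0), eqm, p), c(0, 0))
  # skew tuned to cancel the directional term: adaptation stalls
  stall <- list(VA_a = 40, VA_d = 0, B = 20, mu3_a = (40 + 20) * 2.5,
                mu3_d = 0)
  expect_equal(breeder_step(c(2.5, 0), stall, p)[1], 0)
  # with mu3 = 0 and VA_d = 0 the step is the decoupled linear recursion
  D <- c(3, 1.5)
  expect_equal(breeder_step(D, eqm, p),
               c(-(40 + 20) * 3, -(40 - 20) * 1.5) / (2 * p$VS))
  # sex-specific master form agrees after the change of variables
  Dfm <- from_avg_diff(D[1], D[2])
  mfm <- list(VA_f = 40, VA_m = 40, B = 20, mu3_f = 0, mu3_m = 0)
  dfm <- breeder_step_fm(c(Dfm$f, Dfm$m), mfm, p)
  dad <- to_avg_diff(dfm[1], dfm[2])
  expect_equal(c(dad$a, dad$d), breeder_step(D, eqm, p))
})

test_that("integrating the breeder step over constant moments matches the closed form", {
  p <- test_params()
  sh <- shift_spec(Lambda_a = 0, Lambda_d = 8)
  ms <- data.frame(generation = c(0, 2000), VA_a = 40, VA_d = 0, B = 32,
                   mu3_a = 0, mu3_d = 0)
  pred <- predict_breeder_trajectory(ms, sh, p)
  closed <- lande_trajectories(40, 32, sh, p, times = pred$generation)
  # discrete one-generation recursion vs continuous exponential: the rates
  # here are ~2e-3 per generation, so they agree to first order
  expect_equal(pred$Dd, closed$Dd, tolerance = 2e-3)
  expect_equal(pred$Dd[1], 8)
})

test_that("fixed-background equilibration decays at rate 1/(2N)", {
  p <- test_params()
  sh <- shift_spec(Lambda_a = 7, Lambda_d = 2)
  eq <- equilibration_decay(sh, p, times = c(0, 2 * p$N,
                                             2 * p$N * log(7 / p$delta)))
  expect_equal(eq$Fa[1], 7)
  expect_equal(eq$Fa[2], 7 / exp(1))
  expect_equal(eq$Fa[3], p$delta)  # delta-crossing time 2N ln(Lambda/delta)
  expect_equal(eq$Fd[2], 2 / exp(1))
})
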