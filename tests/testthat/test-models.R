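test_that("GRT drift rates integrate the percept against the bound", {
  expect_equal(unname(marginal_drift(1.3, 1, 1.3)), c(0.5, 0.5))
  expect_equal(unname(marginal_drift(1, 1, 0)[1]), pnorm(1), tolerance = 1e-5)
  expect_equal(unname(marginal_drift(0.7, 0.35, 0, "below")[1]), pnorm(-2),
               tolerance = 1e-6)
  # normalization holds over a randomized grid
  set.seed(14)
  for (k in 1:50) {
    v <- marginal_drift(rnorm(1), runif(1, 0.1, 3), rnorm(1),
                        sample(c("above", "below"), 1))
    expect_equal(unname(sum(v)), 1)
    b <- bivariate_drift(rnorm(1), rnorm(1), runif(1, .1, 3), runif(1, .1, 3),
                         rnorm(1), rnorm(1))
    expect_equal(unname(sum(b)), 1)
  }
  expect_equal(unname(bivariate_drift(0, 0, 1, 1, 0, 0)[1]), 0.25)
  expect_equal(unname(bivariate_drift(1, 1, 1, 1, 0, 0)[1]), pnorm(1)^2,
               tolerance = 1e-6)
})

test_that("model specifications enforce their parameter contracts", {
  expect_error(model_spec("serial_st"), "p_x")
  expect_error(model_spec("banana"), "unknown architecture")
  expect_error(model_spec("mixed_serial_parallel", p_x = 0.5, p_serial = 1.4,
                          m = 1, A_parallel = 100), "p_serial")
  expect_error(model_spec("free_drift", nu = c(a = 0.5)), "9 stimulus roles")
  nu <- setNames(rep(0.6, 9), role_table()$role)
  expect_s3_class(model_spec("free_drift", nu = nu), "model_spec")
  expect_equal(param_names("mixed_serial_parallel")[10:13],
               c("p_x", "p_serial", "m", "A_parallel"))
  expect_length(param_names("parallel_st"), 9)
  expect_length(param_names("free_drift"), 14)
})

test_that("degenerate LBA races follow time = distance / rate", {
  lba <- list(A = 0, s = 1e-9, b_target = 1000, b_contrast = 1000)
  r <- lba_channel_sample(lba, v_first = 1, v_second = 1e-6, n = 50)
  expect_true(all(r$winner == "first"))
  expect_equal(r$decision_time, rep(1000, 50), tolerance = 1e-4)
  # equal drifts: the lower threshold resolves first
  r2 <- lba_channel_sample(lba, 0.5, 0.5, n = 50, b_first = 800,
                           b_second = 900)
  expect_true(all(r2$winner == "first"))
  expect_equal(r2$decision_time, rep(1600, 50), tolerance = 1e-4)
})

test_that("the race simulator matches the analytic LBA first-passage density", {
  A <- 300; b <- 1000; v1 <- 0.8; v2 <- 0.6; s <- 0.15
  Fpt <- function(t, v) {
    z1 <- (b - A - t * v) / (t * s); z2 <- (b - t * v) / (t * s)
    1 + (b - A - t * v) / A * pnorm(z1) - (b - t * v) / A * pnorm(z2) +
      (t * s) / A * (dnorm(z1) - dnorm(z2))
  }
  fpt <- function(t, v) {
    z1 <- (b - A - t * v) / (t * s); z2 <- (b - t * v) / (t * s)
    (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A
  }
  tt <- seq(1, 6000, by = 0.5)
  dens_win <- fpt(tt, v1) * (1 - Fpt(tt, v2)) + fpt(tt, v2) * (1 - Fpt(tt, v1))
  mass <- sum(dens_win) * 0.5
  mean_theory <- sum(tt * dens_win) * 0.5 / mass
  expect_equal(mass, 1, tolerance = 1e-3)   # negative-drift mass negligible
  set.seed(99)
  r <- lba_channel_sample(list(A = A, s = s), v1, v2, n = 1e6,
                          b_first = b, b_second = b)
  expect_equal(mean(r$decision_time), mean_theory, tolerance = 0.01)
  # winner shares match the defective masses
  p1_theory <- sum(fpt(tt, v1) * (1 - Fpt(tt, v2))) * 0.5
  expect_equal(mean(r$winner == "first"), p1_theory, tolerance = 0.01)
})

test_that("architecture composition obeys its boundary cases", {
  # p_serial = 1 mixture is distributionally a serial model
  base <- study_spec("serial_st")
  mix <- study_spec("mixed_serial_parallel", p_serial = 1, s = base$s)
  a <- simulate_model(base, 1, 1, 1e5, seed = 1)
  b <- simulate_model(mix, 1, 1, 1e5, seed = 2)
  ks <- suppressWarnings(stats::ks.test(a$rt_ms, b$rt_ms))
  expect_lt(unname(ks$statistic), 0.01)
  expect_equal(mean(a$response == "target"), mean(b$response == "target"),
               tolerance = 0.01)

  # serial with a deterministic first-channel contrast win: RT = b/v + t0
  d <- stimulus_design(c(-2, 1, 2), c(-2, 1, 2))
  spec <- model_spec("serial_st", d, sigma_x = 0.25, sigma_y = 0.25,
                     D_x = 0, D_y = 0, A = 0, b_target = 800,
                     b_contrast = 800, s = 1e-9, t0 = 200, p_x = 1)
  sim <- simulate_model(spec, 0, 2, 500, seed = 3)
  expect_true(all(sim$response == "contrast"))
  v_contrast <- 1 - pnorm(-2 / 0.25)
  expect_equal(sim$rt_ms, rep(800 / v_contrast + 200, 500), tolerance = 1e-3)

  # pure contaminant: uniform RTs, coin-flip responses
  spec_c <- study_spec("mixed_serial_contaminant", p0 = 1,
                       contaminant_range = c(400, 2400))
  sim_c <- simulate_model(spec_c, 2, 2, 4000, seed = 4)
  expect_true(all(sim_c$rt_ms >= 400 & sim_c$rt_ms <= 2400))
  expect_equal(mean(sim_c$response == "target"), 0.5, tolerance = 0.03)
  ks_u <- suppressWarnings(stats::ks.test(sim_c$rt_ms, "punif", 400, 2400))
  expect_gt(ks_u$p.value, 0.01)
})

test_that("predictions are coherent summaries of the simulator", {
  pr <- model_predictions(study_spec("coactive"), n_sim = 2000, seed = 5)
  expect_equal(nrow(pr), 18)
  probs <- tapply(pr$p, paste(pr$x_level, pr$y_level), sum)
  expect_true(all(abs(probs - 1) < 1e-12))
  ok <- !is.na(pr$q25)
  expect_true(all(pr$q25[ok] <= pr$q50[ok] & pr$q50[ok] <= pr$q75[ok]))
  # all RTs at least the non-decision time
  sim <- simulate_model(study_spec("parallel_st"), 0, 0, 2000, seed = 6)
  expect_true(all(sim$rt_ms >= 300))
  # raising the target threshold slows correct target responses
  lo <- study_spec("parallel_st")
  hi <- study_spec("parallel_st", b_target = 1400)
  m_lo <- mean(simulate_model(lo, 2, 2, 20000, seed = 7)$rt_ms)
  m_hi <- mean(simulate_model(hi, 2, 2, 20000, seed = 7)$rt_ms)
  expect_gt(m_hi, m_lo)
})
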