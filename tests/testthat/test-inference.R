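test_that("PDA defective densities are normalized and floored", {
  spec <- study_spec("parallel_st")
  # the two response-class densities, integrated numerically, sum to ~1
  sim <- simulate_model(spec, 1, 1, 20000, seed = 3)
  total <- 0
  for (cls in c("target", "contrast")) {
    srt <- sim$rt_ms[sim$response == cls]
    if (length(srt) < 2) next
    bw <- bw.nrd0(srt)
    grid <- seq(min(srt) - 4 * bw, max(srt) + 4 * bw, length.out = 3000)
    dens <- sftrules:::cpp_kde_dens(srt, grid, bw)
    total <- total + sum(dens) * diff(grid[1:2]) * length(srt) / 20000
  }
  expect_equal(total, 1, tolerance = 0.01)

  # an observation far outside the simulated support hits the floor
  far <- validate_trials(trials_df(x_level = 1, y_level = 1,
                                   response = "target", rt_ms = 9e5))
  ll_far <- pda_loglik(spec, far, n_sim = 1000, seed = 1)
  expect_equal(ll_far, log(1e-10))

  # likelihood is higher at the generating parameters than far from them
  tr <- simulate_rt_dataset(spec, 100, seed = 8)
  wrong <- study_spec("parallel_st", D_x = 1.8, D_y = 1.8)
  set.seed(30)
  ll_true <- mean(replicate(3, pda_loglik(spec, tr, n_sim = 5000)))
  ll_far2 <- mean(replicate(3, pda_loglik(wrong, tr, n_sim = 5000)))
  expect_gt(ll_true, ll_far2)
})

test_that("repeated PDA evaluations are stable in the log domain", {
  spec <- study_spec("mixed_serial_parallel")
  tr <- simulate_rt_dataset(spec, 400, seed = 11)
  set.seed(55)
  lls <- replicate(8, pda_loglik(spec, tr, n_sim = 10000))
  expect_lt(sd(lls), 6)  # scales roughly as 1/sqrt(n_sim); ~2 at 50k
})

test_that("DE-MCMC is deterministic and samples an analytic Gaussian correctly", {
  lp <- function(th) sum(dnorm(th, c(1, -2), c(2, 0.5), log = TRUE))
  priors <- list(a = c(-20, 20), b = c(-20, 20))
  f1 <- de_mcmc(lp, priors, n_chains = 12, n_iter = 400, seed = 31)
  f2 <- de_mcmc(lp, priors, n_chains = 12, n_iter = 400, seed = 31)
  expect_identical(f1$samples, f2$samples)
  expect_gt(f1$acceptance, 0)
  expect_lt(f1$acceptance, 1)

  fit <- de_mcmc(lp, priors, n_chains = 12, n_iter = 5000, seed = 42)
  flat <- apply(fit$samples, 3, identity)
  n_eff <- nrow(flat) / 20  # generous autocorrelation allowance
  mcse <- apply(flat, 2, sd) / sqrt(n_eff)
  expect_lt(abs(mean(flat[, 1]) - 1), 3 * mcse[1])
  expect_lt(abs(mean(flat[, 2]) + 2), 3 * mcse[2])
  expect_equal(var(flat[, 1]), 4, tolerance = 0.1 * 4)
  expect_equal(var(flat[, 2]), 0.25, tolerance = 0.1 * 0.25)

  expect_error(de_mcmc(lp, list(a = c(2, 1), b = c(0, 1))), "empty prior")
  expect_error(de_mcmc(lp, priors, n_chains = 12,
                       init = list(a = c(30, 40), b = c(0, 1))),
               "outside the prior")
})

test_that("the DIC follows its defining identities", {
  # hand-built posterior: all samples equal, deviance trace constant
  toy <- structure(list(
    samples = array(2, c(10, 4, 1), dimnames = list(NULL, NULL, "mu")),
    deviance = matrix(100, 10, 4),
    log_post = function(th) -45),  # D(theta_bar) = 90
    class = "posterior_fit")
  out <- dic(toy)
  expect_equal(out$p_d, 10)
  expect_equal(out$dic, 120)
  toy$log_post <- function(th) -50  # degenerate: D(theta_bar) = Dbar
  out2 <- dic(toy)
  expect_equal(out2$p_d, 0)
  expect_equal(out2$dic, 100)
  toy$deviance[3, 2] <- NaN
  expect_error(dic(toy), "non-finite deviances")

  # conjugate toy: inferring one Gaussian mean gives p_d ~ 1
  set.seed(17)
  y <- rnorm(40, 0.3, 1)
  lp <- function(th) sum(dnorm(y, th, 1, log = TRUE))
  fit <- de_mcmc(lp, list(mu = c(-10, 10)), n_chains = 8, n_iter = 4000,
                 seed = 5)
  expect_equal(dic(fit)$p_d, 1, tolerance = 0.15)
})

test_that("DIC weights renormalize evidence differences", {
  expect_equal(dic_weights(c(200, 200)), c(0.5, 0.5))
  # printed seven-model comparison: the two near-tied models split .98/.02
  w <- dic_weights(c(-1246, -1222, -766, -1018, -1254, -713, -538))
  expect_equal(round(w[5], 2), 0.98)
  expect_equal(round(w[1], 2), 0.02)
  expect_equal(round(w[2], 2), 0)
  expect_equal(sum(w), 1)
  expect_equal(dic_weights(c(10, 14, 22) + 1e4),
               dic_weights(c(10, 14, 22)), tolerance = 1e-12)
  expect_error(dic_weights(c(NA, 3)), "finite")
})

test_that("rule-model fits expose coherent accessor methods", {
  spec <- study_spec("parallel_st")
  tr <- simulate_rt_dataset(spec, 60, seed = 2)
  init <- list(sigma_x = c(0.5, 2), sigma_y = c(0.5, 2), D_x = c(-0.5, 0.7),
               D_y = c(-0.5, 0.7), A = c(100, 900), b_target = c(400, 1600),
               b_contrast = c(400, 1600), s = c(0.05, 0.3), t0 = c(100, 500))
  fit <- fit_rule_model(tr, "parallel_st", design = spec$design,
                        n_sim = 1000, n_chains = 10, n_iter = 30,
                        init = init, init_candidates = 50, seed = 12)
  expect_s3_class(fit, "rulefit")
  expect_named(coef(fit), param_names("parallel_st"))
  expect_true(is.finite(fit$dic))
  sm <- summary(fit)
  expect_equal(rownames(sm$table), param_names("parallel_st"))
  pr <- predict(fit, n_sim = 1000, seed = 1)
  expect_equal(nrow(pr), 18)
  cmp <- compare_rule_models(list(parallel = fit, again = fit))
  expect_equal(cmp$weight, c(0.5, 0.5), tolerance = 1e-12)
})
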