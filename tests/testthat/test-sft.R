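test_that("survivor estimates count strict exceedances", {
  s <- survivor_fn(c(100, 200, 300), t_grid = c(0, 150, 200, 300, 400))
  expect_equal(s$S, c(1, 2/3, 1/3, 0, 0))
  expect_true(all(diff(s$S) <= 0))
  expect_error(survivor_fn(numeric(0)), "empty")
})

test_that("the mean interaction contrast is the double difference", {
  expect_equal(mic(c(LL = 1000, LH = 900, HL = 800, HH = 700)), 0)
  # observed per-item means for two participants of the source design
  expect_equal(mic(c(LL = 1041, LH = 749, HL = 894, HH = 710)), 108)
  expect_equal(mic(c(LL = 1964, LH = 1530, HL = 1492, HH = 1236)), 178)
  # translation invariance
  m <- c(LL = 1210, LH = 1090, HL = 1130, HH = 940)
  expect_equal(mic(m + 250), mic(m))
})

test_that("the SIC vanishes under cancellation and matches a closed-form parallel oracle", {
  x <- c(300, 400, 500, 700)
  zero <- suppressWarnings(sic(list(LL = x, LH = x, HL = x, HH = x), n_boot = 0))
  expect_true(all(zero$sic == 0))
  expect_equal(zero$mic, 0)
  # samples built so S_LL = S_LH and S_HL = S_HH cancel pairwise
  y <- c(350, 450, 650)
  z <- suppressWarnings(sic(list(LL = x, LH = x, HL = y, HH = y), n_boot = 0))
  expect_true(all(z$sic == 0))

  # parallel exhaustive oracle: max of exponential channels has survivor
  # S(t) = 1 - (1 - exp(-lx t)) (1 - exp(-ly t)); its SIC is <= 0
  set.seed(77)
  lam <- c(L = 1/600, H = 1/300)
  n <- 20000
  draw <- function(lx, ly) pmax(rexp(n, lx), rexp(n, ly))
  samples <- list(LL = draw(lam["L"], lam["L"]), LH = draw(lam["L"], lam["H"]),
                  HL = draw(lam["H"], lam["L"]), HH = draw(lam["H"], lam["H"]))
  grid <- seq(10, 3000, by = 10)
  emp <- suppressWarnings(sic(samples, t_grid = grid, n_boot = 0))
  surv <- function(lx, ly, t) 1 - (1 - exp(-lx * t)) * (1 - exp(-ly * t))
  theo <- (surv(lam["L"], lam["L"], grid) - surv(lam["L"], lam["H"], grid)) -
    (surv(lam["H"], lam["L"], grid) - surv(lam["H"], lam["H"], grid))
  expect_true(all(theo <= 1e-12))
  expect_lt(max(abs(emp$sic - theo)), 0.03)
  expect_true(all(emp$sic <= 0.03))
})

test_that("the SIC integral equals the MIC on arbitrary data", {
  set.seed(123)
  for (k in 1:25) {
    n <- sample(50:300, 4)
    samples <- list(LL = rgamma(n[1], 4, 1/200) + 200,
                    LH = rlnorm(n[2], log(700), 0.3),
                    HL = runif(n[3], 300, 1500),
                    HH = rnorm(n[4], 800, 150))
    s <- suppressWarnings(sic(samples, n_boot = 0))
    rt_range <- diff(range(unlist(samples)))
    expect_lt(abs(sic_integral(s) - s$mic), 0.01 * rt_range)
  }
})

test_that("bootstrap SIC bands cover the point estimate and respect n_boot", {
  rts <- additive_item_rts(n = 120)
  s <- sic(rts, n_boot = 200, seed = 42)
  expect_equal(s$boot$n_boot, 200)
  expect_true(all(s$boot$lower <= s$boot$upper))
  inside <- mean(s$sic >= s$boot$lower & s$sic <= s$boot$upper)
  expect_gt(inside, 0.95)
  expect_warning(sic(rts, n_boot = 0), "bands omitted")
})

test_that("KS dominance statistics and verdicts follow the ECDF definition", {
  x <- c(300, 400, 500, 700)
  same <- ks_dominance_suite(list(LL = x, LH = x, HL = x, HH = x))
  expect_true(all(same$p > 0.99))
  expect_false(attr(same, "dominance"))
  # two samples whose ECDFs differ by at most 0.3: statistic is 0.3
  a <- 1:10
  b <- a + 3
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "greater"))
  expect_equal(unname(kt$statistic), 0.3)
  # shifted channels: dominance detected in nearly all seeds
  verdicts <- logical(10)
  for (k in 1:10) {
    set.seed(500 + k)
    mk <- function(shift) 600 + shift + 300 * rnorm(400)
    rts <- list(LL = mk(300), LH = mk(150), HL = mk(150), HH = mk(0))
    verdicts[k] <- attr(ks_dominance_suite(rts), "dominance")
  }
  expect_gte(sum(verdicts), 9)
})

test_that("deflection tests are null-calibrated and back ends agree", {
  x <- c(300, 400, 500, 700, 900)
  flat <- suppressWarnings(sic(list(LL = x, LH = x, HL = x, HH = x), n_boot = 0))
  perm <- sic_deflection_tests(flat, n_resample = 200, seed = 1)
  asym <- sic_deflection_tests(flat, method = "asymptotic")
  expect_equal(perm$d_plus, 0)
  expect_equal(perm$d_minus, 0)
  expect_gt(perm$p_plus, 0.9)
  expect_gt(perm$p_minus, 0.9)
  expect_equal(asym$d_plus, 0)
  expect_equal(asym$p_plus, 1)
  expect_equal(asym$p_minus, 1)
  # a strong positive-only deflection is detected by both backends
  set.seed(8)
  rts <- list(LL = 1000 + 250 * rnorm(400), LH = 820 + 250 * rnorm(400),
              HL = 820 + 250 * rnorm(400), HH = 780 + 250 * rnorm(400))
  s <- suppressWarnings(sic(rts, n_boot = 0))
  p1 <- sic_deflection_tests(s, n_resample = 300, seed = 2)
  p2 <- sic_deflection_tests(s, method = "asymptotic")
  expect_lt(p1$p_plus, 0.05)
  expect_lt(p2$p_plus, 0.05)
})

test_that("the factorial ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(31)
  cells <- expand.grid(session = 2:4, top = c("L", "H"), bottom = c("L", "H"))
  n_per <- 6
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    mu <- 800 + 40 * (cells$session[i] - 2) + 120 * (cells$top[i] == "L") +
      90 * (cells$bottom[i] == "L") + 35 * (cells$top[i] == "L") * (cells$bottom[i] == "L")
    data.frame(session = cells$session[i],
               x_level = ifelse(cells$bottom[i] == "H", 2, 1),
               y_level = ifelse(cells$top[i] == "H", 2, 1),
               rt_ms = mu + rnorm(n_per, 0, 60))
  }))
  tr <- validate_trials(trials_df(session = rows$session, x_level = rows$x_level,
                                  y_level = rows$y_level, response = "target",
                                  rt_ms = rows$rt_ms))
  out <- target_category_anova(tr)

  # oracle: balanced-design sums of squares from cell and marginal means
  y <- rows$rt_ms
  A <- factor(rows$session); B <- factor(rows$y_level); C <- factor(rows$x_level)
  g <- mean(y)
  ss <- function(f) sum(tapply(y, f, function(v) length(v) * (mean(v) - g)^2))
  ss_a <- ss(A); ss_b <- ss(B); ss_c <- ss(C)
  ss_ab <- ss(interaction(A, B)) - ss_a - ss_b
  ss_ac <- ss(interaction(A, C)) - ss_a - ss_c
  ss_bc <- ss(interaction(B, C)) - ss_b - ss_c
  ss_abc <- ss(interaction(A, B, C)) - ss_a - ss_b - ss_c - ss_ab - ss_ac - ss_bc
  ss_res <- sum((y - ave(y, interaction(A, B, C)))^2)
  df_res <- length(y) - nlevels(A) * 4
  f_or <- function(ss_e, df1) (ss_e / df1) / (ss_res / df_res)
  expect_equal(out$F[out$effect == "session"], f_or(ss_a, 2), tolerance = 1e-9)
  expect_equal(out$F[out$effect == "top"], f_or(ss_b, 1), tolerance = 1e-9)
  expect_equal(out$F[out$effect == "bottom"], f_or(ss_c, 1), tolerance = 1e-9)
  expect_equal(out$F[out$effect == "top:bottom"], f_or(ss_bc, 1), tolerance = 1e-9)
  expect_equal(out$F[out$effect == "session:top:bottom"], f_or(ss_abc, 2),
               tolerance = 1e-9)
  expect_equal(out$partial_eta_sq[out$effect == "top"],
               ss_b / (ss_b + ss_res), tolerance = 1e-9)

  # translation invariance of every F
  tr2 <- tr; tr2$rt_ms <- tr2$rt_ms + 500
  out2 <- target_category_anova(tr2)
  expect_equal(out2$F, out$F, tolerance = 1e-10)

  # empty cell errors informatively
  tr3 <- tr[!(tr$session == 3 & tr$role == "HH"), ]
  expect_error(target_category_anova(tr3), "empty design cell")
})

test_that("a null ANOVA is calibrated at its nominal level", {
  hits <- 0
  for (k in 1:10) {
    set.seed(600 + k)
    g <- expand.grid(session = 2:8, x_level = 1:2, y_level = 1:2,
                     rep = 1:12)
    tr <- validate_trials(trials_df(session = g$session, x_level = g$x_level,
                                    y_level = g$y_level, response = "target",
                                    rt_ms = 900 + rnorm(nrow(g), 0, 150)))
    out <- target_category_anova(tr)
    hits <- hits + (out$p[out$effect == "top:bottom"] < 0.05)
  }
  expect_lte(hits, 2)
})

test_that("contrast-category comparisons read architecture signatures", {
  # identical interior and exterior samples: t exactly 0
  vals <- c(500, 600, 700, 800)
  tr <- validate_trials(trials_df(
    x_level = c(rep(1, 4), rep(2, 4), rep(0, 12)),
    y_level = c(rep(0, 8), rep(1, 4), rep(2, 4), rep(0, 4)),
    response = "contrast",
    rt_ms = c(vals, vals, vals, vals, vals)))
  ct <- contrast_category_tests(tr)
  expect_equal(ct$t[ct$comparison == "E_Bottom - I_Bottom"], 0)
  expect_equal(ct$cohens_d[ct$comparison == "E_Top - I_Top"], 0)
  expect_error(contrast_category_tests(tr[tr$x_level != 0 | tr$y_level != 0, ]),
               "role R")

  # fixed-order serial (lips first): interior slower than exterior on the
  # lips dimension, no difference on the eyes dimension
  tr_s <- simulate_rt_dataset(study_spec("serial_st", p_x = 1), 400, seed = 88)
  ct_s <- contrast_category_tests(tr_s)
  bot <- ct_s[ct_s$comparison == "E_Bottom - I_Bottom", ]
  top <- ct_s[ct_s$comparison == "E_Top - I_Top", ]
  expect_lt(bot$mean_diff, 0)     # exterior faster: interior slower
  expect_lt(bot$p, 0.05)
  expect_gt(top$p, 0.05)

  # parallel self-termination: interior vs exterior null on both dimensions
  nonsig <- 0
  for (k in 1:10) {
    tr_p <- simulate_rt_dataset(study_spec("parallel_st"), 400, seed = 700 + k)
    ct_p <- contrast_category_tests(tr_p)
    nonsig <- nonsig + sum(ct_p$p[ct_p$comparison %in%
      c("E_Top - I_Top", "E_Bottom - I_Bottom")] > 0.05)
  }
  expect_gte(nonsig / 20, 0.85)
})

test_that("the classification rule table reproduces the published readings", {
  expect_equal(classify_architecture("positive", TRUE, "I<E"), "Coactive")
  expect_setequal(classify_architecture("S-shaped", FALSE, "I=E"),
                  c("Parallel ST", "Serial ST"))
  expect_equal(classify_architecture("S-shaped mostly positive", FALSE,
                                     list(top = "I=E", bottom = "I>E")),
               "Serial ST")
  expect_equal(classify_architecture("Mostly negative", FALSE, "I<E"),
               "Parallel ST")
  # both deflections individually significant: coactivity listed alongside
  expect_setequal(classify_architecture(
    list(shape = "S-shaped, neg. then pos.", d_plus_sig = TRUE,
         d_minus_sig = TRUE), FALSE, list(top = "I<E", bottom = "I>E")),
    c("Coactive", "Serial ST"))
  # significant negative interaction contradicts coactivity
  expect_equal(classify_architecture("S-shaped", "sig-negative", "I=E"),
               "Parallel ST")
  expect_error(classify_architecture("wiggly", FALSE, "I=E"), "shape")
  expect_error(classify_architecture("positive", FALSE, "I~E"), "contrast_pattern")
})

test_that("architecture classification recovers the generating architecture", {
  truthmap <- c(serial_st = "Serial ST", parallel_st = "Parallel ST",
                coactive = "Coactive")
  n_seeds <- 7
  for (arch in names(truthmap)) {
    hits <- 0
    for (k in seq_len(n_seeds)) {
      tr <- simulate_rt_dataset(study_spec(arch), 400, seed = 2000 + 17 * k)
      sm <- suppressWarnings(
        sft_summary(tr, n_boot = 0, n_resample = 300, seed = k))
      hits <- hits + (truthmap[[arch]] %in% sm$classification)
    }
    expect_gte(hits / n_seeds, 0.8)
  }
})
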