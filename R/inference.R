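#' @useDynLib sftrules, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.shared_params <- c("sigma_x", "sigma_y", "D_x", "D_y",
                    "A", "b_target", "b_contrast", "s", "t0")
.nu_params <- paste0("nu_", c("HH", "HL", "LH", "LL", "Ex", "Ix", "Ey", "Iy", "R"))

#' Free parameters of an architecture
#'
#' @param architecture architecture tag (see [model_spec()]).
#' @return character vector of parameter names, in fitting order.
#' @export
param_names <- function(architecture) {
  switch(architecture,
    serial_st = c(.shared_params, "p_x"),
    parallel_st = .shared_params,
    coactive = .shared_params,
    mixed_serial_parallel = c(.shared_params, "p_x", "p_serial", "m", "A_parallel"),
    mixed_serial_contaminant = c(.shared_params, "p_x", "p0"),
    mixed_parallel_contaminant = c(.shared_params, "p0"),
    free_drift = c(.nu_params, "A", "b_target", "b_contrast", "s", "t0"),
    stop("unknown architecture: ", architecture))
}

#' Default uniform prior ranges
#'
#' Perceptual SDs in (0.01, 5) psychological units; decision bounds within
#' the coordinate span widened by 2 units; start ranges in (0, 3000) and
#' thresholds in (1, 5000) on the ms-scaled accumulation scale; drift SD
#' in (0.05, 1); non-decision time in (50, 1000) ms; probabilities in
#' (0, 1); SD multiplier `m` in (0.1, 10); free drifts in (0, 1).
#'
#' @param architecture architecture tag.
#' @param design stimulus design (sets the bound ranges).
#' @return named list of `c(lower, upper)` ranges.
#' @export
default_priors <- function(architecture, design = stimulus_design()) {
  span <- range(c(design$x_coords, design$y_coords))
  base <- list(sigma_x = c(0.01, 5), sigma_y = c(0.01, 5),
               D_x = c(span[1] - 2, span[2] + 2),
               D_y = c(span[1] - 2, span[2] + 2),
               A = c(0, 3000), b_target = c(1, 5000), b_contrast = c(1, 5000),
               s = c(0.05, 1), t0 = c(50, 1000),
               p_x = c(0, 1), p_serial = c(0, 1), p0 = c(0, 1),
               m = c(0.1, 10), A_parallel = c(0, 3000))
  for (nm in .nu_params) base[[nm]] <- c(0, 1)
  base[param_names(architecture)]
}

# parameter vector -> model_spec
theta_to_spec <- function(theta, architecture, design = stimulus_design(),
                          contaminant_range = NULL) {
  th <- as.list(theta)
  names(th) <- param_names(architecture)
  if (architecture == "free_drift") {
    nu <- unlist(th[.nu_params])
    names(nu) <- sub("^nu_", "", names(nu))
    model_spec("free_drift", design, A = th$A, b_target = th$b_target,
               b_contrast = th$b_contrast, s = th$s, t0 = th$t0, nu = nu)
  } else {
    model_spec(architecture, design,
               sigma_x = th$sigma_x, sigma_y = th$sigma_y,
               D_x = th$D_x, D_y = th$D_y, A = th$A,
               b_target = th$b_target, b_contrast = th$b_contrast,
               s = th$s, t0 = th$t0,
               p_x = th$p_x, p_serial = th$p_serial, m = th$m,
               A_parallel = th$A_parallel, p0 = th$p0,
               contaminant_range = contaminant_range)
  }
}

#' Simulation-based log-likelihood (probability density approximation)
#'
#' For every stimulus present in `trials`, simulates `n_sim` (response,
#' RT) pairs from the model, forms per-response-class defective densities
#' (class proportion times a Gaussian-kernel density estimate of that
#' class's RTs, Silverman bandwidth), and sums the log density of each
#' observed trial, floored at `floor` so unsupported observations
#' contribute `log(floor)` rather than `-Inf`. A fresh simulation is drawn
#' on every call, so the estimator is noisy (pseudo-marginal) with noise
#' shrinking as `n_sim` grows.
#'
#' @param spec a [model_spec()].
#' @param trials a `trial_table`, typically one participant and condition.
#' @param n_sim simulated trials per stimulus (>= 1000).
#' @param seed optional seed.
#' @param floor density floor.
#' @return scalar log-likelihood.
#' @export
pda_loglik <- function(spec, trials, n_sim = 10000, seed = NULL,
                       floor = 1e-10) {
  stopifnot(n_sim >= 1000)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(spec$p0) && is.null(spec$contaminant_range))
    spec$contaminant_range <- range(trials$rt_ms)
  obs <- .split_obs(trials)
  .pda_loglik_obs(spec, obs, n_sim = n_sim, floor = floor)
}

# observed RTs grouped by stimulus cell and response class, computed once
.split_obs <- function(trials) {
  key <- paste0(trials$x_level, trials$y_level)
  cells <- unique(key)
  lapply(stats::setNames(cells, cells), function(k) {
    idx <- key == k
    list(x_level = trials$x_level[idx][1], y_level = trials$y_level[idx][1],
         target = trials$rt_ms[idx & trials$response == "target"],
         contrast = trials$rt_ms[idx & trials$response == "contrast"])
  })
}

.pda_loglik_obs <- function(spec, obs, n_sim, floor = 1e-10) {
  ll <- 0
  for (cell in obs) {
    sim <- .sim_raw(spec, cell$x_level, cell$y_level, n_sim)
    for (cls in 1:2) {  # 1 = target, 2 = contrast
      o <- if (cls == 1) cell$target else cell$contrast
      if (!length(o)) next
      srt <- sim$rt[sim$resp == (2L - cls)]
      if (length(srt) < 2) { ll <- ll + length(o) * log(floor); next }
      # density estimated on the log-time scale: RT distributions are
      # right-skewed and the log transform keeps the binning grid fine
      # where the data are while still covering the slow tail
      lsrt <- log(srt)
      bw <- stats::bw.nrd0(lsrt)
      dens <- if (bw > 0) cpp_kde_dens(lsrt, log(o), bw) / o
              else rep(0, length(o))
      ll <- ll + sum(log(pmax((length(srt) / n_sim) * dens, floor)))
    }
  }
  ll
}

#' Differential-evolution MCMC
#'
#' Samples from a posterior whose log density is `log_post` over box
#' priors. Each chain's proposal is theta_i + gamma * (theta_j - theta_k)
#' + jitter, with j and k distinct other chains, accepted by a Metropolis
#' step. Because uniform priors cancel in the ratio, `log_post` only needs
#' the log-likelihood; proposals outside the prior box are rejected
#' outright. The current state's stored log density is reused across
#' iterations (pseudo-marginal behaviour when `log_post` is stochastic).
#'
#' @param log_post function(theta) returning a scalar log density.
#' @param priors named list of `c(lower, upper)` box-prior ranges.
#' @param n_chains number of chains; default `3 * d`, at least `d + 1`
#'   and 4.
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded (default half).
#' @param gamma DE step size; default `2.38 / sqrt(2 d)`.
#' @param jitter half-width of the uniform proposal jitter.
#' @param init optional named list like `priors` giving tighter start
#'   ranges.
#' @param refresh `FALSE`/0 to keep stored log densities (classic
#'   pseudo-marginal behaviour), `TRUE`/1 to re-evaluate the current
#'   state's log density every iteration, or an integer period k to
#'   re-evaluate every k-th iteration. With a stochastic `log_post`
#'   (PDA) periodic refreshing prevents chains from sticking to lucky
#'   overestimates at a fraction of the doubled evaluation cost.
#' @param migrate_every during burn-in only, every this many iterations
#'   the lowest-density chain is restarted at the current best chain's
#'   position (plus proposal jitter). 0 disables migration. Rescues
#'   chains stranded far from the mode; retained samples are unaffected
#'   because migration stops at the end of burn-in.
#' @param seed optional seed; fixes the whole trajectory.
#' @return An object of class `"posterior_fit"`: `samples` (iteration x
#'   chain x parameter array of retained draws), `deviance` (matrix,
#'   -2 log-likelihood of retained states), `acceptance` rate, and the
#'   call settings.
#' @export
de_mcmc <- function(log_post, priors, n_chains = NULL, n_iter = 500,
                    burn_in = floor(n_iter / 2), gamma = NULL,
                    jitter = 0.001, init = NULL, refresh = FALSE,
                    migrate_every = 0, seed = NULL) {
  d <- length(priors)
  lo <- vapply(priors, `[`, 1, i = 1L)
  hi <- vapply(priors, `[`, 1, i = 2L)
  if (any(hi <= lo)) stop("empty prior support for: ",
                          paste(names(priors)[hi <= lo], collapse = ", "))
  if (is.null(n_chains)) n_chains <- max(3 * d, d + 1, 4)
  if (n_chains < max(4, d + 1))
    stop("n_chains must be at least max(4, d + 1)")
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- priors
  if (is.matrix(init)) {
    if (nrow(init) != n_chains || ncol(init) != d)
      stop("init matrix must be n_chains x n_parameters")
    theta <- init
    colnames(theta) <- names(priors)
  } else {
    ilo <- vapply(init, `[`, 1, i = 1L)
    ihi <- vapply(init, `[`, 1, i = 2L)
    theta <- matrix(stats::runif(n_chains * d, rep(ilo, each = n_chains),
                                 rep(ihi, each = n_chains)),
                    n_chains, d, dimnames = list(NULL, names(priors)))
  }
  if (any(t(theta) < lo) || any(t(theta) > hi))
    stop("initial points fall outside the prior support")
  lp <- apply(theta, 1, log_post)
  if (any(!is.finite(lp))) stop("initial points have non-finite log density")
  n_keep <- n_iter - burn_in
  samples <- array(NA_real_, c(n_keep, n_chains, d),
                   dimnames = list(NULL, NULL, names(priors)))
  deviance <- matrix(NA_real_, n_keep, n_chains)
  n_acc <- 0L; n_prop <- 0L
  refresh_period <- if (isTRUE(refresh)) 1L else as.integer(refresh)
  for (it in seq_len(n_iter)) {
    do_refresh <- refresh_period > 0L && it %% refresh_period == 0L
    for (i in seq_len(n_chains)) {
      if (do_refresh) lp[i] <- log_post(theta[i, ])
      jk <- sample(seq_len(n_chains)[-i], 2L)
      prop <- theta[i, ] + gamma * (theta[jk[1], ] - theta[jk[2], ]) +
        stats::runif(d, -jitter, jitter)
      n_prop <- n_prop + 1L
      if (any(prop < lo | prop > hi)) next
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < lp_prop - lp[i]) {
        theta[i, ] <- prop
        lp[i] <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    if (migrate_every > 0 && it <= burn_in && it %% migrate_every == 0) {
      worst <- which.min(lp); best <- which.max(lp)
      if (worst != best) {
        theta[worst, ] <- theta[best, ] + stats::runif(d, -jitter, jitter)
        lp[worst] <- log_post(theta[worst, ])
      }
    }
    if (it > burn_in) {
      samples[it - burn_in, , ] <- theta
      deviance[it - burn_in, ] <- -2 * lp
    }
  }
  structure(list(samples = samples, deviance = deviance,
                 acceptance = n_acc / n_prop, priors = priors,
                 n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 gamma = gamma, log_post = log_post, seed = seed),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("DE-MCMC fit: %d chains x %d retained iterations, %d parameters\n",
              d[2], d[1], d[3]))
  cat(sprintf("  acceptance rate %.2f\n", x$acceptance))
  invisible(x)
}

#' Posterior means of a DE-MCMC fit
#' @param object a `posterior_fit`.
#' @param ... ignored.
#' @export
coef.posterior_fit <- function(object, ...) {
  apply(object$samples, 3, mean)
}

#' Deviance information criterion
#'
#' DIC = Dbar + 2 pD with pD = Dbar - D(theta_bar), where Dbar is the
#' mean posterior deviance and theta_bar the per-parameter posterior
#' mean. Smaller is better.
#'
#' @param fit a `posterior_fit`.
#' @return list with `dic` and `p_d`.
#' @export
dic <- function(fit) {
  dev <- as.vector(fit$deviance)
  if (!length(dev)) stop("empty deviance trace")
  bad <- which(!is.finite(dev))
  if (length(bad))
    stop("non-finite deviances at retained iteration(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  d_bar <- mean(dev)
  theta_bar <- coef.posterior_fit(fit)
  d_at_mean <- -2 * fit$log_post(theta_bar)
  p_d <- d_bar - d_at_mean
  list(dic = d_bar + 2 * p_d, p_d = p_d)
}

#' DIC model weights
#'
#' Akaike-style transform of DIC differences:
#' w_i = exp(-(DIC_i - min DIC)/2), normalized to sum to one.
#'
#' @param dics numeric vector of DIC values (names kept).
#' @return numeric weights summing to 1.
#' @examples
#' round(dic_weights(c(-1246, -1222, -766, -1018, -1254, -713, -538)), 2)
#' @export
dic_weights <- function(dics) {
  ok <- is.finite(dics)
  if (sum(ok) < 2) stop("need at least two finite DICs")
  delta <- dics - min(dics[ok])
  w <- ifelse(ok, exp(-delta / 2), 0)
  w / sum(w)
}

#' Fit a logical-rule model to one participant's trials
#'
#' The central fitting function: builds the probability-density-
#' approximation likelihood for the chosen architecture, samples its
#' posterior over the default box priors by DE-MCMC, and packages chains,
#' DIC and posterior summaries.
#'
#' @param trials a `trial_table` (one participant/condition).
#' @param architecture architecture tag (see [model_spec()]).
#' @param design stimulus design supplying perceptual means.
#' @param priors prior ranges (default [default_priors()]).
#' @param n_sim PDA simulants per stimulus per likelihood evaluation.
#' @param n_chains,n_iter,burn_in,init,refresh,migrate_every,seed passed
#'   to [de_mcmc()]; `refresh` defaults to `TRUE` here because the PDA
#'   likelihood is stochastic, and burn-in migration is on by default.
#' @param init_candidates when positive, that many random parameter
#'   vectors are screened per round by one (cheap, `n_sim/5`-simulant)
#'   likelihood evaluation each and the best `n_chains` become the chain
#'   starting points.
#' @param init_rounds screening rounds: rounds after the first resample
#'   candidates around the current elite set (shrinking-Gaussian search),
#'   which locates the high-likelihood region far faster than burn-in
#'   from diffuse starts.
#' @param polish_iter when positive (and screening is on), the screening
#'   incumbent is refined by that many Nelder-Mead iterations on the
#'   full-precision likelihood and the chains start in a tight ball
#'   around the refined mode.
#' @return An object of class `"rulefit"` with the `posterior_fit`, the
#'   DIC, and the posterior-mean `model_spec`.
#' @seealso [compare_rule_models()]
#' @export
fit_rule_model <- function(trials, architecture, design = stimulus_design(),
                           priors = default_priors(architecture, design),
                           n_sim = 10000, n_chains = NULL, n_iter = 500,
                           burn_in = floor(n_iter / 2), init = NULL,
                           init_candidates = 0, init_rounds = 4,
                           polish_iter = 0, refresh = TRUE,
                           migrate_every = 5, seed = NULL) {
  contaminant_range <- if (grepl("contaminant", architecture))
    range(trials$rt_ms) else NULL
  obs <- .split_obs(trials)
  log_post <- function(theta) {
    spec <- theta_to_spec(theta, architecture, design, contaminant_range)
    .pda_loglik_obs(spec, obs, n_sim = n_sim)
  }
  if (is.null(n_chains)) n_chains <- max(3 * length(priors),
                                         length(priors) + 1, 4)
  d <- length(priors)
  lo <- vapply(priors, `[`, 1, i = 1L)
  hi <- vapply(priors, `[`, 1, i = 2L)
  if (init_candidates > 0) {
    # iterated screening: sample candidates, keep an elite set, resample
    # around it; starts the DE population inside the high-likelihood
    # region instead of burning iterations on diffuse starts
    if (!is.null(seed)) set.seed(seed)
    cheap <- function(theta) {
      spec <- theta_to_spec(theta, architecture, design, contaminant_range)
      .pda_loglik_obs(spec, obs, n_sim = max(1000, floor(n_sim / 5)))
    }
    rng <- if (is.null(init)) priors else init
    ilo <- vapply(rng, `[`, 1, i = 1L)
    ihi <- vapply(rng, `[`, 1, i = 2L)
    n_elite <- max(n_chains, 30)
    cand <- matrix(stats::runif(init_candidates * d,
                                rep(ilo, each = init_candidates),
                                rep(ihi, each = init_candidates)),
                   init_candidates, d)
    for (r in seq_len(init_rounds)) {
      scores <- apply(cand, 1, cheap)
      elite <- cand[order(scores, decreasing = TRUE)[seq_len(n_elite)], ,
                    drop = FALSE]
      if (r == init_rounds) break
      mu <- colMeans(elite)
      sdv <- apply(elite, 2, stats::sd) * 1.2 + 1e-8
      cand <- matrix(stats::rnorm(init_candidates * d,
                                  rep(mu, each = init_candidates),
                                  rep(sdv, each = init_candidates)),
                     init_candidates, d)
      cand <- pmin(pmax(cand, rep(lo, each = init_candidates)),
                   rep(hi, each = init_candidates))
    }
    if (polish_iter > 0) {
      # Nelder-Mead refinement of the incumbent on the (noisy) full-n_sim
      # surface, in box-scaled coordinates; centres the chain population
      # on the mode so short runs yield usable posterior summaries
      scale <- hi - lo
      obj <- function(z) -log_post(pmin(pmax(z * scale + lo, lo), hi))
      opt <- stats::optim((elite[1, ] - lo) / scale, obj,
                          method = "Nelder-Mead",
                          control = list(maxit = polish_iter))
      centre <- pmin(pmax(opt$par * scale + lo, lo), hi)
      jit <- 0.02 * scale
      init <- matrix(stats::rnorm(n_chains * d, rep(centre, each = n_chains),
                                  rep(jit, each = n_chains)), n_chains, d)
      eps <- 1e-9 * scale
      init <- pmin(pmax(init, rep(lo + eps, each = n_chains)),
                   rep(hi - eps, each = n_chains))
    } else {
      init <- elite[seq_len(n_chains), , drop = FALSE]
    }
  }
  fit <- de_mcmc(log_post, priors, n_chains = n_chains, n_iter = n_iter,
                 burn_in = burn_in, init = init, refresh = refresh,
                 migrate_every = migrate_every, seed = seed)
  ic <- dic(fit)
  est <- coef.posterior_fit(fit)
  structure(list(architecture = architecture, design = design,
                 posterior = fit, dic = ic$dic, p_d = ic$p_d,
                 estimates = est,
                 spec = theta_to_spec(est, architecture, design,
                                      contaminant_range),
                 n_sim = n_sim, n_trials = nrow(trials)),
            class = "rulefit")
}

#' @export
print.rulefit <- function(x, ...) {
  cat("logical-rule model fit (", x$architecture, ")\n", sep = "")
  cat(sprintf("  %d trials, PDA with %d simulants per stimulus\n",
              x$n_trials, x$n_sim))
  cat(sprintf("  DIC %.1f (p_D %.1f), acceptance %.2f\n",
              x$dic, x$p_d, x$posterior$acceptance))
  cat("posterior means:\n")
  print(signif(x$estimates, 4))
  invisible(x)
}

#' @export
coef.rulefit <- function(object, ...) object$estimates

#' @export
summary.rulefit <- function(object, probs = c(.025, .5, .975), ...) {
  s <- object$posterior$samples
  flat <- apply(s, 3, identity)  # (iter*chain) x d
  qs <- t(apply(flat, 2, stats::quantile, probs))
  out <- data.frame(mean = colMeans(flat), sd = apply(flat, 2, stats::sd), qs,
                    check.names = FALSE)
  structure(list(architecture = object$architecture, table = out,
                 dic = object$dic, p_d = object$p_d), class = "summary.rulefit")
}

#' @export
print.summary.rulefit <- function(x, ...) {
  cat("posterior summary (", x$architecture, "), DIC ",
      sprintf("%.1f", x$dic), "\n", sep = "")
  print(signif(as.matrix(x$table), 4))
  invisible(x)
}

#' @export
predict.rulefit <- function(object, n_sim = 10000, seed = NULL, ...) {
  model_predictions(object$spec, n_sim = n_sim, seed = seed)
}

#' @export
simulate.rulefit <- function(object, nsim = 1, seed = NULL,
                             n_trials_per_item = 400, ...) {
  simulate_rt_dataset(object$spec, n_trials_per_item = n_trials_per_item,
                      n_participants = nsim,
                      seed = if (is.null(seed)) 1 else seed)
}

#' @export
plot.rulefit <- function(x, pars = NULL, ...) {
  s <- x$posterior$samples
  nm <- dimnames(s)[[3]]
  if (is.null(pars)) pars <- utils::head(nm, 4)
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::matplot(s[, , p], type = "l", lty = 1, ylab = p, ...)
  }
  invisible(x)
}

#' Compare fitted rule models by DIC
#'
#' @param ... named `rulefit` objects, or a single list of them.
#' @return data frame with `model`, `dic`, `p_d`, `weight`, `best`,
#'   sorted by DIC.
#' @export
compare_rule_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "rulefit"))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) f$architecture, "")
  dics <- vapply(fits, function(f) f$dic, 1)
  w <- dic_weights(dics)
  out <- data.frame(model = names(fits), dic = dics,
                    p_d = vapply(fits, function(f) f$p_d, 1),
                    weight = w, best = seq_along(dics) == which.min(dics),
                    row.names = NULL)
  out[order(out$dic), ]
}
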