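#' Empirical survivor function
#'
#' S(t) = P(T > t), estimated as the fraction of the sample strictly
#' exceeding each grid point.
#'
#' @param rts non-empty numeric RT sample (ms).
#' @param t_grid evaluation grid; defaults to the sorted unique sample
#'   values.
#' @return list with `t_grid`, `S`, `n`.
#' @export
survivor_fn <- function(rts, t_grid = sort(unique(rts))) {
  if (!length(rts)) stop("empty RT sample")
  srt <- sort(rts)
  S <- 1 - findInterval(t_grid, srt) / length(srt)
  list(t_grid = t_grid, S = S, n = length(srt))
}

#' Mean interaction contrast
#'
#' MIC = (RT_LL - RT_LH) - (RT_HL - RT_HH) over the four target-category
#' item means. Serial exhaustive processing predicts MIC = 0, parallel
#' exhaustive MIC < 0, coactive MIC > 0.
#'
#' @param mean_rts named numeric with elements `LL`, `LH`, `HL`, `HH`
#'   (mean correct RTs, ms).
#' @return MIC in ms.
#' @examples
#' mic(c(LL = 1041, LH = 749, HL = 894, HH = 710))  # 108
#' @export
mic <- function(mean_rts) {
  stopifnot(all(c("LL", "LH", "HL", "HH") %in% names(mean_rts)),
            all(is.finite(mean_rts[c("LL", "LH", "HL", "HH")])))
  unname((mean_rts["LL"] - mean_rts["LH"]) - (mean_rts["HL"] - mean_rts["HH"]))
}

# SIC(t) on a grid from four sorted samples
.sic_curve <- function(samples, t_grid) {
  S <- lapply(samples, function(x) 1 - findInterval(t_grid, sort(x)) / length(x))
  (S$LL - S$LH) - (S$HL - S$HH)
}

#' Survivor interaction contrast
#'
#' SIC(t) = [S_LL(t) - S_LH(t)] - [S_HL(t) - S_HH(t)]. Its integral over t
#' equals the MIC. Serial exhaustive processing predicts equal positive and
#' negative area, parallel exhaustive an entirely negative curve, and
#' coactivity a small early negative deflection followed by a dominant
#' positive one. Percentile bootstrap bands are computed by resampling each
#' item's RTs with replacement.
#'
#' @param rts_by_item named list of four non-empty RT samples (`LL`, `LH`,
#'   `HL`, `HH`), correct trials only.
#' @param t_grid evaluation grid; defaults to the pooled unique RTs.
#' @param n_boot bootstrap replicates for the confidence bands (0 or less
#'   omits bands with a warning).
#' @param conf band coverage.
#' @param seed optional seed for the bootstrap.
#' @return An object of class `"sic"`: `t_grid`, `sic`, `mic`, `boot`
#'   (lower/upper envelopes and replicate count), and the input samples.
#' @export
sic <- function(rts_by_item, t_grid = NULL, n_boot = 1000, conf = 0.95,
                seed = NULL) {
  stopifnot(all(c("LL", "LH", "HL", "HH") %in% names(rts_by_item)))
  samples <- rts_by_item[c("LL", "LH", "HL", "HH")]
  if (any(!vapply(samples, length, 1L))) stop("all four item samples must be non-empty")
  if (is.null(t_grid)) t_grid <- sort(unique(unlist(samples)))
  curve <- .sic_curve(samples, t_grid)
  m <- mic(vapply(samples, mean, 1))
  boot <- NULL
  if (n_boot >= 1) {
    if (!is.null(seed)) set.seed(seed)
    reps <- matrix(0, n_boot, length(t_grid))
    for (b in seq_len(n_boot)) {
      res <- lapply(samples, function(x) x[sample.int(length(x), replace = TRUE)])
      reps[b, ] <- .sic_curve(res, t_grid)
    }
    alpha <- (1 - conf) / 2
    boot <- list(lower = apply(reps, 2, stats::quantile, alpha),
                 upper = apply(reps, 2, stats::quantile, 1 - alpha),
                 n_boot = n_boot, conf = conf)
  } else {
    warning("n_boot < 1: bootstrap bands omitted")
  }
  structure(list(t_grid = t_grid, sic = curve, mic = m, boot = boot,
                 samples = samples),
            class = "sic")
}

#' @export
print.sic <- function(x, ...) {
  cat("survivor interaction contrast\n")
  cat(sprintf("  grid: %d points on [%.0f, %.0f] ms\n",
              length(x$t_grid), min(x$t_grid), max(x$t_grid)))
  cat(sprintf("  MIC: %.1f ms   D+: %.3f   D-: %.3f\n", x$mic,
              max(x$sic), abs(min(x$sic))))
  if (!is.null(x$boot))
    cat(sprintf("  %.0f%% bootstrap bands from %d replicates\n",
                100 * x$boot$conf, x$boot$n_boot))
  invisible(x)
}

#' @export
plot.sic <- function(x, ...) {
  ylim <- range(c(x$sic, x$boot$lower, x$boot$upper, 0))
  graphics::plot(x$t_grid, x$sic, type = "s", ylim = ylim,
                 xlab = "t (ms)", ylab = "SIC(t)", ...)
  if (!is.null(x$boot)) {
    graphics::lines(x$t_grid, x$boot$lower, lty = 2, col = "grey50")
    graphics::lines(x$t_grid, x$boot$upper, lty = 2, col = "grey50")
  }
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Integrate a SIC curve over its grid
#'
#' Step-function integral of SIC(t); equals the MIC up to quadrature
#' error when the grid covers the pooled sample.
#'
#' @param x a `"sic"` object.
#' @return integral in ms.
#' @export
sic_integral <- function(x) {
  # S(t) is a right-continuous step function changing at sample points, so
  # integrate the step curve exactly: value on [t_i, t_{i+1}) is sic[i].
  sum(x$sic[-length(x$sic)] * diff(x$t_grid))
}

#' Stochastic-dominance test suite
#'
#' Eight one-sided two-sample Kolmogorov-Smirnov tests on the target-item
#' RT distributions. A test written `S_a > S_b` asks whether item `a` is
#' stochastically faster than `b` (its CDF lies above): the statistic is
#' the maximum ECDF difference in that direction. If dominance holds the
#' first four tests (HH over HL, HH over LH, HL over LL, LH over LL) are
#' significant and the four reversed tests are not.
#'
#' @param rts_by_item named list with `LL`, `LH`, `HL`, `HH`.
#' @param alpha significance level for the verdict.
#' @return data frame of 8 tests (`test`, `statistic`, `p`), with
#'   attribute `dominance` (logical verdict).
#' @export
ks_dominance_suite <- function(rts_by_item, alpha = 0.05) {
  s <- rts_by_item[c("LL", "LH", "HL", "HH")]
  if (any(vapply(s, length, 1L) < 2)) stop("each item sample needs >= 2 RTs")
  pairs <- list(c("HH", "HL"), c("HH", "LH"), c("HL", "LL"), c("LH", "LL"))
  run <- function(a, b) {
    kt <- suppressWarnings(stats::ks.test(s[[a]], s[[b]], alternative = "greater"))
    data.frame(test = sprintf("S_%s > S_%s", a, b),
               statistic = unname(kt$statistic), p = kt$p.value)
  }
  fwd <- do.call(rbind, lapply(pairs, function(pr) run(pr[1], pr[2])))
  rev <- do.call(rbind, lapply(pairs, function(pr) {
    r <- run(pr[2], pr[1])
    r$test <- sprintf("S_%s < S_%s", pr[1], pr[2])
    r
  }))
  out <- rbind(fwd, rev)
  attr(out, "dominance") <- all(fwd$p < alpha) && all(rev$p >= alpha)
  out
}

#' Significance tests for the SIC deflections
#'
#' D+ is the largest positive and D- the absolute largest negative value of
#' the SIC. The default null distribution is generated by permutation:
#' pooled RTs are reshuffled over the four factorial cells (equivalently,
#' H/L labels are permuted within each dimension), preserving cell sizes.
#' The asymptotic backend uses the sup-Brownian-bridge tail
#' p = exp(-2 m D^2) with m = 1 / sum(1/n_i).
#'
#' @param x a `"sic"` object (must retain its raw samples).
#' @param n_resample permutation replicates.
#' @param seed optional seed.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @return list with `d_plus`, `p_plus`, `d_minus`, `p_minus`, `method`.
#' @export
sic_deflection_tests <- function(x, n_resample = 1000, seed = NULL,
                                 method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "sic"))
  d_plus <- max(c(x$sic, 0))
  d_minus <- abs(min(c(x$sic, 0)))
  ns <- vapply(x$samples, length, 1L)
  if (method == "asymptotic") {
    m <- 1 / sum(1 / ns)
    return(list(d_plus = d_plus, p_plus = min(1, exp(-2 * m * d_plus^2)),
                d_minus = d_minus, p_minus = min(1, exp(-2 * m * d_minus^2)),
                method = method))
  }
  if (sum(ns) < 8) stop("too few trials to permute")
  if (!is.null(seed)) set.seed(seed)
  pool <- unlist(x$samples, use.names = FALSE)
  idx_end <- cumsum(ns)
  idx_start <- c(1, idx_end[-4] + 1)
  ge_plus <- 0L; ge_minus <- 0L
  for (b in seq_len(n_resample)) {
    perm <- pool[sample.int(length(pool))]
    ps <- list(LL = perm[idx_start[1]:idx_end[1]],
               LH = perm[idx_start[2]:idx_end[2]],
               HL = perm[idx_start[3]:idx_end[3]],
               HH = perm[idx_start[4]:idx_end[4]])
    cv <- .sic_curve(ps, x$t_grid)
    if (max(c(cv, 0)) >= d_plus) ge_plus <- ge_plus + 1L
    if (abs(min(c(cv, 0))) >= d_minus) ge_minus <- ge_minus + 1L
  }
  list(d_plus = d_plus, p_plus = (1 + ge_plus) / (1 + n_resample),
       d_minus = d_minus, p_minus = (1 + ge_minus) / (1 + n_resample),
       method = method)
}

# correct target-category RTs of one participant, split by item role
target_item_rts <- function(trials) {
  tt <- trials[trials$correct & trials$role %in% c("LL", "LH", "HL", "HH"), ]
  split(tt$rt_ms, factor(tt$role, levels = c("LL", "LH", "HL", "HH")))
}

#' Per-participant factorial ANOVA on target-category RTs
#'
#' Fixed-effects 7 (session) x 2 (top half H/L) x 2 (bottom half H/L)
#' ANOVA on correct target-category RTs of a single participant. The top
#' factor is eye separation (`y_level`: 2 = H, 1 = L) and the bottom
#' factor lip height (`x_level`). The top x bottom interaction is the
#' MIC significance test; the three-way term asks whether that
#' interaction changes over sessions.
#'
#' @param trials a `trial_table` for one participant.
#' @return data frame with `effect`, `df1`, `df2`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
target_category_anova <- function(trials) {
  tt <- trials[trials$correct & trials$role %in% c("LL", "LH", "HL", "HH"), ]
  dat <- data.frame(rt = tt$rt_ms,
                    session = factor(tt$session),
                    top = factor(ifelse(tt$y_level == 2, "H", "L")),
                    bottom = factor(ifelse(tt$x_level == 2, "H", "L")))
  cells <- table(dat$session, dat$top, dat$bottom)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: session %s, top %s, bottom %s",
                 dimnames(cells)[[1]][empty[1]], dimnames(cells)[[2]][empty[2]],
                 dimnames(cells)[[3]][empty[3]]))
  }
  fit <- stats::aov(rt ~ session * top * bottom, data = dat)
  sm <- summary(fit)[[1]]
  ss_res <- sm["Residuals", "Sum Sq"]
  df2 <- sm["Residuals", "Df"]
  eff <- setdiff(trimws(rownames(sm)), "Residuals")
  rows <- match(eff, trimws(rownames(sm)))
  data.frame(effect = eff,
             df1 = sm[rows, "Df"], df2 = df2,
             F = sm[rows, "F value"], p = sm[rows, "Pr(>F)"],
             partial_eta_sq = sm[rows, "Sum Sq"] / (sm[rows, "Sum Sq"] + ss_res),
             row.names = NULL)
}

#' Planned comparisons on the contrast-category items
#'
#' Welch two-sample t-tests on correct contrast-category RTs of one
#' participant: exterior vs interior on each dimension, and each of the
#' four against the redundant stimulus. `Top` is the eye-separation
#' dimension (roles `Ey`/`Iy`), `Bottom` lip height (`Ex`/`Ix`). Serial
#' self-terminating processing with a fixed order predicts slower interior
#' than exterior items on the second-processed dimension; parallel
#' self-terminating processing predicts no interior/exterior differences;
#' coactivity predicts faster interior than exterior items.
#'
#' @param trials a `trial_table` for one participant.
#' @return data frame with `comparison`, `mean_diff`, `t`, `df`, `p`,
#'   `cohens_d`.
#' @export
contrast_category_tests <- function(trials) {
  tt <- trials[trials$correct & trials$role %in% c("R", "Ix", "Ex", "Iy", "Ey"), ]
  by_role <- split(tt$rt_ms, tt$role)
  for (r in c("R", "Ix", "Ex", "Iy", "Ey"))
    if (!length(by_role[[r]])) stop("no correct trials for role ", r)
  comps <- list(c("E_Top - I_Top", "Ey", "Iy"),
                c("E_Bottom - I_Bottom", "Ex", "Ix"),
                c("E_Top - R", "Ey", "R"),
                c("I_Top - R", "Iy", "R"),
                c("E_Bottom - R", "Ex", "R"),
                c("I_Bottom - R", "Ix", "R"))
  do.call(rbind, lapply(comps, function(cp) {
    a <- by_role[[cp[2]]]; b <- by_role[[cp[3]]]
    wt <- stats::t.test(a, b)
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    data.frame(comparison = cp[1], mean_diff = mean(a) - mean(b),
               t = unname(wt$statistic), df = unname(wt$parameter),
               p = wt$p.value, cohens_d = abs(mean(a) - mean(b)) / sp)
  }))
}

#' Full nonparametric battery for one participant
#'
#' Runs the SIC/MIC analysis, deflection and dominance tests, the
#' factorial ANOVA and the contrast-category comparisons, derives the
#' categorical summaries (SIC shape by thresholding the deflection tests:
#' positive if only D+ is significant, mostly negative if only D-, else
#' S-shaped; MIC significance from the ANOVA top x bottom term with the
#' sign of the sample MIC; interior-vs-exterior pattern per dimension from
#' the planned comparisons), and applies [classify_architecture()].
#'
#' @param trials a `trial_table` for one participant.
#' @param alpha significance level used throughout.
#' @param n_boot bootstrap replicates for SIC bands.
#' @param n_resample permutation replicates for the deflection tests.
#' @param seed optional seed for the resampling steps.
#' @return list with components `sic`, `deflections`, `dominance`,
#'   `anova`, `contrast`, `shape`, `mic_token`, `contrast_pattern`,
#'   `classification`.
#' @export
sft_summary <- function(trials, alpha = 0.05, n_boot = 500,
                        n_resample = 500, seed = NULL) {
  rts <- target_item_rts(trials)
  s <- sic(rts, n_boot = n_boot, seed = seed)
  defl <- sic_deflection_tests(s, n_resample = n_resample, seed = seed)
  dom <- ks_dominance_suite(rts, alpha = alpha)
  an <- target_category_anova(trials)
  ct <- contrast_category_tests(trials)
  dp_sig <- defl$p_plus < alpha
  dm_sig <- defl$p_minus < alpha
  shape <- if (dp_sig && !dm_sig) "positive"
    else if (dm_sig && !dp_sig) "mostly-negative" else "S-shaped"
  mic_p <- an$p[an$effect == "top:bottom"]
  mic_token <- if (mic_p >= alpha) "non-sig"
    else if (s$mic > 0) "sig-positive" else "sig-negative"
  pat <- function(comparison) {
    row <- ct[ct$comparison == comparison, ]
    if (row$p >= alpha) "I=E" else if (row$mean_diff > 0) "I<E" else "I>E"
  }
  pattern <- list(top = pat("E_Top - I_Top"), bottom = pat("E_Bottom - I_Bottom"))
  cls <- classify_architecture(
    list(shape = shape, d_plus_sig = dp_sig, d_minus_sig = dm_sig),
    mic_token, pattern)
  list(sic = s, deflections = defl, dominance = dom, anova = an,
       contrast = ct, shape = shape, mic_token = mic_token,
       contrast_pattern = pattern, classification = cls)
}

#' Qualitative architecture classification
#'
#' Deterministic rule table mapping the categorical summaries of the
#' nonparametric analyses -- SIC shape, MIC significance, and the
#' interior-vs-exterior contrast pattern, interpreted in that order -- to
#' architecture labels. Multiple labels are returned when the evidence is
#' genuinely ambiguous. When the SIC shape is S-shaped but both
#' deflections are individually significant, the positive deflection
#' dominates the reading and coactivity is listed alongside serial
#' processing.
#'
#' @param sic_summary either a shape token or a list with `shape` plus
#'   optional logicals `d_plus_sig`, `d_minus_sig`. Recognized shapes
#'   (case-insensitive, extra qualifiers allowed): `"positive"`,
#'   `"mostly-negative"`, `"S-shaped"`.
#' @param mic_significant logical, or one of `"non-sig"`,
#'   `"sig-positive"`, `"sig-negative"` when the sign of a significant
#'   MIC is known.
#' @param contrast_pattern per-dimension interior/exterior verdicts: a
#'   list with `top` and `bottom`, each `"I<E"`, `"I=E"`, or `"I>E"` (a
#'   single string applies to both).
#' @return character vector of architecture labels.
#' @examples
#' classify_architecture("positive", TRUE, "I<E")        # Coactive
#' classify_architecture("S-shaped", FALSE, "I=E")       # Parallel/Serial ST
#' @export
classify_architecture <- function(sic_summary, mic_significant,
                                  contrast_pattern) {
  if (!is.list(sic_summary)) sic_summary <- list(shape = sic_summary)
  shape_raw <- tolower(sic_summary$shape)
  shape <- if (grepl("s-shaped|s shaped", shape_raw)) "s-shaped"
    else if (grepl("negative", shape_raw)) "mostly-negative"
    else if (grepl("positive", shape_raw)) "positive"
    else stop("unknown SIC shape token: ", sic_summary$shape)
  if (!is.list(contrast_pattern))
    contrast_pattern <- list(top = contrast_pattern, bottom = contrast_pattern)
  ok <- c("I<E", "I=E", "I>E")
  if (!contrast_pattern$top %in% ok || !contrast_pattern$bottom %in% ok)
    stop("contrast_pattern entries must be one of ", paste(ok, collapse = ", "))
  if (is.logical(mic_significant))
    mic_significant <- if (mic_significant) "sig-positive" else "non-sig"
  if (!mic_significant %in% c("non-sig", "sig-positive", "sig-negative"))
    stop("unknown mic_significant token: ", mic_significant)
  both_sig <- isTRUE(sic_summary$d_plus_sig) && isTRUE(sic_summary$d_minus_sig)
  if (shape == "positive") {
    if (mic_significant == "sig-positive") return("Coactive")
    return(c("Coactive", "Serial ST"))
  }
  if (shape == "mostly-negative") {
    # a negative SIC reads parallel, but slower interior than exterior
    # items contradict parallel self-termination; list both readings
    if (contrast_pattern$top == "I>E" || contrast_pattern$bottom == "I>E")
      return(c("Parallel ST", "Serial ST"))
    return("Parallel ST")
  }
  # s-shaped
  if (mic_significant == "sig-negative") return("Parallel ST")
  if (mic_significant == "sig-positive") return("Coactive")
  if (both_sig) return(c("Coactive", "Serial ST"))
  if (contrast_pattern$top == "I=E" && contrast_pattern$bottom == "I=E")
    return(c("Parallel ST", "Serial ST"))
  "Serial ST"
}
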