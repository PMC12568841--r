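#' Equal-variance signal-detection indices
#'
#' d' = z(H) - z(F) and criterion c = -(z(H) + z(F))/2, with "different"
#' trials treated as signal. Extreme proportions (0 or 1) are corrected by
#' the 1/(2N) rule before the z transform.
#'
#' @param hits,misses count of signal ("different") trials answered
#'   "different" / "same".
#' @param false_alarms,correct_rejections counts on noise ("same") trials.
#' @return named numeric `c(d_prime, criterion)`.
#' @examples
#' sdt_indices(42, 8, 8, 42)
#' @export
sdt_indices <- function(hits, misses, false_alarms, correct_rejections) {
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig < 1 || n_noise < 1)
    stop("need at least one signal and one noise trial")
  h <- hits / n_sig
  f <- false_alarms / n_noise
  if (h == 0) h <- 1 / (2 * n_sig)
  if (h == 1) h <- 1 - 1 / (2 * n_sig)
  if (f == 0) f <- 1 / (2 * n_noise)
  if (f == 1) f <- 1 - 1 / (2 * n_noise)
  zh <- stats::qnorm(h); zf <- stats::qnorm(f)
  c(d_prime = zh - zf, criterion = -(zh + zf) / 2)
}

#' Per-cell SDT summary of composite-task trials
#'
#' Aggregates a same/different trial table into hit/false-alarm counts and
#' d'/criterion per participant and congruency x alignment cell.
#'
#' @param trials data frame with `participant`, `alignment`, `congruency`,
#'   `trial_type` ("same"/"different"), `response` ("same"/"different");
#'   see [simulate_composite_trials()].
#' @return data frame with counts, `d_prime` and `criterion` per cell.
#' @export
sdt_summary <- function(trials) {
  key <- interaction(trials$participant, trials$alignment, trials$congruency,
                     drop = TRUE)
  rows <- lapply(split(trials, key), function(cell) {
    sig <- cell$trial_type == "different"
    hits <- sum(sig & cell$response == "different")
    fa <- sum(!sig & cell$response == "different")
    idx <- sdt_indices(hits, sum(sig) - hits, fa, sum(!sig) - fa)
    data.frame(participant = cell$participant[1],
               alignment = cell$alignment[1], congruency = cell$congruency[1],
               n_signal = sum(sig), n_noise = sum(!sig),
               hits = hits, false_alarms = fa,
               d_prime = idx[["d_prime"]], criterion = idx[["criterion"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Within-participant congruency x alignment ANOVA on a per-cell measure
#' (d' or criterion). Each effect is tested against its own
#' participant x effect interaction error term. Reports F, dfs, the error
#' mean square, p, and partial eta squared.
#'
#' @param cells data frame with `participant`, `congruency`, `alignment`
#'   and the response variable.
#' @param dv name of the response column (default `"d_prime"`).
#' @return data frame with one row per effect.
#' @export
rm_anova_2x2 <- function(cells, dv = "d_prime") {
  dat <- data.frame(participant = factor(cells$participant),
                    congruency = factor(cells$congruency),
                    alignment = factor(cells$alignment),
                    y = cells[[dv]])
  if (nlevels(dat$participant) < 3) stop("need at least 3 participants")
  if (any(table(dat$participant, dat$congruency, dat$alignment) != 1))
    stop("each participant needs exactly one value per congruency x alignment cell")
  fit <- stats::aov(y ~ congruency * alignment +
                      Error(participant / (congruency * alignment)), data = dat)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn); j <- match("Residuals", rn)
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[j, "Sum Sq"]
    f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    if (isTRUE(all.equal(ss_e, 0))) { f <- 0; p <- 1 }  # 0/0 guard
    data.frame(effect = effect,
               df1 = tab[i, "Df"], df2 = tab[j, "Df"],
               F = f, MSE = tab[j, "Mean Sq"], p = p,
               partial_eta_sq = if (ss_e + ss_r > 0) ss_e / (ss_e + ss_r) else 0)
  }
  out <- rbind(pull("participant:congruency", "congruency"),
               pull("participant:alignment", "alignment"),
               pull("participant:congruency:alignment", "congruency:alignment"))
  rownames(out) <- NULL
  out
}
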