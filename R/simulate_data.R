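#' Simulate a full categorization dataset with known ground truth
#'
#' Emulates the double-factorial categorization experiment: every stimulus
#' of the 3x3 design is shown `n_trials_per_item` times to each simulated
#' participant, responses and RTs coming from the architecture in `spec`.
#' The design target is 400 presentations per stimulus per participant
#' spread over sessions 2-8 (session 1 being practice and never generated);
#' session indices are assigned uniformly and, by default, carry no
#' learning effect. `session_speedup_ms` subtracts that many ms per
#' session step for testing session terms in the ANOVA.
#'
#' Each participant draws from an independently seeded stream derived from
#' `seed`, so single participants can be regenerated without the rest.
#'
#' @param spec generating [model_spec()].
#' @param n_trials_per_item trials per stimulus per participant.
#' @param n_participants number of simulated participants.
#' @param seed integer master seed; fully determines the output.
#' @param condition label stored in the `condition` column.
#' @param sessions session indices to spread trials over.
#' @param session_speedup_ms linear RT decrease per session step (ms).
#' @return A `trial_table` (see [read_trials()] for the schema).
#' @export
simulate_rt_dataset <- function(spec, n_trials_per_item = 400,
                                n_participants = 1, seed = 1,
                                condition = "aligned", sessions = 2:8,
                                session_speedup_ms = 0) {
  stopifnot(inherits(spec, "model_spec"), n_trials_per_item >= 1,
            n_participants >= 1)
  design <- spec$design
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed((seed + 7919L * p) %% .Machine$integer.max)
    blocks <- vector("list", nrow(design$stimuli))
    for (i in seq_len(nrow(design$stimuli))) {
      st <- design$stimuli[i, ]
      sim <- simulate_model(spec, st$x_level, st$y_level, n_trials_per_item)
      sess <- sample(rep_len(sessions, n_trials_per_item))
      rt <- sim$rt_ms - session_speedup_ms * (sess - min(sessions))
      blocks[[i]] <- data.frame(
        participant = sprintf("P%02d", p), condition = condition,
        session = sess, x_level = st$x_level, y_level = st$y_level,
        response = sim$response, rt_ms = pmax(rt, 1),
        stringsAsFactors = FALSE)
    }
    out[[p]] <- do.call(rbind, blocks)
  }
  validate_trials(do.call(rbind, out), design = design,
                  source = sprintf("simulate_rt_dataset(seed=%d)", seed))
}

#' Simulate pairwise similarity ratings
#'
#' Generates ratings on the 1-8 scale for all 36 unordered pairs of the 9
#' stimuli, three repetitions per participant, from a weighted Minkowski
#' distance model: rating = clamp(round(a - b * w_p * d_ij + eps), 1, 8)
#' with eps ~ Normal(0, noise_sd). Larger distances give lower (less
#' similar) ratings; clamping at the scale ends censors the extremes.
#'
#' @param coords 9 x 2 matrix of stimulus coordinates (rows in the order
#'   of `stimulus_design()$stimuli`).
#' @param weights positive per-participant scale factors.
#' @param metric_r Minkowski exponent (1 = city block, 2 = Euclidean).
#' @param noise_sd rating noise SD (rating units).
#' @param a,b intercept and (positive) slope of the distance-to-rating
#'   map. The defaults (a = 9, b = 8/max distance) make the implied
#'   dissimilarity 9 - rating directly proportional to the weighted
#'   distance — the same zero-intercept form the scaling model fits —
#'   and span the full 1-8 scale, with clamping at the scale ends acting
#'   as censoring.
#' @param seed integer seed.
#' @return data frame with `participant`, `i`, `j` (stimulus indices,
#'   i < j), `repetition`, `rating`.
#' @export
simulate_similarity_ratings <- function(coords, weights, metric_r = 2,
                                        noise_sd = 0.5, a = 9, b = NULL,
                                        seed = 1) {
  stopifnot(nrow(coords) == 9, ncol(coords) == 2, all(weights > 0),
            metric_r >= 1)
  pairs <- t(utils::combn(9, 2))
  d <- apply(pairs, 1, function(pr)
    minkowski_distance(coords[pr[1], ], coords[pr[2], ], r = metric_r))
  if (is.null(b)) b <- 8 / max(d)
  if (b <= 0) stop("b must be positive: similarity must decrease with distance")
  set.seed(seed)
  out <- list()
  for (p in seq_along(weights)) {
    for (rep_i in 1:3) {
      eps <- stats::rnorm(nrow(pairs), 0, noise_sd)
      rating <- pmin(pmax(round(a - b * weights[p] * d + eps), 1), 8)
      out[[length(out) + 1L]] <- data.frame(
        participant = sprintf("P%02d", p),
        i = pairs[, 1], j = pairs[, 2], repetition = rep_i,
        rating = as.integer(rating))
    }
  }
  do.call(rbind, out)
}

#' Simulate composite-face (same/different) trials
#'
#' Equal-variance Gaussian signal-detection generator for the complete
#' composite design: on "different" trials the decision variable is drawn
#' from Normal(d', 1), on "same" trials from Normal(0, 1), and the
#' observer responds "different" iff it exceeds d'/2 + c — the criterion
#' c is measured from the midpoint of the two distributions, so c = 0 is
#' the unbiased observer and the generated c matches the index estimated
#' by [sdt_indices()]. Sensitivity
#' and criterion may differ across the congruency x alignment cells;
#' the default sensitivities build in the holistic-processing marker, a
#' congruency effect for aligned faces (2.0 vs 1.4) that shrinks when the
#' halves are misaligned (1.6 vs 1.4). Per-participant sensitivity
#' offsets (SD `participant_sd`) add realistic heterogeneity.
#'
#' @param dprime 2 x 2 numeric matrix, rows `aligned`/`misaligned`,
#'   columns `congruent`/`incongruent`.
#' @param criterion same shape; decision criterion per cell.
#' @param n_per_cell trials per cell per participant (half "same", half
#'   "different").
#' @param n_participants number of participants.
#' @param participant_sd SD of the per-participant d' offset.
#' @param seed integer seed.
#' @return data frame with `participant`, `alignment`, `congruency`,
#'   `trial_type`, `response`.
#' @export
simulate_composite_trials <- function(
    dprime = matrix(c(2.0, 1.4, 1.6, 1.4), 2, 2, byrow = TRUE,
                    dimnames = list(c("aligned", "misaligned"),
                                    c("congruent", "incongruent"))),
    criterion = matrix(c(0.1, 0.1, -0.1, -0.1), 2, 2, byrow = TRUE,
                       dimnames = dimnames(dprime)),
    n_per_cell = 128, n_participants = 36, participant_sd = 0.2,
    seed = 1) {
  if (n_per_cell < 1) stop("n_per_cell must be >= 1")
  stopifnot(all(dprime >= 0), all(dim(dprime) == c(2, 2)))
  set.seed(seed)
  out <- list()
  n_diff <- ceiling(n_per_cell / 2)
  n_same <- n_per_cell - n_diff
  for (p in seq_len(n_participants)) {
    offs <- stats::rnorm(1, 0, participant_sd)
    for (al in rownames(dprime)) for (cg in colnames(dprime)) {
      dp <- max(dprime[al, cg] + offs, 0)
      thr <- dp / 2 + criterion[al, cg]
      ev <- c(stats::rnorm(n_diff, dp, 1), stats::rnorm(n_same, 0, 1))
      out[[length(out) + 1L]] <- data.frame(
        participant = sprintf("P%02d", p), alignment = al, congruency = cg,
        trial_type = rep(c("different", "same"), c(n_diff, n_same)),
        response = ifelse(ev > thr, "different", "same"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
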