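#' Weighted Minkowski distance
#'
#' `model_distance()` is the INDSCAL-style distance used by the
#' confirmatory MDS models: a common set of coordinates, a Minkowski
#' exponent r (1 = city block, 2 = Euclidean), and a positive
#' per-participant weight that scales all of that participant's distances.
#'
#' @param coord_i,coord_j numeric coordinate vectors of equal length.
#' @param w_p positive participant weight.
#' @param r Minkowski exponent, must be >= 1.
#' @return scalar distance.
#' @examples
#' model_distance(c(0, 0), c(3, 4), w_p = 1, r = 2)  # 5
#' model_distance(c(0, 0), c(3, 4), w_p = 1, r = 1)  # 7
#' @export
model_distance <- function(coord_i, coord_j, w_p = 1, r = 2) {
  if (r < 1) stop("r must be >= 1 (not a metric otherwise)")
  if (w_p <= 0) stop("w_p must be positive")
  w_p * minkowski_distance(coord_i, coord_j, r)
}

minkowski_distance <- function(a, b, r) {
  sum(abs(a - b)^r)^(1 / r)
}

#' Screen similarity-rating participants by response-scale use
#'
#' Removes participants who did not use every response option 1-8, or
#' whose two most frequent options account for more than
#' `dominance_threshold` of their responses.
#'
#' @param ratings data frame with `participant` and `rating` columns
#'   (see [simulate_similarity_ratings()]).
#' @param dominance_threshold maximum allowed share of the two most-used
#'   options.
#' @return list with `kept` and `removed` (participant ids) and `report`,
#'   a per-participant histogram data frame with the removal reason.
#' @export
screen_participants <- function(ratings, dominance_threshold = 0.6) {
  if (!nrow(ratings)) stop("empty ratings table")
  parts <- split(ratings$rating, ratings$participant)
  rep_rows <- lapply(names(parts), function(p) {
    h <- tabulate(parts[[p]], nbins = 8)
    share2 <- sum(sort(h, decreasing = TRUE)[1:2]) / sum(h)
    reason <- if (any(h == 0)) "incomplete scale use"
      else if (share2 > dominance_threshold) "dominant options"
      else ""
    cbind(data.frame(participant = p, t(h), top2_share = share2,
                     removed = nzchar(reason), reason = reason))
  })
  report <- do.call(rbind, rep_rows)
  names(report)[2:9] <- paste0("n", 1:8)
  list(kept = report$participant[!report$removed],
       removed = report$participant[report$removed],
       report = report)
}

#' BIC from a sum of squared deviations
#'
#' Gaussian likelihood with the variance concentrated out
#' (sigma^2 = ssd/n): BIC = n log(ssd/n) + n (1 + log 2 pi) + k log n.
#' Comparable only across models of the same data.
#'
#' @param ssd sum of squared deviations (> 0).
#' @param k number of free parameters.
#' @param n number of data points (> k).
#' @return scalar BIC (`-Inf` with a warning when `ssd` is 0).
#' @export
bic_from_ssd <- function(ssd, k, n) {
  stopifnot(n > k)
  if (ssd <= 0) {
    warning("ssd is 0: perfect-fit degeneracy, returning -Inf")
    return(-Inf)
  }
  n * log(ssd / n) + n * (1 + log(2 * pi)) + k * log(n)
}

# build the 9 x 2 coordinate matrix from the unconstrained parameter block
# stimulus order follows stimulus_design()$stimuli (x_level fastest)
.mds_coords <- function(par, mode) {
  if (mode == "constrained_grid") {
    xs <- c(0, cumsum(exp(par[1:2])))
    ys <- c(0, cumsum(exp(par[3:4])))
    g <- expand.grid(x = 0:2, y = 0:2)
    cbind(xs[g$x + 1], ys[g$y + 1])
  } else {
    # X[x, y-column]: per column a base plus positive increments (8 params);
    # Y[x-row, y] transposed likewise; stimulus x0y0 anchored at (0, 0)
    X <- matrix(0, 3, 3); Y <- matrix(0, 3, 3)
    i <- 1
    for (cc in 1:3) {
      base <- if (cc == 1) 0 else { v <- par[i]; i <- i + 1; v }
      X[, cc] <- base + c(0, cumsum(exp(par[i:(i + 1)]))); i <- i + 2
    }
    for (rr in 1:3) {
      base <- if (rr == 1) 0 else { v <- par[i]; i <- i + 1; v }
      Y[rr, ] <- base + c(0, cumsum(exp(par[i:(i + 1)]))); i <- i + 2
    }
    g <- expand.grid(x = 0:2, y = 0:2)
    cbind(X[cbind(g$x + 1, g$y + 1)], Y[cbind(g$x + 1, g$y + 1)])
  }
}

.mds_npar_coord <- function(mode) if (mode == "constrained_grid") 4L else 16L

#' Confirmatory INDSCAL multidimensional scaling
#'
#' Fits stimulus coordinates to similarity ratings by minimizing the sum
#' of squared deviations between INDSCAL-weighted Minkowski distances and
#' rating-derived dissimilarities (dissimilarity = 9 - rating). Two
#' coordinate models are available: `free_monotone` gives every stimulus
#' its own coordinates, constrained to increase along each dimension
#' within every row/column of the 3x3 design (16 coordinate parameters;
#' the first stimulus is anchored at (0, 0)); `constrained_grid` shares
#' level values across the grid (4 coordinate parameters). The metric is
#' city block (`r = 1`), Euclidean (`r = 2`), or free (`r` estimated in
#' [1, 5]). Participant weights are constrained to geometric mean 1.
#' Optimization is multi-start quasi-Newton on an unconstrained
#' reparameterization (positive increments via log transform).
#'
#' @param ratings data frame with `participant`, `i`, `j`, `rating`
#'   (stimulus indices in design order).
#' @param coordinate_mode `"constrained_grid"` or `"free_monotone"`.
#' @param metric `1`, `2`, or `"free"`.
#' @param n_restarts number of optimizer restarts.
#' @param seed optional seed for the restart jitter.
#' @return An object of class `"mdsfit"`: `coordinates` (9 x 2),
#'   `weights` (named, geometric mean 1), `r`, `ssd`, `bic`, `k`, `n`.
#' @export
fit_mds <- function(ratings, coordinate_mode = c("constrained_grid",
                                                 "free_monotone"),
                    metric = 2, n_restarts = 20, seed = NULL) {
  coordinate_mode <- match.arg(coordinate_mode)
  parts <- sort(unique(ratings$participant))
  P <- length(parts)
  if (P < 2) stop("need ratings from at least 2 participants")
  free_r <- identical(metric, "free")
  if (!free_r && metric < 1) stop("metric r must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dissim <- 9 - ratings$rating
  pi_idx <- match(ratings$participant, parts)
  ii <- ratings$i; jj <- ratings$j
  nc <- .mds_npar_coord(coordinate_mode)
  npar <- nc + (P - 1) + free_r
  objective <- function(par) {
    coords <- .mds_coords(par[1:nc], coordinate_mode)
    lw <- par[nc + seq_len(P - 1)]
    w <- exp(c(lw, -sum(lw)))
    r <- if (free_r) 1 + 4 * stats::plogis(par[npar]) else metric
    dmat <- (abs(coords[ii, 1] - coords[jj, 1])^r +
             abs(coords[ii, 2] - coords[jj, 2])^r)^(1 / r)
    sum((w[pi_idx] * dmat - dissim)^2)
  }
  # start at a unit grid with unit weights, then jittered restarts
  start0 <- rep(0, npar)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    st <- if (rs == 1) start0 else start0 + stats::rnorm(npar, 0, 0.5)
    opt <- stats::nlminb(st, objective,
                         control = list(rel.tol = 1e-10, iter.max = 2000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || !is.finite(best$objective))
    stop("MDS optimization failed to converge; best incumbent: ",
         if (is.null(best)) "none" else best$objective)
  par <- best$par
  coords <- .mds_coords(par[1:nc], coordinate_mode)
  lw <- par[nc + seq_len(P - 1)]
  w <- exp(c(lw, -sum(lw)))
  names(w) <- parts
  r_hat <- if (free_r) 1 + 4 * stats::plogis(par[npar]) else metric
  k <- nc + P + free_r  # one weight parameter counted per participant
  n <- nrow(ratings)
  structure(list(coordinate_mode = coordinate_mode, metric = metric,
                 coordinates = coords, weights = w, r = r_hat,
                 ssd = best$objective, bic = bic_from_ssd(best$objective, k, n),
                 k = k, n = n, convergence = best$convergence),
            class = "mdsfit")
}

#' @export
print.mdsfit <- function(x, ...) {
  cat(sprintf("confirmatory MDS fit: %s, r = %s\n", x$coordinate_mode,
              if (identical(x$metric, "free")) sprintf("%.2f (free)", x$r)
              else format(x$metric)))
  cat(sprintf("  SSD %.2f, BIC %.2f (k = %d, n = %d)\n",
              x$ssd, x$bic, x$k, x$n))
  cat("coordinates:\n")
  m <- round(x$coordinates, 3)
  dimnames(m) <- list(role_table()$role, c("X", "Y"))
  print(m)
  invisible(x)
}

#' @export
coef.mdsfit <- function(object, ...) object$coordinates

#' Fit the standard set of six MDS models
#'
#' Crosses the two coordinate modes with the three metrics and returns a
#' comparison table ranked by BIC.
#'
#' @param ratings as for [fit_mds()].
#' @param n_restarts,seed passed to [fit_mds()].
#' @return list with `fits` (named list of `mdsfit`) and `table`
#'   (data frame: model, ssd, bic, best flag).
#' @export
fit_mds_suite <- function(ratings, n_restarts = 20, seed = NULL) {
  grid <- expand.grid(mode = c("constrained_grid", "free_monotone"),
                      metric = c("1", "2", "free"), stringsAsFactors = FALSE)
  fits <- list()
  for (i in seq_len(nrow(grid))) {
    metric <- if (grid$metric[i] == "free") "free" else as.numeric(grid$metric[i])
    nm <- paste0(grid$mode[i], "_r", grid$metric[i])
    fits[[nm]] <- fit_mds(ratings, grid$mode[i], metric,
                          n_restarts = n_restarts, seed = seed)
  }
  tab <- data.frame(model = names(fits),
                    ssd = vapply(fits, function(f) f$ssd, 1),
                    bic = vapply(fits, function(f) f$bic, 1),
                    row.names = NULL)
  tab$best <- tab$bic == min(tab$bic)
  list(fits = fits, table = tab[order(tab$bic), ])
}
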