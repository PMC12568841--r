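#' Read a trial-level response-time table
#'
#' Reads the tidy CSV schema used throughout the package: columns
#' `participant`, `condition` (aligned/misaligned), `session`, `x_level`,
#' `y_level`, `response` (target/contrast), `rt_ms`. Validates ranges,
#' derives `correct` from the conjunctive target rule, and attaches the
#' stimulus role for each row.
#'
#' @param path path to a CSV file (comma separator, dot decimal, header,
#'   UTF-8).
#' @param design a [stimulus_design()].
#' @return A `trial_table`: a data frame with the input columns plus
#'   `role` and `correct`, and attribute `source` holding `path`.
#' @seealso [write_trials()], [trim_rts()]
#' @export
read_trials <- function(path, design = stimulus_design()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_trials(raw, source = path)
}

#' @rdname read_trials
#' @param trials a data frame in the trials schema (e.g. just read or
#'   simulated); validated and promoted to a `trial_table`.
#' @param source provenance string recorded on the result.
#' @export
validate_trials <- function(trials, design = stimulus_design(), source = "<in-memory>") {
  needed <- c("participant", "condition", "session", "x_level", "y_level",
              "response", "rt_ms")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trials table is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad_lvl <- which(!(trials$x_level %in% 0:2) | !(trials$y_level %in% 0:2))
  if (length(bad_lvl))
    stop("x_level/y_level out of range 0..2 at row(s): ",
         paste(utils::head(bad_lvl, 5), collapse = ", "))
  rt <- suppressWarnings(as.numeric(trials$rt_ms))
  bad_rt <- which(!is.finite(rt) | rt <= 0)
  if (length(bad_rt))
    stop("rt_ms must be finite and positive; offending row(s): ",
         paste(utils::head(bad_rt, 5), collapse = ", "))
  bad_resp <- which(!trials$response %in% c("target", "contrast"))
  if (length(bad_resp))
    stop("response must be 'target' or 'contrast'; offending row(s): ",
         paste(utils::head(bad_resp, 5), collapse = ", "))
  trials$rt_ms <- rt
  trials$role <- .role_map[cbind(trials$x_level + 1L, trials$y_level + 1L)]
  implied <- ifelse(is_target_cell(trials$x_level, trials$y_level),
                    "target", "contrast")
  trials$correct <- trials$response == implied
  attr(trials, "source") <- source
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant", "condition", "session", "x_level", "y_level",
            "response", "rt_ms")
  utils::write.csv(trials[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Trim response times
#'
#' Applies the standard two-part filter: RTs below 200 ms are removed, then
#' RTs strictly greater than mean + 3 SD -- with mean and SD computed per
#' item cell (participant x x_level x y_level x condition) on the data that
#' survived the floor -- are removed. The filter is single pass: the
#' threshold is not recomputed after removal. Cells with a single
#' observation apply only the floor (SD undefined).
#'
#' @param trials a `trial_table`.
#' @param floor_ms lower cutoff in ms (default 200).
#' @param sd_mult upper cutoff multiplier (default 3).
#' @return A list with `kept` (trimmed `trial_table`) and `report`, a data
#'   frame of per-cell counts (`n_before`, `n_removed_floor`,
#'   `n_removed_upper`) plus an `overall_fraction_removed` attribute.
#' @export
trim_rts <- function(trials, floor_ms = 200, sd_mult = 3) {
  key <- interaction(trials$participant, trials$condition,
                     trials$x_level, trials$y_level, drop = TRUE)
  keep <- logical(nrow(trials))
  rows <- split(seq_len(nrow(trials)), key)
  rep_list <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    idx <- rows[[i]]
    if (!length(idx)) next
    rt <- trials$rt_ms[idx]
    above_floor <- rt >= floor_ms
    surv <- rt[above_floor]
    if (length(surv) >= 2 && stats::sd(surv) > 0) {
      thr <- mean(surv) + sd_mult * stats::sd(surv)
      ok <- above_floor & rt <= thr
    } else {
      ok <- above_floor
    }
    keep[idx] <- ok
    rep_list[[i]] <- data.frame(
      participant = trials$participant[idx[1]],
      condition = trials$condition[idx[1]],
      x_level = trials$x_level[idx[1]],
      y_level = trials$y_level[idx[1]],
      n_before = length(idx),
      n_removed_floor = sum(!above_floor),
      n_removed_upper = sum(above_floor & !ok),
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_list)
  kept <- trials[keep, , drop = FALSE]
  attr(kept, "source") <- attr(trials, "source")
  class(kept) <- class(trials)
  attr(report, "overall_fraction_removed") <- 1 - nrow(kept) / nrow(trials)
  list(kept = kept, report = report)
}
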