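#' Stimulus design for the 3x3 double-factorial categorization task
#'
#' Builds the 3x3 stimulus grid used throughout: two dimensions (lip height,
#' coded `x`, and eye separation, coded `y`) each with three ordered levels
#' 0, 1, 2, and a conjunctive target rule: a stimulus belongs to the target
#' category iff `x >= 1 AND y >= 1`. That gives 4 target members and 5
#' contrast members. Each level carries a psychological coordinate
#' (typically taken from an MDS solution); coordinates must be strictly
#' increasing within a dimension.
#'
#' @param x_coords,y_coords numeric(3), strictly increasing psychological
#'   positions of levels 0..2 on each dimension (arbitrary units).
#' @return An object of class `"stimulus_design"`: a list with `x_coords`,
#'   `y_coords`, and a `stimuli` data frame (one row per cell) holding
#'   `x_level`, `y_level`, `role`, `category`, `mu_x`, `mu_y`.
#' @examples
#' d <- stimulus_design()
#' subset(d$stimuli, category == "target")
#' @export
stimulus_design <- function(x_coords = c(0, 1, 2), y_coords = c(0, 1, 2)) {
  stopifnot(length(x_coords) == 3, length(y_coords) == 3)
  if (any(diff(x_coords) <= 0) || any(diff(y_coords) <= 0))
    stop("coordinates must be strictly increasing within each dimension")
  grid <- expand.grid(x_level = 0:2, y_level = 0:2)
  grid$role <- vapply(seq_len(9),
                      function(i) assign_role(grid$x_level[i], grid$y_level[i]),
                      character(1))
  grid$category <- ifelse(grid$x_level >= 1 & grid$y_level >= 1,
                          "target", "contrast")
  grid$mu_x <- x_coords[grid$x_level + 1]
  grid$mu_y <- y_coords[grid$y_level + 1]
  structure(list(x_coords = x_coords, y_coords = y_coords, stimuli = grid),
            class = "stimulus_design")
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat("3x3 conjunctive-rule stimulus design\n")
  cat("  x (lip height) coordinates: ", paste(x$x_coords, collapse = ", "), "\n")
  cat("  y (eye separation) coordinates:", paste(x$y_coords, collapse = ", "), "\n")
  cat("  target = {x1,x2} x {y1,y2}; roles:\n")
  m <- matrix(x$stimuli$role, 3, 3, dimnames = list(paste0("x", 0:2), paste0("y", 0:2)))
  print(m)
  invisible(x)
}

# role lookup, rows = x_level 0..2, cols = y_level 0..2
.role_map <- matrix(c("R",  "Iy", "Ey",
                      "Ix", "LL", "LH",
                      "Ex", "HL", "HH"),
                    nrow = 3, byrow = TRUE)

#' Map a stimulus cell to its design role
#'
#' The 9 cells of the grid play distinct roles in the analyses. The four
#' target members are labelled by their discriminability relative to the
#' decision bounds: `LL` = x1y1, `LH` = x1y2, `HL` = x2y1, `HH` = x2y2.
#' The five contrast members are the redundant stimulus `R` = x0y0, the
#' interior stimuli `Ix` = x1y0 and `Iy` = x0y1 (adjacent to the bounds),
#' and the exterior stimuli `Ex` = x2y0 and `Ey` = x0y2.
#'
#' @param x_level,y_level integer level codes in 0..2.
#' @return A single role string.
#' @examples
#' assign_role(2, 2)  # "HH"
#' assign_role(0, 0)  # "R"
#' @export
assign_role <- function(x_level, y_level) {
  if (length(x_level) != 1L || length(y_level) != 1L ||
      !x_level %in% 0:2 || !y_level %in% 0:2)
    stop("x_level and y_level must each be a single integer in 0..2")
  .role_map[x_level + 1L, y_level + 1L]
}

#' @rdname assign_role
#' @details `role_table()` returns the full bijection as a data frame.
#' @export
role_table <- function() {
  g <- expand.grid(x_level = 0:2, y_level = 0:2)
  g$role <- mapply(assign_role, g$x_level, g$y_level)
  g
}

# TRUE if the cell is in the target category under the conjunctive rule
is_target_cell <- function(x_level, y_level) x_level >= 1 & y_level >= 1
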