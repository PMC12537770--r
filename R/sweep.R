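#' Specification of an interaction-coefficient sweep
#'
#' Defines the grid for a two-coefficient phase diagram: the two axis
#' coefficients range over `[lo, hi]` in steps of `step` (endpoints
#' inclusive: the default 0..3 by 0.01 gives 301 points per axis), all other
#' coefficients are held at `fixed_alpha` (0.01, i.e. effectively
#' non-interacting), and each grid cell is a 24-h batch of the
#' frequency-dependent model classified against the extinction threshold.
#'
#' @param axis_x,axis_y names of two distinct coefficients from
#'   `alpha_EY, alpha_EB, alpha_YB, alpha_YE, alpha_BY, alpha_BE`.
#' @param lo,hi,step grid range and resolution (`lo < hi`, `step > 0`).
#' @param fixed_alpha value of all non-axis coefficients.
#' @param community an [lv_community()] supplying `r`, `K`, `N0` and the
#'   derivative field; its alphas are overridden per grid cell.
#' @param t_end batch duration classified, hours.
#' @param extinction_threshold cells/mL (see [classify_simulation()]).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(axis_x = "alpha_BE", axis_y = "alpha_YB",
                       lo = 0, hi = 3, step = 0.01, fixed_alpha = 0.01,
                       community = default_community(), t_end = 24,
                       extinction_threshold = 1e4,
                       rtol = 1e-8, atol = 1e-3) {
  axis_x <- match.arg(axis_x, .alpha_names)
  axis_y <- match.arg(axis_y, .alpha_names)
  if (axis_x == axis_y) stop("axis_x and axis_y must differ")
  stopifnot(lo < hi, step > 0)
  structure(list(axis_x = axis_x, axis_y = axis_y, lo = lo, hi = hi,
                 step = step, fixed_alpha = fixed_alpha,
                 community = community, t_end = t_end,
                 extinction_threshold = extinction_threshold,
                 rtol = rtol, atol = atol),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  n <- length(seq(x$lo, x$hi, by = x$step))
  cat(sprintf("Sweep of %s (x) vs %s (y): %g..%g by %g (%d x %d cells), others at %g\n",
              x$axis_x, x$axis_y, x$lo, x$hi, x$step, n, n, x$fixed_alpha))
  invisible(x)
}

# classify one grid cell; pure function of (ax, ay, spec)
.sweep_cell <- function(ax, ay, spec) {
  a <- rep(spec$fixed_alpha, 6L)
  names(a) <- .alpha_names
  a[spec$axis_x] <- ax
  a[spec$axis_y] <- ay
  comm <- spec$community
  comm$alphas <- do.call(interaction_matrix, as.list(a))
  traj <- integrate_batch(comm, t_end = spec$t_end, grid = c(0, spec$t_end),
                          rtol = spec$rtol, atol = spec$atol)
  classify_simulation(final_state(traj), spec$extinction_threshold)$category
}

#' Run an interaction-coefficient sweep
#'
#' Classifies every grid cell of the spec; deterministic given the spec, and
#' purely per-cell (results do not depend on evaluation order).
#'
#' @param spec a [sweep_spec()].
#' @return an object of class `sweep_grid`: the spec, the axis values, and a
#'   character matrix `cells` of outcome categories with rows indexed by the
#'   y-axis value and columns by the x-axis value.
#' @export
#' @examples
#' g <- run_sweep(sweep_spec(lo = 0, hi = 0.02, step = 0.02))
#' as.data.frame(g)
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  xs <- seq(spec$lo, spec$hi, by = spec$step)
  ys <- seq(spec$lo, spec$hi, by = spec$step)
  cells <- matrix(NA_character_, nrow = length(ys), ncol = length(xs),
                  dimnames = list(format(ys, trim = TRUE),
                                  format(xs, trim = TRUE)))
  for (j in seq_along(xs)) {
    for (i in seq_along(ys)) {
      cells[i, j] <- tryCatch(
        .sweep_cell(xs[j], ys[i], spec),
        error = function(e) stop(sprintf(
          "sweep failed at (%s = %g, %s = %g): %s",
          spec$axis_x, xs[j], spec$axis_y, ys[i], conditionMessage(e)),
          call. = FALSE))
    }
  }
  structure(list(spec = spec, alpha_x = xs, alpha_y = ys, cells = cells),
            class = "sweep_grid")
}

#' Classify a single slice along one axis
#'
#' Convenience wrapper used for boundary location: varies one coefficient
#' over the spec's grid while the spec's other axis is pinned at `at`.
#'
#' @param spec a [sweep_spec()]; `spec$axis_x` is the swept coefficient.
#' @param at value of `spec$axis_y` on the slice.
#' @return data frame with columns `alpha` (the swept values) and
#'   `category`.
#' @export
run_slice <- function(spec, at = spec$fixed_alpha) {
  xs <- seq(spec$lo, spec$hi, by = spec$step)
  data.frame(alpha = xs,
             category = vapply(xs, .sweep_cell, character(1), ay = at,
                               spec = spec),
             stringsAsFactors = FALSE)
}

#' @export
print.sweep_grid <- function(x, ...) {
  print(x$spec)
  tab <- table(x$cells)
  cat("  outcomes:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.sweep_grid <- function(x, ...) {
  data.frame(alpha_x = rep(x$alpha_x, each = length(x$alpha_y)),
             alpha_y = rep(x$alpha_y, times = length(x$alpha_x)),
             category = as.vector(x$cells),
             stringsAsFactors = FALSE)
}

#' Locate an outcome boundary along a grid slice
#'
#' Scans the requested slice in increasing axis order and returns the
#' smallest axis value labelled `to_label` that immediately follows a run of
#' `from_label`, at the grid's resolution.
#'
#' @param grid a [run_sweep()] result.
#' @param along `"x"` or `"y"`: which axis to scan.
#' @param at value of the other axis identifying the slice (matched to the
#'   nearest grid line).
#' @param from_label,to_label outcome categories on either side of the
#'   boundary.
#' @return the axis value (coefficient) of the first transition.
#' @export
find_boundary <- function(grid, along = c("x", "y"), at,
                          from_label, to_label) {
  along <- match.arg(along)
  if (along == "x") {
    idx <- which.min(abs(grid$alpha_y - at))
    labels <- grid$cells[idx, ]
    axis_vals <- grid$alpha_x
  } else {
    idx <- which.min(abs(grid$alpha_x - at))
    labels <- grid$cells[, idx]
    axis_vals <- grid$alpha_y
  }
  .boundary_in_slice(axis_vals, labels, from_label, to_label)
}

.boundary_in_slice <- function(axis_vals, labels, from_label, to_label) {
  if (length(unique(labels)) == 1L) stop("no transition: slice is uniform")
  prev_from <- c(FALSE, head(labels, -1) == from_label)
  hit <- which(labels == to_label & prev_from)
  if (length(hit) == 0L)
    stop(sprintf("no transition from '%s' to '%s' on this slice",
                 from_label, to_label))
  axis_vals[hit[1]]
}

#' Export a phase diagram as CSV (and optionally a heatmap image)
#'
#' The CSV holds one row per grid cell (`alpha_x`, `alpha_y`, `category`);
#' the optional PNG renders the categorical heatmap with the standard
#' colour convention ([outcome_colors()]).
#'
#' @param grid a [run_sweep()] result.
#' @param csv_path output CSV path.
#' @param image_path optional PNG path.
#' @return the CSV path, invisibly.
#' @export
export_phase_diagram <- function(grid, csv_path, image_path = NULL) {
  df <- as.data.frame(grid)
  write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(image_path)) {
    png(image_path, width = 900, height = 800)
    on.exit(dev.off(), add = TRUE)
    plot(grid)
  }
  invisible(csv_path)
}

#' Read back a phase-diagram CSV
#'
#' @param path CSV written by [export_phase_diagram()].
#' @return data frame `alpha_x`, `alpha_y`, `category`.
#' @export
read_phase_diagram_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("alpha_x", "alpha_y", "category"), names(df))
  if (length(missing))
    stop("phase-diagram CSV missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Plot a phase diagram
#'
#' @param x a `sweep_grid`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_grid <- function(x, ...) {
  cols <- outcome_colors()
  lev <- names(cols)
  z <- matrix(match(x$cells, lev), nrow = nrow(x$cells))
  # image() wants z[x, y]; cells is [y, x]
  image(x$alpha_x, x$alpha_y, t(z), col = cols, zlim = c(0.5, 5.5),
        breaks = seq(0.5, 5.5, by = 1),
        xlab = x$spec$axis_x, ylab = x$spec$axis_y, useRaster = TRUE, ...)
  present <- lev[lev %in% x$cells]
  legend("topright", legend = present, fill = cols[present], bg = "white")
  invisible(x)
}
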