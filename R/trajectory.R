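#' Preprocess a raw cursor trajectory
#'
#' Standard cleanup before destination-vector analysis:
#' \enumerate{
#'   \item recentre all samples on the first recorded position, so the
#'     scale centre is the origin;
#'   \item detect movement onset as the first sample more than
#'     `onset_px` pixels (default 5) from the start in any direction and
#'     drop earlier samples;
#'   \item normalize time from onset to the final click onto 0-100% —
#'     by recorded timestamps when a `t_ms` column is present, by sample
#'     index otherwise — and linearly resample the path at the 21 points
#'     0%, 5%, ..., 100%.
#' }
#' A trajectory that never leaves the `onset_px` radius carries no
#' movement; it is returned with attribute `no_movement = TRUE` and `NA`
#' coordinates so downstream steps can exclude it.
#'
#' @param traj Data frame with columns `x`, `y` (pixels) and optionally
#'   `t_ms`, ordered in time; at least 2 samples.
#' @param onset_px Movement-onset radius in pixels.
#' @param n_out Number of resampled time points (21 gives 20 destination
#'   vectors).
#' @return Data frame with columns `time` (0..1) and `x`, `y`, of
#'   `n_out` rows; attribute `no_movement` is `TRUE` when onset was never
#'   reached.
#' @export
preprocess_trajectory <- function(traj, onset_px = 5, n_out = 21L) {
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)),
            nrow(traj) >= 2L)
  x <- traj$x - traj$x[1]
  y <- traj$y - traj$y[1]
  r <- sqrt(x^2 + y^2)
  onset <- which(r > onset_px)[1]
  tt <- seq(0, 1, length.out = n_out)
  if (is.na(onset)) {
    out <- data.frame(time = tt, x = NA_real_, y = NA_real_)
    attr(out, "no_movement") <- TRUE
    return(out)
  }
  keep <- seq.int(onset, length(x))
  x <- x[keep]; y <- y[keep]
  if ("t_ms" %in% names(traj)) {
    tm <- traj$t_ms[keep]
    u <- (tm - tm[1]) / (tm[length(tm)] - tm[1])
  } else {
    u <- seq(0, 1, length.out = length(keep))
  }
  if (length(keep) == 1L) {
    out <- data.frame(time = tt, x = rep(x, n_out), y = rep(y, n_out))
  } else {
    out <- data.frame(time = tt,
                      x = approx(u, x, xout = tt, ties = "ordered")$y,
                      y = approx(u, y, xout = tt, ties = "ordered")$y)
  }
  attr(out, "no_movement") <- FALSE
  out
}

# Forward intersection of the ray from p1 through p2 with the circle of
# radius R about the origin; NA when the ray never reaches the right
# half-plane arc.
ray_arc_conf <- function(p1, p2, scale_radius) {
  d <- p2 - p1
  a <- sum(d^2)
  if (a == 0) return(NA_real_)
  b <- sum(p1 * d)
  cc <- sum(p1^2) - scale_radius^2
  disc <- b^2 - a * cc
  if (disc < 0) return(NA_real_)
  s <- (-b + sqrt(disc)) / a        # forward-most root
  if (s < 0) return(NA_real_)
  q <- p1 + s * d
  if (q[1] < 0) return(NA_real_)    # left half-plane: off the scale
  theta <- atan2(q[1], q[2]) * 180 / pi   # clockwise from straight-up
  angle_to_conf(theta)
}

#' Destination vectors of a preprocessed trajectory
#'
#' For each of the 20 consecutive sample pairs of a 21-point resampled
#' trajectory, casts a ray from the earlier through the later sample and
#' intersects it with the confidence arc (circle of `scale_radius` about
#' the origin, right half-plane); the intersection angle is converted to
#' a continuous confidence value (see [angle_to_conf()]). This captures
#' where on the scale the cursor is heading at each moment, rather than
#' where it currently is. Zero-length steps inherit the previous step's
#' destination; rays that never meet the right-half arc give `NA`.
#'
#' @param traj Output of [preprocess_trajectory()] (21 rows).
#' @param scale_radius Arc radius in pixels.
#' @return Numeric vector of 20 destination confidences in `[0.5, 90.5]`
#'   (possibly `NA`), or all-`NA` for a no-movement trajectory.
#' @export
destination_vectors <- function(traj, scale_radius = 860) {
  stopifnot(is.data.frame(traj), all(c("x", "y") %in% names(traj)))
  n <- nrow(traj)
  if (isTRUE(attr(traj, "no_movement")) || anyNA(traj$x))
    return(rep(NA_real_, n - 1L))
  dest <- numeric(n - 1L)
  prev <- NA_real_
  for (t in 2:n) {
    p1 <- c(traj$x[t - 1], traj$y[t - 1])
    p2 <- c(traj$x[t], traj$y[t])
    if (all(p1 == p2)) {
      dest[t - 1L] <- prev            # carried forward
    } else {
      dest[t - 1L] <- ray_arc_conf(p1, p2, scale_radius)
    }
    if (!is.na(dest[t - 1L])) prev <- dest[t - 1L]
  }
  dest
}

#' Destination fields for a whole trajectory table
#'
#' Runs [preprocess_trajectory()] and [destination_vectors()] per trial.
#'
#' @param traj_table Long-format samples (see [read_trajectories()]).
#' @param scale_radius Arc radius in pixels.
#' @param onset_px Movement-onset radius.
#' @return Data frame `trial_id, step (1..20), time (0.05..1), conf`.
#' @export
destination_fields <- function(traj_table, scale_radius = 860,
                               onset_px = 5) {
  stopifnot(is.data.frame(traj_table),
            all(c("trial_id", "sample_index", "x", "y") %in%
                  names(traj_table)))
  pieces <- split(traj_table, traj_table$trial_id)
  out <- lapply(names(pieces), function(id) {
    p <- pieces[[id]][order(pieces[[id]]$sample_index), , drop = FALSE]
    dv <- destination_vectors(preprocess_trajectory(p, onset_px),
                              scale_radius)
    data.frame(trial_id = id, step = seq_along(dv),
               time = seq_along(dv) / length(dv), conf = dv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time-by-confidence destination distribution of one condition cell
#'
#' At each of the 20 normalized time steps, histograms the destination
#' confidences of all trials in the cell over `n_conf_bins` equal-width
#' bins spanning the full scale, and normalizes each time row to sum
#' to 1 (missing destinations are excluded from that row's
#' normalization).
#'
#' @param fields Destination fields (see [destination_fields()]),
#'   already subset to the trials of one group/pathology/condition cell.
#' @param n_conf_bins Number of confidence bins (default 18 bins of 5
#'   points).
#' @return A 20 x `n_conf_bins` matrix of probabilities; rows are time
#'   steps 5%..100%.
#' @export
aggregate_distributions <- function(fields, n_conf_bins = 18L) {
  stopifnot(is.data.frame(fields),
            all(c("step", "conf") %in% names(fields)), n_conf_bins >= 2L)
  if (nrow(fields) == 0L) stop("empty destination-field cell", call. = FALSE)
  n_steps <- max(fields$step)
  edges <- seq(0.5, 90.5, length.out = n_conf_bins + 1L)
  m <- matrix(0, n_steps, n_conf_bins)
  for (s in seq_len(n_steps)) {
    v <- fields$conf[fields$step == s]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                n_conf_bins)
    h <- tabulate(idx, nbins = n_conf_bins)
    m[s, ] <- h / sum(h)
  }
  dimnames(m) <- list(time = sprintf("%d%%", round(100 * seq_len(n_steps) /
                                                     n_steps)),
                      conf = sprintf("%g-%g", head(edges, -1) + 0.5,
                                     tail(edges, -1) + 0.5))
  m
}

#' Group destination fields into the 8 design cells
#'
#' Joins destination fields to their trials' design labels and computes
#' one aggregated time-by-confidence matrix per
#' group x pathology x condition cell.
#'
#' @param fields Destination fields (see [destination_fields()]).
#' @param trials Trial table with `trajectory_id` linking to
#'   `fields$trial_id`.
#' @param n_conf_bins Confidence bins per matrix.
#' @return Named list of matrices, names `group.pathology.condition`.
#' @export
cell_distributions <- function(fields, trials, n_conf_bins = 18L) {
  trials <- validate_trials(trials)
  stopifnot("trajectory_id" %in% names(trials))
  lab <- trials[match(fields$trial_id, trials$trajectory_id),
                c("group", "pathology", "condition")]
  key <- interaction(lab, drop = TRUE, sep = ".")
  lapply(split(fields, key), aggregate_distributions,
         n_conf_bins = n_conf_bins)
}

#' Three-way interaction map of destination distributions
#'
#' Computes the cellwise triple difference
#' (experienced - inexperienced) x (abnormal - normal) x
#' (long_second - short_first) over the 8 aggregated time-by-confidence
#' matrices, standardizes it jointly over all cells
#' (`z = (grid - mean) / sd`), and marks cells where `|z|` exceeds the
#' threshold (default 1.96). Positive regions on the abnormal side of
#' the scale read as an expertise gain in hits over false alarms that
#' grows with exposure duration; negative regions on the normal side as
#' improved rejections.
#'
#' @param cell_matrices Named list of 8 equal-shape matrices with names
#'   `group.pathology.condition` (see [cell_distributions()]).
#' @param threshold Absolute z cutoff for the contour mask.
#' @param levels Named list giving the two levels of each factor in
#'   (positive, negative) order; defaults match the task design.
#' @return A list of class `"interaction_map"` with elements `grid`,
#'   `z_grid`, `contour_mask`, `threshold`.
#' @export
interaction_map <- function(cell_matrices, threshold = 1.96,
                            levels = list(
                              group = c("experienced", "inexperienced"),
                              pathology = c("abnormal", "normal"),
                              condition = c("long_second", "short_first"))) {
  stopifnot(is.list(cell_matrices))
  combos <- expand.grid(group = levels$group, pathology = levels$pathology,
                        condition = levels$condition,
                        stringsAsFactors = FALSE)
  need <- with(combos, paste(group, pathology, condition, sep = "."))
  miss <- setdiff(need, names(cell_matrices))
  if (length(miss))
    stop("missing cell matrix/matrices: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dims <- lapply(cell_matrices[need], dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("cell matrices differ in shape", call. = FALSE)
  grid <- 0
  for (i in seq_len(nrow(combos))) {
    sgn <- prod(ifelse(unlist(combos[i, ]) ==
                         vapply(levels, `[`, character(1), 1L), 1, -1))
    grid <- grid + sgn * cell_matrices[[need[i]]]
  }
  s <- sd(grid)
  z <- if (s > 0) (grid - mean(grid)) / s else grid * 0
  structure(list(grid = grid, z_grid = z,
                 contour_mask = abs(z) > threshold, threshold = threshold),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("Three-way interaction map:", nrow(x$grid), "time steps x",
      ncol(x$grid), "confidence bins\n")
  cat("  |z| >", x$threshold, "in", sum(x$contour_mask), "cells\n")
  invisible(x)
}

#' Plot an interaction map as a heat map
#'
#' Heat map of the z-scored three-way interaction over normalized time
#' (y) and confidence (x), with contour outlines at the +/- threshold.
#'
#' @param map An [interaction_map()].
#' @return A ggplot object.
#' @export
plot_interaction_map <- function(map) {
  df <- expand.grid(time = seq_len(nrow(map$z_grid)),
                    conf = seq_len(ncol(map$z_grid)))
  df$z <- as.vector(map$z_grid)
  ggplot2::ggplot(df, ggplot2::aes(x = conf, y = time)) +
    ggplot2::geom_tile(ggplot2::aes(fill = z)) +
    ggplot2::geom_contour(ggplot2::aes(z = z),
                          breaks = c(-map$threshold, map$threshold),
                          colour = "black", linetype = "dotted") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "yellow") +
    ggplot2::labs(x = "confidence bin", y = "normalized time step",
                  fill = "z")
}
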