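#' Confidence-scale geometry
#'
#' The response scale is a half-circle arc of radius `scale_radius` pixels
#' (860 px in the reference task geometry) in the right half-plane,
#' centred on the cursor start. Angles are measured in degrees clockwise
#' from straight-up: 0 deg is the edge of the scale before point 1, 180
#' deg the edge after point 90, and confidence point `p` occupies the arc
#' segment `(2(p-1), 2p]` deg with its centre at `2p - 1` deg. The
#' continuous confidence value of an arc angle `theta` is therefore
#' `theta / 2 + 0.5`, so the straight-right direction (90 deg) maps to
#' 45.5, the normal/abnormal boundary.
#'
#' @param p Confidence point(s) in `[1, 90]` (real-valued allowed).
#' @param theta Arc angle(s) in degrees in `[0, 180]`.
#' @param scale_radius Arc radius in pixels.
#' @return `conf_to_angle()`: degrees; `angle_to_conf()`: confidence
#'   points; `scale_position()`: a matrix with columns `x`, `y` (pixels,
#'   origin at the scale centre, `y` up).
#' @name scale-geometry
NULL

#' @rdname scale-geometry
#' @export
conf_to_angle <- function(p) 2 * p - 1

#' @rdname scale-geometry
#' @export
angle_to_conf <- function(theta) theta / 2 + 0.5

#' @rdname scale-geometry
#' @export
scale_position <- function(p, scale_radius = 860) {
  th <- conf_to_angle(p) * pi / 180
  cbind(x = scale_radius * sin(th), y = scale_radius * cos(th))
}

# Deterministic per-stream seed derivation: mixes a master seed with a
# stream index so that adding streams never perturbs earlier ones.
# Kept below 2^31 - 1 to stay a valid R integer seed.
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream) * 16807) %%
               2147483647)
}

#' Simulation design for DTSD rating data
#'
#' Describes a synthetic study: how many subjects, how many signal
#' (abnormal) and noise (normal) trials per subject per cell, the true
#' DTSD parameter values of every group-by-condition cell, and the
#' between-subject variability. Subject heterogeneity is injected on link
#' scales — identity for d', probit for HT — so subject-level HT values
#' always stay inside `[0, 1)` without truncation.
#'
#' @param n_subjects Subjects per group.
#' @param n_signal_trials,n_noise_trials Trials per subject per cell.
#' @param cell_params Data frame with columns `group`, `condition`,
#'   `d_prime`, `ht`: the true population parameters of every cell. All
#'   conditions are within-subject; groups are between-subject.
#' @param criteria Generating decision criteria, shared by all cells
#'   (default: normal quantiles giving equal expected noise-category
#'   occupancy over 20 bins).
#' @param subject_sd Named vector `c(d_prime = , ht = )` of between-
#'   subject standard deviations on the link scales. The default 0.2 is a
#'   small, realistic heterogeneity for trained observers.
#' @param n_bins,n_points Rating scale resolution (see [bin_ratings()]).
#' @param seed Master seed; fixed seed implies bit-identical output.
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_subjects, n_signal_trials, n_noise_trials,
                              cell_params,
                              criteria = qnorm(seq_len(19) / 20),
                              subject_sd = c(d_prime = 0.2, ht = 0.2),
                              n_bins = 20L, n_points = 90L, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_signal_trials >= 1L, n_noise_trials >= 1L,
            is.data.frame(cell_params),
            all(c("group", "condition", "d_prime", "ht") %in%
                  names(cell_params)),
            all(cell_params$ht >= 0 & cell_params$ht < 1),
            all(diff(criteria) > 0),
            all(subject_sd >= 0), length(criteria) == n_bins - 1L)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_signal_trials = as.integer(n_signal_trials),
                 n_noise_trials = as.integer(n_noise_trials),
                 cell_params = cell_params, criteria = criteria,
                 subject_sd = subject_sd, n_bins = as.integer(n_bins),
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "simulation_design")
}

# integer ratings belonging to bin j under the fixed-edge binning
ratings_in_bin <- function(j, n_bins, n_points) {
  lo <- floor(n_points * (j - 1) / n_bins) + 1L
  hi <- floor(n_points * j / n_bins)
  seq.int(lo, hi)
}

#' Simulate rating trials from the DTSD generative model
#'
#' For each subject, population parameters of every cell are perturbed by
#' that subject's link-scale random effects (shared across conditions, so
#' condition contrasts are genuinely within-subject), a response bin is
#' drawn from the DTSD multinomial [category_probabilities()], and the
#' integer 1-90 rating is drawn uniformly within the bin. Each subject
#' consumes an independent random substream derived from the master seed,
#' so enlarging the design leaves earlier subjects' data untouched.
#'
#' @param design A [simulation_design()].
#' @return A trial data frame in the schema of [validate_trials()], plus a
#'   `trajectory_id` column, with the per-subject true parameter draws in
#'   `attr(, "subject_params")`.
#' @export
simulate_ratings <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  cp <- design$cell_params
  groups <- unique(cp$group)
  out <- vector("list", design$n_subjects * length(groups))
  spar <- vector("list", length(out))
  i <- 0L
  for (g in groups) {
    for (s in seq_len(design$n_subjects)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", substr(g, 1, 3), s)
      set.seed(derive_seed(design$seed, i))
      e_d <- rnorm(1, 0, design$subject_sd[["d_prime"]])
      e_h <- rnorm(1, 0, design$subject_sd[["ht"]])
      rows <- cp[cp$group == g, , drop = FALSE]
      trials <- vector("list", nrow(rows))
      for (r in seq_len(nrow(rows))) {
        d_s <- rows$d_prime[r] + e_d
        ht_s <- pnorm(qnorm(rows$ht[r]) + e_h)
        pars <- dtsd_params(d_s, ht_s, design$criteria)
        draw <- function(n, is_signal) {
          bins <- sample.int(design$n_bins, n, replace = TRUE,
                             prob = category_probabilities(pars, is_signal))
          vapply(bins, function(j) {
            cand <- ratings_in_bin(j, design$n_bins, design$n_points)
            cand[sample.int(length(cand), 1L)]
          }, integer(1))
        }
        rs <- draw(design$n_signal_trials, TRUE)
        rn <- draw(design$n_noise_trials, FALSE)
        trials[[r]] <- data.frame(
          subject_id = sid, group = g, condition = rows$condition[r],
          pathology = rep(c("abnormal", "normal"),
                          c(length(rs), length(rn))),
          rating = c(rs, rn), stringsAsFactors = FALSE)
        spar[[i]] <- rbind(spar[[i]], data.frame(
          subject_id = sid, group = g, condition = rows$condition[r],
          d_prime = d_s, ht = ht_s, stringsAsFactors = FALSE))
      }
      out[[i]] <- do.call(rbind, trials)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$trajectory_id <- sprintf("traj_%05d", seq_len(nrow(res)))
  attr(res, "subject_params") <- do.call(rbind, spar)
  res
}

#' Trajectory simulation design
#'
#' Describes synthetic mouse trajectories on the arc scale. Each trial's
#' cursor starts at the scale centre and moves outward with linearly
#' growing radius; its heading points at the `early_target` confidence
#' point until `switch_time` (as a fraction of normalized movement time),
#' then turns toward `late_target` and is smoothly anchored so that the
#' final sample lands exactly on the arc at the trial's clicked rating.
#' Heading noise is drawn once per movement phase per trial (plus the
#' per-cell targets), emulating smooth human movements whose plans differ
#' across trials rather than jittering sample-by-sample.
#'
#' @param scale_radius Arc radius in pixels (default 860, the reference
#'   task geometry).
#' @param samples_per_trial Number of recorded cursor samples.
#' @param early_target,late_target Confidence points in `[1, 90]` the
#'   cursor heads toward before/after `switch_time`; either scalars or
#'   data frames with columns `group`, `condition`, `pathology`,
#'   `early_target`/`late_target` for cell-specific patterns.
#'   `late_target = NA` means "the trial's own rating".
#' @param heading_noise Angular sd of the per-phase heading error,
#'   degrees.
#' @param switch_time Fraction of movement time in `(0, 1)` at which the
#'   heading switches.
#' @param seed Master seed.
#' @return An object of class `"trajectory_design"`.
#' @export
trajectory_design <- function(scale_radius = 860, samples_per_trial = 101L,
                              early_target = 45.5, late_target = NA,
                              heading_noise = 4, switch_time = 0.5,
                              seed = 1L) {
  stopifnot(scale_radius > 0, samples_per_trial >= 3L,
            switch_time > 0, switch_time < 1, heading_noise >= 0)
  structure(list(scale_radius = scale_radius,
                 samples_per_trial = as.integer(samples_per_trial),
                 early_target = early_target, late_target = late_target,
                 heading_noise = heading_noise, switch_time = switch_time,
                 seed = as.integer(seed)),
            class = "trajectory_design")
}

lookup_target <- function(target, trial) {
  if (is.data.frame(target)) {
    hit <- rep(TRUE, nrow(target))
    for (col in intersect(c("group", "condition", "pathology"),
                          names(target)))
      hit <- hit & target[[col]] == trial[[col]]
    val_col <- setdiff(names(target), c("group", "condition", "pathology"))
    if (!any(hit))
      stop("no trajectory target for cell (", trial$group, ", ",
           trial$condition, ", ", trial$pathology, ")", call. = FALSE)
    return(target[[val_col[1]]][which(hit)[1]])
  }
  target
}

#' Simulate mouse trajectories for a set of rated trials
#'
#' One trajectory per trial row, in the long format
#' `(trial_id, sample_index, x, y)` used by the trajectory analysis. The
#' final sample always lies on the scale arc at the trial's rating
#' position (within floating-point error), so destination vectors of the
#' last step recover the clicked rating.
#'
#' @param design A [trajectory_design()].
#' @param trials A trial table with a `trajectory_id` column (e.g. from
#'   [simulate_ratings()]).
#' @return A long-format data frame of cursor samples.
#' @export
simulate_trajectories <- function(design, trials) {
  stopifnot(inherits(design, "trajectory_design"))
  trials <- validate_trials(trials)
  if (is.null(trials$trajectory_id))
    trials$trajectory_id <- sprintf("traj_%05d", seq_len(nrow(trials)))
  n <- design$samples_per_trial
  u <- seq(0, 1, length.out = n)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    set.seed(derive_seed(design$seed, i))
    early <- lookup_target(design$early_target, tr)
    late <- lookup_target(design$late_target, tr)
    if (is.na(early)) early <- tr$rating
    if (is.na(late)) late <- tr$rating
    a_rating <- conf_to_angle(tr$rating)
    a_early <- conf_to_angle(early) + rnorm(1, 0, design$heading_noise)
    a_late <- conf_to_angle(late) + rnorm(1, 0, design$heading_noise)
    th <- ifelse(u < design$switch_time, a_early,
                 a_late + (u - design$switch_time) /
                   (1 - design$switch_time) * (a_rating - a_late))
    th[n] <- a_rating                    # exact end anchor
    rad <- design$scale_radius * u
    out[[i]] <- data.frame(trial_id = tr$trajectory_id,
                           sample_index = seq_len(n),
                           x = rad * sin(th * pi / 180),
                           y = rad * cos(th * pi / 180),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a long-format trajectory table
#'
#' @param path CSV with columns `trial_id, sample_index, x, y` and
#'   optionally `t_ms`.
#' @return The validated data frame, ordered by trial and sample index.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("trial_id", "sample_index", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[order(df$trial_id, df$sample_index), , drop = FALSE]
}
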