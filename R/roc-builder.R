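#' Validate a trial-level rating table
#'
#' Checks the schema shared by all analysis entry points: one row per
#' response with `subject_id`, `group` (`"experienced"`/`"inexperienced"`),
#' `condition` (`"short_first"`/`"long_second"`), `pathology`
#' (`"normal"`/`"abnormal"`) and an integer confidence `rating` on the
#' 1-90 scale (1-45 are "normal" responses from sure to guess, 46-90
#' "abnormal" responses from guess to sure). An optional `trajectory_id`
#' column links each response to a recorded cursor trajectory.
#'
#' @param trials A data frame of rating trials.
#' @param n_points Number of points on the confidence scale (default 90).
#' @return `trials`, invisibly, with factors normalised to character.
#' @export
validate_trials <- function(trials, n_points = 90L) {
  stopifnot(is.data.frame(trials))
  req <- c("subject_id", "group", "condition", "pathology", "rating")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0L) stop("trial table is empty", call. = FALSE)
  for (col in c("group", "condition", "pathology"))
    trials[[col]] <- as.character(trials[[col]])
  bad_path <- which(!trials$pathology %in% c("normal", "abnormal"))
  if (length(bad_path))
    stop("row ", bad_path[1], ": pathology must be 'normal' or 'abnormal', got '",
         trials$pathology[bad_path[1]], "'", call. = FALSE)
  r <- trials$rating
  bad <- which(!is.finite(r) | r != round(r) | r < 1 | r > n_points)
  if (length(bad))
    stop("row ", bad[1], ": rating must be an integer in 1..", n_points,
         ", got ", r[bad[1]], call. = FALSE)
  invisible(trials)
}

#' Assign 1-90 confidence ratings to ordered bins
#'
#' Bins an integer rating scale of `n_points` points into `n_bins` ordered
#' categories with fixed edges at `n_points / n_bins`-point steps on the
#' continuous scale, so bin `j` covers `((j-1) * w, j * w]` with
#' `w = n_points / n_bins`. For the default 90-point scale and 20 bins the
#' step is 4.5, which keeps the normal/abnormal boundary between ratings
#' 45 and 46 exactly on a bin edge: rating 46 falls in the first bin of
#' the "abnormal" half.
#'
#' @param ratings Integer vector of ratings in `1..n_points`, or a trial
#'   data frame accepted by [validate_trials()].
#' @param n_bins Number of ordered bins (default 20).
#' @param n_points Number of scale points (default 90).
#' @return For a vector input, an integer vector of bin indices in
#'   `1..n_bins`. For a data frame, a list with integer count vectors
#'   `counts_noise` (normal trials) and `counts_signal` (abnormal trials),
#'   each of length `n_bins`.
#' @export
bin_ratings <- function(ratings, n_bins = 20L, n_points = 90L) {
  stopifnot(n_bins >= 2L, n_points >= n_bins)
  if (is.data.frame(ratings)) {
    trials <- validate_trials(ratings, n_points)
    idx <- bin_ratings(trials$rating, n_bins, n_points)
    tab <- function(keep) tabulate(idx[keep], nbins = n_bins)
    return(list(counts_noise = tab(trials$pathology == "normal"),
                counts_signal = tab(trials$pathology == "abnormal")))
  }
  r <- ratings
  bad <- which(!is.finite(r) | r != round(r) | r < 1 | r > n_points)
  if (length(bad))
    stop("rating #", bad[1], " out of range 1..", n_points, ": ", r[bad[1]],
         call. = FALSE)
  as.integer(ceiling(r * n_bins / n_points))
}

#' Empirical ROC curve from per-category counts
#'
#' Sweeps the confidence criterion from the "sure abnormal" end of the
#' scale: operating point `k` is the proportion of responses in the `k`
#' most-confident-abnormal categories, for `k = 1 .. K-1`, giving `K - 1`
#' points for `K` categories (19 points for the default 20 bins).
#' Abnormality is the signal class, so noise counts give false-positive
#' rates and signal counts give true-positive rates. Tied consecutive
#' points (empty categories) are retained so the point count is always
#' `K - 1`.
#'
#' @param counts_noise,counts_signal Equal-length nonnegative count
#'   vectors over the ordered categories (most-confident-normal first).
#' @return A [roc_curve()] with the counts attached.
#' @export
roc_from_counts <- function(counts_noise, counts_signal) {
  stopifnot(is.numeric(counts_noise), is.numeric(counts_signal),
            length(counts_noise) == length(counts_signal),
            length(counts_noise) >= 2L,
            all(counts_noise >= 0), all(counts_signal >= 0))
  nn <- sum(counts_noise); ns <- sum(counts_signal)
  if (nn == 0 || ns == 0)
    stop("each pathology class needs at least one trial (noise: ", nn,
         ", signal: ", ns, ")", call. = FALSE)
  K <- length(counts_noise)
  fpr <- cumsum(rev(counts_noise))[seq_len(K - 1)] / nn
  tpr <- cumsum(rev(counts_signal))[seq_len(K - 1)] / ns
  roc_curve(fpr, tpr, counts_noise = counts_noise,
            counts_signal = counts_signal)
}

#' Build per-cell empirical ROC curves from a trial table
#'
#' Splits the trial table by subject (and any further grouping columns)
#' and computes one binned empirical ROC per cell.
#'
#' @param trials A trial table (see [validate_trials()]).
#' @param by Character vector of grouping columns (default
#'   `"subject_id"`; add `"condition"` for per-condition curves).
#' @param n_bins,n_points Binning resolution, see [bin_ratings()].
#' @return A named list of [roc_curve()] objects, one per cell.
#' @export
build_rocs <- function(trials, by = "subject_id", n_bins = 20L,
                       n_points = 90L) {
  trials <- validate_trials(trials, n_points)
  stopifnot(all(by %in% names(trials)))
  key <- interaction(trials[by], drop = TRUE, sep = ".")
  lapply(split(trials, key), function(cell) {
    cnt <- bin_ratings(cell, n_bins, n_points)
    roc_from_counts(cnt$counts_noise, cnt$counts_signal)
  })
}

#' Read a trial table from CSV/TSV
#'
#' Strict reader for the trial schema of [validate_trials()]; malformed
#' rows are reported with their line number in the file.
#'
#' @param path Path to a comma- or tab-separated file with header
#'   `subject_id, group, condition, pathology, rating[, trajectory_id]`.
#' @param n_points Scale length for rating validation.
#' @return A validated trial data frame.
#' @export
read_trials <- function(path, n_points = 90L) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  out <- tryCatch(validate_trials(df, n_points), error = function(e) {
    m <- regmatches(conditionMessage(e),
                    regexec("^row ([0-9]+): (.*)$", conditionMessage(e)))[[1]]
    if (length(m) == 3L)
      stop(path, " line ", as.integer(m[2]) + 1L, ": ", m[3], call. = FALSE)
    stop(path, ": ", conditionMessage(e), call. = FALSE)
  })
  df
}

#' Write per-cell ROC curves as CSV
#'
#' One file per cell named `roc_<cell>.csv` with columns
#' `criterion_index, fpr, tpr`.
#'
#' @param rocs Named list of [roc_curve()] objects (see [build_rocs()]).
#' @param dir Output directory, created if needed.
#' @return The written file paths, invisibly.
#' @export
write_rocs_csv <- function(rocs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(rocs), function(nm) {
    p <- file.path(dir, paste0("roc_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv"))
    df <- data.frame(criterion_index = seq_len(nrow(rocs[[nm]])),
                     fpr = rocs[[nm]]$fpr, tpr = rocs[[nm]]$tpr)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
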