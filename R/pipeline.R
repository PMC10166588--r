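#' Default pipeline configuration
#'
#' A single nested list drives [run_pipeline()]; it can also be read
#' from a YAML or JSON file. Sections: `simulate` (the rating and
#' trajectory designs), `stages` (logical switches per stage), `fit`
#' (sampler profile and binning), and optional `inputs` naming existing
#' trial/trajectory CSVs to analyze instead of simulating.
#'
#' @param profile `"demo"` for a small, quick end-to-end run; `"full"`
#'   for study-scale settings.
#' @return A configuration list.
#' @export
pipeline_config <- function(profile = c("demo", "full")) {
  profile <- match.arg(profile)
  demo <- profile == "demo"
  list(
    profile = profile,
    stages = list(simulate = TRUE, roc = TRUE, condition_recovery = TRUE,
                  fixed_recovery = !demo, trajectories = TRUE),
    simulate = list(
      n_subjects = if (demo) 6L else 13L,
      n_signal_trials = 20L, n_noise_trials = 20L,
      subject_sd = c(d_prime = 0.2, ht = 0.2),
      trajectory = list(samples_per_trial = if (demo) 41L else 101L,
                        heading_noise = 4, switch_time = 0.5,
                        early_target = 45.5)),
    fit = list(profile = if (demo) "fast" else "recovery",
               n_bins = if (demo) 6L else 20L),
    inputs = list(trials = NULL, trajectories = NULL)
  )
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

stage_log <- function(con, name, t0, status, detail = "") {
  line <- sprintf("[%s] stage %-18s %-8s %6.1fs %s",
                  format(Sys.time(), "%H:%M:%S"), name, status,
                  as.numeric(Sys.time()) - t0, detail)
  message(line)
  writeLines(line, con)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes, as configured: data simulation (ratings + trajectories),
#' per-subject ROC construction, condition-effect recovery, the
#' fixed-parameter recovery grid, and the trajectory destination-vector
#' analysis with its three-way interaction map. Every figure written has
#' a CSV twin holding exactly the plotted numbers. A `manifest.json`
#' records the configuration, master seed, stage status and per-stage
#' wall-clock; a stage failure is recorded there and downstream stages
#' that need its output are skipped.
#'
#' @param config A configuration list from [pipeline_config()], or a
#'   path to a YAML/JSON file with the same structure.
#' @param seed Master seed for the whole run.
#' @param out Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config("demo"), seed = 1L,
                         out = "dtsd_out") {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out, "pipeline.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  manifest <- list(seed = seed, config = config,
                   package_version = as.character(
                     utils::packageVersion("dtsdroc")),
                   started = format(Sys.time()), stages = list())
  n_bins <- config$fit$n_bins %||% 20L
  trials <- traj <- NULL
  run_stage <- function(name, enabled, fun) {
    t0 <- as.numeric(Sys.time())
    if (!isTRUE(enabled)) {
      manifest$stages[[name]] <<- list(status = "skipped")
      stage_log(logcon, name, t0, "skipped")
      return(NULL)
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(res))
      stage_log(logcon, name, t0, "error", conditionMessage(res))
      return(NULL)
    }
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(as.numeric(Sys.time()) - t0, 2))
    stage_log(logcon, name, t0, "ok")
    res
  }

  sim <- run_stage("simulate", config$stages$simulate, function() {
    sc <- config$simulate
    des <- simulation_design(
      n_subjects = sc$n_subjects, n_signal_trials = sc$n_signal_trials,
      n_noise_trials = sc$n_noise_trials,
      cell_params = expand.grid(
        group = c("experienced", "inexperienced"),
        condition = c("short_first", "long_second"),
        stringsAsFactors = FALSE) |>
        transform(d_prime = c(0.5, 0.3, 0.6, 0.35),
                  ht = c(0.05, 0.05, 0.16, 0.06)),
      subject_sd = sc$subject_sd, n_bins = n_bins,
      criteria = qnorm(seq_len(n_bins - 1L) / n_bins),
      seed = derive_seed(seed, 1L))
    tr <- simulate_ratings(des)
    tc <- sc$trajectory
    tdes <- trajectory_design(
      samples_per_trial = tc$samples_per_trial,
      heading_noise = tc$heading_noise, switch_time = tc$switch_time,
      early_target = tc$early_target, seed = derive_seed(seed, 2L))
    tj <- simulate_trajectories(tdes, tr)
    utils::write.csv(tr, file.path(out, "trials.csv"), row.names = FALSE)
    utils::write.csv(tj, file.path(out, "trajectories.csv"),
                     row.names = FALSE)
    list(trials = tr, traj = tj)
  })
  if (!is.null(sim)) { trials <- sim$trials; traj <- sim$traj }
  if (!is.null(config$inputs$trials)) {
    if (!file.exists(config$inputs$trials))
      stop("configured trial file does not exist: ", config$inputs$trials,
           call. = FALSE)
    trials <- read_trials(config$inputs$trials)
  }
  if (!is.null(config$inputs$trajectories)) {
    if (!file.exists(config$inputs$trajectories))
      stop("configured trajectory file does not exist: ",
           config$inputs$trajectories, call. = FALSE)
    traj <- read_trajectories(config$inputs$trajectories)
  }

  run_stage("roc", config$stages$roc && !is.null(trials), function() {
    rocs <- build_rocs(trials, by = c("subject_id", "condition"),
                       n_bins = n_bins)
    write_rocs_csv(rocs, file.path(out, "roc"))
    auc <- data.frame(cell = names(rocs),
                      auc = vapply(rocs, auc_empirical, numeric(1)))
    utils::write.csv(auc, file.path(out, "auc.csv"), row.names = FALSE)
    auc
  })

  run_stage("condition_recovery", config$stages$condition_recovery,
            function() {
    rec <- run_condition_recovery(profile = config$fit$profile,
                                  seed = derive_seed(seed, 3L),
                                  n_bins = n_bins)
    utils::write.csv(rec$effects,
                     file.path(out, "condition_effects.csv"),
                     row.names = FALSE)
    ggplot2::ggsave(file.path(out, "condition_effects.pdf"),
                    plot_condition_recovery(rec), width = 7, height = 3.5)
    rec$effects
  })

  run_stage("fixed_recovery", config$stages$fixed_recovery, function() {
    fx <- run_fixed_recovery(profile = config$fit$profile,
                             seed = derive_seed(seed, 4L),
                             n_bins = n_bins)
    utils::write.csv(fx$cells, file.path(out, "fixed_recovery.csv"),
                     row.names = FALSE)
    utils::write.csv(fx$mle_subjects,
                     file.path(out, "fixed_recovery_mle_subjects.csv"),
                     row.names = FALSE)
    fx$cells
  })

  run_stage("trajectories",
            config$stages$trajectories && !is.null(traj) &&
              !is.null(trials), function() {
    fields <- destination_fields(traj)
    utils::write.csv(fields, file.path(out, "destination_fields.csv"),
                     row.names = FALSE)
    cells <- cell_distributions(fields, trials)
    map <- interaction_map(cells)
    utils::write.csv(map$z_grid, file.path(out, "interaction_z.csv"))
    ggplot2::ggsave(file.path(out, "interaction_map.pdf"),
                    plot_interaction_map(map), width = 6, height = 5)
    map
  })

  manifest$finished <- format(Sys.time())
  ok <- vapply(manifest$stages, function(s) s$status != "error",
               logical(1))
  manifest$ok <- all(ok)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
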