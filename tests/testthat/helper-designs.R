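# Shared small fixtures, generated in code.

# a compact one-group, one-condition design for fast simulation tests
small_design <- function(n_subjects = 3L, n_trials = 20L, d_prime = 1,
                         ht = 0.1, subject_sd = c(d_prime = 0.2, ht = 0.2),
                         n_bins = 20L, seed = 1L) {
  simulation_design(
    n_subjects = n_subjects, n_signal_trials = n_trials,
    n_noise_trials = n_trials,
    cell_params = data.frame(group = "experienced",
                             condition = "short_first",
                             d_prime = d_prime, ht = ht),
    subject_sd = subject_sd, n_bins = n_bins,
    criteria = qnorm(seq_len(n_bins - 1L) / n_bins), seed = seed)
}

# straight-line trajectory from the origin to confidence point p on the arc
straight_traj <- function(p, n = 21L, scale_radius = 860) {
  th <- conf_to_angle(p) * pi / 180
  u <- seq(0, 1, length.out = n)
  data.frame(x = scale_radius * u * sin(th),
             y = scale_radius * u * cos(th))
}
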