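# Shared fixtures: small, fast simulation settings and builders for
# synthetic recordings with exactly known content.

small_sim_config <- function(...) {
  defaults <- list(n_subjects = 3, sample_rate = 256,
                   check_n_reversals = 30, assr_n_trials = 3,
                   eoec_n_cycles = 4, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

noise_free_config <- function(...) {
  small_sim_config(pink_noise_sd = 0, white_noise_sd = 0,
                   drift_sd_dry = 0, drift_sd_gel = 0,
                   line_noise_amp = 0, blink_rate = 0,
                   p_bad_channel_dry = 0, p_bad_channel_gel = 0,
                   subject_amp_cv = 0, ...)
}

# recording with given channel rows (matrix or list of vectors)
make_test_recording <- function(rows, fs = 256, labels = NULL,
                                events = NULL, task = "CHECK",
                                system = "dry") {
  if (is.list(rows)) rows <- do.call(rbind, rows)
  if (is.null(labels)) labels <- shared_channels()[seq_len(nrow(rows))]
  new_recording(rows, fs, labels, events = events, system = system,
                task = task)
}

# independent brute-force GFP: explicit pairwise double sum
gfp_pairwise_oracle <- function(u) {
  n <- length(u)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + (u[i] - u[j])^2
  sqrt(acc / (2 * n^2))
}

# independent exhaustive sign-flip permutation oracle (direct formula
# transcription, no shared code with the implementation)
perm_oracle <- function(A, B, alpha = 0.05) {
  D <- A - B
  n <- nrow(D); P <- ncol(D)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_maps <- matrix(0, nrow(signs), P)
  for (it in seq_len(nrow(signs))) {
    Ds <- D * signs[it, ]
    for (p in seq_len(P)) {
      t_maps[it, p] <- mean(Ds[, p]) / (sd(Ds[, p]) / sqrt(n))
    }
  }
  h0_mean <- colMeans(t_maps)
  h0_sd <- apply(t_maps, 2, sd)
  z_maps <- t((t(t_maps) - h0_mean) / h0_sd)
  mins <- apply(z_maps, 1, min)
  maxs <- apply(z_maps, 1, max)
  t_obs <- vapply(seq_len(P), function(p) mean(D[, p]) / (sd(D[, p]) / sqrt(n)), 0)
  z_obs <- (t_obs - h0_mean) / h0_sd
  list(lower = unname(quantile(mins, alpha / 2)),
       upper = unname(quantile(maxs, 1 - alpha / 2)),
       z_obs = z_obs)
}
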