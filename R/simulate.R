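# Paired-session simulator: dry and gel recordings for the same subjects,
# with known evoked components, oscillatory effects, structured noise and
# deliberately corrupted channels, so every downstream stage of the
# analysis can be checked against ground truth.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the analysis targets: 15
#' subjects at 1024 Hz; a checkerboard task of 300 reversals every 0.45 s
#' (VEP, occipital); an ASSR task of 75 twelve-second 40 Hz
#' amplitude-modulated trials with a 2-3 s jittered intertrial interval
#' (AEP fronto-central in the first second, 40 Hz steady-state response
#' throughout); an eyes-open/eyes-closed task of 30 EO (5 s) / EC (3 s)
#' alternations with occipito-parietal alpha whose power is multiplied by
#' `alpha_ec_gain` while the eyes are closed. Noise is pink (1/f)
#' background plus white sensor noise, a band-limited (<1 Hz) drift that
#' is stronger for the dry cap, 50 Hz line noise, and Poisson-process
#' blinks with a frontal topography. Dry recordings additionally carry
#' `effect_scale_dry_delta`-fold low-frequency (<4 Hz) power.
#'
#' Evoked amplitudes are expressed at the spatial peak of a fixed Gaussian
#' scalp field; their defaults are calibrated so that epoch-averaged
#' global field power peaks fall in the 8-13 microvolt range typical of
#' pattern-reversal VEPs and auditory N1/P1 components.
#'
#' @param n_subjects number of subjects (paired sessions).
#' @param sample_rate sampling frequency, Hz.
#' @param vep_amplitude named numeric, `N75` and `P100` peak amplitudes
#'   (microvolts, at the occipital field center; signs applied internally).
#' @param vep_latency named numeric, component latencies in seconds.
#' @param aep_amplitude,aep_latency same for the auditory `N1`/`P1`.
#' @param assr_amplitude amplitude of the 40 Hz steady-state component
#'   (microvolts at the fronto-central field center).
#' @param alpha_sd standard deviation of the alpha-band (8-13 Hz) process
#'   at its occipito-parietal field center, microvolts.
#' @param alpha_ec_gain multiplier of alpha *power* during eyes-closed
#'   segments.
#' @param pink_noise_sd standard deviation of the pink background noise
#'   per channel, microvolts.
#' @param white_noise_sd standard deviation of white sensor noise,
#'   microvolts.
#' @param drift_sd_dry,drift_sd_gel standard deviation of the sub-1 Hz
#'   drift per channel, microvolts (dry > gel).
#' @param line_noise_amp amplitude of the 50 Hz line component,
#'   microvolts.
#' @param blink_rate blink events per minute.
#' @param blink_amplitude blink peak amplitude at the frontal field
#'   center, microvolts.
#' @param p_bad_channel_dry,p_bad_channel_gel per-channel probability of
#'   deliberate corruption (flat, high-amplitude, or drift).
#' @param effect_scale_dry_delta multiplier of dry-cap power below 4 Hz.
#' @param subject_amp_cv coefficient of variation of the subject-level
#'   latent amplitude scales (shared between the dry and gel session of a
#'   subject, which makes between-system agreement high by construction).
#' @param check_n_reversals,check_interval checkerboard reversal count and
#'   spacing (s).
#' @param assr_n_trials,assr_trial_dur,assr_iti ASSR trial count, trial
#'   duration (s) and intertrial-interval range (s).
#' @param eoec_n_cycles,eo_dur,ec_dur number of EO+EC alternations and
#'   segment durations (s); each cycle contributes one EO and one EC
#'   trial.
#' @param baseline_dur initial baseline before the first event, s.
#' @param seed master seed; every (subject, system, task) draws from an
#'   independent stream derived from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 15,
                       sample_rate = 1024,
                       vep_amplitude = c(N75 = 30, P100 = 40),
                       vep_latency = c(N75 = 0.121, P100 = 0.152),
                       aep_amplitude = c(N1 = 44, P1 = 48),
                       aep_latency = c(N1 = 0.313, P1 = 0.410),
                       assr_amplitude = 0.75,
                       alpha_sd = 3,
                       alpha_ec_gain = 2.5,
                       pink_noise_sd = 8,
                       white_noise_sd = 1,
                       drift_sd_dry = 20,
                       drift_sd_gel = 4,
                       line_noise_amp = 5,
                       blink_rate = 12,
                       blink_amplitude = 100,
                       p_bad_channel_dry = 0.10,
                       p_bad_channel_gel = 0.035,
                       effect_scale_dry_delta = 2,
                       subject_amp_cv = 0.25,
                       check_n_reversals = 300,
                       check_interval = 0.45,
                       assr_n_trials = 75,
                       assr_trial_dur = 12,
                       assr_iti = c(2, 3),
                       eoec_n_cycles = 30,
                       eo_dur = 5,
                       ec_dur = 3,
                       baseline_dur = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  nonneg <- c("vep_amplitude", "aep_amplitude", "assr_amplitude", "alpha_sd",
              "alpha_ec_gain", "pink_noise_sd", "white_noise_sd",
              "drift_sd_dry", "drift_sd_gel", "line_noise_amp", "blink_rate",
              "blink_amplitude", "effect_scale_dry_delta", "subject_amp_cv")
  for (f in nonneg) {
    if (any(cfg[[f]] < 0)) stop("sim_config: ", f, " must be >= 0")
  }
  for (f in c("p_bad_channel_dry", "p_bad_channel_gel")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("sim_config: ", f, " must be in [0, 1]")
  }
  if (cfg$n_subjects < 1) stop("sim_config: n_subjects must be >= 1")
  # highest synthesized frequency: 50 Hz line (or 40 Hz ASSR when line off)
  fmax <- if (cfg$line_noise_amp > 0) 50 else 40
  if (cfg$sample_rate <= 2 * fmax) {
    stop("sim_config: sample_rate must exceed twice the highest synthesized frequency")
  }
  stopifnot(all(c("N75", "P100") %in% names(cfg$vep_amplitude)),
            all(c("N1", "P1") %in% names(cfg$aep_amplitude)))
  invisible(cfg)
}

# Independent, reproducible stream per (subject, system, task).
.sim_seed <- function(seed, subject, system = "", task = "") {
  sys_code <- switch(system, dry = 1L, gel = 2L, 0L)
  task_code <- switch(task, CHECK = 1L, ASSR = 2L, EOEC = 3L, BAD = 7L, 0L)
  ((seed %% 100000) * 20011 + subject * 1009 + sys_code * 211 + task_code * 17) %%
    2147483587L
}

.gauss_field <- function(positions, center, width) {
  exp(-((positions$x - center[1])^2 + (positions$y - center[2])^2) /
        (2 * width^2))
}

# Fixed spatial patterns of the injected sources.
.sim_fields <- function(montage) {
  oz <- unlist(montage_positions("Oz")[, c("x", "y")])
  list(vep = .gauss_field(montage, oz, 0.45),
       aep = .gauss_field(montage, c(0, 0.2), 0.5),
       alpha = .gauss_field(montage, c(0, -0.55), 0.5),
       blink = .gauss_field(montage, c(0, 0.9), 0.4))
}

# 1/f noise via spectral shaping; dry sessions get `delta_scale`-fold
# power below 4 Hz.
.pink_noise <- function(n, fs, sd, delta_scale = 1) {
  if (sd <= 0) return(numeric(n))
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- 1 / sqrt(pmax(f, 0.5))
  amp[f < 4] <- amp[f < 4] * sqrt(delta_scale)
  re <- stats::rnorm(nf) * amp
  im <- stats::rnorm(nf) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * (sd / stats::sd(x))
}

# spectrally shaped noise: complex Gaussian bins with amplitude `amp(f)`
.shaped_noise <- function(n, fs, sd, amp_fun) {
  if (sd <= 0) return(numeric(n))
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- amp_fun(f)
  spec <- complex(real = stats::rnorm(nf) * amp,
                  imaginary = stats::rnorm(nf) * amp)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x * (sd / s)
}

# band-limited (<1 Hz) drift with a random-walk (1/f^2) spectrum
.drift_noise <- function(n, fs, sd) {
  .shaped_noise(n, fs, sd, function(f) (1 / pmax(f, 0.02)) / sqrt(1 + f^4))
}

# narrowband alpha: Gaussian spectral peak centered at 10 Hz
.alpha_process <- function(n, fs, sd) {
  .shaped_noise(n, fs, sd, function(f) exp(-(f - 10)^2 / (2 * 1.5^2)))
}

# Stereotyped blink: dominant positive lobe with a small undershoot,
# about 400 ms long.
.blink_template <- function(fs) {
  t <- seq(0, 0.45, by = 1 / fs)
  exp(-(t - 0.15)^2 / (2 * 0.05^2)) - 0.3 * exp(-(t - 0.3)^2 / (2 * 0.08^2))
}

.add_at <- function(x, onset_sample, template) {
  # add `template` into x starting at 0-based onset_sample, clipped
  i0 <- onset_sample + 1
  len <- min(length(template), length(x) - i0 + 1)
  if (len > 0) x[i0:(i0 + len - 1)] <- x[i0:(i0 + len - 1)] + template[1:len]
  x
}

.component_bump <- function(t, amplitude, latency, width, sign) {
  sign * amplitude * exp(-(t - latency)^2 / (2 * width^2))
}

.sim_task_layout <- function(cfg, task) {
  fs <- cfg$sample_rate
  b <- cfg$baseline_dur
  if (task == "CHECK") {
    onsets_s <- b + cfg$check_interval * (seq_len(cfg$check_n_reversals) - 1)
    labels <- rep("reversal", length(onsets_s))
    dur <- max(onsets_s) + 1 + 1
  } else if (task == "ASSR") {
    iti <- stats::runif(cfg$assr_n_trials, cfg$assr_iti[1], cfg$assr_iti[2])
    onsets_s <- b + cumsum(c(0, (cfg$assr_trial_dur + iti)[-cfg$assr_n_trials]))
    labels <- rep("tone", length(onsets_s))
    dur <- max(onsets_s) + cfg$assr_trial_dur + 2
  } else if (task == "EOEC") {
    cyc <- cfg$eo_dur + cfg$ec_dur
    eo <- b + cyc * (seq_len(cfg$eoec_n_cycles) - 1)
    ec <- eo + cfg$eo_dur
    onsets_s <- as.vector(rbind(eo, ec))
    labels <- rep(c("EO", "EC"), cfg$eoec_n_cycles)
    dur <- max(ec) + cfg$ec_dur + 2
  } else stop("unknown task: ", task)
  list(onsets = round(onsets_s * fs), labels = labels,
       n = ceiling(dur * fs))
}

.sim_evoked <- function(cfg, task, layout, fields, scales, n_ch, fs) {
  n <- layout$n
  evoked_t <- numeric(n)       # shared time course per spatial field
  out <- matrix(0, n_ch, n)
  if (task == "CHECK") {
    tt <- seq(0, 0.4, by = 1 / fs)
    tmpl <- .component_bump(tt, cfg$vep_amplitude["N75"], cfg$vep_latency["N75"], 0.012, -1) +
      .component_bump(tt, cfg$vep_amplitude["P100"], cfg$vep_latency["P100"], 0.015, +1)
    tmpl <- tmpl * scales$vep
    for (on in layout$onsets) evoked_t <- .add_at(evoked_t, on, tmpl)
    out <- out + fields$vep %o% evoked_t
  } else if (task == "ASSR") {
    tt <- seq(0, 0.7, by = 1 / fs)
    aep <- .component_bump(tt, cfg$aep_amplitude["N1"], cfg$aep_latency["N1"], 0.02, -1) +
      .component_bump(tt, cfg$aep_amplitude["P1"], cfg$aep_latency["P1"], 0.03, +1)
    aep <- aep * scales$aep
    trial_len <- round(cfg$assr_trial_dur * fs)
    tone <- cfg$assr_amplitude * scales$assr *
      sin(2 * pi * 40 * seq(0, length.out = trial_len, by = 1 / fs))
    for (on in layout$onsets) {
      evoked_t <- .add_at(evoked_t, on, aep)
      evoked_t <- .add_at(evoked_t, on, tone)
    }
    out <- out + fields$aep %o% evoked_t
  }
  out
}

#' Simulate one subject's session for one system
#'
#' Generates one continuous recording per requested task with event
#' markers, evoked components on fixed Gaussian scalp fields (VEP
#' occipital, AEP/ASSR fronto-central, alpha occipito-parietal), noise as
#' configured, and possibly corrupted channels. Subject-level latent
#' amplitude scales are drawn from a stream that does not depend on the
#' system, so the dry and gel session of a subject share effect sizes.
#' Output is bit-reproducible given (seed, subject_id, system).
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject index, `1:n_subjects`.
#' @param system `"dry"` or `"gel"`.
#' @param tasks subset of `c("CHECK", "ASSR", "EOEC")`.
#' @return list with `recordings` (named list of `eeg_recording`) and
#'   `ground_truth` (latent scales, corrupted channels with corruption
#'   kind, blink onsets per task, and the injected condition effects).
#' @export
simulate_subject <- function(cfg, subject_id, system = c("dry", "gel"),
                             tasks = c("CHECK", "ASSR", "EOEC")) {
  system <- match.arg(system)
  validate_sim_config(cfg)
  if (subject_id < 1 || subject_id > cfg$n_subjects) {
    stop("subject_id must be in 1..n_subjects")
  }
  tasks <- match.arg(tasks, several.ok = TRUE)
  fs <- cfg$sample_rate
  montage <- make_montage(system)
  # gel sessions also record the right mastoid (used later for
  # re-referencing); dry sessions are already M2-referenced.
  rec_labels <- if (system == "gel") c(montage$label, "M2") else montage$label
  pos <- montage_positions(rec_labels)
  fields <- .sim_fields(pos)
  # the mastoid sits outside the scalp fields: no evoked content there
  if (system == "gel") {
    for (f in names(fields)) fields[[f]][length(rec_labels)] <- 0
  }
  n_ch <- length(rec_labels)

  # subject-level latents, shared between systems
  set.seed(.sim_seed(cfg$seed, subject_id))
  cv <- cfg$subject_amp_cv
  draw_scale <- function() if (cv > 0) exp(stats::rnorm(1, -cv^2 / 2, cv)) else 1
  scales <- list(vep = draw_scale(), aep = draw_scale(),
                 assr = draw_scale(), alpha = draw_scale())

  # per-(subject, system) corrupted channels
  set.seed(.sim_seed(cfg$seed, subject_id, system, "BAD"))
  p_bad <- if (system == "dry") cfg$p_bad_channel_dry else cfg$p_bad_channel_gel
  bad_mask <- stats::runif(length(montage$label)) < p_bad
  bad_channels <- data.frame(
    label = montage$label[bad_mask],
    kind = if (any(bad_mask)) {
      sample(c("flat", "high-amplitude", "drift"), sum(bad_mask), replace = TRUE)
    } else character(0),
    stringsAsFactors = FALSE)

  delta_scale <- if (system == "dry") cfg$effect_scale_dry_delta else 1
  drift_sd <- if (system == "dry") cfg$drift_sd_dry else cfg$drift_sd_gel

  recordings <- list()
  blink_truth <- list()
  for (task in tasks) {
    set.seed(.sim_seed(cfg$seed, subject_id, system, task))
    layout <- .sim_task_layout(cfg, task)
    n <- layout$n
    t_axis <- seq(0, length.out = n, by = 1 / fs)

    data <- .sim_evoked(cfg, task, layout, fields, scales, n_ch, fs)

    # alpha with eyes-closed gain (EOEC task only)
    if (task == "EOEC" && cfg$alpha_sd > 0) {
      env <- rep(1, n)
      gain_amp <- sqrt(cfg$alpha_ec_gain)
      ec_idx <- which(layout$labels == "EC")
      for (k in ec_idx) {
        i0 <- layout$onsets[k] + 1
        i1 <- min(i0 + round(cfg$ec_dur * fs) - 1, n)
        env[i0:i1] <- gain_amp
      }
      # one spatially coherent alpha source, like the evoked components
      trace <- .alpha_process(n, fs, 1)
      data <- data + (fields$alpha * scales$alpha * cfg$alpha_sd) %o%
        (env * trace)
    }

    # noise
    for (i in seq_len(n_ch)) {
      ch <- data[i, ]
      ch <- ch + .pink_noise(n, fs, cfg$pink_noise_sd, delta_scale)
      if (cfg$white_noise_sd > 0) ch <- ch + stats::rnorm(n, sd = cfg$white_noise_sd)
      ch <- ch + .drift_noise(n, fs, drift_sd)
      data[i, ] <- ch
    }
    # reference-electrode noise, common to all recorded channels: the dry
    # cap is natively M2-referenced, the gel cap records against CPz
    # (which cancels exactly when the gel data are later re-referenced to
    # the recorded M2 channel)
    ref <- .pink_noise(n, fs, cfg$pink_noise_sd, delta_scale) +
      (if (cfg$white_noise_sd > 0) stats::rnorm(n, sd = cfg$white_noise_sd) else 0) +
      .drift_noise(n, fs, drift_sd)
    data <- sweep(data, 2, ref)
    if (cfg$line_noise_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      base <- sin(2 * pi * 50 * t_axis + phase)
      amp <- cfg$line_noise_amp * stats::runif(n_ch, 0.8, 1.2)
      data <- data + amp %o% base
    }

    # blinks (coherent frontal artifact)
    blink_onsets <- integer(0)
    if (cfg$blink_rate > 0 && cfg$blink_amplitude > 0) {
      n_blink <- stats::rpois(1, cfg$blink_rate / 60 * n / fs)
      if (n_blink > 0) {
        blink_onsets <- sort(sample.int(n - round(0.5 * fs), n_blink))
        tmpl <- .blink_template(fs) * cfg$blink_amplitude
        btrain <- numeric(n)
        for (on in blink_onsets) btrain <- .add_at(btrain, on, tmpl)
        data <- data + fields$blink %o% btrain
      }
    }
    blink_truth[[task]] <- blink_onsets

    # corrupted channels
    for (k in seq_len(nrow(bad_channels))) {
      i <- match(bad_channels$label[k], rec_labels)
      ch <- data[i, ]
      data[i, ] <- switch(bad_channels$kind[k],
        "flat" = stats::rnorm(n, sd = 0.05),
        "high-amplitude" = ch + 150 * sin(2 * pi * 7 * t_axis) +
          stats::rnorm(n, sd = 30),
        "drift" = ch + .drift_noise(n, fs, 80))
    }

    events <- data.frame(onset_sample = layout$onsets, label = layout$labels,
                         stringsAsFactors = FALSE)
    recordings[[task]] <- new_recording(data, fs, rec_labels, events = events,
                                        system = system,
                                        subject_id = subject_id, task = task)
  }

  ground_truth <- list(subject_id = subject_id, system = system,
                       scales = scales, bad_channels = bad_channels,
                       blink_onsets = blink_truth,
                       alpha_ec_gain = cfg$alpha_ec_gain,
                       delta_scale = delta_scale)
  list(recordings = recordings, ground_truth = ground_truth)
}

#' Simulate a full paired cohort
#'
#' @param cfg a [sim_config()].
#' @param tasks tasks to simulate per session.
#' @param out_dir if non-`NULL`, every recording is written there via
#'   [write_session()] together with a JSON ground-truth sidecar
#'   (requires the `jsonlite` package).
#' @param format file format passed to [write_session()].
#' @return list with `sessions` (per subject: list with `dry` and `gel`
#'   recordings) and `ground_truth` (per subject: per-system truth).
#' @export
simulate_cohort <- function(cfg, tasks = c("CHECK", "ASSR", "EOEC"),
                            out_dir = NULL, format = "edf") {
  validate_sim_config(cfg)
  if (cfg$n_subjects < 2) stop("a cohort needs n_subjects >= 2")
  sessions <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    dry <- simulate_subject(cfg, s, "dry", tasks)
    gel <- simulate_subject(cfg, s, "gel", tasks)
    sessions[[s]] <- list(dry = dry$recordings, gel = gel$recordings)
    truth[[s]] <- list(dry = dry$ground_truth, gel = gel$ground_truth)
    if (!is.null(out_dir)) {
      for (sys in c("dry", "gel")) {
        for (task in tasks) write_session(sessions[[s]][[sys]][[task]],
                                          out_dir, format = format)
      }
    }
  }
  if (!is.null(out_dir) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sessions = sessions, ground_truth = truth)
}
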