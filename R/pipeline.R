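# End-to-end orchestration: simulate or accept a paired cohort, run the
# preprocessing and rejection cascade, the time-, frequency- and
# spatial-domain analyses, and collect every result in one bundle.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] used when no pre-built cohort is given.
#' @param sessions optional cohort as returned by [simulate_cohort()]
#'   (`$sessions`); when supplied, `sim` is only used for its metadata.
#' @param tasks tasks to analyze.
#' @param grid_resolution topography grid resolution (66 gives the full
#'   3436-pixel head mask; smaller values give a reduced fast grid).
#' @param perm_enum_cutoff,perm_n_iter,alpha permutation-test controls
#'   (see [permutation_pixel_test()]).
#' @param do_blink_removal identify and remove one blink component per
#'   recording when found?
#' @param out_dir if non-`NULL`, result tables and a run manifest are
#'   written there.
#' @param seed master seed recorded in the manifest (defaults to the
#'   simulator seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), sessions = NULL,
                            tasks = c("CHECK", "ASSR", "EOEC"),
                            grid_resolution = 66,
                            perm_enum_cutoff = 20, perm_n_iter = 10000,
                            alpha = 0.05, do_blink_removal = TRUE,
                            out_dir = NULL, seed = NULL) {
  validate_sim_config(sim)
  structure(list(sim = sim, sessions = sessions, tasks = tasks,
                 grid_resolution = grid_resolution,
                 perm_enum_cutoff = perm_enum_cutoff,
                 perm_n_iter = perm_n_iter, alpha = alpha,
                 do_blink_removal = do_blink_removal,
                 out_dir = out_dir,
                 seed = if (is.null(seed)) sim$seed else seed),
            class = "pipeline_config")
}

# common filtering, global channel rejection (keeping the reference),
# and blink-component removal for one recording
.preprocess_recording <- function(rec, do_blink_removal = TRUE) {
  rec <- filter_zero_phase(rec, "bandpass", 1, 48)
  rec <- filter_zero_phase(rec, "bandstop", 48, 52)
  qc_global <- flag_bad_channels_global(rec)
  keep <- qc_global$channel_flags$kept |
    qc_global$channel_flags$label == rec$reference_label
  rec_clean <- select_channels(rec, rec$channel_labels[keep])
  if (do_blink_removal && nrow(rec_clean$data) >= 3) {
    dec <- decompose_components(rec_clean)
    blink <- identify_blink_component(dec)
    if (!is.na(blink)) rec_clean <- remove_components(rec_clean, dec, blink)
  }
  list(rec = rec_clean, qc_global = qc_global)
}

# crop a recording to its task span plus padding; event samples shifted
.crop_to_task <- function(rec, pad_s = 5) {
  ev <- rec$events
  if (!nrow(ev)) return(rec)
  fs <- rec$sample_rate
  tail_s <- switch(rec$task, CHECK = 1, ASSR = 12, EOEC = 3, 1)
  first <- max(0, min(ev$onset_sample) - round(pad_s * fs))
  last <- min(ncol(rec$data),
              max(ev$onset_sample) + round((tail_s + pad_s) * fs))
  rec$data <- rec$data[, (first + 1):last, drop = FALSE]
  ev$onset_sample <- ev$onset_sample - first
  rec$events <- ev
  rec
}

.task_qc_window <- function(task) {
  switch(task, CHECK = 0.5, ASSR = 11, EOEC = 3, 1)
}

# evoked-potential analysis of one harmonized pair for one task
.analyze_evoked <- function(dry, gel, task, grid_resolution) {
  tmax <- if (task == "CHECK") 0.4 else 0.7
  label <- if (task == "CHECK") "reversal" else "tone"
  windows <- gfp_component_windows(task)
  one <- function(rec) {
    rec <- filter_zero_phase(rec, "bandpass", 1, 30)
    ep <- extract_epochs(rec, -0.1, tmax, c(-0.1, 0), event_label = label)
    qc <- flag_bad_units(ep, band_set(c("delta", "theta", "alpha", "beta")), 2)
    ep <- apply_unit_flags(ep, qc)
    erp <- average_erp(ep)
    list(erp = erp, gfp = gfp_timecourse(erp), qc = qc)
  }
  d <- one(dry); g <- one(gel)
  cmp <- compare_gfp(d$gfp, g$gfp)
  list(dry = d, gel = g, cor = cmp$rho, rmsd = cmp$rmsd,
       peaks_dry = find_gfp_peaks(d$gfp, windows),
       peaks_gel = find_gfp_peaks(g$gfp, windows))
}

# per-channel Welch PSD restricted to clean stretches: for every trial
# and channel, a taper window enters the average only when all of its
# underlying nonoverlapping 1 s QC windows are clean
.masked_welch <- function(trials, flags_by_channel, fs, window_len, hop_s,
                          labels) {
  wl <- round(window_len * fs)
  power <- NULL
  n_used <- integer(length(labels))
  for (c_i in seq_along(labels)) {
    segs <- list()
    for (tr in seq_along(trials)) {
      x <- trials[[tr]][c_i, ]
      n_sec <- length(x) %/% fs
      if (n_sec < window_len) next
      bad <- flags_by_channel[[c_i]][[tr]]
      starts_s <- seq(0, n_sec - window_len, by = hop_s)
      for (s0 in starts_s) {
        covered <- (floor(s0) + 1):ceiling(s0 + window_len)
        if (!any(covered %in% bad)) {
          segs[[length(segs) + 1]] <-
            matrix(x[(round(s0 * fs) + 1):(round(s0 * fs) + wl)], nrow = 1)
        }
      }
    }
    if (!length(segs)) {
      row <- rep(NA_real_, wl %/% 2 + 1)
    } else {
      p <- welch_psd(segs, fs, window_len, overlap = 0)
      row <- p$power[1, ]
      n_used[c_i] <- p$n_windows
    }
    power <- rbind(power, row)
  }
  freqs <- (0:(round(window_len * fs) %/% 2)) * fs / round(window_len * fs)
  rownames(power) <- labels
  structure(list(freqs = freqs, power = power, window_len = window_len,
                 overlap = 1 - hop_s / window_len, sample_rate = fs,
                 n_windows = sum(n_used), z = NULL, z_range = NULL,
                 channel_labels = labels),
            class = "psd_result")
}

# 1 s nonoverlapping QC flags per channel/trial: list over channels of
# lists over trials of flagged window indices (1-based seconds)
.window_flags <- function(trials, fs, bands, min_bands) {
  n_sec <- min(vapply(trials, function(x) ncol(x) %/% fs, 0))
  n_ch <- nrow(trials[[1]])
  units <- array(0, dim = c(length(trials) * n_sec, n_ch, fs))
  u <- 0
  key <- matrix(0L, length(trials) * n_sec, 2)
  for (tr in seq_along(trials)) {
    for (s in seq_len(n_sec)) {
      u <- u + 1
      units[u, , ] <- trials[[tr]][, ((s - 1) * fs + 1):(s * fs)]
      key[u, ] <- c(tr, s)
    }
  }
  attr(units, "sample_rate") <- fs
  dimnames(units) <- list(NULL, rownames(trials[[1]]), NULL)
  qc <- flag_bad_units(units, bands, min_bands)
  flags <- lapply(seq_len(n_ch), function(c_i) {
    lapply(seq_along(trials), function(tr) integer(0))
  })
  labels <- rownames(trials[[1]])
  for (k in seq_len(nrow(qc$unit_flags))) {
    c_i <- match(qc$unit_flags$channel[k], labels)
    u <- qc$unit_flags$unit[k]
    flags[[c_i]][[key[u, 1]]] <- c(flags[[c_i]][[key[u, 1]]], key[u, 2])
  }
  list(flags = flags, qc = qc)
}

.assr_excluded_channels <- c("T7", "T8", "P7", "P8", "O1", "O2", "Oz")

# 40 Hz steady-state analysis of one harmonized recording
.analyze_assr_psd <- function(rec) {
  keep <- setdiff(rec$channel_labels, .assr_excluded_channels)
  rec <- select_channels(rec, keep)
  rec <- filter_zero_phase(rec, "bandpass", 30, 48)
  fs <- rec$sample_rate
  onsets <- rec$events$onset_sample[rec$events$label == "tone"]
  trials <- lapply(onsets, function(on) {
    i0 <- on + round(1 * fs) + 1          # first second removed (AEP)
    i1 <- min(on + round(12 * fs), ncol(rec$data))
    rec$data[, i0:i1, drop = FALSE]
  })
  wf <- .window_flags(trials, fs, band_set("gamma"), 1)
  psd <- .masked_welch(trials, wf$flags, fs, 4, 1, rec$channel_labels)
  psd <- standardize_psd(psd, c(35, 45))
  list(psd = psd, metrics = assr_metrics(psd), qc = wf$qc)
}

# eyes-open/eyes-closed band powers of one harmonized recording
.analyze_eoec_psd <- function(rec) {
  fs <- rec$sample_rate
  get_trials <- function(lab, skip_s, dur_s) {
    onsets <- rec$events$onset_sample[rec$events$label == lab]
    lapply(onsets, function(on) {
      i0 <- on + round(skip_s * fs) + 1
      i1 <- min(on + round((skip_s + dur_s) * fs), ncol(rec$data))
      rec$data[, i0:i1, drop = FALSE]
    })
  }
  conditions <- list(EO = get_trials("EO", 1, 3),   # middle 3 s of 5 s
                     EC = get_trials("EC", 0, 3))
  out <- list()
  for (cond in names(conditions)) {
    trials <- conditions[[cond]]
    wf <- .window_flags(trials, fs, band_set(), 2)
    psd <- .masked_welch(trials, wf$flags, fs, 1, 0.5, rec$channel_labels)
    psd <- standardize_psd(psd, c(1, 48))
    out[[cond]] <- list(psd = psd,
                        band_abs = band_power(psd, band_set(), "absolute"),
                        band_z = band_power(psd, band_set(), "z"),
                        qc = wf$qc)
  }
  out
}

# per-subject component topographies at the group GFP peak latencies
.component_maps <- function(subject_results, task, grid_resolution) {
  windows <- gfp_component_windows(task)
  res <- list()
  for (sys in c("dry", "gel")) {
    gfps <- lapply(subject_results, function(s) s[[sys]]$gfp)
    gmat <- do.call(rbind, lapply(gfps, function(g) g$gfp))
    group_gfp <- structure(list(times = gfps[[1]]$times,
                                gfp = colMeans(gmat),
                                n_channels = NA), class = "gfp_series")
    peaks <- find_gfp_peaks(group_gfp, windows)
    res[[sys]] <- list(peaks = peaks, maps = list())
    for (k in seq_len(nrow(peaks))) {
      comp <- peaks$component[k]
      t_i <- which.min(abs(gfps[[1]]$times - peaks$latency[k]))
      maps <- lapply(subject_results, function(s) {
        erp <- s[[sys]]$erp
        vals <- erp[, t_i]
        names(vals) <- rownames(erp)
        make_topomap(vals[!is.na(vals)], montage_positions(names(vals)[!is.na(vals)]),
                     standardize = TRUE, grid_resolution = grid_resolution)
      })
      res[[sys]]$maps[[comp]] <- maps
    }
  }
  res
}

#' Run the full dual-system comparison pipeline
#'
#' Executes, in order: cohort simulation (or intake), 1-48 Hz bandpass
#' plus 48-52 Hz bandstop filtering, global bad-channel rejection, blink
#' component removal, harmonization to the shared channels with M2
#' re-referencing, per-task extraction with 5 s padding and task-level
#' channel rejection, then the task analyses (VEP/AEP epoching, trial
#' rejection, ERP averaging, GFP with per-subject Spearman/RMSD
#' comparison and component peaks; ASSR window rejection, Welch PSD,
#' 40 Hz power and SNR; eyes-open/closed window rejection and band
#' powers), the topographic permutation tests with pixel-based
#' correction, paired Wilcoxon comparisons with Bonferroni adjustment,
#' pooled electrode-pair Spearman correlations, and the rejected-data
#' summary.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list) with elements `vep`, `aep`, `assr`,
#'   `eoec`, `topo`, `comparisons`, `qc`, `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tasks <- config$tasks
  cohort <- if (!is.null(config$sessions)) config$sessions else
    simulate_cohort(config$sim, tasks = tasks)$sessions
  n_sub <- length(cohort)

  prep <- vector("list", n_sub)
  qc_reports <- list(dry = list(), gel = list())
  for (s in seq_len(n_sub)) {
    per_task <- list()
    for (task in tasks) {
      pre_d <- .preprocess_recording(cohort[[s]]$dry[[task]],
                                     config$do_blink_removal)
      pre_g <- .preprocess_recording(cohort[[s]]$gel[[task]],
                                     config$do_blink_removal)
      pair <- suppressWarnings(harmonize_and_rereference(pre_d$rec, pre_g$rec))
      pair$dry <- .crop_to_task(pair$dry)
      pair$gel <- .crop_to_task(pair$gel)
      wl <- .task_qc_window(task)
      qc_d <- flag_bad_channels_task(pair$dry, wl)
      qc_g <- flag_bad_channels_task(pair$gel, wl)
      pair$dry <- select_channels(pair$dry,
                                  qc_d$channel_flags$label[qc_d$channel_flags$kept])
      pair$gel <- select_channels(pair$gel,
                                  qc_g$channel_flags$label[qc_g$channel_flags$kept])
      qc_reports$dry[[paste(s, task)]] <- list(global = pre_d$qc_global, task = qc_d)
      qc_reports$gel[[paste(s, task)]] <- list(global = pre_g$qc_global, task = qc_g)
      per_task[[task]] <- pair
    }
    prep[[s]] <- per_task
  }

  bundle <- list(meta = list(n_subjects = n_sub, seed = config$seed,
                             tasks = tasks,
                             grid_resolution = config$grid_resolution))

  # ---- time domain -------------------------------------------------------
  for (task in intersect(c("CHECK", "ASSR"), tasks)) {
    key <- if (task == "CHECK") "vep" else "aep"
    subject_results <- lapply(seq_len(n_sub), function(s) {
      pair <- prep[[s]][[task]]
      a <- .analyze_evoked(pair$dry, pair$gel, task, config$grid_resolution)
      qc_reports$dry[[paste(s, task)]]$units <<- a$dry$qc
      qc_reports$gel[[paste(s, task)]]$units <<- a$gel$qc
      a
    })
    cors <- vapply(subject_results, function(x) x$cor, 0)
    rmsds <- vapply(subject_results, function(x) x$rmsd, 0)
    peaks_summary <- function(sys) {
      pk <- lapply(subject_results, function(x) x[[paste0("peaks_", sys)]])
      comps <- pk[[1]]$component
      do.call(rbind, lapply(seq_along(comps), function(k) {
        amp <- vapply(pk, function(p) p$amplitude[k], 0)
        lat <- vapply(pk, function(p) p$latency[k], 0)
        data.frame(system = sys, component = comps[k],
                   amplitude_mean = mean(amp), amplitude_sd = stats::sd(amp),
                   latency_mean = mean(lat), latency_sd = stats::sd(lat),
                   stringsAsFactors = FALSE)
      }))
    }
    bundle[[key]] <- list(
      cor = cors, rmsd = rmsds,
      cor_median = stats::median(cors), cor_sd = stats::sd(cors),
      rmsd_median = stats::median(rmsds), rmsd_sd = stats::sd(rmsds),
      peak_table = rbind(peaks_summary("dry"), peaks_summary("gel")),
      subjects = subject_results)
  }

  # ---- frequency domain: ASSR -------------------------------------------
  if ("ASSR" %in% tasks) {
    per_sys <- list()
    for (sys in c("dry", "gel")) {
      per_sys[[sys]] <- lapply(seq_len(n_sub), function(s) {
        .analyze_assr_psd(prep[[s]]$ASSR[[sys]])
      })
    }
    for (sys in c("dry", "gel")) {
      for (s in seq_len(n_sub)) {
        qc_reports[[sys]][[paste(s, "ASSR")]]$win <- per_sys[[sys]][[s]]$qc
      }
    }
    subj_metric <- function(sys, field) {
      vapply(per_sys[[sys]], function(x) x$metrics[[field]], 0)
    }
    chan_matrix <- function(sys, col) {
      labs <- setdiff(shared_channels(), .assr_excluded_channels)
      t(vapply(per_sys[[sys]], function(x) {
        v <- stats::setNames(x$metrics$per_channel[[col]],
                             x$metrics$per_channel$channel)
        v[labs]
      }, numeric(length(labs))))
    }
    bundle$assr <- list(
      p40_abs = cbind(dry = subj_metric("dry", "p40_mean"),
                      gel = subj_metric("gel", "p40_mean")),
      p40_z = cbind(dry = subj_metric("dry", "p40_z_mean"),
                    gel = subj_metric("gel", "p40_z_mean")),
      snr_abs = cbind(dry = subj_metric("dry", "snr_mean"),
                      gel = subj_metric("gel", "snr_mean")),
      snr_z = cbind(dry = subj_metric("dry", "snr_z_mean"),
                    gel = subj_metric("gel", "snr_z_mean")),
      spearman_p40 = electrode_pair_spearman(chan_matrix("dry", "p40"),
                                             chan_matrix("gel", "p40")),
      spearman_snr = electrode_pair_spearman(chan_matrix("dry", "snr"),
                                             chan_matrix("gel", "snr")),
      subjects = per_sys)
  }

  # ---- frequency domain: EOEC -------------------------------------------
  if ("EOEC" %in% tasks) {
    per_sys <- list()
    for (sys in c("dry", "gel")) {
      per_sys[[sys]] <- lapply(seq_len(n_sub), function(s) {
        .analyze_eoec_psd(prep[[s]]$EOEC[[sys]])
      })
    }
    for (sys in c("dry", "gel")) {
      for (s in seq_len(n_sub)) {
        qc_reports[[sys]][[paste(s, "EOEC")]]$winEO <- per_sys[[sys]][[s]]$EO$qc
        qc_reports[[sys]][[paste(s, "EOEC")]]$winEC <- per_sys[[sys]][[s]]$EC$qc
      }
    }
    band_subject_matrix <- function(sys, cond, use) {
      t(vapply(per_sys[[sys]], function(x) {
        colMeans(x[[cond]][[use]], na.rm = TRUE)
      }, numeric(5)))
    }
    chan_band_matrix <- function(sys, cond, band) {
      labs <- shared_channels()
      t(vapply(per_sys[[sys]], function(x) {
        v <- x[[cond]]$band_abs[, band]
        v[match(labs, rownames(x[[cond]]$band_abs))]
      }, numeric(length(labs))))
    }
    eoec <- list()
    for (cond in c("EO", "EC")) {
      for (use in c("band_abs", "band_z")) {
        d <- band_subject_matrix("dry", cond, use)
        g <- band_subject_matrix("gel", cond, use)
        nm <- paste0(cond, "_", sub("band_", "", use))
        wx <- if (n_sub >= 5) {
          suppressWarnings(paired_band_comparison(d, g, n_tests = 5))
        }   # Wilcoxon needs at least 5 pairs; small cohorts skip it
        eoec[[nm]] <- list(dry = d, gel = g, wilcoxon = wx)
      }
      # pooled electrode-pair agreement per band (absolute power)
      eoec[[paste0(cond, "_spearman")]] <- vapply(names(band_set()), function(b) {
        electrode_pair_spearman(chan_band_matrix("dry", cond, b),
                                chan_band_matrix("gel", cond, b))$rho
      }, 0)
    }
    eoec$subjects <- per_sys
    bundle$eoec <- eoec
  }

  # ---- spatial domain ----------------------------------------------------
  topo <- list()
  run_perm <- function(maps_dry, maps_gel) {
    permutation_pixel_test(maps_dry, maps_gel,
                           n_iter = config$perm_n_iter,
                           enum_cutoff = config$perm_enum_cutoff,
                           seed = config$seed, alpha = config$alpha)
  }
  for (task in intersect(c("CHECK", "ASSR"), tasks)) {
    key <- if (task == "CHECK") "vep" else "aep"
    cm <- .component_maps(bundle[[key]]$subjects, task, config$grid_resolution)
    for (comp in names(cm$dry$maps)) {
      pr <- run_perm(cm$dry$maps[[comp]], cm$gel$maps[[comp]])
      topo[[comp]] <- list(result = pr, sig_pct = 100 * mean(pr$sig_mask))
    }
  }
  if ("EOEC" %in% tasks) {
    for (cond in c("EO", "EC")) {
      maps <- lapply(c("dry", "gel"), function(sys) {
        lapply(bundle$eoec$subjects[[sys]], function(x) {
          ap <- x[[cond]]$band_abs[, "alpha"]
          ap <- ap[is.finite(ap)]
          make_topomap(ap, montage_positions(names(ap)), standardize = TRUE,
                       grid_resolution = config$grid_resolution)
        })
      })
      pr <- run_perm(maps[[1]], maps[[2]])
      topo[[paste0("alpha_", cond)]] <- list(result = pr,
                                             sig_pct = 100 * mean(pr$sig_mask))
    }
  }
  bundle$topo <- topo

  # ---- QC summary --------------------------------------------------------
  qc_summary <- list()
  for (sys in c("dry", "gel")) {
    per_subject <- vapply(seq_len(n_sub), function(s) {
      reps <- list()
      for (task in tasks) {
        rr <- qc_reports[[sys]][[paste(s, task)]]
        for (f in c("task", "units", "win", "winEO", "winEC")) {
          if (!is.null(rr[[f]])) reps <- c(reps, list(rr[[f]]))
        }
      }
      rejection_summary(reps)$subject_pct
    }, 0)
    qc_summary[[sys]] <- list(per_subject_pct = per_subject,
                              mean_pct = mean(per_subject))
  }
  bundle$qc <- qc_summary

  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  bundle
}

.write_bundle <- function(bundle, config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  for (key in intersect(c("vep", "aep"), names(bundle))) {
    export_table(bundle[[key]]$peak_table,
                 file.path(out, paste0(key, "_peaks.tsv")))
    export_table(data.frame(subject = seq_along(bundle[[key]]$cor),
                            cor = bundle[[key]]$cor,
                            rmsd = bundle[[key]]$rmsd),
                 file.path(out, paste0(key, "_gfp_comparison.tsv")))
  }
  if (!is.null(bundle$topo) && length(bundle$topo)) {
    export_table(data.frame(contrast = names(bundle$topo),
                            sig_pct = vapply(bundle$topo, `[[`, 0, "sig_pct")),
                 file.path(out, "topo_significance.tsv"))
  }
  cfg_txt <- utils::capture.output(utils::str(config, max.level = 2))
  cfg_file <- file.path(out, "config.txt")
  writeLines(cfg_txt, cfg_file)
  manifest <- data.frame(key = c("seed", "n_subjects", "config_md5"),
                         value = c(config$seed, bundle$meta$n_subjects,
                                   unname(tools::md5sum(cfg_file))))
  export_table(manifest, file.path(out, "manifest.tsv"))
  invisible(out)
}

#' Human-readable summary of a pipeline bundle
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
generate_report <- function(bundle) {
  fmt <- function(...) sprintf(...)
  lines <- c(fmt("Dual-system EEG comparison: %d subjects",
                 bundle$meta$n_subjects))
  for (key in intersect(c("vep", "aep"), names(bundle))) {
    lines <- c(lines,
               fmt("%s GFP comparison: rho median %.3f (SD %.3f), RMSD median %.3f uV (SD %.3f)",
                   toupper(key), bundle[[key]]$cor_median, bundle[[key]]$cor_sd,
                   bundle[[key]]$rmsd_median, bundle[[key]]$rmsd_sd))
    pt <- bundle[[key]]$peak_table
    lines <- c(lines, vapply(seq_len(nrow(pt)), function(i) {
      fmt("  %s %s: amplitude %.2f +- %.2f uV, latency %.3f +- %.3f s",
          pt$system[i], pt$component[i], pt$amplitude_mean[i],
          pt$amplitude_sd[i], pt$latency_mean[i], pt$latency_sd[i])
    }, ""))
  }
  if (!is.null(bundle$assr)) {
    lines <- c(lines,
               fmt("ASSR 40 Hz power (abs): dry %.3f, gel %.3f uV^2/Hz; SNR (abs): dry %.2f, gel %.2f",
                   mean(bundle$assr$p40_abs[, "dry"]),
                   mean(bundle$assr$p40_abs[, "gel"]),
                   mean(bundle$assr$snr_abs[, "dry"]),
                   mean(bundle$assr$snr_abs[, "gel"])),
               fmt("  electrode-pair Spearman: p40 rho %.2f, SNR rho %.2f",
                   bundle$assr$spearman_p40$rho, bundle$assr$spearman_snr$rho))
  } else {
    lines <- c(lines, "ASSR: not run")
  }
  if (!is.null(bundle$eoec)) {
    for (nm in grep("_(abs|z)$", names(bundle$eoec), value = TRUE)) {
      w <- bundle$eoec[[nm]]$wilcoxon
      if (is.null(w)) {
        lines <- c(lines, fmt("EOEC %s: too few subjects for paired tests", nm))
      } else {
        sig <- paste(w$test[w$significant], collapse = ", ")
        lines <- c(lines,
                   fmt("EOEC %s: significant bands at alpha=%.3g: %s", nm,
                       w$alpha_adj[1], if (nzchar(sig)) sig else "none"))
      }
    }
    for (cond in c("EO", "EC")) {
      sp <- bundle$eoec[[paste0(cond, "_spearman")]]
      if (!is.null(sp)) {
        lines <- c(lines, fmt("EOEC %s electrode-pair Spearman: %s", cond,
                              paste(sprintf("%s %.2f", names(sp), sp),
                                    collapse = ", ")))
      }
    }
  } else {
    lines <- c(lines, "EOEC: not run")
  }
  if (!is.null(bundle$topo)) {
    for (nm in names(bundle$topo)) {
      lines <- c(lines, fmt("Topography %s: %.1f%% of pixels significant",
                            nm, bundle$topo[[nm]]$sig_pct))
    }
  }
  if (!is.null(bundle$qc)) {
    lines <- c(lines, fmt("Rejected data: dry %.1f%%, gel %.1f%% (subject means)",
                          bundle$qc$dry$mean_pct, bundle$qc$gel$mean_pct))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
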