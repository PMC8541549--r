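# Between-system statistics: the sign-flip permutation test with
# pixel-based (max-statistic) correction on topographic maps, pooled
# electrode-pair Spearman correlation, and paired Wilcoxon tests with
# Bonferroni-adjusted significance.

.sign_matrix <- function(n) {
  # all 2^n sign patterns, one per row
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(m) <- NULL
  m
}

#' Paired sign-flip permutation test with pixel-based correction
#'
#' For paired per-subject condition maps, exchanging a subject's
#' condition labels equals negating its difference map, so the exact
#' permutation null is the set of all sign patterns. Per iteration the
#' paired t-map `t = mean(D) / (sd(D)/sqrt(n))` is computed, converted
#' pixelwise to a Z-map using the per-pixel mean and SD of the
#' permutation (H0) distribution, and the Z-map's minimum and maximum
#' over pixels are recorded. The corrected thresholds are the 2.5th
#' percentile of the minima and the 97.5th percentile of the maxima; the
#' observed map is Z-converted identically and a pixel is significant
#' when its Z lies outside the thresholds. All `2^n` sign patterns are
#' enumerated when `n <= enum_cutoff` (seed-independent and exact);
#' otherwise `n_iter` Monte-Carlo draws are used, with the identity
#' pattern always included.
#'
#' @param maps_a,maps_b per-subject maps for the two conditions: lists of
#'   `topo_map`s or subjects x pixels matrices, matched by row.
#' @param n_iter Monte-Carlo iterations when enumeration is not used.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param enum_cutoff maximum `n` for full enumeration (default 20).
#' @param alpha two-sided family-wise level (default 0.05).
#' @return object of class `permutation_result`: `observed_z` (per
#'   pixel), `lower_thr`, `upper_thr`, `sig_mask`, `n_iter`, `min_t`
#'   and `max_t` (per-iteration extremes of the Z-converted maps),
#'   `h0_mean`, `h0_sd`.
#' @export
permutation_pixel_test <- function(maps_a, maps_b, n_iter = 10000,
                                   seed = NULL, enum_cutoff = 20,
                                   alpha = 0.05) {
  A <- if (is.list(maps_a)) stack_topomaps(maps_a) else as.matrix(maps_a)
  B <- if (is.list(maps_b)) stack_topomaps(maps_b) else as.matrix(maps_b)
  if (!identical(dim(A), dim(B))) stop("conditions disagree in subjects or pixels")
  n <- nrow(A)
  if (n < 2) stop("need at least 2 subjects")
  D <- A - B
  P <- ncol(D)
  degenerate <- all(abs(D) < 1e-300)
  if (degenerate) warning("all difference maps are zero; nothing can be significant")

  SS <- colSums(D^2)
  t_of_signs <- function(S) {
    # S: iterations x n matrix of +-1; returns iterations x P t-maps.
    # Per-pixel sums of squares are sign-invariant, so
    # t = sum(sD) * sqrt(n-1) / sqrt(n*SS - sum(sD)^2).
    M <- S %*% D
    denom2 <- sweep(-M^2, 2, n * SS, "+")
    denom2[denom2 < 1e-300] <- Inf   # zero-variance pixels: t := 0
    M * (sqrt(n - 1) / sqrt(denom2))
  }

  enumerate <- n <= enum_cutoff
  if (enumerate) {
    # t(-s) = -t(s): enumerating the half-space with the last sign fixed
    # to +1 and mirroring covers all 2^n patterns exactly
    S_half <- cbind(.sign_matrix(n - 1), 1)
    n_gen <- nrow(S_half)
    n_iter <- 2L * n_gen
    S_all <- S_half
    mirrored <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    S_all <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
    S_all[1, ] <- 1   # identity labeling included
    n_gen <- n_iter
    mirrored <- FALSE
  }

  row_min <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
  row_max <- function(M) do.call(pmax, lapply(seq_len(ncol(M)), function(j) M[, j]))

  chunk <- max(1L, floor(8e6 / max(P, 1)))
  starts <- seq(1, n_gen, by = chunk)
  cache_ok <- n_gen * P <= 2e7
  cache <- if (cache_ok) vector("list", length(starts)) else NULL
  # pass 1: per-pixel H0 moments of t over the full pattern set
  sum_t <- numeric(P); sum_t2 <- numeric(P)
  for (ci in seq_along(starts)) {
    s0 <- starts[ci]
    rows <- s0:min(s0 + chunk - 1, n_gen)
    Tm <- t_of_signs(S_all[rows, , drop = FALSE])
    if (cache_ok) cache[[ci]] <- Tm
    sum_t <- sum_t + colSums(Tm)
    sum_t2 <- sum_t2 + colSums(Tm^2)
  }
  if (mirrored) {
    sum_t <- numeric(P)          # odd under mirroring: cancels exactly
    sum_t2 <- 2 * sum_t2
  }
  h0_mean <- sum_t / n_iter
  h0_var <- pmax(sum_t2 / n_iter - h0_mean^2, 0)
  h0_sd <- sqrt(h0_var * n_iter / (n_iter - 1))
  live <- h0_sd > 1e-300
  # pass 2: per-iteration extremes of the Z-converted maps
  min_gen <- numeric(n_gen); max_gen <- numeric(n_gen)
  for (ci in seq_along(starts)) {
    s0 <- starts[ci]
    rows <- s0:min(s0 + chunk - 1, n_gen)
    Tm <- if (cache_ok) cache[[ci]] else
      t_of_signs(S_all[rows, , drop = FALSE])
    Z <- Tm[, live, drop = FALSE]
    if (any(h0_mean[live] != 0)) Z <- sweep(Z, 2, h0_mean[live])
    Z <- sweep(Z, 2, h0_sd[live], "/")
    if (ncol(Z)) {
      min_gen[rows] <- row_min(Z)
      max_gen[rows] <- row_max(Z)
    }
  }
  if (mirrored) {
    min_t <- c(min_gen, -max_gen)
    max_t <- c(max_gen, -min_gen)
  } else {
    min_t <- min_gen
    max_t <- max_gen
  }
  lower_thr <- as.numeric(stats::quantile(min_t, alpha / 2))
  upper_thr <- as.numeric(stats::quantile(max_t, 1 - alpha / 2))

  mu <- colMeans(D)
  sdv <- apply(D, 2, stats::sd)
  t_obs <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), 0)
  observed_z <- numeric(P)
  observed_z[live] <- (t_obs[live] - h0_mean[live]) / h0_sd[live]
  sig_mask <- observed_z < lower_thr | observed_z > upper_thr
  if (degenerate) sig_mask[] <- FALSE
  structure(list(observed_z = observed_z, lower_thr = lower_thr,
                 upper_thr = upper_thr, sig_mask = sig_mask,
                 n_iter = n_iter, enumerated = enumerate,
                 min_t = min_t, max_t = max_t,
                 h0_mean = h0_mean, h0_sd = h0_sd),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d iterations%s, thresholds [%.3f, %.3f], %.1f%% pixels significant\n",
              x$n_iter, if (x$enumerated) " (full enumeration)" else "",
              x$lower_thr, x$upper_thr, 100 * mean(x$sig_mask)))
  invisible(x)
}

#' Pooled within-subject electrode-pair Spearman correlation
#'
#' Spearman rank correlation over all (subject, electrode) pairs of a
#' metric measured with both systems (average ranks on ties; incomplete
#' pairs removed).
#'
#' @param metric_dry,metric_gel numeric matrices (subjects x electrodes)
#'   or vectors, matched elementwise.
#' @return list with `rho`, `p` (asymptotic, from [stats::cor.test()])
#'   and `n_pairs`.
#' @export
electrode_pair_spearman <- function(metric_dry, metric_gel) {
  a <- as.vector(as.matrix(metric_dry))
  b <- as.vector(as.matrix(metric_gel))
  if (length(a) != length(b)) stop("metrics disagree in shape")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = sum(ok))
}

#' Paired Wilcoxon comparisons with Bonferroni-adjusted significance
#'
#' Two-sided Wilcoxon signed-rank test per column (band or metric);
#' significance is declared at `alpha / n_tests` (five frequency bands
#' give an adjusted level of 0.01).
#'
#' @param per_subject_a,per_subject_b subjects x tests matrices (or
#'   vectors for a single test), paired by row.
#' @param n_tests number of tests for the Bonferroni adjustment
#'   (default: the number of columns).
#' @param alpha unadjusted level (default 0.05).
#' @return data frame with `test`, `statistic`, `p`, `alpha_adj`,
#'   `significant`.
#' @export
paired_band_comparison <- function(per_subject_a, per_subject_b,
                                   n_tests = NULL, alpha = 0.05) {
  A <- as.matrix(per_subject_a); B <- as.matrix(per_subject_b)
  if (!identical(dim(A), dim(B))) stop("paired matrices disagree in shape")
  if (nrow(A) < 5) stop("need at least 5 paired subjects")
  if (is.null(n_tests)) n_tests <- ncol(A)
  alpha_adj <- alpha / n_tests
  nm <- colnames(A)
  if (is.null(nm)) nm <- paste0("test", seq_len(ncol(A)))
  rows <- lapply(seq_len(ncol(A)), function(j) {
    d <- A[, j] - B[, j]
    if (all(d == 0)) {
      warning("all paired differences are zero for ", nm[j])
      return(data.frame(test = nm[j], statistic = 0, p = 1,
                        alpha_adj = alpha_adj, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(A[, j], B[, j], paired = TRUE))
    data.frame(test = nm[j], statistic = unname(wt$statistic), p = wt$p.value,
               alpha_adj = alpha_adj, significant = wt$p.value < alpha_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
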