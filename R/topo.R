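# Scalp topographies: biharmonic spline interpolation of per-electrode
# values onto a pixel grid masked to the unit head disc, with optional
# Z-standardization across the map.

.biharm_green <- function(r) ifelse(r < 1e-300, 0, r^2 * (log(r) - 1))

# augmented thin-membrane system: [G P; P' 0] [w; a] = [v; 0], P = [1 x y];
# the affine part makes constant and linear fields exact
.biharm_fit <- function(values, px, py, d = NULL) {
  n <- length(values)
  if (is.null(d)) d <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
  G <- .biharm_green(d)
  Pm <- cbind(1, px, py)
  M <- rbind(cbind(G, Pm), cbind(t(Pm), matrix(0, 3, 3)))
  rhs <- c(values, 0, 0, 0)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    warning("singular interpolation system; using a ridge-regularized solve")
    solve(M + diag(1e-8, n + 3), rhs)
  })
  list(w = sol[seq_len(n)], a = sol[n + 1:3], px = px, py = py)
}

.biharm_eval <- function(fit, qx, qy) {
  E <- .biharm_green(sqrt(outer(qx, fit$px, "-")^2 + outer(qy, fit$py, "-")^2))
  as.vector(E %*% fit$w) + fit$a[1] + fit$a[2] * qx + fit$a[3] * qy
}

#' Biharmonic spline interpolation onto the head grid
#'
#' Thin-membrane (biharmonic) interpolation with Green's function
#' `g(r) = r^2 (log r - 1)`, `g(0) = 0`, plus an affine part with the
#' usual moment constraints on the weights: the interpolant passes
#' exactly through every electrode value and reproduces constant and
#' linear fields exactly. A numerically singular system is solved with a
#' small ridge and a warning. The grid consists of `grid_resolution^2`
#' square cells tiling `[-1, 1]^2`; cell centers inside the unit disc
#' form the mask (3436 pixels at the default resolution of 66).
#'
#' @param values numeric vector of per-electrode values (finite).
#' @param positions data frame or matrix with columns `x`, `y` in the
#'   unit disc; one row per electrode, positions distinct.
#' @param grid_resolution cells per axis (default 66).
#' @return object of class `topo_map`: `grid_x`, `grid_y` (cell-center
#'   coordinates), `mask` (resolution x resolution logical), `values`
#'   (one value per masked pixel, in column-major mask order),
#'   `n_pixels`, `electrodes` (the input points).
#' @export
biharmonic_interpolate <- function(values, positions, grid_resolution = 66) {
  positions <- as.data.frame(positions)
  ok <- is.finite(values)
  values <- values[ok]
  px <- positions$x[ok]; py <- positions$y[ok]
  n <- length(values)
  if (n < 3) stop("need at least 3 electrodes with finite values")
  d <- sqrt(outer(px, px, "-")^2 + outer(py, py, "-")^2)
  if (any(d[upper.tri(d)] < 1e-12)) stop("duplicate electrode positions")
  fit <- .biharm_fit(values, px, py, d)
  res <- grid_resolution
  centers <- -1 + (seq_len(res) - 0.5) * 2 / res
  gx <- rep(centers, times = res)   # column-major over (x, y)
  gy <- rep(centers, each = res)
  mask <- matrix(gx^2 + gy^2 <= 1, res, res)
  qx <- gx[mask]; qy <- gy[mask]
  structure(list(grid_x = centers, grid_y = centers, mask = mask,
                 values = .biharm_eval(fit, qx, qy), n_pixels = sum(mask),
                 electrodes = data.frame(x = px, y = py, value = values)),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %d masked pixels (%dx%d grid), range [%.3g, %.3g]\n",
              x$n_pixels, length(x$grid_x), length(x$grid_y),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Interpolate electrode values into a (optionally standardized) map
#'
#' Missing electrodes (NA values or labels absent from the montage)
#' simply drop out of the interpolation; no imputation is performed.
#' With `standardize = TRUE` the masked pixels are Z-scored (mean 0,
#' sample SD 1 across the map), which makes maps invariant to a global
#' additive shift of the electrode values.
#'
#' @param values named numeric vector (names = channel labels) or plain
#'   vector aligned with `montage`.
#' @param montage an `eeg_montage` (or data frame with `label`, `x`, `y`).
#' @param standardize Z-score the map across masked pixels?
#' @param grid_resolution passed to [biharmonic_interpolate()].
#' @return a `topo_map`.
#' @export
make_topomap <- function(values, montage, standardize = FALSE,
                         grid_resolution = 66) {
  if (!is.null(names(values))) {
    idx <- match(canonical_label(names(values)), montage$label)
    if (anyNA(idx)) stop("value name(s) missing from montage")
    pos <- montage[idx, , drop = FALSE]
  } else {
    if (length(values) != nrow(montage)) {
      stop("unnamed values must align with the montage rows")
    }
    pos <- montage
  }
  keep <- is.finite(values)
  if (sum(keep) < 3) stop("fewer than 3 surviving electrodes")
  tm <- biharmonic_interpolate(values[keep], pos[keep, , drop = FALSE],
                               grid_resolution)
  if (standardize) {
    tm$values <- (tm$values - mean(tm$values)) / stats::sd(tm$values)
    tm$standardized <- TRUE
  }
  tm
}

#' Stack per-subject maps into a subjects x pixels matrix
#'
#' @param maps list of `topo_map`s sharing one grid.
#' @return numeric matrix, one row per subject.
#' @export
stack_topomaps <- function(maps) {
  np <- vapply(maps, function(m) m$n_pixels, 0L)
  if (length(unique(np)) != 1) stop("maps disagree in grid/mask")
  do.call(rbind, lapply(maps, function(m) m$values))
}
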