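#' Resample a density map to a uniform voxel size
#'
#' Each axis is rescaled by zoom factor = original voxel size / target, so
#' anisotropic input grids come out isotropic at \code{target_voxel}
#' Angstrom (default 1.0). Output dimensions are round-half-up of
#' dim x factor; interpolation is separable per axis (order 3: natural cubic
#' spline; order 1: linear, strictly bounded by the input range), with edge
#' clamping. The origin is preserved: output grid point (1,1,1) sits at the
#' same world position as the input's.
#'
#' @param map a \code{\link{density_map}}.
#' @param target_voxel target voxel edge in Angstrom (> 0).
#' @param order interpolation order, 1 or 3 (default 3).
#' @return a resampled \code{\link{density_map}}.
#' @export
resample <- function(map, target_voxel = 1.0, order = 3) {
  stopifnot(inherits(map, "density_map"), target_voxel > 0, order %in% c(1, 3))
  factor <- map$voxel_size / target_voxel
  out_dim <- as.integer(round_half_up(dim(map$grid) * factor))
  if (any(out_dim < 1))
    stopf("resample: target voxel %.3g A collapses an axis to zero size",
          target_voxel)
  grid <- map$grid
  for (ax in 1:3) {
    if (out_dim[ax] == dim(grid)[ax] && abs(factor[ax] - 1) < 1e-12) next
    grid <- resample_axis(grid, ax, out_dim[ax], factor[ax], order)
  }
  density_map(grid, voxel_size = rep(target_voxel, 3), origin = map$origin)
}

# resample one axis of a 3-D array to n_out samples: output index i (0-based)
# reads input coordinate i/factor, clamped to the grid.
resample_axis <- function(arr, axis, n_out, factor, order) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  xin <- seq_len(d[axis]) - 1
  xout <- pmin(pmax((seq_len(n_out) - 1) / factor, 0), d[axis] - 1)
  if (d[axis] == 1) {
    out <- m[rep(1, n_out), , drop = FALSE]
  } else if (order == 1) {
    lo <- pmin(floor(xout), d[axis] - 2)
    fr <- xout - lo
    out <- m[lo + 1, , drop = FALSE] * (1 - fr) + m[lo + 2, , drop = FALSE] * fr
  } else {
    out <- apply(m, 2, function(col)
      stats::splinefun(xin, col, method = "natural")(xout))
    if (n_out == 1) out <- matrix(out, nrow = 1)
  }
  aperm(array(out, dim = c(n_out, d[perm[2:3]])), order(perm))
}

#' Derive the adaptive denoising threshold of a map
#'
#' Anchors denoising to the deposited recommended contour level: the
#' threshold t is chosen so that the contour level falls at the
#' \code{p}-quantile (default the 85th percentile) of the retained density
#' values (those >= t). With nearest-rank percentiles this has a closed
#' form: if N_above voxels lie strictly above the contour, the retained set
#' must hold k = round(N_above / (1 - p)) values, and t is the k-th largest
#' voxel value.
#'
#' Two degenerate inputs abort normalization (and drop the entry from the
#' pipeline): a contour at or above the map maximum (nothing above it), and
#' a contour below the map's own p-percentile (k would exceed the voxel
#' count).
#'
#' @param map a \code{\link{density_map}}.
#' @param contour recommended contour level, map-density units.
#' @param p anchor percentile as a fraction in (0, 1), default 0.85.
#' @return a list of class \code{"normalization_params"} with elements
#'   \code{contour}, \code{p}, \code{threshold}, \code{v_max},
#'   \code{n_above}, \code{k}.
#' @export
derive_denoise_threshold <- function(map, contour, p = 0.85) {
  stopifnot(inherits(map, "density_map"), is.finite(contour), p > 0, p < 1)
  v <- as.vector(map$grid)
  n_above <- sum(v > contour)
  if (n_above == 0)
    stopf("normalization failed: contour %.4g is at or above the map maximum %.4g",
          contour, max(v))
  k <- round_half_up(n_above / (1 - p))
  if (k > length(v))
    stopf("normalization failed: contour %.4g sits below the map's %.0f%% percentile (needs %d of %d voxels)",
          contour, 100 * p, k, length(v))
  t <- sort(v, decreasing = TRUE)[k]
  structure(list(contour = contour, p = p, threshold = t, v_max = max(v),
                 n_above = n_above, k = as.integer(k)),
            class = "normalization_params")
}

#' Denoise and normalize a map to the 0-1 range
#'
#' Voxels below the adaptive threshold are zeroed (noise removal); voxels at
#' or above it are mapped linearly onto [0, 1], with the threshold at 0 and
#' the map maximum at 1.
#'
#' @param map the \code{\link{density_map}} the parameters were derived from.
#' @param params a \code{\link{derive_denoise_threshold}} result.
#' @return a normalized \code{\link{density_map}} with values in [0, 1].
#' @export
normalize_map <- function(map, params) {
  stopifnot(inherits(map, "density_map"),
            inherits(params, "normalization_params"))
  t <- params$threshold; vmax <- params$v_max
  if (vmax <= t)
    stopf("normalization failed: flat retained set (max %.4g <= threshold %.4g)",
          vmax, t)
  g <- map$grid
  out <- ifelse(g >= t, (g - t) / (vmax - t), 0)
  density_map(array(out, dim = dim(g)), map$voxel_size, map$origin)
}

#' Resample, denoise and normalize one map
#'
#' Convenience wrapper running the conditioning chain in pipeline order:
#' resample to the target voxel size, derive the adaptive threshold from the
#' recommended contour level, then normalize to [0, 1].
#'
#' @inheritParams resample
#' @inheritParams derive_denoise_threshold
#' @return a normalized \code{\link{density_map}}.
#' @export
condition_map <- function(map, contour, target_voxel = 1.0, p = 0.85,
                          order = 3) {
  resampled <- resample(map, target_voxel, order = order)
  params <- derive_denoise_threshold(resampled, contour, p = p)
  normalize_map(resampled, params)
}
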