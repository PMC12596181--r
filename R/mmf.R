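VOF_DIRECTIONS <- c("X", "Y", "Z", "D_xy", "D_yz", "D_xz")

#' Voxelize an atomic model onto a map grid
#'
#' Marks every voxel whose center (origin + index x voxel size) lies within
#' \code{radius} Angstrom of at least one atom. Hydrogens are excluded by
#' default (occupancy of density is dominated by heavy atoms); atoms falling
#' outside the grid are skipped and counted.
#'
#' @param model an \code{"atomic_model"}, or a data frame of atoms with
#'   x/y/z columns.
#' @param frame a \code{\link{density_map}} supplying grid shape, voxel size
#'   and origin.
#' @param radius influence radius in Angstrom (> 0), default 1.5.
#' @param hydrogens include hydrogens (default FALSE).
#' @return integer 0/1 array shaped like \code{frame$grid}, with attribute
#'   \code{"skipped_atoms"}.
#' @export
voxelize_model <- function(model, frame, radius = 1.5, hydrogens = FALSE) {
  stopifnot(radius > 0, inherits(frame, "density_map"))
  atoms <- if (inherits(model, "atomic_model")) model$atoms else model
  if (!hydrogens && nrow(atoms) && "element" %in% names(atoms))
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
  vol <- array(0L, dim = dim(frame$grid))
  hits <- atom_voxel_hits(atoms, frame, radius)
  skipped <- attr(hits, "skipped_atoms")
  if (nrow(hits)) vol[unique(hits$voxel)] <- 1L
  attr(vol, "skipped_atoms") <- skipped
  vol
}

# Shared geometric kernel for voxelization and labeling: for every atom,
# enumerate the voxels whose centers lie within `radius`, returning one row
# per (atom, voxel) hit with the squared distance in Angstrom^2.
atom_voxel_hits <- function(atoms, frame, radius) {
  d <- dim(frame$grid); vs <- frame$voxel_size; org <- frame$origin
  out <- vector("list", nrow(atoms))
  skipped <- 0L
  r2 <- radius^2
  for (a in seq_len(nrow(atoms))) {
    pos <- c(atoms$x[a], atoms$y[a], atoms$z[a])
    idx <- (pos - org) / vs            # 0-based fractional grid coordinate
    if (any(idx < -radius / vs) || any(idx > d - 1 + radius / vs)) {
      skipped <- skipped + 1L
      next
    }
    lo <- pmax(ceiling(idx - radius / vs), 0)
    hi <- pmin(floor(idx + radius / vs), d - 1)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- ((ix - idx[1]) * vs[1])^2
    dy2 <- ((iy - idx[2]) * vs[2])^2
    dz2 <- ((iz - idx[3]) * vs[3])^2
    dist2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    hit <- which(dist2 <= r2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    voxel <- ix[hit[, 1]] + iy[hit[, 2]] * d[1] + iz[hit[, 3]] * d[1] * d[2] + 1
    out[[a]] <- data.frame(atom = a, voxel = voxel, dist2 = dist2[hit])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(atom = integer(0), voxel = integer(0), dist2 = numeric(0))
  attr(res, "skipped_atoms") <- skipped
  res
}

#' Project a volume to 2-D along one of six directions
#'
#' Axis projections sum voxel values along the named axis; the three
#' diagonal projections sum along discrete lines of constant (x - y, z),
#' (x, y - z) and (x - z, y) respectively (difference indices offset to be
#' non-negative), i.e. exact integer-indexed line sums with no
#' interpolation.
#'
#' @param vol 3-D numeric array.
#' @param direction one of "X", "Y", "Z", "D_xy", "D_yz", "D_xz".
#' @return 2-D numeric matrix of line sums.
#' @export
project_volume <- function(vol, direction) {
  stopifnot(is.array(vol), length(dim(vol)) == 3)
  if (!direction %in% VOF_DIRECTIONS)
    stopf("unknown projection direction '%s'", direction)
  d <- dim(vol)
  switch(direction,
    X = apply(vol, c(2, 3), sum),
    Y = apply(vol, c(1, 3), sum),
    Z = apply(vol, c(1, 2), sum),
    D_xy = {   # lines of constant (x - y, z)
      res <- matrix(0, d[1] + d[2] - 1, d[3])
      for (y in seq_len(d[2]))
        res[(seq_len(d[1])) + d[2] - y, ] <-
          res[(seq_len(d[1])) + d[2] - y, , drop = FALSE] + vol[, y, ]
      res
    },
    D_yz = {   # lines of constant (x, y - z)
      res <- matrix(0, d[1], d[2] + d[3] - 1)
      for (z in seq_len(d[3]))
        res[, (seq_len(d[2])) + d[3] - z] <-
          res[, (seq_len(d[2])) + d[3] - z, drop = FALSE] + vol[, , z]
      res
    },
    D_xz = {   # lines of constant (x - z, y)
      res <- matrix(0, d[1] + d[3] - 1, d[2])
      for (z in seq_len(d[3]))
        res[(seq_len(d[1])) + d[3] - z, ] <-
          res[(seq_len(d[1])) + d[3] - z, , drop = FALSE] + vol[, , z]
      res
    })
}

#' Intersection-over-union and Dice-like overlap of two binary images
#'
#' IoU is overlap over union; the Dice-like coefficient is overlap over the
#' summed sizes of both masks (a Dice coefficient without the factor of 2).
#' Two empty masks carry no mismatch evidence and score 1 under both;
#' exactly one empty mask scores 0.
#'
#' @param a,b binary (0/1 or logical) matrices of equal shape.
#' @return list with elements \code{iou} and \code{dice_like}.
#' @export
binary_iou <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stopf("binary_iou: shape mismatch (%s vs %s)",
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  a <- a != 0; b <- b != 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(list(iou = 1, dice_like = 1))
  if (na == 0 || nb == 0) return(list(iou = 0, dice_like = 0))
  inter <- sum(a & b)
  list(iou = inter / sum(a | b), dice_like = inter / (na + nb))
}

#' Volume Overlap Fraction of a map-model pair
#'
#' Projects the normalized map and the voxelized model along six directions
#' (three principal axes and three diagonal line-sum orientations),
#' binarizes every projection at >= 1, and computes the per-direction IoU.
#' The VOF is the mean IoU over the five lowest-scoring directions — the
#' best direction is dropped to mitigate directional bias. The companion
#' Dice-like score averages the per-direction Dice-like coefficients over
#' the same five directions. Ties for the dropped direction resolve to the
#' first in the fixed order X, Y, Z, D_xy, D_yz, D_xz.
#'
#' @param norm_map a normalized \code{\link{density_map}} (values in [0, 1]),
#'   or a plain 3-D array in the same frame.
#' @param model an \code{"atomic_model"} (voxelized at \code{radius}), or a
#'   pre-voxelized 0/1 array of matching shape.
#' @param radius voxelization radius in Angstrom, default 1.5.
#' @return list of class \code{"fitness_scores"}: per-direction \code{iou}
#'   and \code{dice_like} (named vectors), the \code{dropped} direction,
#'   \code{vof} and \code{dice_like_mean}.
#' @export
vof_score <- function(norm_map, model, radius = 1.5) {
  map_grid <- if (inherits(norm_map, "density_map")) norm_map$grid else norm_map
  model_grid <- if (is.array(model) && !inherits(model, "density_map")) model
  else voxelize_model(model,
                      if (inherits(norm_map, "density_map")) norm_map
                      else density_map(norm_map),
                      radius = radius)
  if (!identical(dim(map_grid), dim(model_grid)))
    stopf("vof_score: map and model volumes differ in shape")
  ious <- stats::setNames(numeric(6), VOF_DIRECTIONS)
  dices <- ious
  for (dr in VOF_DIRECTIONS) {
    pa <- project_volume(map_grid, dr) >= 1
    pb <- project_volume(model_grid, dr) >= 1
    sc <- binary_iou(pa, pb)
    ious[dr] <- sc$iou
    dices[dr] <- sc$dice_like
  }
  drop <- which.max(ious)    # first index wins ties
  keep <- setdiff(seq_along(ious), drop)
  structure(list(iou = ious, dice_like = dices,
                 dropped = VOF_DIRECTIONS[drop],
                 vof = mean(ious[keep]),
                 dice_like_mean = mean(dices[keep])),
            class = "fitness_scores")
}

#' @export
print.fitness_scores <- function(x, ...) {
  cat(sprintf("<fitness_scores> VOF = %.4f (dropped %s), dice-like = %.4f\n",
              x$vof, x$dropped, x$dice_like_mean))
  print(round(x$iou, 4))
  invisible(x)
}

#' Map-model fitness validation over a batch of pairs
#'
#' Scores every (map, model) pair with \code{\link{vof_score}} and discards
#' pairs whose VOF falls strictly below \code{threshold}; scores are
#' recorded for all pairs in the report.
#'
#' @param pairs list of lists with elements \code{map} (normalized density
#'   map), \code{model} (atomic model or 0/1 array) and \code{emdb_id}.
#' @param threshold minimum acceptable VOF in [0, 1], default 0.82.
#' @param radius voxelization radius in Angstrom.
#' @return list with \code{kept} (surviving pairs) and \code{report} (a
#'   curation report whose \code{scores} element tabulates VOF and
#'   Dice-like scores per pair).
#' @export
validate_pairs <- function(pairs, threshold = 0.82, radius = 1.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  scores <- lapply(pairs, function(p) vof_score(p$map, p$model, radius = radius))
  vofs <- vapply(scores, `[[`, numeric(1), "vof")
  ids <- vapply(pairs, function(p) p$emdb_id %||% "?", character(1))
  score_tab <- data.frame(
    emdb_id = ids, vof = vofs,
    dice_like = vapply(scores, `[[`, numeric(1), "dice_like_mean"),
    pass = vofs >= threshold, stringsAsFactors = FALSE)
  fail <- which(vofs < threshold)
  rep <- curation_report(
    "mmf", length(pairs),
    discarded = data.frame(
      emdb_id = ids[fail],
      reason = sprintf("VOF %.3f below threshold %.2f", vofs[fail], threshold),
      stringsAsFactors = FALSE),
    scores = score_tab)
  list(kept = pairs[setdiff(seq_along(pairs), fail)], report = rep)
}
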