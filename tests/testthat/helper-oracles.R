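# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain loops and exhaustive scans only.

# Adaptive-threshold oracle: scan every distinct voxel value as a candidate
# threshold and return the one whose retained set holds the contour closest
# to the (1 - p) "above" fraction. Ties resolve to the larger retained set.
oracle_denoise_threshold <- function(values, contour, p = 0.85) {
  n_above <- sum(values > contour)
  stopifnot(n_above > 0)
  cand <- sort(unique(values), decreasing = TRUE)
  best_t <- NA_real_
  best_err <- Inf
  for (t in cand) {
    retained <- values[values >= t]
    err <- abs(n_above / length(retained) - (1 - p))
    if (err < best_err) {
      best_err <- err
      best_t <- t
    }
  }
  best_t
}

# nearest-rank percentile (ceiling convention on the ascending sort)
nearest_rank_percentile <- function(values, p) {
  s <- sort(values)
  s[max(1L, ceiling(p * length(s)))]
}

# VOF oracle: voxel-by-voxel loops accumulating each of the six line-sum
# projections, then pixel-count loops for IoU / Dice-like.
oracle_projection <- function(vol, direction) {
  d <- dim(vol)
  res <- switch(direction,
                X = matrix(0, d[2], d[3]),
                Y = matrix(0, d[1], d[3]),
                Z = matrix(0, d[1], d[2]),
                D_xy = matrix(0, d[1] + d[2] - 1, d[3]),
                D_yz = matrix(0, d[1], d[2] + d[3] - 1),
                D_xz = matrix(0, d[1] + d[3] - 1, d[2]))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- vol[x, y, z]
    switch(direction,
           X = res[y, z] <- res[y, z] + v,
           Y = res[x, z] <- res[x, z] + v,
           Z = res[x, y] <- res[x, y] + v,
           D_xy = res[x - y + d[2], z] <- res[x - y + d[2], z] + v,
           D_yz = res[x, y - z + d[3]] <- res[x, y - z + d[3]] + v,
           D_xz = res[x - z + d[3], y] <- res[x - z + d[3], y] + v)
  }
  res
}

oracle_iou <- function(a, b) {
  a <- a >= 1; b <- b >= 1
  inter <- 0; uni <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
  }
  if (na == 0 && nb == 0) return(c(iou = 1, dice = 1))
  if (na == 0 || nb == 0) return(c(iou = 0, dice = 0))
  c(iou = inter / uni, dice = inter / (na + nb))
}

oracle_vof <- function(map_grid, model_grid) {
  dirs <- c("X", "Y", "Z", "D_xy", "D_yz", "D_xz")
  ious <- numeric(6); dices <- numeric(6)
  for (k in seq_along(dirs)) {
    sc <- oracle_iou(oracle_projection(map_grid, dirs[k]),
                     oracle_projection(model_grid, dirs[k]))
    ious[k] <- sc["iou"]; dices[k] <- sc["dice"]
  }
  drop <- which.max(ious)
  list(iou = ious, vof = mean(ious[-drop]), dice_like = mean(dices[-drop]))
}

# Labeling oracle: triple loop over voxels x atoms; nearest atom within the
# radius wins, earlier file order on exact distance ties.
oracle_label_volume <- function(atoms, dim3, voxel_size, origin, radius) {
  out <- array(0L, dim = dim3)
  for (ix in 1:dim3[1]) for (iy in 1:dim3[2]) for (iz in 1:dim3[3]) {
    center <- origin + (c(ix, iy, iz) - 1) * voxel_size
    best <- Inf; lab <- 0L
    for (a in seq_len(nrow(atoms))) {
      d <- sqrt(sum((center - c(atoms$x[a], atoms$y[a], atoms$z[a]))^2))
      if (d <= radius && d < best) {
        best <- d; lab <- atoms$label[a]
      }
    }
    out[ix, iy, iz] <- lab
  }
  out
}

# Metrics oracle: per-voxel tally loops.
oracle_confusion <- function(pred, truth, label) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == label && truth[i] == label) tp <- tp + 1
    else if (pred[i] == label) fp <- fp + 1
    else if (truth[i] == label) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# brute-force max pairwise similarity among retained entries
max_retained_similarity <- function(tab, method = "containment") {
  n <- nrow(tab)
  if (n < 2) return(0)
  mx <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    mx <- max(mx, xref_similarity(xref_set(tab, i), xref_set(tab, j), method))
  }
  mx
}

# tiny helper: total accounted entries of a report stage
stage_accounts <- function(st) {
  st$n_retained + nrow(st$discarded) + length(st$flagged)
}
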