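#' Label specification
#'
#' An ordered list of (selection rule, label value) pairs plus the labeling
#' radius. Label values are distinct positive integers; 0 is reserved for
#' background.
#'
#' @param rules list of \code{\link{selection_rule}} objects.
#' @param values integer label value per rule (distinct, >= 1).
#' @param radius labeling radius in Angstrom (> 0), default 1.5. The radius
#'   controls how far an atom's influence extends; it should be large enough
#'   to cover the feature of interest without making neighbouring features
#'   overlap.
#' @return an object of class \code{"label_spec"}.
#' @export
label_spec <- function(rules, values, radius = 1.5) {
  stopifnot(length(rules) == length(values), radius > 0)
  values <- as.integer(values)
  if (length(values) && (any(values < 1) || anyDuplicated(values)))
    stopf("label values must be distinct positive integers")
  if (!all(vapply(rules, inherits, logical(1), "selection_rule")))
    stopf("rules must be selection_rule objects")
  structure(list(rules = rules, values = values, radius = radius),
            class = "label_spec")
}

#' Build a voxel label volume from an atomic model
#'
#' Initializes an integer volume matching the map grid and assigns every
#' voxel whose center lies within the labeling radius of at least one
#' selected atom the label of the \emph{nearest} such atom (conflicts
#' between rules are resolved globally by distance, not rule priority).
#' Exact distance ties are broken deterministically in favour of the atom
#' earlier in file order. Voxels near no selected atom stay 0.
#'
#' @param model an \code{"atomic_model"}.
#' @param frame the paired \code{\link{density_map}} (shape, voxel size,
#'   origin).
#' @param spec a \code{\link{label_spec}}.
#' @return integer array of labels shaped like \code{frame$grid}, with
#'   attribute \code{"skipped_atoms"}.
#' @export
build_label_volume <- function(model, frame, spec) {
  stopifnot(inherits(spec, "label_spec"), inherits(frame, "density_map"))
  labels <- array(0L, dim = dim(frame$grid))
  best <- array(Inf, dim = dim(frame$grid))
  skipped <- 0L
  # pool selected atoms across rules, tagged with their rule's label value,
  # keeping file order within and across rules for deterministic ties
  pool <- list()
  for (k in seq_along(spec$rules)) {
    sel <- select_atoms(model, spec$rules[[k]])
    if (nrow(sel)) {
      sel$label <- spec$values[k]
      pool[[length(pool) + 1]] <- sel
    }
  }
  if (!length(pool)) {
    if (length(spec$rules)) warnf("no selected atoms inside the frame; label volume is all zero")
    attr(labels, "skipped_atoms") <- 0L
    return(labels)
  }
  atoms <- do.call(rbind, pool)
  atoms <- atoms[order(atoms$file_order), , drop = FALSE]
  hits <- atom_voxel_hits(atoms, frame, spec$radius)
  skipped <- attr(hits, "skipped_atoms")
  # process in file order: strict < keeps the earlier atom on exact ties
  for (r in seq_len(nrow(hits))) {
    v <- hits$voxel[r]
    if (hits$dist2[r] < best[v]) {
      best[v] <- hits$dist2[r]
      labels[v] <- atoms$label[hits$atom[r]]
    }
  }
  if (all(labels == 0L))
    warnf("no selected atoms inside the frame; label volume is all zero")
  attr(labels, "skipped_atoms") <- skipped
  labels
}

#' Partition a map/label pair into cubic subvolumes
#'
#' Cuts patches of \code{patch}^3 voxels with corners at multiples of
#' \code{stride}, covering the full volume (per-axis patch count =
#' ceiling(dim / stride)); regions extending past the volume are
#' zero-padded. Map and label grids are cut identically.
#'
#' @param map a \code{\link{density_map}}.
#' @param labels integer label array of the same shape.
#' @param patch cube edge in voxels (default 64).
#' @param stride corner spacing in voxels (default = patch; smaller values
#'   give overlapping patches).
#' @return list of records, each with \code{corner} (0-based voxel triple),
#'   \code{patch}, \code{map} and \code{labels} arrays, and \code{split}
#'   (NA until \code{\link{split_dataset}}).
#' @export
partition_volume <- function(map, labels = NULL, patch = 64L, stride = patch) {
  stopifnot(inherits(map, "density_map"))
  patch <- as.integer(patch); stride <- as.integer(stride)
  if (stride <= 0 || stride > patch)
    stopf("partition: need 0 < stride <= patch")
  d <- dim(map$grid)
  if (!is.null(labels) && !identical(dim(labels), d))
    stopf("partition: label shape differs from map shape")
  counts <- ceiling(d / stride)
  cut_patch <- function(grid, corner, fill) {
    out <- array(fill, dim = rep(patch, 3))
    from <- corner + 1
    to <- pmin(corner + patch, d)
    span <- to - from + 1
    if (all(span > 0))
      out[seq_len(span[1]), seq_len(span[2]), seq_len(span[3])] <-
        grid[from[1]:to[1], from[2]:to[2], from[3]:to[3]]
    out
  }
  records <- list()
  for (iz in seq_len(counts[3]) - 1) for (iy in seq_len(counts[2]) - 1)
    for (ix in seq_len(counts[1]) - 1) {
      corner <- c(ix, iy, iz) * stride
      rec <- list(corner = corner, patch = patch,
                  map = cut_patch(map$grid, corner, 0),
                  labels = if (!is.null(labels))
                    cut_patch(labels, corner, 0L),
                  split = NA_character_)
      records[[length(records) + 1]] <- rec
    }
  records
}

#' Stitch stride = patch subvolumes back into one volume
#'
#' Inverse of \code{\link{partition_volume}} for non-overlapping patches;
#' returns the zero-padded volume (dimensions rounded up to a multiple of
#' the patch size).
#'
#' @param records partition records (stride = patch).
#' @param what "map" or "labels".
#' @return 3-D array.
#' @export
stitch_subvolumes <- function(records, what = c("map", "labels")) {
  what <- match.arg(what)
  patch <- records[[1]]$patch
  corners <- t(vapply(records, `[[`, numeric(3), "corner"))
  full <- apply(corners, 2, max) + patch
  out <- array(if (what == "labels") 0L else 0, dim = full)
  for (rec in records) {
    idx <- Map(function(c0) (c0 + 1):(c0 + patch), rec$corner)
    out[idx[[1]], idx[[2]], idx[[3]]] <- rec[[what]]
  }
  out
}

#' Assign subvolume records to train/validation/test splits
#'
#' Shuffles deterministically under \code{seed} and assigns splits so that
#' realized counts match the target ratios to within one unit (largest-
#' remainder apportionment). At \code{"entry"} granularity whole entries are
#' assigned to a single split (no leakage of one structure across splits);
#' at \code{"subvolume"} granularity patches are assigned independently.
#'
#' @param records list of records, each carrying an \code{entry} id (entry
#'   granularity) — as produced by the build stage.
#' @param ratios length-3 non-negative numeric (train, val, test) summing
#'   to 1.
#' @param granularity "entry" (default) or "subvolume".
#' @param seed integer seed fixing the shuffle.
#' @return the records with \code{split} set to "train"/"val"/"test".
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.2, 0),
                          granularity = c("entry", "subvolume"), seed = 1L) {
  granularity <- match.arg(granularity)
  if (length(ratios) != 3 || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stopf("split ratios must be 3 non-negative numbers summing to 1")
  splits <- c("train", "val", "test")
  apportion <- function(n) {
    quota <- n * ratios
    base <- floor(quota)
    extra <- n - sum(base)
    if (extra > 0) {
      ord <- order(quota - base, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
    }
    base
  }
  units <- if (granularity == "entry") {
    ids <- vapply(records, function(r) r$entry %||% "?", character(1))
    unique(ids)
  } else seq_along(records)
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    p <- sample(length(units))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    p
  })
  shuffled <- units[perm]
  counts <- apportion(length(units))
  unit_split <- rep(splits, counts)  # aligned with shuffled order
  names(unit_split) <- as.character(shuffled)
  for (i in seq_along(records)) {
    key <- if (granularity == "entry") records[[i]]$entry %||% "?" else i
    records[[i]]$split <- unit_split[[as.character(key)]]
  }
  records
}
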