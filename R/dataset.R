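#' Write a partitioned, split dataset to disk
#'
#' Serializes every subvolume as a pair of NPY arrays (map as float32,
#' labels as int32) under \code{train/}, \code{val/} or \code{test/}
#' according to each record's split, and writes a manifest CSV listing
#' entry, corner, patch size, split and the two array paths for every
#' record. Re-reading the manifest reproduces the records.
#'
#' @param records split-assigned records from \code{\link{split_dataset}}
#'   (each carrying \code{entry}, \code{corner}, \code{patch}, \code{map},
#'   \code{labels}, \code{split}).
#' @param out_dir output directory (created if missing).
#' @return the manifest CSV path, invisibly.
#' @export
write_dataset <- function(records, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create dataset directory %s", out_dir)
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    split <- rec$split %||% "train"
    if (is.na(split)) split <- "train"
    sub <- file.path(out_dir, split)
    dir.create(sub, showWarnings = FALSE)
    stem <- sprintf("%s_%04d_%04d_%04d", rec$entry %||% "entry",
                    rec$corner[1], rec$corner[2], rec$corner[3])
    map_path <- file.path(sub, paste0(stem, "_map.npy"))
    lab_path <- file.path(sub, paste0(stem, "_label.npy"))
    write_npy(rec$map, map_path, dtype = "<f4")
    write_npy(if (is.null(rec$labels)) array(0L, dim(rec$map)) else rec$labels,
              lab_path, dtype = "<i4")
    rows[[i]] <- data.frame(
      entry = rec$entry %||% "entry", split = split,
      corner_x = rec$corner[1], corner_y = rec$corner[2],
      corner_z = rec$corner[3], patch = rec$patch,
      map_path = map_path, label_path = lab_path, stringsAsFactors = FALSE)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows) %||%
                     data.frame(entry = character(0)), manifest,
                   row.names = FALSE)
  invisible(manifest)
}

#' Re-read a dataset manifest
#'
#' Loads the manifest CSV written by \code{\link{write_dataset}} and, when
#' \code{arrays = TRUE}, the subvolume arrays it references (corrupt or
#' truncated array files raise an error).
#'
#' @param manifest_path path to \code{manifest.csv}.
#' @param arrays also load map/label arrays (default TRUE).
#' @return list of records mirroring the written ones.
#' @export
read_dataset <- function(manifest_path, arrays = TRUE) {
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    rec <- list(entry = df$entry[i], split = df$split[i],
                corner = c(df$corner_x[i], df$corner_y[i], df$corner_z[i]),
                patch = df$patch[i],
                map_path = df$map_path[i], label_path = df$label_path[i])
    if (arrays) {
      rec$map <- read_npy(df$map_path[i])
      rec$labels <- read_npy(df$label_path[i])
    }
    rec
  })
}
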