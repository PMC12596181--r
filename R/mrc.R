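#' Density map container
#'
#' A 3-D voxel grid of cryoEM density with the geometric metadata needed to
#' place it in the model's coordinate frame: per-axis voxel size and the
#' Angstrom offset of the first grid point.
#'
#' @param grid 3-D numeric array (all values finite).
#' @param voxel_size length-3 positive numeric, Angstrom per voxel along
#'   x, y, z (a scalar is recycled).
#' @param origin length-3 numeric, Angstrom position of grid point (1,1,1).
#' @return an object of class \code{"density_map"}.
#' @export
density_map <- function(grid, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!all(is.finite(grid))) stopf("density_map: grid values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stopf("density_map: voxel sizes must be positive")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.3g/%.3g/%.3g A, origin (%.3g, %.3g, %.3g) A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

mrc_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read an MRC2014 density map
#'
#' Reads plain or gzipped MRC2014 files. Voxel size is cell length divided
#' by the sampling count per axis; the origin comes from the ORIGIN header
#' words, falling back to NXSTART-based offsets when ORIGIN is all zero.
#' Non-standard axis orders (MAPC/MAPR/MAPS) are permuted to x, y, z.
#'
#' @param path an \code{.mrc}/\code{.map} file, optionally \code{.gz}.
#' @return a \code{\link{density_map}}.
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stopf("no such map file: %s", path)
  con <- mrc_connection(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  # re-read float words from the raw header
  seek_ok <- !grepl("\\.gz$", path)
  # floats occupy words 11..16 (cell), 20..22 (stats), 50..52 (origin), 55 (rms)
  raw_hdr <- writeBin(hdr_int, raw(), size = 4, endian = "little")
  flt <- function(w) readBin(raw_hdr[((w - 1) * 4 + 1):(w * 4)], "numeric",
                             size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  nstart <- hdr_int[5:7]
  m_samp <- hdr_int[8:10]
  cella <- vapply(11:13, flt, numeric(1))
  mapcrs <- hdr_int[17:19]
  map_tag <- rawToChar(raw_hdr[((53 - 1) * 4 + 1):(53 * 4)])
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stopf("malformed MRC header in %s: non-positive dimensions", path)
  if (!mode %in% c(0, 1, 2))
    stopf("unsupported MRC mode %d in %s (only modes 0/1/2)", mode, path)
  if (map_tag != "MAP ")
    stopf("malformed MRC header in %s: missing 'MAP ' tag", path)
  if (any(m_samp <= 0)) m_samp <- c(nx, ny, nz)
  nsymbt <- hdr_int[24]
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  n <- as.numeric(nx) * ny * nz
  vals <- switch(as.character(mode),
                 "0" = as.numeric(readBin(con, "integer", n = n, size = 1,
                                          signed = TRUE)),
                 "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                                          signed = TRUE, endian = "little")),
                 "2" = readBin(con, "numeric", n = n, size = 4,
                               endian = "little"))
  if (length(vals) != n)
    stopf("MRC payload in %s holds %d values but header promises %d",
          path, length(vals), n)
  grid <- array(vals, dim = c(nx, ny, nz))
  # permute from file axis order (columns/rows/sections) to x,y,z
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    if (!setequal(mapcrs, 1:3))
      stopf("malformed MRC header in %s: MAPC/MAPR/MAPS = %s", path,
            paste(mapcrs, collapse = ","))
    grid <- aperm(grid, order(mapcrs))
    nstart <- nstart[order(mapcrs)]
  }
  voxel <- cella / m_samp
  origin <- vapply(50:52, flt, numeric(1))
  if (all(origin == 0) && any(nstart != 0)) origin <- nstart * voxel
  density_map(grid, voxel_size = voxel, origin = origin)
}

#' Write a density map as MRC2014
#'
#' Writes 32-bit float data (mode 2) in x,y,z axis order with the voxel size
#' encoded as cell length / grid samples and the origin in the ORIGIN header
#' words. A \code{.gz} suffix gzips the output transparently.
#'
#' @param map a \code{\link{density_map}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  hdr <- raw(1024)
  put_int <- function(w, v) {
    hdr[((w - 1) * 4 + 1):(w * 4)] <<- writeBin(as.integer(v), raw(), size = 4,
                                                endian = "little")
  }
  put_flt <- function(w, v) {
    hdr[((w - 1) * 4 + 1):(w * 4)] <<- writeBin(as.numeric(v), raw(), size = 4,
                                                endian = "little")
  }
  put_int(1, d[1]); put_int(2, d[2]); put_int(3, d[3])
  put_int(4, 2)                       # mode 2: float32
  put_int(8, d[1]); put_int(9, d[2]); put_int(10, d[3])
  for (k in 1:3) put_flt(10 + k, d[k] * map$voxel_size[k])   # cell lengths
  for (k in 1:3) put_flt(13 + k, 90)                          # cell angles
  put_int(17, 1); put_int(18, 2); put_int(19, 3)
  put_flt(20, min(map$grid)); put_flt(21, max(map$grid))
  put_flt(22, mean(map$grid))
  put_int(23, 1)                      # ISPG: 3-D volume
  put_int(28, 20140)                  # NVERSION
  for (k in 1:3) put_flt(49 + k, map$origin[k])
  hdr[((53 - 1) * 4 + 1):(53 * 4)] <- charToRaw("MAP ")
  hdr[((54 - 1) * 4 + 1):((54 - 1) * 4 + 2)] <- as.raw(c(0x44, 0x41))
  put_flt(55, stats::sd(as.vector(map$grid)))
  con <- mrc_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(as.numeric(as.vector(map$grid)), con, size = 4, endian = "little")
  invisible(path)
}
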