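#' Minimal NPY array I/O
#'
#' Writes and reads NumPy \code{.npy} files (format version 1.0, C order,
#' little endian) for the dtypes the dataset layer needs: float32
#' (\code{"<f4"}), float64 (\code{"<f8"}) and int32 (\code{"<i4"}).
#'
#' @param arr numeric or integer array.
#' @param path output path.
#' @param dtype one of "<f4", "<f8", "<i4"; default float32 for doubles and
#'   int32 for integers.
#' @return \code{write_npy} returns \code{path} invisibly; \code{read_npy}
#'   returns the array with its original dimensions.
#' @export
write_npy <- function(arr, path, dtype = NULL) {
  if (is.null(dim(arr))) dim(arr) <- length(arr)
  if (is.null(dtype)) dtype <- if (is.integer(arr)) "<i4" else "<f4"
  stopifnot(dtype %in% c("<f4", "<f8", "<i4"))
  shape <- paste0("(", paste(dim(arr), collapse = ", "),
                  if (length(dim(arr)) == 1) "," else "", ")")
  dict <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                  dtype, shape)
  # pad so that magic(6) + version(2) + headerlen(2) + dict is a multiple of 64
  pad <- 64 - ((10 + nchar(dict) + 1) %% 64)
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- as.vector(aperm(arr, rev(seq_along(dim(arr)))))   # C order
  if (dtype == "<i4") writeBin(as.integer(vals), con, size = 4, endian = "little")
  else writeBin(as.numeric(vals), con, size = if (dtype == "<f4") 4 else 8,
                endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stopf("%s is not an NPY file", path)
  hlen <- readBin(con, "integer", size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_txt <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(scan(text = gsub(",", " ", shape_txt), quiet = TRUE))
  n <- prod(shape)
  vals <- switch(descr,
                 "<f4" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
                 "<f8" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
                 "<i4" = readBin(con, "integer", n = n, size = 4, endian = "little"),
                 "<i8" = readBin(con, "integer", n = n, size = 8, endian = "little"),
                 stopf("unsupported NPY dtype %s in %s", descr, path))
  if (length(vals) != n)
    stopf("truncated NPY payload in %s (%d of %d values)", path, length(vals), n)
  arr <- if (fortran) array(vals, dim = shape)
  else aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  arr
}
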