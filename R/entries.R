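#' Construct a metadata table of EMDB entries
#'
#' A metadata table holds one row per EMDB entry with the fields the curation
#' pipeline consumes: accession, title, resolution, fitted PDB ID, Q-score,
#' atom inclusion, recommended contour level, and UniProtKB / AlphaFold
#' cross-reference sets (stored as \code{";"}-joined accession strings).
#'
#' @param emdb_id character vector of EMDB accessions ("EMD-" + digits);
#'   must be non-empty and unique.
#' @param title entry titles.
#' @param resolution reported resolution in Angstrom (positive; smaller is
#'   better).
#' @param pdb_id 4-character fitted PDB accession, or \code{NA} when absent.
#' @param q_score deposited Q-score (atom resolvability; 1 = perfect fit), or
#'   \code{NA}.
#' @param atom_inclusion percent of fitted atoms inside the density, or
#'   \code{NA}.
#' @param contour_level recommended contour level in map-density units, or
#'   \code{NA}.
#' @param xrefs_uniprot,xrefs_alphafold \code{";"}-joined accession sets
#'   (\code{""} for none).
#' @param provenance free-text provenance (query string or fixture path).
#' @return A data frame of class \code{"metadata_table"}.
#' @export
metadata_table <- function(emdb_id, title = "", resolution = NA_real_,
                           pdb_id = NA_character_, q_score = NA_real_,
                           atom_inclusion = NA_real_,
                           contour_level = NA_real_,
                           xrefs_uniprot = "", xrefs_alphafold = "",
                           provenance = "constructed") {
  tab <- data.frame(
    emdb_id = as.character(emdb_id),
    title = as.character(title),
    resolution = as.numeric(resolution),
    pdb_id = as.character(pdb_id),
    q_score = as.numeric(q_score),
    atom_inclusion = as.numeric(atom_inclusion),
    contour_level = as.numeric(contour_level),
    xrefs_uniprot = as.character(xrefs_uniprot),
    xrefs_alphafold = as.character(xrefs_alphafold),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(tab$emdb_id)) || anyNA(tab$emdb_id))
    stopf("every entry needs a non-empty emdb_id")
  if (anyDuplicated(tab$emdb_id))
    stopf("duplicate emdb_id in metadata table: %s",
          paste(unique(tab$emdb_id[duplicated(tab$emdb_id)]), collapse = ", "))
  bad <- !is.na(tab$resolution) & tab$resolution <= 0
  if (any(bad)) stopf("non-positive resolution for %s", tab$emdb_id[bad][1])
  # deduplicate accession sets in place
  tab$xrefs_uniprot <- vapply(tab$xrefs_uniprot,
                              function(x) join_accessions(split_accessions(x)),
                              character(1), USE.NAMES = FALSE)
  tab$xrefs_alphafold <- vapply(tab$xrefs_alphafold,
                                function(x) join_accessions(split_accessions(x)),
                                character(1), USE.NAMES = FALSE)
  attr(tab, "provenance") <- provenance
  attr(tab, "retrieved") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  class(tab) <- c("metadata_table", "data.frame")
  tab
}

as_metadata_table <- function(df, provenance = "constructed") {
  if (nrow(df) == 0) return(empty_metadata_table(provenance))
  do.call(metadata_table, c(as.list(df[intersect(names(df), c(
    "emdb_id", "title", "resolution", "pdb_id", "q_score",
    "atom_inclusion", "contour_level", "xrefs_uniprot", "xrefs_alphafold"
  ))]), list(provenance = provenance)))
}

empty_metadata_table <- function(provenance = "constructed") {
  tab <- metadata_table("EMD-0")[0, ]
  attr(tab, "provenance") <- provenance
  class(tab) <- c("metadata_table", "data.frame")
  tab
}

# subset rows, keeping class and provenance
mt_subset <- function(tab, keep) {
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(tab, "provenance")
  class(out) <- c("metadata_table", "data.frame")
  out
}

#' Merged cross-reference set of one entry
#'
#' UniProtKB and AlphaFold accessions are pooled into one deduplicated set
#' (AlphaFold cross-references are UniProt-derived, so the two namespaces
#' describe the same protein content). Set \code{namespace} to compare one
#' namespace at a time.
#'
#' @param tab a metadata table.
#' @param i row index.
#' @param namespace "merged" (default), "uniprot" or "alphafold".
#' @return character vector of accessions (possibly empty).
#' @export
xref_set <- function(tab, i, namespace = c("merged", "uniprot", "alphafold")) {
  namespace <- match.arg(namespace)
  up <- split_accessions(tab$xrefs_uniprot[i])
  af <- split_accessions(tab$xrefs_alphafold[i])
  switch(namespace, merged = unique(c(up, af)), uniprot = up, alphafold = af)
}

#' Write / read a metadata table as CSV
#'
#' One row per entry; set-valued fields serialized as \code{";"}-joined
#' accessions.
#'
#' @param tab a metadata table.
#' @param path CSV path.
#' @return \code{write_metadata_csv} returns \code{path} invisibly;
#'   \code{read_metadata_csv} returns a metadata table.
#' @export
write_metadata_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(emdb_id = "character",
                                       pdb_id = "character",
                                       title = "character"))
  for (col in c("pdb_id", "title", "xrefs_uniprot", "xrefs_alphafold")) {
    if (!col %in% names(df)) df[[col]] <- ""
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$pdb_id[!nzchar(df$pdb_id)] <- NA_character_
  as_metadata_table(df, provenance = path)
}

#' @export
print.metadata_table <- function(x, ...) {
  cat(sprintf("<metadata_table> %d entries (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "?"))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more\n", nrow(x) - 10))
  invisible(x)
}
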