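#' Retrieve EMDB entry metadata
#'
#' Searches the EMDB for entries matching a query in EMDB's native search
#' syntax (e.g. \code{"ribosome AND resolution:[3 TO 4]"}) and returns one
#' entry per record. In \code{"offline"} mode the response is read from a
#' previously serialized JSON cache instead of the network, which keeps every
#' downstream stage testable without downloads.
#'
#' Each JSON record carries the fields \code{emdb_id}, \code{title},
#' \code{resolution}, \code{fitted_pdbs} (array), \code{q_score},
#' \code{atom_inclusion}, \code{contour_level}, \code{xrefs_uniprot} and
#' \code{xrefs_alphafold} (arrays). When a record lists several fitted PDB
#' IDs, only the first is retained for downstream processing.
#'
#' @param query non-empty EMDB search string.
#' @param mode "offline" (read \code{cache}) or "online" (query the EMDB
#'   REST search API over HTTPS).
#' @param cache path to a JSON cache file (offline mode), or a directory
#'   where the online response is cached.
#' @param retries bounded retry count for online retrieval.
#' @return a \code{\link{metadata_table}} with provenance recorded.
#' @export
fetch_entries <- function(query, mode = c("offline", "online"), cache = NULL,
                          retries = 3) {
  mode <- match.arg(mode)
  if (!nzchar(query)) stopf("fetch_entries: query must be non-empty")
  if (mode == "offline") {
    if (is.null(cache) || !file.exists(cache))
      stopf("offline mode requires an existing cache path")
    records <- tryCatch(jsonlite::fromJSON(cache, simplifyVector = FALSE),
                        error = function(e)
                          stopf("malformed metadata cache '%s': %s", cache,
                                conditionMessage(e)))
    provenance <- sprintf("offline:%s query=%s", cache, query)
  } else {
    url <- paste0("https://www.ebi.ac.uk/emdb/api/search/",
                  utils::URLencode(query, reserved = TRUE),
                  "?rows=1000000&format=json")
    records <- NULL
    for (k in seq_len(max(1, retries))) {
      records <- tryCatch(jsonlite::fromJSON(url, simplifyVector = FALSE),
                          error = function(e) NULL)
      if (!is.null(records)) break
      Sys.sleep(min(2^k, 10))
    }
    if (is.null(records))
      stopf("EMDB retrieval failed after %d attempts: %s", retries, url)
    if (!is.null(cache)) {
      dir.create(cache, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(records, file.path(cache, "response.json"),
                           auto_unbox = TRUE)
    }
    provenance <- sprintf("online:EMDB query=%s", query)
  }
  parse_emdb_records(records, provenance)
}

# turn a list of EMDB-like records into a metadata table; fails closed on a
# malformed record (no partial table).
parse_emdb_records <- function(records, provenance) {
  if (!is.list(records)) stopf("metadata cache is not a JSON array of records")
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (!is.list(r) || is.null(r$emdb_id))
      stopf("malformed metadata record %d: no emdb_id", i)
    pdbs <- unlist(r$fitted_pdbs)
    data.frame(
      emdb_id = as.character(r$emdb_id),
      title = as.character(r$title %||% ""),
      resolution = as.numeric(r$resolution %||% NA_real_),
      # when several fitted models are listed, only the first is kept
      pdb_id = if (length(pdbs)) as.character(pdbs[[1]]) else NA_character_,
      q_score = as.numeric(r$q_score %||% NA_real_),
      atom_inclusion = as.numeric(r$atom_inclusion %||% NA_real_),
      contour_level = as.numeric(r$contour_level %||% NA_real_),
      xrefs_uniprot = join_accessions(as.character(unlist(r$xrefs_uniprot))),
      xrefs_alphafold = join_accessions(as.character(unlist(r$xrefs_alphafold))),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(empty_metadata_table(provenance))
  as_metadata_table(df, provenance = provenance)
}
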