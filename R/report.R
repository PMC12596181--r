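#' Curation reports
#'
#' Every filtering stage of the pipeline returns, alongside the surviving
#' table, a curation report: per stage, the input count, the retained count,
#' the discarded entry IDs with a reason each, and the flagged entry IDs
#' (entries set aside for optional manual review rather than rejected).
#' The accounting invariant \code{retained + discarded + flagged = input}
#' holds for every stage.
#'
#' @param stage stage name.
#' @param n_input number of entries entering the stage.
#' @param discarded data frame with columns \code{emdb_id}, \code{reason}
#'   (zero rows allowed).
#' @param flagged character vector of flagged entry IDs.
#' @param scores optional per-entry score table attached by the stage (e.g.
#'   map-model fitness scores).
#' @return An object of class \code{"curation_report"}.
#' @export
curation_report <- function(stage, n_input, discarded = NULL, flagged = character(0),
                            scores = NULL) {
  if (is.null(discarded))
    discarded <- data.frame(emdb_id = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("emdb_id", "reason") %in% names(discarded)))
  st <- list(stage = stage, n_input = as.integer(n_input),
             n_retained = as.integer(n_input - nrow(discarded) - length(flagged)),
             discarded = discarded, flagged = as.character(flagged),
             scores = scores)
  if (st$n_retained < 0)
    stopf("stage '%s': discarded + flagged exceed input", stage)
  structure(list(stages = list(st)), class = "curation_report")
}

#' Concatenate curation reports stage-by-stage
#' @param ... curation reports (in pipeline order).
#' @return a combined \code{curation_report}.
#' @export
c.curation_report <- function(...) {
  reps <- list(...)
  structure(list(stages = do.call(c, lapply(reps, `[[`, "stages"))),
            class = "curation_report")
}

#' Summarize a curation report as one row per stage
#' @param object a curation report.
#' @param ... unused.
#' @return data frame with stage, input, retained, discarded, flagged counts.
#' @export
summary.curation_report <- function(object, ...) {
  do.call(rbind, lapply(object$stages, function(st) data.frame(
    stage = st$stage, n_input = st$n_input, n_retained = st$n_retained,
    n_discarded = nrow(st$discarded), n_flagged = length(st$flagged),
    stringsAsFactors = FALSE
  )))
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  print(summary(x))
  invisible(x)
}

#' Write a curation report to CSV (one row per discarded/flagged entry)
#' @param report a curation report.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_report_csv <- function(report, path) {
  rows <- do.call(rbind, lapply(report$stages, function(st) {
    rbind(
      if (nrow(st$discarded))
        data.frame(stage = st$stage, emdb_id = st$discarded$emdb_id,
                   status = "discarded", reason = st$discarded$reason,
                   stringsAsFactors = FALSE),
      if (length(st$flagged))
        data.frame(stage = st$stage, emdb_id = st$flagged,
                   status = "flagged", reason = "flagged for manual review",
                   stringsAsFactors = FALSE)
    )
  }))
  if (is.null(rows))
    rows <- data.frame(stage = character(0), emdb_id = character(0),
                       status = character(0), reason = character(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

report_discarded_ids <- function(report) {
  unlist(lapply(report$stages, function(st) st$discarded$emdb_id),
         use.names = FALSE)
}
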