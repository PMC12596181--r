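#' Cross-reference overlap between two entries
#'
#' Redundancy between deposited structures is proxied by the overlap of their
#' UniProtKB/AlphaFold cross-reference sets: the more annotated protein
#' domains two entries share, the more likely they depict the same
#' biomacromolecule in a different state. Two overlap conventions are
#' offered: \emph{containment} |A(intersect)B| / min(|A|,|B|), which calls a
#' sub-complex fully redundant with the larger complex that contains it, and
#' \emph{jaccard} |A(intersect)B| / |A(union)B|.
#'
#' @param a,b character vectors: the two accession sets (each non-empty).
#' @param method "containment" (default) or "jaccard".
#' @return a similarity in [0, 1], symmetric in its arguments.
#' @export
xref_similarity <- function(a, b, method = c("containment", "jaccard")) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0)
    stopf("xref_similarity is undefined for an empty cross-reference set")
  inter <- length(intersect(a, b))
  switch(method,
         containment = inter / min(length(a), length(b)),
         jaccard = inter / length(union(a, b)))
}

#' Pairwise similarity matrix over identifier sets
#'
#' Used both for redundancy filtering diagnostics and for dataset-level
#' similarity assessment over annotation identifiers (e.g. InterPro domain
#' IDs): element (i, j) is \code{xref_similarity(sets[[i]], sets[[j]])}.
#'
#' @param sets list of non-empty character vectors.
#' @param method overlap convention, see \code{\link{xref_similarity}}.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
pairwise_similarity_matrix <- function(sets, method = c("containment", "jaccard")) {
  method <- match.arg(method)
  n <- length(sets)
  if (any(vapply(sets, length, 1L) == 0))
    stopf("pairwise_similarity_matrix: all identifier sets must be non-empty")
  m <- diag(1, n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- xref_similarity(sets[[i]], sets[[j]], method)
    }
  }
  dimnames(m) <- list(names(sets), names(sets))
  m
}

# best-resolution pick inside a candidate index set: numerically smallest
# Angstrom value, ties broken by lexicographically smallest emdb_id.
pick_best_resolution <- function(tab, idx) {
  res <- tab$resolution[idx]
  res[is.na(res)] <- Inf
  idx[order(res, tab$emdb_id[idx])][1]
}

#' Remove incomplete and duplicated entries
#'
#' Entries missing a fitted PDB ID, a resolution, or a recommended contour
#' level cannot be carried through the pipeline and are removed. Within
#' groups sharing a title (duplicate depositions), only the best-resolution
#' member is kept. (Duplicate EMDB IDs are rejected at construction time by
#' \code{\link{metadata_table}}.)
#'
#' @param tab a metadata table.
#' @return list with the cleaned \code{table} and a \code{report}.
#' @export
clean_entries <- function(tab) {
  n0 <- nrow(tab)
  reasons <- character(0); ids <- character(0)
  missing_pdb <- is.na(tab$pdb_id) | !nzchar(tab$pdb_id)
  missing_res <- is.na(tab$resolution)
  missing_ctr <- is.na(tab$contour_level)
  drop <- missing_pdb | missing_res | missing_ctr
  reason_of <- function(i) {
    paste0("missing ", paste(c("fitted PDB ID", "resolution", "contour level")[
      c(missing_pdb[i], missing_res[i], missing_ctr[i])], collapse = " + "))
  }
  ids <- tab$emdb_id[drop]
  reasons <- vapply(which(drop), reason_of, character(1))
  kept <- mt_subset(tab, !drop)
  # duplicate titles: keep the best-resolution member of each group
  if (nrow(kept)) {
    title_grp <- split(seq_len(nrow(kept)), kept$title)
    drop2 <- logical(nrow(kept))
    for (g in title_grp) {
      if (length(g) > 1 && nzchar(kept$title[g[1]])) {
        best <- pick_best_resolution(kept, g)
        loser <- setdiff(g, best)
        drop2[loser] <- TRUE
        ids <- c(ids, kept$emdb_id[loser])
        reasons <- c(reasons, rep(sprintf("duplicate title (kept %s)",
                                          kept$emdb_id[best]), length(loser)))
      }
    }
    kept <- mt_subset(kept, !drop2)
  }
  rep <- curation_report("clean", n0,
                         discarded = data.frame(emdb_id = ids, reason = reasons,
                                                stringsAsFactors = FALSE))
  list(table = kept, report = rep)
}

#' Q-score filter
#'
#' Discards entries whose deposited Q-score (atom-level resolvability of the
#' map-model pair; 1 = perfect fit) is strictly below \code{threshold}.
#' Entries without a Q-score also fail, with a distinct reason, rather than
#' passing silently.
#'
#' @param tab a metadata table.
#' @param threshold minimum acceptable Q-score (default 0.4).
#' @return list with the filtered \code{table} and a \code{report}.
#' @export
filter_qscore <- function(tab, threshold = 0.4) {
  stopifnot(is.finite(threshold))
  missing <- is.na(tab$q_score)
  low <- !missing & tab$q_score < threshold
  drop <- missing | low
  disc <- data.frame(
    emdb_id = tab$emdb_id[drop],
    reason = ifelse(missing[drop], "missing Q-score",
                    sprintf("Q-score below threshold %.3g", threshold)),
    stringsAsFactors = FALSE)
  list(table = mt_subset(tab, !drop),
       report = curation_report("qscore", nrow(tab), discarded = disc))
}

#' First-tier redundancy filter: uniqueness
#'
#' Groups entries whose merged cross-reference sets are identical and keeps
#' only the best-resolution member of each group (the others are exact
#' redundancy). Entries lacking both UniProtKB and AlphaFold
#' cross-references cannot be compared and are flagged for optional manual
#' review instead of being silently retained.
#'
#' @param tab a metadata table.
#' @param namespace which cross-reference namespace(s) to compare
#'   (default "merged").
#' @return list with the filtered \code{table} and a \code{report}.
#' @export
uniqueness_filter <- function(tab, namespace = "merged") {
  n0 <- nrow(tab)
  sets <- lapply(seq_len(n0), function(i) xref_set(tab, i, namespace))
  empty <- vapply(sets, length, 1L) == 0
  flagged <- tab$emdb_id[empty]
  ids <- character(0); reasons <- character(0)
  live <- which(!empty)
  if (length(live)) {
    key <- vapply(sets[live], function(s) paste(sort(s), collapse = "|"),
                  character(1))
    for (g in split(live, key)) {
      if (length(g) > 1) {
        best <- pick_best_resolution(tab, g)
        loser <- setdiff(g, best)
        ids <- c(ids, tab$emdb_id[loser])
        reasons <- c(reasons, rep(sprintf(
          "identical cross-references (kept %s)", tab$emdb_id[best]),
          length(loser)))
      }
    }
  }
  keep <- !(tab$emdb_id %in% c(ids, flagged))
  list(table = mt_subset(tab, keep),
       report = curation_report("uniqueness", n0,
                                discarded = data.frame(emdb_id = ids,
                                                       reason = reasons,
                                                       stringsAsFactors = FALSE),
                                flagged = flagged))
}

#' Second-tier redundancy filter: similarity
#'
#' Greedy sweep in best-resolution-first order: an entry is retained iff its
#' cross-reference overlap with every already-retained entry is at most
#' \code{threshold}; otherwise it is discarded as redundant with a
#' better-resolved retained entry. All retained pairs therefore have
#' similarity <= threshold. The table is expected to be uniqueness-filtered
#' already (no empty cross-reference sets).
#'
#' @param tab a metadata table with no empty cross-reference sets.
#' @param threshold maximum tolerated pairwise overlap, in [0, 1]
#'   (default 0.70).
#' @param method overlap convention, see \code{\link{xref_similarity}}.
#' @param namespace cross-reference namespace(s) to compare.
#' @return list with the filtered \code{table} and a \code{report}.
#' @export
similarity_filter <- function(tab, threshold = 0.70,
                              method = c("containment", "jaccard"),
                              namespace = "merged") {
  method <- match.arg(method)
  stopifnot(threshold >= 0, threshold <= 1)
  n0 <- nrow(tab)
  sets <- lapply(seq_len(n0), function(i) xref_set(tab, i, namespace))
  if (any(vapply(sets, length, 1L) == 0))
    stopf("similarity_filter requires uniqueness-filtered input (empty cross-reference set found)")
  res <- tab$resolution; res[is.na(res)] <- Inf
  sweep_order <- order(res, tab$emdb_id)
  retained <- integer(0)
  ids <- character(0); reasons <- character(0)
  for (i in sweep_order) {
    sims <- vapply(retained, function(j) xref_similarity(sets[[i]], sets[[j]], method),
                   numeric(1))
    if (length(sims) && any(sims > threshold)) {
      ids <- c(ids, tab$emdb_id[i])
      reasons <- c(reasons, sprintf("cross-reference overlap %.3f > %.2f with %s",
                                    max(sims), threshold,
                                    tab$emdb_id[retained[which.max(sims)]]))
    } else {
      retained <- c(retained, i)
    }
  }
  keep <- sort(retained)  # preserve original table order among survivors
  list(table = mt_subset(tab, seq_len(n0) %in% keep),
       report = curation_report("similarity", n0,
                                discarded = data.frame(emdb_id = ids,
                                                       reason = reasons,
                                                       stringsAsFactors = FALSE)))
}
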