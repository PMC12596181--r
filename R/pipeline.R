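#' Pipeline configuration
#'
#' Collects every tunable of the three pipeline stages with the
#' conventional defaults: Q-score minimum 0.4, cross-reference overlap
#' maximum 0.70 (containment), VOF minimum 0.82, voxel size 1.0 Angstrom,
#' normalization anchor percentile 0.85, labeling radius 1.5 Angstrom,
#' 64-voxel patches, 80:20:0 split.
#'
#' @param query EMDB search string.
#' @param workdir directory for stage outputs (created as needed).
#' @param data_dir directory holding \code{<EMDB-ID>.mrc[.gz]} maps and
#'   \code{<PDB-ID>.pdb|.cif} models (download cache in online mode,
#'   fixture dir in offline mode).
#' @param cache metadata cache path (offline JSON file or online cache dir).
#' @param offline run without network access (default TRUE).
#' @param q_score_min,similarity_max,similarity_method,vof_min curation
#'   thresholds.
#' @param voxel_size,anchor_percentile,interp_order map conditioning
#'   parameters.
#' @param label_rules list of lists with fields \code{ss}, \code{residue},
#'   \code{atom_name}, \code{value}; defaults to the four-class secondary
#'   structure labeling (helix=1, sheet=2, coil=3, rna=4).
#' @param label_radius labeling radius in Angstrom.
#' @param patch,stride partition geometry in voxels.
#' @param split_ratios,split_granularity,seed dataset split controls.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(query = "", workdir = "cryocurate_work",
                            data_dir = file.path(workdir, "data"),
                            cache = NULL, offline = TRUE,
                            q_score_min = 0.4, similarity_max = 0.70,
                            similarity_method = "containment",
                            vof_min = 0.82, voxel_size = 1.0,
                            anchor_percentile = 0.85, interp_order = 3,
                            label_rules = NULL, label_radius = 1.5,
                            patch = 64L, stride = patch,
                            split_ratios = c(0.8, 0.2, 0),
                            split_granularity = "entry", seed = 1L) {
  if (is.null(label_rules))
    label_rules <- list(list(ss = "helix", value = 1L),
                        list(ss = "sheet", value = 2L),
                        list(ss = "coil", value = 3L),
                        list(ss = "rna", value = 4L))
  cfg <- list(query = query, workdir = workdir, data_dir = data_dir,
              cache = cache, offline = isTRUE(offline),
              q_score_min = q_score_min, similarity_max = similarity_max,
              similarity_method = similarity_method, vof_min = vof_min,
              voxel_size = voxel_size, anchor_percentile = anchor_percentile,
              interp_order = interp_order, label_rules = label_rules,
              label_radius = label_radius, patch = as.integer(patch),
              stride = as.integer(stride), split_ratios = split_ratios,
              split_granularity = split_granularity, seed = as.integer(seed))
  stopifnot(cfg$similarity_max >= 0, cfg$similarity_max <= 1,
            cfg$vof_min >= 0, cfg$vof_min <= 1, cfg$voxel_size > 0,
            cfg$anchor_percentile > 0, cfg$anchor_percentile < 1,
            cfg$label_radius > 0, cfg$stride > 0, cfg$stride <= cfg$patch)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of \code{\link{pipeline_config}};
#' unspecified keys take the defaults.
#'
#' @param path YAML file.
#' @return a \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

spec_from_config <- function(cfg) {
  rules <- lapply(cfg$label_rules, function(r)
    selection_rule(ss = r$ss, residue = r$residue, atom_name = r$atom_name))
  label_spec(rules, vapply(cfg$label_rules, function(r) as.integer(r$value),
                           integer(1)), radius = cfg$label_radius)
}

log_entry_line <- function(stage, id, status, detail = "") {
  message(sprintf("[%s] %s %s%s", stage, id, status,
                  if (nzchar(detail)) paste0(": ", detail) else ""))
}

#' Run one pipeline stage
#'
#' Stage boundaries are on-disk artifacts, so stages are independently
#' rerunnable:
#' \describe{
#'   \item{fetch}{query (or read from cache) entry metadata; writes
#'     \code{metadata.csv}.}
#'   \item{curate}{clean + Q-score + uniqueness + similarity filters, then
#'     per-entry map conditioning (resample, adaptive normalize) and
#'     map-model fitness validation; writes \code{curated.csv}, conditioned
#'     maps under \code{conditioned/}, \code{fitness.csv} and
#'     \code{report.csv}. Per-entry failures (missing files, unsuccessful
#'     normalization) are logged, tallied in the report and skipped, never
#'     fatal to the batch. Completed conditioned maps are reused on rerun.}
#'   \item{build}{label volumes, partition into patches, split, write the
#'     NPY dataset and \code{manifest.csv}.}
#' }
#'
#' @param stage "fetch", "curate" or "build".
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{status} (0 on success), \code{report} (a
#'   curation report, for stages that filter) and stage-specific paths.
#' @export
run_stage <- function(stage = c("fetch", "curate", "build"), config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
         fetch = stage_fetch(config),
         curate = stage_curate(config),
         build = stage_build(config))
}

stage_fetch <- function(cfg) {
  tab <- fetch_entries(cfg$query,
                       mode = if (cfg$offline) "offline" else "online",
                       cache = cfg$cache)
  path <- file.path(cfg$workdir, "metadata.csv")
  write_metadata_csv(tab, path)
  log_entry_line("fetch", cfg$query, sprintf("%d entries", nrow(tab)))
  list(status = 0L, metadata = path, n_entries = nrow(tab))
}

stage_curate <- function(cfg) {
  meta_path <- file.path(cfg$workdir, "metadata.csv")
  if (!file.exists(meta_path))
    stopf("curate: no metadata.csv in %s (run the fetch stage first)",
          cfg$workdir)
  tab <- read_metadata_csv(meta_path)
  cl <- clean_entries(tab)
  qs <- filter_qscore(cl$table, cfg$q_score_min)
  un <- uniqueness_filter(qs$table)
  si <- similarity_filter(un$table, cfg$similarity_max,
                          method = cfg$similarity_method)
  report <- c(cl$report, qs$report, un$report, si$report)
  surv <- si$table
  cond_dir <- file.path(cfg$workdir, "conditioned")
  dir.create(cond_dir, showWarnings = FALSE)
  pairs <- list()
  cond_fail <- data.frame(emdb_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(surv))) {
    id <- surv$emdb_id[i]
    out_path <- file.path(cond_dir, paste0(id, ".mrc"))
    res <- tryCatch({
      model_path <- find_model_file(cfg$data_dir, surv$pdb_id[i])
      if (file.exists(out_path)) {        # resumability: reuse prior output
        norm <- read_density_map(out_path)
      } else {
        map <- read_density_map(find_map_file(cfg$data_dir, id))
        norm <- condition_map(map, surv$contour_level[i],
                              target_voxel = cfg$voxel_size,
                              p = cfg$anchor_percentile,
                              order = cfg$interp_order)
        write_density_map(norm, out_path)
      }
      model <- parse_model(model_path)
      list(map = norm, model = model, emdb_id = id, model_path = model_path)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      cond_fail <- rbind(cond_fail, data.frame(emdb_id = id, reason = res,
                                               stringsAsFactors = FALSE))
      log_entry_line("curate", id, "failed", res)
    } else {
      pairs[[length(pairs) + 1]] <- res
      log_entry_line("curate", id, "conditioned")
    }
  }
  report <- c(report, curation_report("conditioning", nrow(surv),
                                      discarded = cond_fail))
  mmf <- validate_pairs(pairs, threshold = cfg$vof_min,
                        radius = cfg$label_radius)
  report <- c(report, mmf$report)
  kept_ids <- vapply(mmf$kept, `[[`, character(1), "emdb_id")
  curated <- mt_subset(surv, surv$emdb_id %in% kept_ids)
  curated_path <- file.path(cfg$workdir, "curated.csv")
  write_metadata_csv(curated, curated_path)
  model_paths <- vapply(mmf$kept, `[[`, character(1), "model_path")
  utils::write.csv(data.frame(emdb_id = kept_ids, model_path = model_paths),
                   file.path(cfg$workdir, "models.csv"), row.names = FALSE)
  if (!is.null(mmf$report$stages[[1]]$scores))
    utils::write.csv(mmf$report$stages[[1]]$scores,
                     file.path(cfg$workdir, "fitness.csv"), row.names = FALSE)
  write_report_csv(report, file.path(cfg$workdir, "report.csv"))
  list(status = 0L, report = report, curated = curated_path,
       n_entries = nrow(curated))
}

stage_build <- function(cfg) {
  curated_path <- file.path(cfg$workdir, "curated.csv")
  if (!file.exists(curated_path))
    stopf("build: no curated.csv in %s (run the curate stage first)",
          cfg$workdir)
  curated <- read_metadata_csv(curated_path)
  models <- utils::read.csv(file.path(cfg$workdir, "models.csv"),
                            stringsAsFactors = FALSE)
  spec <- spec_from_config(cfg)
  records <- list()
  for (i in seq_len(nrow(curated))) {
    id <- curated$emdb_id[i]
    norm <- read_density_map(file.path(cfg$workdir, "conditioned",
                                       paste0(id, ".mrc")))
    model <- parse_model(models$model_path[models$emdb_id == id][1])
    labels <- build_label_volume(model, norm, spec)
    recs <- partition_volume(norm, labels, patch = cfg$patch,
                             stride = cfg$stride)
    for (r in seq_along(recs)) recs[[r]]$entry <- id
    records <- c(records, recs)
    log_entry_line("build", id, sprintf("%d subvolumes", length(recs)))
  }
  records <- split_dataset(records, ratios = cfg$split_ratios,
                           granularity = cfg$split_granularity,
                           seed = cfg$seed)
  manifest <- write_dataset(records, file.path(cfg$workdir, "dataset"))
  list(status = 0L, manifest = manifest, n_subvolumes = length(records))
}

find_map_file <- function(data_dir, emdb_id) {
  for (ext in c(".mrc", ".mrc.gz", ".map", ".map.gz")) {
    p <- file.path(data_dir, paste0(emdb_id, ext))
    if (file.exists(p)) return(p)
  }
  stopf("no map file for %s in %s", emdb_id, data_dir)
}

find_model_file <- function(data_dir, pdb_id) {
  for (ext in c(".pdb", ".cif", ".pdb.gz", ".cif.gz")) {
    p <- file.path(data_dir, paste0(pdb_id, ext))
    if (file.exists(p)) return(p)
  }
  stopf("no model file for %s in %s", pdb_id, data_dir)
}
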