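# run expr with a private RNG stream seeded by `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic map-model pair
#'
#' Places pseudo-atoms by layout, renders the density as a sum of isotropic
#' Gaussians plus Gaussian noise, and picks a contour level so that a known
#' fraction of voxels exceed it. The atom layouts are an idealized
#' alpha-helix C-alpha trace (with a consistent HELIX annotation), a nucleic
#' backbone ladder of A/U/G/C residues, or uniformly random atoms. This is
#' a deliberate simplification of cryoEM image formation (no CTF, no
#' resolution-dependent noise); it exists so that every pipeline stage is
#' testable offline against constructions with known properties.
#'
#' @param grid_dim voxels per axis (scalar or length 3), default 32.
#' @param voxel_size Angstrom per voxel, default 1.0.
#' @param layout "helix", "nucleic" or "random".
#' @param n_residues residues (helix/nucleic) or atoms (random), default 10.
#' @param sigma Gaussian width in Angstrom, default 1.5.
#' @param noise_sd additive noise standard deviation, default 0.02.
#' @param contour_fraction fraction of voxels that should exceed the
#'   reported contour level, default 0.05 (safely anchorable at the default
#'   85th-percentile normalization).
#' @param seed integer; fixes all randomness.
#' @return list with \code{map} (a \code{\link{density_map}}),
#'   \code{model} (an \code{"atomic_model"}), \code{contour_level}, and
#'   \code{atoms} (the generating data frame).
#' @export
synth_map_model <- function(grid_dim = 32, voxel_size = 1.0,
                            layout = c("helix", "nucleic", "random"),
                            n_residues = 10, sigma = 1.5, noise_sd = 0.02,
                            contour_fraction = 0.05, seed = 1L) {
  layout <- match.arg(layout)
  if (n_residues < 1) stopf("synth_map_model: need at least one residue")
  grid_dim <- rep_len(as.integer(grid_dim), 3)
  box <- grid_dim * voxel_size
  with_seed(seed, {
    atoms <- switch(layout,
      helix = {
        i <- seq_len(n_residues)
        ang <- (i - 1) * 100 * pi / 180
        data.frame(record = "ATOM", chain_id = "A", residue_number = i,
                   residue_name = "ALA", atom_name = "CA", element = "C",
                   x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = (i - 1) * 1.5,
                   stringsAsFactors = FALSE)
      },
      nucleic = {
        i <- seq_len(n_residues)
        res <- rep(c("A", "U", "G", "C"), length.out = n_residues)
        rbind(
          data.frame(record = "ATOM", chain_id = "A", residue_number = i,
                     residue_name = res, atom_name = "P", element = "P",
                     x = 2 * cos(i), y = 2 * sin(i), z = (i - 1) * 3,
                     stringsAsFactors = FALSE),
          data.frame(record = "ATOM", chain_id = "A", residue_number = i,
                     residue_name = res, atom_name = "C1'", element = "C",
                     x = 2 * cos(i) + 1.5, y = 2 * sin(i), z = (i - 1) * 3 + 1,
                     stringsAsFactors = FALSE))
      },
      random = {
        data.frame(record = "ATOM", chain_id = "A",
                   residue_number = seq_len(n_residues),
                   residue_name = "ALA", atom_name = "CA", element = "C",
                   x = stats::runif(n_residues, 0.25, 0.75) * box[1],
                   y = stats::runif(n_residues, 0.25, 0.75) * box[2],
                   z = stats::runif(n_residues, 0.25, 0.75) * box[3],
                   stringsAsFactors = FALSE)
      })
    if (layout %in% c("helix", "nucleic")) {
      # center the trace in the box
      for (ax in c("x", "y", "z")) {
        shift <- box[match(ax, c("x", "y", "z"))] / 2 - mean(range(atoms[[ax]]))
        atoms[[ax]] <- atoms[[ax]] + shift
      }
    }
    atoms <- atoms[order(atoms$residue_number, atoms$atom_name), ]
    atoms$file_order <- seq_len(nrow(atoms))
    grid <- gaussian_density(atoms, grid_dim, voxel_size, sigma)
    if (noise_sd > 0)
      grid <- grid + array(stats::rnorm(length(grid), sd = noise_sd),
                           dim = grid_dim)
    map <- density_map(grid, voxel_size = voxel_size, origin = c(0, 0, 0))
    contour <- as.numeric(stats::quantile(grid, 1 - contour_fraction,
                                          type = 1))
    helix_ranges <- if (layout == "helix")
      data.frame(chain = "A", start = 1L, end = as.integer(n_residues),
                 stringsAsFactors = FALSE)
    else data.frame(chain = character(0), start = integer(0), end = integer(0))
    model <- structure(list(
      atoms = cbind(atoms[c("record", "chain_id", "residue_number",
                            "residue_name", "atom_name", "element",
                            "x", "y", "z")],
                    data.frame(ss_class = NA_character_,
                               file_order = atoms$file_order)),
      chains = "A", helix = helix_ranges,
      sheet = data.frame(chain = character(0), start = integer(0),
                         end = integer(0)),
      path = sprintf("synthetic:%s", layout)), class = "atomic_model")
    model <- assign_ss(model)
    list(map = map, model = model, contour_level = contour, atoms = atoms)
  })
}

# sum of isotropic Gaussians rendered on the grid (3.5-sigma cutoff)
gaussian_density <- function(atoms, grid_dim, voxel_size, sigma) {
  grid <- array(0, dim = grid_dim)
  frame <- density_map(grid, voxel_size = voxel_size)
  cutoff <- 3.5 * sigma
  hits <- atom_voxel_hits(atoms, frame, cutoff)
  if (nrow(hits)) {
    dens <- exp(-hits$dist2 / (2 * sigma^2))
    agg <- rowsum(dens, hits$voxel)
    grid[as.integer(rownames(agg))] <- agg[, 1]
  }
  grid
}

#' Write an atomic model as a PDB fixture
#'
#' Emits ATOM/HETATM records in file order plus HELIX/SHEET records for the
#' model's annotation ranges, in a form round-trippable by
#' \code{\link{parse_model}}.
#'
#' @param model an \code{"atomic_model"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  lines <- character(0)
  hx <- model$helix
  for (r in seq_len(nrow(hx))) {
    rn1 <- at$residue_name[at$residue_number == hx$start[r] &
                             at$chain_id == hx$chain[r]][1]
    rn2 <- at$residue_name[at$residue_number == hx$end[r] &
                             at$chain_id == hx$chain[r]][1]
    lines <- c(lines, sprintf(
      "HELIX  %3d %3d %3s %1s %4d  %3s %1s %4d  1                          %5d",
      r, r, rn1 %||% "ALA", hx$chain[r], hx$start[r], rn2 %||% "ALA",
      hx$chain[r], hx$end[r], hx$end[r] - hx$start[r] + 1))
  }
  sh <- model$sheet
  for (r in seq_len(nrow(sh))) {
    rn1 <- at$residue_name[at$residue_number == sh$start[r] &
                             at$chain_id == sh$chain[r]][1]
    rn2 <- at$residue_name[at$residue_number == sh$end[r] &
                             at$chain_id == sh$chain[r]][1]
    lines <- c(lines, sprintf(
      "SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d  0",
      r, "S", 1, rn1 %||% "ALA", sh$chain[r], sh$start[r], rn2 %||% "ALA",
      sh$chain[r], sh$end[r]))
  }
  for (i in seq_len(nrow(at))) {
    name <- at$atom_name[i]
    name_field <- if (nchar(name) >= 4) substr(name, 1, 4)
    else sprintf(" %-3s", name)
    lines <- c(lines, sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$record[i], i, name_field, at$residue_name[i], at$chain_id[i],
      at$residue_number[i], at$x[i], at$y[i], at$z[i], 1, 0, at$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an atomic model as an mmCIF fixture
#'
#' Emits an \code{atom_site} loop plus \code{struct_conf} /
#' \code{struct_sheet_range} loops for the annotation ranges.
#'
#' @inheritParams write_model_pdb
#' @return \code{path}, invisibly.
#' @export
write_model_cif <- function(model, path) {
  at <- model$atoms
  lines <- c("data_synthetic", "#", "loop_",
             paste0("_atom_site.", c(
               "group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
               "auth_comp_id", "auth_asym_id", "auth_atom_id",
               "pdbx_PDB_model_num")))
  q <- function(x) ifelse(grepl("'", x), x, ifelse(grepl("[ \"]|^$", x),
                                                   paste0("'", x, "'"), x))
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, paste(
      at$record[i], i, at$element[i], q(at$atom_name[i]), ".",
      at$residue_name[i], at$chain_id[i], 1, at$residue_number[i], "?",
      sprintf("%.3f %.3f %.3f", at$x[i], at$y[i], at$z[i]), "1.00 0.00 ?",
      at$residue_number[i], at$residue_name[i], at$chain_id[i],
      q(at$atom_name[i]), 1))
  }
  lines <- c(lines, "#")
  if (nrow(model$helix)) {
    lines <- c(lines, "loop_",
               paste0("_struct_conf.", c(
                 "conf_type_id", "id", "beg_auth_comp_id",
                 "beg_auth_asym_id", "beg_auth_seq_id", "end_auth_comp_id",
                 "end_auth_asym_id", "end_auth_seq_id")))
    for (r in seq_len(nrow(model$helix)))
      lines <- c(lines, paste("HELX_P", sprintf("HELX_P%d", r), "ALA",
                              model$helix$chain[r], model$helix$start[r],
                              "ALA", model$helix$chain[r],
                              model$helix$end[r]))
    lines <- c(lines, "#")
  }
  if (nrow(model$sheet)) {
    lines <- c(lines, "loop_",
               paste0("_struct_sheet_range.", c(
                 "sheet_id", "id", "beg_auth_comp_id", "beg_auth_asym_id",
                 "beg_auth_seq_id", "end_auth_comp_id", "end_auth_asym_id",
                 "end_auth_seq_id")))
    for (r in seq_len(nrow(model$sheet)))
      lines <- c(lines, paste("S", r, "ALA", model$sheet$chain[r],
                              model$sheet$start[r], "ALA",
                              model$sheet$chain[r], model$sheet$end[r]))
    lines <- c(lines, "#")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate synthetic entry metadata with controlled redundancy structure
#'
#' Builds a metadata table whose cross-reference sets realize a requested
#' pairwise-similarity structure: duplicate groups (identical sets), subset
#' chains (nested sets, fully contained in one another), entries with no
#' cross-references at all, and disjoint singletons for the remainder.
#' Q-scores are drawn uniformly from \code{q_range}; resolutions uniformly
#' from \code{res_range}.
#'
#' @param n number of entries (> 0).
#' @param structure list with any of \code{n_duplicate_groups},
#'   \code{duplicate_group_size} (default 3), \code{n_subset_chains},
#'   \code{subset_chain_length} (default 3), \code{n_empty}.
#' @param q_range Q-score range, default c(0.2, 0.6).
#' @param res_range resolution range in Angstrom, default c(2.5, 4.0).
#' @param seed integer; fixes all randomness.
#' @return a \code{\link{metadata_table}}.
#' @export
synth_metadata <- function(n, structure = list(), q_range = c(0.2, 0.6),
                           res_range = c(2.5, 4.0), seed = 1L) {
  stopifnot(n > 0)
  ndg <- structure$n_duplicate_groups %||% 0
  dgs <- structure$duplicate_group_size %||% 3
  nsc <- structure$n_subset_chains %||% 0
  scl <- structure$subset_chain_length %||% 3
  nem <- structure$n_empty %||% 0
  used <- ndg * dgs + nsc * scl + nem
  if (used > n)
    stopf("synth_metadata: structure needs %d entries but n = %d", used, n)
  with_seed(seed, {
    xrefs <- character(n)
    i <- 1; acc <- 0
    nxt <- function(k) {
      acc <<- acc + k
      sprintf("U%05d", (acc - k + 1):acc)
    }
    for (g in seq_len(ndg)) {
      set <- nxt(4)
      for (m in seq_len(dgs)) { xrefs[i] <- join_accessions(set); i <- i + 1 }
    }
    for (g in seq_len(nsc)) {
      base <- nxt(scl + 1)
      # nested: entry m carries the first m+1 accessions of the chain
      for (m in seq_len(scl)) {
        xrefs[i] <- join_accessions(base[seq_len(m + 1)]); i <- i + 1
      }
    }
    if (nem > 0) { xrefs[i:(i + nem - 1)] <- ""; i <- i + nem }
    while (i <= n) { xrefs[i] <- join_accessions(nxt(2)); i <- i + 1 }
    metadata_table(
      emdb_id = sprintf("EMD-%05d", seq_len(n)),
      title = sprintf("synthetic entry %05d", seq_len(n)),
      resolution = round(stats::runif(n, res_range[1], res_range[2]), 2),
      pdb_id = sprintf("%04X", seq_len(n) + 0x1000),
      q_score = round(stats::runif(n, q_range[1], q_range[2]), 3),
      atom_inclusion = round(stats::runif(n, 80, 100), 1),
      contour_level = round(stats::runif(n, 0.01, 0.1), 4),
      xrefs_uniprot = xrefs,
      xrefs_alphafold = "",
      provenance = sprintf("synthetic seed=%d", seed))
  })
}
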