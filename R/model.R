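STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
RNA_RES <- c("A", "U", "G", "C")
DNA_RES <- c("DA", "DT", "DG", "DC")

#' Parse an atomic model from PDB or mmCIF
#'
#' Returns one atom per ATOM/HETATM record, in file order (file order is the
#' deterministic tie-breaker used by voxel labeling). Only the first model
#' of multi-model files and the first alternate location are kept; hydrogens
#' are retained and can be excluded at selection time. Deposited
#' helix/sheet ranges (HELIX/SHEET records, or struct_conf /
#' struct_sheet_range categories) are carried along for
#' \code{\link{assign_ss}}.
#'
#' @param path a \code{.pdb} or \code{.cif} file.
#' @return an object of class \code{"atomic_model"}: a list with
#'   \code{atoms} (data frame in file order), \code{chains},
#'   \code{helix}/\code{sheet} range tables and the source \code{path}.
#' @export
parse_model <- function(path) {
  if (!file.exists(path)) stopf("no such model file: %s", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) suppressWarnings(bio3d::read.cif(path, multi = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
    error = function(e) stopf("cannot parse model %s: %s", path,
                              conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stopf("empty model: %s", path)
  atoms <- data.frame(
    record = at$type,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    residue_number = as.integer(at$resno),
    residue_name = toupper(trimws(at$resid)),
    atom_name = toupper(trimws(at$elety)),
    element = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
    x = at$x, y = at$y, z = at$z,
    ss_class = NA_character_,
    file_order = seq_len(nrow(at)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stopf("non-finite atom coordinates in %s", path)
  ranges <- if (is_cif) cif_ss_ranges(path) else
    list(helix = bio3d_ranges(pdb$helix), sheet = bio3d_ranges(pdb$sheet))
  model <- structure(list(atoms = atoms, chains = unique(atoms$chain_id),
                          helix = ranges$helix, sheet = ranges$sheet,
                          path = path),
                     class = "atomic_model")
  assign_ss(model)
}

bio3d_ranges <- function(h) {
  if (is.null(h) || length(h$start) == 0)
    return(data.frame(chain = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  data.frame(chain = as.character(h$chain), start = as.integer(h$start),
             end = as.integer(h$end), stringsAsFactors = FALSE)
}

# minimal mmCIF loop reader for the two secondary-structure categories.
cif_ss_ranges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(category) {
    tags <- character(0); rows <- list()
    i <- 1
    while (i <= length(lines)) {
      if (trimws(lines[i]) == "loop_") {
        j <- i + 1; tags <- character(0)
        while (j <= length(lines) && startsWith(trimws(lines[j]), "_")) {
          tags <- c(tags, trimws(lines[j])); j <- j + 1
        }
        if (length(tags) && all(startsWith(tags, paste0(category, ".")))) {
          while (j <= length(lines) && !startsWith(trimws(lines[j]), "_") &&
                 !trimws(lines[j]) %in% c("#", "loop_") && nzchar(trimws(lines[j]))) {
            rows[[length(rows) + 1]] <- scan(text = lines[j], what = character(),
                                             quiet = TRUE)
            j <- j + 1
          }
          break
        }
        i <- j
      } else i <- i + 1
    }
    if (!length(rows)) return(NULL)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- sub(paste0(category, "."), "", tags, fixed = TRUE)
    df
  }
  conf <- grab("_struct_conf")
  helix <- if (!is.null(conf)) {
    hx <- conf[grepl("^HELX", conf$conf_type_id %||% ""), , drop = FALSE]
    data.frame(chain = hx$beg_auth_asym_id,
               start = as.integer(hx$beg_auth_seq_id),
               end = as.integer(hx$end_auth_seq_id), stringsAsFactors = FALSE)
  } else bio3d_ranges(NULL)
  sh <- grab("_struct_sheet_range")
  sheet <- if (!is.null(sh)) {
    data.frame(chain = sh$beg_auth_asym_id,
               start = as.integer(sh$beg_auth_seq_id),
               end = as.integer(sh$end_auth_seq_id), stringsAsFactors = FALSE)
  } else bio3d_ranges(NULL)
  list(helix = helix, sheet = sheet)
}

#' Assign the secondary-structure class of every atom
#'
#' Classes form a partition: standard amino-acid residues inside a deposited
#' helix (sheet) range become \code{helix} (\code{sheet}); remaining
#' standard amino acids are \code{coil}; residues named A/U/G/C are
#' \code{rna}; DA/DT/DG/DC are \code{dna}; everything else (ligands, ions,
#' waters) is \code{other}. When a model carries no annotation ranges all
#' protein residues default to coil. Non-standard amino acids in polymer
#' (ATOM) records map to coil unless \code{nonstandard_as_other}.
#'
#' @param model an \code{"atomic_model"}.
#' @param nonstandard_as_other treat non-standard polymer residues as
#'   \code{other} instead of \code{coil}.
#' @return the model with \code{atoms$ss_class} filled in.
#' @export
assign_ss <- function(model, nonstandard_as_other = FALSE) {
  at <- model$atoms
  cls <- rep("other", nrow(at))
  is_rna <- at$residue_name %in% RNA_RES
  is_dna <- at$residue_name %in% DNA_RES
  is_aa <- at$residue_name %in% STANDARD_AA
  is_poly_nonstd <- !is_aa & !is_rna & !is_dna & at$record == "ATOM" &
    !nonstandard_as_other & !at$residue_name %in% "HOH"
  cls[is_rna] <- "rna"
  cls[is_dna] <- "dna"
  cls[is_aa | is_poly_nonstd] <- "coil"
  in_range <- function(ranges) {
    hit <- rep(FALSE, nrow(at))
    for (r in seq_len(nrow(ranges))) {
      hit <- hit | (at$chain_id == ranges$chain[r] &
                      at$residue_number >= ranges$start[r] &
                      at$residue_number <= ranges$end[r])
    }
    hit
  }
  protein <- cls == "coil"
  if (nrow(model$helix)) cls[protein & in_range(model$helix)] <- "helix"
  if (nrow(model$sheet)) cls[protein & in_range(model$sheet)] <- "sheet"
  model$atoms$ss_class <- cls
  model
}

#' Three-tier atom selection rule
#'
#' Selection mirrors the three hierarchical categories users combine when
#' choosing what to label: secondary-structure class, residue type, and atom
#' name. An unset tier matches everything; \code{ss = "none"} matches only
#' atoms of class \code{other} (the ligand/ion path).
#'
#' @param ss character vector of classes among helix/sheet/coil/rna/dna,
#'   the keyword "none", or NULL (unconstrained).
#' @param residue residue-name set or NULL.
#' @param atom_name atom-name set or NULL.
#' @param hydrogens include hydrogen atoms (default TRUE).
#' @return an object of class \code{"selection_rule"}.
#' @export
selection_rule <- function(ss = NULL, residue = NULL, atom_name = NULL,
                           hydrogens = TRUE) {
  valid <- c("helix", "sheet", "coil", "rna", "dna", "none")
  if (!is.null(ss) && !all(ss %in% valid))
    stopf("unknown secondary-structure selector: %s",
          paste(setdiff(ss, valid), collapse = ", "))
  structure(list(ss = ss,
                 residue = if (!is.null(residue)) toupper(residue),
                 atom_name = if (!is.null(atom_name)) toupper(atom_name),
                 hydrogens = hydrogens),
            class = "selection_rule")
}

#' Select atoms matching a rule
#'
#' An atom matches iff it satisfies every specified tier; file order is
#' preserved.
#'
#' @param model an \code{"atomic_model"} with assigned classes.
#' @param rule a \code{\link{selection_rule}}.
#' @return the matching subset of \code{model$atoms}, in file order.
#' @export
select_atoms <- function(model, rule = selection_rule()) {
  stopifnot(inherits(rule, "selection_rule"))
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(rule$ss)) {
    want <- unique(ifelse(rule$ss == "none", "other", rule$ss))
    keep <- keep & at$ss_class %in% want
  }
  if (!is.null(rule$residue)) keep <- keep & at$residue_name %in% rule$residue
  if (!is.null(rule$atom_name)) keep <- keep & at$atom_name %in% rule$atom_name
  if (!rule$hydrogens) keep <- keep & at$element != "H"
  at[keep, , drop = FALSE]
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, %d chain(s) [%s]\n", nrow(x$atoms),
              length(x$chains), paste(x$chains, collapse = ",")))
  print(table(x$atoms$ss_class))
  invisible(x)
}
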