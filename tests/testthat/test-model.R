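mixed_model_fixture <- function() {
  # 3 helix residues, 2 sheet, 2 coil, 2 RNA, 1 Mg ion
  atoms <- data.frame(
    record = c(rep("ATOM", 9 * 2), "HETATM"),
    chain_id = c(rep("A", 14), rep("B", 4), "A"),
    residue_number = c(rep(1:7, each = 2), rep(8:9, each = 2), 101),
    residue_name = c(rep(c("ALA", "LEU", "GLY", "VAL", "SER", "THR", "LYS"),
                         each = 2), rep(c("A", "U"), each = 2), "MG"),
    atom_name = c(rep(c("N", "CA"), 7), rep(c("P", "C1'"), 2), "MG"),
    element = c(rep(c("N", "C"), 7), rep(c("P", "C"), 2), "MG"),
    x = seq(0, 18), y = 5, z = 5,
    ss_class = NA_character_, file_order = 1:19,
    stringsAsFactors = FALSE)
  structure(list(
    atoms = atoms, chains = c("A", "B"),
    helix = data.frame(chain = "A", start = 1L, end = 3L),
    sheet = data.frame(chain = "A", start = 4L, end = 5L),
    path = "fixture"), class = "atomic_model")
}

test_that("PDB fixtures parse to atoms in file order with annotations", {
  model <- assign_ss(mixed_model_fixture())
  tf <- tempfile(fileext = ".pdb")
  write_model_pdb(model, tf)
  parsed <- parse_model(tf)
  expect_equal(nrow(parsed$atoms), 19)
  expect_identical(parsed$atoms$file_order, 1:19)
  expect_equal(parsed$atoms$x, model$atoms$x, tolerance = 1e-3)
  expect_identical(parsed$atoms$ss_class, model$atoms$ss_class)
})

test_that("the same structure parses identically from PDB and mmCIF", {
  model <- assign_ss(mixed_model_fixture())
  tp <- tempfile(fileext = ".pdb"); tc <- tempfile(fileext = ".cif")
  write_model_pdb(model, tp); write_model_cif(model, tc)
  a <- parse_model(tp); b <- parse_model(tc)
  cols <- c("chain_id", "residue_number", "residue_name", "atom_name",
            "x", "y", "z", "ss_class")
  expect_equal(a$atoms[cols], b$atoms[cols], tolerance = 1e-3)
})

test_that("empty and unparseable models are rejected", {
  tf <- tempfile(fileext = ".pdb")
  writeLines("END", tf)
  expect_error(parse_model(tf))
  expect_error(parse_model(tempfile(fileext = ".pdb")), "no such")
})

test_that("secondary-structure classes partition the atom set", {
  model <- assign_ss(mixed_model_fixture())
  cls <- model$atoms$ss_class
  expect_identical(cls[model$atoms$residue_number <= 3 &
                         model$atoms$record == "ATOM"], rep("helix", 6))
  expect_identical(cls[model$atoms$residue_number %in% 4:5 &
                         model$atoms$record == "ATOM"], rep("sheet", 4))
  expect_identical(cls[model$atoms$residue_number %in% 6:7], rep("coil", 4))
  expect_identical(cls[model$atoms$residue_name %in% c("A", "U")],
                   rep("rna", 4))
  expect_identical(cls[model$atoms$residue_name == "MG"], "other")
  # every atom gets exactly one class; helix/sheet/coil only on amino acids
  expect_false(anyNA(cls))
  aa <- model$atoms$residue_name %in% cryocurate:::STANDARD_AA
  expect_true(all(cls[!aa] %in% c("rna", "dna", "other")))
})

test_that("models without annotation ranges default protein to coil, DNA by residue name", {
  m <- mixed_model_fixture()
  m$helix <- m$helix[0, ]; m$sheet <- m$sheet[0, ]
  m$atoms$residue_name[m$atoms$residue_name == "A"] <- "DA"
  m <- assign_ss(m)
  aa <- m$atoms$residue_name %in% cryocurate:::STANDARD_AA
  expect_true(all(m$atoms$ss_class[aa] == "coil"))
  expect_true(all(m$atoms$ss_class[m$atoms$residue_name == "DA"] == "dna"))
})

test_that("selection rules combine tiers conjunctively", {
  model <- assign_ss(mixed_model_fixture())
  helix_ca <- select_atoms(model, selection_rule(ss = "helix", atom_name = "CA"))
  expect_equal(nrow(helix_ca), 3)
  expect_true(all(helix_ca$atom_name == "CA" & helix_ca$ss_class == "helix"))
  # unconstrained rule selects everything, in file order
  all_atoms <- select_atoms(model, selection_rule())
  expect_identical(all_atoms$file_order, 1:19)
  # the "none" keyword targets non-polymer atoms
  mg <- select_atoms(model, selection_rule(ss = "none", atom_name = "MG"))
  expect_equal(nrow(mg), 1)
  expect_identical(mg$residue_name, "MG")
  # conjunction monotonicity: adding a tier can only shrink the selection
  set.seed(5)
  for (ss in list("helix", c("helix", "sheet"), "rna")) {
    broad <- select_atoms(model, selection_rule(ss = ss))
    narrow <- select_atoms(model, selection_rule(ss = ss, atom_name = "CA"))
    expect_true(all(narrow$file_order %in% broad$file_order))
  }
  expect_error(selection_rule(ss = "turn"), "unknown")
})
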