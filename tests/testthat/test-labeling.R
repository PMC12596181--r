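simple_model <- function(atoms) {
  atoms$record <- "ATOM"
  atoms$chain_id <- "A"
  atoms$residue_number <- seq_len(nrow(atoms))
  atoms$atom_name <- atoms$atom_name %||% "CA"
  atoms$element <- atoms$element %||% "C"
  atoms$ss_class <- atoms$ss_class %||% "coil"
  atoms$residue_name <- atoms$residue_name %||% "ALA"
  atoms$file_order <- seq_len(nrow(atoms))
  structure(list(atoms = atoms, chains = "A",
                 helix = data.frame(chain = character(0), start = integer(0),
                                    end = integer(0)),
                 sheet = data.frame(chain = character(0), start = integer(0),
                                    end = integer(0)),
                 path = "fixture"), class = "atomic_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("single-atom labeling marks exactly the 19 in-radius voxels", {
  frame <- density_map(array(0, dim = rep(9, 3)))
  model <- simple_model(data.frame(x = 4, y = 4, z = 4))
  spec <- label_spec(list(selection_rule(atom_name = "CA")), 1L, radius = 1.5)
  lab <- build_label_volume(model, frame, spec)
  expect_equal(sum(lab == 1L), 19)
  expect_equal(sum(lab != 0L), 19)
})

test_that("empty rule lists give an all-zero volume", {
  frame <- density_map(array(0, dim = rep(5, 3)))
  spec <- label_spec(list(), integer(0), radius = 1.5)
  lab <- build_label_volume(simple_model(data.frame(x = 2, y = 2, z = 2)),
                            frame, spec)
  expect_true(all(lab == 0L))
})

test_that("nearest atom wins and exact ties go to the earlier file order", {
  frame <- density_map(array(0, dim = rep(5, 3)))
  # two atoms 2 A apart on the x axis, labels 1 and 2
  model <- simple_model(data.frame(x = c(1, 3), y = 2, z = 2,
                                   atom_name = c("CA", "CB")))
  spec <- label_spec(list(selection_rule(atom_name = "CA"),
                          selection_rule(atom_name = "CB")),
                     c(1L, 2L), radius = 1.5)
  lab <- build_label_volume(model, frame, spec)
  atoms <- model$atoms
  atoms$label <- c(1L, 2L)
  oracle <- oracle_label_volume(atoms, rep(5L, 3), rep(1, 3), rep(0, 3), 1.5)
  # the mid-plane (x = 2) is equidistant: earlier atom's label must win there
  expect_true(all(lab[3, , ][lab[3, , ] != 0] == 1L))
  expect_equal(lab, oracle, ignore_attr = TRUE)
})

test_that("labeling equals the triple-loop oracle on random small cases", {
  set.seed(53)
  for (rep in 1:5) {
    d <- sample(6:12, 3, replace = TRUE)
    vs <- sample(c(0.8, 1, 1.2), 1)
    org <- runif(3, -2, 2)
    frame <- density_map(array(0, dim = d), voxel_size = vs, origin = org)
    n <- sample(3:10, 1)
    df <- data.frame(x = runif(n, org[1], org[1] + (d[1] - 1) * vs),
                     y = runif(n, org[2], org[2] + (d[2] - 1) * vs),
                     z = runif(n, org[3], org[3] + (d[3] - 1) * vs),
                     atom_name = sample(c("CA", "CB"), n, replace = TRUE))
    model <- simple_model(df)
    spec <- label_spec(list(selection_rule(atom_name = "CA"),
                            selection_rule(atom_name = "CB")),
                       c(1L, 2L), radius = 1.8)
    lab <- build_label_volume(model, frame, spec)
    atoms <- model$atoms
    atoms$label <- ifelse(atoms$atom_name == "CA", 1L, 2L)
    oracle <- oracle_label_volume(atoms, d, rep(vs, 3), org, 1.8)
    expect_equal(lab, oracle, ignore_attr = TRUE)
  }
})

test_that("labeled voxels are sound and complete w.r.t. the radius", {
  frame <- density_map(array(0, dim = rep(8, 3)))
  model <- simple_model(data.frame(x = c(2, 5), y = c(3, 4), z = c(4, 4)))
  spec <- label_spec(list(selection_rule(atom_name = "CA")), 3L, radius = 2)
  lab <- build_label_volume(model, frame, spec)
  idx <- which(lab == 3L, arr.ind = TRUE)
  centers <- idx - 1
  atom_pos <- rbind(c(2, 3, 4), c(5, 4, 4))
  # soundness: every labeled voxel center is within the radius of an atom
  for (r in seq_len(nrow(idx))) {
    dists <- sqrt(rowSums((atom_pos - matrix(centers[r, ], 2, 3,
                                             byrow = TRUE))^2))
    expect_lte(min(dists), 2 + 1e-9)
  }
  # completeness: every in-radius voxel is labeled
  all_idx <- which(array(TRUE, dim = rep(8, 3)), arr.ind = TRUE)
  for (a in 1:2) {
    p <- c(c(2, 5)[a], c(3, 4)[a], 4)
    within <- sqrt(rowSums((all_idx - 1 - matrix(p, nrow(all_idx), 3,
                                                 byrow = TRUE))^2)) <= 2
    expect_true(all(lab[all_idx[within, , drop = FALSE]] == 3L))
  }
})

test_that("partitioning covers the volume with ceil(dim/stride) patches per axis", {
  m64 <- density_map(array(runif(64^3), dim = rep(64, 3)))
  expect_length(partition_volume(m64, patch = 64L), 1)
  m100 <- density_map(array(runif(40 * 100 * 30), dim = c(40, 100, 30)))
  recs <- partition_volume(m100, patch = 64L, stride = 64L)
  expect_length(recs, 1 * 2 * 1)
  overlapping <- partition_volume(m64, patch = 64L, stride = 32L)
  expect_length(overlapping, 8)
  expect_error(partition_volume(m64, patch = 32L, stride = 48L), "stride")
})

test_that("stride = patch subvolumes stitch back to the zero-padded original exactly", {
  set.seed(61)
  g <- array(runif(40 * 50 * 33), dim = c(40, 50, 33))
  lab <- array(sample(0:3, length(g), replace = TRUE), dim = dim(g))
  m <- density_map(g)
  recs <- partition_volume(m, lab, patch = 16L)
  expect_length(recs, prod(ceiling(dim(g) / 16)))
  padded_dim <- ceiling(dim(g) / 16) * 16
  expected_map <- array(0, dim = padded_dim)
  expected_map[1:40, 1:50, 1:33] <- g
  expected_lab <- array(0L, dim = padded_dim)
  expected_lab[1:40, 1:50, 1:33] <- lab
  expect_identical(stitch_subvolumes(recs, "map"), expected_map)
  expect_identical(stitch_subvolumes(recs, "labels"), expected_lab)
})

test_that("dataset splitting is a seeded deterministic partition", {
  recs <- unlist(lapply(1:10, function(e)
    lapply(1:3, function(k) list(entry = sprintf("EMD-%02d", e),
                                 corner = c(0, 0, k), patch = 4,
                                 map = array(0, dim = rep(4, 3)),
                                 labels = array(0L, dim = rep(4, 3)),
                                 split = NA_character_))),
    recursive = FALSE)
  out <- split_dataset(recs, c(0.8, 0.2, 0), "entry", seed = 7)
  splits <- vapply(out, `[[`, character(1), "split")
  entries <- vapply(out, `[[`, character(1), "entry")
  # every record gets exactly one split; no entry spans splits
  expect_true(all(splits %in% c("train", "val")))
  expect_true(all(tapply(splits, entries, function(s) length(unique(s))) == 1))
  expect_equal(length(unique(entries[splits == "train"])), 8)
  expect_equal(length(unique(entries[splits == "val"])), 2)
  # rerun with the same seed reproduces the assignment
  again <- split_dataset(recs, c(0.8, 0.2, 0), "entry", seed = 7)
  expect_identical(splits, vapply(again, `[[`, character(1), "split"))
  # ratios (1, 0, 0): everything train
  all_train <- split_dataset(recs, c(1, 0, 0), "entry", seed = 1)
  expect_true(all(vapply(all_train, `[[`, character(1), "split") == "train"))
  # subvolume granularity: counts within one of target
  sub <- split_dataset(recs, c(0.8, 0.2, 0), "subvolume", seed = 2)
  n_train <- sum(vapply(sub, `[[`, character(1), "split") == "train")
  expect_lte(abs(n_train - 24), 1)
  expect_error(split_dataset(recs, c(0.5, 0.2, 0.2)), "sum")
})

test_that("NPY arrays and dataset manifests round-trip", {
  arr <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  tf <- tempfile(fileext = ".npy")
  write_npy(arr, tf, dtype = "<f8")
  expect_equal(read_npy(tf), arr)
  ints <- array(sample.int(100, 24), dim = c(2, 3, 4))
  write_npy(ints, tf)
  expect_identical(read_npy(tf), ints)
  # dataset write / read round trip
  recs <- lapply(1:2, function(i) list(
    entry = sprintf("EMD-%d", i), corner = c(0, 0, 0), patch = 4L,
    map = array(runif(64), dim = rep(4, 3)),
    labels = array(sample(0:2, 64, replace = TRUE), dim = rep(4, 3)),
    split = c("train", "val")[i]))
  out_dir <- file.path(tempdir(), "ds_test")
  manifest <- write_dataset(recs, out_dir)
  back <- read_dataset(manifest)
  expect_length(back, 2)
  expect_equal(back[[1]]$map, recs[[1]]$map, tolerance = 1e-6)
  expect_identical(back[[1]]$labels, recs[[1]]$labels)
  expect_identical(vapply(back, `[[`, character(1), "split"),
                   c("train", "val"))
  # file count: map + label per record
  expect_length(list.files(out_dir, pattern = "\\.npy$", recursive = TRUE), 4)
  # corrupted array file detected on re-read
  writeBin(as.raw(1:10), back[[1]]$map_path)
  expect_error(read_dataset(manifest), "NPY")
  unlink(out_dir, recursive = TRUE)
})
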