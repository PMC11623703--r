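test_that("one-hot encoding is a unit basis vector and rejects bad indices", {
  expect_equal(encode_onehot(3, 4), c(0, 0, 1, 0))
  expect_equal(encode_onehot(1, 1), 1)
  expect_error(encode_onehot(5, 4), "out of range")
  expect_error(encode_onehot(0, 4), "out of range")
  for (D in c(2, 5, 9)) {
    i <- sample.int(D, 1)
    v <- encode_onehot(i, D)
    expect_equal(sum(v), 1)
    expect_true(all(v >= 0))
    expect_equal(which(v == 1), i)
  }
})

test_that("pair storage covers exactly the unordered pairs", {
  for (n in c(2, 5, 8)) {
    pm <- pairs_matrix(n)
    expect_equal(nrow(pm), n_pairs(n))
    expect_true(all(pm[, 1] < pm[, 2]))
    # closed-form index agrees with row position, in either argument order
    for (r in seq_len(nrow(pm))) {
      expect_equal(pair_index(pm[r, 1], pm[r, 2], n), r)
      expect_equal(pair_index(pm[r, 2], pm[r, 1], n), r)
    }
  }
  expect_error(pair_index(3, 3, 5), "self-pairs")
})

test_that("validate_graph flags shape and range violations", {
  g <- fixtures()$methane
  expect_length(validate_graph(g), 0)
  bad <- unclass(g)
  bad$bond_orders <- bad$bond_orders[-1]
  v <- validate_graph(bad)
  expect_length(v, 1)
  expect_equal(v[[1]]$field, "bond_orders")
  bad2 <- unclass(g)
  bad2$atom_types[2] <- g$vocab$atom$size + 1L  # beyond vocab, no MASK
  v2 <- validate_graph(bad2)
  expect_length(v2, 1)
  expect_equal(v2[[1]]$field, "atom_types")
  expect_error(molecule_graph(g$positions, g$atom_types, g$charges,
                              g$bond_orders[-1]),
               "invalid molecule graph")
})

test_that("benzene fixture parses to the expected graph from SDF", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(fixtures()$benzene, tf)
  mols <- read_sdf(tf)
  expect_length(mols, 1)
  g <- mols[[1]]
  expect_equal(g$n_atoms, 12)
  bt <- bond_table(g)
  expect_equal(sum(bt$order == 1.5), 6)  # aromatic ring
  expect_equal(sum(bt$order == 1), 6)    # C-H bonds
})

test_that("SDF round-trip preserves all fields at format precision", {
  fx <- fixtures()
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(fx, tf)
  back <- read_sdf(tf)
  expect_length(back, length(fx))
  for (k in seq_along(fx)) {
    expect_equal(back[[k]]$n_atoms, fx[[k]]$n_atoms)
    expect_equal(element_symbols(back[[k]]), element_symbols(fx[[k]]))
    expect_equal(charge_value(back[[k]]$charges),
                 charge_value(fx[[k]]$charges))
    expect_equal(back[[k]]$bond_orders, fx[[k]]$bond_orders)
    expect_lt(max(abs(back[[k]]$positions - fx[[k]]$positions)), 1e-4)
  }
})

test_that("empty and partially corrupt SDF files are handled per record", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines("", tf)
  expect_length(read_sdf(tf), 0)
  # a good record followed by a truncated one: warn and keep the good one
  write_sdf(fixtures()$methane, tf)
  txt <- readLines(tf)
  writeLines(c(txt, "broken", "record", "x", "$$$$"), tf)
  expect_warning(mols <- read_sdf(tf), "skipping")
  expect_length(mols, 1)
})

test_that("V3000 records are readable", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "v3k test", "", "",
    "  0  0  0  0  0  0  0  0  0  0999 V3000",
    "M  V30 BEGIN CTAB",
    "M  V30 COUNTS 3 2 0 0 0",
    "M  V30 BEGIN ATOM",
    "M  V30 1 O 0.0000 0.0000 0.0000 0",
    "M  V30 2 H 0.9600 0.0000 0.0000 0",
    "M  V30 3 H -0.2400 0.9300 0.0000 0",
    "M  V30 END ATOM",
    "M  V30 BEGIN BOND",
    "M  V30 1 1 1 2",
    "M  V30 2 1 1 3",
    "M  V30 END BOND",
    "M  V30 END CTAB",
    "M  END",
    "$$$$"), tf)
  mols <- read_sdf(tf)
  expect_length(mols, 1)
  expect_equal(element_symbols(mols[[1]]), c("O", "H", "H"))
  expect_equal(sum(mols[[1]]$bond_orders != 1L), 2)
})

test_that("charge vocabulary clamps out-of-range charges with a warning", {
  expect_warning(idx <- charge_index(c(0, -5, 4)), "clamped")
  expect_equal(charge_value(idx), c(0L, -2L, 3L))
})
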