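fx <- fixtures()

test_that("valency sums bond orders", {
  expect_equal(atom_valency(fx$methane, 1), 4)
  expect_equal(atom_valency(fx$benzene, 1), 4)  # 1.5 + 1.5 + 1
  lone <- molecule_graph(matrix(0, 1, 3), 2L, 3L, integer(0))
  expect_equal(atom_valency(lone, 1), 0)
})

test_that("stability accepts clean fixtures and rejects pentavalent carbon", {
  clean <- fx[setdiff(names(fx), "pentavalent")]
  expect_equal(unname(stability(clean)),
               c(100, 100), tolerance = 1e-12)
  st <- stability(fx$pentavalent)
  expect_equal(unname(st["mols_stable_pct"]), 0)
  mixed <- stability(list(fx$methane, fx$pentavalent))
  expect_equal(unname(mixed["mols_stable_pct"]), 50)
})

test_that("toolkit validity agrees with stability on the fixtures", {
  expect_equal(validity(list(fx$benzene)), 100)
  expect_equal(validity(list(fx$pentavalent)), 0)
  expect_equal(validity(fx[setdiff(names(fx), "pentavalent")]), 100)
  expect_error(validity(list()), "empty")
})

test_that("JS divergence identities", {
  e <- rnorm(100)
  expect_equal(energy_js(e, e), 0)
  # disjoint supports -> ln 2
  expect_equal(energy_js(rep(0, 50), rep(10, 50), n_bins = 10), log(2),
               tolerance = 1e-9)
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)), 0.2157616,
               tolerance = 1e-6)
  # symmetry and bounds on random histograms
  set.seed(6)
  for (r in 1:10) {
    p <- runif(8); q <- runif(8)
    expect_equal(js_divergence(p, q), js_divergence(q, p))
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), log(2) + 1e-12)
  }
  expect_error(energy_js(NA, 1:3), "finite")
})

test_that("MMFF single-point energies exist and are translation invariant", {
  e <- mmff_energy(fx$methane)
  expect_true(is.finite(e))
  shifted <- fx$methane
  shifted$positions <- shifted$positions + 5
  expect_equal(mmff_energy(shifted), e, tolerance = 1e-6)
  expect_true(is.na(mmff_energy(fx$pentavalent)))
})

test_that("alert counting is distinct-pattern per molecule", {
  catalog <- read_alert_catalog(system.file("extdata", "alerts_mini.tsv",
                                            package = "dfmol"))
  expect_equal(as.numeric(alert_rate(fx$methane, catalog)), 0)
  # one-pattern nitro catalog matches nitrobenzene exactly once
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("nitro\t[N+](=O)[O-]\tGlaxo", tf)
  one <- read_alert_catalog(tf)
  expect_equal(as.numeric(alert_rate(fx$nitrobenzene, one)), 1)
  expect_equal(as.numeric(alert_rate(fx$benzene, one)), 0)
  # additive over disjoint catalogs
  full <- as.numeric(alert_rate(fx$nitrobenzene, catalog))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("azo\tN=N\tDundee"), tf2)
  expect_equal(full + as.numeric(alert_rate(fx$nitrobenzene,
                                            read_alert_catalog(tf2))),
               as.numeric(alert_rate(fx$nitrobenzene, catalog)) + 0)
})

test_that("ring systems merge fused rings and separate disconnected ones", {
  expect_length(ring_systems(fx$benzene), 1)
  expect_length(ring_systems(fx$naphthalene), 1)
  rs <- ring_systems(fx$biphenyl)
  expect_length(rs, 2)
  expect_equal(rs[1], rs[2])  # both benzene keys
  expect_length(ring_systems(fx$methane), 0)
})

test_that("OOD ring rate counts unreferenced ring systems", {
  ref <- read_ring_reference(system.file("extdata",
                                         "ring_reference_synthetic.tsv",
                                         package = "dfmol"))
  expect_equal(as.numeric(ood_ring_rate(list(fx$benzene, fx$benzene), ref)),
               0)
  # a reference without the naphthalene key sees one OOD system
  small <- ref["c1ccccc1"]
  expect_equal(as.numeric(ood_ring_rate(list(fx$naphthalene), small)), 1)
  expect_equal(as.numeric(ood_ring_rate(list(fx$methane), ref)), 0)
})

test_that("evaluate_batch reports means with CI conventions", {
  batch <- list(fx$methane, fx$benzene)
  r1 <- evaluate_batch(list(batch), use_rdkit = FALSE)
  expect_true(all(r1$ci95 == 0))
  r2 <- evaluate_batch(list(batch, batch), use_rdkit = FALSE)
  expect_true(all(r2$ci95 == 0))  # identical repeats
  expect_equal(r2$mean[r2$metric == "mols_stable_pct"], 100)
  # distinct repeats give positive widths
  r3 <- evaluate_batch(list(list(fx$methane), list(fx$pentavalent)),
                       use_rdkit = FALSE)
  expect_gt(r3$ci95[r3$metric == "mols_stable_pct"], 0)
})
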