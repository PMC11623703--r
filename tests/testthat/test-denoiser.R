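test_that("denoiser output shapes follow the input molecule", {
  den <- untrained_denoiser("continuous", seed = 5)
  for (n in c(3, 7, 12)) {
    vocab <- den$vocab
    gstate <- list(
      positions = matrix(rnorm(n * 3), n),
      atom = sample_prior("continuous", n, n_real_classes(vocab$atom)),
      charge = sample_prior("continuous", n, n_real_classes(vocab$charge)),
      bond = sample_prior("continuous", n_pairs(n),
                          n_real_classes(vocab$bond)),
      vocab = vocab)
    out <- denoiser_predict(den, gstate, 0.3)
    expect_equal(dim(out$positions_hat), c(n, 3))
    expect_equal(dim(out$atom_logits), c(n, n_real_classes(vocab$atom)))
    expect_equal(dim(out$bond_logits),
                 c(n_pairs(n), n_real_classes(vocab$bond)))
    expect_true(all(is.finite(unlist(out))))
  }
})

test_that("position predictions are translation equivariant", {
  den <- untrained_denoiser("continuous", seed = 6)
  n <- 6
  vocab <- den$vocab
  gstate <- list(
    positions = matrix(rnorm(n * 3), n),
    atom = sample_prior("continuous", n, n_real_classes(vocab$atom)),
    charge = sample_prior("continuous", n, n_real_classes(vocab$charge)),
    bond = sample_prior("continuous", n_pairs(n),
                        n_real_classes(vocab$bond)),
    vocab = vocab)
  out1 <- denoiser_predict(den, gstate, 0.5)
  v <- c(3.2, -1.1, 0.4)
  gstate$positions <- sweep(gstate$positions, 2, v, `+`)
  out2 <- denoiser_predict(den, gstate, 0.5)
  expect_equal(out2$positions_hat,
               sweep(out1$positions_hat, 2, v, `+`), tolerance = 1e-9)
  expect_equal(out2$atom_logits, out1$atom_logits, tolerance = 1e-9)
})

test_that("training reduces the loss and is seed-reproducible", {
  mols <- toy_training_set(60, seed = 19)
  d1 <- train_toy_denoiser(mols, "ctmc", epochs = 60, seed = 3,
                           hidden = 24)
  d2 <- train_toy_denoiser(mols, "ctmc", epochs = 60, seed = 3,
                           hidden = 24)
  expect_identical(d1$history, d2$history)
  expect_lt(mean(tail(d1$history, 10)), d1$history[1])
  # smoothed history is decreasing overall
  sm <- stats::filter(d1$history, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_error(train_toy_denoiser(mols, "ctmc", epochs = 0), "epochs")
})

test_that("checkpoints reload bit-exactly", {
  mols <- toy_training_set(60, seed = 19)
  den <- train_toy_denoiser(mols, "simplex", epochs = 20, seed = 4,
                            hidden = 16)
  tf <- withr::local_tempfile(fileext = ".rds")
  save_denoiser(den, tf)
  back <- load_denoiser(tf)
  expect_identical(back$params, den$params)
  expect_identical(back$history, den$history)
  capture.output(d <- describe(back))
  expect_identical(d$n_parameters, sum(vapply(den$params, length, 0L)))
})

test_that("a trained ctmc denoiser beats uniform logits on held-out data", {
  train <- toy_training_set()
  den <- trained_model("ctmc", seed = 1)
  held <- generate_toy_dataset(toy_cfg, 40, seed = 77)
  vocab <- den$vocab
  # held-out atom-type cross-entropy at mid-trajectory states
  set.seed(5)
  tot_ce <- 0; tot_unif <- 0; n_tot <- 0
  for (g in held) {
    n <- g$n_atoms
    x0 <- sample_prior("ctmc", n, vocab$atom$size)
    at <- sample_conditional_path("ctmc", x0, g$atom_types, 0.5)
    gstate <- list(
      positions = 0.5 * sample_prior("euclidean", n)$vectors +
        0.5 * sweep(g$positions, 2, colMeans(g$positions)),
      atom = at,
      charge = sample_conditional_path("ctmc",
        sample_prior("ctmc", n, vocab$charge$size), g$charges, 0.5),
      bond = sample_conditional_path("ctmc",
        sample_prior("ctmc", n_pairs(n), vocab$bond$size),
        g$bond_orders, 0.5),
      vocab = vocab)
    out <- denoiser_predict(den, gstate, 0.5)
    tot_ce <- tot_ce + ce_loss(out$atom_logits, g$atom_types) * n
    tot_unif <- tot_unif +
      ce_loss(matrix(0, n, n_real_classes(vocab$atom)), g$atom_types) * n
    n_tot <- n_tot + n
  }
  expect_lt(tot_ce / n_tot, tot_unif / n_tot)
})

test_that("ctmc training collapses the atom-type cross-entropy", {
  # heavy atoms span the three classes C, N, O on short chains; after 200
  # epochs the atom CE settles around 0.2-0.3x its initial value (pilot
  # runs over three seeds gave ratios 0.21-0.31; the residual is the
  # genuine conditional entropy of masked states at small t)
  cfg3 <- toy_config(n_heavy_range = 3:4, p_ring = 0)
  mols <- generate_toy_dataset(cfg3, 80, seed = 23)
  den <- train_toy_denoiser(mols, "ctmc", epochs = 200, seed = 2,
                            hidden = 48)
  hm <- den$history_by_modality
  expect_lt(mean(tail(hm[, "a"], 20)), 0.45 * hm[1, "a"])
  expect_lt(mean(tail(den$history, 20)), 0.6 * mean(head(den$history, 5)))
})
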