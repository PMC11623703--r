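test_that("regression loss identities and permutation invariance", {
  expect_equal(regression_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(regression_loss(c(0, 0), c(0, 1)), 0.5)
  expect_error(regression_loss(matrix(0, 2, 3), matrix(0, 3, 2)),
               "shape mismatch")
  set.seed(1)
  x <- matrix(rnorm(30), 10); y <- matrix(rnorm(30), 10)
  p <- sample(10)
  expect_equal(regression_loss(x, y), regression_loss(x[p, ], y[p, ]))
})

test_that("cross-entropy identities", {
  # saturated logits at the target -> ~0
  l <- ce_loss(matrix(c(1000, 0, 0, 0), 1), 1L)
  expect_lt(l, 1e-6)
  # uniform logits over 4 classes -> ln 4
  expect_equal(ce_loss(matrix(0, 5, 4), rep(2L, 5)), log(4))
  # nonnegative on random inputs
  set.seed(2)
  for (r in 1:20) {
    D <- sample(2:6, 1); n <- sample(1:8, 1)
    expect_gte(ce_loss(matrix(rnorm(n * D), n), sample.int(D, n, TRUE)), 0)
  }
  expect_error(ce_loss(matrix(0, 1, 4), 5L, mask_index = 5L), "MASK")
})

test_that("total loss is a weighted sum, linear in weights and losses", {
  w1 <- loss_weights(1, 1, 1, 1)
  expect_equal(total_loss(list(x = 1, a = 2, c = 3, e = 4), w1), 10)
  expect_equal(total_loss(list(x = 0.5), loss_weights(2, 0, 0, 0)), 1)
  l <- list(x = 0.3, a = 0.7, c = 0.1, e = 0.9)
  expect_equal(total_loss(l, loss_weights(6, 2, 2, 2)),
               2 * total_loss(l, loss_weights(3, 1, 1, 1)))
  expect_error(loss_weights(0, 0, 0, 0), "at least one positive")
})

test_that("training times are uniform on [0, 1)", {
  t <- sample_training_time(1e5, seed = 4)
  expect_true(all(t >= 0 & t < 1))
  expect_lt(abs(mean(t) - 0.5), 3 * sqrt(1 / 12 / 1e5))
  expect_identical(sample_training_time(10, seed = 1),
                   sample_training_time(10, seed = 1))
  expect_error(sample_training_time(0), ">= 1")
})

test_that("analytic gradients match finite differences", {
  # small model + batch; compare d(total loss)/d(theta) on sampled
  # coordinates of every parameter block against central differences
  set.seed(10)
  mols <- generate_toy_dataset(toy_cfg, 4, seed = 21)
  for (variant in c("ctmc", "continuous")) {
    vocab <- default_vocabs(mask = variant == "ctmc")
    dims <- dfmol:::.model_dims(vocab, variant, 6)
    params <- dfmol:::.init_params(dims, seed = 2)
    prep <- dfmol:::.prepare_dataset(mols, vocab)
    set.seed(3)
    st <- dfmol:::.sample_epoch_states(prep, variant, 100, 1e-3)
    feats <- dfmol:::.features(dims, st$positions, st$a_mat, st$c_mat,
                               st$e_mat, prep$mol_id_atom, prep$mol_id_pair,
                               prep$pair_i, prep$pair_j, st$t_atom,
                               st$t_pair, prep$sizes)
    targets <- list(atom = prep$atom, charge = prep$charge,
                    bond = prep$bond, X1 = prep$X1)
    w <- loss_weights()
    use_ce <- variant == "ctmc"
    fwd <- dfmol:::.forward(params, feats)
    bk <- dfmol:::.backward(params, feats, fwd, targets, w, use_ce)
    h <- 1e-5
    for (nm in names(params)) {
      for (probe in 1:3) {
        i <- sample(length(params[[nm]]), 1)
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
        fd <- (dfmol:::.loss_only(pp, feats, targets, w, use_ce) -
                 dfmol:::.loss_only(pm, feats, targets, w, use_ce)) / (2 * h)
        an <- bk$grads[[nm]][i]
        denom <- max(abs(fd), abs(an), 1e-4)
        expect_lt(abs(fd - an) / denom, 1e-4)
      }
    }
  }
})
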