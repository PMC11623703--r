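test_that("euler step arithmetic", {
  expect_equal(euler_step(0, 1.6, 0.1), 0.16)
  x <- matrix(runif(6), 2)
  expect_equal(euler_step(x, x * 0, 0.3), x)
  expect_error(euler_step(1, 1, 0), "positive")
})

test_that("ctmc step: absorbing states, unmask probability, final resolve", {
  p1 <- matrix(c(1, 0), 1)  # delta at class 1
  # unmasked positions never change
  for (r in 1:20)
    expect_equal(ctmc_step(2L, matrix(c(0.5, 0.5), 1), 0.5, 0.1, 3L), 2L)
  # unmask frequency dt/(1-t) = 0.2 within 3 sigma (binomial)
  set.seed(3)
  n <- 1e5
  x <- rep(3L, n)
  p <- matrix(rep(c(1, 0), each = n), n)
  out <- ctmc_step(x, p, 0.5, 0.1, 3L)
  f <- mean(out != 3L)
  expect_lt(abs(f - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_true(all(out[out != 3L] == 1L))
  # final step resolves every mask
  out <- ctmc_step(rep(3L, 50), matrix(0.5, 50, 2), 0.99, 0.01, 3L)
  expect_true(all(out != 3L))
  expect_error(ctmc_step(3L, matrix(c(0.7, 0.6), 1), 0.1, 0.1, 3L),
               "normalized")
})

test_that("K-step ctmc sampler matches the exact chain law", {
  # 2 real classes + MASK, constant denoiser distribution
  p_cls <- c(0.7, 0.3)
  exact_chain <- function(K) {
    # state vector over (mask, 1, 2); exact product of transition matrices
    v <- c(1, 0, 0)
    for (k in 0:(K - 1)) {
      t <- k / K
      pu <- if (k == K - 1) 1 else min(1, (1 / K) / (1 - t))
      Tm <- rbind(c(1 - pu, pu * p_cls[1], pu * p_cls[2]),
                  c(0, 1, 0), c(0, 0, 1))
      v <- as.vector(v %*% Tm)
    }
    v
  }
  set.seed(17)
  n <- 1e5
  for (K in c(4, 10)) {
    x <- rep(3L, n)
    p <- matrix(rep(p_cls, each = n), n)
    for (k in 0:(K - 1)) x <- ctmc_step(x, p, k / K, 1 / K, 3L)
    v <- exact_chain(K)
    expect_equal(v[1], 0)            # all masks resolved
    emp <- c(mean(x == 3L), mean(x == 1L), mean(x == 2L))
    for (j in 2:3)
      expect_lt(abs(emp[j] - v[j]), 3 * sqrt(v[j] * (1 - v[j]) / n))
  }
})

test_that("size sampling follows the histogram", {
  expect_equal(sample_sizes(c("5" = 1), 3), c(5L, 5L, 5L))
  expect_equal(sample_sizes(c("4" = 1), 0), integer(0))
  set.seed(2)
  s <- sample_sizes(c("4" = 0.5, "6" = 0.5), 1e4)
  expect_lt(abs(mean(s == 4) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_error(sample_sizes(c("4" = 0), 5), "positive total")
})

test_that("a memorizing denoiser reproduces its molecule for every variant", {
  g <- generate_toy_dataset(toy_cfg, 1, seed = 33)[[1]]
  for (variant in c("ctmc", "continuous", "simplex", "dirichlet")) {
    vocab <- default_vocabs(mask = variant == "ctmc")
    den <- memorize_denoiser(g)
    cfg <- sampler_config(variant, n_steps = 25, seed = 5)
    out <- generate(den, 3, stats::setNames(1, g$n_atoms), cfg,
                    vocab = vocab)
    for (s in out) {
      expect_equal(s$atom_types, g$atom_types)
      expect_equal(s$charges, g$charges)
      expect_equal(s$bond_orders, g$bond_orders)
      expect_length(validate_graph(s), 0)
      expect_false(has_mask(s))
    }
  }
})

test_that("generation is deterministic under a fixed seed", {
  g <- generate_toy_dataset(toy_cfg, 1, seed = 33)[[1]]
  den <- memorize_denoiser(g)
  cfg <- sampler_config("ctmc", n_steps = 10, seed = 99)
  a <- generate(den, 2, stats::setNames(1, g$n_atoms), cfg,
                vocab = default_vocabs(mask = TRUE))
  b <- generate(den, 2, stats::setNames(1, g$n_atoms), cfg,
                vocab = default_vocabs(mask = TRUE))
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  expect_equal(generate(den, 0, c("5" = 1), cfg,
                        vocab = default_vocabs(mask = TRUE)), list())
})

test_that("ctmc trajectories never leave the discrete vocabulary", {
  g <- generate_toy_dataset(toy_cfg, 1, seed = 4)[[1]]
  den <- memorize_denoiser(g)
  cfg <- sampler_config("ctmc", n_steps = 12, seed = 7, record = "raw")
  out <- generate(den, 1, stats::setNames(1, g$n_atoms), cfg,
                  vocab = default_vocabs(mask = TRUE))[[1]]
  traj <- attr(out, "trajectory")
  for (snap in traj$raw) {
    for (md in c("atom", "charge", "bond")) {
      expect_equal(snap[[md]]$kind, "indices")
      expect_true(all(snap[[md]]$indices >= 1 &
                        snap[[md]]$indices <= snap[[md]]$D))
    }
  }
})

test_that("denoiser contract violations name the modality", {
  g <- generate_toy_dataset(toy_cfg, 1, seed = 3)[[1]]
  bad <- function(gstate, t) {
    out <- memorize_denoiser(g)(gstate, t)
    out$charge_logits <- out$charge_logits[, 1:2]
    out
  }
  expect_error(
    generate(bad, 1, stats::setNames(1, g$n_atoms),
             sampler_config("continuous", n_steps = 5, seed = 1),
             vocab = default_vocabs()),
    "charge")
})
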