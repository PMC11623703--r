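test_that("priors have the stated laws", {
  set.seed(42)
  # ctmc: deterministic all-MASK
  s <- sample_prior("ctmc", 5, 5, mask_index = 5)
  expect_equal(s$indices, rep(5L, 5))
  # euclidean: center of mass removed
  s <- sample_prior("euclidean", 7)
  expect_lt(max(abs(colMeans(s$vectors))), 1e-9)
  # simplex: uniform on the simplex; per-coordinate mean 1/3 within 3 SE
  n <- 1e4
  s <- sample_prior("simplex", n, 3)
  expect_true(all(abs(s$vectors) <= 1), label = "simplex coords bounded")
  expect_lt(max(abs(rowSums(s$vectors) - 1)), 1e-9)
  se <- sqrt(1 / 18 / n)  # Var of Dirichlet(1,1,1) coordinate = 1/18
  expect_true(all(abs(colMeans(s$vectors) - 1 / 3) < 3 * se))
  # continuous: standard normal moments
  s <- sample_prior("continuous", n, 4)
  expect_lt(abs(mean(s$vectors)), 3 / sqrt(n * 4))
  expect_lt(abs(stats::sd(s$vectors) - 1), 0.02)
  expect_error(sample_prior("bogus", 3, 4), "unknown variant")
  expect_error(sample_prior("simplex", 3, 1), "D >= 2")
})

test_that("conditional paths hit both endpoints", {
  x1 <- c(2L, 1L, 3L)
  # ctmc endpoints are exact
  x0 <- sample_prior("ctmc", 3, 4, mask_index = 4)
  expect_equal(sample_conditional_path("ctmc", x0, x1, 0)$indices,
               rep(4L, 3))
  expect_equal(sample_conditional_path("ctmc", x0, x1, 1)$indices, x1)
  # linear interpolants: exact endpoints and exact midpoint arithmetic
  for (v in c("continuous", "simplex")) {
    x0 <- sample_prior(v, 3, 3, seed = 7)
    expect_equal(sample_conditional_path(v, x0, x1, 0)$vectors, x0$vectors)
    expect_equal(sample_conditional_path(v, x0, x1, 1)$vectors,
                 onehot_matrix(x1, 3))
    mid <- sample_conditional_path(v, x0, x1, 0.5)$vectors
    expect_equal(mid, 0.5 * x0$vectors + 0.5 * onehot_matrix(x1, 3))
  }
  # euclidean linear path
  x0 <- sample_prior("euclidean", 3)
  X1 <- matrix(rnorm(9), 3)
  expect_equal(sample_conditional_path("euclidean", x0, X1, 0.25)$vectors,
               0.75 * x0$vectors + 0.25 * X1)
  expect_error(sample_conditional_path("ctmc", x0, x1, 1.5), "\\[0, 1\\]")
  expect_error(sample_conditional_path("ctmc",
               sample_prior("ctmc", 3, 4), c(1L, 4L, 2L), 0.5),
               "real")
})

test_that("ctmc path marginal matches P(x_t = x1) = t", {
  set.seed(101)
  n <- 1e5
  x0 <- sample_prior("ctmc", n, 3, mask_index = 3)
  x1 <- rep(2L, n)
  for (t in c(0.1, 0.5, 0.9)) {
    xt <- sample_conditional_path("ctmc", x0, x1, t)$indices
    freq <- mean(xt == 2L)
    expect_lt(abs(freq - t), 3 * sqrt(t * (1 - t) / n))
  }
})

test_that("dirichlet path is on-simplex throughout and collapses at t = 1", {
  set.seed(5)
  n <- 1e4
  x0 <- sample_prior("dirichlet", n, 4)
  x1 <- sample.int(4, n, replace = TRUE)
  for (t in seq(0, 1, by = 0.1)) {
    xt <- sample_conditional_path("dirichlet", x0, x1, t)$vectors
    expect_lt(max(abs(rowSums(xt) - 1)), 1e-6)
    expect_true(all(xt >= 0))
  }
  # total variation between argmax law and the endpoint at t = 1
  xt <- sample_conditional_path("dirichlet", x0, x1, 1)$vectors
  expect_lt(mean(max.col(xt) != x1), 0.05)
})

test_that("linear vector field arithmetic and fixed point", {
  xt <- modality_state(vectors = matrix(0.2, 1, 1))
  u <- conditional_vector_field("continuous", xt,
                                matrix(1.0, 1, 1), 0.5)
  expect_equal(as.numeric(u), 1.6)
  for (v in c("continuous", "simplex", "euclidean")) {
    x <- modality_state(vectors = matrix(runif(6), 2, 3))
    expect_equal(conditional_vector_field(v, x, x$vectors, 0.3),
                 matrix(0, 2, 3))
  }
  expect_error(conditional_vector_field("continuous", xt,
                                        matrix(1, 1, 1), 1), "singular")
})

test_that("simplex Euler updates stay on the simplex for dt <= 1 - t", {
  set.seed(8)
  x <- sample_prior("simplex", 20, 5)
  p_hat <- .runif_simplex_test(20, 5)
  t <- 0.4
  for (dt in c(0.1, 0.3, 0.6)) {
    u <- conditional_vector_field("simplex", x, p_hat, t)
    xn <- euler_step(x$vectors, u, dt)
    expect_lt(max(abs(rowSums(xn) - 1)), 1e-9)
    expect_true(all(xn >= -1e-12))
  }
})

test_that("dirichlet field is tangent to the simplex", {
  set.seed(9)
  for (t in c(0.1, 0.5, 0.9)) {
    x <- sample_prior("dirichlet", 30, 4)
    p_hat <- .runif_simplex_test(30, 4)
    u <- conditional_vector_field("dirichlet", x, p_hat, t)
    expect_lt(max(abs(rowSums(u))), 1e-8)
    expect_true(all(is.finite(u)))
  }
})

test_that("beta schedule is monotone from 0 to the cap", {
  b <- beta_schedule(seq(0, 1, by = 0.05))$beta
  expect_equal(b[1], 0)
  expect_equal(b[length(b)], 100)
  expect_true(all(diff(b) >= 0))
})
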