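# Conditional probability paths for every flow variant, sampleable without
# simulation at any t in [0, 1].
#
# Categorical modalities can be generated by one of four interchangeable
# formulations:
#   continuous - flows from a Gaussian prior to one-hot vertices
#   simplex    - linear interpolants constrained to the probability simplex
#   dirichlet  - Dirichlet paths with a concentration that diverges as t -> 1
#   ctmc       - discrete-state mask flow (tokens jump from MASK to classes)
# Positions always use the euclidean variant (Gaussian prior, linear path).

.cat_variants <- c("continuous", "simplex", "dirichlet", "ctmc")
.all_variants <- c(.cat_variants, "euclidean")

.check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1 ||
      !(variant %in% .all_variants))
    stop("unknown variant: ", paste(variant, collapse = ","),
         " (expected one of ", paste(.all_variants, collapse = ", "), ")")
  variant
}

#' Modality state
#'
#' The time-t state of one categorical modality: either integer class
#' indices (CTMC) or an `n x D` real matrix (continuous variants), never
#' both.
#'
#' @param indices Integer vector of class indices, or `NULL`.
#' @param vectors Numeric matrix, or `NULL`.
#' @param D Number of classes (inferred from `vectors` when absent).
#' @param mask_index Optional MASK index carried along for CTMC states.
#' @return Object of class `dfmol_state` with fields `kind`
#'   (`"indices"`/`"vectors"`), `indices` or `vectors`, `D`, `mask_index`.
#' @export
modality_state <- function(indices = NULL, vectors = NULL, D = NULL,
                           mask_index = NA_integer_) {
  if (is.null(indices) == is.null(vectors))
    stop("exactly one of indices/vectors must be given")
  if (!is.null(vectors)) {
    vectors <- as.matrix(vectors)
    structure(list(kind = "vectors", vectors = vectors, D = ncol(vectors),
                   mask_index = NA_integer_), class = "dfmol_state")
  } else {
    if (is.null(D)) stop("D required for index states")
    structure(list(kind = "indices", indices = as.integer(indices), D = D,
                   mask_index = as.integer(mask_index)),
              class = "dfmol_state")
  }
}

#' Number of entries in a modality state
#' @param s A `dfmol_state`.
#' @return Integer count of positions (atoms or pairs).
#' @export
state_length <- function(s)
  if (s$kind == "indices") length(s$indices) else nrow(s$vectors)

# uniform draw on the (D-1)-simplex: normalized unit-rate exponentials
.runif_simplex <- function(n, D) {
  g <- matrix(stats::rexp(n * D), n, D)
  g / rowSums(g)
}

.rdirichlet <- function(alpha) {
  # alpha: n x D matrix of concentrations
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
  g / rowSums(g)
}

#' Sample the prior of a flow variant
#'
#' Priors: standard normal vectors (continuous), uniform on the simplex
#' (simplex, dirichlet), all-MASK (ctmc), and center-of-mass-free standard
#' normal 3D coordinates (euclidean).
#'
#' @param variant One of `"continuous"`, `"simplex"`, `"dirichlet"`,
#'   `"ctmc"`, `"euclidean"`.
#' @param n Number of positions (atoms or pairs).
#' @param D Vocabulary size (>= 2 for categorical variants; for `ctmc` this
#'   is the size including the MASK class). Ignored for `euclidean`.
#' @param mask_index MASK index for `ctmc` (defaults to `D`).
#' @param seed Optional RNG seed.
#' @return A `dfmol_state`.
#' @export
sample_prior <- function(variant, n, D = NULL, mask_index = NULL,
                         seed = NULL) {
  .check_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  if (variant != "euclidean" && (is.null(D) || D < 2))
    stop("categorical variants require D >= 2")
  switch(variant,
    continuous = modality_state(vectors = matrix(stats::rnorm(n * D), n, D)),
    simplex = ,
    dirichlet = modality_state(vectors = .runif_simplex(n, D)),
    ctmc = {
      if (is.null(mask_index)) mask_index <- D
      modality_state(indices = rep(mask_index, n), D = D,
                     mask_index = mask_index)
    },
    euclidean = {
      x <- matrix(stats::rnorm(n * 3), n, 3)
      modality_state(vectors = sweep(x, 2, colMeans(x)))
    })
}

#' Dirichlet concentration schedule
#'
#' Monotone in t with `beta(0) = 0` and `beta(1) = beta_max`; the
#' concentration grows like `t / (1 - t)` and is capped so arithmetic stays
#' finite.
#'
#' @param t Time(s) in `[0, 1]`.
#' @param beta_max Concentration cap (default 100).
#' @param eps Regularizer of the denominator.
#' @return List with `beta` and its time derivative `dbeta` (0 at the cap).
#' @export
beta_schedule <- function(t, beta_max = 100, eps = 1e-3) {
  raw <- beta_max * t / (1 - t + eps)
  capped <- raw >= beta_max
  list(beta = ifelse(capped, beta_max, raw),
       dbeta = ifelse(capped, 0, beta_max * (1 + eps) / (1 - t + eps)^2))
}

#' Sample the conditional probability path at time t
#'
#' Draws `x_t ~ p_t(. | x0, x1)`. Linear interpolants for continuous,
#' simplex and euclidean variants; an independent mask/data mixture with
#' `P(x_t = x1) = t` for ctmc; and `Dirichlet(1 + beta(t) * onehot(x1))`
#' for dirichlet. At t = 0 the path law equals the prior; at t = 1 it
#' equals the data endpoint (dirichlet: within tolerance at the
#' concentration cap).
#'
#' @param variant Flow variant.
#' @param x0 Prior draw (`dfmol_state`), as from [sample_prior()]. Unused
#'   by `ctmc` and `dirichlet`, whose paths do not depend on x0.
#' @param x1 Data endpoint: integer class indices for categorical variants,
#'   or an `n x 3` coordinate matrix for `euclidean`.
#' @param t Time in `[0, 1]`.
#' @param beta_max,eps Dirichlet schedule parameters.
#' @param seed Optional RNG seed.
#' @return A `dfmol_state`.
#' @export
sample_conditional_path <- function(variant, x0, x1, t, beta_max = 100,
                                    eps = 1e-3, seed = NULL) {
  .check_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  if (length(t) != 1 || is.na(t) || t < 0 || t > 1)
    stop("t must be a scalar in [0, 1]")
  if (variant == "euclidean") {
    x1 <- as.matrix(x1)
    return(modality_state(vectors = (1 - t) * x0$vectors + t * x1))
  }
  x1 <- as.integer(x1)
  D_real <- if (variant == "ctmc") x0$D - 1L else x0$D
  if (anyNA(x1) || any(x1 < 1L | x1 > D_real))
    stop("x1 must be class indices over the real (non-MASK) classes")
  switch(variant,
    continuous = ,
    simplex = {
      y <- onehot_matrix(x1, x0$D)
      modality_state(vectors = (1 - t) * x0$vectors + t * y)
    },
    dirichlet = {
      b <- beta_schedule(t, beta_max, eps)$beta
      alpha <- matrix(1, length(x1), x0$D)
      alpha[cbind(seq_along(x1), x1)] <- 1 + b
      modality_state(vectors = .rdirichlet(alpha))
    },
    ctmc = {
      mask <- x0$mask_index
      keep <- stats::runif(length(x1)) < t
      modality_state(indices = ifelse(keep, x1, mask), D = x0$D,
                     mask_index = mask)
    })
}

# Dirichlet flow coefficient c(x_i, t): the 1-D marginal x_i follows
# Beta(1 + beta(t), D - 1); mass transport along x = e_i + s(x - e_i) gives
# velocity v = -dF/dt / pdf and c = v / (1 - x_i). dI/dbeta is evaluated by
# central difference of the regularized incomplete beta function.
.dirichlet_coeff <- function(xi, t, D, beta_max = 100, eps = 1e-3,
                             c_max = 1e4) {
  sch <- beta_schedule(t, beta_max, eps)
  if (sch$dbeta == 0) return(rep(0, length(xi)))
  a <- 1 + sch$beta
  h <- 1e-4 * max(1, sch$beta)
  dIdb <- (stats::pbeta(xi, a + h, D - 1) -
             stats::pbeta(xi, a - h, D - 1)) / (2 * h)
  dens <- stats::dbeta(xi, a, D - 1)
  v <- -sch$dbeta * dIdb / pmax(dens, 1e-12)
  c_val <- v / pmax(1 - xi, 1e-12)
  pmin(pmax(c_val, 0), c_max)
}

#' Conditional vector field of a continuous-state variant
#'
#' For continuous, simplex and euclidean variants this is the linear-path
#' field `(x1_hat - x_t) / (1 - t)`; for the simplex variant, Euler updates
#' with `dt <= 1 - t` provably stay on the simplex whenever `x1_hat` rows
#' do. For the dirichlet variant the field is the denoiser-weighted mixture
#' of per-vertex Dirichlet-flow fields,
#' `u = sum_i p_hat_i c(x_i, t) (e_i - x)`, which is tangent to the simplex.
#'
#' @param variant A continuous-state variant (not `"ctmc"`).
#' @param x_t Current state (`dfmol_state` with vectors).
#' @param x1_hat Denoiser estimate of the endpoint: an `n x D` matrix; for
#'   categorical variants its rows are class probabilities.
#' @param t Time, `t < 1`.
#' @param beta_max,eps Dirichlet schedule parameters.
#' @return `n x D` velocity matrix.
#' @export
conditional_vector_field <- function(variant, x_t, x1_hat, t,
                                     beta_max = 100, eps = 1e-3) {
  .check_variant(variant)
  if (variant == "ctmc")
    stop("ctmc is a jump process; use ctmc_step()")
  if (t >= 1) stop("vector field is singular at t >= 1")
  x <- x_t$vectors
  x1_hat <- as.matrix(x1_hat)
  if (!all(dim(x) == dim(x1_hat)))
    stop("x1_hat shape mismatch")
  if (variant != "dirichlet") return((x1_hat - x) / (1 - t))
  cmat <- matrix(.dirichlet_coeff(as.vector(x), t, x_t$D, beta_max, eps),
                 nrow(x), ncol(x))
  w <- x1_hat * cmat
  u <- w - rowSums(w) * x
  # total outflow rate per row; Euler steps with dt * rate <= 1 are convex
  # combinations and therefore stay on the simplex (used for step damping)
  attr(u, "mass_rate") <- rowSums(w)
  u
}
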