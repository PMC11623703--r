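# Generation-time integration: Euler steps for continuous-state variants,
# jump transitions for the CTMC variant, and the joint multi-modality
# molecule generation loop on an evenly spaced time grid.

#' Sampler configuration
#'
#' @param variant Categorical flow variant applied to atom types, charges
#'   and bond orders (positions always use the euclidean flow).
#' @param n_steps Number of Euler steps K (>= 2); the time grid is
#'   `0, 1/K, ..., 1`.
#' @param seed Optional RNG seed used by [generate()].
#' @param record One of `"none"`, `"argmax"` (per-grid-point class indices
#'   and denoiser argmax, for assignment-time diagnostics), `"raw"`
#'   (additionally the full modality states).
#' @param beta_max,eps Dirichlet schedule parameters.
#' @return List of class `dfmol_sampler_config`.
#' @export
sampler_config <- function(variant = "ctmc", n_steps = 100, seed = NULL,
                           record = "none", beta_max = 100, eps = 1e-3) {
  .check_variant(variant)
  if (variant == "euclidean") stop("variant applies to categorical modalities")
  if (n_steps < 2) stop("n_steps must be >= 2")
  record <- match.arg(record, c("none", "argmax", "raw"))
  structure(list(variant = variant, n_steps = as.integer(n_steps),
                 seed = seed, record = record, beta_max = beta_max,
                 eps = eps, final_discretization = "argmax"),
            class = "dfmol_sampler_config")
}

#' One explicit Euler step
#' @param x_t Numeric vector/matrix state.
#' @param u Velocity of matching shape.
#' @param dt Step size (> 0).
#' @return `x_t + dt * u`.
#' @export
euler_step <- function(x_t, u, dt) {
  if (dt <= 0) stop("dt must be positive")
  x_t + dt * u
}

#' One CTMC jump step
#'
#' Masked positions unmask with probability `dt / (1 - t)`, drawing the
#' revealed class from the denoiser distribution over real classes;
#' unmasked positions are absorbing. On the final step (`t + dt` reaching
#' 1) all remaining masks are resolved by sampling the denoiser
#' distribution, so outputs are always mask-free at t = 1.
#'
#' @param x_t Integer class indices (MASK = `mask_index`).
#' @param p1_hat `n x D_real` matrix; each row a probability distribution
#'   over the real (non-MASK) classes.
#' @param t Current time, `t + dt <= 1`.
#' @param dt Step size.
#' @param mask_index Index of the MASK class.
#' @return Integer indices after the step.
#' @export
ctmc_step <- function(x_t, p1_hat, t, dt, mask_index) {
  p1_hat <- as.matrix(p1_hat)
  if (length(x_t) != nrow(p1_hat)) stop("p1_hat row count mismatch")
  if (t + dt > 1 + 1e-9) stop("t + dt exceeds 1")
  if (any(abs(rowSums(p1_hat) - 1) > 1e-6))
    stop("p1_hat rows must be normalized")
  final <- t + dt >= 1 - 1e-9
  p_unmask <- if (final) 1 else min(1, dt / (1 - t))
  masked <- which(x_t == mask_index)
  if (length(masked)) {
    jump <- masked[stats::runif(length(masked)) < p_unmask]
    for (i in jump)
      x_t[i] <- sample.int(ncol(p1_hat), 1L, prob = p1_hat[i, ])
  }
  as.integer(x_t)
}

#' Sample molecule sizes from a histogram
#'
#' @param size_histogram Named nonnegative numeric vector: names are atom
#'   counts, values are (unnormalized) frequencies.
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return Integer vector of `n` sizes.
#' @export
sample_sizes <- function(size_histogram, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(size_histogram < 0) || sum(size_histogram) <= 0)
    stop("size histogram must be nonnegative with positive total")
  sizes <- as.integer(names(size_histogram))
  if (anyNA(sizes)) stop("size histogram names must be integer atom counts")
  if (n == 0) return(integer(0))
  sizes[sample.int(length(sizes), n, replace = TRUE,
                   prob = size_histogram)]
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# initial joint state of one molecule; continuous variants operate on the
# real classes only (no MASK dimension)
.init_state <- function(n, vocab, variant) {
  Dof <- function(v) if (variant == "ctmc") v$size else n_real_classes(v)
  list(
    positions = sample_prior("euclidean", n)$vectors,
    atom = sample_prior(variant, n, Dof(vocab$atom),
                        mask_index = vocab$atom$mask_index),
    charge = sample_prior(variant, n, Dof(vocab$charge),
                          mask_index = vocab$charge$mask_index),
    bond = sample_prior(variant, n_pairs(n), Dof(vocab$bond),
                        mask_index = vocab$bond$mask_index)
  )
}

.state_argmax <- function(s) {
  if (s$kind == "indices") s$indices else max.col(s$vectors, "first")
}

#' Generate molecules by integrating the joint flow
#'
#' Initializes every modality from its prior, integrates positions and (for
#' continuous variants) categorical states with Euler steps of the
#' denoiser-parameterized field on the even grid, applies CTMC jump steps
#' for the ctmc variant, and discretizes continuous categorical states by
#' argmax at t = 1.
#'
#' @param denoiser A trained denoiser ([train_toy_denoiser()]), or a
#'   function `f(gstate, t)` returning a [denoiser_output()].
#' @param n_mols Number of molecules.
#' @param size_sampler A size histogram (named numeric, see
#'   [sample_sizes()]) or a function `f(n)` returning `n` atom counts.
#' @param config A [sampler_config()].
#' @param vocab Vocabularies of the generated molecules; must include MASK
#'   classes iff `config$variant == "ctmc"`. Defaults to the denoiser's
#'   vocabularies when available.
#' @return List of `n_mols` mask-free `dfmol_graph` objects. If
#'   `config$record != "none"`, each molecule carries an attribute
#'   `"trajectory"` (see [assignment_time()]).
#' @export
generate <- function(denoiser, n_mols, size_sampler, config = sampler_config(),
                     vocab = NULL) {
  if (is.null(vocab)) vocab <- attr(denoiser, "vocab")
  if (is.null(vocab))
    vocab <- default_vocabs(mask = config$variant == "ctmc")
  if (config$variant == "ctmc" && is.na(vocab$atom$mask_index))
    stop("ctmc requires vocabularies with a MASK class")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (n_mols == 0) return(list())
  sizes <- if (is.function(size_sampler)) size_sampler(n_mols)
           else sample_sizes(size_sampler, n_mols)
  lapply(seq_len(n_mols), function(m)
    .generate_one(denoiser, sizes[m], config, vocab))
}

.predict_any <- function(denoiser, gstate, t) {
  out <- if (is.function(denoiser)) denoiser(gstate, t)
         else denoiser_predict(denoiser, gstate, t)
  .check_output(out, state_length(gstate$atom), state_length(gstate$bond),
                gstate$vocab)
  out
}

.check_output <- function(out, n, p, vocab) {
  need <- c(atom_logits = n, charge_logits = n, bond_logits = p)
  for (nm in names(need)) {
    dims <- dim(out[[nm]])
    Dr <- n_real_classes(vocab[[sub("_logits", "", nm)]])
    if (is.null(dims) || dims[1] != need[nm] || dims[2] != Dr)
      stop("denoiser output contract violated for modality '",
           sub("_logits", "", nm), "': expected ", need[nm], " x ", Dr)
  }
  if (!all(dim(out$positions_hat) == c(n, 3)))
    stop("denoiser output contract violated for modality 'positions'")
  if (!all(vapply(out, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite denoiser output")
  invisible(out)
}

.generate_one <- function(denoiser, n, config, vocab) {
  K <- config$n_steps
  variant <- config$variant
  st <- .init_state(n, vocab, variant)
  grid <- seq(0, 1, length.out = K + 1)
  rec <- config$record != "none"
  if (rec) {
    traj <- list(grid = grid,
                 atom_state = matrix(NA_integer_, K + 1, n),
                 atom_pred = matrix(NA_integer_, K + 1, n))
    if (config$record == "raw") traj$raw <- vector("list", K + 1)
  }
  mods <- c("atom", "charge", "bond")
  for (k in seq_len(K)) {
    t <- grid[k]; dt <- 1 / K
    gstate <- list(positions = st$positions, atom = st$atom,
                   charge = st$charge, bond = st$bond, vocab = vocab,
                   variant = variant)
    out <- .predict_any(denoiser, gstate, t)
    probs <- list(atom = .softmax(out$atom_logits),
                  charge = .softmax(out$charge_logits),
                  bond = .softmax(out$bond_logits))
    if (rec) {
      traj$atom_state[k, ] <- .state_argmax(st$atom)
      traj$atom_pred[k, ] <- max.col(probs$atom, "first")
      if (config$record == "raw") traj$raw[[k]] <- st[mods]
    }
    st$positions <- euler_step(
      st$positions,
      conditional_vector_field("euclidean",
                               modality_state(vectors = st$positions),
                               out$positions_hat, t), dt)
    for (md in mods) {
      if (variant == "ctmc") {
        st[[md]]$indices <- ctmc_step(st[[md]]$indices, probs[[md]], t, dt,
                                      st[[md]]$mask_index)
      } else {
        u <- conditional_vector_field(variant, st[[md]], probs[[md]], t,
                                      config$beta_max, config$eps)
        if (variant == "dirichlet") {
          # damp rows whose outflow would overshoot the simplex in one
          # Euler step; the damped update is a convex combination
          rate <- attr(u, "mass_rate")
          scale <- pmin(1, 1 / pmax(dt * rate, 1e-12))
          u <- u * scale
        }
        st[[md]]$vectors <- euler_step(st[[md]]$vectors, u, dt)
      }
    }
  }
  at <- .state_argmax(st$atom); ch <- .state_argmax(st$charge)
  bo <- .state_argmax(st$bond)
  g <- molecule_graph(st$positions, at, ch, bo, vocab = vocab)
  if (rec) {
    traj$atom_state[K + 1, ] <- at
    # denoiser evaluated at t = 1 for the recorded prediction trajectory
    gstate <- list(positions = st$positions, atom = st$atom,
                   charge = st$charge, bond = st$bond, vocab = vocab,
                   variant = variant)
    out <- .predict_any(denoiser, gstate, 1)
    traj$atom_pred[K + 1, ] <- max.col(.softmax(out$atom_logits), "first")
    if (config$record == "raw") traj$raw[[K + 1]] <- st[mods]
    attr(g, "trajectory") <- traj
  }
  g
}
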