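# The denoiser: a neural network mapping the time-t molecule state to an
# estimate of the final molecule (positions plus class distributions for
# atom types, charges and bond orders). The toy architecture used here is
# deliberately small so every flow variant can be trained on a CPU in
# seconds: per-atom features with a mean-pooled molecular context feed a
# one-hidden-layer perceptron with per-modality heads; pair features feed a
# second perceptron for bonds. Positions are handled relative to the
# molecule centroid, which makes the model translation-equivariant by
# construction. Gradients are exact and hand-derived; the optimizer is Adam.

#' Denoiser output container
#'
#' @param positions_hat `n x 3` coordinate estimates.
#' @param atom_logits,charge_logits `n x D_real` logits over real classes
#'   (the MASK class is never predicted).
#' @param bond_logits `pairs x D_real` logits.
#' @return List of class `dfmol_denoiser_output`.
#' @export
denoiser_output <- function(positions_hat, atom_logits, charge_logits,
                            bond_logits) {
  structure(list(positions_hat = as.matrix(positions_hat),
                 atom_logits = as.matrix(atom_logits),
                 charge_logits = as.matrix(charge_logits),
                 bond_logits = as.matrix(bond_logits)),
            class = "dfmol_denoiser_output")
}

# state representation width per modality
.state_width <- function(vocab_entry, variant) {
  if (variant == "ctmc") vocab_entry$size else n_real_classes(vocab_entry)
}

.model_dims <- function(vocab, variant, hidden) {
  wa <- .state_width(vocab$atom, variant)
  wc <- .state_width(vocab$charge, variant)
  we <- .state_width(vocab$bond, variant)
  # numeric bond order per bond-state column (MASK commits no valency)
  order_vec <- c(.bond_orders[vocab$bond$names[seq_len(n_real_classes(vocab$bond))]],
                 if (we > n_real_classes(vocab$bond)) 0)
  # neutral valency per atom-state column (unknown elements default to 4)
  elem_val <- vapply(vocab$atom$names[seq_len(n_real_classes(vocab$atom))],
                     function(e) {
                       v <- .toy_valency[e]
                       if (is.na(v)) 4 else unname(v)
                     }, 0)
  if (wa > n_real_classes(vocab$atom)) elem_val <- c(elem_val, 0)
  list(wa = wa, wc = wc, we = we,
       da = n_real_classes(vocab$atom), dc = n_real_classes(vocab$charge),
       de = n_real_classes(vocab$bond),
       order_vec = unname(order_vec), elem_val = unname(elem_val),
       # node: own atom/charge state, centered pos + radius, t, molecular
       # context, size, aggregated incident-bond state ("valency so far"),
       # committed valency, remaining-valency deficit, and a
       # distance-kernel-weighted neighbor state (one fixed message pass)
       d_node = 2 * wa + wc + 6 + we + 2 + wa,
       # pair: own bond state, endpoint atom states (sym/antisym), distance,
       # t, context, size, endpoint incident-bond aggregates, and the
       # endpoints' committed/deficit valency summaries
       d_pair = we + 3 * wa + 3 + 2 * we + 4, h = hidden)
}

.init_params <- function(dims, seed) {
  set.seed(seed)
  rn <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))),
                              a, b)
  list(W1 = rn(dims$d_node, dims$h), b1 = numeric(dims$h),
       Wa = rn(dims$h, dims$da), ba = numeric(dims$da),
       Wc = rn(dims$h, dims$dc), bc = numeric(dims$dc),
       Wx = rn(dims$h, 3) * 0.1, bx = numeric(3),
       V1 = rn(dims$d_pair, dims$h), c1 = numeric(dims$h),
       We = rn(dims$h, dims$de), be = numeric(dims$de))
}

# modality state -> its real-matrix representation for the network input
.state_rep <- function(s, width) {
  if (s$kind == "vectors") return(s$vectors)
  onehot_matrix(s$indices, width)
}

# flattened batch features; mol_id maps atom rows (and pair rows) to
# molecules, pair_i/pair_j are global atom row indices
.features <- function(dims, positions, a_mat, c_mat, e_mat, mol_id_atom,
                      mol_id_pair, pair_i, pair_j, t_atom, t_pair, sizes) {
  counts <- as.vector(table(factor(mol_id_atom, levels = seq_along(sizes))))
  centroid <- rowsum(positions, mol_id_atom) / counts
  pos_c <- positions - centroid[mol_id_atom, , drop = FALSE]
  r <- sqrt(rowSums(pos_c^2))
  ctx <- rowsum(a_mat, mol_id_atom) / counts
  ctx_a <- ctx[mol_id_atom, , drop = FALSE]
  size_feat <- sizes[mol_id_atom] / 10
  # per-atom sum of incident pair bond states: the net's view of how much
  # valency each atom has already committed
  n_atom_rows <- nrow(a_mat)
  bsum <- matrix(0, n_atom_rows, ncol(e_mat))
  if (nrow(e_mat)) {
    for (side in list(pair_i, pair_j)) {
      tmp <- rowsum(e_mat, side)
      idx <- as.integer(rownames(tmp))
      bsum[idx, ] <- bsum[idx, , drop = FALSE] + tmp
    }
  }
  # committed valency and remaining-valency deficit per atom
  vcommit <- as.vector(bsum %*% dims$order_vec)
  expect_val <- as.vector(a_mat %*% dims$elem_val)
  deficit <- expect_val - vcommit
  ai <- a_mat[pair_i, , drop = FALSE]; aj <- a_mat[pair_j, , drop = FALSE]
  d <- sqrt(rowSums((positions[pair_i, , drop = FALSE] -
                       positions[pair_j, , drop = FALSE])^2))
  # one fixed-kernel message pass: distance-weighted mean of the other
  # atoms' states, so per-atom predictions respond to the evolving
  # neighborhood rather than only the pooled context
  w <- exp(-(d / 1.8)^2)
  nbr_num <- matrix(0, n_atom_rows, ncol(a_mat))
  nbr_den <- numeric(n_atom_rows)
  if (length(w)) {
    for (side in list(cbind(pair_i, pair_j), cbind(pair_j, pair_i))) {
      tmp <- rowsum(w * a_mat[side[, 2], , drop = FALSE], side[, 1])
      idx <- as.integer(rownames(tmp))
      nbr_num[idx, ] <- nbr_num[idx, , drop = FALSE] + tmp
      tmpd <- rowsum(w, side[, 1])
      nbr_den[as.integer(rownames(tmpd))] <-
        nbr_den[as.integer(rownames(tmpd))] + tmpd
    }
  }
  nbr <- nbr_num / (nbr_den + 1e-6)
  F <- cbind(a_mat, c_mat, pos_c, r, t_atom, ctx_a, size_feat, bsum,
             vcommit, deficit, nbr)
  P <- cbind(e_mat, ai + aj, abs(ai - aj), d, t_pair,
             ctx[mol_id_pair, , drop = FALSE])
  P <- cbind(P, sizes[mol_id_pair] / 10,
             bsum[pair_i, , drop = FALSE] + bsum[pair_j, , drop = FALSE],
             abs(bsum[pair_i, , drop = FALSE] - bsum[pair_j, , drop = FALSE]),
             deficit[pair_i], deficit[pair_j],
             pmin(deficit[pair_i], deficit[pair_j]),
             vcommit[pair_i] + vcommit[pair_j])
  list(F = F, P = P, centroid = centroid, pos_c = pos_c,
       mol_id_atom = mol_id_atom)
}

.forward <- function(params, feats) {
  H1 <- tanh(sweep(feats$F %*% params$W1, 2, params$b1, `+`))
  H2 <- tanh(sweep(feats$P %*% params$V1, 2, params$c1, `+`))
  list(
    H1 = H1, H2 = H2,
    atom_logits = sweep(H1 %*% params$Wa, 2, params$ba, `+`),
    charge_logits = sweep(H1 %*% params$Wc, 2, params$bc, `+`),
    bond_logits = sweep(H2 %*% params$We, 2, params$be, `+`),
    positions_hat = feats$centroid[feats$mol_id_atom, , drop = FALSE] +
      feats$pos_c + sweep(H1 %*% params$Wx, 2, params$bx, `+`)
  )
}

# gradient of the categorical loss wrt logits; `use_ce` selects CTMC
# cross-entropy vs MSE-through-softmax (continuous variants)
.cat_loss_grad <- function(logits, y_idx, eta, use_ce) {
  n <- nrow(logits); D <- ncol(logits)
  p <- .softmax(logits)
  y <- onehot_matrix(y_idx, D)
  if (use_ce) {
    loss <- -mean(log(pmax(p[cbind(seq_len(n), y_idx)], 1e-300)))
    grad <- eta * (p - y) / n
  } else {
    loss <- mean((p - y)^2)
    dLdp <- 2 * (p - y) / (n * D)
    grad <- eta * p * (dLdp - rowSums(dLdp * p))
  }
  list(loss = loss, grad = grad)
}

.backward <- function(params, feats, fwd, targets, weights, use_ce) {
  A <- nrow(feats$F)
  ga <- .cat_loss_grad(fwd$atom_logits, targets$atom, weights[["eta_a"]],
                       use_ce)
  gc_ <- .cat_loss_grad(fwd$charge_logits, targets$charge,
                        weights[["eta_c"]], use_ce)
  ge <- .cat_loss_grad(fwd$bond_logits, targets$bond, weights[["eta_e"]],
                       use_ce)
  dpos <- fwd$positions_hat - targets$X1
  loss_x <- mean(dpos^2)
  dpos <- weights[["eta_x"]] * 2 * dpos / length(dpos)
  dH1 <- ga$grad %*% t(params$Wa) + gc_$grad %*% t(params$Wc) +
    dpos %*% t(params$Wx)
  dZ1 <- dH1 * (1 - fwd$H1^2)
  dH2 <- ge$grad %*% t(params$We)
  dZ2 <- dH2 * (1 - fwd$H2^2)
  grads <- list(
    W1 = t(feats$F) %*% dZ1, b1 = colSums(dZ1),
    Wa = t(fwd$H1) %*% ga$grad, ba = colSums(ga$grad),
    Wc = t(fwd$H1) %*% gc_$grad, bc = colSums(gc_$grad),
    Wx = t(fwd$H1) %*% dpos, bx = colSums(dpos),
    V1 = t(feats$P) %*% dZ2, c1 = colSums(dZ2),
    We = t(fwd$H2) %*% ge$grad, be = colSums(ge$grad))
  losses <- c(x = loss_x, a = ga$loss, c = gc_$loss, e = ge$loss)
  list(grads = grads, losses = losses,
       total = total_loss(as.list(losses), weights))
}

# one joint-loss evaluation without gradients (for checks and baselines)
.loss_only <- function(params, feats, targets, weights, use_ce) {
  fwd <- .forward(params, feats)
  .backward(params, feats, fwd, targets, weights, use_ce)$total
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), step = 0)

.adam_update <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  opt$step <- opt$step + 1
  for (nm in names(params)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$step)
    vhat <- opt$v[[nm]] / (1 - b2^opt$step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# flatten a dataset of graphs into index arrays used every epoch
.prepare_dataset <- function(mols, vocab) {
  sizes <- vapply(mols, `[[`, 0L, "n_atoms")
  offs <- cumsum(c(0L, utils::head(sizes, -1)))
  A <- sum(sizes)
  mol_id_atom <- rep(seq_along(mols), sizes)
  np <- n_pairs(sizes)
  mol_id_pair <- rep(seq_along(mols), np)
  pair_i <- integer(sum(np)); pair_j <- integer(sum(np))
  pos <- 0L
  for (m in seq_along(mols)) {
    pm <- pairs_matrix(sizes[m])
    if (nrow(pm)) {
      idx <- pos + seq_len(nrow(pm))
      pair_i[idx] <- pm[, 1] + offs[m]
      pair_j[idx] <- pm[, 2] + offs[m]
      pos <- pos + nrow(pm)
    }
  }
  X1 <- do.call(rbind, lapply(mols, function(g)
    sweep(g$positions, 2, colMeans(g$positions))))
  list(sizes = sizes, mol_id_atom = mol_id_atom, mol_id_pair = mol_id_pair,
       pair_i = pair_i, pair_j = pair_j, X1 = X1,
       atom = unlist(lapply(mols, `[[`, "atom_types")),
       charge = unlist(lapply(mols, `[[`, "charges")),
       bond = unlist(lapply(mols, `[[`, "bond_orders")),
       vocab = vocab, n_mols = length(mols))
}

# sample x_t representations for one epoch (flattened across molecules)
.sample_epoch_states <- function(prep, variant, beta_max, eps) {
  B <- prep$n_mols
  t_mol <- sample_training_time(B)
  t_atom <- t_mol[prep$mol_id_atom]
  t_pair <- t_mol[prep$mol_id_pair]
  A <- length(prep$atom)
  x0 <- matrix(stats::rnorm(A * 3), A, 3)
  counts <- as.vector(table(factor(prep$mol_id_atom, levels = seq_len(B))))
  x0 <- x0 - (rowsum(x0, prep$mol_id_atom) / counts)[prep$mol_id_atom, ]
  positions <- (1 - t_atom) * x0 + t_atom * prep$X1
  draw_cat <- function(y, t_vec, vocab_entry) {
    D_real <- n_real_classes(vocab_entry)
    n <- length(y)
    switch(variant,
      ctmc = {
        keep <- stats::runif(n) < t_vec
        onehot_matrix(ifelse(keep, y, vocab_entry$mask_index),
                      vocab_entry$size)
      },
      continuous = (1 - t_vec) * matrix(stats::rnorm(n * D_real), n, D_real) +
        t_vec * onehot_matrix(y, D_real),
      simplex = (1 - t_vec) * .runif_simplex(n, D_real) +
        t_vec * onehot_matrix(y, D_real),
      dirichlet = {
        b <- beta_schedule(t_vec, beta_max, eps)$beta
        alpha <- matrix(1, n, D_real)
        alpha[cbind(seq_len(n), y)] <- 1 + b
        .rdirichlet(alpha)
      })
  }
  list(positions = positions,
       a_mat = draw_cat(prep$atom, t_atom, prep$vocab$atom),
       c_mat = draw_cat(prep$charge, t_atom, prep$vocab$charge),
       e_mat = draw_cat(prep$bond, t_pair, prep$vocab$bond),
       t_atom = t_atom, t_pair = t_pair)
}

#' Train the toy denoiser
#'
#' Trains the small feed-forward denoiser jointly on all modalities with
#' the flow-matching objective of the chosen variant (cross-entropy for
#' ctmc, regression to one-hot targets for the continuous variants;
#' positions always regressed). Full-batch Adam; per-epoch resampling of t
#' and the conditional path.
#'
#' @param dataset List of `dfmol_graph` training molecules.
#' @param variant Categorical flow variant.
#' @param epochs Number of epochs (>= 1).
#' @param seed RNG seed controlling initialization and path sampling; the
#'   run is bit-reproducible given the seed.
#' @param hidden Hidden width of both perceptrons.
#' @param lr Adam learning rate.
#' @param weights A [loss_weights()] vector.
#' @param beta_max,eps Dirichlet schedule parameters.
#' @return A `dfmol_denoiser` with elements `params`, `variant`, `vocab`,
#'   `dims`, `history` (per-epoch total loss) and `size_histogram` (the
#'   training-size distribution used at generation time).
#' @export
train_toy_denoiser <- function(dataset, variant, epochs = 150, seed = 1,
                               hidden = 48, lr = 0.01,
                               weights = loss_weights(), beta_max = 100,
                               eps = 1e-3) {
  .check_variant(variant)
  if (variant == "euclidean") stop("variant must be categorical")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!length(dataset)) stop("empty dataset")
  vocab <- default_vocabs(elements =
    setdiff(dataset[[1]]$vocab$atom$names, "<MASK>"),
    mask = variant == "ctmc")
  dims <- .model_dims(vocab, variant, hidden)
  params <- .init_params(dims, seed)
  prep <- .prepare_dataset(dataset, vocab)
  opt <- .adam_init(params)
  history <- numeric(epochs)
  history_mod <- matrix(NA_real_, epochs, 4,
                        dimnames = list(NULL, c("x", "a", "c", "e")))
  use_ce <- variant == "ctmc"
  for (ep in seq_len(epochs)) {
    st <- .sample_epoch_states(prep, variant, beta_max, eps)
    feats <- .features(dims, st$positions, st$a_mat, st$c_mat, st$e_mat,
                       prep$mol_id_atom, prep$mol_id_pair, prep$pair_i,
                       prep$pair_j, st$t_atom, st$t_pair, prep$sizes)
    fwd <- .forward(params, feats)
    bk <- .backward(params, feats, fwd,
                    list(atom = prep$atom, charge = prep$charge,
                         bond = prep$bond, X1 = prep$X1),
                    weights, use_ce)
    if (!is.finite(bk$total)) {
      mod <- names(bk$losses)[!is.finite(bk$losses)][1]
      stop("NaN loss at epoch ", ep, " in modality '",
           c(x = "positions", a = "atom types", c = "charges",
             e = "bonds")[mod], "'")
    }
    history[ep] <- bk$total
    history_mod[ep, ] <- bk$losses
    upd <- .adam_update(params, bk$grads, opt, lr)
    params <- upd$params; opt <- upd$opt
  }
  tb <- table(vapply(dataset, `[[`, 0L, "n_atoms"))
  model <- structure(
    list(params = params, variant = variant, vocab = vocab, dims = dims,
         history = history, history_by_modality = history_mod,
         weights = weights, beta_max = beta_max,
         eps = eps,
         size_histogram = stats::setNames(as.numeric(tb), names(tb))),
    class = "dfmol_denoiser")
  attr(model, "vocab") <- vocab
  model
}

#' Untrained denoiser with the same architecture
#'
#' A freshly initialized model, used as the untrained baseline in
#' evaluations.
#'
#' @inheritParams train_toy_denoiser
#' @param elements Atom-type classes.
#' @param size_histogram Size histogram to carry for generation.
#' @return A `dfmol_denoiser` with random parameters.
#' @export
untrained_denoiser <- function(variant, elements = c("H", "C", "N", "O"),
                               size_histogram = c("8" = 1), seed = 1,
                               hidden = 48) {
  vocab <- default_vocabs(elements = elements, mask = variant == "ctmc")
  dims <- .model_dims(vocab, variant, hidden)
  model <- structure(
    list(params = .init_params(dims, seed), variant = variant,
         vocab = vocab, dims = dims, history = numeric(0),
         weights = loss_weights(), beta_max = 100, eps = 1e-3,
         size_histogram = size_histogram),
    class = "dfmol_denoiser")
  attr(model, "vocab") <- vocab
  model
}

#' Predict the final molecule from a time-t state
#'
#' @param model A `dfmol_denoiser`.
#' @param gstate List with `positions` (matrix), `atom`, `charge`, `bond`
#'   (`dfmol_state`s in the model's representation) and `vocab`.
#' @param t Time in `[0, 1]`.
#' @return A [denoiser_output()]. Deterministic given parameters and input.
#' @export
denoiser_predict <- function(model, gstate, t) {
  if (t < 0 || t > 1) stop("t must lie in [0, 1]")
  dims <- model$dims
  a_mat <- .state_rep(gstate$atom, dims$wa)
  if (ncol(a_mat) != dims$wa)
    stop("state/representation mismatch for modality 'atom' (variant ",
         model$variant, " expects width ", dims$wa, ")")
  c_mat <- .state_rep(gstate$charge, dims$wc)
  e_mat <- .state_rep(gstate$bond, dims$we)
  n <- nrow(a_mat)
  pm <- pairs_matrix(n)
  feats <- .features(dims, gstate$positions, a_mat, c_mat, e_mat,
                     rep(1L, n), rep(1L, nrow(pm)), pm[, 1], pm[, 2],
                     rep(t, n), rep(t, nrow(pm)), n)
  fwd <- .forward(model$params, feats)
  denoiser_output(fwd$positions_hat, fwd$atom_logits, fwd$charge_logits,
                  fwd$bond_logits)
}

#' Describe a denoiser
#' @param model A `dfmol_denoiser`.
#' @return List with `n_parameters`, `variant`, `hidden`, printed summary.
#' @export
describe <- function(model) {
  n_par <- sum(vapply(model$params, length, 0L))
  out <- list(n_parameters = n_par, variant = model$variant,
              hidden = model$dims$h,
              trained_epochs = length(model$history))
  cat("<dfmol_denoiser> variant=", model$variant, ", ", n_par,
      " parameters, hidden=", model$dims$h, ", ",
      length(model$history), " epochs trained\n", sep = "")
  invisible(out)
}

#' @export
print.dfmol_denoiser <- function(x, ...) {
  describe(x)
  invisible(x)
}

#' Save / load a denoiser checkpoint
#'
#' Single-file serialization of parameters, configuration and
#' vocabularies; reloading is bit-exact.
#'
#' @param model A `dfmol_denoiser`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the reloaded model (load).
#' @export
save_denoiser <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dfmol_denoiser")) stop("not a denoiser checkpoint")
  attr(model, "vocab") <- model$vocab
  model
}

#' Perfect-memorization denoiser of a single molecule
#'
#' Returns a denoiser function that always predicts the given molecule
#' (saturated logits, centered positions); useful as an oracle in sampler
#' tests.
#'
#' @param g A `dfmol_graph`.
#' @param sat Logit saturation.
#' @return A function `f(gstate, t)` honoring the denoiser contract.
#' @export
memorize_denoiser <- function(g, sat = 1000) {
  Xc <- sweep(g$positions, 2, colMeans(g$positions))
  function(gstate, t) {
    vocab <- gstate$vocab
    denoiser_output(
      Xc,
      sat * onehot_matrix(g$atom_types, n_real_classes(vocab$atom)),
      sat * onehot_matrix(g$charges, n_real_classes(vocab$charge)),
      sat * onehot_matrix(g$bond_orders, n_real_classes(vocab$bond)))
  }
}
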