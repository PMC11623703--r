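# Training objectives: per-modality flow-matching losses and the weighted
# joint loss. Positions are always regressed; categorical modalities are
# regressed against one-hot targets under the continuous variants and
# trained with cross-entropy under the CTMC variant. All reductions are
# means (not sums) so the weights stay comparable across molecule sizes.

#' Loss weights for the joint objective
#'
#' @param eta_x,eta_a,eta_c,eta_e Nonnegative weights for positions, atom
#'   types, charges and bond orders. Defaults up-weight positions, which
#'   dominate geometric quality.
#' @return Named numeric vector of class `dfmol_loss_weights`.
#' @export
loss_weights <- function(eta_x = 3, eta_a = 1, eta_c = 1, eta_e = 1) {
  w <- c(eta_x = eta_x, eta_a = eta_a, eta_c = eta_c, eta_e = eta_e)
  if (any(w < 0) || all(w == 0))
    stop("weights must be nonnegative with at least one positive")
  structure(w, class = "dfmol_loss_weights")
}

#' Mean-squared-error regression loss
#'
#' The denoiser regression objective: mean squared difference between the
#' prediction and the data endpoint, applied to positions always and to
#' one-hot categorical targets under the continuous variants.
#'
#' @param x1_hat,x1 Numeric vectors/matrices of matching shape.
#' @return Nonnegative scalar.
#' @export
regression_loss <- function(x1_hat, x1) {
  if (!all(dim(as.matrix(x1_hat)) == dim(as.matrix(x1))))
    stop("shape mismatch between prediction and target")
  mean((x1_hat - x1)^2)
}

#' Cross-entropy loss for CTMC training
#'
#' Mean over positions of `-log softmax(logits)[x1]`. Logits are over the
#' real classes only; the MASK class is never a target (endpoints are real
#' data), so an endpoint index equal to `mask_index` is an error.
#'
#' @param logits `n x D_real` matrix of finite logits.
#' @param x1_indices Integer endpoint classes, in `1..D_real`.
#' @param mask_index Optional MASK index to reject in `x1_indices`.
#' @return Nonnegative scalar.
#' @export
ce_loss <- function(logits, x1_indices, mask_index = NA_integer_) {
  logits <- as.matrix(logits)
  if (!all(is.finite(logits))) stop("non-finite logits")
  x1_indices <- as.integer(x1_indices)
  if (length(x1_indices) != nrow(logits)) stop("target length mismatch")
  if (!is.na(mask_index) && any(x1_indices == mask_index))
    stop("endpoint classes cannot be MASK")
  if (any(x1_indices < 1L | x1_indices > ncol(logits)))
    stop("target index out of range")
  p <- .softmax(logits)
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), x1_indices)], 1e-300)))
}

#' Weighted joint loss
#'
#' @param losses Named numeric vector/list with entries `x`, `a`, `c`, `e`
#'   (missing entries count 0).
#' @param weights A [loss_weights()] vector.
#' @return Weighted sum, linear in every component.
#' @export
total_loss <- function(losses, weights = loss_weights()) {
  l <- function(nm) if (is.null(losses[[nm]]) || is.na(losses[[nm]])) 0
                    else losses[[nm]]
  weights[["eta_x"]] * l("x") + weights[["eta_a"]] * l("a") +
    weights[["eta_c"]] * l("c") + weights[["eta_e"]] * l("e")
}

#' Sample training times
#'
#' The flow-matching objectives are expectations over t; times are drawn
#' i.i.d. uniform on `[0, 1)`.
#'
#' @param batch_size Number of draws (>= 1).
#' @param seed Optional RNG seed.
#' @return Numeric vector in `[0, 1)`.
#' @export
sample_training_time <- function(batch_size, seed = NULL) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stats::runif(batch_size)
}
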