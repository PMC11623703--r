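# Assignment-time diagnostics: when does an atom's categorical state become
# final along a generation trajectory, both in the state x_t itself and in
# the denoiser prediction, and how large is the lag between the two. For
# continuous variants the mid-trajectory "state" of a real-vector x_t is
# its argmax class.

#' Assignment time of a categorical trajectory
#'
#' The smallest grid time `t*` such that the state equals its final value
#' at every grid point from `t*` on.
#'
#' @param states Integer class indices along the grid (or a
#'   `CategoricalTrajectory`-like list with `grid` and `states`).
#' @param grid Strictly increasing times ending at 1 (ignored when `states`
#'   is a list carrying its own grid).
#' @param mask_index Optional MASK index; a MASK final state is an error.
#' @return Assignment time in `[0, 1]`.
#' @export
assignment_time <- function(states, grid = NULL, mask_index = NA_integer_) {
  if (is.list(states)) {
    grid <- states$grid
    states <- states$states
  }
  if (!length(states)) stop("empty trajectory")
  if (length(grid) != length(states)) stop("grid/states length mismatch")
  if (is.unsorted(grid, strictly = TRUE) ||
      abs(grid[length(grid)] - 1) > 1e-9)
    stop("grid must be strictly increasing and end at 1")
  final <- states[length(states)]
  if (!is.na(mask_index) && final == mask_index)
    stop("final state is MASK; trajectory is unresolved")
  differs <- which(states != final)
  if (!length(differs)) return(grid[1])
  grid[max(differs) + 1L]
}

#' Empirical CDF of assignment times
#'
#' @param times Assignment times in `[0, 1]`.
#' @param eval_grid Times at which to evaluate the CDF.
#' @return Numeric vector of CDF values; nondecreasing, 1 at `t = 1`.
#' @export
assignment_cdf <- function(times, eval_grid = seq(0, 1, by = 0.01)) {
  if (!length(times)) stop("no assignment times")
  if (any(times < 0 | times > 1)) stop("times must lie in [0, 1]")
  vapply(eval_grid, function(t) mean(times <= t + 1e-12), 0)
}

#' State/denoiser assignment-gap statistic at a query time
#'
#' For paired per-atom assignment times of the state trajectory and of the
#' denoiser-prediction trajectory, the fractions of atoms already assigned
#' by `t_query` in each; their difference is the lag of the state behind
#' the denoiser's decisions.
#'
#' @param state_times,pred_times Equal-length paired assignment times.
#' @param t_query Query time.
#' @return Named vector `c(frac_state_assigned, frac_pred_assigned)` with
#'   attribute `gap` (`frac_pred_assigned - frac_state_assigned`).
#' @export
assignment_gap <- function(state_times, pred_times, t_query) {
  if (length(state_times) != length(pred_times))
    stop("state/pred assignment times must be paired")
  fs <- mean(state_times <= t_query + 1e-12)
  fp <- mean(pred_times <= t_query + 1e-12)
  structure(c(frac_state_assigned = fs, frac_pred_assigned = fp),
            gap = fp - fs)
}

#' Per-atom assignment times from a recorded generation trajectory
#'
#' @param g A molecule generated with `record = "argmax"` (or `"raw"`); see
#'   [generate()].
#' @return List with numeric vectors `state` and `pred` (one entry per
#'   atom) and the `grid`.
#' @export
trajectory_assignment_times <- function(g) {
  traj <- attr(g, "trajectory")
  if (is.null(traj)) stop("molecule carries no recorded trajectory")
  n <- ncol(traj$atom_state)
  list(
    state = vapply(seq_len(n), function(i)
      assignment_time(traj$atom_state[, i], traj$grid), 0),
    pred = vapply(seq_len(n), function(i)
      assignment_time(traj$atom_pred[, i], traj$grid), 0),
    grid = traj$grid
  )
}

#' Mean state-minus-prediction assignment-time lag over a batch
#'
#' @param mols Molecules generated with trajectory recording.
#' @return List with `mean_lag` (mean over atoms of state time minus
#'   prediction time), `cdf_gap` (mean absolute gap between the two CDFs
#'   over a uniform grid), and the pooled `state`/`pred` times.
#' @export
assignment_lag <- function(mols) {
  at <- lapply(mols, trajectory_assignment_times)
  st <- unlist(lapply(at, `[[`, "state"))
  pr <- unlist(lapply(at, `[[`, "pred"))
  grid <- seq(0, 1, by = 0.02)
  list(mean_lag = mean(st - pr),
       cdf_gap = mean(abs(assignment_cdf(st, grid) -
                            assignment_cdf(pr, grid))),
       state = st, pred = pr)
}
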