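#' Point-set distances and the completion F-score
#'
#' Exact (brute-force nearest neighbour) implementations of the five
#' quantities used to train and evaluate completions:
#'
#' * `cd_t(x, y)`: symmetric Chamfer distance, *squared*-distance convention
#'   -- the mean over `x` of the squared Euclidean distance to the nearest
#'   `y` point, plus the same with the roles swapped. This is the quantity
#'   minimized during training and reported (scaled by 1e4) on benchmarks.
#' * `cd_p(x, y)`: the unsquared variant, `(L_xy + L_yx) / 2` with `L` the
#'   mean of unsquared nearest-neighbour distances.
#' * `ucd(partial, full)`: one direction only -- the mean squared distance
#'   from each `partial` point to its nearest `full` point. Usable without
#'   ground truth: it measures how well the completion covers the input.
#' * `uhd(partial, full)`: the one-directional Hausdorff distance, i.e. the
#'   maximum unsquared distance from a `partial` point to the `full` cloud.
#' * `f_score(pred, truth, tau)`: harmonic mean (in percent) of precision
#'   (share of predicted points within `tau` of the truth) and recall (share
#'   of truth points within `tau` of the prediction).
#'
#' `cd_t`, `cd_p` are symmetric in their arguments; `ucd`, `uhd` are not.
#' The identity `cd_t(x, y) == ucd(x, y) + ucd(y, x)` holds exactly.
#'
#' @param x,y,partial,full,pred,truth Non-empty point clouds (or data frames
#'   with `x`, `y`, `z` columns).
#' @param tau Distance threshold for the F-score, in the same (normalized)
#'   units as the clouds; must be positive. The default 0.01 is 1% of the
#'   unit scale of clouds normalized into (-1, 1).
#' @return A single non-negative number (for `f_score`, in `[0, 100]`).
#' @examples
#' a <- point_cloud(cbind(0, 0, 0))
#' b <- point_cloud(cbind(1, 0, 0))
#' cd_t(a, b) # 2
#' cd_p(a, b) # 1
#' @name metrics
NULL

nn_dist2 <- function(from, to) nn1_cpp(from, to)$dist2

check_nonempty <- function(...) {
  for (m in list(...)) if (nrow(m) < 1L) abort("metric inputs must be non-empty clouds")
}

#' @rdname metrics
#' @export
cd_t <- function(x, y) {
  mx <- as_xyz_matrix(x); my <- as_xyz_matrix(y)
  check_nonempty(mx, my)
  mean(nn_dist2(mx, my)) + mean(nn_dist2(my, mx))
}

#' @rdname metrics
#' @export
cd_p <- function(x, y) {
  mx <- as_xyz_matrix(x); my <- as_xyz_matrix(y)
  check_nonempty(mx, my)
  (mean(sqrt(nn_dist2(mx, my))) + mean(sqrt(nn_dist2(my, mx)))) / 2
}

#' @rdname metrics
#' @export
ucd <- function(partial, full) {
  mp <- as_xyz_matrix(partial); mf <- as_xyz_matrix(full)
  check_nonempty(mp, mf)
  mean(nn_dist2(mp, mf))
}

#' @rdname metrics
#' @export
uhd <- function(partial, full) {
  mp <- as_xyz_matrix(partial); mf <- as_xyz_matrix(full)
  check_nonempty(mp, mf)
  sqrt(max(nn_dist2(mp, mf)))
}

#' @rdname metrics
#' @export
f_score <- function(pred, truth, tau = 0.01) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    abort("tau must be a single positive distance threshold")
  }
  mp <- as_xyz_matrix(pred); mt <- as_xyz_matrix(truth)
  check_nonempty(mp, mt)
  precision <- 100 * mean(nn_dist2(mp, mt) <= tau^2)
  recall <- 100 * mean(nn_dist2(mt, mp) <= tau^2)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Evaluation report at benchmark reporting scales
#'
#' Computes the full metric panel for a completed cloud and returns it as a
#' one-row tibble using the conventional reporting scales: `cd_t` and `ucd`
#' multiplied by 1e4, `uhd` by 1e2, `f_score` in percent. `cd_p` is reported
#' unscaled. Ground-truth metrics (`cd_t`, `cd_p`, `f_score`) need `truth`;
#' input-fidelity metrics (`ucd`, `uhd`) need `partial`; omitted comparisons
#' yield `NA`. Raw (unscaled) values are what the loss functions consume --
#' the scaling here is presentation only.
#'
#' @param pred The completed cloud.
#' @param truth Optional ground-truth complete cloud.
#' @param partial Optional partial input cloud.
#' @inheritParams metrics
#' @return A one-row tibble with columns `cd_t`, `cd_p`, `ucd`, `uhd`,
#'   `f_score` (scaled as above) and `n_pred`.
#' @examples
#' evaluate_completion(point_cloud(diag(3)), truth = point_cloud(diag(3)))
#' @export
evaluate_completion <- function(pred, truth = NULL, partial = NULL, tau = 0.01) {
  tibble(
    cd_t = if (!is.null(truth)) 1e4 * cd_t(pred, truth) else NA_real_,
    cd_p = if (!is.null(truth)) cd_p(pred, truth) else NA_real_,
    ucd = if (!is.null(partial)) 1e4 * ucd(partial, pred) else NA_real_,
    uhd = if (!is.null(partial)) 1e2 * uhd(partial, pred) else NA_real_,
    f_score = if (!is.null(truth)) f_score(pred, truth, tau = tau) else NA_real_,
    n_pred = n_points(pred)
  )
}
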