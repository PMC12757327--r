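#' Loss weights for the completion objective
#'
#' Bundles the four scalars that weight the objective: `alpha` and `beta`
#' down-weight the coarser stages of the multi-stage reconstruction loss, and
#' `h_c`, `h_d` mix the reconstruction and feature-matching terms of the
#' total loss. `h_c + h_d` must equal one (validated here, to 1e-9), so the
#' two components keep a balanced influence.
#'
#' @param alpha,beta Non-negative stage weights (defaults 0.5 and 0.25:
#'   geometric down-weighting of the coarser stages).
#' @param h_c,h_d Mixing weights in `[0, 1]` summing to one (defaults
#'   0.8/0.2: reconstruction-dominant, with feature matching refining
#'   detail).
#' @return A `loss_weights` list.
#' @examples
#' loss_weights()
#' try(loss_weights(h_c = 0.6, h_d = 0.5)) # rejected
#' @export
loss_weights <- function(alpha = 0.5, beta = 0.25, h_c = 0.8, h_d = 0.2) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0
  )
  if (!is.numeric(h_c) || !is.numeric(h_d) || h_c < 0 || h_d < 0 || h_c > 1 || h_d > 1) {
    abort("h_c and h_d must lie in [0, 1]")
  }
  if (abs(h_c + h_d - 1) > 1e-9) {
    abort("h_c + h_d must equal 1")
  }
  structure(
    list(alpha = alpha, beta = beta, h_c = h_c, h_d = h_d),
    class = "loss_weights"
  )
}

#' @export
print.loss_weights <- function(x, ...) {
  cat(sprintf(
    "# loss weights: alpha %.3g, beta %.3g, h_c %.3g, h_d %.3g\n",
    x$alpha, x$beta, x$h_c, x$h_d
  ))
  invisible(x)
}

#' Multi-stage reconstruction loss
#'
#' The Chamfer reconstruction term aggregated over the three pyramid stages:
#' `cd_t(Xb, Xin) + alpha * cd_t(Xb', Xin') + beta * cd_t(Xb'', Xin'')`,
#' where the `Xb` clouds are the degraded generated levels and the `Xin`
#' clouds the partial-input pyramid levels. The full-resolution stage drives
#' detail; the coarser stages anchor the backbone structure.
#'
#' @param triplet A `degraded_triplet` from [degrade_pyramid()].
#' @param partial_pyr The partial-input pyramid ([partial_pyramid()]).
#' @param w A [loss_weights()] object.
#' @return A single non-negative number.
#' @export
multi_stage_reconstruction <- function(triplet, partial_pyr, w = loss_weights()) {
  cd_t(triplet$xb, partial_pyr$level1) +
    w$alpha * cd_t(triplet$xb_prime, partial_pyr$level2) +
    w$beta * cd_t(triplet$xb_dprime, partial_pyr$level3)
}

#' Multi-scale feature-matching loss
#'
#' Sum over the three pyramid levels of the L1 distance between the
#' discriminator feature vectors of the degraded generated cloud and of the
#' corresponding partial-input cloud. Each level has its own discriminator
#' (identical architecture, trained at that resolution alongside the
#' generator); the feature vector is the pooled global feature feeding the
#' discriminator's score layer. Matching features rather than raw scores
#' keeps the term informative about structure and detail.
#'
#' @inheritParams multi_stage_reconstruction
#' @param discriminators A list of the three level discriminators (see
#'   [pretrain_gan()]).
#' @return A single non-negative number; zero when the degraded clouds equal
#'   their partial counterparts.
#' @export
feature_matching <- function(triplet, partial_pyr, discriminators) {
  stopifnot(length(discriminators) == 3L)
  degr <- triplet_levels(triplet)
  part <- pyramid_levels(partial_pyr)
  total <- 0
  for (l in 1:3) {
    fd <- discriminate_features(discriminators[[l]], degr[[l]])$features
    fp <- discriminate_features(discriminators[[l]], part[[l]])$features
    if (length(fd) != length(fp)) abort("feature-vector length mismatch")
    total <- total + sum(abs(fd - fp))
  }
  total
}

#' Total completion objective
#'
#' Mixes the reconstruction term and the feature-matching term:
#' `h_c * tc + h_d * td`, with the constraint `h_c + h_d = 1` enforced at
#' [loss_weights()] construction.
#'
#' @param tc Multi-stage reconstruction loss value.
#' @param td Feature-matching loss value.
#' @param w A [loss_weights()] object.
#' @return A single non-negative number.
#' @examples
#' total_loss(2, 1, loss_weights(h_c = 0.7, h_d = 0.3)) # 1.7
#' @export
total_loss <- function(tc, td, w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  w$h_c * tc + w$h_d * td
}

# --- analytic gradients (internal) -----------------------------------------
#
# cd_t value and gradient with respect to the FIRST cloud's coordinates,
# holding nearest-neighbour assignments fixed (valid wherever assignments are
# locally constant, which is almost everywhere).
cdt_value_grad <- function(xm, ym) {
  nx <- nrow(xm); ny <- nrow(ym)
  fwd <- nn1_cpp(xm, ym)
  bwd <- nn1_cpp(ym, xm)
  value <- mean(fwd$dist2) + mean(bwd$dist2)
  diff_fwd <- xm - ym[fwd$idx, , drop = FALSE]
  gx <- (2 / nx) * diff_fwd
  # reverse term: y_j's nearest x point gets pushed toward y_j
  diff_bwd <- xm[bwd$idx, , drop = FALSE] - ym
  add <- rowsum((2 / ny) * diff_bwd, group = bwd$idx)
  rows <- as.integer(rownames(add))
  gx[rows, ] <- gx[rows, ] + add
  list(value = value, grad = gx)
}
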