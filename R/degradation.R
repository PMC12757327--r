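#' K-neighbourhood mask: degrade a complete cloud toward a partial one
#'
#' For each point of the partial observation, take its `K` nearest points in
#' the generated complete cloud; the mask is the union of these
#' neighbourhoods. The result is the part of the generated shape that
#' corresponds to what the scanner saw, so it can be compared against the
#' partial input by Chamfer distances even though the two clouds are never
#' in correspondence. Multiplicity is discarded (the union is a set), so the
#' output is a duplicate-free subset of `generated` with at most
#' `min(n_points(generated), K * n_points(partial))` points.
#'
#' @param generated The complete cloud produced by the generator.
#' @param partial The partial observation.
#' @param k Neighbourhood size (`1 <= k <= n_points(generated)`).
#' @return A [point_cloud] subset of `generated`, rows in increasing
#'   `generated` index order; the indices are in attribute `idx`.
#' @examples
#' line <- point_cloud(cbind(0:5, 0, 0))
#' mk_mask(line, point_cloud(cbind(c(0.1, 1.1), 0, 0)), k = 2) # points 0,1,2
#' @export
mk_mask <- function(generated, partial, k) {
  g <- as_xyz_matrix(generated)
  p <- as_xyz_matrix(partial)
  if (nrow(p) < 1L) abort("partial cloud is empty")
  if (k > nrow(g)) abort("K exceeds the generated cloud size")
  nb <- knn_cpp(p, g, as.integer(k))
  idx <- sort(unique(as.vector(nb)))
  out <- pc_from_matrix(g[idx, , drop = FALSE], template = generated)
  attr(out, "idx") <- idx
  out
}

#' Degrade a whole resolution pyramid
#'
#' Applies [mk_mask()] level by level: the 2048-point generated level is
#' masked toward the full partial input, the 1024-point level toward its
#' 1024-point subsample, and the 512-point level toward its 512-point
#' subsample. The same `K` is used at all levels unless a 3-vector is given.
#'
#' @param gen_pyramid Pyramid of the generated complete cloud
#'   ([build_pyramid()]).
#' @param partial_pyramid Pyramid of the partial input ([partial_pyramid()]).
#' @param k Neighbourhood size, a single count or one per level.
#' @return A `degraded_triplet`: list with clouds `xb`, `xb_prime`,
#'   `xb_dprime` (each a subset of the matching generated level) and `k_used`.
#' @export
degrade_pyramid <- function(gen_pyramid, partial_pyramid, k = 50L) {
  k <- as.integer(rep_len(k, 3L))
  xb <- mk_mask(gen_pyramid$level1, partial_pyramid$level1, k[1])
  xbp <- mk_mask(gen_pyramid$level2, partial_pyramid$level2, k[2])
  xbpp <- mk_mask(gen_pyramid$level3, partial_pyramid$level3, k[3])
  structure(
    list(xb = xb, xb_prime = xbp, xb_dprime = xbpp, k_used = k),
    class = "degraded_triplet"
  )
}

#' @export
print.degraded_triplet <- function(x, ...) {
  cat(sprintf(
    "# degraded triplet (K = %s): %d / %d / %d points\n",
    paste(unique(x$k_used), collapse = "/"),
    n_points(x$xb), n_points(x$xb_prime), n_points(x$xb_dprime)
  ))
  invisible(x)
}

triplet_levels <- function(tri) list(tri$xb, tri$xb_prime, tri$xb_dprime)
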