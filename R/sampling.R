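#' Iterative farthest point sampling
#'
#' Greedy maximin subsampling: starting from the point at `start`, each
#' successive pick is the point whose minimum Euclidean distance to the
#' already-selected set is largest (distance ties broken by lowest input
#' index). The selected points cover the shape far more uniformly than a
#' random subset of the same size, which is why the resolution pyramid is
#' built with it.
#'
#' @param cloud A point cloud (or data frame with `x`, `y`, `z`).
#' @param m Number of points to select (`1 <= m <= n_points(cloud)`).
#' @param start Index of the seed point (1-based; default the first point,
#'   which keeps the procedure deterministic).
#' @return A [point_cloud] of exactly `m` points, all members of the input,
#'   in selection order, with the selected input indices in attribute `idx`.
#' @examples
#' line <- point_cloud(cbind(0:5, 0, 0))
#' ifps(line, 3) # picks x = 0, 5, 2
#' @export
ifps <- function(cloud, m, start = 1L) {
  mtx <- as_xyz_matrix(cloud)
  if (m > nrow(mtx)) abort("m exceeds the number of points in the cloud")
  idx <- fps_cpp(mtx, as.integer(m), as.integer(start))
  out <- pc_from_matrix(mtx[idx, , drop = FALSE], template = cloud)
  attr(out, "idx") <- idx
  out
}

#' K nearest neighbours between two clouds
#'
#' For every query point, the indices of its `K` nearest reference points by
#' Euclidean distance (exact, brute force; distance ties broken by lowest
#' reference index).
#'
#' @param query,reference Point clouds.
#' @param k Neighbourhood size (`1 <= k <= n_points(reference)`).
#' @return An integer matrix with one row per query point and `k` columns of
#'   reference indices, nearest first.
#' @examples
#' knn_query(point_cloud(cbind(0.1, 0, 0)), point_cloud(cbind(0:5, 0, 0)), k = 2)
#' @export
knn_query <- function(query, reference, k) {
  q <- as_xyz_matrix(query)
  r <- as_xyz_matrix(reference)
  if (k > nrow(r)) abort("K exceeds the reference cloud size")
  knn_cpp(q, r, as.integer(k))
}

#' Build the three-level resolution pyramid
#'
#' Downsamples a complete cloud into nested levels of 2048, 1024 and 512
#' points: level 1 is `ifps(cloud, 2048)`, level 2 is sampled from level 1
#' and level 3 from level 2, so the levels are nested as point sets. The
#' coarse levels carry the backbone structure, the fine level the detail; the
#' degradation operator and the discriminators act per level.
#'
#' `partial_pyramid()` is the variant for the partial observation, whose
#' levels are `min(n, 2048) / min(n, 1024) / min(n, 512)` so inputs smaller
#' than the nominal resolution remain usable.
#'
#' @param cloud A point cloud with at least 2048 points (for
#'   `build_pyramid()`).
#' @param start Seed index forwarded to [ifps()].
#' @return A `resolution_pyramid`: list with clouds `level1`, `level2`,
#'   `level3`, index maps `idx2` (level2 rows within level1) and `idx3`
#'   (level3 rows within level2), and `sizes`.
#' @examples
#' \donttest{
#' pyr <- build_pyramid(make_carton(seed = 1))
#' vapply(pyr[c("level1", "level2", "level3")], n_points, integer(1))
#' }
#' @export
build_pyramid <- function(cloud, start = 1L) {
  if (n_points(cloud) < 2048L) {
    abort("build_pyramid() needs at least 2048 points; see partial_pyramid() for smaller inputs")
  }
  new_pyramid(cloud, c(2048L, 1024L, 512L), start)
}

#' @rdname build_pyramid
#' @export
partial_pyramid <- function(cloud, start = 1L) {
  n <- n_points(cloud)
  new_pyramid(cloud, pmin(n, c(2048L, 1024L, 512L)), start)
}

new_pyramid <- function(cloud, sizes, start = 1L) {
  l1 <- ifps(cloud, sizes[1], start = start)
  l2 <- ifps(l1, sizes[2], start = start)
  l3 <- ifps(l2, sizes[3], start = start)
  structure(
    list(
      level1 = l1, level2 = l2, level3 = l3,
      idx2 = attr(l2, "idx"), idx3 = attr(l3, "idx"),
      sizes = sizes
    ),
    class = "resolution_pyramid"
  )
}

#' @export
print.resolution_pyramid <- function(x, ...) {
  cat(sprintf(
    "# resolution pyramid: %d / %d / %d points (nested)\n",
    x$sizes[1], x$sizes[2], x$sizes[3]
  ))
  invisible(x)
}

pyramid_levels <- function(pyr) list(pyr$level1, pyr$level2, pyr$level3)
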