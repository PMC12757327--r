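#' Center a point cloud at the origin
#'
#' Subtracts the axis-wise bounding-box midpoint (not the centroid: for
#' asymmetric clouds the two differ, and the bounding-box convention keeps the
#' normalized cloud symmetric about its extent), realigning the cloud so its
#' bounding box is centered on the coordinate origin.
#'
#' @param cloud A point cloud (or data frame with `x`, `y`, `z`).
#' @return The centered [point_cloud].
#' @examples
#' center_cloud(point_cloud(cbind(c(2, 4), 0, 0)))
#' @export
center_cloud <- function(cloud) {
  m <- as_xyz_matrix(cloud)
  bb <- bounding_box(m)
  pc_from_matrix(sweep(m, 2L, bb$mid, "-"), template = cloud)
}

#' Normalize a centered cloud into (-1, 1)
#'
#' Divides all coordinates by half the extent of the longest axis, so the
#' cloud touches ±1 on that axis and stays within `[-1, 1]` everywhere. The
#' cloud must already be centered (bounding-box midpoint at the origin within
#' `tol`); see [center_cloud()].
#'
#' @param cloud A centered point cloud.
#' @param tol Tolerance on the centering precondition.
#' @return The normalized [point_cloud].
#' @examples
#' normalize_cloud(center_cloud(point_cloud(cbind(c(-5, 5), 0, 0))))
#' @export
normalize_cloud <- function(cloud, tol = 1e-6) {
  m <- as_xyz_matrix(cloud)
  bb <- bounding_box(m)
  if (any(abs(bb$mid) > tol)) {
    abort("cloud is not centered; call center_cloud() first")
  }
  m_max <- max(bb$extent) / 2
  if (m_max <= 0) abort("degenerate cloud (all points identical): no scale defined")
  pc_from_matrix(m / m_max, template = cloud)
}

#' Rotate a point cloud about the origin
#'
#' `rotate_cloud()` applies the proper rotation with the given Euler angles
#' (radians), composed in x-then-y-then-z order. `random_rotation_augment()`
#' draws the three angles independently and uniformly from `[0, 2*pi)` under
#' `seed` -- the augmentation used to diversify training sets of complete
#' shapes.
#'
#' @param cloud A point cloud.
#' @param angles Numeric vector of 3 rotation angles (radians) about x, y, z.
#' @param seed Integer seed for the random angles.
#' @return The rotated [point_cloud].
#' @examples
#' rotate_cloud(point_cloud(cbind(1, 0, 0)), c(0, 0, pi / 2))
#' @export
rotate_cloud <- function(cloud, angles) {
  stopifnot(is.numeric(angles), length(angles) == 3L)
  m <- as_xyz_matrix(cloud)
  pc_from_matrix(m %*% t(rotation_matrix(angles)), template = cloud)
}

#' @rdname rotate_cloud
#' @export
random_rotation_augment <- function(cloud, seed) {
  angles <- withr::with_seed(as.integer(seed), runif(3L, 0, 2 * pi))
  rotate_cloud(cloud, angles)
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Split identifiers into train / validation / test sets
#'
#' Shuffles the identifiers under `seed` and assigns 60% to training, 20% to
#' validation and the remainder (the leftover after flooring, so at least 20%)
#' to testing. The three partitions are disjoint and exhaust the input.
#'
#' @param ids Character or integer identifiers (at least 5).
#' @param seed Integer seed controlling the shuffle.
#' @return A `dataset_split`: list with elements `train`, `val`, `test` and
#'   `seed`. `tidy()` turns it into a two-column tibble (`id`, `set`).
#' @examples
#' split_dataset(sprintf("shape%03d", 1:10), seed = 1)
#' @export
split_dataset <- function(ids, seed) {
  ids <- as.vector(ids)
  if (anyDuplicated(ids)) abort("ids must be unique")
  n <- length(ids)
  if (n < 5L) abort("need at least 5 identifiers to populate train/val/test")
  shuffled <- withr::with_seed(as.integer(seed), sample(ids, n))
  n_train <- floor(0.6 * n)
  n_val <- floor(0.2 * n)
  out <- list(
    train = shuffled[seq_len(n_train)],
    val = shuffled[n_train + seq_len(n_val)],
    test = shuffled[-seq_len(n_train + n_val)],
    seed = as.integer(seed)
  )
  class(out) <- "dataset_split"
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "# dataset split (seed %d): %d train / %d val / %d test\n",
    x$seed, length(x$train), length(x$val), length(x$test)
  ))
  invisible(x)
}

#' @export
tidy.dataset_split <- function(x, ...) {
  tibble(
    id = c(x$train, x$val, x$test),
    set = rep(c("train", "val", "test"), c(length(x$train), length(x$val), length(x$test)))
  )
}
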