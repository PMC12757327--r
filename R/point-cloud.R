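#' Point cloud objects
#'
#' A point cloud is an unordered set of 3D points stored as a tibble with
#' numeric columns `x`, `y`, `z` (one row per point). Duplicate points are
#' permitted -- real scans contain them. Coordinates must be finite and a
#' cloud holds at least one point. Optional metadata travel as attributes:
#' `label` (an object-class tag such as `"carton"`) and `source` (the file a
#' cloud was read from).
#'
#' All user-facing functions in the package accept either a `point_cloud` or
#' any data frame with `x`, `y`, `z` columns (or an unnamed 3-column numeric
#' matrix) and return tibble-backed `point_cloud` objects, so calls compose
#' with the pipe.
#'
#' @param points A data frame with columns `x`, `y`, `z`, or a numeric matrix
#'   with 3 columns.
#' @param label Optional character object-class tag.
#' @param source Optional path the cloud originated from.
#' @return A `point_cloud`: a tibble with columns `x`, `y`, `z`.
#' @examples
#' pc <- point_cloud(data.frame(x = 0:1, y = 0, z = 0))
#' n_points(pc)
#' @export
point_cloud <- function(points, label = NULL, source = NULL) {
  m <- as_xyz_matrix(points)
  if (nrow(m) < 1L) abort("a point cloud needs at least one point")
  if (!all(is.finite(m))) abort("point coordinates must be finite (no NA/NaN/Inf)")
  out <- new_tibble(
    list(x = m[, 1L], y = m[, 2L], z = m[, 3L]),
    nrow = nrow(m),
    class = "point_cloud"
  )
  attr(out, "label") <- label
  attr(out, "source") <- source
  out
}

#' @rdname point_cloud
#' @param cloud An object to convert or test.
#' @export
as_point_cloud <- function(cloud, label = NULL, source = NULL) {
  if (is_point_cloud(cloud) && is.null(label) && is.null(source)) return(cloud)
  point_cloud(cloud,
    label = label %||% attr(cloud, "label"),
    source = source %||% attr(cloud, "source")
  )
}

#' @rdname point_cloud
#' @export
is_point_cloud <- function(cloud) inherits(cloud, "point_cloud")

#' @rdname point_cloud
#' @export
n_points <- function(cloud) nrow(as_xyz_matrix(cloud))

#' @rdname point_cloud
#' @export
cloud_label <- function(cloud) attr(cloud, "label")

# Internal currency: a plain n x 3 double matrix.
as_xyz_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 3L) abort("a point matrix must have exactly 3 columns")
    storage.mode(points) <- "double"
    dimnames(points) <- NULL
    return(points)
  }
  if (is.data.frame(points)) {
    miss <- setdiff(c("x", "y", "z"), names(points))
    if (length(miss)) {
      abort(paste0("point data frame is missing column(s): ", paste(miss, collapse = ", ")))
    }
    return(cbind(as.double(points$x), as.double(points$y), as.double(points$z)))
  }
  abort("points must be a data frame with x/y/z columns or an n x 3 matrix")
}

# Rebuild a cloud from a matrix, carrying metadata from a template.
pc_from_matrix <- function(m, template = NULL, label = NULL, source = NULL) {
  point_cloud(m,
    label = label %||% attr(template, "label"),
    source = source %||% attr(template, "source")
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  lab <- attr(x, "label")
  src <- attr(x, "source")
  cat(sprintf(
    "# point cloud: %d points%s%s\n", nrow(x),
    if (!is.null(lab)) paste0(", label '", lab, "'") else "",
    if (!is.null(src)) paste0(", from ", src) else ""
  ))
  m <- as_xyz_matrix(x)
  rng <- apply(m, 2L, range)
  cat(sprintf(
    "# extent: x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
    rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]
  ))
  NextMethod()
}

#' Axis-aligned bounding box of a cloud
#'
#' @param cloud A point cloud (or data frame with `x`, `y`, `z`).
#' @return A tibble with one row per axis and columns `axis`, `min`, `max`,
#'   `mid` (the midpoint used for centering) and `extent`.
#' @examples
#' bounding_box(point_cloud(cbind(c(0, 2), c(0, 6), c(0, 2))))
#' @export
bounding_box <- function(cloud) {
  m <- as_xyz_matrix(cloud)
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  tibble(
    axis = c("x", "y", "z"),
    min = lo,
    max = hi,
    mid = lo + (hi - lo) / 2,
    extent = hi - lo
  )
}

#' Scatter views of a point cloud
#'
#' Draws the three orthographic projections (xy, xz, yz) of a cloud.
#'
#' @param object A point cloud.
#' @param size Point size passed to [ggplot2::geom_point()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_cloud <- function(object, size = 0.3, ...) {
  m <- as_xyz_matrix(object)
  views <- dplyr::bind_rows(
    tibble(view = "xy", h = m[, 1], v = m[, 2]),
    tibble(view = "xz", h = m[, 1], v = m[, 3]),
    tibble(view = "yz", h = m[, 2], v = m[, 3])
  )
  ggplot2::ggplot(views, ggplot2::aes(.data$h, .data$v)) +
    ggplot2::geom_point(size = size, alpha = 0.6) +
    ggplot2::facet_wrap(~view) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = attr(object, "label") %||% "point cloud",
      subtitle = sprintf("%d points", nrow(object))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
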