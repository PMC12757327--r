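#' Procedural complete shapes: cartons and plants
#'
#' Desk-scale stand-ins for the scanned objects the completion pipeline is
#' aimed at. `make_carton()` samples points uniformly by area over the six
#' faces of a box; `make_plant()` builds a procedural plant from a vertical
#' stem cylinder, branch cylinders attached at parameterized heights and
#' angles, and elliptical leaf discs at branch tips. Both are seeded,
#' centered and (by default) normalized into `(-1, 1)`, and emit exactly
#' `n_points` points. No claim of botanical realism is made -- the plants
#' exist to span "simple external contour" to "intricate contour" with a
#' complexity knob.
#'
#' `plant_preset()` maps a complexity level 1..5 to plant parameters
#' (increasing branch and leaf counts). `carton_population()` and
#' `plant_population()` draw lists of varied shapes for GAN pretraining.
#'
#' @param n_points Number of points to emit (default 2048, at least 512).
#' @param extents Positive full edge lengths of the carton.
#' @param seed Integer seed.
#' @param normalize Center and normalize the cloud into `(-1, 1)` (default
#'   `TRUE`).
#' @return A [point_cloud] with `n_points` rows and label `"carton"` or
#'   `"plant"`.
#' @examples
#' make_carton(n_points = 512, seed = 1)
#' make_plant(n_points = 512, n_branches = 0, n_leaves = 0, seed = 1)
#' @export
make_carton <- function(n_points = 2048L, extents = c(1, 0.8, 0.6), seed = 0L,
                        normalize = TRUE) {
  stopifnot(length(extents) == 3L)
  if (any(extents <= 0)) abort("carton extents must be positive")
  if (n_points < 512L) abort("n_points must be at least 512")
  half <- extents / 2
  # two faces per axis; face perpendicular to axis i has area of the other two
  face_axis <- rep(1:3, each = 2L)
  face_sign <- rep(c(-1, 1), times = 3L)
  areas <- c(
    extents[2] * extents[3], extents[2] * extents[3],
    extents[1] * extents[3], extents[1] * extents[3],
    extents[1] * extents[2], extents[1] * extents[2]
  )
  m <- withr::with_seed(as.integer(seed), {
    face <- sample.int(6L, n_points, replace = TRUE, prob = areas)
    pts <- matrix(runif(3L * n_points, -1, 1), n_points, 3L)
    pts <- sweep(pts, 2L, half, "*")
    pts[cbind(seq_len(n_points), face_axis[face])] <- face_sign[face] * half[face_axis[face]]
    pts
  })
  out <- point_cloud(m, label = "carton")
  if (normalize) normalize_cloud(center_cloud(out)) else out
}

#' @rdname make_carton
#' @param stem_height,stem_radius Stem cylinder dimensions.
#' @param n_branches,branch_length,branch_radius Branch cylinder count and
#'   dimensions.
#' @param n_leaves,leaf_size Leaf disc count and semi-major axis (the minor
#'   axis is 0.6 of it).
#' @export
make_plant <- function(n_points = 2048L, stem_height = 1.6, stem_radius = 0.04,
                       n_branches = 4L, branch_length = 0.5, branch_radius = 0.02,
                       n_leaves = 4L, leaf_size = 0.18, seed = 0L,
                       normalize = TRUE) {
  if (n_points < 512L) abort("n_points must be at least 512")
  if (stem_height <= 0 || stem_radius <= 0) abort("stem dimensions must be positive")
  if (n_branches < 0L || n_leaves < 0L) abort("branch and leaf counts must be non-negative")
  if (n_branches > 0L && (branch_length <= 0 || branch_radius <= 0)) {
    abort("branch dimensions must be positive")
  }
  if (n_leaves > 0L && leaf_size <= 0) abort("leaf_size must be positive")

  m <- withr::with_seed(as.integer(seed), {
    # component layout ------------------------------------------------------
    branches <- if (n_branches > 0L) {
      lapply(seq_len(n_branches), function(i) {
        h <- runif(1, 0.35, 0.9) * stem_height
        az <- 2 * pi * (i - 1) / n_branches + runif(1, -0.3, 0.3)
        elev <- runif(1, pi / 5, pi / 2.6) # angle from the vertical
        dir <- c(sin(elev) * cos(az), sin(elev) * sin(az), cos(elev))
        list(base = c(0, 0, h), dir = dir, len = branch_length * runif(1, 0.8, 1.2))
      })
    } else {
      list()
    }
    leaves <- if (n_leaves > 0L) {
      lapply(seq_len(n_leaves), function(i) {
        anchor <- if (length(branches)) {
          br <- branches[[(i - 1L) %% length(branches) + 1L]]
          br$base + br$dir * br$len
        } else {
          c(0, 0, stem_height)
        }
        nrm <- rnorm(3)
        nrm <- nrm / sqrt(sum(nrm^2))
        list(center = anchor, normal = nrm, a = leaf_size, b = 0.6 * leaf_size)
      })
    } else {
      list()
    }

    # allocate points by surface area (largest remainder) --------------------
    areas <- c(
      2 * pi * stem_radius * stem_height,
      vapply(branches, function(b) 2 * pi * branch_radius * b$len, numeric(1)),
      vapply(leaves, function(l) pi * l$a * l$b, numeric(1))
    )
    share <- n_points * areas / sum(areas)
    counts <- floor(share)
    rest <- n_points - sum(counts)
    if (rest > 0) {
      bump <- order(share - counts, decreasing = TRUE)[seq_len(rest)]
      counts[bump] <- counts[bump] + 1L
    }

    cyl_points <- function(n, base, dir, len, radius) {
      if (n < 1L) return(NULL)
      dir <- dir / sqrt(sum(dir^2))
      # orthonormal frame around dir
      ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * dir) * dir
      u <- u / sqrt(sum(u^2))
      v <- c(
        dir[2] * u[3] - dir[3] * u[2],
        dir[3] * u[1] - dir[1] * u[3],
        dir[1] * u[2] - dir[2] * u[1]
      )
      t <- runif(n, 0, len)
      th <- runif(n, 0, 2 * pi)
      outer(t, dir) + radius * (outer(cos(th), u) + outer(sin(th), v)) +
        matrix(base, n, 3L, byrow = TRUE)
    }
    disc_points <- function(n, leaf) {
      if (n < 1L) return(NULL)
      dir <- leaf$normal
      ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- ref - sum(ref * dir) * dir
      u <- u / sqrt(sum(u^2))
      v <- c(
        dir[2] * u[3] - dir[3] * u[2],
        dir[3] * u[1] - dir[1] * u[3],
        dir[1] * u[2] - dir[2] * u[1]
      )
      r <- sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      outer(leaf$a * r * cos(th), u) + outer(leaf$b * r * sin(th), v) +
        matrix(leaf$center, n, 3L, byrow = TRUE)
    }

    parts <- c(
      list(cyl_points(counts[1], c(0, 0, 0), c(0, 0, 1), stem_height, stem_radius)),
      Map(function(b, n) cyl_points(n, b$base, b$dir, b$len, branch_radius),
        branches, as.list(counts[1L + seq_along(branches)])
      ),
      Map(disc_points,
        as.list(counts[1L + length(branches) + seq_along(leaves)]),
        leaves
      )
    )
    do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  })
  out <- point_cloud(m, label = "plant")
  if (normalize) normalize_cloud(center_cloud(out)) else out
}

#' @rdname make_carton
#' @param level Plant complexity preset, 1 (simple contour) to 5 (intricate).
#' @export
plant_preset <- function(level, n_points = 2048L, seed = 0L, normalize = TRUE) {
  stopifnot(level %in% 1:5)
  branches <- c(1L, 3L, 5L, 8L, 12L)[level]
  leaves <- c(0L, 2L, 5L, 8L, 12L)[level]
  make_plant(
    n_points = n_points,
    n_branches = branches,
    n_leaves = leaves,
    branch_length = 0.4 + 0.05 * (level - 1),
    leaf_size = 0.12 + 0.02 * (level - 1),
    seed = seed,
    normalize = normalize
  )
}

#' @rdname make_carton
#' @param n_shapes Number of shapes to draw.
#' @export
carton_population <- function(n_shapes, n_points = 2048L, seed = 0L) {
  lapply(seq_len(n_shapes), function(i) {
    si <- derived_seed(seed, i)
    extents <- withr::with_seed(derived_seed(seed, 10000L + i), runif(3, 0.6, 1.4))
    make_carton(n_points = n_points, extents = extents, seed = si)
  })
}

#' @rdname make_carton
#' @export
plant_population <- function(n_shapes, level, n_points = 2048L, seed = 0L) {
  lapply(seq_len(n_shapes), function(i) {
    plant_preset(level, n_points = n_points, seed = derived_seed(seed, i))
  })
}

derived_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 7919) %% 2147483647)
}

#' Occlusion recipes for partial-scan synthesis
#'
#' `halfspace_occlusion()` hides every point on the positive side of a
#' plane: points with `<p, normal> > offset` are dropped.
#' `viewpoint_occlusion()` is a hidden-point heuristic: points are binned on
#' an angular grid around the viewpoint and only the points nearest the
#' viewpoint within each cell (within a depth tolerance) survive,
#' emulating self-occlusion of a single-view scan.
#'
#' @param normal Outward normal of the hidden half-space.
#' @param offset Plane offset along the normal (default 0).
#' @param viewpoint 3D scanner position.
#' @param grid Angular grid resolution per axis (default 24).
#' @param depth_tol Depth tolerance as a fraction of the cloud diagonal
#'   (default 0.08).
#' @return An occlusion recipe for [simulate_partial_scan()].
#' @export
halfspace_occlusion <- function(normal = c(1, 0, 0), offset = 0) {
  stopifnot(length(normal) == 3L, any(normal != 0))
  structure(list(type = "halfspace", normal = normal, offset = offset),
    class = "occlusion_spec"
  )
}

#' @rdname halfspace_occlusion
#' @export
viewpoint_occlusion <- function(viewpoint = c(3, 0, 0), grid = 24L, depth_tol = 0.08) {
  stopifnot(length(viewpoint) == 3L, grid >= 2L, depth_tol > 0)
  structure(
    list(type = "viewpoint", viewpoint = viewpoint, grid = as.integer(grid),
         depth_tol = depth_tol),
    class = "occlusion_spec"
  )
}

#' Simulate a LiDAR-like partial scan
#'
#' Degrades a complete cloud into a partial observation by applying, in
#' order: an occlusion mask (see [halfspace_occlusion()] and
#' [viewpoint_occlusion()]), a sparsity schedule (a seeded uniform keep of
#' `ceiling(rho * n)` points), and isotropic Gaussian noise of standard
#' deviation `noise_sigma` per coordinate. With no occlusion, `rho = 1` and
#' `noise_sigma = 0` the input is returned unchanged; with `noise_sigma = 0`
#' every scan point is a member of the source cloud.
#'
#' @param cloud The complete source cloud.
#' @param occlusion `NULL` or an occlusion recipe.
#' @param rho Keep fraction in `(0, 1]`.
#' @param noise_sigma Non-negative noise standard deviation.
#' @param seed Integer seed (sparsity subsampling and noise).
#' @return A [point_cloud]; errors if the occlusion hides every point.
#' @export
simulate_partial_scan <- function(cloud, occlusion = NULL, rho = 1,
                                  noise_sigma = 0, seed = 0L) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1) abort("rho must be in (0, 1]")
  if (noise_sigma < 0) abort("noise_sigma must be non-negative")
  m <- as_xyz_matrix(cloud)

  if (!is.null(occlusion)) {
    stopifnot(inherits(occlusion, "occlusion_spec"))
    keep <- if (occlusion$type == "halfspace") {
      as.vector(m %*% occlusion$normal) <= occlusion$offset
    } else {
      visible_from_viewpoint(m, occlusion)
    }
    if (!any(keep)) abort("occlusion hides every point: empty scan")
    m <- m[keep, , drop = FALSE]
  }

  m <- withr::with_seed(as.integer(seed), {
    if (rho < 1) {
      n_keep <- ceiling(rho * nrow(m))
      m <- m[sort(sample.int(nrow(m), n_keep)), , drop = FALSE]
    }
    if (noise_sigma > 0) {
      m <- m + matrix(rnorm(length(m), sd = noise_sigma), nrow(m), 3L)
    }
    m
  })
  pc_from_matrix(m, template = cloud)
}

visible_from_viewpoint <- function(m, occ) {
  rel <- sweep(m, 2L, occ$viewpoint, "-")
  depth <- sqrt(rowSums(rel^2))
  az <- atan2(rel[, 2], rel[, 1])
  el <- asin(rel[, 3] / pmax(depth, 1e-12))
  cell <- paste(
    pmin(occ$grid, 1L + floor(occ$grid * (az + pi) / (2 * pi))),
    pmin(occ$grid, 1L + floor(occ$grid * (el + pi / 2) / pi))
  )
  diag_len <- sqrt(sum((apply(m, 2, max) - apply(m, 2, min))^2))
  min_depth <- ave(depth, cell, FUN = min)
  depth <= min_depth + occ$depth_tol * diag_len
}
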