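test_that("cartons are box-surface samples with exact counts and seeds", {
  raw <- make_carton(n_points = 800, extents = c(1, 0.8, 0.6), seed = 1, normalize = FALSE)
  m <- as.matrix(as.data.frame(raw))
  expect_equal(nrow(m), 800L)
  half <- c(0.5, 0.4, 0.3)
  on_face <- abs(abs(m) - matrix(half, 800, 3, byrow = TRUE)) < 1e-9
  expect_true(all(rowSums(on_face) >= 1))

  expect_equal(
    as.data.frame(make_carton(n_points = 800, seed = 2)),
    as.data.frame(make_carton(n_points = 800, seed = 2))
  )
  expect_false(isTRUE(all.equal(
    as.data.frame(make_carton(n_points = 800, seed = 2)),
    as.data.frame(make_carton(n_points = 800, seed = 3))
  )))
  expect_error(make_carton(extents = c(1, -1, 1)), "positive")
  expect_error(make_carton(n_points = 100), "512")

  # normalized output touches 1 on the longest axis
  norm <- as.matrix(as.data.frame(make_carton(seed = 4)))
  expect_equal(max(abs(norm)), 1)
})

test_that("plants assemble stem, branches and leaves", {
  stem <- make_plant(n_points = 600, n_branches = 0, n_leaves = 0, seed = 5,
                     normalize = FALSE)
  m <- as.matrix(as.data.frame(stem))
  expect_equal(nrow(m), 600L)
  expect_true(all(sqrt(m[, 1]^2 + m[, 2]^2) <= 0.04 + 1e-9))

  full <- make_plant(n_points = 2048, seed = 6)
  expect_equal(n_points(full), 2048L)
  expect_equal(max(abs(as.matrix(as.data.frame(full)))), 1)

  leafy <- make_plant(n_points = 2048, n_leaves = 12, seed = 6)
  expect_false(isTRUE(all.equal(as.data.frame(full), as.data.frame(leafy))))

  expect_error(make_plant(stem_height = -1), "positive")
  expect_error(make_plant(n_leaves = 2, leaf_size = 0), "leaf_size")

  for (lv in 1:5) {
    expect_equal(n_points(plant_preset(lv, n_points = 512, seed = 1)), 512L)
  }
})

test_that("partial-scan synthesis applies occlusion, sparsity, noise in order", {
  carton <- make_carton(seed = 7)

  # identity recipe
  expect_equal(
    as.data.frame(simulate_partial_scan(carton, NULL, rho = 1, noise_sigma = 0)),
    as.data.frame(carton)
  )

  # half-space crop of an x-symmetric carton keeps about half the points
  scan <- simulate_partial_scan(carton, halfspace_occlusion(c(1, 0, 0)), seed = 1)
  expect_gt(n_points(scan) / 2048, 0.38)
  expect_lt(n_points(scan) / 2048, 0.62)
  expect_true(all(as.data.frame(scan)$x <= 0))

  # sparsity count is exact
  expect_equal(n_points(simulate_partial_scan(carton, NULL, rho = 0.25, seed = 2)), 512L)

  # noiseless scans only select points from the source
  key <- function(pc) do.call(paste, as.data.frame(pc))
  sel <- simulate_partial_scan(carton, halfspace_occlusion(), rho = 0.5, seed = 3)
  expect_true(all(key(sel) %in% key(carton)))
  expect_equal(ucd(sel, carton), 0)

  noisy <- simulate_partial_scan(carton, NULL, noise_sigma = 0.01, seed = 4)
  expect_false(any(key(noisy) %in% key(carton)))
  expect_lt(uhd(noisy, carton), 0.1)

  expect_identical(
    as.data.frame(simulate_partial_scan(carton, halfspace_occlusion(), rho = 0.7,
                                        noise_sigma = 0.01, seed = 5)),
    as.data.frame(simulate_partial_scan(carton, halfspace_occlusion(), rho = 0.7,
                                        noise_sigma = 0.01, seed = 5))
  )

  expect_error(
    simulate_partial_scan(carton, halfspace_occlusion(c(0, 0, 1), offset = -10)),
    "empty scan"
  )
  expect_error(simulate_partial_scan(carton, rho = 0), "rho")
  expect_error(simulate_partial_scan(carton, noise_sigma = -1), "non-negative")
})

test_that("viewpoint occlusion keeps the visible side", {
  carton <- make_carton(seed = 8)
  scan <- simulate_partial_scan(carton, viewpoint_occlusion(c(5, 0, 0)), seed = 1)
  expect_lt(n_points(scan), 2048L)
  expect_gt(n_points(scan), 200L)
  m <- as.matrix(as.data.frame(scan))
  # the far face (x = -1) should be mostly hidden
  expect_lt(mean(m[, 1] < -0.99), 0.25)
})
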