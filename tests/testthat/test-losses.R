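make_triplet <- function(xb, xbp, xbpp) {
  structure(list(xb = xb, xb_prime = xbp, xb_dprime = xbpp, k_used = 1L),
    class = "degraded_triplet"
  )
}

make_pyr <- function(l1, l2, l3) {
  structure(list(level1 = l1, level2 = l2, level3 = l3,
                 sizes = c(n_points(l1), n_points(l2), n_points(l3))),
    class = "resolution_pyramid"
  )
}

test_that("loss weights validate the mixing constraint", {
  w <- loss_weights()
  expect_equal(w$h_c + w$h_d, 1)
  expect_error(loss_weights(h_c = 0.6, h_d = 0.5), "equal 1")
  expect_error(loss_weights(h_c = -0.1, h_d = 1.1), "\\[0, 1\\]")
  expect_error(loss_weights(alpha = -1), "alpha")
  expect_silent(loss_weights(h_c = 1, h_d = 0))
})

test_that("multi-stage reconstruction combines the three stages", {
  at <- function(d) point_cloud(cbind(d, 0, 0))
  origin <- point_cloud(cbind(0, 0, 0))
  # single-point stages with cd_t values 2, 1, 4
  tri <- make_triplet(at(1), at(sqrt(0.5)), at(sqrt(2)))
  pyr <- make_pyr(origin, origin, origin)
  expect_equal(
    multi_stage_reconstruction(tri, pyr, loss_weights(alpha = 0.5, beta = 0.25)),
    2 + 0.5 * 1 + 0.25 * 4
  )
  # alpha = beta = 0 reduces to the full-resolution stage
  expect_equal(
    multi_stage_reconstruction(tri, pyr, loss_weights(alpha = 0, beta = 0)),
    2
  )
  # all stages matching their partials -> 0
  tri0 <- make_triplet(origin, origin, origin)
  expect_equal(multi_stage_reconstruction(tri0, pyr, loss_weights()), 0)

  # monotone nondecreasing in alpha and beta
  lo <- multi_stage_reconstruction(tri, pyr, loss_weights(alpha = 0.1, beta = 0.1))
  hi <- multi_stage_reconstruction(tri, pyr, loss_weights(alpha = 0.9, beta = 0.9))
  expect_lte(lo, hi)
})

test_that("feature matching sums per-level L1 distances and vanishes on identity", {
  model <- tiny_model()
  cloud <- make_carton(seed = 31)
  gp <- build_pyramid(cloud)
  partial <- simulate_partial_scan(cloud, halfspace_occlusion(), seed = 2)
  pp <- partial_pyramid(partial)
  tri <- degrade_pyramid(gp, pp, k = 20)

  total <- feature_matching(tri, pp, model$discriminators)
  by_hand <- sum(vapply(1:3, function(l) {
    fd <- discriminate_features(model$discriminators[[l]],
      list(tri$xb, tri$xb_prime, tri$xb_dprime)[[l]])$features
    fp <- discriminate_features(model$discriminators[[l]],
      list(pp$level1, pp$level2, pp$level3)[[l]])$features
    sum(abs(fd - fp))
  }, numeric(1)))
  expect_equal(total, by_hand, tolerance = 1e-12)
  expect_gt(total, 0)

  # degraded identical to partial at every level -> 0
  tri_id <- make_triplet(pp$level1, pp$level2, pp$level3)
  expect_equal(feature_matching(tri_id, pp, model$discriminators), 0)

  # |a - b| is symmetric in the two clouds
  swapped <- make_pyr(tri$xb, tri$xb_prime, tri$xb_dprime)
  tri_swap <- make_triplet(pp$level1, pp$level2, pp$level3)
  expect_equal(feature_matching(tri_swap, swapped, model$discriminators), total,
    tolerance = 1e-12
  )
})

test_that("total loss mixes the two terms under the constraint", {
  expect_equal(total_loss(2, 1, loss_weights(h_c = 0.7, h_d = 0.3)), 1.7)
  expect_equal(total_loss(5, 99, loss_weights(h_c = 1, h_d = 0)), 5)
  expect_equal(total_loss(0, 0, loss_weights()), 0)
  expect_gt(total_loss(1e-9, 1e-9, loss_weights()), 0)
})

test_that("the Chamfer gradient matches finite differences", {
  cdt_value_grad <- mrcnet:::cdt_value_grad
  x <- rand_cloud(12, seed = 41)
  y <- rand_cloud(9, seed = 42)
  got <- cdt_value_grad(x, y)
  expect_equal(got$value, cd_t_oracle(x, y), tolerance = 1e-12)
  eps <- 1e-6
  for (probe in list(c(1, 1), c(5, 2), c(12, 3))) {
    xp <- x; xp[probe[1], probe[2]] <- xp[probe[1], probe[2]] + eps
    xm <- x; xm[probe[1], probe[2]] <- xm[probe[1], probe[2]] - eps
    fd <- (cd_t_oracle(xp, y) - cd_t_oracle(xm, y)) / (2 * eps)
    expect_equal(got$grad[probe[1], probe[2]], fd, tolerance = 1e-4)
  }
})
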