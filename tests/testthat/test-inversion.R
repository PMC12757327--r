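small_cfg <- function(...) {
  inversion_config(n_init_samples = 8L, n_iterations = 10L, seed = 2, ...)
}

test_that("latent initialization returns the arg-min of the scored candidates", {
  model <- tiny_model()
  partial <- simulate_partial_scan(make_carton(seed = 71), halfspace_occlusion(), seed = 1)
  cfg <- inversion_config(n_init_samples = 16L, seed = 5)
  y <- init_latent(model$generator, partial, cfg)
  scores <- attr(y, "candidate_objectives")
  expect_length(scores, 16L)
  expect_equal(attr(y, "objective"), min(scores))
  cand <- latent_prior_sample(model$generator$latent_dim, 16L, seed = 5)
  expect_equal(as.numeric(y), cand[which.min(scores), ])

  one <- init_latent(model$generator, partial, inversion_config(n_init_samples = 1L, seed = 5))
  expect_equal(as.numeric(one), cand[1, ])
})

test_that("a planted latent is recovered by initialization", {
  model <- tiny_model()
  gen <- model$generator
  y_star <- latent_prior_sample(gen$latent_dim, 1, seed = 17)[1, ]
  # the full generated shape is its own K-mask, so its objective is zero
  planted_input <- generate(gen, y_star)
  y_hat <- init_latent(gen, planted_input, inversion_config(n_init_samples = 12L, seed = 17))
  expect_equal(as.numeric(y_hat), y_star)
  expect_equal(attr(y_hat, "objective"), 0)
})

test_that("zero iterations returns the best-init generation unchanged", {
  model <- tiny_model()
  partial <- simulate_partial_scan(make_carton(seed = 72), halfspace_occlusion(), seed = 2)
  cfg <- inversion_config(n_init_samples = 8L, n_iterations = 0L, seed = 3)
  res <- invert(model, partial, cfg)
  expect_equal(nrow(res$objective_trace), 1L)
  y0 <- init_latent(model$generator, partial, cfg)
  expect_equal(
    unname(as.matrix(as.data.frame(res$completed))),
    unname(as.matrix(as.data.frame(generate(model$generator, as.numeric(y0)))))
  )
})

test_that("inversion is deterministic, finite, and best-iterate tracked", {
  model <- tiny_model()
  partial <- simulate_partial_scan(make_carton(seed = 73), halfspace_occlusion(), seed = 3)
  res1 <- invert(model, partial, small_cfg())
  res2 <- invert(model, partial, small_cfg())
  expect_equal(as.data.frame(res1$completed), as.data.frame(res2$completed))
  expect_identical(res1$objective_trace, res2$objective_trace)

  tr <- res1$objective_trace
  expect_false(anyNA(tr$total))
  expect_lte(min(tr$total), tr$total[1])
  # the returned iterate realizes the minimum recorded objective
  expect_equal(n_points(res1$completed), 2048L)

  expect_error(invert(model, point_cloud(rand_cloud(100, seed = 1))), "512")
  expect_error(
    invert(model, point_cloud(rand_cloud(600, seed = 1) * 3)),
    "normalized"
  )
})

test_that("per-instance adaptation does not leak across inputs", {
  model <- tiny_model()
  pa <- simulate_partial_scan(make_carton(seed = 74), halfspace_occlusion(), seed = 4)
  pb <- simulate_partial_scan(make_carton(seed = 75), halfspace_occlusion(), seed = 5)
  alone <- invert(model, pb, small_cfg())
  invisible(invert(model, pa, small_cfg()))
  after <- invert(model, pb, small_cfg())
  expect_equal(as.data.frame(after$completed), as.data.frame(alone$completed))
})

test_that("tidy/glance/autoplot expose the result", {
  model <- tiny_model()
  partial <- simulate_partial_scan(make_carton(seed = 76), halfspace_occlusion(), seed = 6)
  truth <- make_carton(seed = 76)
  res <- invert(model, partial, small_cfg(), truth = truth)
  td <- tidy(res)
  expect_named(td, c("iteration", "reconstruction", "feature_matching", "total"))
  gl <- glance(res)
  expect_true(all(c("cd_t", "ucd", "objective_best") %in% names(gl)))
  expect_false(is.na(gl$cd_t))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("file-level completion writes the cloud and the report", {
  model <- tiny_model()
  dir <- withr::local_tempdir()
  truth <- make_carton(seed = 77)
  partial <- simulate_partial_scan(truth, halfspace_occlusion(), seed = 7)
  in_path <- file.path(dir, "scan.xyz")
  write_point_cloud(partial, in_path)
  out_path <- file.path(dir, "completed.xyz")
  rep_path <- file.path(dir, "report.json")
  res <- complete_file(model, in_path,
    out = out_path, report = rep_path,
    config = inversion_config(n_init_samples = 4L, n_iterations = 2L, seed = 1)
  )
  expect_equal(n_points(read_point_cloud(out_path)), 2048L)
  rep <- jsonlite::read_json(rep_path, simplifyVector = TRUE)
  expect_equal(rep$n_points, 2048L)
  expect_equal(length(rep$objective_trace$total), 3L)

  # batch mode: one result per input, named by file
  batch_dir <- file.path(dir, "batch")
  dir.create(batch_dir)
  write_point_cloud(partial, file.path(batch_dir, "a.xyz"))
  write_point_cloud(partial, file.path(batch_dir, "b.xyz"))
  out <- complete_file(model, batch_dir,
    config = inversion_config(n_init_samples = 2L, n_iterations = 0L, seed = 1)
  )
  expect_named(out, c("a.xyz", "b.xyz"))
})
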