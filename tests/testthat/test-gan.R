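test_that("the generator emits fixed-size, finite, deterministic clouds", {
  model <- tiny_model()
  gen <- model$generator
  y <- latent_prior_sample(gen$latent_dim, 1, seed = 7)[1, ]
  g1 <- generate(gen, y)
  expect_equal(n_points(g1), 2048L)
  expect_true(all(is.finite(as.matrix(as.data.frame(g1)))))
  expect_equal(as.data.frame(generate(gen, y)), as.data.frame(g1))

  zeros <- generate(gen, numeric(gen$latent_dim))
  expect_true(all(is.finite(as.matrix(as.data.frame(zeros)))))

  # output size constant across latents
  Y <- latent_prior_sample(gen$latent_dim, 25, seed = 8)
  sizes <- vapply(seq_len(25), function(i) n_points(generate(gen, Y[i, ])), integer(1))
  expect_true(all(sizes == 2048L))

  expect_error(generate(gen, numeric(5)), "length 5")
})

test_that("latent prior draws are row-stable across sample counts", {
  one <- latent_prior_sample(96, 1, seed = 3)
  many <- latent_prior_sample(96, 10, seed = 3)
  expect_equal(one[1, ], many[1, ])
})

test_that("discriminator features are pooled symmetrically", {
  model <- tiny_model()
  d1 <- model$discriminators[[1]]
  cloud <- make_carton(n_points = 600, seed = 13)
  out <- discriminate_features(d1, cloud)
  expect_length(out$features, d1$feature_width)
  expect_length(out$score, 1L)

  perm <- withr::with_seed(5, sample(600))
  shuffled <- point_cloud(as.matrix(as.data.frame(cloud))[perm, ])
  out2 <- discriminate_features(d1, shuffled)
  expect_equal(out2$features, out$features, tolerance = 1e-6)
  expect_equal(out2$score, out$score, tolerance = 1e-6)

  # identical clouds -> L1 distance zero
  expect_equal(sum(abs(out$features - discriminate_features(d1, cloud)$features)), 0)

  # configured feature width is honoured
  wide <- pretrain_gan(
    carton_population(4, n_points = 2048, seed = 77),
    desk_config(epochs = 0, batch_size = 4L, feature_width = 128L, seed = 1)
  )
  expect_length(
    discriminate_features(wide$discriminators[[2]], cloud)$features, 128L
  )
})

test_that("pretraining config validates and zero epochs is the identity", {
  expect_equal(train_config()$learning_rate, 1e-4)
  expect_equal(train_config()$batch_size, 64L)
  expect_equal(train_config()$epochs, 2000L)
  expect_equal(desk_config()$epochs, 200L)

  clouds <- carton_population(4, seed = 55)
  cfg0 <- desk_config(epochs = 0, batch_size = 4L, seed = 9)
  m0 <- pretrain_gan(clouds, cfg0)
  expect_equal(nrow(m0$history), 0L)
  m0b <- pretrain_gan(clouds, cfg0)
  expect_identical(m0$generator$params, m0b$generator$params)

  expect_error(pretrain_gan(clouds[1:2], desk_config(batch_size = 4L)), "batch_size")
  shifted <- lapply(clouds, function(cl) point_cloud(as.matrix(as.data.frame(cl)) + 2))
  expect_error(pretrain_gan(shifted, cfg0), "normalized")
  mixed <- clouds
  attr(mixed[[1]], "label") <- "plant"
  expect_error(pretrain_gan(mixed, cfg0), "single object class")
})

test_that("pretraining is reproducible from its seed", {
  clouds <- carton_population(8, seed = 66)
  cfg <- desk_config(epochs = 2, batch_size = 8L, seed = 4)
  m1 <- pretrain_gan(clouds, cfg)
  m2 <- pretrain_gan(clouds, cfg)
  expect_identical(m1$generator$params, m2$generator$params)
  expect_identical(m1$discriminators[[3]]$params, m2$discriminators[[3]]$params)
  expect_identical(m1$history, m2$history)
})

test_that("pretraining moves samples toward the training distribution", {
  train <- carton_training_set()
  model <- carton_model()
  init <- pretrain_gan(train, desk_config(epochs = 0, seed = 0))

  # nearest-training-shape Chamfer statistic at 512-point resolution
  train512 <- lapply(train, function(cl) ifps(cl, 512))
  mean_nearest_cdt <- function(gen) {
    Y <- latent_prior_sample(gen$latent_dim, 32, seed = 1234)
    mean(vapply(seq_len(32), function(i) {
      s <- ifps(generate(gen, Y[i, ]), 512)
      min(vapply(train512, function(tr) cd_t(s, tr), numeric(1)))
    }, numeric(1)))
  }
  after <- mean_nearest_cdt(model$generator)
  before <- mean_nearest_cdt(init$generator)
  expect_lt(after, before)
})

test_that("models survive a save/load round trip", {
  model <- tiny_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(back$generator$params$W1, model$generator$params$W1, tolerance = 1e-12)
  expect_equal(back$discriminators[[2]]$params$A2,
    model$discriminators[[2]]$params$A2,
    tolerance = 1e-12
  )
  y <- latent_prior_sample(96, 1, seed = 2)[1, ]
  expect_equal(
    as.data.frame(generate(back$generator, y)),
    as.data.frame(generate(model$generator, y)),
    tolerance = 1e-12
  )
  expect_error(load_model(withr::local_tempfile(lines = "{}", fileext = ".json")), "model file")
})
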