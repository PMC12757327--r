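#' Training configuration for GAN pretraining
#'
#' `train_config()` carries the adversarial pretraining settings. The
#' defaults are the benchmark-scale settings (Adam with initial learning
#' rate 1e-4, batch size 64, 2000 epochs, one model per object class).
#' `desk_config()` is the CPU desk-scale preset used throughout the tests
#' and examples: 200 epochs, batch size 16 and a larger Adam step (2e-3),
#' sized so that a few hundred updates on a few dozen shapes produce a
#' usable class prior in minutes on one core.
#'
#' @param learning_rate Positive Adam step size.
#' @param batch_size Positive minibatch size (training needs at least this
#'   many clouds).
#' @param epochs Non-negative number of passes over the training set.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param class_tag Optional object-class label recorded in the model.
#' @param latent_dim,output_size,feature_width Architecture sizes: latent
#'   dimension of the generator, number of generated points, and width of the
#'   discriminators' pooled feature vector.
#' @param ... For `desk_config()`, overrides passed on to `train_config()`.
#' @return A `train_config` list.
#' @examples
#' train_config()
#' desk_config(seed = 0)
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L, epochs = 2000L,
                         seed = 0L, class_tag = NULL,
                         latent_dim = 96L, output_size = 2048L,
                         feature_width = 64L) {
  stopifnot(
    learning_rate > 0, batch_size >= 1L, epochs >= 0L,
    latent_dim >= 1L, output_size >= 1L, feature_width >= 1L
  )
  structure(
    list(
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      seed = as.integer(seed),
      class_tag = class_tag,
      latent_dim = as.integer(latent_dim),
      output_size = as.integer(output_size),
      feature_width = as.integer(feature_width)
    ),
    class = "train_config"
  )
}

#' @rdname train_config
#' @export
desk_config <- function(..., seed = 0L) {
  defaults <- list(
    learning_rate = 2e-3, batch_size = 16L, epochs = 200L, seed = seed
  )
  do.call(train_config, modifyList(defaults, list(...)))
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf(
    "# train config: lr %.2g, batch %d, epochs %d, seed %d, latent %d -> %d points\n",
    x$learning_rate, x$batch_size, x$epochs, x$seed, x$latent_dim, x$output_size
  ))
  invisible(x)
}

#' Sample latent codes from the generator prior
#'
#' Latent codes are drawn from a standard normal prior. Draws are row-major
#' under the seed, so the first row of `latent_prior_sample(d, n, seed)` is
#' identical for every `n` -- convenient for reproducing the candidate set
#' scored during inversion initialization.
#'
#' @param latent_dim Latent dimension `d`.
#' @param n Number of codes.
#' @param seed Integer seed.
#' @return An `n x latent_dim` matrix, one code per row.
#' @export
latent_prior_sample <- function(latent_dim, n, seed) {
  withr::with_seed(
    as.integer(seed),
    matrix(rnorm(n * latent_dim), n, latent_dim, byrow = TRUE)
  )
}

#' Generate a complete point cloud from a latent code
#'
#' Deterministic map from a latent code (and the generator parameters) to a
#' cloud of exactly `output_size` points with finite coordinates in (-1, 1).
#'
#' @param generator An `mrc_generator` (from [pretrain_gan()] or a model's
#'   `$generator`).
#' @param y Numeric latent code of length `latent_dim`.
#' @return A [point_cloud] of `generator$output_size` points.
#' @export
generate <- function(generator, y) {
  stopifnot(inherits(generator, "mrc_generator"))
  y <- as.numeric(y)
  if (length(y) != generator$latent_dim) {
    abort(sprintf(
      "latent code has length %d but the generator expects %d",
      length(y), generator$latent_dim
    ))
  }
  cache <- gen_forward(generator, matrix(y, 1L))
  point_cloud(gen_cloud(generator, cache), label = "generated")
}

#' Discriminator features and realness score
#'
#' Runs one level discriminator on a cloud and returns its pooled global
#' feature vector (the penultimate layer, used by the feature-matching loss)
#' together with the scalar realness score. The pooling is symmetric (max
#' over points), so the output is invariant to point order.
#'
#' @param discriminator An `mrc_discriminator`.
#' @param cloud A non-empty point cloud.
#' @return A list with `features` (length `feature_width`) and `score`
#'   (scalar).
#' @export
discriminate_features <- function(discriminator, cloud) {
  stopifnot(inherits(discriminator, "mrc_discriminator"))
  m <- as_xyz_matrix(cloud)
  if (nrow(m) < 1L) abort("discriminator input cloud is empty")
  cache <- disc_forward(discriminator, m, n = nrow(m), B = 1L)
  list(features = cache$g[1L, ], score = cache$scores[1L])
}

#' Pretrain the point-cloud GAN on complete shapes
#'
#' Adversarial pretraining of the compact generator against three
#' discriminators, one per pyramid resolution (2048 / 1024 / 512 points;
#' the coarser discriminators see farthest-point-sampled versions of both
#' real and generated clouds, so each is calibrated to its level). The
#' objective is the non-saturating GAN loss, optimized with Adam at the
#' configured learning rate. Training one model per object class gives the
#' inversion stage a clean class prior.
#'
#' @param complete_clouds List of complete, normalized point clouds (all of
#'   one class, each with at least 2048 points, coordinates in `[-1, 1]`).
#'   At least `batch_size` clouds are required.
#' @param config A [train_config()] (see [desk_config()] for the CPU-scale
#'   preset).
#' @return An `mrc_model`: list with `generator`, `discriminators` (list of
#'   3), `config` and a per-epoch `history` tibble (`epoch`, `d_loss`,
#'   `g_loss`). With `epochs = 0` the freshly initialized states are
#'   returned untouched.
#' @export
pretrain_gan <- function(complete_clouds, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  n_shapes <- length(complete_clouds)
  if (n_shapes < config$batch_size) {
    abort("need at least batch_size complete clouds to pretrain")
  }
  mats <- lapply(complete_clouds, as_xyz_matrix)
  for (m in mats) {
    if (nrow(m) < config$output_size) {
      abort(sprintf("every training cloud needs at least %d points", config$output_size))
    }
    if (max(abs(m)) > 1 + 1e-9) {
      abort("training clouds must be normalized into [-1, 1]; see normalize_cloud()")
    }
  }
  labels <- unique(unlist(lapply(complete_clouds, function(cl) attr(cl, "label") %||% NA_character_)))
  labels <- labels[!is.na(labels)]
  if (length(labels) > 1L) {
    abort("pretraining expects clouds of a single object class; got multiple labels")
  }
  class_tag <- config$class_tag %||% (if (length(labels)) labels else NULL)

  sizes <- c(config$output_size, 1024L, 512L)
  sizes <- pmin(sizes, config$output_size)

  withr::with_seed(config$seed, {
    gen <- new_generator(config$latent_dim, config$output_size)
    discs <- lapply(1:3, function(l) new_discriminator(l, config$feature_width))

    # real clouds at each pyramid level, precomputed once
    reals <- lapply(mats, function(m) {
      l1 <- if (nrow(m) == sizes[1]) m else m[fps_cpp(m, sizes[1], 1L), , drop = FALSE]
      l2 <- l1[fps_cpp(l1, sizes[2], 1L), , drop = FALSE]
      l3 <- l2[fps_cpp(l2, sizes[3], 1L), , drop = FALSE]
      list(l1, l2, l3)
    })

    opt_g <- adam_new(gen$params)
    opt_d <- lapply(discs, function(d) adam_new(d$params))
    history <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n_shapes)
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      d_losses <- g_losses <- numeric(0)
      for (batch in batches) {
        B <- length(batch)
        # -- fakes ----------------------------------------------------------
        Y <- matrix(rnorm(B * gen$latent_dim), B, gen$latent_dim)
        cache_g <- gen_forward(gen, Y)
        fake_pts <- lapply(seq_len(B), function(b) gen_cloud(gen, cache_g, b))
        fake_idx <- lapply(fake_pts, function(pm) {
          i2 <- fps_cpp(pm, sizes[2], 1L)
          i3 <- i2[fps_cpp(pm[i2, , drop = FALSE], sizes[3], 1L)]
          list(seq_len(sizes[1]), i2, i3)
        })

        # -- simultaneous gradients: both players differentiate the same
        # forward passes, then all updates are applied together -------------
        d_loss <- 0
        g_loss <- 0
        d_grads <- vector("list", 3L)
        dP <- matrix(0, B, 3L * gen$output_size)
        m_out <- gen$output_size
        for (l in 1:3) {
          level_idx <- vapply(fake_idx, function(fi) fi[[l]], integer(sizes[l]))
          real_stack <- do.call(rbind, lapply(batch, function(i) reals[[i]][[l]]))
          fake_stack <- do.call(rbind, lapply(seq_len(B), function(b) {
            fake_pts[[b]][level_idx[, b], , drop = FALSE]
          }))
          fr <- disc_forward(discs[[l]], real_stack, sizes[l], B)
          ff <- disc_forward(discs[[l]], fake_stack, sizes[l], B)
          d_loss <- d_loss + mean(softplus(-fr$scores)) + mean(softplus(ff$scores))
          g_loss <- g_loss + mean(softplus(-ff$scores))

          br <- disc_backward(discs[[l]], fr, dscore = -sigmoid(-fr$scores) / B)
          bf <- disc_backward(discs[[l]], ff, dscore = sigmoid(ff$scores) / B)
          d_grads[[l]] <- Map(`+`, br$grads, bf$grads)

          bk <- disc_backward(discs[[l]], ff,
            dscore = -sigmoid(-ff$scores) / B, need_dP = TRUE
          )
          # scatter point gradients back into each sample's full cloud
          b_of <- (bk$dP_rows - 1L) %/% sizes[l] + 1L
          i_lvl <- bk$dP_rows - (b_of - 1L) * sizes[l]
          i_full <- level_idx[cbind(i_lvl, b_of)]
          for (co in 1:3) {
            at <- cbind(b_of, i_full + (co - 1L) * m_out)
            dP[at] <- dP[at] + bk$dP_vals[, co]
          }
        }
        for (l in 1:3) {
          upd <- adam_step(opt_d[[l]], discs[[l]]$params, d_grads[[l]], config$learning_rate)
          opt_d[[l]] <- upd$state
          discs[[l]]$params <- upd$params
        }
        bg <- gen_backward(gen, cache_g, dP)
        upd <- adam_step(opt_g, gen$params, bg$grads, config$learning_rate)
        opt_g <- upd$state
        gen$params <- upd$params

        d_losses <- c(d_losses, d_loss)
        g_losses <- c(g_losses, g_loss)
      }
      history[[epoch]] <- tibble(
        epoch = epoch, d_loss = mean(d_losses), g_loss = mean(g_losses)
      )
    }

    structure(
      list(
        generator = gen,
        discriminators = discs,
        config = config,
        class_tag = class_tag,
        history = if (config$epochs > 0) dplyr::bind_rows(history) else
          tibble(epoch = integer(), d_loss = double(), g_loss = double())
      ),
      class = "mrc_model"
    )
  })
}

#' @export
print.mrc_model <- function(x, ...) {
  cat(sprintf(
    "# completion model%s: latent %d -> %d points, feature width %d, %d epochs\n",
    if (!is.null(x$class_tag)) paste0(" ('", x$class_tag, "')") else "",
    x$generator$latent_dim, x$generator$output_size,
    x$discriminators[[1]]$feature_width, nrow(x$history)
  ))
  invisible(x)
}

#' @export
tidy.mrc_model <- function(x, ...) x$history

#' @export
glance.mrc_model <- function(x, ...) {
  tibble(
    latent_dim = x$generator$latent_dim,
    output_size = x$generator$output_size,
    feature_width = x$discriminators[[1]]$feature_width,
    epochs = nrow(x$history),
    final_d_loss = if (nrow(x$history)) x$history$d_loss[nrow(x$history)] else NA_real_,
    final_g_loss = if (nrow(x$history)) x$history$g_loss[nrow(x$history)] else NA_real_
  )
}

#' Save and load completion models
#'
#' Models are serialized as a single JSON archive: a manifest (latent
#' dimension, output size, feature widths, class tag, seed) plus all named
#' parameter arrays. The format is plain text and versioned by the package.
#'
#' @param model An `mrc_model`.
#' @param path File path (conventionally `.json`).
#' @return `save_model()` invisibly returns `path`; `load_model()` returns
#'   the `mrc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mrc_model"))
  payload <- list(
    format = "mrcnet-model",
    version = 1L,
    manifest = list(
      latent_dim = model$generator$latent_dim,
      output_size = model$generator$output_size,
      hidden = model$generator$hidden,
      feature_width = model$discriminators[[1]]$feature_width,
      disc_hidden = model$discriminators[[1]]$hidden,
      class_tag = model$class_tag,
      seed = model$config$seed
    ),
    generator = model$generator$params,
    discriminators = setNames(
      lapply(model$discriminators, function(d) d$params),
      paste0("d", 1:3)
    ),
    history = model$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "mrcnet-model")) {
    abort(paste0("not an mrcnet model file: ", path))
  }
  man <- raw$manifest
  gen <- new_generator(man$latent_dim, man$output_size, man$hidden)
  gen$params <- list(
    W1 = as.matrix(raw$generator$W1), b1 = as.numeric(raw$generator$b1),
    W2 = as.matrix(raw$generator$W2), b2 = as.numeric(raw$generator$b2),
    W3 = as.matrix(raw$generator$W3), b3 = as.numeric(raw$generator$b3)
  )
  discs <- lapply(1:3, function(l) {
    d <- new_discriminator(l, man$feature_width, man$disc_hidden)
    dp <- raw$discriminators[[paste0("d", l)]]
    d$params <- list(
      A1 = as.matrix(dp$A1), c1 = as.numeric(dp$c1),
      A2 = as.matrix(dp$A2), c2 = as.numeric(dp$c2),
      v = as.numeric(dp$v), b0 = as.numeric(dp$b0)
    )
    d
  })
  structure(
    list(
      generator = gen,
      discriminators = discs,
      config = train_config(seed = man$seed %||% 0L,
        latent_dim = man$latent_dim, output_size = man$output_size,
        feature_width = man$feature_width
      ),
      class_tag = man$class_tag,
      history = tibble::as_tibble(raw$history)
    ),
    class = "mrc_model"
  )
}
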