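#' Inversion configuration
#'
#' Settings for the completion engine: how many prior samples to score for
#' latent initialization, how many joint gradient iterations to run, the
#' Adam step sizes for the latent code (`latent_step`) and the generator
#' parameters (`delta_step`), the loss weights, and the neighbourhood size
#' `k` of the degradation mask.
#'
#' @param n_init_samples Number of latent candidates scored at
#'   initialization (default 256).
#' @param n_iterations Number of optimization iterations (default 200).
#' @param latent_step,delta_step Positive Adam step sizes for the latent
#'   code and the generator parameters (defaults 0.01 and 1e-4: the latent
#'   does most of the moving, the generator adapts gently around it).
#' @param seed Integer seed for the initialization draws.
#' @param weights A [loss_weights()] object.
#' @param k Mask neighbourhood size (default 50).
#' @param schedule `"joint"` updates the latent code and the generator
#'   parameters every iteration; `"alternating"` updates them in turn.
#' @return An `inversion_config` list.
#' @export
inversion_config <- function(n_init_samples = 256L, n_iterations = 200L,
                             latent_step = 0.01, delta_step = 1e-4,
                             seed = 0L, weights = loss_weights(), k = 50L,
                             schedule = c("joint", "alternating")) {
  stopifnot(
    n_init_samples >= 1L, n_iterations >= 0L,
    latent_step > 0, delta_step > 0, k >= 1L,
    inherits(weights, "loss_weights")
  )
  structure(
    list(
      n_init_samples = as.integer(n_init_samples),
      n_iterations = as.integer(n_iterations),
      latent_step = latent_step,
      delta_step = delta_step,
      seed = as.integer(seed),
      weights = weights,
      k = as.integer(k),
      schedule = match.arg(schedule)
    ),
    class = "inversion_config"
  )
}

#' Initialize the latent code by random search
#'
#' Draws `n_init_samples` latent codes from the generator's standard-normal
#' prior (see [latent_prior_sample()]; reproducible from `config$seed`),
#' scores each candidate by the degraded objective -- the Chamfer distance
#' `cd_t` between the mask of its generated shape toward the partial input
#' and the partial input itself -- and returns the arg-min.
#'
#' @param generator An `mrc_generator`.
#' @param partial The partial input cloud.
#' @param config An [inversion_config()].
#' @return The best latent code (numeric vector) with attributes
#'   `objective` (its score) and `candidate_objectives` (all scores, in
#'   draw order).
#' @export
init_latent <- function(generator, partial, config = inversion_config()) {
  stopifnot(inherits(generator, "mrc_generator"))
  pm <- as_xyz_matrix(partial)
  cand <- latent_prior_sample(generator$latent_dim, config$n_init_samples, config$seed)
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    cache <- gen_forward(generator, cand[i, , drop = FALSE])
    gm <- gen_cloud(generator, cache)
    idx <- sort(unique(as.vector(knn_cpp(pm, gm, config$k))))
    cd_t(gm[idx, , drop = FALSE], pm)
  }, numeric(1))
  best <- which.min(scores)
  structure(cand[best, ], objective = scores[best], candidate_objectives = scores)
}

# Objective value and gradients at the current (y, delta).
# scale_c / scale_d normalize the two loss components (each is divided by its
# value at initialization, so h_c and h_d weight dimensionless quantities of
# comparable size -- the feature term's raw scale depends on the arbitrary
# magnitude of the learned discriminator features).
# Returns tc, td (raw), total (normalized mix), generator-parameter grads and
# the latent grad.
inversion_eval <- function(gen, y, ppyr, part_feats, discs, cfg,
                           scale_c = 1, scale_d = 1) {
  w <- cfg$weights
  m <- gen$output_size
  cache <- gen_forward(gen, matrix(y, 1L))
  Xa <- gen_cloud(gen, cache)

  sizes <- ppyr$sizes
  i2 <- fps_cpp(Xa, min(1024L, m), 1L)
  Xa2 <- Xa[i2, , drop = FALSE]
  i3l <- fps_cpp(Xa2, min(512L, m), 1L)
  Xa3 <- Xa2[i3l, , drop = FALSE]
  gen_levels <- list(Xa, Xa2, Xa3)
  maps <- list(seq_len(m), i2, i2[i3l]) # level row -> full-cloud row

  stage_w <- c(1, w$alpha, w$beta)
  gradXa <- matrix(0, m, 3L)
  tc <- 0
  td <- 0
  for (l in 1:3) {
    part_l <- as_xyz_matrix(pyramid_levels(ppyr)[[l]])
    k_l <- min(cfg$k, nrow(gen_levels[[l]]))
    mask_idx <- sort(unique(as.vector(knn_cpp(part_l, gen_levels[[l]], k_l))))
    mask_pts <- gen_levels[[l]][mask_idx, , drop = FALSE]
    full_rows <- maps[[l]][mask_idx]

    cg <- cdt_value_grad(mask_pts, part_l)
    tc <- tc + stage_w[l] * cg$value
    gradXa[full_rows, ] <- gradXa[full_rows, ] +
      (w$h_c * stage_w[l] / scale_c) * cg$grad

    dcache <- disc_forward(discs[[l]], mask_pts, n = nrow(mask_pts), B = 1L)
    gdiff <- dcache$g[1L, ] - part_feats[[l]]
    td <- td + sum(abs(gdiff))
    if (w$h_d > 0) {
      bk <- disc_backward(discs[[l]], dcache,
        dg = matrix(sign(gdiff), 1L), need_dP = TRUE
      )
      rows <- full_rows[bk$dP_rows]
      gradXa[rows, ] <- gradXa[rows, ] + (w$h_d / scale_d) * bk$dP_vals
    }
  }

  bg <- gen_backward(gen, cache, matrix(as.vector(gradXa), 1L))
  list(
    tc = tc, td = td,
    total = total_loss(tc / scale_c, td / scale_d, w),
    grads_delta = bg$grads, grad_y = as.vector(bg$dY), Xa = Xa
  )
}

#' Complete a partial cloud by GAN inversion
#'
#' The completion engine. Starting from the best of `n_init_samples`
#' prior draws ([init_latent()]), the latent code `y` and the generator
#' parameters `delta` are jointly refined by adaptive (Adam) gradient
#' descent on the total objective: at every iteration the current generated
#' shape is downsampled into its resolution pyramid, each level is degraded
#' toward the matching level of the partial input by the K-neighbourhood
#' mask, and the multi-stage Chamfer reconstruction loss plus the
#' multi-scale discriminator feature-matching loss are evaluated and
#' backpropagated. Inside the optimizer each component is normalized by its
#' value at the initial iterate, so the `h_c`/`h_d` mixing weights act on
#' dimensionless quantities of comparable size (the raw feature-matching
#' scale depends on the arbitrary magnitude of the learned discriminator
#' features). The discriminators stay frozen; the generator adaptation
#' is per instance (the input model is never modified, so completing one
#' scan cannot leak into the next). The iterate with the lowest recorded
#' objective is returned, since the adversarial term can oscillate.
#'
#' @param model An `mrc_model` from [pretrain_gan()] (or a path for
#'   [complete_file()]).
#' @param partial The partial input cloud, normalized into `(-1, 1)`, with
#'   at least 512 points.
#' @param config An [inversion_config()].
#' @param truth Optional ground-truth cloud; when given, the result's
#'   metrics include `cd_t`/`cd_p`/`f_score` against it.
#' @return A `completion_result`: list with `completed` (a 2048-point
#'   [point_cloud]), `best_latent`, `adapted_delta`, `objective_trace`
#'   (tibble: `iteration`, raw `reconstruction` and `feature_matching`
#'   values, and the normalized `total` that is optimized), `metrics` (see
#'   [evaluate_completion()]) and `config`.
#' @export
invert <- function(model, partial, config = inversion_config(), truth = NULL) {
  stopifnot(inherits(model, "mrc_model"))
  partial <- as_point_cloud(partial)
  pm <- as_xyz_matrix(partial)
  if (nrow(pm) < 512L) {
    abort("partial input needs at least 512 points for the resolution pyramid")
  }
  if (max(abs(pm)) > 1 + 1e-9) {
    abort("partial input must be normalized into (-1, 1); see center_cloud()/normalize_cloud()")
  }

  gen <- model$generator
  discs <- model$discriminators
  ppyr <- partial_pyramid(partial)
  part_feats <- lapply(1:3, function(l) {
    discriminate_features(discs[[l]], pyramid_levels(ppyr)[[l]])$features
  })

  y <- as.numeric(init_latent(gen, partial, config))
  opt_y <- adam_new(list(y = y))
  opt_d <- adam_new(gen$params)

  # calibrate the per-component normalization at the initial iterate
  ev0 <- inversion_eval(gen, y, ppyr, part_feats, discs, config)
  scale_c <- max(ev0$tc, 1e-12)
  scale_d <- max(ev0$td, 1e-12)

  n_it <- config$n_iterations
  trace <- matrix(NA_real_, n_it + 1L, 3L)
  best <- list(total = Inf, y = y, params = gen$params)

  for (it in 0:n_it) {
    ev <- inversion_eval(gen, y, ppyr, part_feats, discs, config,
      scale_c = scale_c, scale_d = scale_d
    )
    if (!is.finite(ev$total)) {
      abort(
        "inversion objective diverged (non-finite loss)",
        class = "mrcnet_divergence",
        trace = trace[seq_len(it), , drop = FALSE]
      )
    }
    trace[it + 1L, ] <- c(ev$tc, ev$td, ev$total)
    if (ev$total < best$total) {
      best <- list(total = ev$total, y = y, params = gen$params)
    }
    if (it == n_it) break

    do_y <- config$schedule == "joint" || it %% 2L == 0L
    do_d <- config$schedule == "joint" || it %% 2L == 1L
    if (do_y) {
      upd <- adam_step(opt_y, list(y = y), list(y = ev$grad_y), config$latent_step)
      opt_y <- upd$state
      y <- upd$params$y
    }
    if (do_d) {
      upd <- adam_step(opt_d, gen$params, ev$grads_delta, config$delta_step)
      opt_d <- upd$state
      gen$params <- upd$params
    }
  }

  gen$params <- best$params
  completed <- generate(gen, best$y)
  attr(completed, "label") <- model$class_tag %||% "completed"

  structure(
    list(
      completed = completed,
      best_latent = best$y,
      adapted_delta = best$params,
      objective_trace = tibble(
        iteration = 0:n_it,
        reconstruction = trace[, 1],
        feature_matching = trace[, 2],
        total = trace[, 3]
      ),
      metrics = evaluate_completion(completed, truth = truth, partial = partial),
      config = config
    ),
    class = "completion_result"
  )
}

#' @export
print.completion_result <- function(x, ...) {
  tr <- x$objective_trace
  cat(sprintf(
    "# completion: %d points; objective %.4g (init) -> %.4g (best of %d iterations)\n",
    n_points(x$completed), tr$total[1], min(tr$total), nrow(tr) - 1L
  ))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.completion_result <- function(x, ...) x$objective_trace

#' @export
glance.completion_result <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble(
      objective_init = x$objective_trace$total[1],
      objective_best = min(x$objective_trace$total),
      iterations = nrow(x$objective_trace) - 1L
    )
  )
}

#' @export
autoplot.completion_result <- function(object, ...) {
  tr <- trace_long(object$objective_trace)
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$value, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "iteration", y = "loss", colour = NULL,
      title = "inversion objective trace"
    ) +
    ggplot2::theme_minimal()
}

trace_long <- function(trace) {
  dplyr::bind_rows(
    tibble(iteration = trace$iteration, term = "reconstruction", value = trace$reconstruction),
    tibble(iteration = trace$iteration, term = "feature matching", value = trace$feature_matching),
    tibble(iteration = trace$iteration, term = "total", value = trace$total)
  )
}

#' End-to-end completion of files on disk
#'
#' Loads a model and one partial scan (or a directory of scans, processed
#' sequentially, one result per input), preprocesses each scan (center,
#' normalize), runs [invert()], and optionally writes the completed cloud
#' and a JSON report (objective trace and metric panel) per input.
#'
#' @param model An `mrc_model` or path to a file written by [save_model()].
#' @param partial_path Path to an XYZ/PLY file, or a directory of them.
#' @param out Optional output path for the completed cloud (for a directory
#'   input, a directory; files are named `<input>_completed.xyz`).
#' @param report Optional path for the JSON report (directory input: one
#'   `<input>_report.json` per scan in `report`).
#' @param config An [inversion_config()].
#' @param truth_path Optional path to the ground-truth cloud (single-file
#'   mode only), enabling ground-truth metrics.
#' @return A `completion_result`, or a list of them for a directory input.
#' @export
complete_file <- function(model, partial_path, out = NULL, report = NULL,
                          config = inversion_config(), truth_path = NULL) {
  if (is.character(model)) model <- load_model(model)
  if (dir.exists(partial_path)) {
    files <- list.files(partial_path, pattern = "\\.(xyz|ply)$", full.names = TRUE)
    if (!length(files)) abort(paste0("no .xyz/.ply files in ", partial_path))
    res <- lapply(files, function(f) {
      stem <- sub("\\.(xyz|ply)$", "", basename(f))
      complete_file(model, f,
        out = if (!is.null(out)) file.path(out, paste0(stem, "_completed.xyz")),
        report = if (!is.null(report)) file.path(report, paste0(stem, "_report.json")),
        config = config
      )
    })
    names(res) <- basename(files)
    return(res)
  }

  partial <- read_point_cloud(partial_path)
  partial <- normalize_cloud(center_cloud(partial))
  truth <- if (!is.null(truth_path)) {
    normalize_cloud(center_cloud(read_point_cloud(truth_path)))
  }
  result <- invert(model, partial, config = config, truth = truth)
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    write_point_cloud(result$completed, out)
  }
  if (!is.null(report)) {
    dir.create(dirname(report), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        input = partial_path,
        n_points = n_points(result$completed),
        metrics = result$metrics,
        objective_trace = result$objective_trace
      ),
      report,
      digits = NA, auto_unbox = TRUE, dataframe = "columns"
    )
  }
  result
}
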