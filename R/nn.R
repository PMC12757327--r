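# Internal neural-network machinery: a compact set-decoder generator
# (latent -> MLP -> m x 3, tanh-bounded) and PointNet-style discriminators
# (shared per-point MLP + max pooling -> global feature -> score), with
# hand-written backpropagation and an Adam optimizer. Everything is plain
# matrix algebra so training is reproducible from a single RNG seed.

relu <- function(x) (x > 0) * x

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(nin, nout, scale = 1) {
  matrix(rnorm(nin * nout, sd = scale * sqrt(2 / nin)), nin, nout)
}

# --- generator --------------------------------------------------------------

new_generator <- function(latent_dim = 96L, output_size = 2048L,
                          hidden = c(128L, 128L)) {
  params <- list(
    W1 = he_init(latent_dim, hidden[1]),
    b1 = numeric(hidden[1]),
    W2 = he_init(hidden[1], hidden[2]),
    b2 = numeric(hidden[2]),
    # smaller scale on the output layer: early samples start as a compact
    # blob well inside (-1,1) instead of saturating tanh
    W3 = he_init(hidden[2], 3L * output_size, scale = 0.3),
    b3 = numeric(3L * output_size)
  )
  structure(
    list(
      latent_dim = as.integer(latent_dim),
      output_size = as.integer(output_size),
      hidden = as.integer(hidden),
      params = params
    ),
    class = "mrc_generator"
  )
}

# Y: B x d latent matrix. Returns activations for backprop; P is B x 3m,
# row b reshaped column-major to an m x 3 cloud.
gen_forward <- function(gen, Y) {
  p <- gen$params
  H1 <- relu(sweep(Y %*% p$W1, 2L, p$b1, "+"))
  H2 <- relu(sweep(H1 %*% p$W2, 2L, p$b2, "+"))
  Z <- sweep(H2 %*% p$W3, 2L, p$b3, "+")
  P <- tanh(Z)
  list(Y = Y, H1 = H1, H2 = H2, P = P)
}

gen_cloud <- function(gen, cache, b = 1L) {
  matrix(cache$P[b, ], gen$output_size, 3L)
}

# dP: B x 3m gradient of the loss in the generator's output coordinates.
gen_backward <- function(gen, cache, dP) {
  p <- gen$params
  dZ <- dP * (1 - cache$P^2)
  gW3 <- crossprod(cache$H2, dZ)
  gb3 <- colSums(dZ)
  dH2 <- tcrossprod(dZ, p$W3) * (cache$H2 > 0)
  gW2 <- crossprod(cache$H1, dH2)
  gb2 <- colSums(dH2)
  dH1 <- tcrossprod(dH2, p$W2) * (cache$H1 > 0)
  gW1 <- crossprod(cache$Y, dH1)
  gb1 <- colSums(dH1)
  dY <- tcrossprod(dH1, p$W1)
  list(
    grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3),
    dY = dY
  )
}

# --- discriminator ----------------------------------------------------------

new_discriminator <- function(level, feature_width = 64L, hidden = 32L) {
  params <- list(
    A1 = he_init(3L, hidden),
    c1 = numeric(hidden),
    A2 = he_init(hidden, feature_width),
    c2 = numeric(feature_width),
    v = rnorm(feature_width, sd = sqrt(1 / feature_width)),
    b0 = 0
  )
  structure(
    list(
      level = as.integer(level),
      feature_width = as.integer(feature_width),
      hidden = as.integer(hidden),
      params = params
    ),
    class = "mrc_discriminator"
  )
}

# Batched forward over B clouds of identical size n, stacked row-wise into
# Pstack ((B*n) x 3). Max pooling per cloud yields the global feature (the
# penultimate layer, used for feature matching); a linear head scores it.
# The heavy lifting (matmul + relu + pooling) happens in C++.
disc_forward <- function(disc, Pstack, n, B) {
  p <- disc$params
  fw <- disc_forward_cpp(Pstack, p$A1, p$c1, p$A2, p$c2, p$v, p$b0,
    as.integer(n), as.integer(B)
  )
  list(
    Pstack = Pstack, U1 = fw$U1, g = fw$g, amax = fw$amax,
    scores = as.vector(fw$scores), n = n, B = B
  )
}

# Backward pass. dscore: length-B gradient in the scores; dg: optional B x f
# gradient in the pooled features (used for feature matching). Returns
# parameter gradients and, when `need_dP`, the (sparse) gradient in the input
# points as global row indices plus a 3-column value matrix.
disc_backward <- function(disc, cache, dscore = NULL, dg = NULL, need_dP = FALSE) {
  p <- disc$params
  f <- disc$feature_width
  B <- cache$B
  dg_tot <- if (is.null(dg)) matrix(0, B, f) else dg
  gv <- numeric(f)
  gb0 <- 0
  if (!is.null(dscore)) {
    dg_tot <- dg_tot + outer(dscore, p$v)
    gv <- as.vector(crossprod(cache$g, dscore))
    gb0 <- sum(dscore)
  }
  # relu subgradient at the pooled max: zero where the pooled feature is zero
  dg_eff <- dg_tot * (cache$g > 0)

  gA2 <- matrix(0, disc$hidden, f)
  gc2 <- colSums(dg_eff)
  # gradient reaches U1 only at the B*f argmax rows; keep it compact
  rows_all <- sort(unique(as.vector(cache$amax)))
  dU1c <- matrix(0, length(rows_all), disc$hidden)
  for (j in seq_len(f)) {
    rows_j <- cache$amax[, j]
    w <- dg_eff[, j]
    if (all(w == 0)) next
    U1j <- cache$U1[rows_j, , drop = FALSE]
    gA2[, j] <- colSums(U1j * w)
    dU1c[match(rows_j, rows_all), ] <-
      dU1c[match(rows_j, rows_all), , drop = FALSE] + outer(w, p$A2[, j])
  }
  dU1c <- dU1c * (cache$U1[rows_all, , drop = FALSE] > 0)
  gA1 <- crossprod(cache$Pstack[rows_all, , drop = FALSE], dU1c)
  gc1 <- colSums(dU1c)
  out <- list(grads = list(A1 = gA1, c1 = gc1, A2 = gA2, c2 = gc2, v = gv, b0 = gb0))
  if (need_dP) {
    out$dP_rows <- rows_all
    out$dP_vals <- tcrossprod(dU1c, p$A1)
  }
  out
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}
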