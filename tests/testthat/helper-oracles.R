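# Plain-R brute-force oracles, kept deliberately independent of the package
# internals: nested loops and full distance matrices only.

dist2_matrix <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

fps_oracle <- function(pts, m, start = 1L) {
  n <- nrow(pts)
  sel <- integer(m)
  sel[1] <- start
  mind <- rep(Inf, n)
  for (s in seq_len(m - 1L)) {
    d <- rowSums((pts - matrix(pts[sel[s], ], n, 3, byrow = TRUE))^2)
    mind <- pmin(mind, d)
    mind[sel[seq_len(s)]] <- -1
    sel[s + 1L] <- which.max(mind) # which.max takes the first (lowest index) tie
  }
  sel
}

knn_oracle <- function(q, r, k) {
  rows <- lapply(seq_len(nrow(q)), function(i) {
    d <- rowSums((r - matrix(q[i, ], nrow(r), 3, byrow = TRUE))^2)
    order(d, seq_along(d))[seq_len(k)]
  })
  matrix(unlist(rows), nrow = nrow(q), ncol = k, byrow = TRUE)
}

mk_mask_oracle <- function(gen, part, k) {
  sort(unique(as.vector(knn_oracle(part, gen, k))))
}

cd_t_oracle <- function(x, y) {
  d2 <- dist2_matrix(x, y)
  mean(apply(d2, 1, min)) + mean(apply(d2, 2, min))
}

cd_p_oracle <- function(x, y) {
  d2 <- pmax(dist2_matrix(x, y), 0)
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

ucd_oracle <- function(p, f) {
  mean(apply(dist2_matrix(p, f), 1, min))
}

uhd_oracle <- function(p, f) {
  sqrt(max(apply(pmax(dist2_matrix(p, f), 0), 1, min)))
}

f_score_oracle <- function(pred, truth, tau) {
  d2 <- dist2_matrix(pred, truth)
  prec <- 100 * mean(apply(d2, 1, min) <= tau^2)
  rec <- 100 * mean(apply(d2, 2, min) <= tau^2)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

rand_cloud <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(3 * n, -1, 1), n, 3))
}
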