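# Independent brute-force oracles. These implement the same mathematical
# definitions as the package primitives but by direct enumeration, never by
# the package's algorithms (separable distance transforms, pruned sphere
# painting, FFT filtering).

# Brute-force squared Euclidean distance to the nearest background voxel.
oracle_edt <- function(phase) {
  d <- dim(phase)
  bg <- which(!phase, arr.ind = TRUE)
  ph_all <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  best <- rep(Inf, nrow(ph_all))
  for (i in seq_len(nrow(bg))) {
    d2 <- (ph_all[, 1] - bg[i, 1])^2 + (ph_all[, 2] - bg[i, 2])^2 +
      (ph_all[, 3] - bg[i, 3])^2
    best <- pmin(best, d2)
  }
  array(best, d)
}

# Brute-force local thickness: largest inscribed sphere containing each phase
# voxel, with centres enumerated over the half-voxel grid and radii measured
# to the phase boundary (distance to nearest background voxel centre minus
# half a voxel).
oracle_local_thickness <- function(phase) {
  d <- dim(phase)
  bg <- which(!phase, arr.ind = TRUE)
  ph <- which(phase, arr.ind = TRUE)
  ctr <- as.matrix(expand.grid(x = seq(1, d[1], by = 0.5),
                               y = seq(1, d[2], by = 0.5),
                               z = seq(1, d[3], by = 0.5)))
  best <- rep(Inf, nrow(ctr))
  for (i in seq_len(nrow(bg))) {
    d2 <- (ctr[, 1] - bg[i, 1])^2 + (ctr[, 2] - bg[i, 2])^2 +
      (ctr[, 3] - bg[i, 3])^2
    best <- pmin(best, d2)
  }
  r <- sqrt(best) - 0.5
  keep <- r > 0
  cs <- ctr[keep, , drop = FALSE]
  rs <- r[keep]
  lt <- numeric(nrow(ph))
  for (k in order(rs, decreasing = TRUE)) {
    d2 <- (ph[, 1] - cs[k, 1])^2 + (ph[, 2] - cs[k, 2])^2 +
      (ph[, 3] - cs[k, 3])^2
    cover <- d2 <= rs[k]^2 + 1e-9
    lt[cover] <- pmax(lt[cover], 2 * rs[k])
  }
  out <- array(0, d)
  out[phase] <- lt
  out
}

# The Laplace-Hamming frequency response, written out directly (scalar loops)
# from its definition: H(f) = [(1-w) + w * sum_i 4 sin^2(pi f_i)] * W(rho),
# rho = |f/0.5| / sqrt(3), W a Hamming window vanishing at the cutoff.
oracle_lh_response <- function(d, cutoff, weight) {
  H <- array(0, d)
  fr <- function(n) { k <- 0:(n - 1); ifelse(k <= n / 2, k, k - n) / n }
  f1 <- fr(d[1]); f2 <- fr(d[2]); f3 <- fr(d[3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    lap <- 4 * (sin(pi * f1[i])^2 + sin(pi * f2[j])^2 + sin(pi * f3[k])^2)
    rho <- sqrt((f1[i] / 0.5)^2 + (f2[j] / 0.5)^2 + (f3[k] / 0.5)^2) / sqrt(3)
    W <- if (rho <= cutoff) 0.54 + 0.46 * cos(pi * rho / cutoff) else 0
    H[i, j, k] <- ((1 - weight) + weight * lap) * W
  }
  H
}

# Direct circular convolution of x with kernel k (same dims), by explicit
# shifting: y[p] = sum_q k[q] x[p - q].
oracle_circular_convolution <- function(x, k) {
  d <- dim(x)
  y <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    if (abs(k[i, j, l]) < 1e-14) next
    xi <- ((seq_len(d[1]) - (i - 1) - 1) %% d[1]) + 1
    yi <- ((seq_len(d[2]) - (j - 1) - 1) %% d[2]) + 1
    zi <- ((seq_len(d[3]) - (l - 1) - 1) %% d[3]) + 1
    y <- y + k[i, j, l] * x[xi, yi, zi]
  }
  y
}
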