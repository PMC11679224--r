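# shared fixtures and small oracles, built in code at test time

tiny_atlas <- function(V = 200, R = 12, seed = 1) make_rsn_atlas(V, R, seed)

tiny_cohort <- function(n_pos = 6, n_neg = 4, T = 40, V = 200,
                        n_sources = 4, effect_size = 1, snr = 10, seed = 7,
                        atlas = tiny_atlas(V, max(n_sources, 12), seed)) {
  make_cohort(n_pos, n_neg, T, V, n_sources, effect_size, atlas,
              snr = snr, seed = seed)
}

# greedy absolute-correlation matching of estimated to true source rows;
# returns the matched |correlation| per true component
match_components <- function(est, truth) {
  C <- abs(stats::cor(t(est), t(truth)))
  n <- ncol(C)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- arrayInd(which.max(C), dim(C))
    out[idx[2]] <- C[idx[1], idx[2]]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  out
}

# straight-line per-element transliteration of the FGRU cell equations,
# independent of the package's vectorised implementation
fgru_cell_reference <- function(W_z, W_r, W_h, b_z, b_r, b_h, h_prev, x_t) {
  d <- length(x_t)
  xf <- numeric(d)
  for (j in seq_len(d)) {
    acc <- 0
    for (k in seq_len(d))
      acc <- acc + x_t[k] * cos(2 * pi * (j - 1) * (k - 1) / d)
    xf[j] <- acc
  }
  H <- length(h_prev)
  hx <- c(h_prev, xf)
  z <- r <- hc <- hnew <- numeric(H)
  for (i in seq_len(H)) {
    sz <- b_z[i]; sr <- b_r[i]
    for (k in seq_along(hx)) {
      sz <- sz + W_z[i, k] * hx[k]
      sr <- sr + W_r[i, k] * hx[k]
    }
    z[i] <- 1 / (1 + exp(-sz))
    r[i] <- 1 / (1 + exp(-sr))
  }
  hx2 <- c(r * h_prev, xf)
  for (i in seq_len(H)) {
    sh <- b_h[i]
    for (k in seq_along(hx2)) sh <- sh + W_h[i, k] * hx2[k]
    hc[i] <- tanh(sh)
    hnew[i] <- (1 - z[i]) * h_prev[i] + z[i] * hc[i]
  }
  hnew
}

# O(n^2) direct DFT, real part
dft_real_reference <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(n))
      s <- s + x[k] * cos(2 * pi * (j - 1) * (k - 1) / n)
    out[j] <- s
  }
  out
}
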