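test_that("fft_real handles constants, zeros and matches the direct DFT", {
  expect_equal(fft_real(rep(3, 8)), c(24, rep(0, 7)), tolerance = 1e-12)
  expect_equal(fft_real(rep(0, 5)), rep(0, 5))
  expect_error(fft_real(numeric(0)), "non-empty")
  set.seed(12)
  for (i in 1:50) {
    n <- sample(2:64, 1)
    x <- rnorm(n)
    expect_equal(fft_real(x), dft_real_reference(x), tolerance = 1e-8)
  }
  # even-symmetric input has a purely real DFT
  half <- rnorm(7)
  x <- c(rnorm(1), half, rev(half))
  expect_lt(max(abs(Im(stats::fft(x)))), 1e-10)
})

test_that("the FGRU cell matches hand-evaluated special cases", {
  H <- 3; d <- 4
  zero <- fgru_params(matrix(0, H, H + d), matrix(0, H, H + d),
                      matrix(0, H, H + d))
  v <- c(0.4, -0.2, 1)
  # zero weights: z = r = 1/2, candidate 0, new state v/2
  expect_equal(fgru_cell_step(zero, v, rep(0, d)), 0.5 * v)
  # huge update-gate bias forces z ~ 1 so the state equals the candidate
  forced <- fgru_params(matrix(0, H, H + d), matrix(0, H, H + d),
                        matrix(0.3, H, H + d), b_z = rep(50, H))
  x <- rnorm(d)
  xf <- fft_real(x)
  cand <- tanh(drop(matrix(0.3, H, H + d) %*% c(0.5 * v, xf)))
  expect_equal(fgru_cell_step(forced, v, x), cand, tolerance = 1e-12)
  # scalar case with unit weights and zero input
  ones <- fgru_params(matrix(1, 1, 2), matrix(1, 1, 2), matrix(1, 1, 2))
  expect_equal(fgru_cell_step(ones, 0, 0), 0)
})

test_that("the FGRU cell equals a loop-level transliteration", {
  set.seed(13)
  worst <- 0
  for (i in 1:100) {
    H <- sample(1:4, 1); d <- sample(1:6, 1)
    W_z <- matrix(rnorm(H * (H + d)), H); W_r <- matrix(rnorm(H * (H + d)), H)
    W_h <- matrix(rnorm(H * (H + d)), H)
    b_z <- rnorm(H); b_r <- rnorm(H); b_h <- rnorm(H)
    h <- rnorm(H); x <- rnorm(d)
    got <- fgru_cell_step(fgru_params(W_z, W_r, W_h, b_z, b_r, b_h), h, x)
    ref <- fgru_cell_reference(W_z, W_r, W_h, b_z, b_r, b_h, h, x)
    worst <- max(worst, max(abs(got - ref)))
  }
  expect_lt(worst, 1e-10)
})

test_that("an FGRU layer composes cell steps and stays bounded", {
  set.seed(14)
  H <- 3; d <- 5; Tn <- 7
  p <- fgru_params(matrix(rnorm(H * (H + d)), H),
                   matrix(rnorm(H * (H + d)), H),
                   matrix(rnorm(H * (H + d)), H))
  sq <- matrix(rnorm(Tn * d), Tn, d)
  out <- fgru_layer(p, sq)
  h <- rep(0, H)
  for (t in seq_len(Tn)) {
    h <- fgru_cell_step(p, h, sq[t, ])
    expect_equal(out[t, ], h, tolerance = 1e-12)
  }
  # convex-combination recurrence keeps the state in [-1, 1] from h0 = 0
  expect_true(all(abs(out) <= 1))
  # zero weights from zero state stay at zero
  zp <- fgru_params(matrix(0, H, H + d), matrix(0, H, H + d),
                    matrix(0, H, H + d))
  expect_true(all(fgru_layer(zp, sq) == 0))
  expect_equal(nrow(fgru_layer(p, sq[1, , drop = FALSE])), 1L)
  expect_error(fgru_layer(p, sq[0, , drop = FALSE]), "empty")
})

test_that("attention pooling is a softmax-weighted convex combination", {
  set.seed(15)
  H <- 4; Tn <- 6
  params <- list(v = rnorm(H), W = matrix(rnorm(H * H), H), b = rnorm(H))
  hid <- matrix(rnorm(Tn * H), Tn, H)
  ctx <- attention_pool(hid, params)
  al <- attr(ctx, "weights")
  expect_equal(sum(al), 1, tolerance = 1e-12)
  # independent oracle for the weights
  e <- apply(hid, 1, function(h)
    sum(params$v * tanh(params$W %*% h + params$b)))
  al_ref <- exp(e - max(e)) / sum(exp(e - max(e)))
  expect_equal(as.numeric(al), al_ref, tolerance = 1e-10)
  expect_equal(as.numeric(ctx), colSums(al_ref * hid), tolerance = 1e-10)
  # identical states pool to themselves whatever the weights
  same <- matrix(rep(rnorm(H), each = Tn), Tn, H)
  expect_equal(as.numeric(attention_pool(same, params)), same[1, ],
               tolerance = 1e-10)
  # a dominating energy acts as a hard max
  params2 <- list(v = c(1000, rep(0, H - 1)), W = diag(H), b = rep(0, H))
  hid2 <- rbind(c(1, 0, 0, 0), matrix(-1, Tn - 1, H))
  expect_equal(as.numeric(attention_pool(hid2, params2)), hid2[1, ],
               tolerance = 1e-6)
})

test_that("adaptive weight updates stay on the simplex", {
  set.seed(16)
  w <- rep(1 / 6, 6)
  preds <- matrix(runif(20 * 6), 20, 6)
  y <- rbinom(20, 1, 0.5)
  # lr = 0 and equal-error cases leave w unchanged
  expect_equal(adaptive_weight_update(w, preds, y, lr = 0), w)
  eq <- matrix(0.7, 20, 6)
  expect_equal(adaptive_weight_update(w, eq, y, lr = 0.05), w,
               tolerance = 1e-12)
  # hand-computed two-active-branch case
  w0 <- c(0.5, 0.5, rep(0, 4)) + 1e-12
  pr <- cbind(y + 1, y - 1, y, y, y, y)      # mean errors (+1, -1, 0, 0, 0, 0)
  upd <- adaptive_weight_update(w0, pr, y, lr = 0.01)
  raw <- w0 * exp(-0.01 * c(1, -1, 0, 0, 0, 0))
  expect_equal(upd, raw / sum(raw), tolerance = 1e-12)
  # simplex invariant across 500 random rounds
  wr <- abs(rnorm(6)); wr <- wr / sum(wr)
  for (i in 1:500) {
    wr <- adaptive_weight_update(wr, matrix(runif(12 * 6), 12, 6),
                                 rbinom(12, 1, 0.4), lr = 0.01)
    expect_true(all(wr > 0))
    expect_lt(abs(sum(wr) - 1), 1e-12)
  }
})

test_that("the forward pass combines branch scores with the weights", {
  set.seed(17)
  lay <- list(list(branch = "time", kernel_size = 3, start = 1L, end = 24L,
                   dim = c(2L, 4L, 3L)),
              list(branch = "spatial", kernel_size = 3, start = 25L,
                   end = 36L, dim = c(2L, 2L, 3L)))
  ds <- labeled_dataset(matrix(abs(rnorm(20 * 36)), 20, 36),
                        rep(c(0, 1), 10))
  m <- afgru_train(ds, lay, hidden = 6, layers = 3, epochs = 5, seed = 3)
  f <- afgru_forward(m, ds$vectors[4, ])
  expect_equal(f$score, sum(m$w * f$branch_outputs), tolerance = 1e-10)
  expect_equal(f$prob, 1 / (1 + exp(-f$score)), tolerance = 1e-12)
  # one-hot weights select a single branch
  m1 <- m; m1$w <- c(0, 0, 1, 0, 0, 0)
  f1 <- afgru_forward(m1, ds$vectors[4, ])
  expect_equal(f1$score, f$branch_outputs[3], tolerance = 1e-10)
  # batch prediction equals per-sample prediction
  batch <- predict(m, ds$vectors[1:5, ])
  single <- vapply(1:5, function(i)
    afgru_forward(m, ds$vectors[i, ])$prob, numeric(1))
  expect_equal(batch, single, tolerance = 1e-10)
})

test_that("training fits separable data and is deterministic", {
  set.seed(18)
  lay <- list(list(branch = "time", kernel_size = 3, start = 1L, end = 24L,
                   dim = c(2L, 4L, 3L)),
              list(branch = "spatial", kernel_size = 3, start = 25L,
                   end = 36L, dim = c(2L, 2L, 3L)))
  y <- rep(c(0, 1), each = 15)
  X <- t(vapply(y, function(yy) abs(rnorm(36, mean = 1.5 * yy, sd = 0.3)),
                numeric(36)))
  ds <- labeled_dataset(X, y)
  m <- afgru_train(ds, lay, hidden = 8, layers = 3, epochs = 120, seed = 5)
  expect_gte(mean(predict(m, ds, type = "class") == y), 0.95)
  expect_lt(tail(m$loss_history, 1), 0.05)
  m2 <- afgru_train(ds, lay, hidden = 8, layers = 3, epochs = 120, seed = 5)
  expect_identical(m$w, m2$w)
  expect_identical(m$theta$Wd, m2$theta$Wd)
  # constant labels are fitted to a constant with vanishing loss
  dsc <- labeled_dataset(X, rep(1, 30))
  mc <- afgru_train(dsc, lay, hidden = 6, layers = 2, epochs = 150, seed = 2)
  expect_lt(tail(mc$loss_history, 1), 0.02)
  expect_true(all(predict(mc, dsc) > 0.7))
})

test_that("trained branch weights remain a probability vector", {
  lay <- list(list(branch = "time", kernel_size = 3, start = 1L, end = 12L,
                   dim = c(1L, 4L, 3L)))
  set.seed(19)
  ds <- labeled_dataset(matrix(abs(rnorm(12 * 12)), 12, 12), rep(c(0, 1), 6))
  m <- afgru_train(ds, lay, hidden = 4, layers = 3, epochs = 30, seed = 1)
  expect_true(all(m$w > 0))
  expect_equal(sum(m$w), 1, tolerance = 1e-12)
})
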