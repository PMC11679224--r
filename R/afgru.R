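# Fourier-augmented GRU classifier with attention pooling and adaptively
# weighted branch outputs.
#
# Each input step is replaced by the real part of its discrete Fourier
# transform before entering the gates, so the recurrence sees both temporal
# order (through the hidden state) and frequency content (through the
# transformed input). Three FGRU layers are stacked; six branch outputs are
# tapped (input projection, the three final hidden states, the attention
# context, and a dense transform of the context), each scored by an affine
# head, and combined with branch weights that live on the probability
# simplex and are updated multiplicatively from each branch's mean signed
# error after every epoch. Training minimises the mean squared error
# between the sigmoid-squashed weighted score and the 0/1 label, with
# adaptive-moment gradient descent and analytic backpropagation.

#' Real part of the discrete Fourier transform
#'
#' @param x Finite numeric vector, length >= 1.
#' @return `Re(fft(x))`, same length as `x`.
#' @examples
#' fft_real(rep(2, 4))  # c(8, 0, 0, 0)
#' @export
fft_real <- function(x) {
  if (length(x) < 1) stop("`x` must be non-empty", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  Re(stats::fft(x))
}

# symmetric cosine matrix implementing fft_real as a linear map:
# fft_real(x) == C %*% x  with C[j, k] = cos(2*pi*(j-1)*(k-1)/d)
dft_cos_matrix <- function(d) {
  jk <- outer(seq_len(d) - 1, seq_len(d) - 1)
  cos(2 * pi * jk / d)
}

#' Construct one FGRU cell's parameters
#'
#' Each gate matrix maps the concatenation `[h_prev, x_fft]` (length
#' `hidden + input_dim`) to `hidden` values.
#'
#' @param W_z,W_r,W_h Gate weight matrices, each `H x (H + d)`.
#' @param b_z,b_r,b_h Optional bias vectors (default zero).
#' @return An object of class `fgru_params`.
#' @export
fgru_params <- function(W_z, W_r, W_h, b_z = NULL, b_r = NULL, b_h = NULL) {
  H <- nrow(W_z)
  stopifnot(nrow(W_r) == H, nrow(W_h) == H,
            ncol(W_r) == ncol(W_z), ncol(W_h) == ncol(W_z),
            ncol(W_z) > H)
  zeros <- rep(0, H)
  structure(list(W_z = W_z, W_r = W_r, W_h = W_h,
                 b_z = b_z %||% zeros, b_r = b_r %||% zeros,
                 b_h = b_h %||% zeros,
                 hidden = H, input_dim = ncol(W_z) - H),
            class = "fgru_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One FGRU cell step
#'
#' Applies the Fourier-augmented gated recurrence: the input is transformed
#' with [fft_real()], then
#' `z = sigmoid(W_z [h, x_fft])`, `r = sigmoid(W_r [h, x_fft])`,
#' `h_cand = tanh(W_h [r*h, x_fft])`, and
#' `h_new = (1 - z)*h + z*h_cand`.
#'
#' @param params An [fgru_params()].
#' @param h_prev Hidden state vector, length `H`.
#' @param x_t Input vector, length `input_dim`.
#' @return The new hidden state (length `H`).
#' @export
fgru_cell_step <- function(params, h_prev, x_t) {
  stopifnot(inherits(params, "fgru_params"))
  if (!all(is.finite(h_prev)) || !all(is.finite(x_t)))
    stop("inputs must be finite", call. = FALSE)
  stopifnot(length(h_prev) == params$hidden,
            length(x_t) == params$input_dim)
  xf <- fft_real(x_t)
  hx <- c(h_prev, xf)
  z <- sigmoid(drop(params$W_z %*% hx) + params$b_z)
  r <- sigmoid(drop(params$W_r %*% hx) + params$b_r)
  h_cand <- tanh(drop(params$W_h %*% c(r * h_prev, xf)) + params$b_h)
  (1 - z) * h_prev + z * h_cand
}

#' Run an FGRU layer over a sequence
#'
#' Applies [fgru_cell_step()] across timesteps starting from `h_0 = 0` and
#' returns every hidden state.
#'
#' @param params An [fgru_params()].
#' @param sequence `T x d` matrix (rows are timesteps).
#' @return A `T x H` matrix of hidden states.
#' @export
fgru_layer <- function(params, sequence) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1) stop("empty sequence", call. = FALSE)
  H <- params$hidden
  out <- matrix(0, nrow(sequence), H)
  h <- rep(0, H)
  for (t in seq_len(nrow(sequence))) {
    h <- fgru_cell_step(params, h, sequence[t, ])
    out[t, ] <- h
  }
  out
}

#' Additive attention pooling over hidden states
#'
#' Scores each timestep with a single-layer additive energy
#' `e_t = v' tanh(W h_t + b)`, normalises with a softmax, and returns the
#' weighted sum of hidden states. The weights are attached as attribute
#' `"weights"`.
#'
#' @param hidden `T x H` matrix of hidden states.
#' @param params List with `v` (length `H`), `W` (`H x H`), `b` (length `H`).
#' @return The pooled context vector (length `H`).
#' @export
attention_pool <- function(hidden, params) {
  hidden <- as.matrix(hidden)
  stopifnot(nrow(hidden) >= 1)
  M <- tanh(sweep(hidden %*% t(params$W), 2, params$b, "+"))
  e <- drop(M %*% params$v)
  alpha <- softmax(e)
  ctx <- drop(crossprod(hidden, alpha))
  attr(ctx, "weights") <- alpha
  ctx
}

#' Multiplicative update of the branch weights
#'
#' Each branch weight is scaled by `exp(-lr * mean(prediction - truth))`
#' over the training samples and the vector is renormalised to the simplex,
#' so branches that systematically over-predict lose weight. With `lr = 0`,
#' or when all branches share the same mean error, the weights are
#' unchanged.
#'
#' @param w Positive weight vector summing to 1 (length 6 in the full
#'   model).
#' @param branch_preds `n x length(w)` matrix of per-branch predictions.
#' @param truths Length-`n` vector of 0/1 labels.
#' @param lr Learning rate of the multiplicative update.
#' @return The updated weight vector (positive, sums to 1).
#' @export
adaptive_weight_update <- function(w, branch_preds, truths, lr = 0.01) {
  branch_preds <- as.matrix(branch_preds)
  stopifnot(length(w) == ncol(branch_preds),
            nrow(branch_preds) == length(truths), all(w > 0))
  err <- colMeans(branch_preds - truths)
  w_new <- unname(w * exp(-lr * err))
  s <- sum(w_new)
  if (!is.finite(s) || s <= 0)
    stop("branch-weight update degenerated", call. = FALSE)
  w_new / s
}

# ---------------------------------------------------------------------------
# internal batched network used for training

afgru_init <- function(input_dim, hidden, layers, seed) {
  with_seed(seed, {
    gm <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)),
                                  nr, nc)
    # input-side gate matrices see Re(FFT(x)), whose per-coordinate variance
    # is ~d/2 times that of x; shrink their initial scale accordingly so the
    # gates start in their linear range
    gx <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2) / nc),
                                  nr, nc)
    theta <- list(W_in = gm(hidden, input_dim), b_in = rep(0, hidden))
    for (l in seq_len(layers)) {
      d <- if (l == 1) input_dim else hidden
      for (g in c("z", "r", "h")) {
        theta[[sprintf("W%s_h%d", g, l)]] <- gm(hidden, hidden)
        theta[[sprintf("W%s_x%d", g, l)]] <- gx(hidden, d)
        theta[[sprintf("b%s%d", g, l)]] <- rep(0, hidden)
      }
    }
    theta$Wa <- gm(hidden, hidden); theta$ba <- rep(0, hidden)
    theta$va <- stats::rnorm(hidden, sd = 1 / sqrt(hidden))
    theta$Wd <- gm(hidden, hidden); theta$bd <- rep(0, hidden)
    theta$Ahead <- gm(6, hidden); theta$bhead <- rep(0, 6)
    w0 <- abs(stats::rnorm(6))
    theta
    list(theta = theta, w = w0 / sum(w0))
  })
}

# Xlist: list over timesteps of n x d input matrices (raw, pre-FFT).
# Returns scores, branch scores and all caches needed for the backward pass.
afgru_forward_batch <- function(theta, w, Xlist, layers, Cin, Chid) {
  n <- nrow(Xlist[[1]]); Tn <- length(Xlist)
  H <- length(theta$b_in)
  xbar <- Reduce(`+`, Xlist) / Tn
  X1 <- tanh(xbar %*% t(theta$W_in) +
               matrix(theta$b_in, n, H, byrow = TRUE))
  caches <- vector("list", layers)
  inp <- Xlist
  for (l in seq_len(layers)) {
    C <- if (l == 1) Cin else Chid
    Wzh <- theta[[sprintf("Wz_h%d", l)]]; Wzx <- theta[[sprintf("Wz_x%d", l)]]
    Wrh <- theta[[sprintf("Wr_h%d", l)]]; Wrx <- theta[[sprintf("Wr_x%d", l)]]
    Whh <- theta[[sprintf("Wh_h%d", l)]]; Whx <- theta[[sprintf("Wh_x%d", l)]]
    bz <- theta[[sprintf("bz%d", l)]]; br <- theta[[sprintf("br%d", l)]]
    bh <- theta[[sprintf("bh%d", l)]]
    Hseq <- vector("list", Tn + 1L)
    Hseq[[1]] <- matrix(0, n, H)
    Z <- R <- Hc <- Xf <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      xf <- inp[[t]] %*% C                      # C is symmetric
      hp <- Hseq[[t]]
      z <- sigmoid(hp %*% t(Wzh) + xf %*% t(Wzx) +
                     matrix(bz, n, H, byrow = TRUE))
      r <- sigmoid(hp %*% t(Wrh) + xf %*% t(Wrx) +
                     matrix(br, n, H, byrow = TRUE))
      hc <- tanh((r * hp) %*% t(Whh) + xf %*% t(Whx) +
                   matrix(bh, n, H, byrow = TRUE))
      Hseq[[t + 1L]] <- (1 - z) * hp + z * hc
      Z[[t]] <- z; R[[t]] <- r; Hc[[t]] <- hc; Xf[[t]] <- xf
    }
    caches[[l]] <- list(Hseq = Hseq, Z = Z, R = R, Hc = Hc, Xf = Xf,
                        input = inp)
    inp <- Hseq[-1L]
  }
  Htop <- caches[[layers]]$Hseq[-1L]
  # attention over the top layer
  Mlist <- lapply(Htop, function(h)
    tanh(h %*% t(theta$Wa) + matrix(theta$ba, n, H, byrow = TRUE)))
  E <- vapply(Mlist, function(m) drop(m %*% theta$va), numeric(n))
  E <- matrix(E, n, Tn)
  Emax <- apply(E, 1, max)
  A <- exp(E - Emax); A <- A / rowSums(A)       # n x T attention weights
  ctx <- matrix(0, n, H)
  for (t in seq_len(Tn)) ctx <- ctx + A[, t] * Htop[[t]]
  X6 <- tanh(ctx %*% t(theta$Wd) + matrix(theta$bd, n, H, byrow = TRUE))
  branches <- list(X1,
                   caches[[1]]$Hseq[[Tn + 1L]],
                   if (layers >= 2) caches[[2]]$Hseq[[Tn + 1L]] else X1 * 0,
                   if (layers >= 3) caches[[3]]$Hseq[[Tn + 1L]] else X1 * 0,
                   ctx, X6)
  S <- vapply(seq_len(6), function(i)
    drop(branches[[i]] %*% theta$Ahead[i, ]) + theta$bhead[i], numeric(n))
  S <- matrix(S, n, 6)
  score <- drop(S %*% w)
  P <- sigmoid(score)
  list(P = P, score = score, S = S, branches = branches, A = A, ctx = ctx,
       X1 = X1, X6 = X6, Mlist = Mlist, caches = caches, xbar = xbar,
       Htop = Htop, n = n, Tn = Tn, H = H)
}

afgru_backward_batch <- function(theta, w, y, fw, layers, Cin, Chid) {
  n <- fw$n; Tn <- fw$Tn; H <- fw$H
  grads <- lapply(theta, function(p) p * 0)
  dP <- 2 * (fw$P - y) / n
  dscore <- dP * fw$P * (1 - fw$P)
  dS <- outer(dscore, w)                        # n x 6
  dbr <- vector("list", 6)
  for (i in seq_len(6)) {
    dbr[[i]] <- outer(dS[, i], theta$Ahead[i, ])
    grads$Ahead[i, ] <- crossprod(fw$branches[[i]], dS[, i])
    grads$bhead[i] <- sum(dS[, i])
  }
  # X6 = tanh(Wd ctx + bd)
  dX6pre <- dbr[[6]] * (1 - fw$X6^2)
  grads$Wd <- crossprod(dX6pre, fw$ctx)
  grads$bd <- colSums(dX6pre)
  dctx <- dbr[[5]] + dX6pre %*% theta$Wd
  # attention: ctx = sum_t A_t * Htop_t
  dHtop <- lapply(seq_len(Tn), function(t) fw$A[, t] * dctx)
  dAmat <- vapply(seq_len(Tn),
                  function(t) rowSums(dctx * fw$Htop[[t]]), numeric(n))
  dAmat <- matrix(dAmat, n, Tn)
  dE <- fw$A * (dAmat - rowSums(fw$A * dAmat))  # softmax backward
  for (t in seq_len(Tn)) {
    dM <- outer(dE[, t], theta$va)
    grads$va <- grads$va + crossprod(fw$Mlist[[t]], dE[, t])[, 1]
    dMpre <- dM * (1 - fw$Mlist[[t]]^2)
    grads$Wa <- grads$Wa + crossprod(dMpre, fw$Htop[[t]])
    grads$ba <- grads$ba + colSums(dMpre)
    dHtop[[t]] <- dHtop[[t]] + dMpre %*% theta$Wa
  }
  # external grads flowing into each layer's hidden sequence
  dH_ext <- vector("list", layers)
  for (l in seq_len(layers)) dH_ext[[l]] <-
    lapply(seq_len(Tn), function(t) matrix(0, n, H))
  dH_ext[[layers]] <- dHtop
  if (layers >= 1) dH_ext[[1]][[Tn]] <- dH_ext[[1]][[Tn]] + dbr[[2]]
  if (layers >= 2) dH_ext[[2]][[Tn]] <- dH_ext[[2]][[Tn]] + dbr[[3]]
  if (layers >= 3) dH_ext[[3]][[Tn]] <- dH_ext[[3]][[Tn]] + dbr[[4]]

  for (l in rev(seq_len(layers))) {
    C <- if (l == 1) Cin else Chid
    cc <- fw$caches[[l]]
    Wzh <- theta[[sprintf("Wz_h%d", l)]]; Wzx <- theta[[sprintf("Wz_x%d", l)]]
    Wrh <- theta[[sprintf("Wr_h%d", l)]]; Wrx <- theta[[sprintf("Wr_x%d", l)]]
    Whh <- theta[[sprintf("Wh_h%d", l)]]; Whx <- theta[[sprintf("Wh_x%d", l)]]
    gWzh <- Wzh * 0; gWzx <- Wzx * 0; gbz <- rep(0, H)
    gWrh <- Wrh * 0; gWrx <- Wrx * 0; gbr <- rep(0, H)
    gWhh <- Whh * 0; gWhx <- Whx * 0; gbh <- rep(0, H)
    carry <- matrix(0, n, H)
    dInput <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      dh <- dH_ext[[l]][[t]] + carry
      z <- cc$Z[[t]]; r <- cc$R[[t]]; hc <- cc$Hc[[t]]
      hp <- cc$Hseq[[t]]; xf <- cc$Xf[[t]]
      dz <- dh * (hc - hp)
      dhc <- dh * z
      dhp <- dh * (1 - z)
      dhcpre <- dhc * (1 - hc^2)
      gWhh <- gWhh + crossprod(dhcpre, r * hp)
      gWhx <- gWhx + crossprod(dhcpre, xf)
      gbh <- gbh + colSums(dhcpre)
      drh <- dhcpre %*% Whh
      dr <- drh * hp
      dhp <- dhp + drh * r
      dxf <- dhcpre %*% Whx
      dzpre <- dz * z * (1 - z)
      gWzh <- gWzh + crossprod(dzpre, hp)
      gWzx <- gWzx + crossprod(dzpre, xf)
      gbz <- gbz + colSums(dzpre)
      dhp <- dhp + dzpre %*% Wzh
      dxf <- dxf + dzpre %*% Wzx
      drpre <- dr * r * (1 - r)
      gWrh <- gWrh + crossprod(drpre, hp)
      gWrx <- gWrx + crossprod(drpre, xf)
      gbr <- gbr + colSums(drpre)
      dhp <- dhp + drpre %*% Wrh
      dxf <- dxf + drpre %*% Wrx
      dInput[[t]] <- dxf %*% C                  # C symmetric
      carry <- dhp
    }
    grads[[sprintf("Wz_h%d", l)]] <- gWzh
    grads[[sprintf("Wz_x%d", l)]] <- gWzx
    grads[[sprintf("bz%d", l)]] <- gbz
    grads[[sprintf("Wr_h%d", l)]] <- gWrh
    grads[[sprintf("Wr_x%d", l)]] <- gWrx
    grads[[sprintf("br%d", l)]] <- gbr
    grads[[sprintf("Wh_h%d", l)]] <- gWhh
    grads[[sprintf("Wh_x%d", l)]] <- gWhx
    grads[[sprintf("bh%d", l)]] <- gbh
    if (l > 1)
      for (t in seq_len(Tn))
        dH_ext[[l - 1]][[t]] <- dH_ext[[l - 1]][[t]] + dInput[[t]]
    else {
      # input-projection branch X1 also depends on the data; its own grads:
      dX1pre <- dbr[[1]] * (1 - fw$X1^2)
      grads$W_in <- crossprod(dX1pre, fw$xbar)
      grads$b_in <- colSums(dX1pre)
    }
  }
  grads
}

#' Train the AFGRU classifier on fused features
#'
#' Full-batch training: each epoch takes one adaptive-moment (Adam) gradient
#' step on the mean squared error between the sigmoid of the
#' branch-weighted score and the 0/1 label, followed by one multiplicative
#' branch-weight update ([adaptive_weight_update()]) using the sigmoid of
#' each branch's own score as that branch's prediction.
#'
#' @param data A [labeled_dataset()] of fused feature vectors.
#' @param layout The fused-vector layout (from [fuse_cohort()]), used to
#'   reshape each vector into a (steps x channels) sequence: the pooled
#'   time-branch maps form the leading steps, and the pooled spatial-branch
#'   maps (which share the channel width, both branches having the
#'   component axis as columns) are appended as trailing steps.
#' @param hidden Hidden size `H` (default 200).
#' @param layers Number of stacked FGRU layers (default 3).
#' @param lr Learning rate for Adam and the weight update (default 0.01).
#' @param epochs Weight-update rounds (default 500).
#' @param seed Integer seed.
#' @return An object of class `afgru_model`.
#' @export
afgru_train <- function(data, layout, hidden = 200L, layers = 3L,
                        lr = 0.01, epochs = 500L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  assert_count(hidden, "hidden"); assert_count(layers, "layers")
  assert_count(epochs, "epochs")
  if (layers > 3L) stop("at most 3 stacked layers are supported", call. = FALSE)
  # standardize features on the training set; the statistics travel with the
  # model so prediction sees the same scale
  center <- colMeans(data$vectors)
  scl <- pmax(apply(data$vectors, 2, stats::sd), 1e-8)
  Xstd <- sweep(sweep(data$vectors, 2, center), 2, scl, "/")
  Xlist <- build_sequences(Xstd, layout)
  d <- ncol(Xlist[[1]])
  y <- data$labels
  ini <- afgru_init(d, hidden, layers, seed)
  theta <- ini$theta; w <- ini$w
  Cin <- dft_cos_matrix(d); Chid <- dft_cos_matrix(hidden)
  mom <- lapply(theta, function(p) p * 0)
  vel <- lapply(theta, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- afgru_forward_batch(theta, w, Xlist, layers, Cin, Chid)
    loss[ep] <- mean((fw$P - y)^2)
    if (!is.finite(loss[ep]))
      stop("training diverged (non-finite loss)", call. = FALSE)
    gr <- afgru_backward_batch(theta, w, y, fw, layers, Cin, Chid)
    for (nm in names(theta)) {
      mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gr[[nm]]
      vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gr[[nm]]^2
      mhat <- mom[[nm]] / (1 - b1^ep)
      vhat <- vel[[nm]] / (1 - b2^ep)
      theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    w <- adaptive_weight_update(w, sigmoid(fw$S), y, lr)
  }
  structure(list(theta = theta, w = w, layout = layout,
                 hidden = hidden, layers = layers, lr = lr,
                 epochs = epochs, seed = seed, input_dim = d,
                 center = center, scale = scl,
                 loss_history = loss, trained = TRUE),
            class = "afgru_model")
}

# fused vectors (n x d matrix) -> list over timesteps of n x d_in matrices
build_sequences <- function(vectors, layout) {
  seqs <- apply(vectors, 1, function(v) fused_to_sequence(v, layout)$seq,
                simplify = FALSE)
  Tn <- nrow(seqs[[1]])
  lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(seqs, function(s) s[t, ])))
}

#' Forward pass of a trained model on one fused feature vector
#'
#' @param model An `afgru_model`.
#' @param fused A `fused_feature` or a bare numeric vector laid out like the
#'   training data.
#' @return A list with `score` (raw branch-weighted sum), `branch_outputs`
#'   (the six branch scores), and `prob` (sigmoid of `score`).
#' @export
afgru_forward <- function(model, fused) {
  stopifnot(inherits(model, "afgru_model"))
  vec <- if (inherits(fused, "fused_feature")) fused$vector else fused
  if (!is.null(model$center)) vec <- (vec - model$center) / model$scale
  fw <- afgru_forward_batch(model$theta, model$w,
                            build_sequences(matrix(vec, 1), model$layout),
                            model$layers,
                            dft_cos_matrix(model$input_dim),
                            dft_cos_matrix(model$hidden))
  list(score = fw$score[1], branch_outputs = fw$S[1, ], prob = fw$P[1])
}

#' Predict class probabilities for fused feature vectors
#'
#' The sigmoid-squashed branch-weighted score; class 1 is predicted when the
#' score is at least 0.5 (ties go to the positive class).
#'
#' @param object An `afgru_model`.
#' @param newdata `n x d` matrix (or `labeled_dataset`) of fused vectors.
#' @param type `"prob"` (default) or `"class"`.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 classes.
#' @export
predict.afgru_model <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  if (is.null(object$trained) || !object$trained)
    stop("model is not trained", call. = FALSE)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$vectors
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
                   object$scale, "/")
  Xlist <- build_sequences(newdata, object$layout)
  fw <- afgru_forward_batch(object$theta, object$w, Xlist, object$layers,
                            dft_cos_matrix(object$input_dim),
                            dft_cos_matrix(object$hidden))
  if (type == "prob") fw$P else as.integer(fw$P >= 0.5)
}

#' @export
print.afgru_model <- function(x, ...) {
  cat(sprintf(
    "<afgru_model> %d FGRU layer(s), hidden %d, input dim %d, %d epochs\n",
    x$layers, x$hidden, x$input_dim, x$epochs))
  cat("branch weights:", sprintf("%.3f", x$w), "\n")
  invisible(x)
}
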