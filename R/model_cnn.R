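# Convolutional sequence classifier with single-head self-attention.
#
# Architecture: trainable embedding of the token alphabet, three 1-d
# convolutional layers (same padding, rectifier activations), scaled
# dot-product self-attention over positions, global max pooling, and a
# linear softmax head. Trained with Adam on the cross-entropy loss.
# Forward and backward passes are written directly as matrix algebra,
# vectorized over the minibatch (samples are stacked row-wise so each
# convolution is a single matrix product), so training is fast in BLAS
# and exactly reproducible from the seed.

#' Convolutional network configuration
#'
#' @param embedding_dim Width of the token embedding vectors.
#' @param conv_filters Number of filters in each of the three
#'   convolutional layers.
#' @param kernel_widths Odd kernel widths of the three convolutional
#'   layers (exactly 3).
#' @param attention Apply single-head scaled dot-product self-attention
#'   after the convolution stack.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(embedding_dim = 64L, conv_filters = 64L,
                       kernel_widths = c(3L, 5L, 7L), attention = TRUE,
                       epochs = 20L, batch_size = 32L,
                       learning_rate = 1e-3, seed = 1L) {
  if (length(kernel_widths) != 3L) stopf("exactly 3 convolutional layers are required")
  if (any(kernel_widths %% 2L == 0L)) stopf("kernel widths must be odd (same padding)")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 conv_filters = as.integer(conv_filters),
                 kernel_widths = as.integer(kernel_widths),
                 attention = isTRUE(attention),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# Row-index matrix of a width-w same-padded convolution over B stacked
# length-L sequences; out-of-range positions point at a sentinel zero
# row (B*L + 1) so padding never leaks across samples.
#' @noRd
build_conv_idx <- function(B, L, w) {
  pad <- (w - 1L) %/% 2L
  sentinel <- B * L + 1L
  l <- rep(seq_len(L), times = B)
  base <- rep((seq_len(B) - 1L) * L, each = L)
  idx <- matrix(sentinel, B * L, w)
  for (j in seq_len(w)) {
    pos <- l + (j - 1L) - pad
    valid <- pos >= 1L & pos <= L
    idx[valid, j] <- base[valid] + pos[valid]
  }
  idx
}

# Unfold stacked inputs into the patch matrix of the convolution; column
# (ch-1)*w + j holds input channel ch at kernel offset j.
#' @noRd
unfold <- function(X, idx) {
  aug <- rbind(X, 0)
  matrix(aug[as.vector(idx), , drop = FALSE], nrow = nrow(idx))
}

# Adjoint of unfold: scatter-add patch gradients back onto positions.
# For fixed kernel offset j target rows are unique, so indexed addition
# is safe; sentinel rows are dropped.
#' @noRd
fold_add <- function(dXc, idx, n_rows, nc) {
  w <- ncol(idx)
  dX <- matrix(0, n_rows, nc)
  for (j in seq_len(w)) {
    cols <- (seq_len(nc) - 1L) * w + j
    tgt <- idx[, j]
    valid <- tgt <= n_rows
    dX[tgt[valid], ] <- dX[tgt[valid], , drop = FALSE] +
      dXc[valid, cols, drop = FALSE]
  }
  dX
}

#' @noRd
softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

#' @noRd
relu_ <- function(M) { M[M < 0] <- 0; M }

#' @noRd
cnn_init_params <- function(vocab_size, n_classes, cfg) {
  d <- cfg$embedding_dim; f <- cfg$conv_filters; w <- cfg$kernel_widths
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  p <- list(
    E  = matrix(stats::rnorm((vocab_size + 1L) * d, sd = 0.1), vocab_size + 1L, d),
    W1 = he(w[1] * d, f, w[1] * d), b1 = numeric(f),
    W2 = he(w[2] * f, f, w[2] * f), b2 = numeric(f),
    W3 = he(w[3] * f, f, w[3] * f), b3 = numeric(f),
    Wo = he(f, n_classes, f), bo = numeric(n_classes))
  if (cfg$attention) {
    p$Wq <- he(f, f, f); p$Wk <- he(f, f, f); p$Wv <- he(f, f, f)
  }
  p$E[1L, ] <- 0   # padding embedding starts at zero (still trainable)
  p
}

# Forward pass over a B x L token batch; samples are stacked row-wise
# into (B*L) x channels matrices. Returns caches when `keep = TRUE`.
#' @noRd
cnn_forward <- function(tokens, p, cfg, keep = FALSE) {
  B <- nrow(tokens); L <- ncol(tokens); f <- cfg$conv_filters
  w <- cfg$kernel_widths
  tokvec <- as.vector(t(tokens)) + 1L      # sample-major position order
  X0 <- p$E[tokvec, , drop = FALSE]
  idx1 <- build_conv_idx(B, L, w[1])
  idx2 <- build_conv_idx(B, L, w[2])
  idx3 <- build_conv_idx(B, L, w[3])
  Xc1 <- unfold(X0, idx1); H1 <- relu_(Xc1 %*% p$W1 + rep(p$b1, each = B * L))
  Xc2 <- unfold(H1, idx2); H2 <- relu_(Xc2 %*% p$W2 + rep(p$b2, each = B * L))
  Xc3 <- unfold(H2, idx3); H3 <- relu_(Xc3 %*% p$W3 + rep(p$b3, each = B * L))
  att <- NULL
  if (cfg$attention) {
    Z <- matrix(0, B * L, f)
    att <- vector("list", B)
    for (s in seq_len(B)) {
      r <- ((s - 1L) * L + 1L):(s * L)
      Hs <- H3[r, , drop = FALSE]
      Q <- Hs %*% p$Wq; K <- Hs %*% p$Wk; V <- Hs %*% p$Wv
      A <- softmax_rows((Q %*% t(K)) / sqrt(f))
      Z[r, ] <- A %*% V
      if (keep) att[[s]] <- list(Q = Q, K = K, V = V, A = A)
    }
  } else {
    Z <- H3
  }
  # global max pooling per sample and filter
  mi <- matrix(0L, B, f)
  zpool <- matrix(0, B, f)
  for (s in seq_len(B)) {
    r <- ((s - 1L) * L + 1L):(s * L)
    Zs <- Z[r, , drop = FALSE]
    m <- max.col(t(Zs), ties.method = "first")
    mi[s, ] <- m
    zpool[s, ] <- Zs[cbind(m, seq_len(f))]
  }
  logits <- zpool %*% p$Wo + rep(p$bo, each = B)
  probs <- softmax_rows(logits)
  if (!keep) return(list(probs = probs))
  list(probs = probs, tokvec = tokvec, X0 = X0, Xc1 = Xc1, H1 = H1,
       Xc2 = Xc2, H2 = H2, Xc3 = Xc3, H3 = H3, att = att, mi = mi,
       zpool = zpool, idx1 = idx1, idx2 = idx2, idx3 = idx3,
       B = B, L = L)
}

# Batched backward pass; `y` holds 1-based true classes. Returns the
# gradient list (averaged over the batch).
#' @noRd
cnn_backward <- function(fw, y, p, cfg) {
  B <- fw$B; L <- fw$L; f <- cfg$conv_filters
  g <- list()
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  g$Wo <- t(fw$zpool) %*% dlogits
  g$bo <- colSums(dlogits)
  dzpool <- dlogits %*% t(p$Wo)
  dZ <- matrix(0, B * L, f)
  for (s in seq_len(B)) {
    dZ[cbind((s - 1L) * L + fw$mi[s, ], seq_len(f))] <- dzpool[s, ]
  }
  if (cfg$attention) {
    dH3 <- matrix(0, B * L, f)
    g$Wq <- matrix(0, f, f); g$Wk <- matrix(0, f, f); g$Wv <- matrix(0, f, f)
    for (s in seq_len(B)) {
      r <- ((s - 1L) * L + 1L):(s * L)
      a <- fw$att[[s]]
      Hs <- fw$H3[r, , drop = FALSE]
      dZs <- dZ[r, , drop = FALSE]
      dA <- dZs %*% t(a$V)
      dV <- t(a$A) %*% dZs
      dS <- a$A * (dA - rowSums(dA * a$A))   # softmax Jacobian, row-wise
      dS <- dS / sqrt(f)
      dQ <- dS %*% a$K
      dK <- t(dS) %*% a$Q
      g$Wq <- g$Wq + t(Hs) %*% dQ
      g$Wk <- g$Wk + t(Hs) %*% dK
      g$Wv <- g$Wv + t(Hs) %*% dV
      dH3[r, ] <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    }
  } else {
    dH3 <- dZ
  }
  dP3 <- dH3 * (fw$H3 > 0)
  g$W3 <- t(fw$Xc3) %*% dP3
  g$b3 <- colSums(dP3)
  dH2 <- fold_add(dP3 %*% t(p$W3), fw$idx3, B * L, f)
  dP2 <- dH2 * (fw$H2 > 0)
  g$W2 <- t(fw$Xc2) %*% dP2
  g$b2 <- colSums(dP2)
  dH1 <- fold_add(dP2 %*% t(p$W2), fw$idx2, B * L, f)
  dP1 <- dH1 * (fw$H1 > 0)
  g$W1 <- t(fw$Xc1) %*% dP1
  g$b1 <- colSums(dP1)
  dX0 <- fold_add(dP1 %*% t(p$W1), fw$idx1, B * L, cfg$embedding_dim)
  agg <- rowsum(dX0, group = fw$tokvec)
  g$E <- matrix(0, nrow(p$E), ncol(p$E))
  g$E[as.integer(rownames(agg)), ] <- agg
  g
}

#' @noRd
zero_like <- function(params) lapply(params, function(x) x * 0)

#' @noRd
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the convolutional component classifier
#'
#' @param tokens A `token_matrix` from [encode_tokens()].
#' @param labels Class labels aligned to the token rows (factor or
#'   character); at least two classes must be present.
#' @param config A [cnn_config()].
#' @return A fitted component model of class `c("ros_cnn",
#'   "ros_component")` honouring the [predict_proba()] contract. The
#'   per-epoch mean training loss is kept in `$history`.
#' @export
train_cnn <- function(tokens, labels, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  n <- nrow(tokens)
  if (n == 0L) stopf("cannot train on an empty input")
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (length(labels) != n) stopf("labels must align with token rows")
  if (nlevels(labels) < 2L) stopf("training data contains a single class")
  classes <- levels(labels)
  y <- as.integer(labels)
  vocab_size <- attr(tokens, "max_index") %||% max(tokens)
  cfg <- config
  history <- numeric(cfg$epochs)
  params <- NULL
  with_seed(cfg$seed, {
    params <- cnn_init_params(vocab_size, length(classes), cfg)
    state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      total_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- cnn_forward(tokens[idx, , drop = FALSE], params, cfg, keep = TRUE)
        total_loss <- total_loss -
          sum(log(pmax(fw$probs[cbind(seq_along(idx), y[idx])], 1e-12)))
        grads <- cnn_backward(fw, y[idx], params, cfg)
        upd <- adam_step(params, grads[names(params)], state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      history[epoch] <- total_loss / n
    }
  })
  structure(list(kind = "cnn", params = params, config = cfg,
                 classes = classes, n_classes = length(classes),
                 feature_spec = "tokens", vocab_size = vocab_size,
                 pad_length = ncol(tokens), history = history),
            class = c("ros_cnn", "ros_component"))
}

#' @rdname predict_proba
#' @export
predict_proba.ros_cnn <- function(model, newdata, ...) {
  if (!is.matrix(newdata)) stopf("newdata must be a token matrix")
  if (nrow(newdata) == 0L) {
    return(matrix(numeric(0), 0L, model$n_classes,
                  dimnames = list(NULL, model$classes)))
  }
  if (max(newdata) > model$vocab_size) {
    stopf("token index %d exceeds the model vocabulary (%d)",
          max(newdata), model$vocab_size)
  }
  chunks <- split(seq_len(nrow(newdata)),
                  ceiling(seq_len(nrow(newdata)) / 64))
  out <- do.call(rbind, lapply(chunks, function(i) {
    cnn_forward(newdata[i, , drop = FALSE], model$params, model$config)$probs
  }))
  dimnames(out) <- list(rownames(newdata), model$classes)
  out
}
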