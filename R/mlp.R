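# Internal fully-connected network engine: forward/backprop with inverted
# dropout, Adam updates, MSE and class-weighted binary cross-entropy losses.
# Written against BLAS-backed base matrix ops; all randomness (init,
# shuffling, dropout masks, validation split) is drawn inside one seeded
# stream so training is exactly reproducible.

# He-style initialization for a stack of layers.
# widths: vector c(in, h1, ..., out); returns list of list(W, b).
.mlp_init <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(l) {
    fan_in <- widths[l]
    list(W = matrix(rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                    fan_in, widths[l + 1L]),
         b = numeric(widths[l + 1L]))
  })
}

.act_apply <- function(z, act) {
  switch(act,
         relu = { z[z < 0] <- 0; z },
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         stop("unknown activation: ", act))
}

# Forward pass. training=TRUE applies inverted dropout after every layer
# except the last. Returns activations (a[[1]] = input) and masks.
.mlp_forward <- function(X, layers, acts, dropout = 0, training = FALSE) {
  L <- length(layers)
  a <- vector("list", L + 1L)
  z <- vector("list", L)
  masks <- vector("list", L)
  a[[1L]] <- X
  for (l in seq_len(L)) {
    z[[l]] <- a[[l]] %*% layers[[l]]$W +
      rep(layers[[l]]$b, each = nrow(X))
    h <- .act_apply(z[[l]], acts[l])
    if (training && dropout > 0 && l < L) {
      m <- matrix(stats::rbinom(length(h), 1L, 1 - dropout) / (1 - dropout),
                  nrow(h), ncol(h))
      h <- h * m
      masks[[l]] <- m
    }
    a[[l + 1L]] <- h
  }
  list(a = a, z = z, masks = masks)
}

# Loss and output-layer delta (dL/dz_L).
#  mse : mean squared error over all entries, linear output assumed.
#  wbce: per-sample-weighted binary cross-entropy, sigmoid output; computed
#        from pre-activations for numerical stability.
.mlp_loss <- function(fwd, Y, loss, w = NULL) {
  L <- length(fwd$z)
  if (loss == "mse") {
    diff <- fwd$a[[L + 1L]] - Y
    list(value = mean(diff^2), delta = 2 * diff / length(diff))
  } else if (loss == "wbce") {
    zl <- fwd$z[[L]]
    y <- as.numeric(Y)
    if (is.null(w)) w <- rep(1, length(y))
    softplus <- ifelse(zl > 30, zl, log1p(exp(zl)))
    value <- mean(w * (softplus - y * zl))
    p <- 1 / (1 + exp(-zl))
    list(value = value, delta = matrix(w * (p - y) / length(y), ncol = 1L))
  } else stop("unknown loss: ", loss)
}

# Backward pass from the output delta; returns per-layer gradients.
.mlp_backward <- function(fwd, layers, acts, dropout, delta) {
  L <- length(layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fwd$a[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      if (!is.null(fwd$masks[[l - 1L]])) delta <- delta * fwd$masks[[l - 1L]]
      if (acts[l - 1L] == "relu") delta <- delta * (fwd$z[[l - 1L]] > 0)
      else if (acts[l - 1L] == "sigmoid") {
        s <- fwd$a[[l]] # note: post-dropout; sigmoid hidden layers unused
        delta <- delta * s * (1 - s)
      }
    }
  }
  grads
}

.adam_init <- function(layers) {
  list(m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       t = 0L)
}

.adam_step <- function(layers, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / bc1
      vhat <- state$v[[l]][[p]] / bc2
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# Mini-batch training loop. Returns trained layers plus a per-epoch history
# of training loss (mean over batches) and validation loss (dropout off).
# val_idx rows are held out; if empty, val_loss is NA.
.mlp_train <- function(X, Y, layers, acts, loss, epochs, batch_size,
                       dropout, lr, sample_w = NULL, val_fraction = 0.1,
                       seed = 1L, phase_name = "train") {
  .with_seed(seed, {
    n <- nrow(X)
    n_val <- floor(n * val_fraction)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer()
    tr_idx <- setdiff(seq_len(n), val_idx)
    state <- .adam_init(layers)
    hist <- data.frame(phase = character(), epoch = integer(),
                       train_loss = numeric(), val_loss = numeric())
    for (ep in seq_len(epochs)) {
      ord <- tr_idx[sample.int(length(tr_idx))]
      starts <- seq(1L, length(ord), by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- ord[s:min(s + batch_size - 1L, length(ord))]
        fwd <- .mlp_forward(X[b, , drop = FALSE], layers, acts, dropout,
                            training = TRUE)
        lo <- .mlp_loss(fwd, Y[b, , drop = FALSE], loss, sample_w[b])
        if (!is.finite(lo$value))
          stop(sprintf("non-finite training loss at epoch %d", ep),
               call. = FALSE)
        grads <- .mlp_backward(fwd, layers, acts, dropout, lo$delta)
        upd <- .adam_step(layers, grads, state, lr)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + lo$value * length(b)
      }
      val_loss <- NA_real_
      if (length(val_idx) > 0) {
        fwd <- .mlp_forward(X[val_idx, , drop = FALSE], layers, acts,
                            training = FALSE)
        val_loss <- .mlp_loss(fwd, Y[val_idx, , drop = FALSE], loss,
                              sample_w[val_idx])$value
      }
      hist <- rbind(hist, data.frame(phase = phase_name, epoch = ep,
                                     train_loss = ep_loss / length(ord),
                                     val_loss = val_loss))
    }
    list(layers = layers, history = hist)
  })
}
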