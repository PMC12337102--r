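# Parameter containers, Adam, and training loops for the compiled recurrent
# networks in src/nets.cpp. All randomness flows through R's RNG so that a
# single seed makes training bit-reproducible on CPU.

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Initialize a stacked-LSTM frame classifier
#'
#' Three (by default) unidirectional LSTM layers followed by one fully
#' connected softmax layer, the architecture used for streaming speech
#' detection. Weights are Glorot-uniform; forget-gate biases start at 1.
#'
#' @param n_in number of input features
#' @param hidden hidden units per layer
#' @param n_layers number of LSTM layers
#' @param n_class output classes
#' @param seed RNG seed for the draw
#' @return a list of parameters understood by the compiled forward/backward
#' @export
init_lstm_net <- function(n_in, hidden, n_layers = 3, n_class = 5, seed = 1) {
  with_seed(seed, {
    layers <- vector("list", n_layers)
    fin <- n_in
    for (l in seq_len(n_layers)) {
      b <- rep(0, 4 * hidden)
      b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
      layers[[l]] <- list(W = glorot(4 * hidden, fin),
                          U = glorot(4 * hidden, hidden), b = b)
      fin <- hidden
    }
    list(layers = layers, Wy = glorot(n_class, hidden), by = rep(0, n_class))
  })
}

#' Initialize a conv + GRU sequence classifier
#'
#' One 1-D temporal convolution (ReLU), a stack of GRU layers, and a fully
#' connected softmax head read from the final hidden state -- the
#' architecture used for speech verification and word classification.
#'
#' @param n_in input features per time step
#' @param conv_channels,kern,stride convolution shape
#' @param hidden,n_layers GRU shape
#' @param n_class output classes
#' @param seed RNG seed
#' @param gate_bias initial GRU update-gate bias; positive values start the
#'   network with long memory so evidence early in the window survives to the
#'   final-state readout
#' @export
init_seqnet <- function(n_in, conv_channels = 32, kern = 5, stride = 1,
                        hidden = 64, n_layers = 2, n_class = 3, seed = 1,
                        gate_bias = 2) {
  with_seed(seed, {
    glayers <- vector("list", n_layers)
    fin <- conv_channels
    for (l in seq_len(n_layers)) {
      b <- rep(0, 3 * hidden)
      b[(hidden + 1):(2 * hidden)] <- gate_bias
      glayers[[l]] <- list(W = glorot(3 * hidden, fin),
                           U = glorot(3 * hidden, hidden), b = b)
      fin <- hidden
    }
    list(Wc = glorot(conv_channels, n_in * kern), bc = rep(0, conv_channels),
         kern = as.integer(kern), stride = as.integer(stride),
         glayers = glayers, Wy = glorot(n_class, hidden), by = rep(0, n_class))
  })
}

# ---- Adam over nested lists of numeric arrays -------------------------------

leaves_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) out[[k]] <- leaves_map2(a[[k]], b[[k]], f)
    out
  } else if (is.numeric(a) && length(a) > 1 || is.matrix(a)) {
    f(a, b)
  } else a  # scalars (kern, stride) pass through
}

adam_new <- function(params) {
  zero <- function(x, y) x * 0
  list(m = leaves_map2(params, params, zero),
       v = leaves_map2(params, params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- leaves_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- leaves_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- leaves_map2(state$m, state$v,
                     function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- leaves_map2(params, upd, function(p, u) p - u)
  if (weight_decay > 0) {
    # decoupled decay on weight matrices only (biases are plain vectors)
    decay <- function(p, u) if (is.matrix(p)) p * (1 - lr * weight_decay) else p
    params <- leaves_map2(params, params, decay)
  }
  list(params = params, state = state)
}

# align a gradient list (from C++) onto the parameter structure of a seqnet,
# inserting zero entries for the non-trainable kern/stride slots
seqnet_grad_shape <- function(params, g) {
  list(Wc = g$Wc, bc = as.numeric(g$bc), kern = params$kern,
       stride = params$stride, glayers = g$layers, Wy = g$Wy,
       by = as.numeric(g$by))
}

lstm_grad_shape <- function(params, g) {
  list(layers = g$layers, Wy = g$Wy, by = as.numeric(g$by))
}

# ---- training loops ---------------------------------------------------------

# X: array (F, B, T); Y, mask: (T, B)
train_lstm_net <- function(params, X, Y, mask, epochs = 30, lr = 1e-3,
                           batch_size = 8, seed = 1, weight_decay = 0) {
  st <- adam_new(params)
  nb <- dim(X)[2]
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nb)
      groups <- split(ord, ceiling(seq_along(ord) / batch_size))
      tot <- 0
      for (g in groups) {
        r <- cpp_lstm_run(params$layers, params$Wy, params$by,
                          X[, g, , drop = FALSE], Y[, g, drop = FALSE],
                          mask[, g, drop = FALSE], TRUE, FALSE, FALSE)
        upd <- adam_step(params, lstm_grad_shape(params, r$grads), st, lr,
                         weight_decay = weight_decay)
        params <- upd$params
        st <- upd$state
        tot <- tot + r$loss * length(g)
      }
      losses[ep] <- tot / nb
    }
  })
  list(params = params, losses = losses)
}

# X: array (F, B, T); y: integer vector length B (1..C)
train_seqnet <- function(params, X, y, epochs = 30, lr = 1e-3, batch_size = 16,
                         seed = 1, X_val = NULL, y_val = NULL, patience = 5,
                         weight_decay = 0) {
  st <- adam_new(params)
  nb <- dim(X)[2]
  best <- list(loss = Inf, params = params)
  wait <- 0L
  losses <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nb)
      groups <- split(ord, ceiling(seq_along(ord) / batch_size))
      tot <- 0
      for (g in groups) {
        r <- cpp_seqnet_run(params$Wc, params$bc, params$kern, params$stride,
                            params$glayers, params$Wy, params$by,
                            X[, g, , drop = FALSE], y[g], TRUE, FALSE)
        upd <- adam_step(params, seqnet_grad_shape(params, r$grads), st, lr,
                         weight_decay = weight_decay)
        params <- upd$params
        st <- upd$state
        tot <- tot + r$loss * length(g)
      }
      losses <- c(losses, tot / nb)
      if (!is.null(X_val)) {
        vr <- cpp_seqnet_run(params$Wc, params$bc, params$kern, params$stride,
                             params$glayers, params$Wy, params$by,
                             X_val, y_val, FALSE, FALSE)
        if (vr$loss < best$loss - 1e-6) {
          best <- list(loss = vr$loss, params = params)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      }
    }
  })
  if (!is.null(X_val) && is.finite(best$loss)) params <- best$params
  list(params = params, losses = losses)
}

seqnet_probs <- function(params, X) {
  r <- cpp_seqnet_run(params$Wc, params$bc, params$kern, params$stride,
                      params$glayers, params$Wy, params$by, X,
                      rep(0L, dim(X)[2]), FALSE, FALSE)
  r$probs  # C x B
}

seqnet_input_grad <- function(params, X, y) {
  r <- cpp_seqnet_run(params$Wc, params$bc, params$kern, params$stride,
                      params$glayers, params$Wy, params$by, X,
                      as.integer(y), FALSE, TRUE)
  r$dX  # F x B x T
}

lstm_probs <- function(params, X) {
  TT <- dim(X)[3]
  B <- dim(X)[2]
  zero <- matrix(0L, TT, B)
  r <- cpp_lstm_run(params$layers, params$Wy, params$by, X, zero, zero,
                    FALSE, FALSE, TRUE)
  r$probs  # C x B x T
}

lstm_input_grad <- function(params, X, Y, mask) {
  r <- cpp_lstm_run(params$layers, params$Wy, params$by, X,
                    Y, mask, FALSE, TRUE, FALSE)
  r$dX
}
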