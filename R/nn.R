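# Native neural-network engine: a small multilayer perceptron and a stacked
# LSTM with vectorised mini-batch backpropagation(-through-time) and Adam.
# Gate order throughout: input, forget, cell (g), output.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- MLP (the DNN family) --------------------------------------------------

mlp_init <- function(d_in, layers) {
  dims <- c(d_in, layers)
  params <- list()
  for (l in seq_along(layers)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, dims[l + 1])
  }
  params
}

mlp_forward <- function(params, X, activation = "sigmoid", dropout = 0,
                        training = FALSE) {
  n_layers <- length(params) / 2
  act_fn <- switch(activation, sigmoid = sigmoid, tanh = tanh,
                   relu = function(x) pmax(x, 0))
  a <- X
  cache <- list(a0 = X, masks = list())
  for (l in seq_len(n_layers)) {
    z <- a %*% params[[paste0("W", l)]] +
      matrix(params[[paste0("b", l)]], nrow(a), ncol(params[[paste0("W", l)]]),
             byrow = TRUE)
    a <- if (l == n_layers) sigmoid(z) else act_fn(z)
    if (training && dropout > 0 && l < n_layers) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                     nrow(a), ncol(a))
      a <- a * mask
      cache$masks[[l]] <- mask
    }
    cache[[paste0("z", l)]] <- z
    cache[[paste0("a", l)]] <- a
  }
  list(out = a, cache = cache)
}

mlp_backward <- function(params, cache, dy, activation = "sigmoid") {
  n_layers <- length(params) / 2
  dact <- switch(activation,
    sigmoid = function(z, a) a * (1 - a),
    tanh = function(z, a) 1 - a^2,
    relu = function(z, a) (z > 0) * 1)
  grads <- list()
  da <- dy  # gradient wrt pre-sigmoid logit supplied directly by caller
  for (l in rev(seq_len(n_layers))) {
    a_prev <- cache[[paste0("a", l - 1)]] %||% cache$a0
    dz <- if (l == n_layers) {
      da  # caller passes dL/dz for the output layer (BCE + sigmoid)
    } else {
      mask <- if (length(cache$masks) >= l) cache$masks[[l]] else NULL
      dai <- if (!is.null(mask)) da * mask else da
      dai * dact(cache[[paste0("z", l)]],
                 if (!is.null(mask)) {
                   cache[[paste0("a", l)]] / mask_safe(mask)
                 } else {
                   cache[[paste0("a", l)]]
                 })
    }
    grads[[paste0("W", l)]] <- crossprod(a_prev, dz)
    grads[[paste0("b", l)]] <- matrix(colSums(dz), 1)
    da <- dz %*% t(params[[paste0("W", l)]])
  }
  grads
}

mask_safe <- function(mask) {
  mask[mask == 0] <- 1
  mask
}

mlp_train <- function(X, y, layers, activation = "sigmoid", dropout = 0,
                      batch_size = 44, epochs = 100, lr = 1e-3, seed = NULL) {
  with_seed(seed, {
    params <- mlp_init(ncol(X), layers)
    st <- adam_init(params)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1, n)]
        fwd <- mlp_forward(params, X[b, , drop = FALSE], activation,
                           dropout, training = TRUE)
        dz <- (fwd$out - y[b]) / length(b)  # BCE with sigmoid output
        grads <- mlp_backward(params, fwd$cache, dz, activation)
        upd <- adam_step(params, grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
      }
    }
    list(params = params, layers = layers, activation = activation)
  })
}

mlp_predict <- function(model, X) {
  as.numeric(mlp_forward(model$params, X, model$activation)$out)
}

# ---- stacked LSTM ----------------------------------------------------------

lstm_init <- function(d_in, hidden) {
  dims <- c(d_in, hidden)
  params <- list()
  for (l in seq_along(hidden)) {
    H <- hidden[l]
    params[[paste0("Wx", l)]] <- glorot(dims[l], 4 * H)
    params[[paste0("Wh", l)]] <- glorot(H, 4 * H)
    b <- matrix(0, 1, 4 * H)
    b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
    params[[paste0("b", l)]] <- b
  }
  params$w_out <- glorot(hidden[length(hidden)], 1)
  params$b_out <- matrix(0, 1, 1)
  params
}

# X: B x L x d array. Returns probabilities and (optionally) full caches.
lstm_forward <- function(params, X, hidden, keep_cache = FALSE) {
  B <- dim(X)[1]; L <- dim(X)[2]
  n_lay <- length(hidden)
  h <- purrr::map(hidden, ~ matrix(0, B, .x))
  cc <- purrr::map(hidden, ~ matrix(0, B, .x))
  cache <- if (keep_cache) {
    purrr::map(seq_len(n_lay), ~ vector("list", L))
  }
  for (t in seq_len(L)) {
    inp <- matrix(X[, t, ], nrow = B)
    for (l in seq_len(n_lay)) {
      H <- hidden[l]
      A <- inp %*% params[[paste0("Wx", l)]] +
        h[[l]] %*% params[[paste0("Wh", l)]] +
        matrix(params[[paste0("b", l)]], B, 4 * H, byrow = TRUE)
      i_g <- sigmoid(A[, 1:H, drop = FALSE])
      f_g <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
      g_g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
      o_g <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cc[[l]]
      cc[[l]] <- f_g * c_prev + i_g * g_g
      tc <- tanh(cc[[l]])
      h_prev <- h[[l]]
      h[[l]] <- o_g * tc
      if (keep_cache) {
        cache[[l]][[t]] <- list(x = inp, h_prev = h_prev, c_prev = c_prev,
                                i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
      }
      inp <- h[[l]]
    }
  }
  logit <- h[[n_lay]] %*% params$w_out +
    matrix(params$b_out, B, 1, byrow = TRUE)
  list(prob = as.numeric(sigmoid(logit)), h_last = h[[n_lay]], cache = cache)
}

lstm_backward <- function(params, X, hidden, fwd, dlogit) {
  B <- dim(X)[1]; L <- dim(X)[2]
  n_lay <- length(hidden)
  grads <- purrr::map(params, ~ .x * 0)
  grads$w_out <- crossprod(fwd$h_last, dlogit)
  grads$b_out <- matrix(sum(dlogit), 1, 1)

  dh <- purrr::map(hidden, ~ matrix(0, B, .x))
  dc <- purrr::map(hidden, ~ matrix(0, B, .x))
  dh[[n_lay]] <- dlogit %*% t(params$w_out)

  for (t in rev(seq_len(L))) {
    dx_below <- NULL  # gradient into the next-lower layer's output at time t
    for (l in rev(seq_len(n_lay))) {
      ch <- fwd$cache[[l]][[t]]
      H <- hidden[l]
      dht <- dh[[l]]
      if (!is.null(dx_below)) dht <- dht + dx_below
      do <- dht * ch$tc
      dct <- dc[[l]] + dht * ch$o * (1 - ch$tc^2)
      di <- dct * ch$g
      dg <- dct * ch$i
      df <- dct * ch$c_prev
      dc[[l]] <- dct * ch$f
      dA <- cbind(di * ch$i * (1 - ch$i),
                  df * ch$f * (1 - ch$f),
                  dg * (1 - ch$g^2),
                  do * ch$o * (1 - ch$o))
      grads[[paste0("Wx", l)]] <- grads[[paste0("Wx", l)]] +
        crossprod(ch$x, dA)
      grads[[paste0("Wh", l)]] <- grads[[paste0("Wh", l)]] +
        crossprod(ch$h_prev, dA)
      grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + colSums(dA)
      dh[[l]] <- dA %*% t(params[[paste0("Wh", l)]])
      dx_below <- if (l > 1) dA %*% t(params[[paste0("Wx", l)]]) else NULL
    }
  }
  grads
}

lstm_train <- function(X, y, hidden = c(4, 4), batch_size = 4, epochs = 1,
                       lr = 1e-3, seed = NULL) {
  with_seed(seed, {
    params <- lstm_init(dim(X)[3], hidden)
    st <- adam_init(params)
    n <- dim(X)[1]
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1, n)]
        Xb <- X[b, , , drop = FALSE]
        fwd <- lstm_forward(params, Xb, hidden, keep_cache = TRUE)
        dlogit <- matrix((fwd$prob - y[b]) / length(b), ncol = 1)
        grads <- lstm_backward(params, Xb, hidden, fwd, dlogit)
        upd <- adam_step(params, grads, st, lr = lr)
        params <- upd$params
        st <- upd$state
      }
    }
    list(params = params, hidden = hidden)
  })
}

lstm_predict <- function(model, X) {
  lstm_forward(model$params, X, model$hidden)$prob
}
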