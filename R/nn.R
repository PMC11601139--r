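# Native recurrent-network internals for the ADR post classifier.
#
# All layers are implemented directly with base-R matrix algebra: embedding
# lookup, unidirectional LSTM / GRU cells run in both directions, an optional
# 1-D convolution + max-pool front end, a sigmoid output unit, binary
# cross-entropy, backpropagation through time, and Adam. Gradients are
# checked against finite differences in the test suite.
#
# Index convention: token ids are 0-based (0 = padding, 1 = OOV, terms >= 2);
# embedding row in R is id + 1. The padding row of the embedding matrix is
# held at zero and never updated.

nn_init_params <- function(arch, vocab_size, embedding_dim, hidden_units,
                           cnn_filters = 128L, seed = 1, init_E = NULL) {
  set.seed(seed)
  d <- embedding_dim; H <- hidden_units
  rmat <- function(r, c, sc) matrix(stats::runif(r * c, -sc, sc), r, c)
  E <- rmat(vocab_size, d, 0.5 / d)
  E[1, ] <- 0  # padding row
  if (!is.null(init_E)) {
    stopifnot(ncol(init_E) == d)
    rows <- which(!is.na(init_E[, 1, drop = TRUE]))
    E[rows, ] <- init_E[rows, , drop = FALSE]
    E[1, ] <- 0
  }
  rnn_in <- if (arch == "cnn_bilstm") cnn_filters else d
  gates <- if (arch == "gru") 3L else 4L
  sc_x <- sqrt(1 / rnn_in); sc_h <- sqrt(1 / H)
  dir_params <- function() {
    b <- numeric(gates * H)
    # LSTM forget-gate bias starts at 1 so memory survives early training
    if (gates == 4L) b[(H + 1):(2 * H)] <- 1
    list(Wx = rmat(rnn_in, gates * H, sc_x),
         Wh = rmat(H, gates * H, sc_h), b = b)
  }
  p <- list(E = E, fwd = dir_params(), bwd = dir_params(),
            out = list(w = rmat(2 * H, 1, sc_h), b = 0))
  if (arch == "cnn_bilstm")
    p$conv <- list(Wc = rmat(3 * d, cnn_filters, sqrt(1 / (3 * d))),
                   bc = numeric(cnn_filters))
  p
}

# ---- recurrent cells ------------------------------------------------------

# X: list of T matrices n x d_in; M: list of T mask vectors (1 = real token,
# 0 = padding; state is carried through masked steps unchanged, the standard
# sequence-masking behaviour). Returns final hidden state and caches.
rnn_dir_forward <- function(X, prm, type, M = NULL) {
  T_ <- length(X); n <- nrow(X[[1]]); H <- nrow(prm$Wh)
  if (is.null(M)) M <- rep(list(rep(1, n)), T_)
  h <- matrix(0, n, H); c <- matrix(0, n, H)
  cache <- vector("list", T_)
  if (type == "lstm") {
    for (t in seq_len(T_)) {
      m <- M[[t]]
      A <- X[[t]] %*% prm$Wx + h %*% prm$Wh +
        matrix(prm$b, n, 4 * H, byrow = TRUE)
      i <- sigmoid(A[, 1:H, drop = FALSE])
      f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
      o <- sigmoid(A[, (2 * H + 1):(3 * H), drop = FALSE])
      g <- tanh(A[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- f * c + i * g
      tc <- tanh(c_new)
      cache[[t]] <- list(i = i, f = f, o = o, g = g, c_prev = c, tc = tc,
                         h_prev = h, m = m)
      c <- m * c_new + (1 - m) * c
      h <- m * (o * tc) + (1 - m) * h
    }
  } else {  # gru: h' = z * h_prev + (1 - z) * n
    for (t in seq_len(T_)) {
      m <- M[[t]]
      pre_zr <- X[[t]] %*% prm$Wx[, 1:(2 * H), drop = FALSE] +
        h %*% prm$Wh[, 1:(2 * H), drop = FALSE] +
        matrix(prm$b[1:(2 * H)], n, 2 * H, byrow = TRUE)
      z <- sigmoid(pre_zr[, 1:H, drop = FALSE])
      r <- sigmoid(pre_zr[, (H + 1):(2 * H), drop = FALSE])
      rh <- r * h
      nn <- tanh(X[[t]] %*% prm$Wx[, (2 * H + 1):(3 * H), drop = FALSE] +
                   rh %*% prm$Wh[, (2 * H + 1):(3 * H), drop = FALSE] +
                   matrix(prm$b[(2 * H + 1):(3 * H)], n, H, byrow = TRUE))
      cache[[t]] <- list(z = z, r = r, n = nn, rh = rh, h_prev = h, m = m)
      h <- m * (z * h + (1 - z) * nn) + (1 - m) * h
    }
  }
  list(h_last = h, cache = cache)
}

rnn_dir_backward <- function(dh_last, X, prm, cache, type) {
  T_ <- length(X); n <- nrow(X[[1]]); H <- nrow(prm$Wh)
  dWx <- matrix(0, nrow(prm$Wx), ncol(prm$Wx))
  dWh <- matrix(0, H, ncol(prm$Wh))
  db <- numeric(length(prm$b))
  dX <- vector("list", T_)
  dh <- dh_last
  dc <- matrix(0, n, H)
  if (type == "lstm") {
    for (t in rev(seq_len(T_))) {
      cc <- cache[[t]]
      m <- cc$m
      dh_new <- m * dh                 # gradient reaching this step's update
      dc_new <- m * dc + dh_new * cc$o * (1 - cc$tc^2)
      do_ <- dh_new * cc$tc
      di <- dc_new * cc$g
      dg <- dc_new * cc$i
      df <- dc_new * cc$c_prev
      dA <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dg * (1 - cc$g^2))
      dWx <- dWx + crossprod(X[[t]], dA)
      dWh <- dWh + crossprod(cc$h_prev, dA)
      db <- db + colSums(dA)
      dX[[t]] <- dA %*% t(prm$Wx)
      dh <- dA %*% t(prm$Wh) + (1 - m) * dh
      dc <- dc_new * cc$f + (1 - m) * dc
    }
  } else {
    Wh_n <- prm$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
    Wx_n <- prm$Wx[, (2 * H + 1):(3 * H), drop = FALSE]
    Wh_zr <- prm$Wh[, 1:(2 * H), drop = FALSE]
    Wx_zr <- prm$Wx[, 1:(2 * H), drop = FALSE]
    for (t in rev(seq_len(T_))) {
      cc <- cache[[t]]
      m <- cc$m
      dh_new <- m * dh
      dz <- dh_new * (cc$h_prev - cc$n)
      dn <- dh_new * (1 - cc$z)
      dh_prev <- dh_new * cc$z + (1 - m) * dh
      dpre_n <- dn * (1 - cc$n^2)
      dWx[, (2 * H + 1):(3 * H)] <- dWx[, (2 * H + 1):(3 * H)] +
        crossprod(X[[t]], dpre_n)
      dWh[, (2 * H + 1):(3 * H)] <- dWh[, (2 * H + 1):(3 * H)] +
        crossprod(cc$rh, dpre_n)
      db[(2 * H + 1):(3 * H)] <- db[(2 * H + 1):(3 * H)] + colSums(dpre_n)
      drh <- dpre_n %*% t(Wh_n)
      dr <- drh * cc$h_prev
      dh_prev <- dh_prev + drh * cc$r
      dx <- dpre_n %*% t(Wx_n)
      dpre_zr <- cbind(dz * cc$z * (1 - cc$z), dr * cc$r * (1 - cc$r))
      dWx[, 1:(2 * H)] <- dWx[, 1:(2 * H)] + crossprod(X[[t]], dpre_zr)
      dWh[, 1:(2 * H)] <- dWh[, 1:(2 * H)] + crossprod(cc$h_prev, dpre_zr)
      db[1:(2 * H)] <- db[1:(2 * H)] + colSums(dpre_zr)
      dh_prev <- dh_prev + dpre_zr %*% t(Wh_zr)
      dX[[t]] <- dx + dpre_zr %*% t(Wx_zr)
      dh <- dh_prev
    }
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dX = dX)
}

# ---- convolution front end (width-3 same-padded conv + width-2 max pool) --

conv_pool_forward <- function(X, conv) {
  T_ <- length(X); n <- nrow(X[[1]]); d <- ncol(X[[1]])
  zero <- matrix(0, n, d)
  A <- vector("list", T_)
  cache_cat <- vector("list", T_)
  for (t in seq_len(T_)) {
    xc <- cbind(if (t > 1) X[[t - 1]] else zero, X[[t]],
                if (t < T_) X[[t + 1]] else zero)
    pre <- xc %*% conv$Wc + matrix(conv$bc, n, ncol(conv$Wc), byrow = TRUE)
    A[[t]] <- pmax(pre, 0)
    cache_cat[[t]] <- xc
  }
  Tp <- ceiling(T_ / 2)
  P <- vector("list", Tp)
  take_right <- vector("list", Tp)  # TRUE where the right member won the max
  for (j in seq_len(Tp)) {
    l <- 2 * j - 1; r <- min(2 * j, T_)
    if (r > l) {
      right_wins <- A[[r]] >= A[[l]]
      P[[j]] <- ifelse(right_wins, A[[r]], A[[l]])
      take_right[[j]] <- right_wins
    } else {
      P[[j]] <- A[[l]]
      take_right[[j]] <- NULL
    }
  }
  list(P = P, A = A, cache_cat = cache_cat, take_right = take_right, T_ = T_)
}

conv_pool_backward <- function(dP, fwd, conv) {
  T_ <- fwd$T_; n <- nrow(dP[[1]]); d3 <- nrow(conv$Wc); d <- d3 / 3
  dA <- rep(list(matrix(0, n, ncol(conv$Wc))), T_)
  for (j in seq_along(dP)) {
    l <- 2 * j - 1; r <- min(2 * j, T_)
    if (r > l) {
      tr <- fwd$take_right[[j]]
      dA[[r]] <- dA[[r]] + dP[[j]] * tr
      dA[[l]] <- dA[[l]] + dP[[j]] * !tr
    } else {
      dA[[l]] <- dA[[l]] + dP[[j]]
    }
  }
  dWc <- matrix(0, d3, ncol(conv$Wc))
  dbc <- numeric(ncol(conv$Wc))
  dX <- rep(list(matrix(0, n, d)), T_)
  for (t in seq_len(T_)) {
    dpre <- dA[[t]] * (fwd$A[[t]] > 0)
    dWc <- dWc + crossprod(fwd$cache_cat[[t]], dpre)
    dbc <- dbc + colSums(dpre)
    dcat <- dpre %*% t(conv$Wc)
    if (t > 1) dX[[t - 1]] <- dX[[t - 1]] + dcat[, 1:d, drop = FALSE]
    dX[[t]] <- dX[[t]] + dcat[, (d + 1):(2 * d), drop = FALSE]
    if (t < T_) dX[[t + 1]] <- dX[[t + 1]] + dcat[, (2 * d + 1):(3 * d), drop = FALSE]
  }
  list(grads = list(Wc = dWc, bc = dbc), dX = dX)
}

# ---- full model -----------------------------------------------------------

cell_type <- function(arch) if (arch == "gru") "gru" else "lstm"

# ids: n x T integer matrix of 0-based token indices.
nn_forward <- function(ids, params, arch, dropout = 0, train_mode = FALSE) {
  n <- nrow(ids); T_ <- ncol(ids)
  X <- lapply(seq_len(T_), function(t)
    params$E[ids[, t] + 1L, , drop = FALSE])
  cache <- list(X = X, ids = ids)
  M <- lapply(seq_len(T_), function(t) as.numeric(ids[, t] != 0L))
  R_in <- X
  if (arch == "cnn_bilstm") {
    cache$conv <- conv_pool_forward(X, params$conv)
    R_in <- cache$conv$P
    # a pooled step is real if either member of its window is
    M <- lapply(seq_along(R_in), function(j) {
      l <- 2 * j - 1; r <- min(2 * j, T_)
      pmax(M[[l]], M[[r]])
    })
  }
  ct <- cell_type(arch)
  cache$R_in <- R_in
  cache$fwd <- rnn_dir_forward(R_in, params$fwd, ct, M)
  cache$bwd <- rnn_dir_forward(rev(R_in), params$bwd, ct, rev(M))
  rep_ <- cbind(cache$fwd$h_last, cache$bwd$h_last)
  if (train_mode && dropout > 0) {
    mask <- matrix(stats::rbinom(length(rep_), 1, 1 - dropout), nrow(rep_)) /
      (1 - dropout)
    rep_ <- rep_ * mask
    cache$drop_mask <- mask
  }
  cache$rep <- rep_
  z <- as.vector(rep_ %*% params$out$w) + params$out$b
  p <- sigmoid(z)
  list(p = p, cache = cache)
}

nn_backward <- function(y, p, cache, params, arch, freeze_embeddings = FALSE) {
  n <- length(y)
  dz <- matrix((p - y) / n, ncol = 1)  # BCE + sigmoid
  g <- list(out = list(w = crossprod(cache$rep, dz), b = sum(dz)))
  drep <- dz %*% t(params$out$w)
  if (!is.null(cache$drop_mask)) drep <- drep * cache$drop_mask
  H <- ncol(cache$fwd$h_last)
  ct <- cell_type(arch)
  bf <- rnn_dir_backward(drep[, 1:H, drop = FALSE], cache$R_in,
                         params$fwd, cache$fwd$cache, ct)
  bb <- rnn_dir_backward(drep[, (H + 1):(2 * H), drop = FALSE], rev(cache$R_in),
                         params$bwd, cache$bwd$cache, ct)
  g$fwd <- bf$grads
  g$bwd <- bb$grads
  dR <- Map(`+`, bf$dX, rev(bb$dX))
  if (arch == "cnn_bilstm") {
    cb <- conv_pool_backward(dR, cache$conv, params$conv)
    g$conv <- cb$grads
    dX <- cb$dX
  } else {
    dX <- dR
  }
  if (!freeze_embeddings) {
    rows <- as.vector(cache$ids) + 1L
    flat <- do.call(rbind, dX)
    dEacc <- rowsum(flat, group = rows)
    dE <- matrix(0, nrow(params$E), ncol(params$E))
    ri <- as.integer(rownames(dEacc))
    dE[ri, ] <- dEacc
    dE[1, ] <- 0  # padding row frozen
    g$E <- dE
  }
  g
}

nn_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
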