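# Single-layer LSTM with a 4-way softmax readout, written in base R matrix
# ops. Gate order in the stacked weight blocks: input (i), forget (f),
# candidate (g), output (o). Batches are N x D per time step; the readout
# uses the final hidden state only.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.lstm_init <- function(input_dim, hidden, n_out = 4L) {
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  b <- rep(0, 4 * hidden)
  b[hidden + seq_len(hidden)] <- 1   # forget-gate bias at 1
  list(W = gl(input_dim, 4 * hidden),
       U = gl(hidden, 4 * hidden),
       b = b,
       Wy = gl(hidden, n_out),
       by = rep(0, n_out))
}

# X: list of T matrices (N x D). Returns probs (N x 4) and, if keep_cache,
# the per-step activations needed for backprop.
.lstm_forward <- function(par, X, keep_cache = FALSE) {
  H <- ncol(par$U)
  h_units <- nrow(par$U)
  N <- nrow(X[[1]])
  Tn <- length(X)
  ii <- seq_len(h_units)
  fi <- h_units + ii
  gi <- 2 * h_units + ii
  oi <- 3 * h_units + ii
  h <- matrix(0, N, h_units)
  cc <- matrix(0, N, h_units)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    z <- X[[t]] %*% par$W + h %*% par$U
    z <- sweep(z, 2, par$b, "+")
    i_g <- .sigmoid(z[, ii, drop = FALSE])
    f_g <- .sigmoid(z[, fi, drop = FALSE])
    g_g <- tanh(z[, gi, drop = FALSE])
    o_g <- .sigmoid(z[, oi, drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    if (keep_cache) {
      cache[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                         c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
    }
  }
  logits <- sweep(h %*% par$Wy, 2, par$by, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, h = h, cache = cache)
}

# y: integer class labels in 1..n_out. Returns mean cross-entropy loss and
# gradients for every parameter.
.lstm_backward <- function(par, X, y, fwd) {
  N <- nrow(fwd$probs)
  h_units <- nrow(par$U)
  Tn <- length(X)
  ii <- seq_len(h_units)
  fi <- h_units + ii
  gi <- 2 * h_units + ii
  oi <- 3 * h_units + ii

  dlogits <- fwd$probs
  dlogits[cbind(seq_len(N), y)] <- dlogits[cbind(seq_len(N), y)] - 1
  dlogits <- dlogits / N
  gWy <- crossprod(fwd$h, dlogits)
  gby <- colSums(dlogits)
  dh <- tcrossprod(dlogits, par$Wy)

  gW <- matrix(0, nrow(par$W), ncol(par$W))
  gU <- matrix(0, h_units, 4 * h_units)
  gb <- rep(0, 4 * h_units)
  dc <- matrix(0, N, h_units)
  for (t in rev(seq_len(Tn))) {
    ch <- fwd$cache[[t]]
    do <- dh * ch$tc
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    df <- dc * ch$c_prev
    dg <- dc * ch$i
    dz <- cbind(di * ch$i * (1 - ch$i),
                df * ch$f * (1 - ch$f),
                dg * (1 - ch$g^2),
                do * ch$o * (1 - ch$o))
    gW <- gW + crossprod(X[[t]], dz)
    gU <- gU + crossprod(ch$h_prev, dz)
    gb <- gb + colSums(dz)
    dh <- tcrossprod(dz, par$U)
    dc <- dc * ch$f
  }
  list(W = gW, U = gU, b = gb, Wy = gWy, by = gby)
}

.lstm_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y)], 1e-12)))
}

.adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(par, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, st = st)
}
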