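# Minimal convolutional network machinery: im2col convolution with explicit
# forward/backward passes and an Adam optimizer. Written in base matrix
# algebra; sized for the compact desk-scale network this package trains.

conv_geom <- function(H, W, C, k, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  di <- rep(seq_len(k), times = k * C)
  dj <- rep(rep(seq_len(k), each = k), times = C)
  ch <- rep(seq_len(C), each = k * k)
  rowpart <- di + (dj - 1L) * Hp + (ch - 1L) * Hp * Wp
  i0 <- (seq_len(Ho) - 1L) * stride
  j0 <- (seq_len(Wo) - 1L) * stride
  colpart <- rep(i0, times = Wo) + rep(j0, each = Ho) * Hp
  idx <- outer(rowpart, colpart, "+")
  inner <- as.vector(outer(
    rep(seq_len(H) + pad, times = W) +
      rep((seq_len(W) + pad - 1L) * Hp, each = H),
    (seq_len(C) - 1L) * Hp * Wp, "+"
  ))
  list(H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx, inner = inner)
}

pad_input <- function(x, geom) {
  xp <- numeric(geom$Hp * geom$Wp * geom$C)
  xp[geom$inner] <- as.vector(x)
  xp
}

conv_forward <- function(x, Wmat, b, geom) {
  xp <- pad_input(x, geom)
  cols <- matrix(xp[geom$idx], nrow = nrow(geom$idx))
  out <- Wmat %*% cols + b
  list(out = array(t(out), c(geom$Ho, geom$Wo, nrow(Wmat))), cols = cols)
}

conv_backward <- function(dout, Wmat, cols, geom) {
  P <- geom$Ho * geom$Wo
  dmat <- t(matrix(dout, P, nrow(Wmat)))
  dW <- dmat %*% t(cols)
  db <- rowSums(dmat)
  dcols <- crossprod(Wmat, dmat)
  dxp <- numeric(geom$Hp * geom$Wp * geom$C)
  for (r in seq_len(nrow(geom$idx))) {
    pos <- geom$idx[r, ]
    dxp[pos] <- dxp[pos] + dcols[r, ]
  }
  list(dx = array(dxp[geom$inner], c(geom$H, geom$W, geom$C)),
       dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)

he_init <- function(n_out, n_in) {
  matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("^W", nm)) g <- g + weight_decay * params[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
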