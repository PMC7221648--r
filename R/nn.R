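# Internal network numerics: forward pass with caching, hand-derived
# backward pass, loss heads and the Adam optimizer. Everything is plain
# double-precision matrix algebra; sequences are processed one at a time
# (rows = positions, columns = hidden channels).

.affine <- function(X, W, b) {
  X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
}

.softmax_rows <- function(Z) {
  # max.col is C-level; ties.method irrelevant for the max value itself
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Layer norm over the channel dimension (per row), eps 1e-12.
.ln_fwd <- function(X, g, b, eps = 1e-12) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  Y <- xhat * matrix(g, nrow(X), length(g), byrow = TRUE) +
    matrix(b, nrow(X), length(b), byrow = TRUE)
  list(Y = Y, xhat = xhat, inv = inv)
}

.ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# Inverted dropout; returns the scaled keep mask (NULL when inactive).
.dropout_mask <- function(dim, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((stats::runif(prod(dim)) >= p) / (1 - p), dim[1], dim[2])
}

.apply_mask <- function(X, mask) if (is.null(mask)) X else X * mask

# Full encoder forward. When train = TRUE, dropout is active (driven by
# the current RNG state) and all intermediates are cached for .nn_backward.
.nn_forward <- function(w, cfg, ids, train = FALSE) {
  .check_ids(cfg, ids)
  L <- length(ids)
  h <- cfg$hidden
  nh <- cfg$n_heads
  dh <- h %/% nh
  scale <- 1 / sqrt(dh)

  E <- w$tok_emb[ids + 1L, , drop = FALSE] +
    w$pos_emb[seq_len(L), , drop = FALSE]
  ln_e <- .ln_fwd(E, w$ln_emb_g, w$ln_emb_b)
  m_e <- .dropout_mask(dim(ln_e$Y), cfg$dropout, train)
  X <- .apply_mask(ln_e$Y, m_e)

  layers <- if (train) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    nm <- sprintf("l%02d_", l)
    X_in <- X
    Q <- .affine(X, w[[paste0(nm, "Wq")]], w[[paste0(nm, "bq")]])
    K <- .affine(X, w[[paste0(nm, "Wk")]], w[[paste0(nm, "bk")]])
    V <- .affine(X, w[[paste0(nm, "Wv")]], w[[paste0(nm, "bv")]])
    Ctx <- matrix(0, L, h)
    Ps <- if (train) vector("list", nh) else NULL
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      P <- .softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                    K[, cols, drop = FALSE]) * scale)
      Ctx[, cols] <- P %*% V[, cols, drop = FALSE]
      if (train) Ps[[hd]] <- P
    }
    O <- .affine(Ctx, w[[paste0(nm, "Wo")]], w[[paste0(nm, "bo")]])
    m_o <- .dropout_mask(dim(O), cfg$dropout, train)
    A1 <- X_in + .apply_mask(O, m_o)
    ln1 <- .ln_fwd(A1, w[[paste0(nm, "ln1_g")]], w[[paste0(nm, "ln1_b")]])
    X1 <- ln1$Y
    Z <- .affine(X1, w[[paste0(nm, "W1")]], w[[paste0(nm, "b1")]])
    G <- .gelu(Z)
    FF <- .affine(G, w[[paste0(nm, "W2")]], w[[paste0(nm, "b2")]])
    m_f <- .dropout_mask(dim(FF), cfg$dropout, train)
    A2 <- X1 + .apply_mask(FF, m_f)
    ln2 <- .ln_fwd(A2, w[[paste0(nm, "ln2_g")]], w[[paste0(nm, "ln2_b")]])
    X <- ln2$Y
    if (train) {
      layers[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, Ps = Ps,
                          Ctx = Ctx, m_o = m_o, ln1 = ln1, X1 = X1,
                          Z = Z, G = G, m_f = m_f, ln2 = ln2)
    }
  }
  list(X = X,
       cache = if (train) list(ids = ids, ln_e = ln_e, m_e = m_e,
                               layers = layers) else NULL)
}

# Backward through the encoder given dX at the final hidden states.
# Returns the gradient list (same names/shapes as w).
.nn_backward <- function(w, cfg, cache, dX) {
  ids <- cache$ids
  L <- length(ids)
  h <- cfg$hidden
  nh <- cfg$n_heads
  dh <- h %/% nh
  scale <- 1 / sqrt(dh)
  g <- list()

  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- sprintf("l%02d_", l)
    cc <- cache$layers[[l]]
    lb2 <- .ln_bwd(dX, cc$ln2, w[[paste0(nm, "ln2_g")]])
    g[[paste0(nm, "ln2_g")]] <- lb2$dg
    g[[paste0(nm, "ln2_b")]] <- lb2$db
    dA2 <- lb2$dX
    dX1 <- dA2
    dFF <- .apply_mask(dA2, cc$m_f)
    g[[paste0(nm, "W2")]] <- crossprod(cc$G, dFF)
    g[[paste0(nm, "b2")]] <- colSums(dFF)
    dG <- tcrossprod(dFF, w[[paste0(nm, "W2")]])
    dZ <- dG * .gelu_grad(cc$Z)
    g[[paste0(nm, "W1")]] <- crossprod(cc$X1, dZ)
    g[[paste0(nm, "b1")]] <- colSums(dZ)
    dX1 <- dX1 + tcrossprod(dZ, w[[paste0(nm, "W1")]])

    lb1 <- .ln_bwd(dX1, cc$ln1, w[[paste0(nm, "ln1_g")]])
    g[[paste0(nm, "ln1_g")]] <- lb1$dg
    g[[paste0(nm, "ln1_b")]] <- lb1$db
    dA1 <- lb1$dX
    dX_in <- dA1
    dO <- .apply_mask(dA1, cc$m_o)
    g[[paste0(nm, "Wo")]] <- crossprod(cc$Ctx, dO)
    g[[paste0(nm, "bo")]] <- colSums(dO)
    dCtx <- tcrossprod(dO, w[[paste0(nm, "Wo")]])

    dQ <- matrix(0, L, h)
    dK <- matrix(0, L, h)
    dV <- matrix(0, L, h)
    for (hd in seq_len(nh)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      P <- cc$Ps[[hd]]
      dCtx_h <- dCtx[, cols, drop = FALSE]
      Vh <- cc$V[, cols, drop = FALSE]
      dP <- tcrossprod(dCtx_h, Vh)
      dV[, cols] <- crossprod(P, dCtx_h)
      dS <- P * (dP - rowSums(dP * P))
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE] * scale
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE]) * scale
    }
    g[[paste0(nm, "Wq")]] <- crossprod(cc$X_in, dQ)
    g[[paste0(nm, "bq")]] <- colSums(dQ)
    g[[paste0(nm, "Wk")]] <- crossprod(cc$X_in, dK)
    g[[paste0(nm, "bk")]] <- colSums(dK)
    g[[paste0(nm, "Wv")]] <- crossprod(cc$X_in, dV)
    g[[paste0(nm, "bv")]] <- colSums(dV)
    dX <- dX_in + tcrossprod(dQ, w[[paste0(nm, "Wq")]]) +
      tcrossprod(dK, w[[paste0(nm, "Wk")]]) +
      tcrossprod(dV, w[[paste0(nm, "Wv")]])
  }

  dE_ln <- .apply_mask(dX, cache$m_e)
  lbe <- .ln_bwd(dE_ln, cache$ln_e, w$ln_emb_g)
  g$ln_emb_g <- lbe$dg
  g$ln_emb_b <- lbe$db
  dE <- lbe$dX

  dTok <- matrix(0, cfg$vocab, h)
  agg <- rowsum(dE, group = ids)
  dTok[as.integer(rownames(agg)) + 1L, ] <- agg
  g$tok_emb <- dTok
  dPos <- matrix(0, cfg$max_positions, h)
  dPos[seq_len(L), ] <- dE
  g$pos_emb <- dPos
  g
}

# Loss heads: forward the relevant decoder, compute mean cross-entropy and
# the gradient w.r.t. the final hidden states, then backprop. Each returns
# list(loss, grads). `mask_rows` selects the positions entering the mean.
.head_loss_grads <- function(w, cfg, fwd, W_name, b_name, targets1,
                             mask_rows) {
  X <- fwd$X
  logits <- .affine(X, w[[W_name]], w[[b_name]])
  P <- .softmax_rows(logits)
  n <- length(mask_rows)
  idx <- cbind(mask_rows, targets1[mask_rows])
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dLogits <- matrix(0, nrow(P), ncol(P))
  dLogits[mask_rows, ] <- P[mask_rows, , drop = FALSE] / n
  dLogits[idx] <- dLogits[idx] - 1 / n
  g <- .nn_backward(w, cfg, fwd$cache, tcrossprod(dLogits, w[[W_name]]))
  g[[W_name]] <- crossprod(X, dLogits)
  g[[b_name]] <- colSums(dLogits)
  list(loss = loss, grads = g)
}

.mlm_step <- function(w, cfg, ex) {
  fwd <- .nn_forward(w, cfg, ex$corrupted_ids, train = TRUE)
  .head_loss_grads(w, cfg, fwd, "decA_W", "decA_b",
                   ex$target_ids + 1L, sort(ex$mask_positions) + 1L)
}

.sel_step <- function(w, cfg, ids, labels01) {
  fwd <- .nn_forward(w, cfg, ids, train = TRUE)
  .head_loss_grads(w, cfg, fwd, "decS_W", "decS_b",
                   labels01 + 1L, seq_along(ids))
}

# --- Adam -------------------------------------------------------------

.adam_init <- function(w) {
  zero <- lapply(w, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
  list(m = zero, v = zero, t = 0L)
}

.adam_update <- function(w, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / c1) /
      (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(w = w, state = state)
}

# Sum two gradient lists (for minibatch accumulation).
.grads_add <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

.grads_scale <- function(g, s) lapply(g, function(x) x * s)
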