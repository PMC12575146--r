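# Minimal transformer encoder with analytic backpropagation.
#
# Parameters live in a flat named list of matrices/vectors; gradients use
# the same names. Batches are "packed": the sequences of a minibatch are
# stacked row-wise into one N x H matrix so all position-wise operations
# (embeddings, projections, layer norm, feed-forward) run as single matrix
# products, and only the attention matrices are computed per sequence.
# Correctness of every backward pass is pinned by finite-difference
# gradient checks in the test suite.

#' Transformer encoder configuration
#'
#' The reference configuration ships the pretraining hyperparameters used
#' for the tabular trajectory encoder: 5 hidden layers, 12 attention
#' heads, hidden size 144, intermediate size 133, 120 epochs, Adam with
#' learning rate 1e-3 and batch size 64, maximum sequence length 512.
#' Tests and examples use much smaller configurations.
#'
#' @param n_layers Number of encoder layers.
#' @param n_heads Attention heads; must divide `hidden`.
#' @param hidden Hidden size.
#' @param intermediate Feed-forward inner size.
#' @param max_len Maximum sequence length (<= 512).
#' @param learning_rate,batch_size,epochs Optimizer settings (Adam).
#' @param seed Integer seed controlling initialization, data order and
#'   masking.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 5, n_heads = 12, hidden = 144,
                           intermediate = 133, max_len = 512,
                           learning_rate = 1e-3, batch_size = 64,
                           epochs = 120, seed = 1) {
  if (hidden %% n_heads != 0) {
    stop_input("hidden (%d) must be divisible by n_heads (%d)",
               hidden, n_heads)
  }
  if (max_len > 512) stop_input("max_len must be <= 512")
  structure(
    list(n_layers = n_layers, n_heads = n_heads, hidden = hidden,
         intermediate = intermediate, max_len = max_len,
         learning_rate = learning_rate, batch_size = batch_size,
         epochs = epochs, seed = as.integer(seed)),
    class = "encoder_config"
  )
}

rmat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

addb <- function(X, b) {
  X + matrix(b, nrow(X), ncol(X), byrow = TRUE)
}

init_encoder_layers <- function(cfg) {
  H <- cfg$hidden; FF <- cfg$intermediate
  params <- list()
  for (i in seq_len(cfg$n_layers)) {
    p <- sprintf("l%d_", i)
    params[[paste0(p, "Wq")]] <- rmat(H, H)
    params[[paste0(p, "bq")]] <- numeric(H)
    params[[paste0(p, "Wk")]] <- rmat(H, H)
    params[[paste0(p, "bk")]] <- numeric(H)
    params[[paste0(p, "Wv")]] <- rmat(H, H)
    params[[paste0(p, "bv")]] <- numeric(H)
    params[[paste0(p, "Wo")]] <- rmat(H, H)
    params[[paste0(p, "bo")]] <- numeric(H)
    params[[paste0(p, "ln1_g")]] <- rep(1, H)
    params[[paste0(p, "ln1_b")]] <- numeric(H)
    params[[paste0(p, "W1")]] <- rmat(H, FF)
    params[[paste0(p, "b1")]] <- numeric(FF)
    params[[paste0(p, "W2")]] <- rmat(FF, H)
    params[[paste0(p, "b2")]] <- numeric(H)
    params[[paste0(p, "ln2_g")]] <- rep(1, H)
    params[[paste0(p, "ln2_b")]] <- numeric(H)
  }
  params
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ln_forward <- function(Z, g, b, eps = 1e-5) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  inv <- 1 / sqrt(rowMeans(Zc * Zc) + eps)
  xhat <- Zc * inv
  list(out = addb(xhat * matrix(g, nrow(Z), ncol(Z), byrow = TRUE), b),
       xhat = xhat, inv = inv)
}

ln_backward <- function(cache, g, dout) {
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- dout * matrix(g, nrow(dout), ncol(dout), byrow = TRUE)
  dz <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dz = dz, dg = dg, db = db)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Forward through the encoder stack. X is the packed input (N x H), seqs a
# list of row-index vectors, one per sequence.
encoder_forward <- function(params, cfg, X, seqs) {
  nh <- cfg$n_heads
  dh <- cfg$hidden / nh
  scale <- 1 / sqrt(dh)
  caches <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    p <- sprintf("l%d_", i)
    Q <- addb(X %*% params[[paste0(p, "Wq")]], params[[paste0(p, "bq")]])
    K <- addb(X %*% params[[paste0(p, "Wk")]], params[[paste0(p, "bk")]])
    V <- addb(X %*% params[[paste0(p, "Wv")]], params[[paste0(p, "bv")]])
    Ctx <- matrix(0, nrow(X), ncol(X))
    A_list <- vector("list", length(seqs))
    for (b in seq_along(seqs)) {
      idx <- seqs[[b]]
      A_list[[b]] <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        S <- tcrossprod(Q[idx, cols, drop = FALSE],
                        K[idx, cols, drop = FALSE]) * scale
        A <- softmax_rows(S)
        Ctx[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
        A_list[[b]][[h]] <- A
      }
    }
    O <- addb(Ctx %*% params[[paste0(p, "Wo")]], params[[paste0(p, "bo")]])
    ln1 <- ln_forward(X + O, params[[paste0(p, "ln1_g")]],
                      params[[paste0(p, "ln1_b")]])
    X1 <- ln1$out
    FF1 <- addb(X1 %*% params[[paste0(p, "W1")]], params[[paste0(p, "b1")]])
    G <- gelu(FF1)
    FF2 <- addb(G %*% params[[paste0(p, "W2")]], params[[paste0(p, "b2")]])
    ln2 <- ln_forward(X1 + FF2, params[[paste0(p, "ln2_g")]],
                      params[[paste0(p, "ln2_b")]])
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, Ctx = Ctx,
                        A = A_list, ln1 = ln1, X1 = X1, FF1 = FF1, G = G,
                        ln2 = ln2)
    X <- ln2$out
  }
  list(H = X, caches = caches)
}

# Backward through the encoder stack; returns parameter gradients and the
# gradient with respect to the packed input.
encoder_backward <- function(params, cfg, fwd, seqs, dH) {
  nh <- cfg$n_heads
  dh <- cfg$hidden / nh
  scale <- 1 / sqrt(dh)
  grads <- list()
  for (i in rev(seq_len(cfg$n_layers))) {
    p <- sprintf("l%d_", i)
    cc <- fwd$caches[[i]]
    b2 <- ln_backward(cc$ln2, params[[paste0(p, "ln2_g")]], dH)
    grads[[paste0(p, "ln2_g")]] <- b2$dg
    grads[[paste0(p, "ln2_b")]] <- b2$db
    dX1 <- b2$dz
    dFF2 <- b2$dz
    grads[[paste0(p, "W2")]] <- crossprod(cc$G, dFF2)
    grads[[paste0(p, "b2")]] <- colSums(dFF2)
    dG <- tcrossprod(dFF2, params[[paste0(p, "W2")]])
    dFF1 <- dG * gelu_grad(cc$FF1)
    grads[[paste0(p, "W1")]] <- crossprod(cc$X1, dFF1)
    grads[[paste0(p, "b1")]] <- colSums(dFF1)
    dX1 <- dX1 + tcrossprod(dFF1, params[[paste0(p, "W1")]])
    b1 <- ln_backward(cc$ln1, params[[paste0(p, "ln1_g")]], dX1)
    grads[[paste0(p, "ln1_g")]] <- b1$dg
    grads[[paste0(p, "ln1_b")]] <- b1$db
    dX <- b1$dz
    dO <- b1$dz
    grads[[paste0(p, "Wo")]] <- crossprod(cc$Ctx, dO)
    grads[[paste0(p, "bo")]] <- colSums(dO)
    dCtx <- tcrossprod(dO, params[[paste0(p, "Wo")]])
    dQ <- matrix(0, nrow(dH), ncol(dH))
    dK <- matrix(0, nrow(dH), ncol(dH))
    dV <- matrix(0, nrow(dH), ncol(dH))
    for (b in seq_along(seqs)) {
      idx <- seqs[[b]]
      for (h in seq_len(nh)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        A <- cc$A[[b]][[h]]
        dCtx_bh <- dCtx[idx, cols, drop = FALSE]
        Vb <- cc$V[idx, cols, drop = FALSE]
        dA <- tcrossprod(dCtx_bh, Vb)
        dV[idx, cols] <- crossprod(A, dCtx_bh)
        dS <- A * (dA - rowSums(dA * A))
        dQ[idx, cols] <- dS %*% cc$K[idx, cols, drop = FALSE] * scale
        dK[idx, cols] <- crossprod(dS, cc$Q[idx, cols, drop = FALSE]) * scale
      }
    }
    grads[[paste0(p, "Wq")]] <- crossprod(cc$X, dQ)
    grads[[paste0(p, "bq")]] <- colSums(dQ)
    grads[[paste0(p, "Wk")]] <- crossprod(cc$X, dK)
    grads[[paste0(p, "bk")]] <- colSums(dK)
    grads[[paste0(p, "Wv")]] <- crossprod(cc$X, dV)
    grads[[paste0(p, "bv")]] <- colSums(dV)
    dX <- dX + tcrossprod(dQ, params[[paste0(p, "Wq")]]) +
      tcrossprod(dK, params[[paste0(p, "Wk")]]) +
      tcrossprod(dV, params[[paste0(p, "Wv")]])
    dH <- dX
  }
  list(grads = grads, dX = dH)
}

# --- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Accumulate gradient lists elementwise (grads may cover disjoint names).
acc_grads <- function(total, grads) {
  for (nm in names(grads)) {
    total[[nm]] <- if (is.null(total[[nm]])) grads[[nm]]
                   else total[[nm]] + grads[[nm]]
  }
  total
}

# --- Packing ----------------------------------------------------------

# Stack encoded trajectories into one packed batch.
pack_batch <- function(trajectories) {
  lens <- vapply(trajectories, function(tr) length(tr$token_ids), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(
    tok = unlist(lapply(trajectories, `[[`, "token_ids")),
    mod = unlist(lapply(trajectories, `[[`, "modality_ids")),
    del = unlist(lapply(trajectories, `[[`, "delay_ids")),
    pos = unlist(lapply(trajectories, `[[`, "positions")),
    seqs = mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE),
    cls_rows = starts,
    lens = lens
  )
}

# Input embedding of a packed tabular batch: the sum of token, modality,
# delay and position embeddings.
embed_tabular <- function(params, batch) {
  params$emb_tok[batch$tok, , drop = FALSE] +
    params$emb_mod[batch$mod, , drop = FALSE] +
    params$emb_del[batch$del, , drop = FALSE] +
    params$emb_pos[batch$pos + 1L, , drop = FALSE]
}

# Scatter packed input gradients back onto the embedding tables.
embed_tabular_backward <- function(params, batch, dX) {
  g <- list(emb_tok = params$emb_tok * 0, emb_mod = params$emb_mod * 0,
            emb_del = params$emb_del * 0, emb_pos = params$emb_pos * 0)
  scatter <- function(M, idx) {
    rs <- rowsum(dX, group = idx)
    M[as.integer(rownames(rs)), ] <- rs
    M
  }
  g$emb_tok <- scatter(g$emb_tok, batch$tok)
  g$emb_mod <- scatter(g$emb_mod, batch$mod)
  g$emb_del <- scatter(g$emb_del, batch$del)
  g$emb_pos <- scatter(g$emb_pos, batch$pos + 1L)
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))
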