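# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The training loop records every matrix operation of a forward pass on a
# tape; backward() then walks the tape in reverse, accumulating gradients.
# All values are plain numeric matrices (scalars are 1x1). This is internal
# machinery: its correctness is established by finite-difference tests, and
# the numeric (non-tape) layer implementations are the public API.

# Nodes live in environments keyed by stringified id: environment assignment
# is O(1) and never copies, whereas growing a list held in an environment
# would copy it on every push.
tape_new <- function(capacity = NULL) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- new.env(parent = emptyenv())
  tp$parents <- new.env(parent = emptyenv())
  tp$backs <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, parents = NULL, back = NULL) {
  n <- tp$n + 1L
  k <- as.character(n)
  assign(k, val, envir = tp$vals)
  if (!is.null(parents)) {
    assign(k, parents, envir = tp$parents)
    assign(k, back, envir = tp$backs)
  }
  tp$n <- n
  n
}

tp_val <- function(tp, id) get(as.character(id), envir = tp$vals)

# Node-id arguments are forced before tp$vals is read: an argument may itself
# be a tape-pushing call, and R would otherwise fetch the vals list before the
# promise runs, reading a stale copy.

ad_leaf <- function(tp, x) tp_push(tp, as.matrix(x))

ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) + tp_val(tp, b), c(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp_val(tp, a) - tp_val(tp, b), c(a, b), function(g) list(g, -g))
}

# matrix + row-vector bias, broadcast over rows
ad_add_bias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp_val(tp, a); b <- tp_val(tp, bias)
  tp_push(tp, sweep(A, 2L, as.vector(b), "+"), c(a, bias), function(g) {
    list(g, matrix(colSums(g), nrow(b), ncol(b)))
  })
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_div <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  tp_push(tp, A / B, c(a, b), function(g) list(g / B, -g * A / (B * B)))
}

# rows of m scaled by column vector s (n x 1)
ad_scale_rows <- function(tp, m, s) {
  force(m); force(s)
  M <- tp_val(tp, m); S <- as.vector(tp_val(tp, s))
  tp_push(tp, M * S, c(m, s), function(g) {
    list(g * S, matrix(rowSums(g * M), ncol = 1L))
  })
}

ad_affine <- function(tp, a, mult = 1, add = 0) {
  force(a)
  A <- tp_val(tp, a)
  tp_push(tp, A * mult + add, a, function(g) list(g * mult))
}

ad_pow <- function(tp, a, p) {
  force(a)
  A <- tp_val(tp, a)
  tp_push(tp, A^p, a, function(g) list(g * p * A^(p - 1)))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  y <- sigmoid(tp_val(tp, a))
  tp_push(tp, y, a, function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp_val(tp, a))
  tp_push(tp, y, a, function(g) list(g * (1 - y * y)))
}

ad_relu <- function(tp, a) {
  force(a)
  A <- tp_val(tp, a)
  mask <- A > 0
  tp_push(tp, A * mask, a, function(g) list(g * mask))
}

ad_softmax_rows <- function(tp, a) {
  force(a)
  y <- softmax_rows(tp_val(tp, a))
  tp_push(tp, y, a, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

ad_transpose <- function(tp, a) {
  force(a)
  tp_push(tp, t(tp_val(tp, a)), a, function(g) list(t(g)))
}

ad_cbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, tp_val, tp = tp)
  widths <- vapply(vals, ncol, 0L)
  tp_push(tp, do.call(cbind, vals), ids, function(g) {
    to <- cumsum(widths)
    from <- c(1L, head(to, -1L) + 1L)
    lapply(seq_along(ids), function(k) g[, from[k]:to[k], drop = FALSE])
  })
}

ad_rbind <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, tp_val, tp = tp)
  heights <- vapply(vals, nrow, 0L)
  tp_push(tp, do.call(rbind, vals), ids, function(g) {
    to <- cumsum(heights)
    from <- c(1L, head(to, -1L) + 1L)
    lapply(seq_along(ids), function(k) g[from[k]:to[k], , drop = FALSE])
  })
}

ad_rows <- function(tp, a, idx) {
  force(a)
  A <- tp_val(tp, a)
  dims <- dim(A)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g) {
    out <- matrix(0, dims[1], dims[2])
    agg <- rowsum(g, group = idx)  # handles repeated indices
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

ad_cols <- function(tp, a, from, to) {
  force(a)
  A <- tp_val(tp, a)
  dims <- dim(A)
  tp_push(tp, A[, from:to, drop = FALSE], a, function(g) {
    out <- matrix(0, dims[1], dims[2])
    out[, from:to] <- g
    list(out)
  })
}

# elementwise gather: column vector of A[cbind(i, j)]; (i, j) must be unique
ad_gather <- function(tp, a, i, j) {
  force(a)
  A <- tp_val(tp, a)
  dims <- dim(A)
  tp_push(tp, matrix(A[cbind(i, j)], ncol = 1L), a, function(g) {
    out <- matrix(0, dims[1], dims[2])
    out[cbind(i, j)] <- g
    list(out)
  })
}

ad_mean <- function(tp, a) {
  force(a)
  A <- tp_val(tp, a)
  dims <- dim(A)
  tp_push(tp, matrix(mean(A), 1L, 1L), a, function(g) {
    list(matrix(g[1] / (dims[1] * dims[2]), dims[1], dims[2]))
  })
}

ad_sum <- function(tp, a) {
  force(a)
  A <- tp_val(tp, a)
  dims <- dim(A)
  tp_push(tp, matrix(sum(A), 1L, 1L), a, function(g) {
    list(matrix(g[1], dims[1], dims[2]))
  })
}

ad_log <- function(tp, a) {
  force(a)
  A <- tp_val(tp, a)
  tp_push(tp, log(A), a, function(g) list(g / A))
}

# Fused LSTM over a whole sequence: one tape node instead of ~12 per
# timestep, with hand-derived backpropagation through time. Gate layout in
# the fused weights is [input, forget, cell, output]; initial state is zero.
ad_lstm <- function(tp, x, wx, wh, b, hidden, reverse = FALSE) {
  force(x); force(wx); force(wh); force(b)
  X <- tp_val(tp, x); Wx <- tp_val(tp, wx); Wh <- tp_val(tp, wh); B <- tp_val(tp, b)
  n <- nrow(X)
  XW <- sweep(X %*% Wx, 2L, as.vector(B), "+")  # input contribution, all steps
  I <- matrix(0, n, hidden); F <- matrix(0, n, hidden)
  G <- matrix(0, n, hidden); Oo <- matrix(0, n, hidden)
  C <- matrix(0, n, hidden); TC <- matrix(0, n, hidden)
  H <- matrix(0, n, hidden)
  h_prev <- matrix(0, 1L, hidden); c_prev <- matrix(0, 1L, hidden)
  steps <- if (reverse) rev(seq_len(n)) else seq_len(n)
  for (t in steps) {
    z <- XW[t, , drop = FALSE] + h_prev %*% Wh
    i <- sigmoid(z[, 1:hidden, drop = FALSE])
    f <- sigmoid(z[, (hidden + 1):(2 * hidden), drop = FALSE])
    g <- tanh(z[, (2 * hidden + 1):(3 * hidden), drop = FALSE])
    o <- sigmoid(z[, (3 * hidden + 1):(4 * hidden), drop = FALSE])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    I[t, ] <- i; F[t, ] <- f; G[t, ] <- g; Oo[t, ] <- o
    C[t, ] <- cc; TC[t, ] <- tc
    H[t, ] <- o * tc
    h_prev <- H[t, , drop = FALSE]; c_prev <- C[t, , drop = FALSE]
  }
  tp_push(tp, H, c(x, wx, wh, b), function(gH) {
    gX <- matrix(0, n, ncol(X))
    gWx <- matrix(0, nrow(Wx), ncol(Wx)); gWh <- matrix(0, hidden, 4L * hidden)
    gB <- matrix(0, 1L, 4L * hidden)
    dh_carry <- matrix(0, 1L, hidden); dc_carry <- matrix(0, 1L, hidden)
    for (k in seq(n, 1L)) {
      t <- steps[k]
      t_prev <- if (k > 1L) steps[k - 1L] else 0L
      h_before <- if (t_prev > 0L) H[t_prev, , drop = FALSE] else matrix(0, 1L, hidden)
      c_before <- if (t_prev > 0L) C[t_prev, , drop = FALSE] else matrix(0, 1L, hidden)
      dh <- gH[t, , drop = FALSE] + dh_carry
      i <- I[t, , drop = FALSE]; f <- F[t, , drop = FALSE]
      g <- G[t, , drop = FALSE]; o <- Oo[t, , drop = FALSE]
      tc <- TC[t, , drop = FALSE]
      dct <- dh * o * (1 - tc * tc) + dc_carry
      dz <- cbind(dct * g * i * (1 - i),
                  dct * c_before * f * (1 - f),
                  dct * i * (1 - g * g),
                  dh * tc * o * (1 - o))
      gWx <- gWx + crossprod(X[t, , drop = FALSE], dz)
      gWh <- gWh + crossprod(h_before, dz)
      gB <- gB + dz
      gX[t, ] <- dz %*% t(Wx)
      dh_carry <- dz %*% t(Wh)
      dc_carry <- dct * f
    }
    list(gX, gWx, gWh, gB)
  })
}

# inverted dropout: training-time mask drawn from the current RNG
ad_dropout <- function(tp, a, rate) {
  force(a)
  if (rate <= 0) return(a)
  A <- tp_val(tp, a)
  mask <- matrix((runif(length(A)) >= rate) / (1 - rate), nrow(A), ncol(A))
  tp_push(tp, A * mask, a, function(g) list(g * mask))
}

# Backward pass from a scalar root; returns a list of gradients indexed by
# node id (NULL where the node does not influence the root).
backward <- function(tp, root) {
  n <- tp$n
  grads <- vector("list", n)
  grads[[root]] <- matrix(1, 1L, 1L)
  for (i in seq(n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    k <- as.character(i)
    parents <- get0(k, envir = tp$parents)
    if (is.null(parents)) next
    pg <- get0(k, envir = tp$backs)(g)
    for (k in seq_along(parents)) {
      p <- parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}
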