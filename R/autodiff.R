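# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape is an environment holding a list of nodes; each node stores its
# value, its parent ids, and a backward closure mapping the incoming gradient
# to per-parent gradients.  Batched node-feature matrices are stacked
# row-wise as (B*n) x F; ops that involve a per-graph matrix (structure
# matrix, prolongation) loop over the B row blocks inside a single node, so
# tape length is independent of batch size.
#
# This engine trains every model in the package; the closed-form input
# gradients in energy-gradients.R are derived independently and validated
# against it.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tp_node <- function(tp, value, parents = integer(0), backward = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(value = value, parents = parents,
                           backward = backward)
  tp$n
}

tp_value <- function(tp, id) tp$nodes[[id]]$value

tp_const <- function(tp, value) tp_node(tp, value)

# matmul: C = A %*% B (A, B node ids)
tp_matmul <- function(tp, a, b) {
  A <- tp_value(tp, a); B <- tp_value(tp, b)
  tp_node(tp, A %*% B, c(a, b), function(g)
    list(g %*% t(B), crossprod(A, g)))
}

# add a bias row vector b (length F) to every row of X
tp_add_bias <- function(tp, x, b) {
  X <- tp_value(tp, x); bv <- tp_value(tp, b)
  tp_node(tp, sweep(X, 2, bv, "+"), c(x, b), function(g)
    list(g, colSums(g)))
}

tp_relu <- function(tp, x) {
  X <- tp_value(tp, x)
  M <- X > 0
  tp_node(tp, X * M, x, function(g) list(g * M))
}

tp_sigmoid <- function(tp, x) {
  S <- 1 / (1 + exp(-tp_value(tp, x)))
  tp_node(tp, S, x, function(g) list(g * S * (1 - S)))
}

tp_identity_act <- function(tp, x) x

# column-concatenate several nodes
tp_cbind <- function(tp, ids) {
  vals <- lapply(ids, tp_value, tp = tp)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths); starts <- c(1L, head(ends, -1) + 1L)
  tp_node(tp, do.call(cbind, vals), unlist(ids), function(g)
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

# elementwise sum of several same-shaped nodes
tp_add <- function(tp, ids) {
  if (length(ids) == 1) return(ids[[1]])
  tp_node(tp, Reduce(`+`, lapply(ids, tp_value, tp = tp)), unlist(ids),
          function(g) rep(list(g), length(ids)))
}

# apply an n x m matrix P (node) blockwise to a stacked (B*rows(X)) x F node:
# transpose = FALSE:  out block = P %*% X_b      (X blocks are m-row)
# transpose = TRUE :  out block = t(P) %*% X_b   (X blocks are n-row)
tp_block_proj <- function(tp, p, x, nblk, transpose = FALSE) {
  P <- tp_value(tp, p); X <- tp_value(tp, x)
  rin <- nrow(X) / nblk
  rout <- if (transpose) ncol(P) else nrow(P)
  out <- matrix(0, rout * nblk, ncol(X))
  for (b in seq_len(nblk)) {
    Xb <- X[((b - 1) * rin + 1):(b * rin), , drop = FALSE]
    out[((b - 1) * rout + 1):(b * rout), ] <-
      if (transpose) crossprod(P, Xb) else P %*% Xb
  }
  tp_node(tp, out, c(p, x), function(g) {
    gP <- matrix(0, nrow(P), ncol(P))
    gX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(nblk)) {
      Xb <- X[((b - 1) * rin + 1):(b * rin), , drop = FALSE]
      gb <- g[((b - 1) * rout + 1):(b * rout), , drop = FALSE]
      if (transpose) {
        gP <- gP + Xb %*% t(gb)
        gX[((b - 1) * rin + 1):(b * rin), ] <- P %*% gb
      } else {
        gP <- gP + gb %*% t(Xb)
        gX[((b - 1) * rin + 1):(b * rin), ] <- crossprod(P, gb)
      }
    }
    list(gP, gX)
  })
}

# aggregate with a constant (sparse) square structure matrix, batched:
# out block = Z %*% X_b.  Implemented in one multiply via bdiag(Z, ..., Z).
tp_struct_mul <- function(tp, Zb, x) {
  X <- tp_value(tp, x)
  tp_node(tp, as.matrix(Zb %*% X), x, function(g)
    list(as.matrix(Matrix::crossprod(Zb, g))))
}

# batched multiply by per-block square matrices stacked rowwise:
# Astack is (B*m) x m (node), X is (B*m) x F (node); out block = A_b %*% X_b.
tp_block_pair_mul <- function(tp, astack, x, nblk) {
  A <- tp_value(tp, astack); X <- tp_value(tp, x)
  m <- ncol(A)
  out <- matrix(0, nrow(X), ncol(X))
  for (b in seq_len(nblk)) {
    rows <- ((b - 1) * m + 1):(b * m)
    out[rows, ] <- A[rows, , drop = FALSE] %*% X[rows, , drop = FALSE]
  }
  tp_node(tp, out, c(astack, x), function(g) {
    gA <- matrix(0, nrow(A), ncol(A)); gX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(nblk)) {
      rows <- ((b - 1) * m + 1):(b * m)
      gA[rows, ] <- g[rows, , drop = FALSE] %*% t(X[rows, , drop = FALSE])
      gX[rows, ] <- crossprod(A[rows, , drop = FALSE], g[rows, , drop = FALSE])
    }
    list(gA, gX)
  })
}

# batched pooled coarsening: given assignment stack S ((B*n) x nc, node) and
# constant sparse Z (n x n), produce stacked coarse structure matrices
# (B*nc) x nc with block t(S_b) %*% Z %*% S_b.
tp_block_coarsen_Z <- function(tp, s, Z, nblk) {
  S <- tp_value(tp, s)
  n <- nrow(S) / nblk; nc <- ncol(S)
  out <- matrix(0, nc * nblk, nc)
  ZS <- vector("list", nblk)
  for (b in seq_len(nblk)) {
    Sb <- S[((b - 1) * n + 1):(b * n), , drop = FALSE]
    ZS[[b]] <- as.matrix(Z %*% Sb)
    out[((b - 1) * nc + 1):(b * nc), ] <- crossprod(Sb, ZS[[b]])
  }
  tp_node(tp, out, s, function(g) {
    gS <- matrix(0, nrow(S), ncol(S))
    for (b in seq_len(nblk)) {
      Sb <- S[((b - 1) * n + 1):(b * n), , drop = FALSE]
      gb <- g[((b - 1) * nc + 1):(b * nc), , drop = FALSE]
      # d/dS of t(S) M S with M = Z symmetric: M S gb^T + M S gb
      gS[((b - 1) * n + 1):(b * n), ] <-
        ZS[[b]] %*% t(gb) + ZS[[b]] %*% gb
    }
    list(gS)
  })
}

# batched pooled coarsening with per-block structure matrices: S is a stacked
# (B*n) x nc node, Zstack a stacked (B*n) x n node; out block = t(S_b) Z_b S_b
tp_block_coarsen_pair <- function(tp, s, zstack, nblk) {
  S <- tp_value(tp, s); Z <- tp_value(tp, zstack)
  n <- ncol(Z); nc <- ncol(S)
  out <- matrix(0, nc * nblk, nc)
  for (b in seq_len(nblk)) {
    rows <- ((b - 1) * n + 1):(b * n)
    Sb <- S[rows, , drop = FALSE]
    out[((b - 1) * nc + 1):(b * nc), ] <- crossprod(Sb, Z[rows, , drop = FALSE] %*% Sb)
  }
  tp_node(tp, out, c(s, zstack), function(g) {
    gS <- matrix(0, nrow(S), ncol(S)); gZ <- matrix(0, nrow(Z), ncol(Z))
    for (b in seq_len(nblk)) {
      rows <- ((b - 1) * n + 1):(b * n)
      crows <- ((b - 1) * nc + 1):(b * nc)
      Sb <- S[rows, , drop = FALSE]
      Zb <- Z[rows, , drop = FALSE]
      gb <- g[crows, , drop = FALSE]
      gS[rows, ] <- Zb %*% Sb %*% t(gb) + crossprod(Zb, Sb) %*% gb
      gZ[rows, ] <- Sb %*% gb %*% t(Sb)
    }
    list(gS, gZ)
  })
}

# batched coarsening of data: out block = t(S_b) %*% X_b (S node, X node)
tp_block_restrict <- function(tp, s, x, nblk) {
  S <- tp_value(tp, s); X <- tp_value(tp, x)
  n <- nrow(S) / nblk; nc <- ncol(S)
  out <- matrix(0, nc * nblk, ncol(X))
  for (b in seq_len(nblk)) {
    rows <- ((b - 1) * n + 1):(b * n)
    out[((b - 1) * nc + 1):(b * nc), ] <-
      crossprod(S[rows, , drop = FALSE], X[rows, , drop = FALSE])
  }
  tp_node(tp, out, c(s, x), function(g) {
    gS <- matrix(0, nrow(S), ncol(S)); gX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(nblk)) {
      rows <- ((b - 1) * n + 1):(b * n)
      crows <- ((b - 1) * nc + 1):(b * nc)
      gb <- g[crows, , drop = FALSE]
      gS[rows, ] <- X[rows, , drop = FALSE] %*% t(gb)
      gX[rows, ] <- S[rows, , drop = FALSE] %*% gb
    }
    list(gS, gX)
  })
}

# batched upsample: out block = S_b %*% X_b (X blocks are nc-row)
tp_block_upsample <- function(tp, s, x, nblk) {
  S <- tp_value(tp, s); X <- tp_value(tp, x)
  n <- nrow(S) / nblk; nc <- ncol(S)
  out <- matrix(0, n * nblk, ncol(X))
  for (b in seq_len(nblk)) {
    rows <- ((b - 1) * n + 1):(b * n)
    crows <- ((b - 1) * nc + 1):(b * nc)
    out[rows, ] <- S[rows, , drop = FALSE] %*% X[crows, , drop = FALSE]
  }
  tp_node(tp, out, c(s, x), function(g) {
    gS <- matrix(0, nrow(S), ncol(S)); gX <- matrix(0, nrow(X), ncol(X))
    for (b in seq_len(nblk)) {
      rows <- ((b - 1) * n + 1):(b * n)
      crows <- ((b - 1) * nc + 1):(b * nc)
      gb <- g[rows, , drop = FALSE]
      gS[rows, ] <- gb %*% t(X[crows, , drop = FALSE])
      gX[crows, ] <- crossprod(S[rows, , drop = FALSE], gb)
    }
    list(gS, gX)
  })
}

# row-wise softmax
tp_row_softmax <- function(tp, x) {
  X <- tp_value(tp, x)
  M <- exp(X - apply(X, 1, max))
  S <- M / rowSums(M)
  tp_node(tp, S, x, function(g) {
    list(S * (g - rowSums(g * S)))
  })
}

# scalar mean squared error against a constant target
tp_mse <- function(tp, pred, target) {
  P <- tp_value(tp, pred)
  D <- P - target
  tp_node(tp, mean(D^2), pred, function(g)
    list((2 * g / length(D)) * D))
}

# reverse pass from a scalar node; returns list of gradients by node id
tape_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- 1
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}
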