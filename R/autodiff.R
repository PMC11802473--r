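# Reverse-mode automatic differentiation on a linear tape.
#
# Values are plain double matrices. A tape records, per node, its value, the
# ids of its parents and a backward closure mapping the node's output gradient
# to a list of parent gradients. Gradients are accumulated by a single reverse
# sweep. This is all the machinery the model needs: matrix products,
# elementwise nonlinearities, row softmax, layer norm, row gather/scatter
# (padding, convolution shifts), column slicing/binding and spatial pooling.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$vals <- vector("list", 512L)
  e$parents <- vector("list", 512L)
  e$bw <- vector("list", 512L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_push <- function(tape, val, parents = integer(), backward = NULL) {
  # Force arguments before touching the counter: evaluating `val` or
  # `parents` may itself push nodes (lazily passed op/const expressions).
  force(val); force(parents); force(backward)
  n <- tape$n + 1L
  if (n > length(tape$vals)) {
    m <- 2L * length(tape$vals)
    length(tape$vals) <- m
    length(tape$parents) <- m
    length(tape$bw) <- m
  }
  tape$vals[[n]] <- val
  tape$parents[[n]] <- parents
  tape$bw[[n]] <- backward
  tape$n <- n
  structure(list(tape = tape, id = n), class = "ad_node")
}

ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  ad_push(tape, x)
}

ad_val <- function(x) x$tape$vals[[x$id]]

is_ad_node <- function(x) inherits(x, "ad_node")

# Reverse sweep from `node` (typically a 1x1 loss). Returns the list of
# gradients indexed by node id (NULL where no gradient flows).
ad_backward <- function(node, seed_grad = NULL) {
  tape <- node$tape
  grads <- vector("list", tape$n)
  g0 <- if (is.null(seed_grad)) {
    v <- tape$vals[[node$id]]
    matrix(1, nrow(v), ncol(v))
  } else seed_grad
  grads[[node$id]] <- g0
  for (i in seq.int(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bw <- tape$bw[[i]]
    if (is.null(bw)) next
    pg <- bw(g)
    ps <- tape$parents[[i]]
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- pg[[j]]
      if (is.null(gj)) next
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

# ---- arithmetic ----

ad_matmul <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  ad_push(a$tape, A %*% B, c(a$id, b$id), function(g) {
    list(tcrossprod(g, B), crossprod(A, g))
  })
}

ad_t <- function(a) {
  ad_push(a$tape, t(ad_val(a)), a$id, function(g) list(t(g)))
}

ad_add <- function(a, b) {
  ad_push(a$tape, ad_val(a) + ad_val(b), c(a$id, b$id),
          function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_push(a$tape, ad_val(a) - ad_val(b), c(a$id, b$id),
          function(g) list(g, -g))
}

# constant matrix C minus node x
ad_csub <- function(C, x) {
  ad_push(x$tape, C - ad_val(x), x$id, function(g) list(-g))
}

ad_scale <- function(a, s) {
  ad_push(a$tape, s * ad_val(a), a$id, function(g) list(s * g))
}

ad_mul <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  ad_push(a$tape, A * B, c(a$id, b$id), function(g) list(g * B, g * A))
}

# broadcast a 1 x k row vector over n rows as an n x k matrix; the rank-one
# outer product goes through BLAS and beats rep()/byrow= by several times
bcast_rows <- function(V, n) matrix(1, n, 1L) %*% matrix(V, 1L)

# matrix `a` (n x k) plus row vector node `v` (1 x k), broadcast over rows
ad_add_rowvec <- function(a, v) {
  A <- ad_val(a); V <- ad_val(v)
  k <- ncol(A)
  val <- A + bcast_rows(V, nrow(A))
  ad_push(a$tape, val, c(a$id, v$id), function(g) {
    list(g, matrix(colSums(g), 1L, k))
  })
}

# matrix `a` (n x k) times row vector node `v` (1 x k), broadcast over rows
ad_mul_rowvec <- function(a, v) {
  A <- ad_val(a); V <- ad_val(v)
  k <- ncol(A)
  Vb <- bcast_rows(V, nrow(A))
  ad_push(a$tape, A * Vb, c(a$id, v$id), function(g) {
    list(g * Vb, matrix(colSums(g * A), 1L, k))
  })
}

# ---- nonlinearities ----

ad_relu <- function(a) {
  A <- ad_val(a)
  mask <- A > 0
  ad_push(a$tape, A * mask, a$id, function(g) list(g * mask))
}

ad_tanh <- function(a) {
  Tv <- tanh(ad_val(a))
  ad_push(a$tape, Tv, a$id, function(g) list(g * (1 - Tv * Tv)))
}

# logistic with temperature: 1 / (1 + exp(-tau * x))
ad_sigmoid <- function(a, tau = 1) {
  S <- 1 / (1 + exp(-tau * ad_val(a)))
  ad_push(a$tape, S, a$id, function(g) list(g * tau * S * (1 - S)))
}

ad_log <- function(a) {
  A <- ad_val(a)
  ad_push(a$tape, log(A), a$id, function(g) list(g / A))
}

ad_clamp <- function(a, lo, hi) {
  A <- ad_val(a)
  mask <- A >= lo & A <= hi
  ad_push(a$tape, pmin(pmax(A, lo), hi), a$id, function(g) list(g * mask))
}

ad_softmax_rows <- function(a) {
  A <- ad_val(a)
  A <- A - A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(A)
  S <- E / rowSums(E)
  ad_push(a$tape, S, a$id, function(g) {
    list(S * (g - rowSums(g * S)))
  })
}

# ---- normalization ----

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  X <- ad_val(x); G <- ad_val(gamma); B <- ad_val(beta)
  d <- ncol(X)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  Gb <- bcast_rows(G, nrow(X))
  val <- xhat * Gb + bcast_rows(B, nrow(X))
  ad_push(x$tape, val, c(x$id, gamma$id, beta$id), function(g) {
    dgamma <- matrix(colSums(g * xhat), 1L, d)
    dbeta <- matrix(colSums(g), 1L, d)
    dxh <- g * Gb
    dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

# ---- shape ops ----

# Row gather with implicit zero rows: idx[i] == 0L emits a zero row.
# Used for square padding/unpadding and shifted reads in convolutions.
ad_gather_rows <- function(x, idx) {
  X <- ad_val(x)
  nz <- idx > 0L
  all_nz <- all(nz)
  out <- if (all_nz) X[idx, , drop = FALSE] else {
    o <- matrix(0, length(idx), ncol(X))
    o[nz, ] <- X[idx[nz], , drop = FALSE]
    o
  }
  inj <- anyDuplicated(idx[nz]) == 0L
  ad_push(x$tape, out, x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    if (inj) {
      dX[idx[nz], ] <- if (all_nz) g else g[nz, , drop = FALSE]
    } else if (any(nz)) {
      acc <- rowsum(g[nz, , drop = FALSE], group = idx[nz])
      dX[as.integer(rownames(acc)), ] <- acc
    }
    list(dX)
  })
}

# Fused depth-wise convolution on a raster grid: out[p, c] =
# sum_o Z[shift_o(p), c] * W[o, c] (+ zero outside), one spatial filter per
# channel. `idx_list` holds one conv_shift_index() map per kernel offset.
ad_dwconv <- function(z, w, idx_list) {
  Z <- ad_val(z); W <- ad_val(w)
  n <- nrow(Z); d <- ncol(Z)
  out <- matrix(0, n, d)
  shifts <- vector("list", length(idx_list))
  for (o in seq_along(idx_list)) {
    idx <- idx_list[[o]]
    nz <- idx > 0L
    Zs <- matrix(0, n, d)
    Zs[nz, ] <- Z[idx[nz], , drop = FALSE]
    shifts[[o]] <- Zs
    out <- out + Zs * bcast_rows(W[o, ], n)
  }
  ad_push(z$tape, out, c(z$id, w$id), function(g) {
    dZ <- matrix(0, n, d)
    dW <- matrix(0, nrow(W), d)
    for (o in seq_along(idx_list)) {
      idx <- idx_list[[o]]
      nz <- idx > 0L
      gw <- g * bcast_rows(W[o, ], n)
      # scatter-add the shifted gradient back (shift maps are injective)
      dZ[idx[nz], ] <- dZ[idx[nz], , drop = FALSE] + gw[nz, , drop = FALSE]
      dW[o, ] <- colSums(g * shifts[[o]])
    }
    list(dZ, dW)
  })
}

ad_cols <- function(x, j) {
  X <- ad_val(x)
  ad_push(x$tape, X[, j, drop = FALSE], x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    dX[, j] <- g
    list(dX)
  })
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, ad_val)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_push(nodes[[1L]]$tape, do.call(cbind, vals),
          vapply(nodes, function(n) n$id, 0L), function(g) {
    lapply(seq_along(widths), function(j) {
      g[, starts[j]:ends[j], drop = FALSE]
    })
  })
}

ad_rbind <- function(a, b) {
  A <- ad_val(a); B <- ad_val(b)
  na <- nrow(A)
  ad_push(a$tape, rbind(A, B), c(a$id, b$id), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

# ---- reductions ----

ad_colmeans <- function(x) {
  X <- ad_val(x)
  n <- nrow(X)
  ad_push(x$tape, matrix(colMeans(X), 1L), x$id, function(g) {
    list(bcast_rows(g / n, n))
  })
}

ad_colmax <- function(x) {
  X <- ad_val(x)
  am <- max.col(t(X), ties.method = "first")
  val <- matrix(X[cbind(am, seq_len(ncol(X)))], 1L)
  ad_push(x$tape, val, x$id, function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    dX[cbind(am, seq_len(ncol(X)))] <- g
    list(dX)
  })
}

ad_sum <- function(x) {
  X <- ad_val(x)
  ad_push(x$tape, matrix(sum(X), 1L, 1L), x$id, function(g) {
    list(matrix(g[1L], nrow(X), ncol(X)))
  })
}

# ---- parameter context ----
#
# A forward pass pulls named parameters from a flat list; each parameter is
# materialized as a tape node once per pass so repeated uses accumulate
# gradient through one node.

ad_ctx <- function(tape, params) {
  e <- new.env(parent = emptyenv())
  e$tape <- tape
  e$params <- params
  e$pid <- new.env(parent = emptyenv())
  e
}

ctx_param <- function(ctx, name) {
  id <- ctx$pid[[name]]
  if (!is.null(id)) {
    return(structure(list(tape = ctx$tape, id = id), class = "ad_node"))
  }
  p <- ctx$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  node <- ad_push(ctx$tape, p)
  ctx$pid[[name]] <- node$id
  node
}

# Collect d(loss)/d(param) for every parameter touched during the pass.
ctx_param_grads <- function(ctx, grads) {
  nms <- ls(ctx$pid)
  out <- setNames(vector("list", length(nms)), nms)
  for (nm in nms) {
    g <- grads[[ctx$pid[[nm]]]]
    out[[nm]] <- if (is.null(g)) ctx$params[[nm]] * 0 else g
  }
  out
}
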