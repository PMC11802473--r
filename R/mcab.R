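# Multi-scale channel attention block (MCAB).
#
# A token sequence is zero-padded to the smallest square M x M grid
# (raster/row-major order), passed through two depth-wise separable
# convolution branches with different kernel sizes, recombined by a
# shared-MLP channel gate with temperature sigmoid, and flattened back to a
# sequence of the original length. The padding tokens exist only inside the
# block. Because convolution reads neighbours in the grid, the block is
# order-sensitive and acts as an implicit positional encoding for the
# otherwise permutation-equivariant transformer layers.

# grid side for N tokens: smallest M with M^2 >= N
grid_side <- function(N) as.integer(ceiling(sqrt(N)))

# raster-order <-> array converters for an M^2 x d matrix (row-major grid)
grid_matrix_to_array <- function(Gm, M) {
  d <- ncol(Gm)
  aperm(array(t(Gm), c(d, M, M)), c(3L, 2L, 1L))
}

grid_array_to_matrix <- function(arr) {
  d <- dim(arr)[3L]
  t(matrix(aperm(arr, c(3L, 2L, 1L)), d))
}

# Index map for a depth-wise convolution offset (dr, dc) on an M x M raster
# grid: entry p gives the raster index read for output position p, 0 when the
# read falls outside the grid (zero padding).
conv_shift_index <- function(M, dr, dc) {
  p <- seq_len(M * M)
  r <- (p - 1L) %/% M + 1L
  cc <- (p - 1L) %% M + 1L
  rr <- r + dr
  c2 <- cc + dc
  idx <- (rr - 1L) * M + c2
  idx[rr < 1L | rr > M | c2 < 1L | c2 > M] <- 0L
  idx
}

#' Square-pad a token sequence into a 2-D grid
#'
#' Reshapes an N x d token sequence into the smallest M x M x d grid with
#' `M^2 >= N`, filling positions in raster (row-major) order and appending
#' `M^2 - N` all-zero padding tokens at the tail. The padding tokens take
#' part only in the channel-attention computations, never in the
#' transformer.
#'
#' @param Z Numeric N x d token matrix.
#' @return An object of class `padded_grid`: list with `grid` (M x M x d
#'   array), `valid_mask` (M x M logical, `TRUE` at the N filled positions),
#'   `M` and `N`.
#' @export
#' @examples
#' g <- pad_and_square(matrix(1:20, 10, 2))
#' g$M            # 4: the smallest square covering 10 tokens
#' sum(!g$valid_mask)  # 6 padding positions
pad_and_square <- function(Z) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  stopifnot(N >= 1L)
  M <- grid_side(N)
  Gm <- matrix(0, M * M, ncol(Z))
  Gm[seq_len(N), ] <- Z
  mask <- matrix(seq_len(M * M) <= N, M, M, byrow = TRUE)
  structure(list(grid = grid_matrix_to_array(Gm, M), valid_mask = mask,
                 M = M, N = N),
            class = "padded_grid")
}

#' Flatten a padded grid back to its token sequence
#'
#' Exact left inverse of [pad_and_square()]: reads the grid in raster order
#' and drops the padding tail.
#'
#' @param g A `padded_grid`.
#' @return The N x d token matrix.
#' @export
flatten_and_unpad <- function(g) {
  stopifnot(inherits(g, "padded_grid"))
  mask_raster <- as.vector(t(g$valid_mask))
  if (!identical(mask_raster, seq_len(g$M^2) <= g$N))
    stop("invariant error: valid_mask must be a raster-order prefix of N = ",
         g$N, " positions")
  Gm <- grid_array_to_matrix(g$grid)
  Gm[seq_len(g$N), , drop = FALSE]
}

as_grid_matrix <- function(x) {
  if (inherits(x, "padded_grid")) {
    list(Gm = grid_array_to_matrix(x$grid), M = x$M)
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[1L] == dim(x)[2L])
    list(Gm = grid_array_to_matrix(x), M = dim(x)[1L])
  }
}

# ---- tape-level building blocks (shared by the model forward pass) ----

# depth-wise (per-channel spatial filter) + ReLU + optional point-wise (1x1)
fwd_conv_branch <- function(ctx, Zg, pfx, M, kernel, use_pwconv = TRUE) {
  p <- function(nm) ctx_param(ctx, paste0(pfx, nm))
  half <- (kernel - 1L) %/% 2L
  offs <- expand.grid(dc = -half:half, dr = -half:half)
  idx_list <- lapply(seq_len(nrow(offs)), function(o)
    conv_shift_index(M, offs$dr[o], offs$dc[o]))
  acc <- ad_dwconv(Zg, p("dw"), idx_list) # dw: kernel^2 x d, (dr, dc) raster
  out <- ad_relu(ad_add_rowvec(acc, p("db")))
  if (use_pwconv) out <- ad_add_rowvec(ad_matmul(out, p("pw")), p("pb"))
  out
}

# shared-MLP channel gate over the fused map F = Z1 + Z2 + Z^
fwd_channel_gate <- function(ctx, Z1, Z2, Zg, pfx, tau) {
  p <- function(nm) ctx_param(ctx, paste0(pfx, nm))
  mlp <- function(x) {
    h <- ad_relu(ad_add_rowvec(ad_matmul(x, p("W1")), p("b1")))
    ad_add_rowvec(ad_matmul(h, p("W2")), p("b2"))
  }
  F_ <- ad_add(ad_add(Z1, Z2), Zg)
  L <- ad_add(mlp(ad_colmax(F_)), mlp(ad_colmeans(F_)))
  d <- ncol(ad_val(Z1))
  g1 <- ad_sigmoid(ad_cols(L, seq_len(d)), tau)
  g2 <- ad_sigmoid(ad_cols(L, d + seq_len(d)), tau)
  g3 <- ad_sigmoid(ad_cols(L, 2L * d + seq_len(d)), tau)
  out <- ad_add(ad_add(ad_mul_rowvec(Z1, g1), ad_mul_rowvec(Zg, g2)),
                ad_mul_rowvec(Z2, g3))
  list(out = out, gates = list(g1, g2, g3), L = L)
}

fwd_mcab <- function(ctx, Z, pfx, kernel_sizes, tau, use_pwconv = TRUE) {
  N <- nrow(ad_val(Z))
  M <- grid_side(N)
  pad_idx <- c(seq_len(N), rep(0L, M * M - N))
  Zg <- ad_gather_rows(Z, pad_idx)
  Z1 <- fwd_conv_branch(ctx, Zg, paste0(pfx, "c1."), M, kernel_sizes[1L],
                        use_pwconv)
  Z2 <- fwd_conv_branch(ctx, Zg, paste0(pfx, "c2."), M, kernel_sizes[2L],
                        use_pwconv)
  gated <- fwd_channel_gate(ctx, Z1, Z2, Zg, paste0(pfx, "g."), tau)
  ad_gather_rows(gated$out, seq_len(N))
}

# ---- standalone parameter builders and numeric wrappers ----

#' Random MCAB parameters
#'
#' @param d Token width.
#' @param kernel_sizes Odd kernel-size pair for the two branches.
#' @param reduction_ratio Hidden-width divisor `r` of the shared gate MLP.
#' @param seed Integer seed.
#' @return Named list: per-branch depth-wise filters `dw` (`k^2 x d`), bias
#'   `db`, point-wise matrix `pw` (`d x d`), bias `pb` (prefixes `c1.`,
#'   `c2.`), and gate MLP `g.W1`, `g.b1`, `g.W2`, `g.b2`.
#' @export
mcab_params <- function(d, kernel_sizes = c(3L, 5L), reduction_ratio = 16L,
                        seed = 1L) {
  set.seed(seed)
  hid <- gate_hidden_width(d, reduction_ratio)
  branch <- function(k) {
    list(dw = matrix(stats::rnorm(k * k * d, sd = 1 / k), k * k, d),
         db = matrix(0, 1L, d),
         pw = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
         pb = matrix(0, 1L, d))
  }
  b1 <- branch(kernel_sizes[1L]); b2 <- branch(kernel_sizes[2L])
  out <- c(stats::setNames(b1, paste0("c1.", names(b1))),
           stats::setNames(b2, paste0("c2.", names(b2))))
  out$g.W1 <- matrix(stats::rnorm(d * hid, sd = 1 / sqrt(d)), d, hid)
  out$g.b1 <- matrix(0, 1L, hid)
  out$g.W2 <- matrix(stats::rnorm(hid * 3L * d, sd = 1 / sqrt(hid)), hid,
                     3L * d)
  out$g.b2 <- matrix(0, 1L, 3L * d)
  out
}

#' Depth-wise separable convolution branch
#'
#' One MCAB branch: shape-preserving depth-wise convolution (one `k x k`
#' spatial filter per channel, zero same-padding), elementwise ReLU, then a
#' point-wise (1x1) convolution mixing channels.
#'
#' @param g A `padded_grid` or an M x M x d array.
#' @param kernel Odd kernel size.
#' @param params List with `dw` (`k^2 x d`, rows in row-major offset order),
#'   `db`, `pw`, `pb` (as the `c1.`/`c2.` entries of [mcab_params()], without
#'   the prefix).
#' @param use_pwconv If `FALSE` the point-wise convolution is omitted
#'   ("w/o PWConv" ablation).
#' @return M x M x d output array.
#' @export
conv_branch <- function(g, kernel, params, use_pwconv = TRUE) {
  if (kernel %% 2L == 0L || kernel < 1L)
    stop("config error: kernel size must be odd and >= 1")
  gm <- as_grid_matrix(g)
  if (kernel > 2L * gm$M - 1L)
    stop("config error: kernel size ", kernel,
         " exceeds grid support (2M-1 = ", 2L * gm$M - 1L, ")")
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  out <- fwd_conv_branch(ctx, ad_const(tape, gm$Gm), "", gm$M, kernel,
                         use_pwconv)
  grid_matrix_to_array(ad_val(out), gm$M)
}

#' Shared-MLP channel gate
#'
#' Fuses the two branch outputs with the identity path:
#' `F = Z1 + Z2 + Z^`; spatial max- and average-pooling of `F` give two
#' channel descriptors, both mapped by one shared MLP
#' (`d -> d/r -> 3d`, ReLU between) and summed into `L`; `L` splits evenly
#' into `L1, L2, L3` and each source is gated channelwise with the
#' temperature sigmoid `1/(1 + exp(-tau * x))`:
#' `Z = s(L1) * Z1 + s(L2) * Z^ + s(L3) * Z2` (gates broadcast over space).
#'
#' @param Z1,Z2 Branch outputs (M x M x d arrays or `padded_grid`s).
#' @param Zg The identity path `Z^` (the padded grid itself).
#' @param params List with `W1`, `b1`, `W2`, `b2` (gate MLP).
#' @param temperature Sigmoid temperature `tau > 0`.
#' @return List with `grid` (gated M x M x d array), `gates` (three length-d
#'   vectors strictly inside (0, 1)) and `L` (the length-3d pre-activation).
#' @export
channel_gate <- function(Z1, Z2, Zg, params, temperature = 1) {
  stopifnot(temperature > 0)
  a <- as_grid_matrix(Z1); b <- as_grid_matrix(Z2); g <- as_grid_matrix(Zg)
  if (!identical(dim(a$Gm), dim(b$Gm)) || !identical(dim(a$Gm), dim(g$Gm)))
    stop("shape error: channel_gate inputs must share M x M x d shape")
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  res <- fwd_channel_gate(ctx, ad_const(tape, a$Gm), ad_const(tape, b$Gm),
                          ad_const(tape, g$Gm), "", temperature)
  list(grid = grid_matrix_to_array(ad_val(res$out), a$M),
       gates = lapply(res$gates, function(n) as.vector(ad_val(n))),
       L = as.vector(ad_val(res$L)))
}

#' Full MCAB forward pass
#'
#' `pad_and_square` -> two depth-wise separable branches (small and large
#' kernel) -> shared-MLP channel gate -> `flatten_and_unpad`. Output length
#' equals input length; padding tokens are created and discarded inside.
#'
#' @param Z Numeric N x d token matrix.
#' @param params Parameters from [mcab_params()].
#' @param kernel_sizes Odd kernel-size pair.
#' @param temperature Gate sigmoid temperature.
#' @param use_pwconv If `FALSE`, drop the point-wise convolutions.
#' @return N x d output token matrix.
#' @export
mcab_forward <- function(Z, params, kernel_sizes = c(3L, 5L),
                         temperature = 1, use_pwconv = TRUE) {
  Z <- check_tokens(Z)
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  out <- fwd_mcab(ctx, ad_const(tape, Z), "", kernel_sizes, temperature,
                  use_pwconv)
  ad_val(out)
}
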