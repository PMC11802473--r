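# Multi-head self-attention: exact softmax attention (the testing oracle and
# the small-bag path) and its Nystrom landmark approximation (the
# linear-complexity path used when N exceeds the landmark count), plus the
# pre-norm residual transformer layer Z^ = MHA(LayerNorm(H)) + H.

# Segment-mean landmark matrix: m contiguous segments of 1..N, as equal as
# possible; row s averages the tokens of segment s. With m == N this is the
# identity, so the landmarks are the tokens themselves.
segment_mean_matrix <- function(N, m) {
  stopifnot(m >= 1L, m <= N)
  sizes <- rep(N %/% m, m)
  extra <- N %% m
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  M <- matrix(0, m, N)
  at <- 0L
  for (s in seq_len(m)) {
    M[s, at + seq_len(sizes[s])] <- 1 / sizes[s]
    at <- at + sizes[s]
  }
  M
}

# Moore-Penrose pseudo-inverse by Newton-Schulz iteration on the tape.
# Third-order scheme V <- V (13 I - AV (15 I - AV (7 I - AV))) / 4 with the
# norm-scaled initialization V0 = A^T / (||A||_1 ||A||_inf), which guarantees
# convergence; the initial scaling factor is treated as a constant.
ad_pinv_ns <- function(A, iters) {
  Av <- ad_val(A)
  m <- nrow(Av)
  s <- 1 / (max(rowSums(abs(Av))) * max(colSums(abs(Av))))
  V <- ad_scale(ad_t(A), s)
  I7 <- 7 * diag(m); I15 <- 15 * diag(m); I13 <- 13 * diag(m)
  for (i in seq_len(iters)) {
    AV <- ad_matmul(A, V)
    T1 <- ad_csub(I7, AV)
    T2 <- ad_csub(I15, ad_matmul(AV, T1))
    T3 <- ad_csub(I13, ad_matmul(AV, T2))
    V <- ad_scale(ad_matmul(V, T3), 0.25)
  }
  V
}

# Multi-head attention on the tape. `method` is "exact", "nystrom" or
# "auto" (exact when N <= n_landmarks, the default policy). `collect`, if an
# environment, receives per-head softmax factors for diagnostics.
fwd_mha <- function(ctx, Xn, pfx, method = "auto", n_heads = 1L,
                    n_landmarks = 128L, pinv_iterations = 20L,
                    collect = NULL) {
  p <- function(nm) ctx_param(ctx, paste0(pfx, nm))
  Q <- ad_add_rowvec(ad_matmul(Xn, p("Wq")), p("bq"))
  K <- ad_add_rowvec(ad_matmul(Xn, p("Wk")), p("bk"))
  V <- ad_add_rowvec(ad_matmul(Xn, p("Wv")), p("bv"))
  N <- nrow(ad_val(Xn))
  d <- ncol(ad_val(Q))
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  sc <- 1 / sqrt(dh)
  use_exact <- method == "exact" || (method == "auto" && N <= n_landmarks)
  m <- min(n_landmarks, N)
  if (!use_exact) Mseg <- ad_const(ctx$tape, segment_mean_matrix(N, m))
  heads <- vector("list", n_heads)
  if (!is.null(collect)) collect$heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    j <- seq.int((h - 1L) * dh + 1L, h * dh)
    Qh <- ad_cols(Q, j); Kh <- ad_cols(K, j); Vh <- ad_cols(V, j)
    if (use_exact) {
      S <- ad_softmax_rows(ad_scale(ad_matmul(Qh, ad_t(Kh)), sc))
      heads[[h]] <- ad_matmul(S, Vh)
      if (!is.null(collect))
        collect$heads[[h]] <- list(S = ad_val(S), exact = TRUE)
    } else {
      Qt <- ad_matmul(Mseg, Qh)
      Kt <- ad_matmul(Mseg, Kh)
      F1 <- ad_softmax_rows(ad_scale(ad_matmul(Qh, ad_t(Kt)), sc))
      F2 <- ad_softmax_rows(ad_scale(ad_matmul(Qt, ad_t(Kt)), sc))
      F3 <- ad_softmax_rows(ad_scale(ad_matmul(Qt, ad_t(Kh)), sc))
      P <- ad_pinv_ns(F2, pinv_iterations)
      heads[[h]] <- ad_matmul(F1, ad_matmul(P, ad_matmul(F3, Vh)))
      if (!is.null(collect))
        collect$heads[[h]] <- list(F1 = ad_val(F1), F2 = ad_val(F2),
                                   F3 = ad_val(F3), pinv_F2 = ad_val(P),
                                   S_hat = ad_val(F1) %*% ad_val(P) %*%
                                     ad_val(F3),
                                   exact = FALSE)
    }
  }
  O <- if (n_heads == 1L) heads[[1L]] else ad_cbind(heads)
  ad_add_rowvec(ad_matmul(O, p("Wo")), p("bo"))
}

fwd_transformer_layer <- function(ctx, H, pfx, method = "auto",
                                  n_heads = 1L, n_landmarks = 128L,
                                  pinv_iterations = 20L) {
  Xn <- ad_layernorm(H, ctx_param(ctx, paste0(pfx, "ln_g")),
                     ctx_param(ctx, paste0(pfx, "ln_b")))
  A <- fwd_mha(ctx, Xn, pfx, method = method, n_heads = n_heads,
               n_landmarks = n_landmarks, pinv_iterations = pinv_iterations)
  ad_add(A, H)
}

#' Random multi-head attention parameters
#'
#' Convenience initializer for the standalone attention operators: query,
#' key, value and output projections (`d x d` with fan-in scaled Gaussian
#' entries) plus biases and layer-norm scale/shift.
#'
#' @param d Token width.
#' @param n_heads Number of heads (must divide `d`).
#' @param seed Integer seed.
#' @return Named list of parameter matrices (`Wq`, `bq`, ..., `Wo`, `bo`,
#'   `ln_g`, `ln_b`).
#' @export
attention_params <- function(d, n_heads = 1L, seed = 1L) {
  stopifnot(d %% n_heads == 0L)
  set.seed(seed)
  sd <- 1 / sqrt(d)
  mk <- function() matrix(stats::rnorm(d * d, sd = sd), d, d)
  list(Wq = mk(), bq = matrix(0, 1L, d),
       Wk = mk(), bk = matrix(0, 1L, d),
       Wv = mk(), bv = matrix(0, 1L, d),
       Wo = mk(), bo = matrix(0, 1L, d),
       ln_g = matrix(1, 1L, d), ln_b = matrix(0, 1L, d))
}

check_tokens <- function(H) {
  H <- as.matrix(H)
  if (!all(is.finite(H))) stop("numeric error: non-finite token values")
  H
}

#' Exact multi-head self-attention
#'
#' Standard softmax attention: per head,
#' `softmax(Q K' / sqrt(d_q)) V`, heads concatenated and passed through the
#' output projection. Quadratic in the number of tokens; serves as the
#' oracle for [nystrom_attention()] and as the small-bag fast path.
#'
#' @param H Numeric N x d token matrix.
#' @param params Parameter list as from [attention_params()].
#' @param n_heads Number of heads.
#' @return N x d output token matrix.
#' @export
exact_attention <- function(H, params, n_heads = 1L) {
  H <- check_tokens(H)
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  out <- fwd_mha(ctx, ad_const(tape, H), "", method = "exact",
                 n_heads = n_heads)
  ad_val(out)
}

#' Nystrom-approximated multi-head self-attention
#'
#' Approximates the softmax attention matrix per head as
#' `softmax(Q Kt'/sqrt(d_q)) pinv(softmax(Qt Kt'/sqrt(d_q)))
#' softmax(Qt K'/sqrt(d_q))`, where the landmark matrices `Qt`, `Kt` are
#' means of `m = n_landmarks` contiguous token segments and the
#' pseudo-inverse is computed by Newton-Schulz iteration. Cost is linear in
#' the number of tokens at fixed `m`. With `method = "auto"` (the model's
#' policy) bags with `N <= n_landmarks` fall back to exact attention, where
#' the approximation is not needed; `method = "nystrom"` forces the
#' approximation (with `m = min(n_landmarks, N)`, so `n_landmarks = N` makes
#' the landmarks the tokens themselves and recovers exact attention up to
#' pseudo-inverse accuracy).
#'
#' @inheritParams exact_attention
#' @param n_landmarks Landmark count `m`.
#' @param pinv_iterations Newton-Schulz iterations for the pseudo-inverse.
#' @param method `"auto"`, `"nystrom"` or `"exact"`.
#' @param diagnostics If `TRUE`, return a list with the output and the
#'   per-head softmax factors (`F1`, `F2`, `F3`, each row-stochastic, and the
#'   assembled approximate softmax matrix `S_hat`).
#' @return N x d output matrix, or a list when `diagnostics = TRUE`.
#' @export
nystrom_attention <- function(H, params, n_heads = 1L, n_landmarks = 128L,
                              pinv_iterations = 20L,
                              method = c("auto", "nystrom", "exact"),
                              diagnostics = FALSE) {
  method <- match.arg(method)
  H <- check_tokens(H)
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  collect <- if (diagnostics) new.env(parent = emptyenv()) else NULL
  out <- fwd_mha(ctx, ad_const(tape, H), "", method = method,
                 n_heads = n_heads, n_landmarks = n_landmarks,
                 pinv_iterations = pinv_iterations, collect = collect)
  if (diagnostics) {
    list(output = ad_val(out), heads = collect$heads)
  } else {
    ad_val(out)
  }
}

#' Pre-norm residual transformer layer
#'
#' Computes `MHA(LayerNorm(H)) + H`: layer normalization is applied before
#' attention and the input is added back unchanged. No feed-forward sublayer
#' follows; spatial mixing alternates with the channel-attention block
#' instead (see [mcab_forward()]).
#'
#' @inheritParams nystrom_attention
#' @param params Parameters from [attention_params()] (includes `ln_g`,
#'   `ln_b`).
#' @return N x d output token matrix.
#' @export
transformer_layer <- function(H, params, n_heads = 1L, n_landmarks = 128L,
                              pinv_iterations = 20L,
                              method = c("auto", "nystrom", "exact")) {
  method <- match.arg(method)
  H <- check_tokens(H)
  if (ncol(H) != ncol(params$Wq))
    stop("shape error: token width ", ncol(H), " does not match parameters (",
         ncol(params$Wq), ")")
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  out <- fwd_transformer_layer(ctx, ad_const(tape, H), "", method = method,
                               n_heads = n_heads, n_landmarks = n_landmarks,
                               pinv_iterations = pinv_iterations)
  ad_val(out)
}
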