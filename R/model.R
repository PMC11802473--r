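# The CAMIL network: input projection, a stack of paired transformer + MCAB
# blocks, slide-level pooling and the classifier head.
#
# Binary tasks use a single sigmoid logit; multi-class tasks a softmax head.
# The default pooling is gated attention: per-instance weights
# a_k = softmax_k( w' (tanh(V z_k) * sigm(U z_k)) ), h = sum_k a_k z_k.

PROB_EPS <- 1e-7

#' Initialize model parameters
#'
#' Builds the flat named-parameter list for a configuration: fan-in scaled
#' Gaussian weights, zero biases, unit layer-norm scales. All randomness
#' comes from `config$seed`.
#'
#' @param config A [camil_config()].
#' @return Named list of parameter matrices.
#' @export
camil_init_params <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  d <- config$d_model
  D <- config$input_dim
  rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  params <- list(
    proj.W = rmat(D, d, 1 / sqrt(D)),
    proj.b = matrix(0, 1L, d)
  )
  hid <- gate_hidden_width(d, config$reduction_ratio)
  for (l in seq_len(config$n_layers)) {
    pfx <- sprintf("l%d.", l)
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      params[[paste0(pfx, nm)]] <- rmat(d, d, 1 / sqrt(d))
    for (nm in c("bq", "bk", "bv", "bo"))
      params[[paste0(pfx, nm)]] <- matrix(0, 1L, d)
    params[[paste0(pfx, "ln_g")]] <- matrix(1, 1L, d)
    params[[paste0(pfx, "ln_b")]] <- matrix(0, 1L, d)
    for (b in 1:2) {
      k <- config$kernel_sizes[b]
      bp <- sprintf("%sc%d.", pfx, b)
      params[[paste0(bp, "dw")]] <- rmat(k * k, d, 1 / k)
      params[[paste0(bp, "db")]] <- matrix(0, 1L, d)
      params[[paste0(bp, "pw")]] <- rmat(d, d, 1 / sqrt(d))
      params[[paste0(bp, "pb")]] <- matrix(0, 1L, d)
    }
    params[[paste0(pfx, "g.W1")]] <- rmat(d, hid, 1 / sqrt(d))
    params[[paste0(pfx, "g.b1")]] <- matrix(0, 1L, hid)
    params[[paste0(pfx, "g.W2")]] <- rmat(hid, 3L * d, 1 / sqrt(hid))
    params[[paste0(pfx, "g.b2")]] <- matrix(0, 1L, 3L * d)
  }
  if (config$pooling == "attention") {
    params$pool.V <- rmat(d, d, 1 / sqrt(d))
    params$pool.U <- rmat(d, d, 1 / sqrt(d))
    params$pool.w <- rmat(d, 1L, 1 / sqrt(d))
  } else if (config$pooling == "class_token") {
    params$pool.cls <- rmat(1L, d, 1 / sqrt(d))
  }
  n_out <- if (config$n_classes == 2L) 1L else config$n_classes
  params$cls.W <- rmat(d, n_out, 1 / sqrt(d))
  params$cls.b <- matrix(0, 1L, n_out)
  params
}

# gated attention pooling on the tape; returns list(h = 1 x d, a = 1 x N)
fwd_gated_pool <- function(ctx, Z) {
  p <- function(nm) ctx_param(ctx, nm)
  gate_t <- ad_tanh(ad_matmul(Z, ad_t(p("pool.V"))))
  gate_s <- ad_sigmoid(ad_matmul(Z, ad_t(p("pool.U"))))
  e <- ad_matmul(ad_mul(gate_t, gate_s), p("pool.w")) # N x 1 scores
  a <- ad_softmax_rows(ad_t(e))                       # 1 x N weights
  list(h = ad_matmul(a, Z), a = a)
}

# Full forward pass on an existing tape. Returns nodes for the logits, the
# pooled representation and (attention pooling only) the instance weights.
fwd_camil <- function(ctx, X, config) {
  d <- config$d_model
  if (ncol(X) != config$input_dim)
    stop("shape error: bag has D = ", ncol(X), " but config$input_dim = ",
         config$input_dim)
  tape <- ctx$tape
  H <- ad_relu(ad_add_rowvec(ad_matmul(ad_const(tape, X),
                                       ctx_param(ctx, "proj.W")),
                             ctx_param(ctx, "proj.b")))
  N <- nrow(X)
  has_cls <- config$pooling == "class_token"
  if (has_cls) H <- ad_rbind(ctx_param(ctx, "pool.cls"), H)
  for (l in seq_len(config$n_layers)) {
    pfx <- sprintf("l%d.", l)
    H <- fwd_transformer_layer(ctx, H, pfx, method = "auto",
                               n_heads = config$n_heads,
                               n_landmarks = config$n_landmarks,
                               pinv_iterations = config$pinv_iterations)
    if (config$use_mcab) {
      if (has_cls) {
        # the class token crosses only transformer layers, never the MCAB
        cls_row <- ad_gather_rows(H, 1L)
        body <- ad_gather_rows(H, 1L + seq_len(N))
        body <- fwd_mcab(ctx, body, pfx, config$kernel_sizes,
                         config$temperature, config$use_pwconv)
        H <- ad_rbind(cls_row, body)
      } else {
        H <- fwd_mcab(ctx, H, pfx, config$kernel_sizes, config$temperature,
                      config$use_pwconv)
      }
    }
  }
  a <- NULL
  h <- switch(config$pooling,
    attention = {
      pooled <- fwd_gated_pool(ctx, H)
      a <- pooled$a
      pooled$h
    },
    class_token = ad_gather_rows(H, 1L),
    max = ad_colmax(H),
    mean = ad_colmeans(H))
  logits <- ad_add_rowvec(ad_matmul(h, ctx_param(ctx, "cls.W")),
                          ctx_param(ctx, "cls.b"))
  list(logits = logits, h = h, a = a)
}

# loss node for one bag given its integer label (0-based)
fwd_loss <- function(ctx, logits, label, n_classes) {
  one <- matrix(1, 1L, 1L)
  if (n_classes == 2L) {
    p <- ad_clamp(ad_sigmoid(logits), PROB_EPS, 1 - PROB_EPS)
    if (label == 1L) ad_scale(ad_log(p), -1)
    else ad_scale(ad_log(ad_csub(one, p)), -1)
  } else {
    probs <- ad_clamp(ad_softmax_rows(logits), PROB_EPS, 1 - PROB_EPS)
    ad_scale(ad_log(ad_cols(probs, label + 1L)), -1)
  }
}

#' Project raw instance features into model tokens
#'
#' Affine map from the encoder dimension D down to `d_model`, followed by
#' ReLU.
#'
#' @param x A `feature_bag` or an N x D matrix.
#' @param params Parameter list containing `proj.W` (D x d) and `proj.b`.
#' @return N x d token matrix.
#' @export
project_input <- function(x, params) {
  X <- if (inherits(x, "feature_bag")) x$features else as.matrix(x)
  if (ncol(X) != nrow(params$proj.W))
    stop("shape error: input has D = ", ncol(X), " but projection expects ",
         nrow(params$proj.W))
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  out <- ad_relu(ad_add_rowvec(ad_matmul(ad_const(tape, X),
                                         ctx_param(ctx, "proj.W")),
                               ctx_param(ctx, "proj.b")))
  ad_val(out)
}

#' Gated attention pooling
#'
#' Per-instance weights `a_k = softmax_k( w' (tanh(V z_k) * sigm(U z_k)) )`
#' and the pooled representation `h = sum_k a_k z_k`. The weights sum to 1
#' and are strictly positive; they are the scores exported for attention
#' heatmaps.
#'
#' @param Z Numeric N x d token matrix.
#' @param params List with `pool.V`, `pool.U` (d x d) and `pool.w` (d x 1).
#' @return List with `h` (length-d vector) and `profile` (list with the
#'   length-N weight vector `a`).
#' @export
gated_attention_pool <- function(Z, params) {
  Z <- check_tokens(Z)
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  pooled <- fwd_gated_pool(ctx, ad_const(tape, Z))
  list(h = as.vector(ad_val(pooled$h)),
       profile = list(a = as.vector(ad_val(pooled$a))))
}

#' Forward pass of the full model on one bag
#'
#' @param bag A `feature_bag` (or N x D matrix).
#' @param params Parameters from [camil_init_params()] (or a fitted model's
#'   `$params`).
#' @param config The matching [camil_config()].
#' @return List with `record` (a prediction record: `slide_id`, `logits`,
#'   `prob`, `pred`, `label`) and `profile` (instance attention weights, or
#'   `NULL` for non-attention pooling).
#' @export
camil_forward <- function(bag, params, config) {
  if (!inherits(bag, "feature_bag")) bag <- feature_bag(bag)
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  fw <- fwd_camil(ctx, bag$features, config)
  logits <- as.vector(ad_val(fw$logits))
  if (config$n_classes == 2L) {
    prob <- 1 / (1 + exp(-logits))
    pred <- as.integer(prob >= 0.5)
  } else {
    e <- exp(logits - max(logits))
    prob <- e / sum(e)
    pred <- which.max(prob) - 1L
  }
  list(record = list(slide_id = bag$slide_id, logits = logits, prob = prob,
                     pred = pred, label = bag$label),
       profile = if (is.null(fw$a)) NULL else
         list(a = as.vector(ad_val(fw$a))))
}

#' Cross-entropy loss over prediction records
#'
#' Mean over bags of the (binary or multi-class) cross-entropy
#' `-[Y log Yhat + (1-Y) log(1-Yhat)]`, probabilities clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param records List of prediction records (see [camil_forward()]), each
#'   with a non-`NULL` `label`.
#' @return Scalar mean loss.
#' @export
bce_loss <- function(records) {
  if (length(records) == 0L) stop("bce_loss: empty record list")
  losses <- vapply(records, function(r) {
    if (is.null(r$label)) stop("bce_loss: record without a label")
    p <- pmin(pmax(r$prob, PROB_EPS), 1 - PROB_EPS)
    if (length(p) == 1L) {
      y <- as.numeric(r$label)
      -(y * log(p) + (1 - y) * log(1 - p))
    } else {
      -log(p[r$label + 1L])
    }
  }, 0)
  mean(losses)
}
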