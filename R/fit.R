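# Model fitting and evaluation.
#
# `camil()` is the fitting entry point: one bag per optimization step
# (variable bag sizes preclude naive batching), Adam with decoupled weight
# decay, early stopping on validation loss, best-validation checkpointing.
# The returned object carries the learned parameters, the resolved
# configuration and the run record, and answers the usual generics.

# Optimizer state lives in environments and is updated in place; the moment
# buffers total as many doubles as the model itself, and functional-style
# copies of them every step would dominate the step cost.
adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st$t <- 0L
  st
}

adam_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  # exact refactor of the bias-corrected update m/c1 / (sqrt(v/c2) + eps):
  # pull the scalar corrections out of the elementwise expressions
  k <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  eps2 <- eps * sqrt(1 - beta2^state$t)
  decay <- 1 - lr * wd
  m <- state$m; v <- state$v
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * (g * g)
    params[[nm]] <- decay * params[[nm]] -
      k * (m[[nm]] / (sqrt(v[[nm]]) + eps2))
  }
  params
}

# loss + parameter gradients for one bag
bag_loss_grads <- function(params, X, label, config, want_grads = TRUE) {
  tape <- ad_tape()
  ctx <- ad_ctx(tape, params)
  fw <- fwd_camil(ctx, X, config)
  loss <- fwd_loss(ctx, fw$logits, label, config$n_classes)
  lv <- ad_val(loss)[1L]
  if (!want_grads) return(list(loss = lv))
  grads <- ctx_param_grads(ctx, ad_backward(loss))
  list(loss = lv, grads = grads)
}

mean_split_loss <- function(params, bags, config) {
  mean(vapply(bags, function(b) {
    bag_loss_grads(params, b$features, b$label, config,
                   want_grads = FALSE)$loss
  }, 0))
}

#' Fit a CAMIL model to labelled feature bags
#'
#' Trains the channel-attention MIL aggregator by gradient descent on the
#' cross-entropy loss, one bag per step, with early stopping on validation
#' loss (falling back to training loss when no validation bags are given).
#' The parameters from the best validation epoch are kept. Fully
#' deterministic for a given configuration and seed.
#'
#' @param bags List of labelled `feature_bag`s (training split).
#' @param val_bags Optional list of validation bags supervising early
#'   stopping.
#' @param config A [camil_config()]; `config$seed` governs initialization
#'   and shuffling.
#' @param verbose Emit one structured line per epoch to the message stream.
#' @return An object of class `camil`: list with `params` (best-epoch
#'   weights), `config`, and `record` (per-epoch train/val loss, best epoch,
#'   elapsed epochs, seed).
#' @export
#' @seealso [predict.camil()], [evaluate_bags()], [export_attention()],
#'   [run_ablation()]
camil <- function(bags, val_bags = NULL, config = camil_config(),
                  verbose = FALSE) {
  validate_config(config)
  if (length(bags) == 0L) stop("empty training split")
  invisible(bag_labels(bags)) # fails early on unlabelled bags
  params <- camil_init_params(config)
  state <- adam_state(params)
  monitor <- if (is.null(val_bags) || length(val_bags) == 0L) "train" else
    "val"
  train_curve <- numeric(0)
  val_curve <- numeric(0)
  best <- list(loss = Inf, epoch = 0L, params = params)
  for (epoch in seq_len(config$max_epochs)) {
    set.seed(config$seed + epoch)
    order_ <- sample.int(length(bags))
    step_losses <- numeric(length(bags))
    for (i in seq_along(order_)) {
      b <- bags[[order_[i]]]
      X <- b$features
      if (config$shuffle_tokens) X <- X[sample.int(nrow(X)), , drop = FALSE]
      fit <- bag_loss_grads(params, X, b$label, config)
      if (!is.finite(fit$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", bag ", b$slide_id)
      step_losses[i] <- fit$loss
      params <- adam_step(params, fit$grads, state, config$learning_rate,
                          config$weight_decay)
    }
    train_curve[epoch] <- mean(step_losses)
    val_curve[epoch] <- if (monitor == "val")
      mean_split_loss(params, val_bags, config) else train_curve[epoch]
    if (verbose)
      message(sprintf("epoch %3d | train loss %.4f | %s loss %.4f", epoch,
                      train_curve[epoch], monitor, val_curve[epoch]))
    if (val_curve[epoch] < best$loss) {
      best <- list(loss = val_curve[epoch], epoch = epoch, params = params)
    }
    if (epoch - best$epoch >= config$patience) break
  }
  record <- list(config = config, train_loss = train_curve,
                 val_loss = val_curve, monitor = monitor,
                 best_epoch = best$epoch, best_loss = best$loss,
                 epochs = length(train_curve), seed = config$seed,
                 n_train = length(bags),
                 n_val = if (monitor == "val") length(val_bags) else 0L)
  structure(list(params = best$params, config = config, record = record),
            class = "camil")
}

#' @export
print.camil <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("CAMIL model: %d x (transformer + MCAB), d_model %d, pooling %s, %d classes\n",
              cfg$n_layers, cfg$d_model, cfg$pooling, cfg$n_classes))
  cat(sprintf("  trained %d epoch(s) on %d bags; best %s loss %.4f at epoch %d\n",
              x$record$epochs, x$record$n_train, x$record$monitor,
              x$record$best_loss, x$record$best_epoch))
  invisible(x)
}

#' @export
summary.camil <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, 0L))
  out <- list(config = object$config, record = object$record,
              n_parameters = n_par)
  class(out) <- "summary.camil"
  out
}

#' @export
print.summary.camil <- function(x, ...) {
  print(x$config)
  cat(sprintf("parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  cat(sprintf("epochs run: %d (best %s loss %.4f at epoch %d)\n",
              x$record$epochs, x$record$monitor, x$record$best_loss,
              x$record$best_epoch))
  invisible(x)
}

#' @export
coef.camil <- function(object, ...) object$params

#' @export
plot.camil <- function(x, ...) {
  r <- x$record
  ylim <- range(c(r$train_loss, r$val_loss))
  graphics::plot(seq_along(r$train_loss), r$train_loss, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss", ylim = ylim,
                 main = "CAMIL training", ...)
  graphics::lines(seq_along(r$val_loss), r$val_loss, lty = 2)
  graphics::abline(v = r$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", legend = c("train", r$monitor),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

as_bag_list <- function(newdata) {
  if (inherits(newdata, "feature_bag")) return(list(newdata))
  if (is.matrix(newdata)) return(list(feature_bag(newdata)))
  stopifnot(is.list(newdata))
  newdata
}

#' Predict slide labels or probabilities for feature bags
#'
#' @param object A fitted `camil` model.
#' @param newdata A `feature_bag`, a list of them, or an N x D matrix (one
#'   bag).
#' @param type `"prob"` (positive-class probability or probability matrix),
#'   `"class"` (0-based predicted labels) or `"record"` (full prediction
#'   records including logits and true labels where known).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.camil <- function(object, newdata,
                          type = c("prob", "class", "record"), ...) {
  type <- match.arg(type)
  bags <- as_bag_list(newdata)
  records <- lapply(bags, function(b)
    camil_forward(b, object$params, object$config)$record)
  switch(type,
    record = records,
    class = vapply(records, `[[`, 0L, "pred"),
    prob = if (object$config$n_classes == 2L)
      vapply(records, `[[`, 0, "prob")
    else do.call(rbind, lapply(records, `[[`, "prob")))
}

#' Evaluate a fitted model on a bag split
#'
#' Runs the model over every bag, computes the metrics report and optionally
#' writes `metrics.json` and `predictions.csv`.
#'
#' @param object A fitted `camil` model (or loaded checkpoint).
#' @param bags Labelled bags to score.
#' @param out_dir Optional directory for the JSON report and predictions
#'   CSV.
#' @return List with `report` (a [mil_metrics()] report) and `records`
#'   (prediction data frame).
#' @export
evaluate_bags <- function(object, bags, out_dir = NULL) {
  bags <- as_bag_list(bags)
  if (length(bags) == 0L) stop("empty bag list")
  if (ncol(bags[[1L]]$features) != object$config$input_dim)
    stop("dimension mismatch: bags have D = ", ncol(bags[[1L]]$features),
         " but checkpoint expects ", object$config$input_dim)
  records <- predict(object, bags, type = "record")
  y <- vapply(records, `[[`, 0L, "label")
  prob <- if (object$config$n_classes == 2L)
    vapply(records, `[[`, 0, "prob")
  else do.call(rbind, lapply(records, `[[`, "prob"))
  report <- mil_metrics(y, prob, n_classes = object$config$n_classes)
  df <- data.frame(slide_id = vapply(records, `[[`, "", "slide_id"),
                   label = y,
                   pred = vapply(records, `[[`, 0L, "pred"),
                   stringsAsFactors = FALSE)
  if (is.matrix(prob)) {
    colnames(prob) <- paste0("prob_", seq_len(ncol(prob)) - 1L)
    df <- cbind(df, prob)
  } else df$prob <- prob
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_json(report, file.path(out_dir, "metrics.json"))
    utils::write.csv(df, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
  }
  list(report = report, records = df)
}

#' Export per-instance attention scores for heatmap rendering
#'
#' Runs the attention-pooled model on one bag and returns the pooling
#' weights per instance, with the bag's patch-grid coordinates when present.
#' Scores sum to 1 over the slide.
#'
#' @param object A fitted `camil` model with `pooling = "attention"`.
#' @param bag A `feature_bag`.
#' @param path Optional CSV output path.
#' @return Data frame with columns `slide_id`, `instance_index`, `x`, `y`,
#'   `attention_score`.
#' @export
export_attention <- function(object, bag, path = NULL) {
  if (object$config$pooling != "attention")
    stop("unsupported mode: attention export requires pooling = \"attention\", ",
         "got \"", object$config$pooling, "\"")
  fw <- camil_forward(bag, object$params, object$config)
  a <- fw$profile$a
  n <- length(a)
  df <- data.frame(slide_id = bag$slide_id, instance_index = seq_len(n),
                   x = if (is.null(bag$coords)) NA_integer_ else
                     bag$coords[, 1L],
                   y = if (is.null(bag$coords)) NA_integer_ else
                     bag$coords[, 2L],
                   attention_score = a, stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Save or load a model checkpoint
#'
#' A checkpoint is the flat named-parameter list plus the resolved
#' configuration and run record.
#'
#' @param object A fitted `camil` model.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns the restored `camil` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "camil"))
  saveRDS(list(format = "camil-checkpoint-v1", params = object$params,
               config = unclass(object$config), record = object$record),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "camil-checkpoint-v1"))
    stop("not a camil checkpoint: ", path)
  cfg <- x$config
  class(cfg) <- "camil_config"
  structure(list(params = x$params, config = cfg, record = x$record),
            class = "camil")
}

#' Write a run record as JSON
#'
#' @param object A fitted `camil` model.
#' @param path Output path.
#' @export
write_run_record <- function(object, path) {
  r <- object$record
  r$config <- unclass(r$config)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
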