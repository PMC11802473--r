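# Model and training configuration.

#' Model configuration
#'
#' Builds the full set of architectural and training hyperparameters for a
#' CAMIL model. Any subset may be overridden; the rest take the defaults
#' below, which follow the published architecture: a four-deep stack of
#' paired transformer and multi-scale channel attention (MCAB) modules over
#' 512-dimensional tokens, 3x3 and 5x5 depth-wise kernels, and gated
#' attention pooling.
#'
#' @param d_model Token width of the aggregator (instance features are
#'   projected from `input_dim` down to this). Default 512.
#' @param n_layers Number of paired transformer + MCAB blocks. Default 4.
#' @param kernel_sizes Integer pair of odd depth-wise convolution kernel
#'   sizes for the two MCAB branches. Default `c(3, 5)`.
#' @param reduction_ratio Hidden-layer reduction ratio `r` of the shared
#'   channel-gate MLP (`d -> d/r -> 3d`). Default 16.
#' @param temperature Temperature `tau` of the channel-gate sigmoid
#'   `1/(1 + exp(-tau * x))`; larger values sharpen channel selection.
#'   Must be positive. Default 1.
#' @param n_heads Attention heads; must divide `d_model`. Default 8.
#' @param n_landmarks Landmark count `m` of the Nystrom attention
#'   approximation; bags with `N <= m` instances use exact attention.
#'   Default 128.
#' @param pinv_iterations Newton-Schulz iterations for the pseudo-inverse in
#'   the Nystrom core. Default 20: the third-order iteration needs roughly
#'   `log3(condition number)` extra steps, and small softmax kernels can be
#'   conditioned as badly as 1e3, while the added cost (m x m products) is
#'   negligible.
#' @param pooling Slide-level pooling: `"attention"` (gated attention,
#'   default), `"class_token"`, `"max"` or `"mean"`.
#' @param n_classes Number of slide classes (2 = binary head with a single
#'   sigmoid logit; >2 = softmax head).
#' @param input_dim Dimension D of the raw instance features produced by the
#'   external patch encoder. Default 1024.
#' @param learning_rate,weight_decay Adam step size and decoupled weight
#'   decay. Defaults 1e-4 and 1e-5.
#' @param max_epochs,patience Epoch cap and early-stopping patience on
#'   validation loss. Defaults 100 and 10.
#' @param batch_size Bags per optimization step; variable bag sizes make 1
#'   the only supported value.
#' @param seed Integer seed governing all randomness (initialization,
#'   shuffling).
#' @param dropout Attention/projection dropout rate (default 0; kept for
#'   experimentation, off in the published configuration).
#' @param use_mcab If `FALSE` the MCAB is bypassed (identity), leaving a pure
#'   transformer aggregator; used by the token-order ablation as the
#'   positional-encoding-free reference.
#' @param use_pwconv If `FALSE` the point-wise (1x1) convolutions are removed
#'   from both MCAB branches ("w/o PWConv" ablation).
#' @param shuffle_tokens If `TRUE` the training loop shuffles instance order
#'   within each bag once per epoch (seeded); the token-order ablation axis.
#'
#' @return An object of class `camil_config` (a validated named list).
#' @export
#' @examples
#' cfg <- camil_config(n_classes = 2, input_dim = 64, d_model = 64)
#' cfg$kernel_sizes
camil_config <- function(d_model = 512L,
                         n_layers = 4L,
                         kernel_sizes = c(3L, 5L),
                         reduction_ratio = 16L,
                         temperature = 1,
                         n_heads = 8L,
                         n_landmarks = 128L,
                         pinv_iterations = 20L,
                         pooling = c("attention", "class_token", "max", "mean"),
                         n_classes = 2L,
                         input_dim = 1024L,
                         learning_rate = 1e-4,
                         weight_decay = 1e-5,
                         max_epochs = 100L,
                         patience = 10L,
                         batch_size = 1L,
                         seed = 1L,
                         dropout = 0,
                         use_mcab = TRUE,
                         use_pwconv = TRUE,
                         shuffle_tokens = FALSE) {
  pooling <- match.arg(pooling)
  cfg <- list(
    d_model = as.integer(d_model), n_layers = as.integer(n_layers),
    kernel_sizes = as.integer(kernel_sizes),
    reduction_ratio = as.integer(reduction_ratio),
    temperature = as.numeric(temperature), n_heads = as.integer(n_heads),
    n_landmarks = as.integer(n_landmarks),
    pinv_iterations = as.integer(pinv_iterations), pooling = pooling,
    n_classes = as.integer(n_classes), input_dim = as.integer(input_dim),
    learning_rate = as.numeric(learning_rate),
    weight_decay = as.numeric(weight_decay),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    batch_size = as.integer(batch_size), seed = as.integer(seed),
    dropout = as.numeric(dropout), use_mcab = isTRUE(use_mcab),
    use_pwconv = isTRUE(use_pwconv), shuffle_tokens = isTRUE(shuffle_tokens)
  )
  class(cfg) <- "camil_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "camil_config"))
  err <- function(...) stop("config error: ", ..., call. = FALSE)
  if (cfg$d_model < 1L) err("d_model must be >= 1")
  if (cfg$d_model %% cfg$n_heads != 0L)
    err("d_model (", cfg$d_model, ") must be divisible by n_heads (",
        cfg$n_heads, ")")
  if (length(cfg$kernel_sizes) != 2L)
    err("kernel_sizes must be a pair of odd integers")
  if (any(cfg$kernel_sizes < 1L) || any(cfg$kernel_sizes %% 2L == 0L))
    err("kernel sizes must be odd and >= 1, got (",
        paste(cfg$kernel_sizes, collapse = ", "), ")")
  if (cfg$temperature <= 0) err("temperature must be > 0")
  if (cfg$reduction_ratio < 1L) err("reduction_ratio must be >= 1")
  if (cfg$n_classes < 2L) err("n_classes must be >= 2")
  if (cfg$n_landmarks < 1L) err("n_landmarks must be >= 1")
  if (cfg$pinv_iterations < 1L) err("pinv_iterations must be >= 1")
  if (cfg$batch_size != 1L) err("batch_size must be 1 (one bag per step)")
  if (cfg$patience < 0L) err("patience must be >= 0")
  if (cfg$max_epochs < 1L) err("max_epochs must be >= 1")
  if (cfg$dropout < 0 || cfg$dropout >= 1) err("dropout must be in [0, 1)")
  invisible(cfg)
}

# hidden width of the channel-gate MLP: floor(d/r), at least 1
gate_hidden_width <- function(d, r) max(1L, d %/% r)

#' Load a model configuration from a key-value file
#'
#' Reads a flat YAML file of configuration keys, fills unspecified keys with
#' the [camil_config()] defaults, validates the result and echoes the fully
#' resolved configuration to the message stream. Unknown keys are an error
#' (listing the valid ones), so typos never silently fall back to defaults.
#'
#' @param path Path to a YAML (or empty) file.
#' @param quiet If `TRUE`, suppress the resolved-config echo.
#' @return A `camil_config` object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config error: file must be a flat key-value map")
  valid <- names(formals(camil_config))
  unknown <- setdiff(names(raw), valid)
  if (length(unknown) > 0L)
    stop("config error: unknown key(s) ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "), call. = FALSE)
  if (!is.null(raw$kernel_sizes)) raw$kernel_sizes <- unlist(raw$kernel_sizes)
  cfg <- do.call(camil_config, raw)
  if (!quiet) {
    message("resolved configuration:")
    for (k in names(cfg)) {
      message("  ", k, " = ", paste(cfg[[k]], collapse = " "))
    }
  }
  cfg
}

#' @export
print.camil_config <- function(x, ...) {
  cat("CAMIL configuration\n")
  cat(sprintf("  aggregator: %d x (transformer + MCAB), d_model = %d, %d heads\n",
              x$n_layers, x$d_model, x$n_heads))
  cat(sprintf("  MCAB: kernels (%s), r = %d, tau = %g, pwconv = %s, enabled = %s\n",
              paste(x$kernel_sizes, collapse = ", "), x$reduction_ratio,
              x$temperature, x$use_pwconv, x$use_mcab))
  cat(sprintf("  attention: Nystrom with %d landmarks (%d pinv iters), exact when N <= m\n",
              x$n_landmarks, x$pinv_iterations))
  cat(sprintf("  head: pooling = %s, %d classes, input dim %d\n",
              x$pooling, x$n_classes, x$input_dim))
  cat(sprintf("  training: lr = %g, wd = %g, max %d epochs, patience %d, seed %d\n",
              x$learning_rate, x$weight_decay, x$max_epochs, x$patience,
              x$seed))
  invisible(x)
}
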