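# Ablation runner: retrains the model along one design axis on identical
# seeded splits and tabulates test metrics per variant.

ablation_variants <- function(axis) {
  switch(axis,
    pooling = lapply(c("attention", "class_token", "max", "mean"),
                     function(p) list(label = p, pooling = p)),
    kernels = {
      pairs <- list(c(3L, 5L), c(3L, 7L), c(5L, 7L))
      out <- list()
      for (kp in pairs) for (pw in c(TRUE, FALSE)) {
        out[[length(out) + 1L]] <- list(
          label = sprintf("%dx%d_%dx%d%s", kp[1L], kp[1L], kp[2L], kp[2L],
                          if (pw) "" else "_no_pwconv"),
          kernel_sizes = kp, use_pwconv = pw)
      }
      out
    },
    token_order = list(list(label = "ordered", shuffle_tokens = FALSE),
                       list(label = "shuffled", shuffle_tokens = TRUE)),
    pwconv = list(list(label = "with_pwconv", use_pwconv = TRUE),
                  list(label = "no_pwconv", use_pwconv = FALSE)),
    stop("unknown ablation axis: ", axis))
}

#' Run an ablation study along one design axis
#'
#' Splits the bags once (patient-safe, seeded), then trains and evaluates
#' one model per variant of the chosen axis, holding everything else —
#' splits, initialization seed, training schedule — identical. Axes:
#' \describe{
#'   \item{`pooling`}{attention, class-token, max, mean pooling.}
#'   \item{`kernels`}{depth-wise kernel pairs 3x3/5x5, 3x3/7x7, 5x5/7x7,
#'     each with and without the point-wise convolution.}
#'   \item{`token_order`}{instances in their grid order vs shuffled
#'     (seeded) per bag per epoch — probes the MCAB's positional encoding.}
#'   \item{`pwconv`}{point-wise convolution on/off at the default kernels.}
#' }
#'
#' @param bags List of labelled `feature_bag`s.
#' @param axis One of `"kernels"`, `"token_order"`, `"pooling"`,
#'   `"pwconv"`.
#' @param config Base [camil_config()] shared by all variants.
#' @param split_seed Seed for the train/val/test split.
#' @param out_dir Optional directory for `ablation_<axis>.csv` and `.json`.
#' @param verbose Forwarded to [camil()].
#' @return Data frame (class `camil_ablation`) with one row per variant:
#'   `variant`, `accuracy`, `f1`, `auc`, `best_epoch`, `epochs`. The fitted
#'   models are attached as attribute `"models"` and the shared split slide
#'   ids as attribute `"splits"`.
#' @export
run_ablation <- function(bags, axis = c("kernels", "token_order", "pooling",
                                        "pwconv"),
                         config = camil_config(), split_seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  axis <- match.arg(axis)
  splits <- split_bags(bags, ratio = c(3, 1, 1), by_patient = TRUE,
                       seed = split_seed)
  variants <- ablation_variants(axis)
  rows <- vector("list", length(variants))
  models <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    cfg <- config
    for (nm in setdiff(names(v), "label")) cfg[[nm]] <- v[[nm]]
    validate_config(cfg)
    fit <- camil(splits$train, splits$val, cfg, verbose = verbose)
    ev <- evaluate_bags(fit, splits$test)
    rows[[i]] <- data.frame(variant = v$label,
                            accuracy = ev$report$accuracy,
                            f1 = ev$report$f1, auc = ev$report$auc,
                            best_epoch = fit$record$best_epoch,
                            epochs = fit$record$epochs,
                            stringsAsFactors = FALSE)
    models[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  attr(out, "models") <- stats::setNames(models, out$variant)
  attr(out, "splits") <- lapply(splits, function(s)
    vapply(s, `[[`, "", "slide_id"))
  class(out) <- c("camil_ablation", class(out))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(out),
                     file.path(out_dir, paste0("ablation_", axis, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(as.data.frame(out),
                         file.path(out_dir, paste0("ablation_", axis,
                                                   ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.camil_ablation <- function(x, ...) {
  cat("ablation axis:", attr(x, "axis"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
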