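# Training loop, evaluation, attention export, checkpoints, ablation
# machinery and the command-line wrapper, all at deliberately small scale.

fit_tiny <- function(ds, cfg = tiny_config(max_epochs = 4L), seed = 1L) {
  sp <- split_bags(ds$bags, ratio = c(3, 1, 1), seed = seed)
  list(fit = camil(sp$train, val_bags = sp$val, config = cfg), split = sp)
}

test_that("training reduces the validation loss on separable data", {
  ds <- tiny_dataset(n_bags = 24L, seed = 71L)
  sp <- split_bags(ds$bags, ratio = c(3, 1, 1), seed = 1L)
  cfg <- tiny_config(max_epochs = 6L, learning_rate = 1e-3)
  fit <- camil(sp$train, val_bags = sp$val, config = cfg)
  expect_lt(min(fit$record$val_loss), fit$record$val_loss[1L])
  expect_identical(fit$record$best_epoch, which.min(fit$record$val_loss))
  expect_s3_class(fit, "camil")
})

test_that("patience zero trains for exactly one epoch", {
  ds <- tiny_dataset(n_bags = 12L, seed = 72L)
  sp <- split_bags(ds$bags, ratio = c(2, 1, 1), seed = 1L)
  cfg <- tiny_config(max_epochs = 10L, patience = 0L)
  fit <- camil(sp$train, val_bags = sp$val, config = cfg)
  expect_identical(fit$record$epochs, 1L)
})

test_that("identical config and seed reproduce the loss curves exactly", {
  ds <- tiny_dataset(n_bags = 12L, seed = 73L)
  sp <- split_bags(ds$bags, ratio = c(2, 1, 1), seed = 1L)
  cfg <- tiny_config(max_epochs = 3L)
  f1 <- camil(sp$train, val_bags = sp$val, config = cfg)
  f2 <- camil(sp$train, val_bags = sp$val, config = cfg)
  expect_identical(f1$record$train_loss, f2$record$train_loss)
  expect_identical(f1$record$val_loss, f2$record$val_loss)
  expect_identical(f1$params, f2$params)
})

test_that("training without a validation split monitors the training loss", {
  ds <- tiny_dataset(n_bags = 8L, seed = 74L)
  cfg <- tiny_config(max_epochs = 2L)
  fit <- camil(ds$bags, config = cfg)
  expect_identical(fit$record$monitor, "train")
  expect_identical(fit$record$val_loss, fit$record$train_loss)
  expect_identical(fit$record$n_val, 0L)
})

test_that("unlabelled bags abort training early", {
  b <- feature_bag(matrix(rnorm(8), 2, 4), slide_id = "nolab")
  expect_error(camil(list(b), config = tiny_config()), "label")
  expect_error(camil(list(), config = tiny_config()), "empty")
})

test_that("the fitted object answers the classic S3 generics", {
  ds <- tiny_dataset(n_bags = 12L, seed = 75L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 2L))
  fit <- r$fit
  expect_output(print(fit), "CAMIL")
  expect_output(print(summary(fit)), "epoch")
  cf <- coef(fit)
  expect_true(is.list(cf) && "proj.W" %in% names(cf))
  pr <- predict(fit, r$split$test)
  expect_length(pr, length(r$split$test))
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, r$split$test, type = "class")
  expect_true(all(cl %in% c(0L, 1L)))
  rec <- predict(fit, r$split$test[[1L]], type = "record")
  expect_identical(rec[[1L]]$slide_id, r$split$test[[1L]]$slide_id)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("evaluation reports reproduce from the written predictions CSV", {
  ds <- tiny_dataset(n_bags = 16L, seed = 76L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 2L))
  out <- tempfile()
  ev <- evaluate_bags(r$fit, r$split$test, out_dir = out)
  df <- utils::read.csv(file.path(out, "predictions.csv"))
  expect_equal(compute_accuracy(df$label, df$prob), ev$report$accuracy)
  expect_equal(compute_auc(df$label, df$prob), ev$report$auc)
  expect_equal(compute_f1(df$label, df$prob), ev$report$f1)
  js <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_equal(js$auc, ev$report$auc)
})

test_that("evaluation rejects dimension mismatches and empty lists", {
  ds <- tiny_dataset(n_bags = 8L, seed = 77L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 1L))
  wrong <- list(feature_bag(matrix(1, 2, 9), slide_id = "w", label = 0L))
  expect_error(evaluate_bags(r$fit, wrong), "dimension mismatch")
  expect_error(evaluate_bags(r$fit, list()), "empty")
})

test_that("attention export is normalized, coordinate-tagged and gated by mode", {
  ds <- tiny_dataset(n_bags = 8L, seed = 78L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 1L))
  b <- r$split$test[[1L]]
  path <- tempfile(fileext = ".csv")
  df <- export_attention(r$fit, b, path = path)
  expect_identical(nrow(df), nrow(b$features))
  expect_equal(sum(df$attention_score), 1, tolerance = 1e-9)
  expect_identical(df$instance_index, seq_len(nrow(b$features)))
  expect_identical(df$x, as.integer(b$coords[, 1L]))
  expect_true(file.exists(path))
  one <- feature_bag(matrix(rnorm(4), 1, 4), slide_id = "one")
  d1 <- export_attention(r$fit, one)
  expect_identical(nrow(d1), 1L)
  expect_equal(d1$attention_score, 1, tolerance = 1e-12)
  cfgm <- tiny_config(max_epochs = 1L, pooling = "mean")
  fitm <- fit_tiny(ds, cfgm)$fit
  expect_error(export_attention(fitm, b), "unsupported mode")
})

test_that("checkpoints round-trip the model", {
  ds <- tiny_dataset(n_bags = 8L, seed = 79L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 1L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(r$fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, r$fit$params)
  expect_identical(predict(back, r$split$test), predict(r$fit, r$split$test))
  suppressWarnings(expect_error(load_checkpoint(tempfile()), "."))
})

test_that("run records serialize config, curves and the best epoch", {
  ds <- tiny_dataset(n_bags = 8L, seed = 80L)
  r <- fit_tiny(ds, tiny_config(max_epochs = 2L))
  path <- tempfile(fileext = ".json")
  write_run_record(r$fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$config$d_model, 8L)
  expect_length(js$train_loss, r$fit$record$epochs)
  expect_equal(js$best_epoch, r$fit$record$best_epoch)
})

test_that("ablation axes enumerate exactly the published variants", {
  expect_identical(vapply(ablation_variants("pooling"), `[[`, "", "label"),
                   c("attention", "class_token", "max", "mean"))
  kv <- ablation_variants("kernels")
  expect_length(kv, 6L)
  pairs <- t(vapply(kv, `[[`, integer(2), "kernel_sizes"))
  expect_identical(unique(pairs), rbind(c(3L, 5L), c(3L, 7L), c(5L, 7L)))
  expect_identical(vapply(kv, `[[`, TRUE, "use_pwconv"),
                   rep(c(TRUE, FALSE), 3L))
  expect_identical(vapply(ablation_variants("token_order"), `[[`, "", "label"),
                   c("ordered", "shuffled"))
  expect_length(ablation_variants("pwconv"), 2L)
  expect_error(ablation_variants("nope"), ".")
})

test_that("the ablation runner shares splits across variants", {
  ds <- tiny_dataset(n_bags = 16L, seed = 81L)
  out <- tempfile()
  tab <- run_ablation(ds$bags, axis = "pooling",
                      config = tiny_config(max_epochs = 1L),
                      split_seed = 2L, out_dir = out)
  expect_s3_class(tab, "camil_ablation")
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$variant,
                   c("attention", "class_token", "max", "mean"))
  models <- attr(tab, "models")
  splits <- lapply(models, function(m) m$record$n_train)
  expect_length(unique(splits), 1L)
  expect_true(file.exists(file.path(out, "ablation_pooling.csv")))
  expect_true(file.exists(file.path(out, "ablation_pooling.json")))
  expect_output(print(tab), "pooling")
})

test_that("the command-line wrapper runs simulate, train, evaluate end to end", {
  cli <- system.file("cli", "camil.R", package = "camil")
  skip_if(cli == "", "CLI script not installed")
  rbin <- file.path(R.home("bin"), "Rscript")
  work <- tempfile(); dir.create(work)
  run <- function(...) {
    res <- suppressWarnings(system2(rbin, c(cli, ...), stdout = TRUE,
                                    stderr = TRUE))
    expect_true(is.null(attr(res, "status")) || attr(res, "status") == 0L,
                info = paste(res, collapse = "\n"))
    res
  }
  bags_dir <- file.path(work, "bags")
  run("simulate", "--n-bags", "12", "--bag-size-min", "4", "--bag-size-max",
      "8", "--feature-dim", "4", "--separation", "4", "--seed", "3",
      "--out", bags_dir)
  expect_true(file.exists(file.path(bags_dir, "labels.csv")))
  cfg <- file.path(work, "config.yaml")
  writeLines(c("d_model: 8", "n_layers: 1", "n_heads: 2", "input_dim: 4",
               "reduction_ratio: 2", "max_epochs: 1", "n_landmarks: 8"), cfg)
  ckpt <- file.path(work, "model.rds")
  run("train", "--config", cfg, "--bags-dir", bags_dir,
      "--labels", file.path(bags_dir, "labels.csv"), "--out", ckpt)
  expect_true(file.exists(ckpt))
  evdir <- file.path(work, "eval")
  run("evaluate", "--checkpoint", ckpt, "--bags-dir", bags_dir,
      "--labels", file.path(bags_dir, "labels.csv"), "--out", evdir)
  expect_true(file.exists(file.path(evdir, "metrics.json")))
  slide <- list.files(bags_dir, pattern = "[.]bag$", full.names = TRUE)[1L]
  att <- file.path(work, "att.csv")
  run("export-attention", "--checkpoint", ckpt, "--slide", slide,
      "--out", att)
  expect_true(file.exists(att))
  expect_gt(nrow(utils::read.csv(att)), 0L)
})
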