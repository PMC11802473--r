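test_that("generator honors the MIL bag-label semantics by construction", {
  ds <- tiny_dataset(n_bags = 30L, seed = 61L)
  for (b in ds$bags) {
    wit <- ds$witness_masks[[b$slide_id]]
    expect_length(wit, nrow(b$features))
    if (b$label == 1L) expect_gte(sum(wit), 1L) else
      expect_identical(sum(wit), 0L)
  }
})

test_that("positive bags carry ceiling(witness_rate * N) witnesses", {
  spec <- synthetic_spec(n_bags = 40L, bag_size_range = c(10L, 30L),
                         witness_rate = 0.3, feature_dim = 8L, seed = 62L)
  ds <- generate_bags(spec)
  for (b in ds$bags) {
    if (b$label != 1L) next
    n <- nrow(b$features)
    expect_identical(sum(ds$witness_masks[[b$slide_id]]),
                     as.integer(ceiling(0.3 * n)))
  }
})

test_that("witness instances are shifted along the seeded unit direction", {
  spec <- synthetic_spec(n_bags = 60L, bag_size_range = c(40L, 60L),
                         witness_rate = 0.5, feature_dim = 16L,
                         separation = 6, noise_sd = 1, seed = 63L)
  ds <- generate_bags(spec)
  u <- ds$directions[, 1L]
  expect_equal(sum(u * u), 1, tolerance = 1e-12)
  wit <- bg <- c()
  for (b in ds$bags) {
    proj <- b$features %*% u
    m <- ds$witness_masks[[b$slide_id]]
    wit <- c(wit, proj[m]); bg <- c(bg, proj[!m])
  }
  # witnesses project near the separation delta, background near 0
  expect_equal(mean(wit), 6, tolerance = 0.2)
  expect_equal(mean(bg), 0, tolerance = 0.2)
})

test_that("empirical witness fraction matches witness_rate within binomial error", {
  spec <- synthetic_spec(n_bags = 100L, bag_size_range = c(50L, 100L),
                         witness_rate = 0.3, feature_dim = 8L, seed = 64L)
  ds <- generate_bags(spec)
  fracs <- vapply(ds$bags[vapply(ds$bags, `[[`, 0L, "label") == 1L],
                  function(b) mean(ds$witness_masks[[b$slide_id]]), 0)
  # ceiling() only rounds up: within 1/min(N) of the target
  expect_true(all(fracs >= 0.3 & fracs <= 0.3 + 1 / 50))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  a <- tiny_dataset(seed = 65L); b <- tiny_dataset(seed = 65L)
  c_ <- tiny_dataset(seed = 66L)
  expect_identical(lapply(a$bags, `[[`, "features"),
                   lapply(b$bags, `[[`, "features"))
  expect_false(identical(a$bags[[1L]]$features, c_$bags[[1L]]$features))
})

test_that("bag sizes stay inside the requested range", {
  spec <- synthetic_spec(n_bags = 50L, bag_size_range = c(7L, 11L),
                         feature_dim = 4L, seed = 67L)
  ds <- generate_bags(spec)
  sizes <- vapply(ds$bags, function(b) nrow(b$features), 0L)
  expect_true(all(sizes >= 7L & sizes <= 11L))
})

test_that("invalid generator settings produce config errors", {
  expect_error(synthetic_spec(witness_rate = 0), "config error")
  expect_error(synthetic_spec(witness_rate = 1.2), "config error")
  expect_error(synthetic_spec(bag_size_range = c(10L, 5L)), "config error")
  expect_error(synthetic_spec(n_bags = 0L), "config error")
  expect_error(synthetic_spec(noise_sd = -1), "config error")
})

test_that("splits are stratified, disjoint, exhaustive and patient-safe", {
  spec <- synthetic_spec(n_bags = 60L, bag_size_range = c(4L, 6L),
                         feature_dim = 4L, slides_per_patient = 2L,
                         seed = 68L)
  ds <- generate_bags(spec)
  sp <- split_bags(ds$bags, ratio = c(3, 1, 1), seed = 1L)
  ids <- lapply(sp, function(s) vapply(s, `[[`, "", "slide_id"))
  expect_identical(sort(unname(unlist(ids))),
                   sort(vapply(ds$bags, `[[`, "", "slide_id")))
  expect_length(intersect(ids$train, ids$val), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  pat <- lapply(sp, function(s) unique(vapply(s, `[[`, "", "patient_id")))
  expect_length(intersect(pat$train, pat$val), 0L)
  expect_length(intersect(pat$train, pat$test), 0L)
  expect_length(intersect(pat$val, pat$test), 0L)
  # stratification: each split keeps both classes
  for (s in sp) {
    labs <- vapply(s, `[[`, 0L, "label")
    expect_true(all(c(0L, 1L) %in% labs))
  }
})

test_that("k-fold folds partition patients without overlap", {
  spec <- synthetic_spec(n_bags = 40L, bag_size_range = c(4L, 6L),
                         feature_dim = 4L, slides_per_patient = 2L,
                         seed = 69L)
  ds <- generate_bags(spec)
  folds <- kfold_bags(ds$bags, k = 4L)
  expect_length(folds, 4L)
  all_ids <- unlist(lapply(folds, function(f)
    vapply(f$test, `[[`, "", "slide_id")))
  expect_identical(sort(all_ids), sort(vapply(ds$bags, `[[`, "", "slide_id")))
  for (f in folds) {
    ptr <- unique(vapply(f$train, `[[`, "", "patient_id"))
    pte <- unique(vapply(f$test, `[[`, "", "patient_id"))
    expect_length(intersect(ptr, pte), 0L)
  }
})

test_that("a written dataset flows back through the generic readers", {
  ds <- tiny_dataset(n_bags = 8L, seed = 70L)
  dir <- file.path(tempfile(), "ds")
  write_bag_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  bags <- read_bag_dir(dir, read_label_table(file.path(dir, "labels.csv")))
  expect_length(bags, 8L)
  lab0 <- vapply(ds$bags, `[[`, 0L, "label")
  names(lab0) <- vapply(ds$bags, `[[`, "", "slide_id")
  for (b in bags) expect_identical(b$label, lab0[[b$slide_id]])
})
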