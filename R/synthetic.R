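# Synthetic MIL bag generator.
#
# Emulates the statistical structure of the MIL assumption in feature space:
# background instances are isotropic Gaussians around the origin; each
# positive class c has a fixed unit "witness direction" u_c, and its witness
# instances are Gaussians shifted by a separation delta along u_c. A bag is
# negative iff it contains zero witnesses; positive bags contain
# ceiling(witness_rate * N) witnesses at random positions. Per-instance
# witness masks are returned as ground truth for attention-enrichment tests.

#' Specification for the synthetic bag generator
#'
#' @param n_bags Number of bags (slides).
#' @param bag_size_range Integer `(min, max)`; bag sizes drawn uniformly.
#' @param witness_rate Fraction of witness instances per positive bag, in
#'   `(0, 1]`; rounded up so every positive bag has at least one witness.
#' @param feature_dim Instance feature dimension D.
#' @param separation Mean shift `delta` of the witness distribution along
#'   its class direction.
#' @param noise_sd Isotropic standard deviation of all instances.
#' @param class_balance Fraction of bags in the negative class (class 0);
#'   the remaining bags split evenly over the positive classes.
#' @param n_classes Number of classes (>= 2); classes `1..C-1` each get
#'   their own orthogonalized witness direction.
#' @param slides_per_patient Slides sharing one patient id (for exercising
#'   patient-safe splitting). Default 1.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bags = 200L, bag_size_range = c(32L, 256L),
                           witness_rate = 0.3, feature_dim = 64L,
                           separation = 3, noise_sd = 1,
                           class_balance = 0.5, n_classes = 2L,
                           slides_per_patient = 1L, seed = 1L) {
  spec <- list(n_bags = as.integer(n_bags),
               bag_size_range = as.integer(bag_size_range),
               witness_rate = as.numeric(witness_rate),
               feature_dim = as.integer(feature_dim),
               separation = as.numeric(separation),
               noise_sd = as.numeric(noise_sd),
               class_balance = as.numeric(class_balance),
               n_classes = as.integer(n_classes),
               slides_per_patient = as.integer(slides_per_patient),
               seed = as.integer(seed))
  err <- function(...) stop("config error: ", ..., call. = FALSE)
  if (spec$n_bags < 2L) err("n_bags must be >= 2")
  if (length(spec$bag_size_range) != 2L || spec$bag_size_range[1L] < 1L ||
      diff(spec$bag_size_range) < 0L)
    err("bag_size_range must be (min, max) with min >= 1")
  if (spec$witness_rate <= 0 || spec$witness_rate > 1)
    err("witness_rate must be in (0, 1]")
  if (spec$noise_sd <= 0) err("noise_sd must be > 0")
  if (spec$n_classes < 2L) err("n_classes must be >= 2")
  if (spec$class_balance <= 0 || spec$class_balance >= 1)
    err("class_balance must be in (0, 1)")
  structure(spec, class = "synthetic_spec")
}

# Orthogonalized random unit directions, one per positive class.
witness_directions <- function(D, n_pos) {
  stopifnot(n_pos <= D)
  A <- matrix(stats::rnorm(D * n_pos), D, n_pos)
  qr.Q(qr(A))[, seq_len(n_pos), drop = FALSE]
}

#' Generate synthetic feature bags with known witnesses
#'
#' @param spec A [synthetic_spec()].
#' @return List with `bags` (list of `feature_bag`s with labels and patient
#'   ids), `witness_masks` (per-bag logical vectors marking witness
#'   instances, named by slide id), `labels` (label table data frame) and `directions` (D x
#'   (C-1) witness direction matrix).
#' @export
generate_bags <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  D <- spec$feature_dim
  n_pos_classes <- spec$n_classes - 1L
  U <- witness_directions(D, n_pos_classes)
  n_neg <- round(spec$n_bags * spec$class_balance)
  n_neg <- max(1L, min(spec$n_bags - n_pos_classes, n_neg))
  pos_counts <- rep((spec$n_bags - n_neg) %/% n_pos_classes, n_pos_classes)
  left <- spec$n_bags - n_neg - sum(pos_counts)
  if (left > 0L) pos_counts[seq_len(left)] <- pos_counts[seq_len(left)] + 1L
  labels_vec <- sample(rep.int(0:n_pos_classes, c(n_neg, pos_counts)))
  bags <- vector("list", spec$n_bags)
  masks <- vector("list", spec$n_bags)
  for (i in seq_len(spec$n_bags)) {
    N <- sample(seq.int(spec$bag_size_range[1L], spec$bag_size_range[2L]),
                1L)
    X <- matrix(stats::rnorm(N * D, sd = spec$noise_sd), N, D)
    lab <- labels_vec[i]
    wit <- rep(FALSE, N)
    if (lab > 0L) {
      n_wit <- min(N, ceiling(spec$witness_rate * N))
      wit[sample.int(N, n_wit)] <- TRUE
      shift <- spec$separation * U[, lab]
      X[wit, ] <- X[wit, , drop = FALSE] +
        matrix(shift, sum(wit), D, byrow = TRUE)
    }
    side <- grid_side(N)
    pos0 <- seq_len(N) - 1L
    coords <- cbind(pos0 %% side, pos0 %/% side)
    storage.mode(coords) <- "integer"
    pid <- sprintf("patient_%03d", (i - 1L) %/% spec$slides_per_patient + 1L)
    bags[[i]] <- feature_bag(X, slide_id = sprintf("slide_%03d", i),
                             label = lab, coords = coords, patient_id = pid)
    masks[[i]] <- wit
  }
  labels <- data.frame(
    slide_id = vapply(bags, `[[`, "", "slide_id"),
    patient_id = vapply(bags, `[[`, "", "patient_id"),
    label = labels_vec, stringsAsFactors = FALSE)
  names(masks) <- vapply(bags, `[[`, "", "slide_id")
  list(bags = bags, witness_masks = masks, labels = labels, directions = U)
}

bag_labels <- function(bags) vapply(bags, function(b) {
  if (is.null(b$label)) stop("bag ", b$slide_id, " has no label")
  b$label
}, 0L)

bag_patients <- function(bags) vapply(bags, function(b) {
  if (is.null(b$patient_id)) b$slide_id else b$patient_id
}, "")

# largest-remainder apportionment of `total` slides over parts
apportion <- function(total, ratio) {
  q <- total * ratio / sum(ratio)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0L) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Patient-safe train/validation/test split
#'
#' Partitions bags into splits honoring the given ratio within rounding,
#' stratified by label, with all slides of a patient co-assigned so no
#' patient appears in more than one split.
#'
#' @param bags List of labelled `feature_bag`s.
#' @param ratio Positive split proportions, default `c(3, 1, 1)` for
#'   train/validation/test.
#' @param by_patient Co-assign slides sharing a patient id (default `TRUE`).
#' @param seed Integer seed for the shuffle.
#' @return List of bag lists, named `train`, `val`, `test` for a 3-way
#'   ratio, `split1..k` otherwise.
#' @export
split_bags <- function(bags, ratio = c(3, 1, 1), by_patient = TRUE,
                       seed = 1L) {
  stopifnot(length(ratio) >= 2L, all(ratio > 0))
  labels <- bag_labels(bags)
  patients <- if (by_patient) bag_patients(bags) else
    vapply(bags, `[[`, "", "slide_id")
  # one row per patient: its label stratum (first slide's label) and size
  pt <- unique(patients)
  pt_label <- labels[match(pt, patients)]
  pt_size <- as.integer(table(factor(patients, levels = pt))[pt])
  set.seed(seed)
  assign <- integer(length(pt))
  for (str in unique(pt_label)) {
    sel <- which(pt_label == str)
    sel <- sel[sample.int(length(sel))]
    quota <- apportion(sum(pt_size[sel]), ratio)
    part <- 1L
    filled <- 0L
    for (i in sel) {
      while (part < length(ratio) && filled >= quota[part]) {
        part <- part + 1L
        filled <- 0L
      }
      assign[i] <- part
      filled <- filled + pt_size[i]
    }
  }
  part_of_bag <- assign[match(patients, pt)]
  out <- lapply(seq_along(ratio), function(p) bags[part_of_bag == p])
  names(out) <- if (length(ratio) == 3L) c("train", "val", "test")
  else paste0("split", seq_along(ratio))
  out
}

#' Patient-safe stratified k-fold partition
#'
#' @inheritParams split_bags
#' @param k Number of folds (default 5).
#' @return List of `k` folds, each a list with `train` and `test` bag lists;
#'   every patient appears in exactly one test fold.
#' @export
kfold_bags <- function(bags, k = 5L, by_patient = TRUE, seed = 1L) {
  labels <- bag_labels(bags)
  patients <- if (by_patient) bag_patients(bags) else
    vapply(bags, `[[`, "", "slide_id")
  pt <- unique(patients)
  if (length(pt) < k)
    stop("fewer patients (", length(pt), ") than folds (", k, ")")
  pt_label <- labels[match(pt, patients)]
  set.seed(seed)
  fold_of <- integer(length(pt))
  for (str in unique(pt_label)) {
    sel <- which(pt_label == str)
    sel <- sel[sample.int(length(sel))]
    fold_of[sel] <- rep_len(seq_len(k), length(sel))
  }
  fold_of_bag <- fold_of[match(patients, pt)]
  lapply(seq_len(k), function(f) {
    list(train = bags[fold_of_bag != f], test = bags[fold_of_bag == f])
  })
}

#' Write generated bags and their label table to disk
#'
#' Writes one `<slide_id>.bag` container per bag plus `labels.csv`, so
#' synthetic and real data flow through identical reading code.
#'
#' @param gen Result of [generate_bags()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bag_dataset <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (bag in gen$bags)
    write_feature_bag(bag, file.path(dir, paste0(bag$slide_id, ".bag")))
  write_label_table(gen$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
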