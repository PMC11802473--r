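# Feature bags: the MIL data model and its on-disk container.
#
# One whole slide = one bag: an N x D matrix of patch feature vectors from an
# external encoder, an optional N x 2 patch-grid coordinate matrix, a slide
# label and an optional patient id. On disk a bag is a sectioned plain-text
# container, one file per slide, with named datasets "features" and "coords";
# values are written with 17 significant digits so the round trip is
# bit-exact.

#' Construct a feature bag
#'
#' @param features Numeric N x D matrix of instance (patch) feature vectors.
#' @param slide_id Slide identifier.
#' @param label Optional class index in `0..C-1` (bag-level label).
#' @param coords Optional integer N x 2 matrix of 0-based patch grid
#'   positions (column, row); carried through for heatmap export only.
#' @param patient_id Optional patient identifier for leakage-safe splitting.
#' @return An object of class `feature_bag`.
#' @export
feature_bag <- function(features, slide_id = "slide", label = NULL,
                        coords = NULL, patient_id = NULL) {
  if (!is.null(dim(features)) && length(dim(features)) != 2L)
    stop("format error: 'features' must be a 2-dimensional matrix, got ",
         length(dim(features)), " dimensions")
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  bag <- structure(
    list(slide_id = as.character(slide_id), features = features,
         coords = coords, label = if (is.null(label)) NULL else as.integer(label),
         patient_id = if (is.null(patient_id)) NULL else as.character(patient_id)),
    class = "feature_bag")
  validate_bag(bag)
  bag
}

validate_bag <- function(bag) {
  if (!is.matrix(bag$features) || length(dim(bag$features)) != 2L)
    stop("format error: 'features' must be a 2-dimensional matrix")
  n <- nrow(bag$features)
  if (n < 1L) stop("invalid bag: N must be >= 1")
  if (!all(is.finite(bag$features)))
    stop("data error: non-finite values in 'features' of bag ", bag$slide_id)
  if (!is.null(bag$coords)) {
    if (!is.matrix(bag$coords) || ncol(bag$coords) != 2L)
      stop("format error: 'coords' must be an N x 2 matrix")
    if (nrow(bag$coords) != n)
      stop("format error: 'coords' has ", nrow(bag$coords),
           " rows but 'features' has ", n)
  }
  if (!is.null(bag$label) && bag$label < 0L)
    stop("invalid bag: label must be a non-negative class index")
  invisible(bag)
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("feature bag '%s': %d instances x %d features%s%s\n",
              x$slide_id, nrow(x$features), ncol(x$features),
              if (is.null(x$coords)) "" else ", with grid coords",
              if (is.null(x$label)) "" else sprintf(", label %d", x$label)))
  invisible(x)
}

#' Write a feature bag to its per-slide container file
#'
#' The container is a sectioned text format: a header line, then one
#' `@<dataset> <nrow> <ncol>` line per dataset followed by its rows
#' (tab-separated). Feature values use 17 significant digits, making
#' [read_feature_bag()] an exact inverse.
#'
#' @param bag A `feature_bag`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_feature_bag <- function(bag, path) {
  validate_bag(bag)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#camil-bag v1", paste0("#slide_id ", bag$slide_id)), con)
  writeLines(sprintf("@features %d %d", nrow(bag$features),
                     ncol(bag$features)), con)
  writeLines(apply_rows_fmt(bag$features), con)
  if (!is.null(bag$coords)) {
    writeLines(sprintf("@coords %d 2", nrow(bag$coords)), con)
    writeLines(paste(bag$coords[, 1L], bag$coords[, 2L], sep = "\t"), con)
  }
  invisible(path)
}

apply_rows_fmt <- function(m) {
  # %.17g round-trips IEEE doubles exactly
  chr <- sprintf("%.17g", t(m))
  dim(chr) <- c(ncol(m), nrow(m))
  apply(chr, 2L, paste, collapse = "\t")
}

#' Read a feature bag from its per-slide container file
#'
#' @param path Path to a container written by [write_feature_bag()].
#' @param slide_id Optional override for the slide id recorded in the file.
#' @return A `feature_bag` (label attached later by joining a label table).
#' @export
read_feature_bag <- function(path, slide_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "#camil-bag"))
    stop("format error: not a camil bag container: ", path)
  sid <- sub("^#slide_id ", "", grep("^#slide_id ", lines, value = TRUE)[1L])
  if (is.na(sid)) sid <- tools::file_path_sans_ext(basename(path))
  if (!is.null(slide_id)) sid <- slide_id
  heads <- grep("^@", lines)
  if (length(heads) == 0L)
    stop("format error: missing dataset \"features\" in ", path)
  datasets <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(lines[[heads[i]]], "[[:space:]]+")[[1L]]
    name <- sub("^@", "", hd[[1L]])
    if (length(hd) < 3L)
      stop("format error: dataset \"", name, "\" must declare 2 dimensions")
    nr <- as.integer(hd[[2L]]); nc <- as.integer(hd[[3L]])
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    body <- lines[seq.int(from, length.out = to - from + 1L)]
    body <- body[nzchar(body)]
    if (length(body) != nr)
      stop("format error: dataset \"", name, "\" declares ", nr,
           " rows but has ", length(body))
    vals <- scan(text = body, quiet = TRUE)
    if (length(vals) != nr * nc)
      stop("format error: ragged dataset \"", name, "\" in ", path)
    datasets[[name]] <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  }
  if (is.null(datasets$features))
    stop("format error: missing dataset \"features\" in ", path)
  coords <- datasets$coords
  if (!is.null(coords)) storage.mode(coords) <- "integer"
  feature_bag(datasets$features, slide_id = sid, coords = coords)
}

#' Read or write a slide label table
#'
#' The label table is a CSV with header `slide_id,patient_id,label`; slide
#' ids must be unique and labels are class indices `0..C-1`.
#'
#' @param path CSV path.
#' @return `read_label_table()`: a data frame with columns `slide_id`,
#'   `patient_id`, `label`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "integer"))
  needed <- c("slide_id", "patient_id", "label")
  if (!all(needed %in% names(df)))
    stop("format error: label table needs columns ",
         paste(needed, collapse = ", "))
  if (anyDuplicated(df$slide_id))
    stop("format error: duplicated slide_id in label table")
  if (any(df$label < 0L)) stop("format error: negative label")
  df[needed]
}

#' @rdname read_label_table
#' @param labels Data frame with columns `slide_id`, `patient_id`, `label`.
#' @export
write_label_table <- function(labels, path) {
  utils::write.csv(labels[c("slide_id", "patient_id", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach labels and patient ids from a label table to bags
#'
#' @param bags List of `feature_bag`s.
#' @param labels Label table data frame (see [read_label_table()]).
#' @return The bags with `label` and `patient_id` filled in.
#' @export
join_labels <- function(bags, labels) {
  idx <- match(vapply(bags, `[[`, "", "slide_id"), labels$slide_id)
  if (anyNA(idx))
    stop("label table is missing slide(s): ",
         paste(vapply(bags[is.na(idx)], `[[`, "", "slide_id"),
               collapse = ", "))
  Map(function(bag, i) {
    bag$label <- labels$label[i]
    bag$patient_id <- labels$patient_id[i]
    bag
  }, bags, idx)
}

#' Read every bag container in a directory
#'
#' Reads all `.bag` files under `dir` (sorted by file name, so ordering is
#' stable across platforms) and optionally joins a label table.
#'
#' @param dir Directory containing `.bag` files.
#' @param labels Optional label table (see [read_label_table()]).
#' @return List of `feature_bag`s.
#' @export
read_bag_dir <- function(dir, labels = NULL) {
  files <- list.files(dir, pattern = "\\.bag$", full.names = TRUE)
  if (length(files) == 0L) stop("no .bag files found in ", dir)
  bags <- lapply(files, read_feature_bag)
  if (!is.null(labels)) bags <- join_labels(bags, labels)
  bags
}
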