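# Reading and writing the supported on-disk dataset formats:
# header CSV (tabular / EHR), directory-per-class PNG trees (images),
# and JSON id lists so that splits are replayable.

#' Write / read a labeled dataset as CSV
#'
#' The CSV has a header row with an `id` column, a `label` column (class
#' indices in `0..C-1`) and one numeric column per feature. The class count is
#' declared by the caller on read, never inferred from the labels present.
#'
#' @param data a [labeled_dataset()].
#' @param path file path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns a `labeled_dataset`.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  feats <- data$features
  if (is.null(colnames(feats))) colnames(feats) <- sprintf("f%03d", seq_len(ncol(feats)))
  df <- data.frame(id = data$ids, label = data$labels, feats,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @param num_classes declared number of classes of the stored data.
#' @param label_col,id_col names of the label and id columns.
#' @export
read_dataset_csv <- function(path, num_classes, label_col = "label", id_col = "id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df)) stop("no '", label_col, "' column in ", path)
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else NULL
  feat_cols <- setdiff(names(df), c(label_col, id_col))
  feats <- as.matrix(df[feat_cols])
  storage.mode(feats) <- "double"
  labeled_dataset(feats, df[[label_col]], num_classes = num_classes, ids = ids)
}

#' Write / read a labeled image dataset as a directory-per-class PNG tree
#'
#' Images are stored as `dir/class_<c>/<id>.png` greyscale PNGs. On read,
#' class indices come from the sorted `class_*` directory names (the class
#' count is the number of class directories); RGB files are averaged to one
#' channel.
#'
#' @param data a [labeled_dataset()] whose features carry a
#'   `shape = c(H, W, 1)` attribute (see [gen_toy_images()]).
#' @param dir directory to create.
#' @return `write_png_tree()` returns `dir` invisibly; `read_png_tree()`
#'   returns a `labeled_dataset`.
#' @export
write_png_tree <- function(data, dir) {
  stopifnot(inherits(data, "labeled_dataset"))
  shp <- attr(data$features, "shape")
  if (is.null(shp)) stop("dataset features carry no image shape attribute")
  for (cl in 0:(data$num_classes - 1L)) {
    cdir <- file.path(dir, sprintf("class_%d", cl))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(data$ids)) {
    img <- matrix(data$features[i, ], shp[1], shp[2])
    png::writePNG(pmin(pmax(img, 0), 1),
                  file.path(dir, sprintf("class_%d", data$labels[i]),
                            paste0(data$ids[i], ".png")))
  }
  invisible(dir)
}

#' @rdname write_png_tree
#' @export
read_png_tree <- function(dir) {
  cdirs <- sort(list.dirs(dir, recursive = FALSE))
  cdirs <- cdirs[grepl("class_", basename(cdirs))]
  if (length(cdirs) < 2L) stop("expected at least two class_* directories under ", dir)
  ids <- character(0); labels <- integer(0); rows <- list()
  shp <- NULL
  for (ci in seq_along(cdirs)) {
    files <- sort(list.files(cdirs[ci], pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
      if (is.null(shp)) shp <- c(dim(img), 1L)
      rows[[length(rows) + 1L]] <- as.vector(img)
      ids <- c(ids, sub("\\.png$", "", basename(f)))
      labels <- c(labels, ci - 1L)
    }
  }
  feats <- do.call(rbind, rows)
  attr(feats, "shape") <- shp
  labeled_dataset(feats, labels, num_classes = length(cdirs), ids = ids)
}

#' Persist and replay split id lists
#'
#' Writes the train/test/calibration/holdout id vectors of a
#' [make_splits()] result as a JSON object, and reconstructs an identical
#' `split_collection` from a pool and such a file.
#'
#' @param splits a `split_collection`.
#' @param path JSON file path.
#' @return `write_split_ids()` returns `path` invisibly; `read_split_ids()`
#'   returns the parsed id lists; `splits_from_ids()` a `split_collection`.
#' @export
write_split_ids <- function(splits, path) {
  stopifnot(inherits(splits, "split_collection"))
  obj <- list(train = splits$train$ids, test = splits$test$ids,
              calibration = splits$calibration$ids, holdout = splits$holdout$ids,
              seed = splits$seed)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split_ids
#' @export
read_split_ids <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_split_ids
#' @param pool the [labeled_dataset()] the ids refer to.
#' @param ids an id list as returned by [read_split_ids()].
#' @export
splits_from_ids <- function(pool, ids) {
  structure(list(train = dataset_subset(pool, ids$train),
                 test = dataset_subset(pool, ids$test),
                 calibration = dataset_subset(pool, ids$calibration),
                 holdout = dataset_subset(pool, ids$holdout %||% character(0)),
                 seed = as.integer(ids$seed %||% NA_integer_)),
            class = "split_collection")
}
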