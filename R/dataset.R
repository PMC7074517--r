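#' Construct a multi-block case-control dataset
#'
#' The universal input of the analysis pipeline: a samples-by-analytes
#' numeric matrix, a 0/1 class label per sample (1 = case, 0 = control) and
#' a block (measurement platform) assignment per analyte. All blocks share
#' the sample order; an analyte belongs to exactly one block.
#'
#' @param x Numeric matrix, samples in rows, analytes in named columns.
#' @param labels Binary vector (1 = case, 0 = control), length `nrow(x)`.
#' @param block Named character vector mapping every column of `x` to a
#'   block label.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to rownames of `x` or `sample_1 ...`.
#' @param units Optional named character vector of analyte units.
#' @return An object of class `multiblock_dataset`.
#' @seealso [generate_cohort()], [write_dataset()], [dataset_blocks()]
#' @export
multiblock_dataset <- function(x, labels, block, sample_ids = NULL,
                               units = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop_input("`x` must have analyte column names")
  if (anyDuplicated(colnames(x))) stop_input("duplicated analyte names")
  labels <- check_binary_labels(labels, require_both = FALSE)
  if (length(labels) != nrow(x)) {
    stop_input("length(labels) must equal nrow(x)")
  }
  if (is.null(names(block)) || !setequal(names(block), colnames(x))) {
    stop_input("`block` must be a named vector covering every analyte")
  }
  block <- block[colnames(x)]
  if (is.null(sample_ids)) {
    sample_ids <- rownames(x)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(x)))
  }
  rownames(x) <- sample_ids
  if (is.null(units)) {
    units <- stats::setNames(rep("", ncol(x)), colnames(x))
  } else {
    units <- units[colnames(x)]
  }
  structure(
    list(sample_ids = sample_ids, labels = labels, x = x,
         block = block, units = units),
    class = "multiblock_dataset"
  )
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat(sprintf(
    "multiblock_dataset: %d samples (%d case / %d control), %d analytes\n",
    nrow(x$x), sum(x$labels == 1), sum(x$labels == 0), ncol(x$x)
  ))
  for (b in unique(x$block)) {
    cat(sprintf("  block %-22s %d analytes\n", b, sum(x$block == b)))
  }
  invisible(x)
}

#' @export
dim.multiblock_dataset <- function(x) dim(x$x)

#' Split a multi-block dataset into its per-block matrices
#'
#' @param data A `multiblock_dataset`.
#' @return Named list of numeric matrices, one per block, in block order.
#' @export
dataset_blocks <- function(data) {
  stopifnot(inherits(data, "multiblock_dataset"))
  lapply(split(colnames(data$x), factor(data$block, unique(data$block))),
         function(cols) data$x[, cols, drop = FALSE])
}

# Row subset preserving all metadata (internal; used by CV loops).
dataset_subset <- function(data, idx) {
  structure(
    list(sample_ids = data$sample_ids[idx], labels = data$labels[idx],
         x = data$x[idx, , drop = FALSE], block = data$block,
         units = data$units),
    class = "multiblock_dataset"
  )
}

#' Write / read a multi-block dataset as CSV plus JSON sidecar
#'
#' The CSV holds `sample_id`, `label`, then one column per analyte; the
#' sidecar JSON maps each analyte to its block and units, preserving block
#' and analyte order.
#'
#' @param data A `multiblock_dataset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.schema.json`.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `multiblock_dataset`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "multiblock_dataset"))
  df <- data.frame(sample_id = data$sample_ids, label = data$labels,
                   data$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  schema <- lapply(colnames(data$x), function(a) {
    list(block = unname(data$block[[a]]), units = unname(data$units[[a]]))
  })
  names(schema) <- colnames(data$x)
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop_input("dataset CSV must have `sample_id` and `label` columns")
  }
  schema <- jsonlite::read_json(paste0(path, ".schema.json"))
  analytes <- names(schema)
  if (!all(analytes %in% names(df))) {
    stop_input("CSV is missing analytes declared in the sidecar schema")
  }
  x <- as.matrix(df[, analytes, drop = FALSE])
  storage.mode(x) <- "double"
  multiblock_dataset(
    x, labels = df$label,
    block = vapply(schema, function(s) s$block, character(1)),
    sample_ids = as.character(df$sample_id),
    units = vapply(schema, function(s) s$units %||% "", character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
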