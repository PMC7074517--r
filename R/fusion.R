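#' Learn low-level fusion scaling from training samples
#'
#' Low-level (measurement-level) fusion proceeds in three steps, all
#' parametrized on training data only: (i) autoscale every analyte
#' (subtract its training mean, divide by its training standard deviation,
#' `n - 1` denominator); (ii) divide each platform block by the Frobenius
#' norm of its autoscaled training submatrix, so every block contributes
#' unit total variance regardless of how many analytes it holds; (iii)
#' concatenate the blocks in fixed order.
#'
#' @param train A [multiblock_dataset()] of training samples (at least 2).
#' @return A `scaling_model` storing per-analyte means/SDs, per-block
#'   Frobenius norms and the analyte-to-block map.
#' @seealso [apply_scaling()], [invert_scaling()]
#' @export
fit_scaling <- function(train) {
  stopifnot(inherits(train, "multiblock_dataset"))
  x <- train$x
  if (nrow(x) < 2L) stop_input("need at least 2 training samples")
  center <- colMeans(x)
  sdev <- sqrt(colSums(sweep(x, 2, center)^2) / (nrow(x) - 1))
  if (any(sdev <= 0 | !is.finite(sdev))) {
    bad <- colnames(x)[sdev <= 0 | !is.finite(sdev)]
    stop_input("zero-variance analyte(s) in training data: ",
               paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center), 2, sdev, "/")
  block_order <- unique(train$block)
  block_norm <- vapply(block_order, function(b) {
    sqrt(sum(z[, train$block == b, drop = FALSE]^2))
  }, numeric(1))
  structure(
    list(center = center, sd = sdev,
         block_norm = stats::setNames(block_norm, block_order),
         block = train$block,
         analytes = colnames(x)),
    class = "scaling_model"
  )
}

#' Apply (or invert) a fitted fusion scaling
#'
#' Transforms each entry to `((x - mean) / sd) / block_norm` and
#' concatenates blocks in the model's fixed order (block order, analyte
#' order within block). Applying a model to its own training data yields
#' columns with mean zero and blocks with Frobenius norm one.
#'
#' @param model A `scaling_model` from [fit_scaling()].
#' @param data A [multiblock_dataset()] (or numeric matrix with matching
#'   column names) whose analytes match the model's.
#' @return Numeric fused matrix (samples x analytes) with a `"block"`
#'   attribute mapping columns to blocks.
#' @export
apply_scaling <- function(model, data) {
  stopifnot(inherits(model, "scaling_model"))
  x <- if (inherits(data, "multiblock_dataset")) data$x else as.matrix(data)
  if (is.null(colnames(x)) || !setequal(colnames(x), model$analytes)) {
    missing <- setdiff(model$analytes, colnames(x) %||% character())
    extra <- setdiff(colnames(x) %||% character(), model$analytes)
    stop_input(
      "analyte mismatch between scaling model and data",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
    )
  }
  ord <- fused_order(model)
  x <- x[, ord, drop = FALSE]
  z <- sweep(sweep(x, 2, model$center[ord]), 2, model$sd[ord], "/")
  denom <- model$block_norm[model$block[ord]]
  z <- sweep(z, 2, denom, "/")
  attr(z, "block") <- stats::setNames(model$block[ord], ord)
  z
}

# Fixed fused column order: blocks in model order, analytes within block in
# panel order.
fused_order <- function(model) {
  unlist(lapply(names(model$block_norm), function(b) {
    model$analytes[model$block == b]
  }), use.names = FALSE)
}

#' @rdname apply_scaling
#' @param fused A fused matrix produced by [apply_scaling()] with this model.
#' @return `invert_scaling()` returns the matrix on the original
#'   measurement scale, columns in fused order.
#' @export
invert_scaling <- function(model, fused) {
  stopifnot(inherits(model, "scaling_model"))
  ord <- colnames(fused)
  denom <- model$block_norm[model$block[ord]]
  z <- sweep(fused, 2, denom, "*")
  sweep(sweep(z, 2, model$sd[ord], "*"), 2, model$center[ord], "+")
}

#' Serialize / restore a scaling model as JSON
#'
#' @param model A `scaling_model`.
#' @param path JSON file path.
#' @return `scaling_to_json()` returns `path` invisibly;
#'   `scaling_from_json()` returns the restored `scaling_model`.
#' @export
scaling_to_json <- function(model, path) {
  stopifnot(inherits(model, "scaling_model"))
  jsonlite::write_json(
    list(center = as.list(model$center), sd = as.list(model$sd),
         block_norm = as.list(model$block_norm),
         block = as.list(model$block), analytes = model$analytes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname scaling_to_json
#' @export
scaling_from_json <- function(path) {
  j <- jsonlite::read_json(path)
  structure(
    list(center = unlist(j$center), sd = unlist(j$sd),
         block_norm = unlist(j$block_norm),
         block = unlist(j$block),
         analytes = unlist(j$analytes)),
    class = "scaling_model"
  )
}
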