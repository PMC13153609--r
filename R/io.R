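# Plain-format readers/writers used by the experiment harness.  All
# spatial grids serialize as delimited integer/numeric matrices (or
# grayscale images); metadata and reports as JSON.

#' Write / read a numeric matrix as TSV
#'
#' @param m matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a label/mask grid as an 8-bit grayscale PNG
#'
#' Region codes are spread over the 8-bit range so the image is viewable
#' directly (0, 128, 255 for codes 0..2; masks map to 0/255).
#'
#' @param m integer/logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(m, path) {
  m <- if (is.logical(m)) m * 2L else as.matrix(m)
  png::writePNG(m / max(2L, max(m)), path)
  invisible(path)
}

#' Write / read a layer stack as a multi-page 16-bit grayscale TIFF
#'
#' Pages are the retained layers in order.  Values are scaled to the
#' 16-bit range; the scale factor and per-layer mass intervals go to a
#' JSON sidecar (`<path>.json`) so the stack round-trips numerically.
#'
#' @param stack a [fractionate()] result.
#' @param path output `.tif` path.
#' @return `read_stack_tiff` returns a `layer_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  w <- window_stack(stack)
  hi <- max(w$signal, 1e-12)
  pages <- lapply(seq_along(w$layers),
                  function(i) w$signal[, , i] / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(scale = hi, layers = w$layers,
                  fraction_window = w$fraction_window,
                  layer_mass_intervals = w$layer_mass_intervals,
                  model = list(n_layers = w$model$n_layers,
                               ladder_top = w$model$ladder_top,
                               ladder_bottom = w$model$ladder_bottom,
                               dispersion_sigma = w$model$dispersion_sigma))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  model <- calibrate_migration(side$model$ladder_top,
                               side$model$ladder_bottom,
                               side$model$n_layers,
                               side$model$dispersion_sigma)
  n <- model$n_layers
  res <- nrow(pages[[1]])
  sig <- array(0, c(res, res, n))
  for (i in seq_along(side$layers)) {
    sig[, , side$layers[i]] <- pages[[i]] * side$scale
  }
  structure(list(signal = sig,
                 layer_mass_intervals = model$layer_mass_intervals,
                 layers = seq_len(n),
                 fraction_window = as.integer(side$fraction_window),
                 model = model),
            class = "layer_stack")
}

#' Write contours as a CSV vertex list
#'
#' One row per boundary well: `component, vertex, row, col` with 0-based
#' row-major well coordinates (origin top-left).
#'
#' @param call a [call_margin()] result.
#' @param path output CSV path.
#' @export
write_contour_csv <- function(call, path) {
  stopifnot(inherits(call, "margin_call"))
  rows <- do.call(rbind, lapply(seq_along(call$contour), function(i) {
    ct <- call$contour[[i]]
    data.frame(component = i, vertex = seq_len(nrow(ct)),
               row = ct[, "row"], col = ct[, "col"])
  }))
  if (is.null(rows)) {
    rows <- data.frame(component = integer(), vertex = integer(),
                       row = integer(), col = integer())
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read per-sample captured-protein id sets
#'
#' Each file holds one protein id per line; the result feeds
#' [set_analysis()].
#'
#' @param paths character vector of file paths (one per sample).
#' @return List of character vectors.
#' @export
read_sample_sets <- function(paths) {
  lapply(paths, function(p) unique(readLines(p, warn = FALSE)))
}

#' Export microwell values as CSV with row/col headers
#'
#' @param image a [microwell_image].
#' @param path output CSV path.
#' @export
write_wells_csv <- function(image, path) {
  stopifnot(inherits(image, "microwell_image"))
  m <- image$values
  dimnames(m) <- list(paste0("r", seq_len(nrow(m)) - 1L),
                      paste0("c", seq_len(ncol(m)) - 1L))
  utils::write.csv(m, path)
  invisible(path)
}
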