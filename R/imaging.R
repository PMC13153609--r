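# Block aggregation of a fine grid to a coarser well grid.
.block_sum <- function(m, factor) {
  if (factor == 1L) return(m)
  n <- nrow(m) / factor
  stopifnot(n == round(n))
  g <- rep(seq_len(n), each = factor)
  t(rowsum(t(rowsum(m, g)), g))
}

.block_mean <- function(m, factor) .block_sum(m, factor) / factor^2

#' Construct a microwell image
#'
#' @param values square numeric matrix of non-negative well intensities.
#' @param layer_index 1-based gel-layer index the image came from.
#' @param noise_meta optional list describing applied degradation.
#' @return An object of class `microwell_image`.
#' @export
microwell_image <- function(values, layer_index = NA_integer_,
                            noise_meta = NULL) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            all(values >= 0))
  structure(list(values = values, array_size = nrow(values),
                 layer_index = as.integer(layer_index),
                 noise_meta = noise_meta),
            class = "microwell_image")
}

#' @export
print.microwell_image <- function(x, ...) {
  cat(sprintf("microwell_image: %d x %d wells (layer %s)%s\n",
              x$array_size, x$array_size, x$layer_index,
              if (is.null(x$noise_meta)) "" else ", degraded"))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.4g\n",
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

#' @export
plot.microwell_image <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, ]),
                  col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Rasterize a layer stack to microwell readouts
#'
#' Aggregates each retained layer of the stack onto an
#' `array_size x array_size` well grid by block summation (each well
#' collects every source cell it covers), conserving total signal
#' exactly.  The stack's spatial resolution must be an integer multiple
#' of `array_size`; asking for more wells than source cells is an error.
#'
#' @param stack a [fractionate()] result (windowing is applied here).
#' @param array_size wells per side (20 and 40 are the standard molds).
#' @return List of [microwell_image] objects, one per retained layer, in
#'   stack order.
#' @export
rasterize <- function(stack, array_size = 40L) {
  stopifnot(inherits(stack, "layer_stack"))
  array_size <- as.integer(array_size)
  res <- dim(stack$signal)[1]
  if (array_size > res) {
    stop("array_size (", array_size, ") exceeds source resolution (",
         res, ")", call. = FALSE)
  }
  if (res %% array_size != 0L) {
    stop("source resolution ", res,
         " is not divisible by array_size ", array_size, call. = FALSE)
  }
  w <- window_stack(stack)
  f <- res %/% array_size
  lapply(seq_along(w$layers), function(i) {
    microwell_image(.block_sum(w$signal[, , i], f),
                    layer_index = w$layers[i])
  })
}

#' Degrade a microwell image with optics and noise
#'
#' Applies, in order: Gaussian optical blur of width `psf_sigma` wells,
#' a uniform additive background, optional Poisson-like shot noise
#' (well value replaced by a Poisson draw with that mean), additive
#' Gaussian read noise, and clamping at zero.  With all parameters zero
#' the image is returned unchanged.  Noise draws are governed by `seed`
#' and reproducible.
#'
#' @param image a [microwell_image].
#' @param psf_sigma blur standard deviation in wells (>= 0).
#' @param background additive background intensity (>= 0).
#' @param read_noise_sd Gaussian read-noise standard deviation (>= 0).
#' @param shot_noise logical; apply Poisson resampling.
#' @param seed integer seed for the random noise components.
#' @return A degraded [microwell_image] with `noise_meta` recorded.
#' @export
degrade <- function(image, psf_sigma = 0.5, background = 0,
                    read_noise_sd = 0, shot_noise = FALSE, seed = 1L) {
  stopifnot(inherits(image, "microwell_image"))
  if (psf_sigma < 0 || background < 0 || read_noise_sd < 0) {
    stop("psf_sigma, background and read_noise_sd must be >= 0",
         call. = FALSE)
  }
  v <- image$values
  if (psf_sigma > 0) {
    v <- as.matrix(EBImage::gblur(EBImage::Image(v), sigma = psf_sigma))
    v <- pmax(v, 0)  # gblur can leave tiny negative ringing
  }
  v <- v + background
  sub <- derive_seed(seed, "imaging",
                     k = max(image$layer_index, 0L, na.rm = TRUE))
  v <- with_seed(sub, {
    if (shot_noise) v <- matrix(stats::rpois(length(v), v), nrow(v))
    if (read_noise_sd > 0) {
      v <- v + stats::rnorm(length(v), 0, read_noise_sd)
    }
    v
  })
  microwell_image(pmax(v, 0), layer_index = image$layer_index,
                  noise_meta = list(psf_sigma = psf_sigma,
                                    background = background,
                                    read_noise_sd = read_noise_sd,
                                    shot_noise = shot_noise,
                                    seed = as.integer(seed)))
}
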