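#' Calibrate the layer-migration model from ladder anchors
#'
#' SDS-PAGE migration distance is close to linear in log molecular
#' weight, so the z-stack of gel layers is calibrated by log-spacing the
#' mass boundaries between the top and bottom ladder anchors:
#' `b_k = top * (bottom/top)^(k/n)`, k = 0..n.  Layer 1 is the top of the
#' stack and owns the highest-mass interval (large proteins migrate
#' least); layer k owns the closed mass interval `[b_k, b_{k-1}]`.
#'
#' @param ladder_top mass of the top boundary in kDa (default 100, the
#'   upper end of the analysis range).
#' @param ladder_bottom mass of the bottom boundary in kDa (default 15).
#' @param n_layers number of gel layers (default 13).
#' @param dispersion_sigma fraction of each species' signal leaking to
#'   adjacent layers (default 0.05).
#' @return An object of class `migration_model` with `boundaries`
#'   (length `n_layers + 1`, strictly decreasing) and a
#'   `layer_mass_intervals` data frame.
#' @examples
#' m <- calibrate_migration()
#' m$boundaries[3]  # 74.69 kDa
#' @export
calibrate_migration <- function(ladder_top = 100, ladder_bottom = 15,
                                n_layers = 13L, dispersion_sigma = 0.05) {
  if (!is.numeric(ladder_top) || !is.numeric(ladder_bottom) ||
      ladder_bottom <= 0 || ladder_top <= ladder_bottom) {
    stop("require ladder_top > ladder_bottom > 0", call. = FALSE)
  }
  stopifnot(n_layers >= 2, dispersion_sigma >= 0, dispersion_sigma < 1)
  n_layers <- as.integer(n_layers)
  k <- seq(0, n_layers)
  b <- ladder_top * (ladder_bottom / ladder_top)^(k / n_layers)
  intervals <- data.frame(layer = seq_len(n_layers),
                          mass_lo = b[-1], mass_hi = b[-length(b)])
  structure(list(n_layers = n_layers, boundaries = b,
                 layer_mass_intervals = intervals,
                 dispersion_sigma = dispersion_sigma,
                 ladder_top = ladder_top, ladder_bottom = ladder_bottom),
            class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat(sprintf(
    "migration_model: %d layers, ladder %g -> %g kDa (log-spaced)\n",
    x$n_layers, x$ladder_top, x$ladder_bottom))
  cat(sprintf("  dispersion to adjacent layers: %g\n", x$dispersion_sigma))
  print(transform(x$layer_mass_intervals,
                  mass_lo = round(mass_lo, 2), mass_hi = round(mass_hi, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Layer owning a given mass
#'
#' Masses exactly on an interior boundary belong to the higher-index
#' (lighter) layer; masses outside the ladder range are clamped to the
#' end layers with a warning.
#'
#' @param model a [calibrate_migration()] model.
#' @param mw_kda numeric vector of masses in kDa.
#' @return Integer vector of 1-based layer indices (1 = top, heaviest).
#' @export
layer_of_mass <- function(model, mw_kda) {
  stopifnot(inherits(model, "migration_model"))
  b <- model$boundaries
  n <- model$n_layers
  if (any(mw_kda > b[1] | mw_kda < b[n + 1L])) {
    warning("mass outside ladder range [", round(b[n + 1L], 2), ", ",
            round(b[1], 2), "] kDa; clamped to end layers", call. = FALSE)
  }
  inner <- b[2:n]  # interior boundaries b_1 .. b_{n-1}
  idx <- 1L + vapply(mw_kda, function(m) sum(inner >= m), integer(1))
  pmin(pmax(idx, 1L), n)
}

#' Fractionate a labeled lysate into a layer stack
#'
#' Assigns each species' covalent signal to the gel layer owning its
#' molecular weight.  A `dispersion_sigma` fraction of every species'
#' signal leaks to the adjacent layers, split equally when both
#' neighbours exist (an end layer passes its whole leak to its single
#' neighbour), so total signal is conserved exactly.
#'
#' @param lysate a [label_lysate()] result.
#' @param model a [calibrate_migration()] model.
#' @param fraction_window integer `c(first, last)` of layers retained for
#'   analysis (default `c(3, 13)`; layers 1–2 sit above the analysis
#'   window and are discarded at windowing time, not here).
#' @return An object of class `layer_stack`: `signal` array
#'   `[row, col, layer]` over all `n_layers`, `layer_mass_intervals`,
#'   `layers` (indices present) and `fraction_window`.
#' @export
fractionate <- function(lysate, model = calibrate_migration(),
                        fraction_window = c(3L, 13L)) {
  stopifnot(inherits(lysate, "labeled_lysate"),
            inherits(model, "migration_model"))
  sp <- lysate$species
  n <- model$n_layers
  stopifnot(length(fraction_window) == 2L,
            fraction_window[1] >= 1, fraction_window[2] <= n,
            fraction_window[1] <= fraction_window[2])
  d <- dim(lysate$signal)
  if (nrow(sp) == 0L || d[3] == 0L) {
    return(structure(list(
      signal = array(0, c(d[1], d[2], n)),
      layer_mass_intervals = model$layer_mass_intervals,
      layers = seq_len(n), fraction_window = as.integer(fraction_window),
      model = model), class = "layer_stack"))
  }

  main <- layer_of_mass(model, sp$mw_kda)
  # per-species weights over layers (n_species x n_layers)
  W <- matrix(0, nrow(sp), n)
  ds <- model$dispersion_sigma
  for (j in seq_len(nrow(sp))) {
    k <- main[j]
    nb <- c(if (k > 1L) k - 1L, if (k < n) k + 1L)
    W[j, k] <- 1 - if (length(nb)) ds else 0
    if (length(nb)) W[j, nb] <- ds / length(nb)
  }
  flat <- matrix(lysate$signal, d[1] * d[2], d[3])
  out <- array(flat %*% W, c(d[1], d[2], n))

  structure(list(signal = out,
                 layer_mass_intervals = model$layer_mass_intervals,
                 layers = seq_len(n),
                 fraction_window = as.integer(fraction_window),
                 model = model),
            class = "layer_stack")
}

#' Apply the fraction window to a layer stack
#'
#' Retains only the layers inside `fraction_window` (default layers 3–13,
#' the 11 analysis fractions).  Idempotent: windowing an already windowed
#' stack is a no-op.
#'
#' @param stack a [fractionate()] result.
#' @return A `layer_stack` containing only the retained layers; the
#'   `layers` field keeps their original 1-based indices.
#' @export
window_stack <- function(stack) {
  stopifnot(inherits(stack, "layer_stack"))
  keep <- stack$layers >= stack$fraction_window[1] &
          stack$layers <= stack$fraction_window[2]
  stack$signal <- stack$signal[, , keep, drop = FALSE]
  stack$layers <- stack$layers[keep]
  stack$layer_mass_intervals <-
    stack$layer_mass_intervals[stack$layer_mass_intervals$layer %in%
                                 stack$layers, ]
  stack
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("layer_stack: %d x %d cells, layers %s (window %d..%d)\n",
              d[1], d[2], paste(range(x$layers), collapse = ".."),
              x$fraction_window[1], x$fraction_window[2]))
  cat(sprintf("  total signal %.4g\n", sum(x$signal)))
  invisible(x)
}

#' Layers intersecting a mass window
#'
#' Returns all (necessarily contiguous) layer indices whose mass interval
#' overlaps the window `[lo, hi]` with positive length.  Adjacent layers
#' share a single boundary mass; a shared endpoint alone does not count
#' as overlap (consistent with boundary-exact masses belonging to one
#' layer only), so a window equal to one layer's interval returns exactly
#' that layer.  The default model maps the 60–75 kDa target-protein
#' window onto 3 contiguous layers.
#'
#' @param model a [calibrate_migration()] model.
#' @param lo,hi window bounds in kDa, `lo < hi`.
#' @return Increasing integer vector of layer indices (empty, with a
#'   warning, if the window lies outside the ladder range).
#' @examples
#' layers_for_mass_window(calibrate_migration(), 60, 75)  # 3 layers
#' @export
layers_for_mass_window <- function(model, lo, hi) {
  stopifnot(inherits(model, "migration_model"), lo < hi)
  iv <- model$layer_mass_intervals
  hit <- which(iv$mass_lo < hi & iv$mass_hi > lo)
  if (!length(hit)) {
    warning("mass window [", lo, ", ", hi,
            "] kDa does not intersect the ladder range", call. = FALSE)
  }
  as.integer(hit)
}
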