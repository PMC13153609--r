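#' Generate a synthetic tissue-section phantom
#'
#' Builds a 2D section discretized to a microwell grid with three region
#' codes — tumor, paracancerous and normal — together with ground-truth
#' masks for evaluating margin calls.  Geometries cover a circular tumor
#' (`disc`), an irregular tumor outline (`blob`, a disc with smooth
#' low-order radial harmonics), a needle-biopsy core (`punch_core`, an
#' elongated strip spanning the section in which a contiguous segment is
#' tumor) and a user-supplied mask (`custom`).
#'
#' Geometry is defined in continuous unit coordinates and rasterized, so
#' the same seed yields the same tissue at any resolution: a section
#' generated at `array_size = 20, oversample = 4` and one at
#' `array_size = 40, oversample = 2` sample the identical field.
#' Paracancerous tissue forms a rim of `rim_wells` wells (Chebyshev
#' dilation) around the tumor; everything else is normal.
#'
#' @param geometry one of `"disc"`, `"blob"`, `"punch_core"`, `"custom"`.
#' @param array_size wells per side of the target microwell array
#'   (20 and 40 are the standard mold sizes; any positive integer works).
#' @param tumor_fraction for `disc`/`blob`, target tumor area as a fraction
#'   of the section; for `punch_core`, the fraction of the core length that
#'   is tumor. Must lie in `[0, 1]`; `0` yields an all-normal section.
#' @param tumor_radius optional tumor radius in wells (disc only);
#'   overrides `tumor_fraction`.
#' @param rim_wells paracancerous rim width in wells (default 2).
#' @param core_width_frac width of the punch core as a fraction of the
#'   section side (default 0.1: 4 wells on a 40-grid, 2 on a 20-grid).
#' @param oversample sub-well resolution factor; the label grid has
#'   `array_size * oversample` cells per side.
#' @param seed integer seed; output is deterministic given all arguments.
#' @param custom_mask logical matrix of tumor cells (geometry `"custom"`).
#' @return An object of class `tissue_phantom`: list with `labels`
#'   (integer matrix, 0 = normal, 1 = paracancerous, 2 = tumor),
#'   `tumor_mask` (logical, `labels == 2`), well-resolution `truth_mask`
#'   and `truth_labels`, plus the generating parameters.
#' @examples
#' ph <- generate_phantom("disc", array_size = 40, tumor_fraction = 0.25,
#'                        seed = 1)
#' table(ph$labels)
#' @export
generate_phantom <- function(geometry = c("disc", "blob", "punch_core",
                                          "custom"),
                             array_size = 40L, tumor_fraction = 0.25,
                             tumor_radius = NULL, rim_wells = 2L,
                             core_width_frac = 0.1, oversample = 1L,
                             seed = 1L, custom_mask = NULL) {
  geometry <- match.arg(geometry)
  if (!is.numeric(array_size) || length(array_size) != 1L ||
      array_size < 1 || array_size != round(array_size)) {
    stop("array_size must be a positive integer", call. = FALSE)
  }
  .check_number(tumor_fraction, "tumor_fraction", 0, 1)
  .check_number(oversample, "oversample", 1, Inf)
  array_size <- as.integer(array_size)
  oversample <- as.integer(oversample)
  res <- array_size * oversample

  cc <- (seq_len(res) - 0.5) / res
  xg <- matrix(cc, res, res, byrow = TRUE)  # column coordinate
  yg <- matrix(cc, res, res)                # row coordinate, row 1 = top

  tumor <- with_seed(derive_seed(seed, "phantom"), {
    if (geometry == "custom") {
      if (is.null(custom_mask)) {
        stop("geometry 'custom' requires custom_mask", call. = FALSE)
      }
      stopifnot(is.logical(custom_mask), all(dim(custom_mask) == res))
      custom_mask
    } else if (tumor_fraction == 0 && is.null(tumor_radius)) {
      matrix(FALSE, res, res)
    } else if (geometry == "disc") {
      ctr <- 0.5 + stats::runif(2, -0.05, 0.05)
      r <- if (!is.null(tumor_radius)) tumor_radius / array_size
           else sqrt(tumor_fraction / pi)
      (xg - ctr[1])^2 + (yg - ctr[2])^2 <= r^2
    } else if (geometry == "blob") {
      ctr <- 0.5 + stats::runif(2, -0.05, 0.05)
      h <- 2:4
      amp <- stats::runif(3, 0, 0.15) / h
      phs <- stats::runif(3, 0, 2 * pi)
      r0 <- sqrt(tumor_fraction / pi / (1 + sum(amp^2) / 2))
      th <- atan2(yg - ctr[2], xg - ctr[1])
      rth <- r0 * (1 + amp[1] * cos(2 * th + phs[1]) +
                       amp[2] * cos(3 * th + phs[2]) +
                       amp[3] * cos(4 * th + phs[3]))
      sqrt((xg - ctr[1])^2 + (yg - ctr[2])^2) <= rth
    } else { # punch_core
      cx <- 0.5 + stats::runif(1, -0.1, 0.1)
      halfw <- core_width_frac / 2
      core <- abs(xg - cx) <= halfw
      seg <- max(0, min(1, tumor_fraction))
      y0 <- stats::runif(1, 0.05, max(0.05, 0.95 - seg))
      core & yg >= y0 & yg <= y0 + seg
    }
  })

  para <- if (any(tumor) && rim_wells > 0) {
    r <- as.integer(rim_wells) * oversample
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "box")
    dil <- EBImage::dilate(EBImage::Image(tumor * 1), brush) > 0.5
    matrix(dil, res, res) & !tumor
  } else {
    matrix(FALSE, res, res)
  }

  labels <- matrix(0L, res, res)
  labels[para] <- 1L
  labels[tumor] <- 2L

  # well-resolution ground truth: majority vote within each block
  ft <- .block_mean(tumor * 1, oversample)
  fp <- .block_mean(para * 1, oversample)
  fn <- 1 - ft - fp
  truth_labels <- matrix(0L, array_size, array_size)
  truth_labels[fp > fn & fp >= ft] <- 1L
  truth_labels[ft >= 0.5] <- 2L
  truth_mask <- truth_labels == 2L

  structure(list(labels = labels, tumor_mask = tumor,
                 truth_labels = truth_labels, truth_mask = truth_mask,
                 width = array_size, height = array_size,
                 array_size = array_size, oversample = oversample,
                 geometry = geometry, rim_wells = as.integer(rim_wells),
                 tumor_fraction = tumor_fraction, seed = as.integer(seed)),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  n <- tabulate(x$labels + 1L, 3L)
  cat("tissue_phantom:", x$array_size, "x", x$array_size, "wells",
      sprintf("(oversample %d, geometry '%s', seed %d)\n",
              x$oversample, x$geometry, x$seed))
  cat(sprintf("  cells: %d tumor, %d paracancerous, %d normal\n",
              n[3], n[2], n[1]))
  cat(sprintf("  truth mask: %d of %d wells tumor-positive\n",
              sum(x$truth_mask), x$array_size^2))
  invisible(x)
}

#' @export
plot.tissue_phantom <- function(x, ...) {
  graphics::image(t(x$labels[nrow(x$labels):1, ]),
                  col = c("grey90", "steelblue2", "firebrick"),
                  axes = FALSE, asp = 1,
                  main = sprintf("phantom (%s)", x$geometry), ...)
  invisible(x)
}

#' Generate a synthetic region proteome
#'
#' Draws a panel of protein species with molecular weights, reactive-site
#' counts and per-region abundances.  Common species span the full
#' analysis mass range with equal abundance in all regions (fold change
#' ~ 1); signature species are confined to the target mass window
#' (default 60–75 kDa) and enriched `fc`-fold in tumor relative to
#' paracancerous/normal tissue.  The signature definition requires
#' `fc > 2` and signature masses inside 15–100 kDa; violating either is
#' an error, never silently relaxed.
#'
#' @param n_common number of non-enriched species across 15–100 kDa.
#' @param n_signature number of tumor-enriched signature species.
#' @param fc tumor/paracancerous fold change of signature species
#'   (must exceed 2 when `n_signature > 0`).
#' @param mw_window signature mass window in kDa, within `[15, 100]`.
#' @param mw_range common-species mass range in kDa.
#' @param noise_cv coefficient of variation of per-well abundance draws
#'   (log-normal; see [sample_well_abundances()]).
#' @param base_abundance median species abundance (arbitrary units).
#' @param seed integer seed.
#' @return An object of class `proteome_profile`: list with a `species`
#'   data frame (`id`, `mw_kda`, `n_sites`, `pocket_intact`,
#'   `abund_normal`, `abund_para`, `abund_tumor`, `fold_change`,
#'   `signature`), `signature_ids` and `noise_cv`.
#' @export
generate_proteome <- function(n_common = 30L, n_signature = 5L, fc = 3,
                              mw_window = c(60, 75), mw_range = c(15, 100),
                              noise_cv = 0.1, base_abundance = 1,
                              seed = 1L) {
  stopifnot(n_common >= 0, n_signature >= 0, length(mw_window) == 2L)
  if (n_signature > 0 && fc <= 2) {
    stop("signature species require fold change > 2; got fc = ", fc,
         call. = FALSE)
  }
  if (mw_window[1] < 15 || mw_window[2] > 100 ||
      mw_window[1] >= mw_window[2]) {
    stop("mw_window must be an increasing interval within [15, 100] kDa",
         call. = FALSE)
  }
  .check_number(noise_cv, "noise_cv", 0, Inf)

  species <- with_seed(derive_seed(seed, "proteome"), {
    n <- n_common + n_signature
    sig <- rep(c(FALSE, TRUE), c(n_common, n_signature))
    mw <- numeric(n)
    mw[!sig] <- stats::runif(n_common, mw_range[1], mw_range[2])
    mw[sig]  <- stats::runif(n_signature, mw_window[1], mw_window[2])
    base <- base_abundance * stats::rlnorm(n, 0, 0.3)
    data.frame(
      id = c(sprintf("common_%02d", seq_len(n_common)),
             sprintf("sig_%02d", seq_len(n_signature)))[seq_len(n)],
      mw_kda = mw,
      n_sites = sample(1:3, n, replace = TRUE),
      pocket_intact = TRUE,
      abund_normal = base,
      abund_para = base,
      abund_tumor = ifelse(sig, fc * base, base),
      signature = sig,
      stringsAsFactors = FALSE
    )
  })
  species$fold_change <- species$abund_tumor / species$abund_para

  structure(list(species = species,
                 signature_ids = species$id[species$signature],
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "proteome_profile")
}

#' @export
print.proteome_profile <- function(x, ...) {
  s <- x$species
  cat("proteome_profile:", nrow(s), "species (",
      sum(s$signature), "signature,", sum(!s$signature), "common )\n")
  if (any(s$signature)) {
    cat(sprintf("  signature MW %.1f-%.1f kDa, fold change %.2f\n",
                min(s$mw_kda[s$signature]), max(s$mw_kda[s$signature]),
                mean(s$fold_change[s$signature])))
  }
  cat("  per-well abundance CV:", x$noise_cv, "\n")
  invisible(x)
}

#' Draw per-well, per-species abundances
#'
#' Each well's abundance of each species is drawn log-normally around the
#' mean of the well's region (tumor / paracancerous / normal), with the
#' proteome's `noise_cv` as coefficient of variation.  `noise_cv = 0`
#' returns the region means exactly.  All draws are non-negative by
#' construction.
#'
#' @param phantom a [tissue_phantom][generate_phantom].
#' @param proteome a [proteome_profile][generate_proteome].
#' @param seed integer seed; a fixed seed gives bit-identical grids.
#' @return 3D numeric array `[row, col, species]` at the phantom's label
#'   resolution, with species ids as the third dimnames.
#' @export
sample_well_abundances <- function(phantom, proteome, seed = 1L) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(proteome, "proteome_profile"))
  sp <- proteome$species
  res <- nrow(phantom$labels)
  cv <- proteome$noise_cv
  means <- rbind(sp$abund_normal, sp$abund_para, sp$abund_tumor)
  idx <- as.integer(phantom$labels) + 1L  # 1 normal, 2 para, 3 tumor

  out <- with_seed(derive_seed(seed, "abundance"), {
    a <- array(0, c(res, res, nrow(sp)),
               dimnames = list(NULL, NULL, sp$id))
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      for (j in seq_len(nrow(sp))) {
        mu <- means[idx, j]
        a[, , j] <- stats::rlnorm(res * res,
                                  meanlog = log(mu) - sdlog^2 / 2,
                                  sdlog = sdlog)
      }
    } else {
      for (j in seq_len(nrow(sp))) a[, , j] <- means[idx, j]
    }
    a
  })
  out
}
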