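#' Per-well tumor-to-reference ratio map
#'
#' Aggregates the selected gel layers per well and divides by the median
#' aggregated signal over an annotated reference region (paracancerous /
#' normal wells).  The ratio is the classifier statistic for margin
#' calling; reference wells themselves receive ratios too.
#'
#' @param images list of [microwell_image] objects (as from
#'   [rasterize()]/[degrade()]); selected by their `layer_index`.
#' @param layers_used integer layer indices to aggregate (the 60–75 kDa
#'   target-window layers by default in the pipeline).
#' @param reference_mask logical well matrix marking reference wells
#'   (non-empty).
#' @param aggregation `"mean"` or `"sum"` across the selected layers.
#' @return An object of class `ratio_map`: `values` (well matrix of
#'   ratios), `reference_stat` (the reference median), `layers_used`,
#'   `aggregation`.
#' @export
ratio_map <- function(images, layers_used, reference_mask,
                      aggregation = c("mean", "sum")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(images) > 0L, length(layers_used) > 0L)
  idx <- vapply(images, function(im) im$layer_index, integer(1))
  sel <- images[idx %in% layers_used]
  if (!length(sel)) {
    stop("none of the requested layers are present in `images`",
         call. = FALSE)
  }
  agg <- Reduce(`+`, lapply(sel, function(im) im$values))
  if (aggregation == "mean") agg <- agg / length(sel)
  stopifnot(is.logical(reference_mask),
            all(dim(reference_mask) == dim(agg)))
  if (!any(reference_mask)) {
    stop("reference_mask is empty", call. = FALSE)
  }
  ref <- stats::median(agg[reference_mask])
  if (!is.finite(ref) || ref <= 0) {
    stop("degenerate reference: median reference signal is ", ref,
         call. = FALSE)
  }
  structure(list(values = agg / ref, reference_stat = ref,
                 layers_used = sort(as.integer(layers_used)),
                 aggregation = aggregation),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf(
    "ratio_map: %d x %d wells, layers {%s} (%s), reference median %.4g\n",
    nrow(x$values), ncol(x$values),
    paste(x$layers_used, collapse = ","), x$aggregation,
    x$reference_stat))
  cat(sprintf("  ratio range [%.3f, %.3f]\n", min(x$values),
              max(x$values)))
  invisible(x)
}

#' @export
plot.ratio_map <- function(x, ...) {
  graphics::image(t(x$values[nrow(x$values):1, ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = 1, main = "tumor/reference ratio",
                  ...)
  invisible(x)
}

#' Empirical ROC curve and Youden-optimal cutoff
#'
#' Builds the empirical ROC of the rule "positive when ratio >= cutoff"
#' over candidate cutoffs placed at the midpoints between consecutive
#' distinct pooled values (plus open ends), computes AUC by trapezoid,
#' and selects the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1.  Ties in J are broken toward
#' higher specificity, then toward the higher cutoff.
#'
#' @param positive_ratios ratios from tumor-positive material.
#' @param negative_ratios ratios from tumor-negative material.
#' @return An object of class `roc_result`: `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden` and the `curve` data frame
#'   (`cutoff`, `fpr`, `tpr`).
#' @export
roc_cutoff <- function(positive_ratios, negative_ratios) {
  pos <- sort(as.numeric(positive_ratios))
  neg <- sort(as.numeric(negative_ratios))
  if (!length(pos) || !length(neg)) {
    stop("both ratio lists must be non-empty", call. = FALSE)
  }
  if (length(pos) < 2L || length(neg) < 2L) {
    warning("fewer than 2 values in a group: degenerate ROC curve",
            call. = FALSE)
  }
  v <- sort(unique(c(pos, neg)))
  cand <- if (length(v) > 1L) {
    c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
  } else {
    c(v - 1, v + 1)
  }
  # classify positive when x >= cutoff
  sens <- 1 - findInterval(cand, pos) / length(pos)
  spec <- findInterval(cand, neg) / length(neg)
  fpr <- 1 - spec
  tpr <- sens
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(ord)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.max(cand[best])]
  structure(list(auc = auc, cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best],
                 curve = data.frame(cutoff = cand, fpr = fpr, tpr = tpr),
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.4f (n+ = %d, n- = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf(
    "  Youden cutoff %.4f: sensitivity %.3f, specificity %.3f, J %.3f\n",
    x$cutoff, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# 4-connectivity components + hole filling + boundary tracing via EBImage.
.clean_mask <- function(mask, min_component_wells, fill_holes) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_component_wells)
  m <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  if (fill_holes && any(m)) {
    m <- matrix(EBImage::fillHull(EBImage::Image(m * 1)) > 0.5,
                nrow(mask), ncol(mask))
  }
  m
}

#' Call the tumor margin from a ratio map
#'
#' Thresholds the ratio map at `threshold` (wells with ratio >= threshold
#' are tumor-positive), removes connected components smaller than
#' `min_component_wells` (4-connectivity), fills interior holes, and
#' traces the boundary of each remaining component.  An empty mask after
#' cleanup is a valid (negative) call.
#'
#' @param rmap a [ratio_map()] result.
#' @param threshold positive ratio cutoff (default 1.330, the
#'   ROC-calibrated cutoff used when no calibration data is supplied).
#' @param min_component_wells minimum component size kept (default 3).
#' @param fill_holes fill interior holes of the mask (default TRUE).
#' @return An object of class `margin_call`: `mask` (logical well
#'   matrix), `contour` (list of per-component boundary-well coordinate
#'   matrices, columns `row`/`col`, 0-based, row-major origin top-left),
#'   `threshold_used` and `cleanup_meta`.
#' @export
call_margin <- function(rmap, threshold = 1.330,
                        min_component_wells = 3L, fill_holes = TRUE) {
  stopifnot(inherits(rmap, "ratio_map"))
  .check_number(threshold, "threshold", 1e-12, Inf)
  raw <- rmap$values >= threshold
  mask <- .clean_mask(raw, min_component_wells, fill_holes)
  contour <- if (any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    lapply(EBImage::ocontour(lab), function(oc) {
      # EBImage coords are 0-based (dim1, dim2) = (row, col)
      m <- cbind(row = oc[, 1], col = oc[, 2])
      m
    })
  } else {
    list()
  }
  structure(list(mask = mask, contour = contour,
                 threshold_used = threshold,
                 cleanup_meta = list(
                   min_component_wells = as.integer(min_component_wells),
                   holes_filled = isTRUE(fill_holes))),
            class = "margin_call")
}

#' @export
print.margin_call <- function(x, ...) {
  cat(sprintf(
    "margin_call: %d tumor-positive wells in %d component(s), cutoff %.3f\n",
    sum(x$mask), length(x$contour), x$threshold_used))
  invisible(x)
}

#' Similarity between a margin call and ground truth
#'
#' Dice coefficient of the predicted and true tumor masks, reported as a
#' percentage: `100 * 2|A&B| / (|A| + |B|)`; two empty masks score 100.
#' The simple overlap `|A&B| / |truth|` is reported alongside for
#' transparency.
#'
#' @param call a [call_margin()] result or a logical mask matrix.
#' @param truth_mask logical well matrix of true tumor wells.
#' @return An object of class `similarity_report`: `similarity_pct`,
#'   `overlap_pct`, `intersection_wells`, `pred_wells`, `truth_wells`.
#' @export
similarity <- function(call, truth_mask) {
  pred <- if (inherits(call, "margin_call")) call$mask else call
  stopifnot(is.logical(pred), is.logical(truth_mask))
  if (!all(dim(pred) == dim(truth_mask))) {
    stop("predicted and truth masks differ in dimensions", call. = FALSE)
  }
  inter <- sum(pred & truth_mask)
  a <- sum(pred); b <- sum(truth_mask)
  dice <- if (a + b == 0L) 100 else 100 * 2 * inter / (a + b)
  overlap <- if (b == 0L) NA_real_ else 100 * inter / b
  structure(list(similarity_pct = dice, overlap_pct = overlap,
                 intersection_wells = inter, pred_wells = a,
                 truth_wells = b),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "similarity_report: Dice %.1f%% (overlap %.1f%%), |pred| %d, |truth| %d, |both| %d\n",
    x$similarity_pct, x$overlap_pct, x$pred_wells, x$truth_wells,
    x$intersection_wells))
  invisible(x)
}

#' Test inclusion of annotated regions of interest
#'
#' An ROI passes when every one of its wells lies inside the predicted
#' tumor mask (the criterion used for pathologist-marked regions C1–C3).
#'
#' @param call a [call_margin()] result.
#' @param rois named list of ROI well-coordinate matrices (columns
#'   row/col, 1-based matrix indices).
#' @return Named logical vector, one entry per ROI.
#' @export
inclusion_test <- function(call, rois) {
  stopifnot(inherits(call, "margin_call"), is.list(rois))
  vapply(rois, function(r) {
    if (is.null(r) || nrow(r) == 0L) {
      stop("inclusion is undefined for an empty ROI", call. = FALSE)
    }
    if (any(r[, 1] < 1 | r[, 1] > nrow(call$mask) |
            r[, 2] < 1 | r[, 2] > ncol(call$mask))) {
      stop("ROI wells fall outside the grid", call. = FALSE)
    }
    all(call$mask[cbind(r[, 1], r[, 2])])
  }, logical(1))
}

#' Rank-sum comparison of two ratio cohorts
#'
#' Two-sided Mann–Whitney U test of tumor/normal against normal/normal
#' ratio pools: exact enumeration for small tie-free samples, normal
#' approximation with tie correction otherwise (the behaviour of
#' [stats::wilcox.test()], which backs this operation).
#'
#' @param tumor_normal_ratios,normal_normal_ratios numeric vectors,
#'   each of length >= 3.
#' @return List with `u` (the U statistic of the first sample), `p_value`
#'   and `method`.
#' @export
compare_groups <- function(tumor_normal_ratios, normal_normal_ratios) {
  x <- as.numeric(tumor_normal_ratios)
  y <- as.numeric(normal_normal_ratios)
  if (length(x) < 3L || length(y) < 3L) {
    stop("each cohort needs at least 3 values", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied; p = 1", call. = FALSE)
    return(list(u = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate (all tied)"))
  }
  exact <- max(length(x), length(y)) < 20L && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(u = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}
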