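make_images <- function(mats, layers = seq_along(mats)) {
  Map(function(m, k) microwell_image(m, k), mats, as.integer(layers))
}

test_that("null contrast gives unit ratios everywhere", {
  m <- matrix(2, 10, 10)
  rm <- ratio_map(make_images(list(m, m), 3:4), 3:4,
                  matrix(TRUE, 10, 10))
  expect_true(all(rm$values == 1))
  expect_equal(rm$reference_stat, 2)
})

test_that("ratios are linear in the tumor signal", {
  base <- matrix(1, 10, 10)
  tum <- base; tum[3:6, 3:6] <- 2
  ref <- matrix(TRUE, 10, 10); ref[3:6, 3:6] <- FALSE
  r1 <- ratio_map(make_images(list(tum), 3), 3, ref)
  tum2 <- base; tum2[3:6, 3:6] <- 4
  r2 <- ratio_map(make_images(list(tum2), 3), 3, ref)
  expect_equal(r2$values[3:6, 3:6], 2 * r1$values[3:6, 3:6])
  expect_equal(r1$values[1, 1], r2$values[1, 1])
})

test_that("degenerate references are rejected", {
  imgs <- make_images(list(matrix(0, 5, 5)), 3)
  expect_error(ratio_map(imgs, 3, matrix(TRUE, 5, 5)), "degenerate")
  expect_error(ratio_map(imgs, 3, matrix(FALSE, 5, 5)), "empty")
  expect_error(ratio_map(imgs, 7, matrix(TRUE, 5, 5)), "layers")
})

test_that("perfectly separated cohorts give AUC 1 and an interior cutoff", {
  roc <- roc_cutoff(c(2, 2.5, 3), c(0.5, 0.8, 1))
  expect_equal(roc$auc, 1)
  expect_gt(roc$cutoff, 1)
  expect_lt(roc$cutoff, 2)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
})

test_that("Youden cutoff equals the exhaustive-threshold brute force", {
  brute <- function(pos, neg) {
    v <- sort(unique(c(pos, neg)))
    cand <- c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
    best <- c(-Inf, NA, NA)
    for (cc in cand) {
      sens <- mean(pos >= cc); spec <- mean(neg < cc)
      j <- sens + spec - 1
      if (j > best[1] + 1e-12 ||
          (abs(j - best[1]) <= 1e-12 && spec > best[3] + 1e-12) ||
          (abs(j - best[1]) <= 1e-12 && abs(spec - best[3]) <= 1e-12 &&
           cc > best[2])) {
        best <- c(j, cc, spec)
      }
    }
    best
  }
  set.seed(42)
  for (rep in 1:20) {
    pos <- round(rnorm(25, 1.6, 0.8), 1)  # rounding forces ties
    neg <- round(rnorm(30, 1.0, 0.6), 1)
    roc <- roc_cutoff(pos, neg)
    b <- brute(pos, neg)
    expect_equal(roc$youden, b[1], tolerance = 1e-12)
    expect_equal(roc$cutoff, b[2], tolerance = 1e-12)
  }
})

test_that("empirical AUC matches the closed-form binormal value", {
  set.seed(7)
  pos <- rnorm(1e5, 1, 1)
  neg <- rnorm(1e5, 0, 1)
  roc <- roc_cutoff(pos, neg)
  expect_equal(roc$auc, pnorm(1 / sqrt(2)), tolerance = 0.01)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  pos <- round(rnorm(80, 1.4, 0.7), 1)
  neg <- round(rnorm(90, 1.0, 0.5), 1)
  roc <- roc_cutoff(pos, neg)
  ref <- pROC::roc(response = rep(c(1, 0), c(80, 90)),
                   predictor = c(pos, neg), quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(3)
  pos <- rlnorm(200, 0.4, 0.5); neg <- rlnorm(200, 0, 0.5)
  a1 <- roc_cutoff(pos, neg)$auc
  a2 <- roc_cutoff(exp(pos), exp(neg))$auc
  a3 <- roc_cutoff(log(pos), log(neg))$auc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("margin calls threshold, clean and trace the ratio field", {
  v <- matrix(1, 20, 20)
  v[5:14, 5:14] <- 2          # main tumor block
  v[18, 18] <- 2              # speck below the component minimum
  v[9, 9] <- 1                # interior hole
  rm <- structure(list(values = v, reference_stat = 1, layers_used = 3L,
                       aggregation = "mean"), class = "ratio_map")
  call <- call_margin(rm, threshold = 1.330, min_component_wells = 3)
  expect_equal(sum(call$mask), 100)      # hole filled, speck removed
  expect_true(call$mask[9, 9])
  expect_false(call$mask[18, 18])
  expect_length(call$contour, 1)
  # contour vertices lie on the mask boundary
  ct <- call$contour[[1]] + 1L
  on_mask <- call$mask[ct]
  expect_true(all(on_mask))
  inner <- call$mask
  inner[5, ] <- inner[14, ] <- inner[, 5] <- inner[, 14] <- FALSE
  expect_false(any(inner[ct]))
})

test_that("an all-negative field yields a valid empty call", {
  rm <- structure(list(values = matrix(1, 8, 8), reference_stat = 1,
                       layers_used = 3L, aggregation = "mean"),
                  class = "ratio_map")
  call <- call_margin(rm, threshold = 1.330)
  expect_false(any(call$mask))
  expect_length(call$contour, 0)
})

test_that("raising the threshold never grows the mask", {
  set.seed(5)
  v <- matrix(rlnorm(400, 0, 0.5), 20)
  rm <- structure(list(values = v, reference_stat = 1, layers_used = 3L,
                       aggregation = "mean"), class = "ratio_map")
  sizes <- vapply(seq(0.5, 3, by = 0.25), function(th) {
    sum(call_margin(rm, th, min_component_wells = 1,
                    fill_holes = FALSE)$mask)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("Dice similarity matches hand-enumerated overlaps", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE   # 50-well overlap
  s <- similarity(a, b)
  expect_equal(s$similarity_pct, 50)
  expect_equal(s$intersection_wells, 50)
  expect_equal(similarity(a, a)$similarity_pct, 100)
  disj <- matrix(FALSE, 20, 20); disj[15:20, 15:20] <- TRUE
  expect_equal(similarity(a, disj)$similarity_pct, 0)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(similarity(empty, empty)$similarity_pct, 100)
  expect_error(similarity(a, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("ROI inclusion demands every well inside the mask", {
  v <- matrix(1, 10, 10); v[3:8, 3:8] <- 2
  rm <- structure(list(values = v, reference_stat = 1, layers_used = 3L,
                       aggregation = "mean"), class = "ratio_map")
  call <- call_margin(rm, 1.33)
  inside <- cbind(4:6, 4:6)
  outside <- cbind(c(1, 2), c(1, 2))
  straddle <- rbind(inside, c(2, 5))
  res <- inclusion_test(call, list(C1 = inside, NC1 = outside,
                                   C2 = straddle))
  expect_identical(res, c(C1 = TRUE, NC1 = FALSE, C2 = FALSE))
  expect_error(inclusion_test(call, list(bad = inside[0, ])), "empty ROI")
  expect_error(inclusion_test(call, list(bad = cbind(99, 1))),
               "outside the grid")
})

test_that("rank-sum comparison handles null and degenerate inputs", {
  x <- c(1.1, 1.2, 1.3, 1.4, 1.5)
  res <- compare_groups(x, x + 1e-9)
  expect_gt(res$p_value, 0.5)
  expect_warning(tied <- compare_groups(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(tied$p_value, 1)
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("exact rank-sum p-values match full enumeration for small n", {
  enum_p <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) sum(seq_len(n1 + n2)[ix]) -
                  n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.8)
    res <- compare_groups(x, y)
    expect_equal(res$p_value, enum_p(x, y), tolerance = 1e-12)
  }
})
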