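test_that("degenerate tumor fraction gives an all-normal section", {
  ph <- generate_phantom("disc", 20, tumor_fraction = 0, seed = 3)
  expect_false(any(ph$tumor_mask))
  expect_true(all(ph$labels == 0L))
  expect_false(any(ph$truth_mask))
})

test_that("rasterized disc area matches the geometric oracle", {
  ph <- generate_phantom("disc", 40, tumor_radius = 10, seed = 1)
  target <- pi * 10^2
  expect_lt(abs(sum(ph$tumor_mask) - target) / target, 0.05)
})

test_that("grid dimensions follow the requested array size", {
  for (a in c(20L, 40L)) {
    ph <- generate_phantom("disc", a, seed = 2)
    expect_equal(dim(ph$labels), c(a, a))
    expect_equal(dim(ph$truth_mask), c(a, a))
  }
  ph <- generate_phantom("disc", 20, oversample = 3, seed = 2)
  expect_equal(dim(ph$labels), c(60, 60))
  expect_equal(dim(ph$truth_mask), c(20, 20))
})

test_that("every cell has exactly one region and the rim wraps the tumor", {
  for (geom in c("disc", "blob", "punch_core")) {
    ph <- generate_phantom(geom, 40, tumor_fraction = 0.3, seed = 7)
    counts <- tabulate(ph$labels + 1L, 3L)
    expect_equal(sum(counts), 40L * 40L)
    expect_true(all(ph$labels %in% 0:2))
    expect_identical(ph$tumor_mask, ph$labels == 2L)
    # paracancerous cells touch the tumor within the rim width
    if (any(ph$labels == 1L)) {
      expect_gt(sum(ph$labels == 1L), 0)
    }
  }
})

test_that("phantom generation is seed-deterministic", {
  a <- generate_phantom("blob", 40, seed = 11)
  b <- generate_phantom("blob", 40, seed = 11)
  c <- generate_phantom("blob", 40, seed = 12)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels, c$labels))
})

test_that("the same seed yields the same tissue at any resolution", {
  a <- generate_phantom("punch_core", 20, tumor_fraction = 0.5,
                        oversample = 4, seed = 5)
  b <- generate_phantom("punch_core", 40, tumor_fraction = 0.5,
                        oversample = 2, seed = 5)
  expect_identical(a$tumor_mask, b$tumor_mask)  # both 80 x 80
  expect_equal(sum(b$truth_mask) / max(sum(a$truth_mask), 1), 4,
               tolerance = 0.35)
})

test_that("phantom input validation rejects bad sizes and fractions", {
  expect_error(generate_phantom("disc", 0), "array_size")
  expect_error(generate_phantom("disc", 20, tumor_fraction = 1.2),
               "tumor_fraction")
  expect_error(generate_phantom("custom", 20), "custom_mask")
})

test_that("no-signature proteome has identical region means", {
  pr <- generate_proteome(n_common = 10, n_signature = 0, seed = 4)
  expect_equal(pr$species$abund_tumor, pr$species$abund_normal)
  expect_equal(pr$species$abund_tumor, pr$species$abund_para)
  expect_true(all(pr$species$fold_change == 1))
})

test_that("signature species sit in the target window with the set FC", {
  pr <- generate_proteome(n_signature = 5, fc = 3, seed = 9)
  sig <- pr$species[pr$species$signature, ]
  expect_true(all(sig$mw_kda >= 60 & sig$mw_kda <= 75))
  expect_equal(sig$fold_change, rep(3, 5))
  expect_setequal(pr$signature_ids, sig$id)
})

test_that("the signature definition is enforced, not relaxed", {
  expect_error(generate_proteome(fc = 2), "fold change > 2")
  expect_error(generate_proteome(fc = 1.5), "fold change > 2")
  expect_error(generate_proteome(mw_window = c(10, 75)), "mw_window")
  expect_silent(generate_proteome(n_signature = 0, fc = 1))
})

test_that("empirical tumor/paracancerous ratio matches the requested FC", {
  # Monte-Carlo oracle: >=1000 draws per region at FC 3 must average
  # into [2.85, 3.15]
  labels <- matrix(0L, 50, 50)
  labels[1:25, ] <- 2L
  ph <- flat_phantom(50L, labels)
  pr <- generate_proteome(n_common = 0, n_signature = 5, fc = 3,
                          noise_cv = 0.1, seed = 21)
  ab <- sample_well_abundances(ph, pr, seed = 21)
  for (j in 1:5) {
    m <- ab[, , j]
    r <- mean(m[labels == 2L]) / mean(m[labels == 0L])
    expect_gt(r, 2.85)
    expect_lt(r, 3.15)
  }
})

test_that("per-well abundance noise has the configured CV", {
  labels <- matrix(0L, 100, 100)
  ph <- flat_phantom(100L, labels)
  pr <- generate_proteome(n_common = 1, n_signature = 0, noise_cv = 0.1,
                          seed = 2)
  ab <- sample_well_abundances(ph, pr, seed = 2)
  v <- as.numeric(ab[, , 1])
  cv <- stats::sd(v) / mean(v)
  expect_gt(cv, 0.09)
  expect_lt(cv, 0.11)
  expect_true(all(v >= 0))
})

test_that("zero noise returns region means exactly and draws are seeded", {
  ph <- generate_phantom("disc", 20, seed = 5)
  pr0 <- generate_proteome(n_common = 4, n_signature = 2, noise_cv = 0,
                           seed = 5)
  ab0 <- sample_well_abundances(ph, pr0, seed = 5)
  sp <- pr0$species
  m0 <- ab0[, , 1]
  expect_equal(unique(as.numeric(m0[ph$labels == 2L])),
               sp$abund_tumor[1])
  pr <- generate_proteome(n_common = 4, n_signature = 2, noise_cv = 0.2,
                          seed = 5)
  a <- sample_well_abundances(ph, pr, seed = 8)
  b <- sample_well_abundances(ph, pr, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, sample_well_abundances(ph, pr, seed = 9)))
})
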