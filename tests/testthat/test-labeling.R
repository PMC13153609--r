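test_that("no reaction happens at time zero or with zero sites", {
  oc <- site_occupancy(2, 2, conditions = labeling_conditions(time_min = 0))
  expect_equal(unname(oc$probs), c(1, 0, 0))
  oc0 <- site_occupancy(0, 5)
  expect_equal(unname(oc0$probs), 1)
  expect_equal(oc0$bound_mean, 0)
})

test_that("substoichiometric dye gives the bimodal all-or-nothing outcome", {
  # 1:1 dye on the two-pocket model protein, run to completion:
  # roughly half the proteins stay unlabeled, labeled ones carry 2 dyes
  oc <- site_occupancy(2, 1, mode = "completion")
  labeled <- oc$probs[-1]
  expect_equal(names(which.max(labeled)), "2")
  expect_equal(oc$unlabeled, 0.5, tolerance = 0.02)
  expect_gt(oc$probs[["2"]], 10 * oc$probs[["1"]])
})

test_that("single-site occupancy matches the pseudo-first-order closed form", {
  p <- kinetic_params(k1_ref = 5e-9)
  cond <- labeling_conditions(temperature_c = 37, time_min = 100,
                              dye_protein_ratio = 1e6)
  oc <- site_occupancy(1, 1e6, params = p, conditions = cond)
  expected <- 1 - exp(-5e-9 * 1e6 * 100)
  expect_lt(abs(oc$bound_mean - expected), 1e-6)
})

test_that("completion state agrees with an independent matrix-exponential
           oracle", {
  skip_if_not_installed("Matrix")
  chain_expm <- function(u, n, coop) {
    cs <- c(1, rep(coop, n - 1))
    A <- matrix(0, n + 1, n + 1)
    for (i in seq_len(n)) {
      A[i, i] <- A[i, i] - cs[i]
      A[i + 1, i] <- cs[i]
    }
    as.numeric(Matrix::expm(A * u) %*% c(1, rep(0, n)))
  }
  for (n in 2:3) for (r in seq_len(n - 1)) {
    oc <- site_occupancy(n, r, mode = "completion")
    u <- stats::uniroot(function(u) {
      sum(seq(0, n) * chain_expm(u, n, 100)) - r
    }, c(1e-9, 100), tol = 1e-12)$root
    expect_equal(unname(oc$probs), chain_expm(u, n, 100),
                 tolerance = 1e-7)
  }
})

test_that("minimal complete ratio equals one dye equivalent per site", {
  expect_identical(minimal_complete_ratio(2), 2L)
  expect_identical(minimal_complete_ratio(1), 1L)
  expect_identical(minimal_complete_ratio(3), 3L)
  expect_warning(r0 <- minimal_complete_ratio(5, max_ratio = 3),
                 "no dye:protein ratio")
  expect_identical(r0, NA_integer_)
})

test_that("dye is conserved through the reaction", {
  for (temp in c(23, 37, 60)) for (ratio in c(0.5, 1, 2, 4)) {
    oc <- site_occupancy(2, ratio,
                         conditions = labeling_conditions(
                           temperature_c = temp, time_min = 45,
                           dye_protein_ratio = ratio))
    expect_lt(abs(oc$bound_mean + oc$free_dye - ratio) / max(ratio, 1),
              1e-9)
    expect_equal(sum(oc$probs), 1, tolerance = 1e-9)
  }
})

test_that("signal grows with temperature: 23 < 37 < 60 degC", {
  sig <- vapply(c(23, 37, 60), function(temp) {
    site_occupancy(2, 2, conditions = labeling_conditions(
      temperature_c = temp, time_min = 60))$bound_mean
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("temperature moves the signal more than time", {
  s <- temperature_time_sensitivity()
  expect_gt(s$per_degc, s$per_min)
  expect_gt(s$per_degc, 0)
  expect_gt(s$per_min, 0)
})

test_that("control dyes and digested lysates give zero covalent signal", {
  ph <- generate_phantom("disc", 10, seed = 2)
  pr <- generate_proteome(n_common = 5, n_signature = 2, seed = 2)
  ab <- sample_well_abundances(ph, pr, seed = 2)
  for (variant in c("ac_control", "icg_control")) {
    lys <- label_lysate(ab, pr, labeling_conditions(dye_variant = variant))
    expect_true(all(lys$signal == 0))
  }
  lys <- label_lysate(ab, pr, labeling_conditions(digested = TRUE))
  expect_true(all(lys$signal == 0))
})

test_that("denaturation reduces but does not abolish the signal", {
  ph <- generate_phantom("disc", 10, seed = 2)
  pr <- generate_proteome(n_common = 5, n_signature = 2, seed = 2)
  ab <- sample_well_abundances(ph, pr, seed = 2)
  intact <- sum(label_lysate(ab, pr, labeling_conditions())$signal)
  denat <- sum(label_lysate(ab, pr,
                            labeling_conditions(denatured = TRUE))$signal)
  expect_gt(denat, 0)
  expect_lt(denat, intact)
})

test_that("bound signal never exceeds sites times protein amount", {
  ph <- generate_phantom("disc", 10, seed = 3)
  pr <- generate_proteome(n_common = 6, n_signature = 2, seed = 3)
  ab <- sample_well_abundances(ph, pr, seed = 3)
  lys <- label_lysate(ab, pr, labeling_conditions(dye_protein_ratio = 10,
                                                  time_min = 1e4))
  cap <- sweep(ab, 3, pr$species$n_sites, `*`)
  expect_true(all(lys$signal <= cap + 1e-9))
})

test_that("stochastic simulation converges to the deterministic mean", {
  det <- site_occupancy(2, 2)$bound_mean
  emp <- site_occupancy_stochastic(2, 2, n_molecules = 4000, seed = 7)
  emp_mean <- sum(as.numeric(names(emp)) * emp)
  expect_equal(emp_mean, det, tolerance = 0.05)
  expect_identical(emp, site_occupancy_stochastic(2, 2,
                                                  n_molecules = 4000,
                                                  seed = 7))
})
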