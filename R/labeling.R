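#' Labeling reaction conditions
#'
#' Conditions under which the chlorine-bearing cyanine dye reacts with
#' lysate proteins: pocket insertion followed by nucleophilic substitution
#' of the dye's reactive chlorine by a pocket cysteine thiol.  The two
#' control variants carry no reactive chlorine (`ac_control`, the
#' chlorine-blocked analog) or no pocket chemistry at all (`icg_control`)
#' and therefore form no covalent adduct under any conditions.
#'
#' @param temperature_c reaction temperature in deg C (0–100; default 60,
#'   the optimum for margin discrimination).
#' @param time_min reaction time in minutes (default 60).
#' @param dye_protein_ratio dye equivalents supplied per protein molecule
#'   (default 2, the complete-labeling stoichiometry for the two-pocket
#'   model protein).
#' @param dye_variant `"cl_dye"` (reactive), `"ac_control"` or
#'   `"icg_control"`.
#' @param digested lysate trypsin-digested before labeling (destroys the
#'   binding pockets; no covalent signal).
#' @param denatured lysate heat-denatured (90 deg C / 30 min class of
#'   treatment): covalent labeling persists at reduced brightness.
#' @return An object of class `labeling_conditions`.
#' @export
labeling_conditions <- function(temperature_c = 60, time_min = 60,
                                dye_protein_ratio = 2,
                                dye_variant = c("cl_dye", "ac_control",
                                                "icg_control"),
                                digested = FALSE, denatured = FALSE) {
  .check_number(temperature_c, "temperature_c", 0, 100)
  .check_number(time_min, "time_min", 0, Inf)
  .check_number(dye_protein_ratio, "dye_protein_ratio", 0, Inf)
  .check_flag(digested, "digested")
  .check_flag(denatured, "denatured")
  structure(list(temperature_c = temperature_c, time_min = time_min,
                 dye_protein_ratio = dye_protein_ratio,
                 dye_variant = match.arg(dye_variant),
                 digested = digested, denatured = denatured),
            class = "labeling_conditions")
}

#' Kinetic parameters of the covalent labeling model
#'
#' Sequential irreversible two-step (or n-step) mass-action kinetics:
#' the first site reacts at `k1_ref` (per minute per unit dye
#' concentration, at the 37 deg C reference), subsequent sites at
#' `coop * k1_ref`.  A cooperativity `coop >> 1` reproduces the observed
#' bimodal outcome at substoichiometric dye — proteins are either fully
#' labeled or untouched.  Temperature scales every rate by
#' `exp(ea_like * (T - 37))`, an Arrhenius-like single-coefficient law.
#'
#' @param k1_ref first-site rate constant at 37 deg C (1/min per unit
#'   dye). Default 0.01 so that the 60 deg C / 60 min standard reaction
#'   approaches completion while 23 deg C stays visibly partial.
#' @param coop ratio of subsequent-site to first-site rate constants
#'   (>= 1; default 100).
#' @param ea_like temperature-sensitivity coefficient per deg C (default
#'   0.06: 60 deg C runs ~4x faster than 37 deg C).
#' @param denature_scale multiplicative brightness factor in (0, 1)
#'   applied to denatured lysates (default 0.5).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k1_ref = 0.01, coop = 100, ea_like = 0.06,
                           denature_scale = 0.5) {
  .check_number(k1_ref, "k1_ref", 1e-12, Inf)
  if (!is.numeric(coop) || coop < 1) {
    stop("coop must be >= 1", call. = FALSE)
  }
  .check_number(ea_like, "ea_like", 1e-12, Inf)
  .check_number(denature_scale, "denature_scale", 1e-12, 1 - 1e-12)
  structure(list(k1_ref = k1_ref, coop = coop, ea_like = ea_like,
                 denature_scale = denature_scale),
            class = "kinetic_params")
}

# Per-site rate multipliers c_i = k_i / k1 of the sequential chain.
.site_rates <- function(n_sites, coop) c(1, rep(coop, n_sites - 1L))

# Occupancy distribution of the linear chain in the transformed variable
# u = integral of k1_eff * D dt.  Because every reaction rate is
# proportional to the free-dye concentration D, dividing the mass-action
# system by dD-consumption removes D entirely: in u the chain is linear
# with rates c_i, P0(u) = exp(-u).  This makes the run-to-completion state
# solvable by root-finding instead of integrating a singular t -> Inf ODE.
.chain_probs <- function(u, n_sites, coop) {
  if (u <= 0) return(c(1, rep(0, n_sites)))
  cs <- .site_rates(n_sites, coop)
  deriv <- function(t, y, parms) {
    flux <- cs * y[seq_len(n_sites)]
    list(c(-flux, 0) + c(0, flux))
  }
  y0 <- c(1, rep(0, n_sites))
  out <- deSolve::ode(y0, c(0, u), deriv, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  p <- pmax(out[2, -1], 0)
  p / sum(p)
}

.chain_bound <- function(u, n_sites, coop) {
  sum(seq(0, n_sites) * .chain_probs(u, n_sites, coop))
}

#' Site-occupancy distribution of the covalent labeling reaction
#'
#' Deterministic expectation of the number of dye molecules covalently
#' bound per protein, under sequential irreversible mass-action kinetics
#' with shared (depletable) dye.  Two modes: `"time"` integrates the
#' reaction for `conditions$time_min` minutes at `conditions$temperature_c`;
#' `"completion"` returns the run-to-completion limit, reached when either
#' the supplied dye or the reactive sites are exhausted.
#'
#' @param n_sites reactive cysteine pockets per protein molecule (>= 0).
#' @param dye_protein_ratio dye equivalents per protein; defaults to the
#'   value in `conditions`.
#' @param params a [kinetic_params()] object.
#' @param conditions a [labeling_conditions()] object.
#' @param mode `"time"` or `"completion"`.
#' @return An object of class `site_occupancy`: `probs` (fractions over
#'   occupancy 0..n_sites, summing to 1), `bound_mean` (expected dye per
#'   protein), `free_dye` (unreacted dye per protein; `bound_mean +
#'   free_dye` equals the supplied ratio to numerical tolerance) and
#'   `unlabeled` (`probs[1]`).
#' @examples
#' oc <- site_occupancy(2, 1, kinetic_params(), labeling_conditions(),
#'                      mode = "completion")
#' oc$probs  # bimodal: ~half unlabeled, ~half doubly labeled
#' @export
site_occupancy <- function(n_sites, dye_protein_ratio = NULL,
                           params = kinetic_params(),
                           conditions = labeling_conditions(),
                           mode = c("time", "completion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "kinetic_params"),
            inherits(conditions, "labeling_conditions"))
  if (!is.numeric(n_sites) || n_sites < 0 || n_sites != round(n_sites)) {
    stop("n_sites must be a non-negative integer", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  ratio <- if (is.null(dye_protein_ratio)) conditions$dye_protein_ratio
           else dye_protein_ratio
  .check_number(ratio, "dye_protein_ratio", 0, Inf)

  no_reaction <- n_sites == 0L || ratio == 0 ||
    conditions$dye_variant != "cl_dye" || conditions$digested ||
    (mode == "time" && conditions$time_min == 0)

  probs <- if (no_reaction) {
    c(1, rep(0, n_sites))
  } else if (mode == "completion") {
    if (ratio >= n_sites) {
      # dye never limits: every site reacts (u -> Inf limit of the chain)
      c(rep(0, n_sites), 1)
    } else {
      U <- 1
      while (.chain_bound(U, n_sites, params$coop) < ratio && U < 1e6) {
        U <- U * 2
      }
      us <- stats::uniroot(function(u) {
        .chain_bound(u, n_sites, params$coop) - ratio
      }, c(0, U), tol = 1e-12)$root
      .chain_probs(us, n_sites, params$coop)
    }
  } else {
    keff <- params$k1_ref *
      exp(params$ea_like * (conditions$temperature_c - 37))
    cs <- .site_rates(n_sites, params$coop)
    deriv <- function(t, y, parms) {
      P <- y[seq_len(n_sites + 1L)]
      D <- y[n_sites + 2L]
      flux <- keff * cs * D * P[seq_len(n_sites)]
      list(c(c(-flux, 0) + c(0, flux), -sum(flux)))
    }
    y0 <- c(1, rep(0, n_sites), ratio)
    out <- deSolve::ode(y0, c(0, conditions$time_min), deriv, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-13)
    p <- pmax(out[2, 2:(n_sites + 2L)], 0)
    p / sum(p)
  }

  names(probs) <- as.character(seq(0, n_sites))
  bound <- sum(seq(0, n_sites) * probs)
  structure(list(probs = probs, bound_mean = bound,
                 free_dye = max(ratio - bound, 0), unlabeled = probs[[1L]],
                 n_sites = n_sites, dye_protein_ratio = ratio,
                 mode = mode),
            class = "site_occupancy")
}

#' @export
print.site_occupancy <- function(x, ...) {
  cat(sprintf(
    "site_occupancy (%s): %d site(s), dye ratio %.3g\n", x$mode,
    x$n_sites, x$dye_protein_ratio))
  print(round(x$probs, 4))
  cat(sprintf("  mean bound %.4f, free dye %.4f, unlabeled %.2e\n",
              x$bound_mean, x$free_dye, x$unlabeled))
  invisible(x)
}

#' Stochastic (per-molecule) labeling simulation
#'
#' Gillespie counterpart of [site_occupancy()], provided for validating
#' the deterministic expectation at finite molecule numbers.
#'
#' @inheritParams site_occupancy
#' @param n_molecules number of protein molecules simulated.
#' @param seed integer seed.
#' @return Named occupancy-fraction vector over 0..n_sites.
#' @export
site_occupancy_stochastic <- function(n_sites, dye_protein_ratio = 2,
                                      params = kinetic_params(),
                                      conditions = labeling_conditions(),
                                      n_molecules = 1000L, seed = 1L) {
  n_sites <- as.integer(n_sites)
  N <- as.integer(n_molecules)
  with_seed(derive_seed(seed, "stochastic"), {
    P <- c(N, rep(0L, n_sites))
    D <- round(dye_protein_ratio * N)
    keff <- params$k1_ref *
      exp(params$ea_like * (conditions$temperature_c - 37))
    cs <- .site_rates(n_sites, params$coop)
    t <- 0
    blocked <- n_sites == 0L || conditions$dye_variant != "cl_dye" ||
      conditions$digested
    while (!blocked && D > 0L) {
      a <- keff * cs * P[seq_len(n_sites)] * D / N
      a0 <- sum(a)
      if (a0 <= 0) break
      t <- t + stats::rexp(1, a0)
      if (t > conditions$time_min) break
      i <- sample.int(n_sites, 1L, prob = a)
      P[i] <- P[i] - 1L
      P[i + 1L] <- P[i + 1L] + 1L
      D <- D - 1L
    }
    stats::setNames(P / N, as.character(seq(0, n_sites)))
  })
}

#' Minimal dye:protein ratio for complete labeling
#'
#' Sweeps integer dye:protein ratios from 1 upward, running the labeling
#' reaction to completion at each, and returns the smallest ratio leaving
#' an unlabeled-protein fraction below `tol`.  For the default two-pocket
#' model protein this is 2 — one dye equivalent per reactive site.
#'
#' @param n_sites reactive sites of the model protein (default 2).
#' @param params a [kinetic_params()] object.
#' @param max_ratio largest ratio tried (>= 1).
#' @param tol unlabeled-fraction threshold defining "complete"
#'   (default 1e-6).
#' @return The smallest qualifying integer ratio, or `NA_integer_` (with
#'   a warning) if none is found within `max_ratio`.
#' @export
minimal_complete_ratio <- function(n_sites = 2L, params = kinetic_params(),
                                   max_ratio = 10L, tol = 1e-6) {
  stopifnot(max_ratio >= 1)
  for (r in seq_len(max_ratio)) {
    oc <- site_occupancy(n_sites, r, params, labeling_conditions(),
                         mode = "completion")
    if (oc$unlabeled < tol) return(as.integer(r))
  }
  warning("no dye:protein ratio within 1..", max_ratio,
          " achieves unlabeled fraction < ", tol, call. = FALSE)
  NA_integer_
}

#' Label a lysate grid covalently
#'
#' Applies the labeling model to per-well, per-species protein abundances,
#' producing the covalently bound fluorophore signal per well and species.
#' Per-well signal is protein amount times the expected occupancy under
#' the supplied conditions (times a unit quantum-yield factor).  Species
#' with destroyed pockets (`pocket_intact = FALSE`), trypsin-digested
#' lysates and the chlorine-blocked / ICG control dyes contribute zero
#' covalent signal; denatured lysates keep covalent binding at
#' `denature_scale` brightness.
#'
#' @param abundances 3D array from [sample_well_abundances()].
#' @param proteome the matching [proteome_profile][generate_proteome].
#' @param conditions a [labeling_conditions()] object.
#' @param params a [kinetic_params()] object.
#' @return An object of class `labeled_lysate`: `signal` (array
#'   `[row, col, species]` of bound fluorophore-equivalents), `species`,
#'   `conditions`, `params` and dye optical `metadata`
#'   (absorption 787 nm, emission 822 nm).
#' @export
label_lysate <- function(abundances, proteome,
                         conditions = labeling_conditions(),
                         params = kinetic_params()) {
  stopifnot(inherits(proteome, "proteome_profile"))
  sp <- proteome$species
  if (length(dim(abundances)) != 3L || dim(abundances)[3] != nrow(sp)) {
    stop("abundance grid does not match the proteome species list",
         call. = FALSE)
  }
  # expected bound dye per protein depends only on n_sites
  bound_by_sites <- vapply(sort(unique(sp$n_sites)), function(ns) {
    site_occupancy(ns, conditions$dye_protein_ratio, params, conditions,
                   mode = "time")$bound_mean
  }, numeric(1))
  names(bound_by_sites) <- as.character(sort(unique(sp$n_sites)))

  signal <- abundances
  for (j in seq_len(nrow(sp))) {
    b <- if (sp$pocket_intact[j]) bound_by_sites[[as.character(sp$n_sites[j])]]
         else 0
    signal[, , j] <- abundances[, , j] * b
  }
  if (conditions$denatured) signal <- signal * params$denature_scale

  structure(list(signal = signal, species = sp, conditions = conditions,
                 params = params,
                 metadata = list(abs_nm = 787, em_nm = 822)),
            class = "labeled_lysate")
}

#' @export
print.labeled_lysate <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("labeled_lysate: %d x %d cells x %d species\n",
              d[1], d[2], d[3]))
  cat(sprintf("  conditions: %g degC, %g min, dye:protein 1:%g, %s%s%s\n",
              x$conditions$temperature_c, x$conditions$time_min,
              x$conditions$dye_protein_ratio, x$conditions$dye_variant,
              if (x$conditions$digested) ", digested" else "",
              if (x$conditions$denatured) ", denatured" else ""))
  cat(sprintf("  total covalent signal %.4g (abs %d nm / em %d nm)\n",
              sum(x$signal), x$metadata$abs_nm, x$metadata$em_nm))
  invisible(x)
}

#' Temperature vs time sensitivity of the labeling signal
#'
#' Quantifies the normalized signal change per degree Celsius across a
#' temperature range (at fixed reaction time) and per minute across a
#' time range (at fixed temperature), for a protein with `n_sites`
#' reactive sites.  Under the default kinetics temperature is the
#' stronger lever, mirroring the staining-optimization observation.
#'
#' @param params a [kinetic_params()] object.
#' @param conditions baseline [labeling_conditions()]; its time anchors
#'   the temperature sweep and its temperature anchors the time sweep.
#' @param temp_range temperature endpoints in deg C.
#' @param time_range time endpoints in minutes.
#' @param n_sites reactive sites of the probe protein.
#' @return List with `per_degc`, `per_min` (normalized relative change
#'   per unit) and the endpoint signals.
#' @export
temperature_time_sensitivity <- function(params = kinetic_params(),
                                         conditions = labeling_conditions(),
                                         temp_range = c(23, 60),
                                         time_range = c(10, 120),
                                         n_sites = 2L) {
  sig <- function(temp, time) {
    site_occupancy(n_sites, conditions$dye_protein_ratio, params,
                   labeling_conditions(temperature_c = temp,
                                       time_min = time,
                                       dye_protein_ratio =
                                         conditions$dye_protein_ratio),
                   mode = "time")$bound_mean
  }
  fT <- c(sig(temp_range[1], conditions$time_min),
          sig(temp_range[2], conditions$time_min))
  ft <- c(sig(conditions$temperature_c, time_range[1]),
          sig(conditions$temperature_c, time_range[2]))
  list(per_degc = diff(fT) / mean(fT) / diff(temp_range),
       per_min = diff(ft) / mean(ft) / diff(time_range),
       signal_temp_endpoints = fT, signal_time_endpoints = ft)
}
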