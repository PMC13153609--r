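#' Build an experiment configuration
#'
#' One object holds every tunable of the forward simulation and the
#' margin analysis, with the standard workflow constants as defaults:
#' labeling at 60 deg C for 60 min at dye:protein 1:2, the 60–75 kDa
#' target-protein window, a 13-layer ladder from 100 to 15 kDa with
#' analysis fractions 3–13, 20/40-well arrays and the ratio cutoff 1.330.
#' Configs serialize to JSON and round-trip unchanged.
#'
#' @param phantom,proteome,labeling,kinetics,migration,imaging,margin
#'   named lists overriding individual defaults of each stage (see the
#'   stage constructors for meanings and units).
#' @param seed master seed; per-stage sub-seeds are derived from it by
#'   fixed arithmetic ([derive_seed()]), so adding a stage never
#'   reshuffles the randomness of earlier ones.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = list(), proteome = list(),
                              labeling = list(), kinetics = list(),
                              migration = list(), imaging = list(),
                              margin = list(), seed = 1L) {
  merge1 <- function(def, ovr) {
    bad <- setdiff(names(ovr), names(def))
    if (length(bad)) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    def[names(ovr)] <- ovr
    def
  }
  cfg <- list(
    phantom = merge1(list(geometry = "blob", array_size = 40L,
                          tumor_fraction = 0.25, rim_wells = 2L,
                          core_width_frac = 0.1, oversample = 1L),
                     phantom),
    proteome = merge1(list(n_common = 30L, n_signature = 5L, fc = 3,
                           mw_window = c(60, 75), noise_cv = 0.1,
                           base_abundance = 1), proteome),
    labeling = merge1(list(temperature_c = 60, time_min = 60,
                           dye_protein_ratio = 2, dye_variant = "cl_dye",
                           digested = FALSE, denatured = FALSE),
                      labeling),
    kinetics = merge1(list(k1_ref = 0.01, coop = 100, ea_like = 0.06,
                           denature_scale = 0.5), kinetics),
    migration = merge1(list(ladder_top = 100, ladder_bottom = 15,
                            n_layers = 13L, dispersion_sigma = 0.05,
                            fraction_window = c(3L, 13L)), migration),
    imaging = merge1(list(psf_sigma = 0.5, background_frac = 0.02,
                          read_noise_frac = 0.01, shot_noise = FALSE),
                     imaging),
    margin = merge1(list(layers_used = integer(0), threshold = 1.330,
                         min_component_wells = 3L, fill_holes = TRUE,
                         aggregation = "mean"), margin),
    seed = seed
  )
  .canonical_config(cfg)
}

# enforce storage types so that save -> load -> identical() holds
.canonical_config <- function(cfg) {
  int <- function(x) as.integer(x)
  num <- function(x) as.numeric(x)
  cfg$phantom$array_size <- int(cfg$phantom$array_size)
  cfg$phantom$rim_wells <- int(cfg$phantom$rim_wells)
  cfg$phantom$oversample <- int(cfg$phantom$oversample)
  cfg$phantom$tumor_fraction <- num(cfg$phantom$tumor_fraction)
  cfg$phantom$core_width_frac <- num(cfg$phantom$core_width_frac)
  cfg$proteome$n_common <- int(cfg$proteome$n_common)
  cfg$proteome$n_signature <- int(cfg$proteome$n_signature)
  for (f in c("fc", "noise_cv", "base_abundance")) {
    cfg$proteome[[f]] <- num(cfg$proteome[[f]])
  }
  cfg$proteome$mw_window <- num(cfg$proteome$mw_window)
  for (f in c("temperature_c", "time_min", "dye_protein_ratio")) {
    cfg$labeling[[f]] <- num(cfg$labeling[[f]])
  }
  for (f in c("k1_ref", "coop", "ea_like", "denature_scale")) {
    cfg$kinetics[[f]] <- num(cfg$kinetics[[f]])
  }
  for (f in c("ladder_top", "ladder_bottom", "dispersion_sigma")) {
    cfg$migration[[f]] <- num(cfg$migration[[f]])
  }
  cfg$migration$n_layers <- int(cfg$migration$n_layers)
  cfg$migration$fraction_window <- int(cfg$migration$fraction_window)
  for (f in c("psf_sigma", "background_frac", "read_noise_frac")) {
    cfg$imaging[[f]] <- num(cfg$imaging[[f]])
  }
  cfg$margin$layers_used <- int(cfg$margin$layers_used)
  cfg$margin$threshold <- num(cfg$margin$threshold)
  cfg$margin$min_component_wells <- int(cfg$margin$min_component_wells)
  cfg$seed <- int(cfg$seed)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config (seed", x$seed, ")\n")
  cat(sprintf("  phantom: %s, %dx%d wells (oversample %d), tumor %.2f\n",
              x$phantom$geometry, x$phantom$array_size,
              x$phantom$array_size, x$phantom$oversample,
              x$phantom$tumor_fraction))
  cat(sprintf("  proteome: %d common + %d signature (FC %.1f, %g-%g kDa)\n",
              x$proteome$n_common, x$proteome$n_signature, x$proteome$fc,
              x$proteome$mw_window[1], x$proteome$mw_window[2]))
  cat(sprintf("  labeling: %g degC, %g min, dye:protein 1:%g\n",
              x$labeling$temperature_c, x$labeling$time_min,
              x$labeling$dye_protein_ratio))
  cat(sprintf("  migration: %g->%g kDa, %d layers, fractions %d..%d\n",
              x$migration$ladder_top, x$migration$ladder_bottom,
              x$migration$n_layers, x$migration$fraction_window[1],
              x$migration$fraction_window[2]))
  cat(sprintf("  margin: cutoff %.3f, min component %d wells\n",
              x$margin$threshold, x$margin$min_component_wells))
  invisible(x)
}

#' Save / load an experiment configuration (JSON)
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return `config_load()` returns the `experiment_config`;
#'   `load(save(config)) == config` holds exactly.
#' @export
config_save <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$margin$layers_used <- as.integer(unlist(cfg$margin$layers_used))
  .canonical_config(cfg)
}

#' Run the forward simulation stages in memory
#'
#' phantom -> proteome -> per-well abundances -> covalent labeling ->
#' mass fractionation -> rasterization -> optical/noise degradation.
#' The imaging background and read-noise magnitudes are tied to the mean
#' tumor-well signal of the clean rasterized window layers
#' (`background_frac` and `read_noise_frac` of it respectively).
#'
#' @param config an [experiment_config()].
#' @return List with every stage product: `phantom`, `proteome`,
#'   `abundances`, `lysate`, `model`, `stack`, `images_clean`, `images`
#'   (degraded), `layers_used` (target-window layers inside the retained
#'   fraction window), `reference_mask` and the `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ph <- config$phantom
  phantom <- generate_phantom(ph$geometry, ph$array_size,
                              ph$tumor_fraction, rim_wells = ph$rim_wells,
                              core_width_frac = ph$core_width_frac,
                              oversample = ph$oversample,
                              seed = config$seed)
  pr <- config$proteome
  proteome <- generate_proteome(pr$n_common, pr$n_signature, pr$fc,
                                pr$mw_window, noise_cv = pr$noise_cv,
                                base_abundance = pr$base_abundance,
                                seed = config$seed)
  ab <- sample_well_abundances(phantom, proteome, seed = config$seed)
  conditions <- do.call(labeling_conditions, config$labeling)
  params <- do.call(kinetic_params, config$kinetics)
  lysate <- label_lysate(ab, proteome, conditions, params)
  mg <- config$migration
  model <- calibrate_migration(mg$ladder_top, mg$ladder_bottom,
                               mg$n_layers, mg$dispersion_sigma)
  stack <- fractionate(lysate, model, mg$fraction_window)
  clean <- rasterize(stack, ph$array_size)

  truth_tumor <- phantom$truth_mask
  base_sig <- mean(vapply(clean, function(im) {
    if (any(truth_tumor)) mean(im$values[truth_tumor])
    else mean(im$values)
  }, numeric(1)))
  im <- config$imaging
  degraded <- lapply(clean, degrade, psf_sigma = im$psf_sigma,
                     background = im$background_frac * base_sig,
                     read_noise_sd = im$read_noise_frac * base_sig,
                     shot_noise = im$shot_noise, seed = config$seed)

  layers_used <- if (length(config$margin$layers_used)) {
    config$margin$layers_used
  } else {
    intersect(layers_for_mass_window(model, pr$mw_window[1],
                                     pr$mw_window[2]),
              seq(mg$fraction_window[1], mg$fraction_window[2]))
  }
  list(phantom = phantom, proteome = proteome, abundances = ab,
       lysate = lysate, model = model, stack = stack,
       images_clean = clean, images = degraded,
       layers_used = as.integer(layers_used),
       reference_mask = phantom$truth_labels != 2L, config = config)
}

# per-layer cohort ratios: tumor/normal and normal/normal (the normal
# wells are split deterministically into two pseudo-sections)
.layer_cohort_ratios <- function(images, truth_labels) {
  tum <- truth_labels == 2L
  nrm <- truth_labels == 0L
  nidx <- which(nrm)
  a <- nidx[seq_along(nidx) %% 2L == 1L]
  b <- nidx[seq_along(nidx) %% 2L == 0L]
  do.call(rbind, lapply(images, function(imw) {
    v <- imw$values
    data.frame(layer = imw$layer_index,
               tumor_normal = mean(v[tum]) / mean(v[nrm]),
               normal_normal = mean(v[a]) / mean(v[b]))
  }))
}

#' Evaluate a simulated run against its ground truth
#'
#' Runs the margin analysis on the degraded well images: ratio map over
#' the target-window layers, margin call at the configured cutoff,
#' Dice similarity against the phantom truth mask, per-layer
#' tumor/normal vs normal/normal cohort ratios with their ROC and
#' rank-sum comparison.
#'
#' @param pipe a [run_pipeline()] result.
#' @return List with `rmap`, `call`, `similarity`, `layer_ratios`,
#'   `roc` and `group_test`.
#' @export
evaluate_pipeline <- function(pipe) {
  cfgm <- pipe$config$margin
  rmap <- ratio_map(pipe$images, pipe$layers_used, pipe$reference_mask,
                    aggregation = cfgm$aggregation)
  call <- call_margin(rmap, cfgm$threshold, cfgm$min_component_wells,
                      cfgm$fill_holes)
  sim <- similarity(call, pipe$phantom$truth_mask)
  lr <- .layer_cohort_ratios(pipe$images, pipe$phantom$truth_labels)
  roc <- if (all(is.finite(lr$tumor_normal)) && nrow(lr) >= 2L) {
    roc_cutoff(lr$tumor_normal, lr$normal_normal)
  } else NULL
  gt <- if (nrow(lr) >= 3L && all(is.finite(lr$tumor_normal)) &&
            all(is.finite(lr$normal_normal))) {
    compare_groups(lr$tumor_normal, lr$normal_normal)
  } else NULL
  list(rmap = rmap, call = call, similarity = sim, layer_ratios = lr,
       roc = roc, group_test = gt)
}

#' Simulate an experiment and write its outputs
#'
#' Runs [run_pipeline()] and serializes every stage product to
#' `out_dir`: label/mask grids (TSV + PNG), the windowed layer stack
#' (multi-page 16-bit TIFF + JSON sidecar), degraded well images (CSV)
#' and the config.  A manifest records the config hash, package/R
#' versions, per-stage seeds, wall time and an MD5 checksum for every
#' output file.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return An object of class `run_manifest` (invisibly also written as
#'   `manifest.json`); the in-memory pipeline is attached as
#'   `attr(, "pipeline")`.
#' @export
simulate_experiment <- function(config, out_dir) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipe <- run_pipeline(config)

  paths <- character(0)
  put <- function(p) { paths[[length(paths) + 1L]] <<- p; p }
  write_matrix_tsv(pipe$phantom$labels, put(file.path(out_dir,
                                                      "labels.tsv")))
  write_matrix_tsv(pipe$phantom$tumor_mask * 1L,
                   put(file.path(out_dir, "tumor_mask.tsv")))
  write_matrix_tsv(pipe$phantom$truth_labels,
                   put(file.path(out_dir, "truth_labels.tsv")))
  write_matrix_tsv(pipe$phantom$truth_mask * 1L,
                   put(file.path(out_dir, "truth_mask.tsv")))
  write_mask_png(pipe$phantom$labels, put(file.path(out_dir,
                                                    "labels.png")))
  write_stack_tiff(pipe$stack, put(file.path(out_dir, "stack.tif")))
  put(file.path(out_dir, "stack.tif.json"))
  for (imw in pipe$images) {
    write_wells_csv(imw, put(file.path(out_dir,
      sprintf("wells_layer_%02d.csv", imw$layer_index))))
  }
  config_save(config, put(file.path(out_dir, "config.json")))

  cfg_tmp <- tempfile(fileext = ".json")
  config_save(config, cfg_tmp)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("nirmargin")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    out_dir = normalizePath(out_dir),
    seed_ledger = list(
      master = config$seed,
      phantom = derive_seed(config$seed, "phantom"),
      proteome = derive_seed(config$seed, "proteome"),
      abundance = derive_seed(config$seed, "abundance"),
      imaging = derive_seed(config$seed, "imaging")),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) list(path = basename(p),
                                    md5 = unname(tools::md5sum(p)))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(manifest, class = "run_manifest", pipeline = pipe)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$out_dir, "\n")
  cat(sprintf("  %d files, config %s, %.2f s\n", length(x$files),
              substr(x$config_hash, 1, 8), x$wall_time_s))
  invisible(x)
}

#' Re-evaluate a stored run from its files
#'
#' Reads the stored config, degraded well images and truth grids from a
#' run directory (or `run_manifest`) and reruns the margin analysis.
#' The computation is deterministic, so repeated evaluation of the same
#' stored run reproduces the report bit-for-bit.
#'
#' @param manifest a [simulate_experiment()] result or a run directory.
#' @param report_file optional path for the JSON report (default
#'   `report.json` inside the run directory).
#' @return The evaluation list of [evaluate_pipeline()] plus `report`
#'   (what was written to JSON).
#' @export
evaluate_experiment <- function(manifest, report_file = NULL) {
  out_dir <- if (inherits(manifest, "run_manifest")) manifest$out_dir
             else manifest
  config <- config_load(file.path(out_dir, "config.json"))
  truth_labels <- read_matrix_tsv(file.path(out_dir, "truth_labels.tsv"))
  truth_mask <- truth_labels == 2L
  wf <- sort(list.files(out_dir, pattern = "^wells_layer_[0-9]+\\.csv$",
                        full.names = TRUE))
  if (!length(wf)) stop("no stored well images in ", out_dir,
                        call. = FALSE)
  images <- lapply(wf, function(p) {
    k <- as.integer(sub(".*wells_layer_([0-9]+)\\.csv$", "\\1", p))
    microwell_image(as.matrix(utils::read.csv(p, row.names = 1)), k)
  })
  mg <- config$migration
  model <- calibrate_migration(mg$ladder_top, mg$ladder_bottom,
                               mg$n_layers, mg$dispersion_sigma)
  layers_used <- if (length(config$margin$layers_used)) {
    config$margin$layers_used
  } else {
    intersect(layers_for_mass_window(model, config$proteome$mw_window[1],
                                     config$proteome$mw_window[2]),
              seq(mg$fraction_window[1], mg$fraction_window[2]))
  }
  pipe <- list(images = images, layers_used = as.integer(layers_used),
               reference_mask = truth_labels != 2L,
               phantom = list(truth_mask = truth_mask,
                              truth_labels = truth_labels),
               config = config)
  ev <- evaluate_pipeline(pipe)
  report <- list(
    threshold_used = ev$call$threshold_used,
    layers_used = pipe$layers_used,
    similarity = unclass(ev$similarity),
    roc = if (!is.null(ev$roc)) {
      ev$roc[c("auc", "cutoff", "sensitivity", "specificity")]
    },
    group_test = ev$group_test[c("u", "p_value")],
    layer_ratios = ev$layer_ratios)
  if (is.null(report_file)) report_file <- file.path(out_dir,
                                                     "report.json")
  jsonlite::write_json(report, report_file, auto_unbox = TRUE,
                       digits = NA)
  ev$report <- report
  ev
}

#' Batch margin study over seeds
#'
#' Runs the full simulate-then-call pipeline for a batch of phantoms
#' (one master seed each) and collects per-phantom similarity, the
#' pooled per-layer cohort ratios, the pooled ROC/Youden cutoff and the
#' pooled rank-sum comparison — the desk-scale analog of a multi-patient
#' margin-assessment study.
#'
#' @param seeds integer vector of master seeds (one phantom each).
#' @param config base [experiment_config()]; its seed field is replaced
#'   per phantom.
#' @return List with `per_seed` (data frame of seed, similarity and the
#'   phantom-level Youden cutoff), `median_similarity`, pooled
#'   `positive`/`negative` ratio vectors, `roc` and `group_test`.
#' @export
run_margin_study <- function(seeds = 1:20,
                             config = experiment_config()) {
  rows <- vector("list", length(seeds))
  pos <- neg <- numeric(0)
  for (i in seq_along(seeds)) {
    config$seed <- as.integer(seeds[i])
    pipe <- run_pipeline(config)
    ev <- evaluate_pipeline(pipe)
    rows[[i]] <- data.frame(seed = seeds[i],
                            similarity_pct = ev$similarity$similarity_pct,
                            cutoff = if (!is.null(ev$roc)) ev$roc$cutoff
                                     else NA_real_)
    pos <- c(pos, ev$layer_ratios$tumor_normal)
    neg <- c(neg, ev$layer_ratios$normal_normal)
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       median_similarity = stats::median(per_seed$similarity_pct),
       positive = pos, negative = neg,
       roc = roc_cutoff(pos, neg),
       group_test = compare_groups(pos, neg))
}
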