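# Shared fixtures: small configs keep the default suite fast.

tiny_config <- function(...) {
  experiment_config(
    phantom = list(array_size = 20L, geometry = "disc"),
    proteome = list(n_common = 12L, n_signature = 3L),
    ...
  )
}

# custom phantom whose labels are given directly (res x res)
flat_phantom <- function(res, labels) {
  ph <- generate_phantom("custom", array_size = res, oversample = 1L,
                         rim_wells = 0L, custom_mask = labels == 2L,
                         seed = 1L)
  ph$labels <- labels
  ph$tumor_mask <- labels == 2L
  ph$truth_labels <- labels
  ph$truth_mask <- labels == 2L
  ph
}

# uniform-species lysate built by hand for imaging/electrophoresis tests
toy_lysate <- function(res = 8L, mws = 70, values = 1) {
  ab <- array(values, c(res, res, length(mws)))
  prot <- generate_proteome(n_common = length(mws), n_signature = 0L,
                            seed = 1L)
  prot$species <- prot$species[seq_along(mws), , drop = FALSE]
  prot$species$mw_kda <- mws
  prot$species$n_sites <- 2L
  lys <- label_lysate(ab, prot)
  lys
}
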