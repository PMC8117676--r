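# Fixtures built in code: representative bilayer and nanodisc ground truths.

# Pristine tail-deuterated DMPC bilayer (head 9.0 A / 62 %, tails 27.2 A /
# 96 %, dry tail SLD 6.93).
ddmpc_model <- function(...) {
  base <- list(head_thickness = 9.0, head_coverage = 0.62,
               head_sld_material = 1.84,
               tail_thickness = 27.2, tail_coverage = 0.96,
               tail_sld_material = 6.93)
  do.call(slb_model, utils::modifyList(base, list(...)))
}

# Post-incubation bilayer whose dry tail SLD is the d/h mixture at a given
# exchanged (hydrogenous) fraction, with optional net lipid removal.
# Removal strips whole lipids, so both leaflet coverages drop by the same
# factor and the head/tail mean molecular areas stay consistent.
exchanged_model <- function(exchange = 0.404, removal = 0, ...) {
  keep <- (0.96 - removal) / 0.96
  ddmpc_model(tail_sld_material = 6.93 + exchange * (-0.39 - 6.93),
              tail_coverage = 0.96 * keep, head_coverage = 0.62 * keep, ...)
}

# ApoE3-scale nanodisc.
apoe3_disc <- function(...) {
  nanodisc_model(r_minor = 42.0, ellipticity = 1.4, d_belt = 11.0,
                 t_face = 9.0, core_length = 28, ...)
}

# A random physical stack for oracle-equivalence sweeps.
random_stack <- function() {
  n <- sample(1:7, 1)
  slabs <- lapply(seq_len(n), function(i)
    slab(runif(1, 5, 60), runif(1, -0.6, 7), roughness = runif(1, 0, 10)))
  layer_stack(runif(1, -0.6, 3), slabs, runif(1, 3, 7),
              backing_roughness = runif(1, 0, 10))
}

# Fast three-contrast recipe for fit-based tests (reduced q grid).
fast_nr_recipe <- function(truth, seed = 1, noise_rel = 0.03, n_q = 80) {
  nr_recipe(truth = truth, seed = seed, noise_rel = noise_rel, n_q = n_q)
}
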