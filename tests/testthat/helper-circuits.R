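# Small hand-built circuits used across the tests, built in code.

# One gene whose single active site is saturated by the basic TF, so its
# transcription rate is effectively r_max whenever any basic TF is present:
# its mRNA is then a simple birth-death process with birth r_max and death
# mrna_decay, the cleanest probe of the tau-leap scheme.
saturated_genotype <- function() {
  genotype(list(gene(
    kind = "regulatory",
    site_motif = rep(0L, 20), site_effect = c(1e9, rep(0, 19)),
    site_mismatch = rep(0L, 20),
    inherent_effect = 1, target_motif = 19L, lineage_id = 1L
  )))
}

# Minimal distinct genotypes for Wright-Fisher bookkeeping tests; their
# developmental behavior is irrelevant.
tag_genotype <- function(tag) {
  genotype(list(gene(
    kind = "regulatory",
    site_motif = rep(0L, 20), site_effect = rep(0, 20),
    site_mismatch = rep(0L, 20),
    inherent_effect = 1, target_motif = 19L, lineage_id = as.integer(tag)
  )))
}

# A minimal stand-in for a simulation record, for summary-layer tests.
fake_record <- function(treatment, environment, start_plastic, end_plastic,
                        noise) {
  structure(list(
    config = list(treatment = treatment, environment = environment),
    founder_assay = list(is_plastic = start_plastic),
    final_assay = list(is_plastic = end_plastic, sd_low = noise,
                       mean_low = 1000, mean_high = 1000, n_redevelop = 10)
  ), class = "simulation_record")
}

# A small random cell state for reference-vs-compiled comparisons.
random_state <- function(g) {
  cell_state(g,
             mrna = rpois(length(g), 5),
             protein = rpois(length(g), 150),
             basic_tf = rpois(1, 200),
             signal = rpois(1, 2e4))
}
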