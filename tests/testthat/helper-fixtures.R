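# Shared fixtures, built in code at test time.

# Small two-domain gene model: domains A (1-4) and B (6-9) with a gap at 5
# and 10.
tiny_model <- function(protein_aa = 10L) {
  gene_model("TEST", "T1", 3L * protein_aa, protein_aa,
             data.frame(name = c("A", "B"),
                        start_aa = c(1L, 6L),
                        end_aa = c(4L, 9L)))
}

# The 16 prioritized coding-variant CDS anchor positions of the packaged
# PAM table (splice variant anchored at its exonic base).
pam_coding_positions <- function() {
  v <- pam_variant_table()
  sort(v$anchor_bp[v$variant_class == "coding"])
}

# HWE genotypes + null phenotypes at a given size, as a list.
null_dataset <- function(n, mafs, seed, prevalence = 0.1) {
  spec <- simulation_spec(n_individuals = n, variant_mafs = mafs,
                          baseline_prevalence = prevalence, seed = seed)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, rep(0, length(mafs)), spec)
  list(g = g, y = y, spec = spec)
}
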