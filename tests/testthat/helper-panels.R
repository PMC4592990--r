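# Small simulated panels shared across test files.  Built in code at test
# time; sizes chosen to keep each file's runtime in seconds.
tiny_panel <- function(seed = 11, n_families = 2, lines_per_family = 60,
                       n_groups = 2, markers_per_group = 25,
                       spacing_cM = 2, heritability = 0.8,
                       founder_polymorphism_rate = 1, qtl = NULL) {
  if (is.null(qtl)) {
    extent <- (markers_per_group - 1) * spacing_cM
    qtl <- data.frame(chrom = as.character(c(1, min(2, n_groups))),
                      cM = extent * c(0.2, 0.45))
    for (f in seq_len(n_families)) qtl[[paste0("eff", f)]] <- c(1, 0.6)
  }
  simulate_panel(sim_config(
    n_families = n_families, lines_per_family = lines_per_family,
    n_groups = n_groups, markers_per_group = markers_per_group,
    spacing_cM = spacing_cM, qtl = qtl, heritability = heritability,
    founder_polymorphism_rate = founder_polymorphism_rate, seed = seed))
}

# hand-built panel wrapper around an explicit dosage matrix
manual_panel <- function(dosage, family, spacing_cM = 1) {
  map <- linkage_map(colnames(dosage), rep("1", ncol(dosage)),
                     seq(0, by = spacing_cM, length.out = ncol(dosage)),
                     sort = FALSE)
  genotype_panel(dosage, family, map)
}
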