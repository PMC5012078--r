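#!/usr/bin/env Rscript
# Stage 1: generate the synthetic raw inputs for the whole workflow.
#
# Writes, per species, a tabular BLAST hit table (outfmt-6 columns plus a
# species column) with a known fraction of hits passing the homology
# filters, and a small set of aligned coding-sequence variants per gene
# used downstream for consensus building and frame validation.

suppressPackageStartupMessages(library(eggspot))

seed <- 1
out_dir <- "results/01_inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

species <- c("eggspot_A", "eggspot_B", "blotch_A", "blotch_B")
seeds <- stage_seeds(seed, length(species) + 1L)

# hit tables: 200 hits per species, 40 % engineered to pass the filters
for (i in seq_along(species)) {
  hits <- simulate_hit_table(n_hits = 200, fraction_passing = 0.4,
                             seed = seeds[i], species = species[i])
  write_blast_hits(hits, file.path(out_dir, paste0("hits_", species[i],
                                                   ".tsv")))
}

# three aligned variants of one 120-codon gene (ancestor plus two
# descendants) standing in for per-species assemblies of an ortholog
sim <- simulate_codon_pair(120, omega = 0.5, subs_per_site = 0.1,
                           seed = seeds[length(seeds)],
                           gene_id = "fhl2_like")
variants <- c(ancestor = sim$ancestor,
              variant_1 = unname(sim$sequences[[1]]),
              variant_2 = unname(sim$sequences[[2]]))
write_fasta(variants, file.path(out_dir, "fhl2_like_variants.fasta"))

cat("wrote hit tables for", length(species), "species and",
    length(variants), "gene variants to", out_dir, "\n")
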