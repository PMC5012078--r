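#!/usr/bin/env Rscript
# Stage 2: homology filtering, presence selection, consensus and frame
# validation.
#
# Reads the per-species hit tables from stage 1, applies the strict
# filters (identity > 90 %, alignment length > 200 bp, bit score > 200),
# keeps genes recovered in every species, and builds a plurality-1.5
# consensus of the aligned gene variants with reading-frame validation.

suppressPackageStartupMessages(library(eggspot))

in_dir <- "results/01_inputs"
out_dir <- "results/02_orthologs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

species <- c("eggspot_A", "eggspot_B", "blotch_A", "blotch_B")
hits <- do.call(rbind, lapply(species, function(sp)
  read_blast_hits(file.path(in_dir, paste0("hits_", sp, ".tsv")),
                  species = sp)))

kept <- filter_hits(hits)
cat(sprintf("filters retained %d of %d hits (%.1f %%)\n",
            nrow(kept), nrow(hits), 100 * nrow(kept) / nrow(hits)))
write_blast_hits(kept, file.path(out_dir, "hits_filtered.tsv"))

shared <- select_genes_present_in_all(kept, required_species = species)
writeLines(shared, file.path(out_dir, "genes_present_in_all.txt"))
cat(sprintf("%d genes pass the filters in all %d species\n",
            length(shared), length(species)))

variants <- read_fasta(file.path(in_dir, "fhl2_like_variants.fasta"))
cons <- build_consensus(variants, plurality = 1.5)
frame <- validate_frame(c(variants, consensus = cons))
write_fasta(c(consensus = cons), file.path(out_dir, "fhl2_like_consensus.fasta"))
cat(sprintf("consensus length %d nt; %d ambiguous positions; frame check: %s\n",
            nchar(cons), lengths(regmatches(cons, gregexpr("n", cons))),
            if (attr(frame, "alignment_pass")) "pass" else "FAIL"))
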