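#!/usr/bin/env Rscript

# Stage 4: combined candidate detection (polarized and unpolarized modes).
#
# Applies the full candidate rule to every species of the stage-1 dataset:
# z >= 4 under at least 3 of the 6 Markov orders on the core genes, plus
# strand polarization of genomic occurrences at P < 0.001 (rank-sum test).
# Also records the unpolarized-mode calls (overrepresentation only) and
# aggregates candidates across species.

library(chiscan)

seed <- 20260925L
ds <- "results/dataset"
manifest <- read.delim(file.path(ds, "manifest.tsv"))
species <- c(manifest$species, "og_terra1", "og_terra2")

motifs <- hamming_neighborhood("GCTGGTGG", 1L, include_seed = TRUE)
all_calls <- list()
for (i in seq_along(species)) {
  sp <- species[i]
  genomes <- read_genome_fasta(file.path(ds, paste0(sp, ".fna")),
                               species_id = sp)
  core <- as.character(Biostrings::readBStringSet(
    file.path(ds, paste0(sp, "_core.fna"))))
  cfg <- detection_config(seed = seed + i)
  calls <- detect_candidates(core, genomes, motifs, cfg, species_id = sp)
  unpol <- calls
  unpol$candidate <- unpol$models_passed >= cfg$min_models
  unpol$mode <- "unpolarized"
  all_calls[[sp]] <- calls
  cand <- calls$motif[calls$candidate]
  cat(sprintf("  %-12s candidates: %s\n", sp,
              if (length(cand)) paste(cand, collapse = ", ") else "none"))
}

calls_df <- do.call(rbind, all_calls)
write_results_table(calls_df, "results/detection_calls.tsv")
saveRDS(all_calls, "results/detection_calls.rds")  # consumed by stages 5 and 7

agg <- aggregate_across_species(calls_df)
write_results_table(agg$per_motif, "results/candidates_per_motif.tsv")
write_results_table(agg$per_species, "results/candidates_per_species.tsv")
cat(sprintf("\n%.0f%% of species carry at least one candidate motif\n",
            100 * agg$fraction_species_with_candidate))
print(agg$per_motif)
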