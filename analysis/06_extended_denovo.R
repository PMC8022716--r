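#!/usr/bin/env Rscript

# Stage 6: extended two-mismatch search and de novo octamer discovery.
#
# First expands the search space to all octamers at Hamming distance exactly
# two from the five frequent candidate motifs (ball-excluded against their
# one-mismatch neighborhoods) and re-runs detection on one planted species.
# Then scores all 65,536 octamers de novo on the same core and looks for
# shared submotifs among the top hits.

library(chiscan)

seed <- 20260925L
ds <- "results/dataset"
five <- c("GCTGGTGG", "GCTGGCGG", "GCTGCTGG", "GGTGGTGG", "GCTGGAGG")

two <- expand_two_mismatch(five)
cat("two-mismatch expansion of the five motifs:", length(two$members),
    "non-redundant octamers\n")

sp <- "sp_entero1"
genomes <- read_genome_fasta(file.path(ds, paste0(sp, ".fna")),
                             species_id = sp)
core <- as.character(Biostrings::readBStringSet(
  file.path(ds, paste0(sp, "_core.fna"))))

## extended search: scores come from the de novo table (one batched bootstrap
## per order covers every octamer, including the 25 + two-mismatch sets)
cfg <- detection_config(seed = seed + 61)
full <- denovo_scan(core, cfg, full_table = TRUE)
ext <- full[full$motif %in% two$members & full$models_passed >= cfg$min_models, ]
cat("two-mismatch motifs overrepresented in >= 3 models:", nrow(ext), "\n")
if (nrow(ext)) {
  ext$polarity_p <- vapply(ext$motif, function(m) {
    polarity_test(find_occurrences(genomes[[1]], m))$p_value
  }, numeric(1))
  print(head(ext, 10))
}

dn <- full[full$models_passed >= cfg$min_models, ]
write_results_table(dn, "results/denovo_candidates.tsv")
cat("\nde novo candidates at default thresholds:", nrow(dn), "octamers\n")
cat("top 5 by models passed then mean z:\n")
print(head(dn[, c("motif", "observed", "models_passed", "mean_z")], 5))

if (nrow(dn) >= 2) {
  sub <- submotif_enrichment(dn$motif[seq_len(min(75, nrow(dn)))], k = 4,
                             seed = seed)
  cat("\nmost enriched 4-mers within the top de novo motifs:\n")
  print(head(sub, 5))
  write_results_table(sub, "results/denovo_submotifs.tsv")
}
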