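#!/usr/bin/env Rscript

# Stage 5: false-positive estimation on the outgroup and GC contrast.
#
# The og_terra* species carry no planted motif and stand in for a divergent
# outgroup clade expected to use different motifs; any candidate there is a
# false positive. Reports the rate under both denominators (the natural one
# is ambiguous) and compares genomic GC between species with and without
# candidates, the diagnostic for residual compositional bias.

library(chiscan)

ds <- "results/dataset"
all_calls <- readRDS("results/detection_calls.rds")
outgroup <- grep("^og_", names(all_calls), value = TRUE)

fpr <- estimate_fpr(all_calls, outgroup)
cat(sprintf("outgroup false positives: %.1f%% per species (n = %d), %.2f%% per test (n = %d)\n",
            100 * fpr$per_species_rate, fpr$n_outgroup,
            100 * fpr$per_test_rate, fpr$n_tests))

gc_tab <- do.call(rbind, lapply(names(all_calls), function(sp) {
  g <- read_genome_fasta(file.path(ds, paste0(sp, ".fna")), species_id = sp)
  data.frame(species = sp, gc = gc_content(g[[1]]$sequence),
             has_candidate = any(all_calls[[sp]]$candidate))
}))
write_results_table(gc_tab, "results/species_gc.tsv")

cmp <- gc_group_comparison(gc_tab)
if (cmp$skipped) {
  cat(cmp$message, "\n")
} else {
  cat(sprintf("genomic GC: %.1f%% with candidates vs %.1f%% without (P = %.3g)\n",
              100 * cmp$mean_with, 100 * cmp$mean_without, cmp$p_value))
}
cat(sprintf("searched motifs themselves average %.1f%% GC\n",
            100 * mean(gc_content(hamming_neighborhood("GCTGGTGG")$members))))
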