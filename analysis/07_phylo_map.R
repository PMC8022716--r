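#!/usr/bin/env Rscript

# Stage 7: map candidate-motif presence/absence onto the species tree.
#
# Joins the stage-4 calls onto the stage-1 species tree and reconstructs each
# motif's gain/loss history by parsimony. With the planted clade carrying the
# motif and the null/outgroup species lacking it, the most parsimonious
# reconstruction places the motif in the planted clade's ancestor.

library(chiscan)

ds <- "results/dataset"
all_calls <- readRDS("results/detection_calls.rds")
calls_df <- do.call(rbind, all_calls)

tree <- read_newick(file.path(ds, "species_tree.nwk"))
ann <- annotate_tree(tree, calls_df)

cat("tip annotations:\n")
print(ann$tips)
write_results_table(ann$tips, "results/tree_tip_annotations.tsv")

if (nrow(ann$ancestry)) {
  cat("\nper-motif parsimony reconstructions:\n")
  print(ann$ancestry)
  write_results_table(ann$ancestry, "results/tree_ancestry.tsv")
  ## explicit reconstruction for the primary motif
  covered <- tree$tip.label[tree$tip.label %in% calls_df$species]
  st <- setNames(ifelse(covered %in%
                          calls_df$species[calls_df$candidate &
                                             calls_df$motif == "GCTGGTGG"],
                        "present", "absent"), covered)
  if (length(covered) == length(tree$tip.label)) {
    anc <- fitch_presence_absence(tree, st)
    cat(sprintf("\nGCTGGTGG: %d gain/loss event(s); root state {%s}\n",
                anc$min_changes, paste(anc$root_states, collapse = ", ")))
  }
} else {
  cat("\nno candidate motifs to reconstruct\n")
}
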