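#!/usr/bin/env Rscript

# Stage 1: build the synthetic study dataset.
#
# Generates a small community of species: three with the E. coli Chi motif
# GCTGGTGG planted at one site per 5 kb and 90% leading-strand polarization
# (the densities and polarization reported for E. coli), two null species with
# the same background composition, and two GC-rich "outgroup" species used
# later for false-positive estimation. Writes genomes (FASTA), annotations
# (GFF3), core gene FASTA, a species tree and the planting truth tables under
# results/dataset/.

library(chiscan)

seed <- 20260925L
out_dir <- "results/dataset"

manifest <- make_toy_dataset(out_dir, config = list(
  planted_species = c("sp_entero1", "sp_entero2", "sp_entero3"),
  null_species = c("sp_null1", "sp_null2"),
  motif = "GCTGGTGG",
  length = 5e5,
  gc = 0.5,
  density = 0.2,            # one site per 5 kb on average
  polarization_level = 0.9
), seed = seed)

## two GC-rich outgroup species (no planting), emulating a divergent clade
for (i in 1:2) {
  sp <- sprintf("og_terra%d", i)
  sim <- simulate_species(sp, length = 5e5, gc = 0.62, motif = NULL,
                          seed = seed + 1000 + i)
  write_genome_fasta(list(sim$genome), file.path(out_dir, paste0(sp, ".fna")))
  Biostrings::writeXStringSet(Biostrings::BStringSet(sim$core),
                              file.path(out_dir, paste0(sp, "_core.fna")))
}

cat("dataset written to", out_dir, "\n")
print(manifest)
cat("\nSpecies sp_entero1..3 carry GCTGGTGG at ~1/5kb, 90% leading strand;\n")
cat("sp_null1..2 share the background; og_terra1..2 are GC-rich outgroups.\n")
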