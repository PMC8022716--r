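test_that("background genomes hit the target GC and are reproducible", {
  g <- simulate_genome(1e5, gc = 0.5, seed = 91)
  emp <- gc_content(g$sequence)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(emp - 0.5), 3 * se)
  g6 <- simulate_genome(1e5, gc = 0.65, seed = 92)
  expect_lt(abs(gc_content(g6$sequence) - 0.65), 3 * sqrt(0.65 * 0.35 / 1e5))
  expect_identical(simulate_genome(5000, gc = 0.4, seed = 7)$sequence,
                   simulate_genome(5000, gc = 0.4, seed = 7)$sequence)
  expect_error(simulate_genome(100, gc = 1.0), "strictly between")
  expect_error(simulate_genome(100, order = 2), "template")
  tmpl <- random_dna(20000, gc = 0.6)
  gt <- simulate_genome(5e4, order = 2, template = tmpl, seed = 93)
  expect_lt(abs(gc_content(gt$sequence) - 0.6), 0.03)
})

test_that("planting respects density, polarization, and truth recovery", {
  g <- simulate_genome(2e5, gc = 0.5, seed = 94)
  res <- plant_polarized_motifs(g, "GCTGGTGG", density = 0.2, ori = 1,
                                ter = 1e5, polarization_level = 1.0, seed = 95)
  truth <- res$truth
  n <- nrow(truth$planted)
  lambda <- 0.2 * 2e5 / 1000  # 40 expected
  expect_lt(abs(n - lambda), 3 * sqrt(lambda) + 1)
  ## full polarization: "+" only on the ori->ter arc, "-" only on the other
  on_arc1 <- truth$planted$position > 1 & truth$planted$position <= 1e5
  expect_true(all(truth$planted$strand[on_arc1] == "+"))
  expect_true(all(truth$planted$strand[!on_arc1] == "-"))
  ## every planted site recovered by the occurrence scanner
  occ <- find_occurrences(res$genome, "GCTGGTGG")$occurrences
  key <- paste(occ$position, occ$strand)
  expect_true(all(paste(truth$planted$position, truth$planted$strand) %in% key))
  ## genome length unchanged (overwrite, not insert)
  expect_equal(nchar(res$genome$sequence), 2e5)
  expect_error(plant_polarized_motifs(g, "GCTGGTGG", density = 0.2,
                                      ori = 5, ter = 5), "differ")
  expect_error(plant_polarized_motifs(g, "GCTGGTGG", density = 1e-6,
                                      ori = 1, ter = 1e5), "density too low")
})

test_that("half-polarized planting keeps strand placement near 50/50", {
  g <- simulate_genome(2e5, gc = 0.5, seed = 96)
  res <- plant_polarized_motifs(g, "GCTGGTGG", density = 0.3, ori = 1,
                                ter = 1e5, polarization_level = 0.5, seed = 97)
  frac_leading <- mean(res$truth$planted$leading)
  n <- nrow(res$truth$planted)
  expect_lt(abs(frac_leading - 0.5), 3 * sqrt(0.25 / n))
})

test_that("species trios hit their target nucleotide identities exactly", {
  trio <- simulate_species_trio(5, gene_length = 300,
                                identities = c(0.9, 0.8), seed = 98)
  expect_true(all(abs(trio$truth$identity_nt1 - 0.9) <= 0.02))
  expect_true(all(abs(trio$truth$identity_nt2 - 0.8) <= 0.02))
  ## proteins have no internal stops and the right length
  aa <- trio$species$neighbor1$proteins
  expect_false(any(grepl("\\*", aa)))
  expect_true(all(nchar(aa) == nchar(trio$species$focal$genes[1]) / 3 - 1))
  perfect <- simulate_species_trio(3, gene_length = 150,
                                   identities = c(1, 1), seed = 99)
  expect_identical(perfect$species$focal$genes, perfect$species$neighbor1$genes)
  expect_error(simulate_species_trio(0), "n_genes")
})

test_that("toy datasets are byte-identical under a fixed seed and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(planted_species = "sp_a", null_species = "sp_b", length = 5e4)
  make_toy_dataset(d1, cfg, seed = 100)
  make_toy_dataset(d2, cfg, seed = 100)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(all(c("sp_a.fna", "sp_a.gff3", "sp_a_core.fna", "sp_a_truth.tsv",
                    "sp_b.fna", "species_tree.nwk", "manifest.tsv") %in%
                    list.files(d1)))
  ## files round-trip through the package readers
  g <- read_genome_fasta(file.path(d1, "sp_a.fna"), species_id = "sp_a")
  feats <- read_gene_features(file.path(d1, "sp_a.gff3"))
  core <- extract_gene_sequences(g, feats)
  on_disk <- Biostrings::readBStringSet(file.path(d1, "sp_a_core.fna"))
  expect_equal(unname(core), unname(as.character(on_disk)))
  tree <- read_newick(file.path(d1, "species_tree.nwk"))
  expect_setequal(tree$tip.label, c("sp_a", "sp_b"))
  expect_error(make_toy_dataset(withr::local_tempdir(),
                                list(planted_species = character(),
                                     null_species = character())),
               "zero species")
  expect_error(make_toy_dataset(withr::local_tempdir(), list(bogus = 1)),
               "invalid config key")
})
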