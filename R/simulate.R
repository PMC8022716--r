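#' Simulate a background genome
#'
#' Either a parametric order-0 background with a target GC content
#' (`p(G) = p(C) = gc/2`) or, when `template` is supplied, an order-`m`
#' Markov background fitted to the template sequence.
#'
#' @param length Genome length (`>= 1`).
#' @param gc Target GC fraction in `(0, 1)` (parametric mode).
#' @param order Markov order; `> 0` requires a `template`.
#' @param template Optional template sequence to fit an order-`order` model.
#' @param seed Integer seed.
#' @param species_id,replicon_id Labels for the record.
#' @param circular Logical (default `TRUE`).
#' @return A [genome_record()].
#' @export
simulate_genome <- function(length, gc = 0.5, order = 0L, template = NULL,
                            seed = 1L, species_id = "synthetic",
                            replicon_id = "chr", circular = TRUE) {
  stopifnot(length >= 1L)
  if (is.null(template)) {
    if (order > 0L) stop("order > 0 requires a template sequence")
    if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
      stop("gc must lie strictly between 0 and 1")
    }
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    withr_seed(seed)
    seq <- cpp_sim_markov(0L, numeric(0), cumsum(probs), 1L, cumsum(probs),
                          as.integer(length))
  } else {
    model <- fit_markov(template, order)
    seq <- simulate_from_model(model, length, seed = seed)
  }
  genome_record(species_id, replicon_id, seq, circular = circular)
}

#' Plant polarized motif occurrences into a genome
#'
#' Draws a Poisson number of non-overlapping positions
#' (`Poisson(length / 1000 * density)`, uniform over the genome) and writes
#' the motif over the background at each. With probability
#' `polarization_level` the motif goes on the *leading* strand of its
#' replichore -- the forward strand on the ori -> ter arc, the reverse
#' complement elsewhere -- otherwise on the lagging strand. Planting
#' overwrites in place, so genome length and ori/ter geometry are untouched.
#'
#' @param genome A [genome_record()].
#' @param motif ACGT word.
#' @param density Target occurrences per kb (e.g. 0.2 = one per 5 kb).
#' @param ori,ter Origin and terminus positions (1-based, distinct).
#' @param polarization_level Probability of leading-strand placement, in
#'   `[0.5, 1]`; 0.5 is unpolarized.
#' @param seed Integer seed.
#' @return List with `genome` (modified record) and `truth` (class
#'   `synthetic_truth`): `planted` (`position`, `strand`, `leading`),
#'   `background` (chance occurrences of the motif not planted), `ori`,
#'   `ter`, `target_density`, `polarization_level`.
#' @export
plant_polarized_motifs <- function(genome, motif, density, ori, ter,
                                   polarization_level = 0.9, seed = 1L) {
  stopifnot(inherits(genome, "genome_record"))
  check_acgt(motif, "motif")
  if (ori == ter) stop("ori and ter must differ")
  stopifnot(polarization_level >= 0.5, polarization_level <= 1)
  L <- nchar(genome$sequence)
  h <- nchar(motif)
  if (density * L / 1000 < 1) stop("density too low: fewer than one expected site")
  withr_seed(seed)
  n <- rpois(1L, L / 1000 * density)
  positions <- integer(0)
  tries <- 0L
  while (length(positions) < n && tries < 50L * n + 100L) {
    p <- sample.int(L - h + 1L, 1L)
    if (!any(abs(positions - p) < h)) positions <- c(positions, p)
    tries <- tries + 1L
  }
  if (length(positions) < n) {
    stop("could not place ", n, " non-overlapping sites at density ", density)
  }
  positions <- sort(positions)
  on_arc1 <- if (ori < ter) positions > ori & positions <= ter else
    positions > ori | positions <= ter
  leading_strand <- ifelse(on_arc1, "+", "-")
  lagging_strand <- ifelse(on_arc1, "-", "+")
  use_leading <- runif(length(positions)) < polarization_level
  strand <- ifelse(use_leading, leading_strand, lagging_strand)
  seq <- genome$sequence
  rc <- reverse_complement(motif)
  for (i in seq_along(positions)) {
    word <- if (strand[i] == "+") motif else rc
    substr(seq, positions[i], positions[i] + h - 1L) <- word
  }
  genome$sequence <- seq
  occ <- find_occurrences(genome, motif)$occurrences
  planted_key <- paste(positions, strand)
  occ_key <- paste(occ$position, occ$strand)
  background <- occ[!occ_key %in% planted_key, , drop = FALSE]
  rownames(background) <- NULL
  truth <- structure(list(
    motif = motif,
    planted = data.frame(position = positions, strand = strand,
                         leading = use_leading, stringsAsFactors = FALSE),
    background = background, ori = ori, ter = ter, target_density = density,
    polarization_level = polarization_level), class = "synthetic_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s: %d planted (%.0f%% leading), %d background, ori %d, ter %d\n",
              x$motif, nrow(x$planted), 100 * mean(x$planted$leading),
              nrow(x$background), x$ori, x$ter))
  invisible(x)
}

#' Tile synthetic gene features along a replicon
#'
#' Places genes of fixed length at a fixed spacing, each on a random strand,
#' producing the feature table a real annotation would supply.
#'
#' @param replicon_id Replicon label for the features.
#' @param length Replicon length.
#' @param gene_length Gene length in nt (default 900).
#' @param spacing Distance between successive gene starts (default 3000).
#' @param seed Integer seed for the strand draws.
#' @return Feature `data.frame` as from [read_gene_features()].
#' @export
tile_gene_features <- function(replicon_id, length, gene_length = 900L,
                               spacing = 3000L, seed = 1L) {
  starts <- seq(1L, length - gene_length, by = spacing)
  withr_seed(seed)
  strand <- sample(c("+", "-"), length(starts), replace = TRUE)
  data.frame(gene_id = sprintf("gene%04d", seq_along(starts)),
             replicon_id = replicon_id, start = starts,
             end = starts + gene_length - 1L, strand = strand,
             stringsAsFactors = FALSE)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      c3 <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!c3 %in% STOP_CODONS) break
    }
    codons[i] <- c3
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

translate_cds <- function(nt) {
  ## drop the terminal stop; sequences are internal-stop-free by construction
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, nchar(nt) - 3L)), no.init.codon = TRUE))
  aa
}

## mutate exactly k sites (distinct positions, never creating internal stops,
## never touching the start/stop codons); returns the mutated sequence
mutate_cds <- function(nt, k, max_tries = 10000L) {
  L <- nchar(nt)
  mutable <- 4:(L - 3L)
  if (k > length(mutable)) stop("target identity unattainable for gene length ", L)
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  mutated <- integer(0)
  tries <- 0L
  while (length(mutated) < k && tries < max_tries) {
    tries <- tries + 1L
    p <- sample(mutable, 1L)
    if (p %in% mutated) next
    old <- chars[p]
    new <- sample(setdiff(DNA_BASES, old), 1L)
    chars[p] <- new
    cod_start <- p - ((p - 1L) %% 3L)
    codon <- paste(chars[cod_start:(cod_start + 2L)], collapse = "")
    if (codon %in% STOP_CODONS) {
      chars[p] <- old
      next
    }
    mutated <- c(mutated, p)
  }
  if (length(mutated) < k) stop("could not reach target identity after retries")
  paste(chars, collapse = "")
}

#' Simulate a trio of related species for core-genome tests
#'
#' Simulates `n_genes` ancestor coding sequences (ATG + stop-free codons +
#' TAA), then derives two neighbor species by planting point mutations down
#' to the target nucleotide identities (mutations are placed without regard
#' to codon degeneracy; internal stops are rejected and redrawn). The focal
#' species keeps the ancestral sequences, so the focal-neighbor nucleotide
#' identity equals the target exactly; the realized protein identities are
#' recorded per gene in the truth table.
#'
#' @param n_genes Number of genes (`>= 1`).
#' @param gene_length Gene length in nt (rounded up to full codons,
#'   `ATG`/`TAA` included).
#' @param identities Length-2 numeric vector in `(0, 1]`: target nucleotide
#'   identity of each derived neighbor to the focal species.
#' @param seed Integer seed.
#' @return List with `species` (named list `focal`, `neighbor1`, `neighbor2`,
#'   each holding `genes` and `proteins` named vectors) and `truth`
#'   (`data.frame`: `gene_id`, `identity_nt1`, `identity_nt2`,
#'   `identity_aa1`, `identity_aa2`).
#' @export
simulate_species_trio <- function(n_genes, gene_length = 900L,
                                  identities = c(0.9, 0.9), seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  stopifnot(length(identities) == 2L, all(identities > 0), all(identities <= 1))
  n_codons <- max(1L, ceiling(gene_length / 3L) - 2L)
  withr_seed(seed)
  ids <- sprintf("gene%04d", seq_len(n_genes))
  anc <- setNames(vapply(ids, function(i) random_cds(n_codons), character(1)), ids)
  derive <- function(identity) {
    setNames(vapply(ids, function(g) {
      L <- nchar(anc[[g]])
      k <- round((1 - identity) * L)
      if (k == 0L) anc[[g]] else mutate_cds(anc[[g]], k)
    }, character(1)), ids)
  }
  nb1 <- derive(identities[1L])
  nb2 <- derive(identities[2L])
  aa_identity <- function(a, b) {
    x <- strsplit(a, "", fixed = TRUE)[[1]]
    y <- strsplit(b, "", fixed = TRUE)[[1]]
    mean(x == y)
  }
  species <- list(
    focal = list(genes = anc, proteins = vapply(anc, translate_cds, character(1))),
    neighbor1 = list(genes = nb1, proteins = vapply(nb1, translate_cds, character(1))),
    neighbor2 = list(genes = nb2, proteins = vapply(nb2, translate_cds, character(1))))
  nt_identity <- function(a, b) {
    mean(strsplit(a, "", fixed = TRUE)[[1]] == strsplit(b, "", fixed = TRUE)[[1]])
  }
  truth <- data.frame(
    gene_id = ids,
    identity_nt1 = vapply(ids, function(g) nt_identity(anc[[g]], nb1[[g]]), numeric(1)),
    identity_nt2 = vapply(ids, function(g) nt_identity(anc[[g]], nb2[[g]]), numeric(1)),
    identity_aa1 = vapply(ids, function(g) {
      aa_identity(species$focal$proteins[[g]], species$neighbor1$proteins[[g]])
    }, numeric(1)),
    identity_aa2 = vapply(ids, function(g) {
      aa_identity(species$focal$proteins[[g]], species$neighbor2$proteins[[g]])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(species = species, truth = truth)
}

#' Simulate one annotated species with an optional planted motif
#'
#' Convenience wrapper joining [simulate_genome()], [tile_gene_features()],
#' [plant_polarized_motifs()] and [extract_gene_sequences()] into the
#' per-species bundle the detection pipeline consumes.
#'
#' @param species_id Label.
#' @param length Genome length.
#' @param gc Background GC fraction.
#' @param motif Motif to plant, or `NULL` for a null species.
#' @param density Planted occurrences per kb.
#' @param polarization_level Leading-strand probability.
#' @param gene_length,spacing Gene tiling parameters.
#' @param seed Integer seed.
#' @return List with `genome`, `features`, `core` (named gene-sequence
#'   vector), and `truth` (`NULL` for null species).
#' @export
simulate_species <- function(species_id, length = 1e6, gc = 0.5, motif = NULL,
                             density = 0.2, polarization_level = 0.9,
                             gene_length = 900L, spacing = 3000L, seed = 1L) {
  genome <- simulate_genome(length, gc = gc, seed = seed,
                            species_id = species_id,
                            replicon_id = paste0(species_id, "_chr"))
  truth <- NULL
  if (!is.null(motif)) {
    planted <- plant_polarized_motifs(genome, motif, density = density,
                                      ori = 1L, ter = floor(length / 2),
                                      polarization_level = polarization_level,
                                      seed = seed + 1L)
    genome <- planted$genome
    truth <- planted$truth
  }
  features <- tile_gene_features(genome$replicon_id, length,
                                 gene_length = gene_length, spacing = spacing,
                                 seed = seed + 2L)
  core <- extract_gene_sequences(list(genome), features)
  list(genome = genome, features = features, core = core, truth = truth)
}

#' Write a complete toy dataset to disk
#'
#' Emits, for each configured species, a genome FASTA and GFF3 plus a core
#' gene FASTA, and dataset-level truth TSV and Newick tree, so every pipeline
#' stage can be run end-to-end from files. Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param config List with entries `planted_species` (character vector),
#'   `null_species` (character vector), `motif`, `length`, `gc`, `density`,
#'   `polarization_level`. Unknown keys are an error.
#' @param seed Integer seed.
#' @return Invisibly, the manifest `data.frame` (species, files, planted).
#' @export
make_toy_dataset <- function(out_dir, config = list(), seed = 1L) {
  defaults <- list(planted_species = c("sp_chi1", "sp_chi2"),
                   null_species = "sp_null1", motif = "GCTGGTGG",
                   length = 2e5, gc = 0.5, density = 0.2,
                   polarization_level = 0.9)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("invalid config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  all_sp <- c(cfg$planted_species, cfg$null_species)
  if (!length(all_sp)) stop("config lists zero species")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_along(all_sp)) {
    sp <- all_sp[i]
    planted <- sp %in% cfg$planted_species
    sim <- simulate_species(sp, length = cfg$length, gc = cfg$gc,
                            motif = if (planted) cfg$motif else NULL,
                            density = cfg$density,
                            polarization_level = cfg$polarization_level,
                            seed = seed + 10L * i)
    write_genome_fasta(list(sim$genome), file.path(out_dir, paste0(sp, ".fna")))
    gff <- sprintf("%s\tchiscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                   sim$features$replicon_id, sim$features$start,
                   sim$features$end, sim$features$strand, sim$features$gene_id)
    writeLines(c("##gff-version 3", gff), file.path(out_dir, paste0(sp, ".gff3")))
    core_set <- Biostrings::BStringSet(sim$core)
    Biostrings::writeXStringSet(core_set, file.path(out_dir, paste0(sp, "_core.fna")))
    if (planted) {
      write_results_table(cbind(species = sp, sim$truth$planted),
                          file.path(out_dir, paste0(sp, "_truth.tsv")))
    }
    manifest[[i]] <- data.frame(species = sp, planted = planted,
                                genome = paste0(sp, ".fna"),
                                features = paste0(sp, ".gff3"),
                                core = paste0(sp, "_core.fna"),
                                stringsAsFactors = FALSE)
  }
  ## a caterpillar tree over the species, planted clade first
  tip <- function(x) paste0(x, ":1")
  newick <- paste0("(", tip(all_sp[1L]), ",")
  if (length(all_sp) >= 2L) {
    rest <- all_sp[-1L]
    inner <- tip(rest[length(rest)])
    for (s in rev(rest[-length(rest)])) {
      inner <- paste0("(", tip(s), ",", inner, "):1")
    }
    newick <- paste0(newick, inner, ");")
  } else {
    newick <- paste0(newick, ");")
  }
  writeLines(newick, file.path(out_dir, "species_tree.nwk"))
  out <- do.call(rbind, manifest)
  write_results_table(out, file.path(out_dir, "manifest.tsv"))
  invisible(out)
}
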