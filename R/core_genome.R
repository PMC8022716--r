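#' Marker alignment constructor
#'
#' A concatenated marker alignment: one aligned row (protein alphabet plus
#' `-`) per species, all rows equal length.
#'
#' @param species_ids Character vector of unique species labels (`>= 2`).
#' @param rows Character vector of aligned sequences, same length as
#'   `species_ids`.
#' @return An object of class `marker_alignment`.
#' @export
marker_alignment <- function(species_ids, rows) {
  stopifnot(length(species_ids) == length(rows), length(species_ids) >= 2L,
            !anyDuplicated(species_ids))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  structure(list(species_ids = species_ids, rows = toupper(rows)),
            class = "marker_alignment")
}

#' Read an aligned FASTA as a marker alignment
#'
#' @param path Aligned FASTA (protein or nucleotide, `-` gaps).
#' @return A [marker_alignment()].
#' @export
read_marker_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  marker_alignment(sub("\\s.*$", "", names(set)), as.character(set))
}

#' Drop gap-rich alignment columns
#'
#' Retains exactly the columns whose gap fraction is `<= max_gap_fraction`,
#' preserving row order. A coarse, deterministic stand-in for heuristic
#' alignment trimmers: only the distance *ranking* between species feeds the
#' downstream pipeline, so column-level filtering suffices.
#'
#' @param alignment A [marker_alignment()].
#' @param max_gap_fraction Fraction in `[0, 1]` (default 0.5).
#' @return Filtered [marker_alignment()]; zero-length rows (with a warning)
#'   if every column is gap-rich.
#' @export
filter_alignment_columns <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(inherits(alignment, "marker_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  mat <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) warning("all alignment columns removed by the gap filter")
  rows <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  if (!length(rows)) rows <- rep("", length(alignment$species_ids))
  out <- alignment
  out$rows <- unname(rows)
  out
}

#' Pairwise p-distance matrix from a marker alignment
#'
#' Entry `(i, j)` is the proportion of mismatches among columns where neither
#' row has a gap. Pairs with zero comparable columns get distance 1 and a
#' warning.
#'
#' @param alignment A [marker_alignment()].
#' @return An object of class `distance_matrix`: list with `species_ids` and
#'   `values` (symmetric matrix, zero diagonal).
#' @export
pairwise_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "marker_alignment"))
  n <- length(alignment$species_ids)
  if (n < 2L) stop("need at least 2 species")
  mat <- do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(alignment$species_ids,
                                       alignment$species_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        warning("no comparable columns between ", alignment$species_ids[i],
                " and ", alignment$species_ids[j], "; distance set to 1")
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
      }
    }
  }
  distance_matrix(alignment$species_ids, d)
}

#' Distance matrix constructor
#'
#' @param species_ids Character vector of labels.
#' @param values Symmetric nonnegative matrix with zero diagonal.
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(species_ids, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(species_ids),
            ncol(values) == length(species_ids))
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be exactly 0")
  if (any(values < 0)) stop("distances must be nonnegative")
  dimnames(values) <- list(species_ids, species_ids)
  structure(list(species_ids = species_ids, values = values),
            class = "distance_matrix")
}

#' Read a TSV distance matrix
#'
#' Square TSV with species ids as both header and first column.
#'
#' @param path TSV file.
#' @return A [distance_matrix()].
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  distance_matrix(rownames(df), as.matrix(df))
}

#' The k phylogenetically closest species to a query
#'
#' @param matrix A [distance_matrix()].
#' @param species Query species id.
#' @param k Number of neighbors.
#' @return Character vector of the `k` species with smallest distance to the
#'   query, ascending; ties broken by lexicographic label.
#' @export
closest_relatives <- function(matrix, species, k = 2L) {
  stopifnot(inherits(matrix, "distance_matrix"), k >= 1L)
  if (!species %in% matrix$species_ids) stop("unknown species: ", species)
  others <- setdiff(matrix$species_ids, species)
  if (k > length(others)) stop("k = ", k, " exceeds available species")
  d <- matrix$values[species, others]
  others[order(d, others)][seq_len(k)]
}

## global Needleman-Wunsch identity: matches / alignment length (gapped
## columns count in the denominator); match +1, mismatch -1, gap open -5,
## gap extend -1 by default
global_identity <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 1) {
  alph <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]])
  mat <- matrix(mismatch, length(alph), length(alph),
                dimnames = list(alph, alph))
  diag(mat) <- match
  al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "", fixed = TRUE)[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "", fixed = TRUE)[[1]]
  sum(pa == ps & pa != "-") / length(pa)
}

#' Best reciprocal hits between two proteomes
#'
#' For each sequence its best hit in the other proteome is the sequence
#' maximizing global-alignment identity (Needleman-Wunsch; identity =
#' matches / alignment length, gap columns included in the denominator;
#' best-hit ties broken by lexicographic id). A pair is reported iff the two
#' sequences are each other's best hit, their identity reaches
#' `min_identity`, and `min(len) / max(len) >= min_length_conservation`.
#'
#' @param proteome_a,proteome_b Named character vectors, id -> sequence.
#' @param min_identity Identity threshold (default 0.70).
#' @param min_length_conservation Length-ratio threshold (default 0.80).
#' @return `data.frame` with columns `id_a`, `id_b`, `identity`.
#' @export
best_reciprocal_hits <- function(proteome_a, proteome_b, min_identity = 0.70,
                                 min_length_conservation = 0.80) {
  if (!length(proteome_a) || !length(proteome_b)) stop("empty proteome")
  ids_a <- sort(names(proteome_a))
  ids_b <- sort(names(proteome_b))
  idm <- matrix(NA_real_, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
  for (i in ids_a) {
    for (j in ids_b) {
      idm[i, j] <- global_identity(proteome_a[[i]], proteome_b[[j]])
    }
  }
  best_a <- ids_b[apply(idm, 1L, which.max)]           # ties -> first, i.e. lexicographic
  best_b <- ids_a[apply(idm, 2L, which.max)]
  names(best_a) <- ids_a
  names(best_b) <- ids_b
  pairs <- list()
  for (i in ids_a) {
    j <- best_a[[i]]
    if (best_b[[j]] != i) next
    ident <- idm[i, j]
    la <- nchar(proteome_a[[i]])
    lb <- nchar(proteome_b[[j]])
    if (ident < min_identity) next
    if (min(la, lb) / max(la, lb) < min_length_conservation) next
    pairs[[length(pairs) + 1L]] <- data.frame(id_a = i, id_b = j,
                                              identity = ident,
                                              stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Build the pseudo core genome of a species
#'
#' Most bacterial species have too few sequenced strains to define a true
#' core genome, so the conserved gene set is approximated by the genes shared
#' (as best reciprocal hits) with the species' two phylogenetically closest
#' relatives: a gene is core iff it has a BRH partner in *both* neighbors.
#'
#' @param species Species id.
#' @param gene_seqs Named character vector, gene id -> coding-strand
#'   nucleotide sequence.
#' @param proteome Named character vector, gene id -> protein sequence (same
#'   ids as `gene_seqs`).
#' @param neighbor_proteomes List of two named character vectors (the two
#'   closest species' proteomes), optionally named by neighbor id.
#' @param min_identity,min_length_conservation BRH thresholds, see
#'   [best_reciprocal_hits()].
#' @return An object of class `core_genome`: `species_id`, `neighbor_ids`,
#'   `genes` (named nucleotide vector), `hits` (per-gene neighbor hit table).
#' @export
build_pseudo_core <- function(species, gene_seqs, proteome, neighbor_proteomes,
                              min_identity = 0.70,
                              min_length_conservation = 0.80) {
  stopifnot(length(neighbor_proteomes) == 2L)
  if (!setequal(names(gene_seqs), names(proteome))) {
    stop("gene ids differ between gene_seqs and proteome")
  }
  nb_ids <- names(neighbor_proteomes) %||% c("neighbor1", "neighbor2")
  brh <- lapply(neighbor_proteomes, function(nb) {
    best_reciprocal_hits(proteome, nb, min_identity, min_length_conservation)
  })
  core_ids <- sort(intersect(brh[[1L]]$id_a, brh[[2L]]$id_a))
  if (!length(core_ids)) {
    warning("empty pseudo core genome for species ", species)
  }
  hits <- data.frame(
    gene_id = core_ids,
    length = nchar(gene_seqs[core_ids]),
    neighbor1_hit = brh[[1L]]$id_b[match(core_ids, brh[[1L]]$id_a)],
    neighbor2_hit = brh[[2L]]$id_b[match(core_ids, brh[[2L]]$id_a)],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(species_id = species, neighbor_ids = nb_ids,
                 genes = gene_seqs[core_ids], hits = hits),
            class = "core_genome")
}

#' @export
print.core_genome <- function(x, ...) {
  cat(sprintf("<core_genome> %s (neighbors %s, %s): %d genes, %s nt\n",
              x$species_id, x$neighbor_ids[1L], x$neighbor_ids[2L],
              length(x$genes),
              format(sum(nchar(x$genes)), big.mark = ",")))
  invisible(x)
}
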