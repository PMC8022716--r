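#' Hamming neighborhood of a seed motif
#'
#' All words over `{A,C,G,T}` within a given Hamming distance of the seed.
#' With `radius = 1` and the seed included, an octamer yields
#' `1 + 8 * 3 = 25` motifs -- the classical one-mismatch neighborhood of the
#' *E. coli* Chi site used to seed cross-species searches.
#'
#' @param seed Uppercase ACGT word.
#' @param radius Maximum Hamming distance (non-negative integer).
#' @param include_seed If `FALSE`, only words at distance `>= 1` are returned.
#' @return A `motif_set`: list with `seeds`, `members` (lexicographically
#'   sorted character vector) and `generation_rule`.
#' @export
#' @examples
#' length(hamming_neighborhood("GCTGGTGG", 1)$members)  # 25
hamming_neighborhood <- function(seed, radius = 1L, include_seed = TRUE) {
  check_acgt(seed, "seed")
  stopifnot(radius >= 0L)
  h <- nchar(seed)
  members <- seed
  frontier <- seed
  r <- 0L
  while (r < radius) {
    nxt <- unlist(lapply(frontier, function(w) {
      chars <- strsplit(w, "", fixed = TRUE)[[1]]
      unlist(lapply(seq_len(h), function(i) {
        vapply(setdiff(DNA_BASES, chars[i]), function(b) {
          chars2 <- chars; chars2[i] <- b
          paste(chars2, collapse = "")
        }, character(1))
      }))
    }))
    frontier <- setdiff(nxt, members)
    members <- union(members, frontier)
    r <- r + 1L
  }
  if (!include_seed) members <- setdiff(members, seed)
  structure(list(seeds = seed, members = sort(members),
                 generation_rule = sprintf("hamming<=%d of %s%s", radius, seed,
                                           if (include_seed) "" else " (seed excluded)")),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motifs [%s]\n", length(x$members),
              x$generation_rule))
  invisible(x)
}

hamming_distance <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## all words of length h over ACGT, lexicographic (A<C<G<T); h <= 8
all_words <- function(h) {
  idx <- 0:(4^h - 1)
  decode_word(idx, h)
}

## 2-bit codes: A=0, C=1, G=2, T=3, word read left-to-right, first char most
## significant -- numeric order equals lexicographic order
encode_word <- function(words) {
  h <- nchar(words[1L])
  m <- matrix(match(unlist(strsplit(words, "", fixed = TRUE)), DNA_BASES) - 1L,
              ncol = h, byrow = TRUE)
  as.vector(m %*% 4^((h - 1):0))
}

decode_word <- function(codes, h) {
  m <- matrix(0L, nrow = length(codes), ncol = h)
  x <- codes
  for (j in h:1) {
    m[, j] <- x %% 4
    x <- x %/% 4
  }
  apply(m, 1L, function(r) paste(DNA_BASES[r + 1L], collapse = ""))
}

#' Two-mismatch expansion of a motif set
#'
#' Takes the union over seeds of all words at Hamming distance exactly 2,
#' deduplicates, then removes every word within distance `<= 1` of *any* seed
#' (the "ball exclusion" rule) and every word listed in `exclude`. This is the
#' expansion used to extend a one-mismatch candidate search to more divergent
#' sequences without re-testing anything already in a seed's immediate
#' neighborhood.
#'
#' @param seeds Character vector of equal-length ACGT words.
#' @param exclude Optional character vector of words to drop.
#' @return A `motif_set` whose members are all at distance exactly 2 from at
#'   least one seed and at distance `>= 2` from every seed.
#' @export
expand_two_mismatch <- function(seeds, exclude = character()) {
  stopifnot(length(seeds) >= 1L)
  for (s in seeds) check_acgt(s, "seed")
  h <- nchar(seeds[1L])
  stopifnot(all(nchar(seeds) == h))
  members <- unique(unlist(lapply(seeds, function(s) {
    nb2 <- hamming_neighborhood(s, 2L, include_seed = TRUE)$members
    nb2
  })))
  ## keep words whose min distance to the seed set is exactly 2
  dmat <- vapply(seeds, function(s) {
    vapply(members, hamming_distance, numeric(1), a = s)
  }, numeric(length(members)))
  dmin <- if (is.matrix(dmat)) apply(dmat, 1L, min) else dmat
  members <- members[dmin == 2]
  members <- setdiff(members, exclude)
  structure(list(seeds = seeds, members = sort(members),
                 generation_rule = sprintf(
                   "exact hamming 2 from %d seed(s), ball-excluded", length(seeds))),
            class = "motif_set")
}

#' GC content of a nucleotide string
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from both numerator and
#' denominator.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence))
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n_acgt <- sum(chars %in% DNA_BASES)
    if (n_acgt == 0L) stop("sequence has no A/C/G/T characters")
    sum(chars %in% c("G", "C")) / n_acgt
  }, numeric(1), USE.NAMES = FALSE)
}

IUPAC_CODE <- c(A = "A", C = "C", G = "G", T = "T",
                AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Degenerate IUPAC consensus of equal-length motifs
#'
#' Per column, the IUPAC code covering exactly the set of observed
#' nucleotides (e.g. `S` = G/C, `Y` = C/T).
#'
#' @param motifs Character vector of equal-length ACGT words.
#' @return Single IUPAC string.
#' @export
#' @examples
#' degenerate_consensus(c("GCTGGTGG", "GCTGGCGG", "GCTGCTGG"))  # "GCTGSYGG"
degenerate_consensus <- function(motifs) {
  stopifnot(length(motifs) >= 1L)
  for (m in motifs) check_acgt(m, "motif")
  h <- nchar(motifs[1L])
  if (!all(nchar(motifs) == h)) stop("motifs have unequal lengths")
  mat <- do.call(rbind, strsplit(motifs, "", fixed = TRUE))
  paste(vapply(seq_len(h), function(j) {
    key <- paste(sort(unique(mat[, j])), collapse = "")
    IUPAC_CODE[[key]]
  }, character(1)), collapse = "")
}

#' Submotif enrichment within a motif list
#'
#' Counts every k-mer occurring inside the motifs and compares it with its
#' expectation under independent per-column shuffles of the motif matrix
#' (which preserve columnwise composition but break inter-column structure).
#' Ranks k-mers by observed/expected ratio; used e.g. to spot a palindromic
#' core such as GCGC shared by de novo candidate motifs.
#'
#' @param motifs Character vector of equal-length words.
#' @param k Submotif length, `< nchar(motifs)`.
#' @param n_shuffles Number of column shuffles for the null expectation.
#' @param seed Integer seed; output is deterministic given `seed`.
#' @return `data.frame` with columns `kmer`, `observed`, `expected`, `ratio`,
#'   sorted by ratio (descending, ties by kmer).
#' @export
submotif_enrichment <- function(motifs, k, n_shuffles = 200L, seed = 1L) {
  stopifnot(length(motifs) >= 1L)
  h <- nchar(motifs[1L])
  if (k >= h) stop("k must be smaller than the motif length")
  count_in <- function(words) {
    tab <- table(unlist(lapply(words, function(w) {
      vapply(seq_len(h - k + 1L), function(i) substr(w, i, i + k - 1L), character(1))
    })))
    tab
  }
  obs <- count_in(motifs)
  mat <- do.call(rbind, strsplit(motifs, "", fixed = TRUE))
  set.seed(as.integer(seed))
  exp_tab <- list()
  for (b in seq_len(n_shuffles)) {
    shuf <- apply(mat, 2L, sample)
    if (!is.matrix(shuf)) shuf <- matrix(shuf, nrow = nrow(mat))
    words <- apply(shuf, 1L, paste, collapse = "")
    exp_tab[[b]] <- count_in(words)
  }
  kmers <- sort(unique(c(names(obs), unlist(lapply(exp_tab, names)))))
  observed <- as.numeric(obs[kmers]); observed[is.na(observed)] <- 0
  expected <- rowMeans(vapply(exp_tab, function(t) {
    x <- as.numeric(t[kmers]); x[is.na(x)] <- 0; x
  }, numeric(length(kmers))))
  ratio <- ifelse(expected > 0, observed / expected, Inf)
  out <- data.frame(kmer = kmers, observed = observed, expected = expected,
                    ratio = ratio, stringsAsFactors = FALSE)
  out <- out[order(-out$ratio, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}
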