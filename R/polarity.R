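#' Locate all occurrences of a motif on a replicon, both strands
#'
#' `+` entries mark forward-strand matches of the motif; `-` entries mark
#' forward-strand matches of its reverse complement (i.e. the motif on the
#' reverse strand), recorded at the forward-strand start of the match. For
#' circular replicons the origin junction (last `h - 1` plus first `h - 1`
#' nucleotides) is additionally scanned, without double counting.
#'
#' @param genome A [genome_record()].
#' @param motif ACGT word.
#' @return An object of class `occurrence_set`: list with `motif`,
#'   `replicon_id`, and `occurrences` (`data.frame` of `position`, `strand`,
#'   positions sorted ascending).
#' @export
find_occurrences <- function(genome, motif) {
  stopifnot(inherits(genome, "genome_record"))
  check_acgt(motif, "motif")
  h <- nchar(motif)
  seq <- genome$sequence
  L <- nchar(seq)
  rc <- reverse_complement(motif)
  scan_one <- function(subject, pattern) {
    if (nchar(subject) < nchar(pattern)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(pattern,
                                               Biostrings::DNAString(subject),
                                               fixed = TRUE))
  }
  pos_f <- scan_one(seq, motif)
  pos_r <- scan_one(seq, rc)
  if (genome$circular && L >= h && h >= 2L) {
    junction <- paste0(substr(seq, L - h + 2L, L), substr(seq, 1L, h - 1L))
    jf <- scan_one(junction, motif)
    jr <- scan_one(junction, rc)
    ## only starts 1..h-1 of the junction window truly span the boundary
    jf <- jf[jf <= h - 1L]
    jr <- jr[jr <= h - 1L]
    pos_f <- c(pos_f, L - h + 1L + jf)
    pos_r <- c(pos_r, L - h + 1L + jr)
  }
  occ <- data.frame(position = c(pos_f, pos_r),
                    strand = rep(c("+", "-"), c(length(pos_f), length(pos_r))),
                    stringsAsFactors = FALSE)
  occ <- occ[order(occ$position, occ$strand), , drop = FALSE]
  rownames(occ) <- NULL
  structure(list(motif = motif, replicon_id = genome$replicon_id,
                 occurrences = occ),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  n <- table(factor(x$occurrences$strand, levels = c("+", "-")))
  cat(sprintf("<occurrence_set> %s on %s: %d (+), %d (-)\n", x$motif,
              x$replicon_id, n[["+"]], n[["-"]]))
  invisible(x)
}

## pool occurrence sets from several replicons of one species
pool_occurrences <- function(occ_list) {
  stopifnot(length(occ_list) >= 1L)
  occ <- do.call(rbind, lapply(occ_list, `[[`, "occurrences"))
  structure(list(motif = occ_list[[1L]]$motif,
                 replicon_id = paste(vapply(occ_list, `[[`, "", "replicon_id"),
                                     collapse = ";"),
                 occurrences = occ),
            class = "occurrence_set")
}

#' Strand-polarization test of motif occurrences
#'
#' Chi motifs ride the leading strand of replication, so their forward- and
#' reverse-strand occurrences occupy different arcs of the chromosome
#' (replichores). Without knowing the origin and terminus, this shows up as a
#' location shift between the forward-strand start positions of `+` and `-`
#' occurrences, tested here with a two-sided two-sample Wilcoxon rank-sum
#' test: exact when both strands have `<= 25` occurrences (and positions are
#' untied), otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param occ An `occurrence_set` from [find_occurrences()].
#' @param alpha Significance level (default 0.001).
#' @param min_per_strand Minimum occurrences required on *each* strand
#'   (default 3); below it the test is `indeterminate` and never polarized.
#' @return An object of class `polarity_result`: `n_plus`, `n_minus`,
#'   `statistic` (rank-sum W), `p_value`, `polarized`, `indeterminate`.
#' @export
polarity_test <- function(occ, alpha = 0.001, min_per_strand = 3L) {
  stopifnot(inherits(occ, "occurrence_set"), alpha > 0, alpha < 1)
  pos <- occ$occurrences$position[occ$occurrences$strand == "+"]
  neg <- occ$occurrences$position[occ$occurrences$strand == "-"]
  n_plus <- length(pos)
  n_minus <- length(neg)
  if (n_plus < min_per_strand || n_minus < min_per_strand) {
    return(structure(list(n_plus = n_plus, n_minus = n_minus,
                          statistic = NA_real_, p_value = NA_real_,
                          polarized = FALSE, indeterminate = TRUE),
                     class = "polarity_result"))
  }
  exact <- min(n_plus, n_minus) <= 25L
  wt <- suppressWarnings(wilcox.test(pos, neg, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  p <- min(wt$p.value, 1)
  structure(list(n_plus = n_plus, n_minus = n_minus,
                 statistic = unname(wt$statistic), p_value = p,
                 polarized = p < alpha, indeterminate = FALSE),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  if (x$indeterminate) {
    cat(sprintf("<polarity_result> indeterminate (n+ = %d, n- = %d)\n",
                x$n_plus, x$n_minus))
  } else {
    cat(sprintf("<polarity_result> n+ = %d, n- = %d, W = %.1f, P = %.3g%s\n",
                x$n_plus, x$n_minus, x$statistic, x$p_value,
                if (x$polarized) " [polarized]" else ""))
  }
  invisible(x)
}

#' Same-strand adjacency test
#'
#' Complementary polarization statistic: the fraction of position-adjacent
#' occurrence pairs lying on the same strand. Under polarization, consecutive
#' occurrences share a strand more often than expected; the null is built by
#' permuting strand labels over the fixed positions.
#'
#' @param occ An `occurrence_set` with `>= 2` occurrences.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return List with `statistic` (observed same-strand adjacency fraction)
#'   and `p_value` (one-sided, `(1 + #null >= observed) / (1 + B)`).
#' @export
same_strand_run_test <- function(occ, n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"))
  o <- occ$occurrences[order(occ$occurrences$position), , drop = FALSE]
  n <- nrow(o)
  if (n < 2L) stop("need at least 2 occurrences")
  adj_frac <- function(strands) mean(strands[-1L] == strands[-length(strands)])
  obs <- adj_frac(o$strand)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_permutations),
                 function(i) adj_frac(sample(o$strand)), numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_permutations))
}
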