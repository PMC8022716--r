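# Independent oracles: deliberately naive implementations used only to check
# the package's optimized paths.

## position-by-position word count; windows with N never match an ACGT word
naive_count <- function(sequences, word) {
  k <- nchar(word)
  sum(vapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(0L)
    starts <- seq_len(L - k + 1L)
    sum(substring(s, starts, starts + k - 1L) == word)
  }, integer(1)))
}

## exact two-sided rank-sum p-value by enumeration over all assignments of
## the pooled positions to the two strands (no ties assumed)
enum_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  all_sets <- utils::combn(length(pooled), n)
  sums <- apply(all_sets, 2L, function(idx) sum(r[idx]))
  p_le <- mean(sums <= obs)
  p_ge <- mean(sums >= obs)
  min(1, 2 * min(p_le, p_ge))
}

## brute-force minimum-change count over all internal-node labelings,
## plus the set of states each node takes in some optimal labeling
brute_parsimony <- function(tree, tip_states) {
  states <- c("present", "absent")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_idx <- match(tip_states[tree$tip.label], states)
  best <- Inf
  node_sets <- vector("list", ntip + nnode)
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)] + 1L
    assign_all <- c(tip_idx, internal)
    changes <- sum(assign_all[tree$edge[, 1L]] != assign_all[tree$edge[, 2L]])
    if (changes < best) {
      best <- changes
      node_sets <- lapply(assign_all, function(s) states[s])
    } else if (changes == best) {
      node_sets <- Map(function(old, s) union(old, states[s]),
                       node_sets, assign_all)
    }
  }
  list(min_changes = best, node_states = node_sets)
}

## exhaustive octamer enumeration for the two-mismatch expansion rule
enum_two_mismatch <- function(seeds, exclude = character()) {
  bases <- c("A", "C", "G", "T")
  h <- nchar(seeds[1L])
  codes <- 0:(4^h - 1)
  mats <- matrix(0L, length(codes), h)
  x <- codes
  for (j in h:1) { mats[, j] <- x %% 4L; x <- x %/% 4L }
  dmin <- rep(Inf, length(codes))
  for (s in seeds) {
    sc <- match(strsplit(s, "")[[1]], bases) - 1L
    d <- rowSums(mats != matrix(sc, length(codes), h, byrow = TRUE))
    dmin <- pmin(dmin, d)
  }
  words <- apply(mats, 1L, function(r) paste(bases[r + 1L], collapse = ""))
  setdiff(sort(words[dmin == 2]), exclude)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## the classical one-mismatch neighborhood of the E. coli Chi site
CHI_25 <- c("GCTGGTGG", "ACTGGTGG", "CCTGGTGG", "TCTGGTGG", "GATGGTGG",
            "GGTGGTGG", "GTTGGTGG", "GCAGGTGG", "GCGGGTGG", "GCCGGTGG",
            "GCTAGTGG", "GCTTGTGG", "GCTCGTGG", "GCTGATGG", "GCTGTTGG",
            "GCTGCTGG", "GCTGGAGG", "GCTGGCGG", "GCTGGGGG", "GCTGGTAG",
            "GCTGGTCG", "GCTGGTTG", "GCTGGTGA", "GCTGGTGC", "GCTGGTGT")

CHI_FIVE <- c("GCTGGTGG", "GCTGGCGG", "GCTGCTGG", "GGTGGTGG", "GCTGGAGG")
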