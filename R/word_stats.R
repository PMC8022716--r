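#' Count occurrences of a word in a set of sequences
#'
#' Overlapping occurrences are counted; windows never span sequence
#' boundaries; any window containing `N` is skipped (an ACGT word cannot match
#' it).
#'
#' @param sequences Character vector of nucleotide strings over `{A,C,G,T,N}`.
#' @param word ACGT word, length `>= 1`.
#' @return Integer count summed across sequences.
#' @export
#' @examples
#' count_word("GCTGGTGGCTGGTGG", "GCTGGTGG")  # 2 (overlapping)
count_word <- function(sequences, word) {
  check_acgt(word)
  sequences <- as.character(sequences)
  keep <- nchar(sequences) >= nchar(word)
  if (!any(keep)) return(0L)
  sum(Biostrings::vcountPattern(word, Biostrings::DNAStringSet(sequences[keep]),
                                fixed = TRUE))
}

#' Count all k-mers in a set of sequences
#'
#' Overlapping windows summed across sequences; windows containing `N`
#' contribute to no k-mer. The total over all `4^k` k-mers therefore equals
#' the number of valid windows.
#'
#' @param sequences Character vector of nucleotide strings.
#' @param k Word length, `>= 1`.
#' @return Named numeric vector over all `4^k` ACGT k-mers in lexicographic
#'   order (empty, with a warning, if no sequence is long enough).
#' @export
count_all_kmers <- function(sequences, k) {
  stopifnot(k >= 1L)
  sequences <- as.character(sequences)
  keep <- nchar(sequences) >= k
  if (!any(keep)) {
    warning("k = ", k, " exceeds every sequence length")
    return(setNames(numeric(0), character(0)))
  }
  freq <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences[keep]), width = k)
  if (is.matrix(freq)) colSums(freq) else freq
}

#' Fit a Markov model of a given order to training sequences
#'
#' Stores overlapping m-mer and (m+1)-mer counts (windows containing `N`
#' excluded). The transition probability
#' `p(b | x_1..x_m) = N(x_1..x_m b) / sum_b' N(x_1..x_m b')` and the plug-in
#' expectation of any word of length `>= m + 2` are derived from these counts.
#'
#' @param sequences Character vector of training sequences.
#' @param order Model order `m` in `0..6`; order 0 is mononucleotide
#'   composition, order 5 hexanucleotide composition.
#' @return An object of class `markov_model` with elements `order`,
#'   `counts_m` (for `m = 0` the total 1-mer window count), `counts_m1`,
#'   and `train_lengths`.
#' @export
fit_markov <- function(sequences, order) {
  stopifnot(order >= 0L, order <= 6L)
  sequences <- as.character(sequences)
  counts_m1 <- count_all_kmers(sequences, order + 1L)
  if (length(counts_m1) == 0L || sum(counts_m1) == 0) {
    stop("no valid windows of length ", order + 1L, " in the training sequences")
  }
  counts_m <- if (order == 0L) {
    sum(counts_m1)  # N(empty word) = total 1-mer window count
  } else {
    count_all_kmers(sequences, order)
  }
  structure(list(order = as.integer(order), counts_m = counts_m,
                 counts_m1 = counts_m1,
                 train_lengths = nchar(sequences)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> order %d, trained on %d sequence(s), %s valid (m+1)-mer windows\n",
              x$order, length(x$train_lengths),
              format(sum(x$counts_m1), big.mark = ",")))
  invisible(x)
}

## cumulative-probability arrays consumed by the C++ simulator
markov_sim_arrays <- function(model) {
  m <- model$order
  c1 <- model$counts_m1
  base_counts <- if (m == 0L) c1 else {
    ## order-0 fallback distribution from the (m+1)-mer counts' last position
    tapply(c1, substr(names(c1), m + 1L, m + 1L), sum)[DNA_BASES]
  }
  base_counts[is.na(base_counts)] <- 0
  base_cum <- cumsum(base_counts / sum(base_counts))
  if (m == 0L) {
    trans <- matrix(c1 / sum(c1), nrow = 1L)
    return(list(order = 0L, init_cum = numeric(0),
                trans_cum = as.numeric(cumsum(trans[1L, ])),
                trans_ok = 1L, base_cum = as.numeric(base_cum)))
  }
  tm <- matrix(c1, nrow = 4L^m, ncol = 4L, byrow = TRUE)  # rows: contexts in lexicographic order
  rs <- rowSums(tm)
  ok <- as.integer(rs > 0)
  tm[rs > 0, ] <- tm[rs > 0, , drop = FALSE] / rs[rs > 0]
  tcum <- t(apply(tm, 1L, cumsum))
  tcum[rs == 0, ] <- 0
  init <- model$counts_m
  if (sum(init) == 0) stop("model has no initial-context counts")
  list(order = m, init_cum = as.numeric(cumsum(init / sum(init))),
       trans_cum = as.numeric(t(tcum)),  # row-major flatten
       trans_ok = ok, base_cum = as.numeric(base_cum))
}

#' Simulate sequences from a fitted Markov model
#'
#' The first `m` symbols are drawn from the empirical m-mer distribution, then
#' the chain follows the fitted transition probabilities; contexts never seen
#' in training fall back to the order-0 (mononucleotide) distribution. Fully
#' reproducible given `seed`.
#'
#' @param model A [fit_markov()] model.
#' @param lengths Integer vector of sequence lengths to generate.
#' @param seed Integer seed.
#' @return Character vector of simulated ACGT sequences.
#' @export
simulate_from_model <- function(model, lengths, seed) {
  stopifnot(inherits(model, "markov_model"), all(lengths >= 1L))
  a <- markov_sim_arrays(model)
  withr_seed(seed)
  cpp_sim_markov(a$order, a$init_cum, a$trans_cum, a$trans_ok, a$base_cum,
                 as.integer(lengths))
}

withr_seed <- function(seed) set.seed(as.integer(seed))

#' Bootstrap null distribution of word counts under a Markov model
#'
#' Simulates `B` replicate sequence sets from the model (same lengths as
#' requested), counts all `4^h` words of length `h` in each replicate in one
#' batched pass, and returns the per-word sample mean and standard deviation
#' (denominator `B - 1`). This is the parametric-bootstrap realization of the
#' Gaussian count statistic.
#'
#' @param model A [fit_markov()] model.
#' @param word_length Word length `h`.
#' @param lengths Sequence lengths per replicate (typically the training
#'   lengths).
#' @param B Number of replicates, `>= 2`.
#' @param seed Integer seed.
#' @param words Optional character vector restricting the returned (and
#'   accumulated) words.
#' @return List with named numeric vectors `mean` and `sd`.
#' @export
null_distribution <- function(model, word_length, lengths, B = 200L, seed = 1L,
                              words = NULL) {
  stopifnot(inherits(model, "markov_model"), B >= 2L, word_length >= 1L)
  a <- markov_sim_arrays(model)
  codes <- if (is.null(words)) integer(0) else as.integer(encode_word(words))
  withr_seed(seed)
  res <- cpp_markov_null(a$order, a$init_cum, a$trans_cum, a$trans_ok,
                         a$base_cum, as.integer(lengths),
                         as.integer(word_length), as.integer(B), codes)
  nm <- if (is.null(words)) all_words(word_length) else words
  list(mean = setNames(res$mean, nm), sd = setNames(res$sd, nm))
}

#' Plug-in expected count of a word under a fitted Markov model
#'
#' The maximal-overlap plug-in estimator
#' \deqn{\hat E_m(w) = \frac{\prod_{j=1}^{h-m} N(w_j \dots w_{j+m})}
#'                          {\prod_{j=2}^{h-m} N(w_j \dots w_{j+m-1})}}
#' where `N(.)` are overlapping window counts on the training sequences and
#' `N(empty)` is the total 1-mer window count. For `h = m + 1` the denominator
#' product is empty and the estimator degenerates to the observed count.
#' Returns `NA` (non-evaluable) when any denominator factor is zero.
#'
#' @param model A [fit_markov()] model.
#' @param word ACGT word of length `>= order + 1`.
#' @return Expected count (numeric), or `NA_real_` when non-evaluable.
#' @export
expected_count <- function(model, word) {
  check_acgt(word)
  m <- model$order
  h <- nchar(word)
  if (h < m + 1L) stop("word length ", h, " below order + 1 = ", m + 1L)
  num_words <- vapply(seq_len(h - m), function(j) substr(word, j, j + m),
                      character(1))
  num <- as.numeric(model$counts_m1[num_words])
  num[is.na(num)] <- 0
  if (h == m + 1L) {
    ## degenerate case: the estimator is the observed (m+1)-mer count itself
    return(as.numeric(model$counts_m1[word]))
  }
  den <- if (m == 0L) {
    rep(as.numeric(model$counts_m), h - 1L)
  } else {
    den_words <- vapply(2:(h - m), function(j) substr(word, j, j + m - 1L),
                        character(1))
    x <- as.numeric(model$counts_m[den_words])
    x[is.na(x)] <- 0
    x
  }
  if (any(den == 0)) return(NA_real_)
  prod(num) / prod(den)
}

## vectorized expectation for ALL words of length h (codes 0..4^h-1);
## returns numeric vector with NA at non-evaluable words
expected_count_all <- function(model, h) {
  m <- model$order
  stopifnot(h >= m + 2L)
  codes <- 0:(4^h - 1)
  sub_code <- function(codes, j, len) {
    ## code of substring starting at j (1-based) of length len within an h-mer
    (codes %/% 4^(h - (j + len - 1))) %% 4^len
  }
  logE <- numeric(length(codes))
  bad <- logical(length(codes))
  zero <- logical(length(codes))
  c1 <- as.numeric(model$counts_m1)
  for (j in seq_len(h - m)) {
    f <- c1[sub_code(codes, j, m + 1L) + 1L]
    zero <- zero | f == 0
    logE <- logE + log(ifelse(f > 0, f, 1))
  }
  cm <- if (m == 0L) as.numeric(model$counts_m) else as.numeric(model$counts_m)
  for (j in if (h - m >= 2L) 2:(h - m) else integer(0)) {
    f <- if (m == 0L) rep(cm, length(codes)) else cm[sub_code(codes, j, m) + 1L]
    bad <- bad | f == 0
    logE <- logE - log(ifelse(f > 0, f, 1))
  }
  out <- exp(logE)
  out[zero] <- 0
  out[bad] <- NA_real_
  setNames(out, all_words(h))
}

#' Overrepresentation z-score of a word in a core genome
#'
#' The word is counted on the core sequences; the order-`m` Markov model is
#' fitted on the *same* sequences (plug-in null); the expected count comes
#' from [expected_count()] and the standard deviation from the parametric
#' bootstrap ([null_distribution()] with the training lengths). The statistic
#' is `z = (observed - expected) / sd`, approximately standard normal under
#' the null for words without extreme self-overlap.
#'
#' @param core A `core_genome` object or character vector of sequences.
#' @param word ACGT word (octamers in the standard Chi analysis).
#' @param order Markov order in `0..5`.
#' @param B Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return An object of class `word_statistic`: list with `word`,
#'   `model_order`, `observed`, `expected`, `sd`, `z`, `evaluable`.
#' @export
zscore_word <- function(core, word, order, B = 200L, seed = 1L) {
  check_acgt(word)
  seqs <- core_sequences(core)
  stopifnot(order >= 0L, order <= 5L)
  if (nchar(word) < order + 2L) {
    stop("word length must be >= order + 2 for a non-degenerate statistic")
  }
  model <- fit_markov(seqs, order)
  observed <- count_word(seqs, word)
  expected <- expected_count(model, word)
  nd <- null_distribution(model, nchar(word), nchar(seqs), B = B, seed = seed,
                          words = word)
  s <- as.numeric(nd$sd[word])
  evaluable <- !is.na(expected) && is.finite(s) && s > 0
  z <- if (evaluable) (observed - expected) / s else NA_real_
  structure(list(word = word, model_order = as.integer(order),
                 observed = observed, expected = expected, sd = s, z = z,
                 evaluable = evaluable),
            class = "word_statistic")
}

#' @export
print.word_statistic <- function(x, ...) {
  cat(sprintf("<word_statistic> %s (order %d): obs %d, exp %.2f, sd %.2f, z %s%s\n",
              x$word, x$model_order, x$observed,
              if (is.na(x$expected)) NaN else x$expected,
              x$sd, if (x$evaluable) sprintf("%.2f", x$z) else "NA",
              if (x$evaluable) "" else " (non-evaluable)"))
  invisible(x)
}

core_sequences <- function(core) {
  if (inherits(core, "core_genome")) {
    as.character(core$genes)
  } else {
    as.character(core)
  }
}

#' Score one word under several Markov orders
#'
#' One [zscore_word()]-style statistic per order, sharing a single observed
#' count. Per-order bootstrap seeds are derived from `seed`.
#'
#' @inheritParams zscore_word
#' @param orders Integer vector of Markov orders (default `0:5`).
#' @return `data.frame` with one row per order: `word`, `order`, `observed`,
#'   `expected`, `sd`, `z`, `evaluable`.
#' @export
score_all_models <- function(core, word, orders = 0:5, B = 200L, seed = 1L) {
  score_words(core_sequences(core), word, orders = orders, B = B, seed = seed)
}

#' Score a set of words under several Markov orders with shared bootstraps
#'
#' Fits one model and runs one batched bootstrap per order, scoring every
#' word against it; the cost is therefore independent of the number of words.
#'
#' @param sequences Character vector of core sequences.
#' @param words Character vector of equal-length ACGT words.
#' @param orders Integer vector of Markov orders.
#' @param B Bootstrap replicates per order.
#' @param seed Integer seed (per-order seeds derived as `seed + order`).
#' @return `data.frame` with one row per word x order.
#' @export
score_words <- function(sequences, words, orders = 0:5, B = 200L, seed = 1L) {
  sequences <- core_sequences(sequences)
  stopifnot(length(words) >= 1L)
  h <- nchar(words[1L])
  stopifnot(all(nchar(words) == h))
  observed <- vapply(words, function(w) count_word(sequences, w), integer(1))
  out <- list()
  for (m in orders) {
    if (h < m + 2L) stop("word length ", h, " below order + 2 for order ", m)
    model <- fit_markov(sequences, m)
    expd <- vapply(words, function(w) expected_count(model, w), numeric(1))
    nd <- null_distribution(model, h, nchar(sequences), B = B,
                            seed = seed + m, words = words)
    s <- as.numeric(nd$sd[words])
    evaluable <- !is.na(expd) & is.finite(s) & s > 0
    z <- ifelse(evaluable, (observed - expd) / s, NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      word = words, order = m, observed = as.integer(observed),
      expected = expd, sd = s, z = z, evaluable = evaluable,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
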