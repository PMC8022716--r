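#' Detection configuration
#'
#' Bundles the thresholds of the combined detection rule: a motif is a
#' candidate when its overrepresentation z-score reaches the per-order
#' threshold under at least `min_models` Markov orders and (in `polarized`
#' mode) its genomic occurrences pass the strand-polarization test.
#'
#' @param z_thresholds Named or unnamed numeric vector of minimum z per model
#'   order (recycled over `orders`); default 4 for every order, roughly a
#'   one-sided Gaussian tail of 3.2e-5.
#' @param min_models Minimum number of orders that must pass (default 3).
#' @param orders Markov orders evaluated (default `0:5`).
#' @param alpha Polarity significance level (default 0.001).
#' @param min_per_strand Minimum occurrences per strand for the polarity test
#'   (default 3).
#' @param mode `"polarized"` (overrepresentation AND polarity) or
#'   `"unpolarized"` (overrepresentation only; polarity still reported).
#' @param bootstrap_B Bootstrap replicates per order (default 200).
#' @param seed Integer seed for all bootstrap randomness.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(z_thresholds = 4, min_models = 3L, orders = 0:5,
                             alpha = 0.001, min_per_strand = 3L,
                             mode = c("polarized", "unpolarized"),
                             bootstrap_B = 200L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(min_models >= 1L, min_models <= length(orders),
            alpha > 0, alpha < 1)
  zt <- rep_len(z_thresholds, length(orders))
  names(zt) <- as.character(orders)
  structure(list(z_thresholds = zt, min_models = as.integer(min_models),
                 orders = as.integer(orders), alpha = alpha,
                 min_per_strand = as.integer(min_per_strand), mode = mode,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed)),
            class = "detection_config")
}

#' Calibrate per-order z thresholds on a reference species
#'
#' Recomputes the thresholds as the z-scores of a reference motif in a
#' reference core genome (the classical anchor is the *E. coli* Chi site in
#' the *E. coli* pseudo-core): any motif at least as overrepresented as the
#' anchor, order by order, passes.
#'
#' @param core Reference `core_genome` or character vector of sequences.
#' @param motif Reference motif (e.g. `"GCTGGTGG"`).
#' @param config A [detection_config()] whose thresholds are replaced.
#' @return The config with calibrated `z_thresholds`.
#' @export
calibrate_thresholds <- function(core, motif, config = detection_config()) {
  stats <- score_words(core_sequences(core), motif, orders = config$orders,
                       B = config$bootstrap_B, seed = config$seed)
  zt <- setNames(stats$z, as.character(stats$order))
  if (any(!stats$evaluable)) {
    warning("reference motif non-evaluable under order(s) ",
            paste(stats$order[!stats$evaluable], collapse = ", "),
            "; those thresholds kept at their previous values")
    zt[!stats$evaluable] <- config$z_thresholds[!stats$evaluable]
  }
  config$z_thresholds <- zt
  config
}

## polarity of one motif over the supplied replicons of one species
species_polarity <- function(genomes, motif, config) {
  occ <- pool_occurrences(lapply(genomes, find_occurrences, motif = motif))
  polarity_test(occ, alpha = config$alpha,
                min_per_strand = config$min_per_strand)
}

#' Combined candidate detection for a set of motifs in one species
#'
#' Scores every motif on the core gene sequences under all configured Markov
#' orders (one shared bootstrap per order, so cost does not grow with the
#' motif count), computes occurrence polarity on the supplied replicons, and
#' applies the candidate rule. All calls are returned, candidates or not.
#'
#' @param core A `core_genome` or character vector of core gene sequences.
#' @param genomes List of [genome_record()]s scanned for occurrences.
#' @param motifs A `motif_set` or character vector of octamers.
#' @param config A [detection_config()].
#' @param species_id Species label for the output (default: taken from
#'   `core`, else `"species"`).
#' @return `data.frame` of class `motif_calls`, one row per motif: per-order
#'   z columns (`z0`..), `models_passed`, `n_plus`, `n_minus`, `polarity_p`,
#'   `polarized`, `indeterminate`, `candidate`, `mode`.
#' @export
detect_candidates <- function(core, genomes, motifs, config = detection_config(),
                              species_id = NULL) {
  words <- if (inherits(motifs, "motif_set")) motifs$members else motifs
  if (!length(words)) {
    out <- data.frame(species = character(), motif = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("motif_calls", class(out))
    return(out)
  }
  if (is.null(species_id)) {
    species_id <- if (inherits(core, "core_genome")) core$species_id else "species"
  }
  seqs <- core_sequences(core)
  if (!length(seqs) || !sum(nchar(seqs))) stop("empty core genome")
  stats <- score_words(seqs, words, orders = config$orders,
                       B = config$bootstrap_B, seed = config$seed)
  pol <- lapply(words, function(w) species_polarity(genomes, w, config))
  rows <- lapply(seq_along(words), function(i) {
    w <- words[i]
    st <- stats[stats$word == w, , drop = FALSE]
    passed <- st$evaluable & !is.na(st$z) &
      st$z >= config$z_thresholds[as.character(st$order)]
    p <- pol[[i]]
    zcols <- setNames(as.list(st$z), paste0("z", st$order))
    candidate <- sum(passed) >= config$min_models &&
      (config$mode == "unpolarized" || isTRUE(p$polarized))
    cbind(data.frame(species = species_id, motif = w,
                     observed = st$observed[1L], stringsAsFactors = FALSE),
          as.data.frame(zcols),
          data.frame(models_passed = sum(passed), n_plus = p$n_plus,
                     n_minus = p$n_minus, polarity_p = p$p_value,
                     polarized = p$polarized, indeterminate = p$indeterminate,
                     candidate = candidate, mode = config$mode,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_calls", class(out))
  out
}

#' Detection without the polarity constraint
#'
#' Same scoring as [detect_candidates()] but the candidate flag only requires
#' overrepresentation under `min_models` orders; polarity is still computed
#' and reported. Polarized-mode candidates are always a subset of the
#' unpolarized-mode candidates.
#'
#' @inheritParams detect_candidates
#' @return `data.frame` of calls with `mode = "unpolarized"`.
#' @export
detect_unpolarized <- function(core, genomes, motifs,
                               config = detection_config(), species_id = NULL) {
  config$mode <- "unpolarized"
  detect_candidates(core, genomes, motifs, config, species_id = species_id)
}

#' De novo scan of all octamers in a core genome
#'
#' Scores every word of length `word_length` (all `4^8 = 65536` octamers by
#' default) under the configured Markov orders, using one batched bootstrap
#' per order that yields the null mean and sd of every word at once. Words
#' passing the per-order z thresholds in at least `min_models` orders are the
#' de novo candidates.
#'
#' @param core A `core_genome` or character vector of sequences.
#' @param config A [detection_config()].
#' @param word_length Word length (default 8).
#' @param full_table If `TRUE`, return all words, not only candidates.
#' @return `data.frame` with `motif`, `observed`, per-order `z` columns,
#'   `models_passed`, `mean_z`, sorted by `models_passed` then `mean_z`
#'   (descending).
#' @export
denovo_scan <- function(core, config = detection_config(), word_length = 8L,
                        full_table = FALSE) {
  seqs <- core_sequences(core)
  if (!length(seqs)) stop("empty core genome")
  h <- as.integer(word_length)
  observed <- count_all_kmers(seqs, h)
  zmat <- matrix(NA_real_, nrow = 4^h, ncol = length(config$orders),
                 dimnames = list(all_words(h), paste0("z", config$orders)))
  for (k in seq_along(config$orders)) {
    m <- config$orders[k]
    model <- fit_markov(seqs, m)
    expd <- expected_count_all(model, h)
    nd <- null_distribution(model, h, nchar(seqs), B = config$bootstrap_B,
                            seed = config$seed + m)
    ok <- !is.na(expd) & nd$sd > 0
    zmat[ok, k] <- (observed[ok] - expd[ok]) / nd$sd[ok]
  }
  thr <- config$z_thresholds[as.character(config$orders)]
  passmat <- sweep(zmat, 2L, thr, `>=`)
  passmat[is.na(passmat)] <- FALSE
  models_passed <- rowSums(passmat)
  mean_z <- rowMeans(zmat, na.rm = TRUE)
  out <- data.frame(motif = rownames(zmat), observed = as.numeric(observed),
                    zmat, models_passed = models_passed, mean_z = mean_z,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!full_table) out <- out[out$models_passed >= config$min_models, , drop = FALSE]
  out <- out[order(-out$models_passed, -out$mean_z, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate candidate calls across species
#'
#' Counts, per motif, the number of *species* in which it is a candidate (a
#' species with several candidate motifs contributes to each), and summarizes
#' per-species candidate lists.
#'
#' @param calls A `motif_calls` data.frame (rows from one or more species,
#'   e.g. `rbind` of per-species [detect_candidates()] outputs).
#' @return List with `per_motif` (`motif`, `n_species_candidate`, `species`),
#'   `per_species` (`species`, semicolon-joined candidate motifs),
#'   `fraction_species_with_candidate`.
#' @export
aggregate_across_species <- function(calls) {
  stopifnot(nrow(calls) >= 1L)
  cand <- calls[calls$candidate, , drop = FALSE]
  per_motif <- if (nrow(cand)) {
    sp <- split(cand$species, cand$motif)
    data.frame(motif = names(sp),
               n_species_candidate = vapply(sp, function(x) length(unique(x)), integer(1)),
               species = vapply(sp, function(x) paste(sort(unique(x)), collapse = ";"), character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(motif = character(), n_species_candidate = integer(),
               species = character(), stringsAsFactors = FALSE)
  }
  per_motif <- per_motif[order(-per_motif$n_species_candidate, per_motif$motif), ,
                         drop = FALSE]
  rownames(per_motif) <- NULL
  all_sp <- unique(calls$species)
  per_species <- data.frame(
    species = all_sp,
    motifs = vapply(all_sp, function(s) {
      m <- sort(unique(cand$motif[cand$species == s]))
      if (length(m)) paste(m, collapse = ";") else "none"
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(per_motif = per_motif, per_species = per_species,
       fraction_species_with_candidate =
         mean(all_sp %in% unique(cand$species)))
}

#' False-positive rates on a labeled outgroup
#'
#' Species in the outgroup are assumed not to share the searched motifs, so
#' any candidate there is a false positive. Because the natural denominator
#' is ambiguous, both rates are reported: per species (species with at least
#' one candidate / outgroup species) and per test (candidate motif-species
#' pairs / all motif-species pairs evaluated).
#'
#' @param calls_by_species Named list, species -> `motif_calls` data.frame.
#' @param outgroup_labels Character vector of outgroup species ids.
#' @return List with `per_species_rate`, `per_test_rate`, `n_outgroup`,
#'   `n_tests`.
#' @export
estimate_fpr <- function(calls_by_species, outgroup_labels) {
  if (!length(outgroup_labels)) stop("empty outgroup")
  missing <- setdiff(outgroup_labels, names(calls_by_species))
  if (length(missing)) {
    stop("outgroup species without calls: ", paste(missing, collapse = ", "))
  }
  og <- calls_by_species[outgroup_labels]
  has_cand <- vapply(og, function(cc) any(cc$candidate), logical(1))
  n_tests <- sum(vapply(og, nrow, integer(1)))
  n_cand <- sum(vapply(og, function(cc) sum(cc$candidate), integer(1)))
  list(per_species_rate = mean(has_cand),
       per_test_rate = if (n_tests) n_cand / n_tests else 0,
       n_outgroup = length(outgroup_labels), n_tests = n_tests)
}

#' Compare genomic GC content between species with and without candidates
#'
#' Two-sided two-sample Wilcoxon rank-sum on the genomic GC fractions of the
#' two groups (exact for small untied samples, normal approximation
#' otherwise). GC-rich genomes inflate the background frequency of GC-rich
#' motifs, so a GC contrast between candidate and non-candidate species flags
#' residual compositional bias.
#'
#' @param species_table `data.frame` with columns `gc` (fraction) and
#'   `has_candidate` (logical).
#' @return List with per-group `n`, `mean`, `median`, and `p_value`; if a
#'   group is empty, a skip message is returned instead.
#' @export
gc_group_comparison <- function(species_table) {
  stopifnot(all(c("gc", "has_candidate") %in% names(species_table)))
  with_c <- species_table$gc[species_table$has_candidate]
  without <- species_table$gc[!species_table$has_candidate]
  if (!length(with_c) || !length(without)) {
    return(list(skipped = TRUE,
                message = "one group is empty; comparison skipped"))
  }
  exact <- min(length(with_c), length(without)) <= 25L
  wt <- suppressWarnings(wilcox.test(with_c, without, exact = exact,
                                     alternative = "two.sided", correct = TRUE))
  list(skipped = FALSE,
       n_with = length(with_c), n_without = length(without),
       mean_with = mean(with_c), mean_without = mean(without),
       median_with = median(with_c), median_without = median(without),
       p_value = wt$p.value)
}
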