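# one small planted species shared across detection tests
local_species <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_species("sp_test", length = 2e5, gc = 0.5,
                                 motif = "GCTGGTGG", density = 0.3,
                                 polarization_level = 0.95, seed = 71)
    }
    cache
  }
})

test_that("a densely planted polarized motif is called, junk motifs are not", {
  sp <- local_species()
  cfg <- detection_config(seed = 72)
  calls <- detect_candidates(sp$core, list(sp$genome),
                             c("GCTGGTGG", "AAAAAAAA"), cfg,
                             species_id = "sp_test")
  chi <- calls[calls$motif == "GCTGGTGG", ]
  expect_true(chi$candidate)
  expect_gte(chi$models_passed, 3L)
  expect_true(chi$polarized)
  junk <- calls[calls$motif == "AAAAAAAA", ]
  expect_false(junk$candidate)
})

test_that("zero-occurrence motifs are indeterminate and never candidates", {
  sp <- local_species()
  cfg <- detection_config(orders = 0:2, bootstrap_B = 50, seed = 73)
  ## pick an octamer genuinely absent from both strands of this genome
  counts <- count_all_kmers(sp$genome$sequence, 8)
  zero <- names(counts)[counts == 0]
  absent <- zero[match(TRUE, counts[reverse_complement(zero)] == 0)]
  calls <- detect_candidates(sp$core, list(sp$genome), absent, cfg)
  expect_true(calls$indeterminate)
  expect_false(calls$candidate)
  expect_equal(calls$n_plus + calls$n_minus, 0L)
})

test_that("unpolarized mode weakens the rule monotonically", {
  sp <- local_species()
  cfg <- detection_config(seed = 74, orders = 0:3, bootstrap_B = 100)
  pol <- detect_candidates(sp$core, list(sp$genome), CHI_FIVE, cfg)
  unpol <- detect_unpolarized(sp$core, list(sp$genome), CHI_FIVE, cfg)
  expect_true(all(pol$motif[pol$candidate] %in% unpol$motif[unpol$candidate]))
  ## z columns identical across modes: same seeds, same statistics
  expect_equal(pol$z0, unpol$z0)
  empty <- detect_candidates(sp$core, list(sp$genome), character(0), cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("candidate calls are monotone in thresholds and K", {
  sp <- local_species()
  strict <- detection_config(z_thresholds = 6, min_models = 4, seed = 75,
                             orders = 0:3, bootstrap_B = 100)
  loose <- detection_config(z_thresholds = 2, min_models = 2, seed = 75,
                            orders = 0:3, bootstrap_B = 100)
  cs <- detect_candidates(sp$core, list(sp$genome), CHI_FIVE, strict)
  cl <- detect_candidates(sp$core, list(sp$genome), CHI_FIVE, loose)
  expect_true(all(cs$motif[cs$candidate] %in% cl$motif[cl$candidate]))
})

test_that("threshold calibration anchors on a reference motif's z-scores", {
  sp <- local_species()
  cfg <- detection_config(orders = 0:2, bootstrap_B = 100, seed = 76)
  cal <- calibrate_thresholds(sp$core, "GCTGGTGG", cfg)
  ref <- score_words(sp$core, "GCTGGTGG", orders = 0:2, B = 100, seed = 76)
  expect_equal(unname(cal$z_thresholds), ref$z)
  ## the anchor motif passes its own thresholds in every order
  calls <- detect_candidates(sp$core, list(sp$genome), "GCTGGTGG", cal)
  expect_equal(calls$models_passed, 3L)
})

test_that("de novo scan ranks a heavily planted octamer first", {
  sp <- local_species()
  cfg <- detection_config(orders = 0:2, bootstrap_B = 60, seed = 77)
  tab <- denovo_scan(sp$core, cfg)
  expect_equal(tab$motif[1L], "GCTGGTGG")
  expect_gte(tab$models_passed[1L], cfg$min_models)
  again <- denovo_scan(sp$core, cfg)
  expect_identical(tab, again)
  full <- denovo_scan(sp$core, cfg, full_table = TRUE)
  expect_equal(nrow(full), 4^8)
  ## scan z-scores agree with the per-word scoring path up to bootstrap noise
  st <- score_words(sp$core, "GCTGGTGG", orders = 0:2, B = 60,
                    seed = cfg$seed)
  row <- full[full$motif == "GCTGGTGG", ]
  expect_equal(row$observed, st$observed[1L])
})

test_that("aggregation counts species, not calls", {
  calls <- rbind(
    data.frame(species = "s1", motif = "X", candidate = TRUE),
    data.frame(species = "s1", motif = "Y", candidate = TRUE),
    data.frame(species = "s2", motif = "X", candidate = TRUE),
    data.frame(species = "s3", motif = "X", candidate = FALSE))
  agg <- aggregate_across_species(calls)
  expect_equal(agg$per_motif$n_species_candidate[agg$per_motif$motif == "X"], 2L)
  expect_equal(agg$per_motif$n_species_candidate[agg$per_motif$motif == "Y"], 1L)
  expect_equal(agg$per_species$motifs[agg$per_species$species == "s1"], "X;Y")
  expect_equal(agg$per_species$motifs[agg$per_species$species == "s3"], "none")
  expect_equal(agg$fraction_species_with_candidate, 2 / 3)
  expect_gte(sum(agg$per_motif$n_species_candidate),
             sum(tapply(calls$candidate, calls$species, any)))
  none <- aggregate_across_species(
    data.frame(species = "s1", motif = "X", candidate = FALSE))
  expect_equal(nrow(none$per_motif), 0L)
})

test_that("false positive rates use both denominators", {
  mk <- function(sp, flags) data.frame(species = sp,
                                       motif = paste0("m", seq_along(flags)),
                                       candidate = flags)
  calls <- list(og1 = mk("og1", c(TRUE, FALSE)),
                og2 = mk("og2", c(FALSE, FALSE)),
                og3 = mk("og3", c(FALSE, FALSE)),
                og4 = mk("og4", c(FALSE, FALSE)),
                in1 = mk("in1", c(TRUE, TRUE)))
  fpr <- estimate_fpr(calls, paste0("og", 1:4))
  expect_equal(fpr$per_species_rate, 0.25)
  expect_equal(fpr$per_test_rate, 1 / 8)
  ## duplicating a non-outgroup species changes nothing
  calls2 <- c(calls, list(in2 = mk("in2", c(TRUE, TRUE))))
  expect_equal(estimate_fpr(calls2, paste0("og", 1:4))$per_species_rate, 0.25)
  no_cand <- estimate_fpr(calls[2:4], paste0("og", 2:4))
  expect_equal(no_cand$per_species_rate, 0)
  expect_equal(no_cand$per_test_rate, 0)
  expect_error(estimate_fpr(calls, character(0)), "empty outgroup")
  expect_error(estimate_fpr(calls, "missing_sp"), "without calls")
})

test_that("GC group comparison reports means and an exact small-sample p", {
  tab <- data.frame(gc = c(0.6, 0.61, 0.5, 0.51),
                    has_candidate = c(TRUE, TRUE, FALSE, FALSE))
  r <- gc_group_comparison(tab)
  expect_equal(r$mean_with - r$mean_without, 0.10)
  expect_equal(r$p_value, enum_ranksum_p(c(0.6, 0.61), c(0.5, 0.51)))
  same <- gc_group_comparison(data.frame(gc = c(0.5, 0.6, 0.5, 0.6),
                                         has_candidate = c(TRUE, TRUE, FALSE, FALSE)))
  expect_gt(same$p_value, 0.99)
  skip <- gc_group_comparison(data.frame(gc = 0.5, has_candidate = TRUE))
  expect_true(skip$skipped)
})
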