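make_aln <- function(...) {
  rows <- c(...)
  marker_alignment(paste0("sp", seq_along(rows)), rows)
}

test_that("gap filtering keeps exactly the columns at or below the threshold", {
  aln <- make_aln("AA-", "A--")
  filtered <- filter_alignment_columns(aln, 0.4)
  expect_equal(filtered$rows, c("A", "A"))
  expect_equal(filter_alignment_columns(aln, 1.0)$rows, aln$rows)
  gapfree <- make_aln("ACD", "ACE")
  expect_equal(filter_alignment_columns(gapfree, 0.0)$rows, gapfree$rows)
  expect_warning(gone <- filter_alignment_columns(make_aln("--", "--"), 0.4),
                 "all alignment columns")
  expect_equal(nchar(gone$rows), c(0L, 0L))
})

test_that("p-distance counts mismatches over gap-free comparable columns", {
  expect_equal(pairwise_distance_matrix(make_aln("ACDE", "ACDE"))$values[1, 2], 0)
  ten <- make_aln("ACDEFGHIKL", "ACDEFGHIKM")
  expect_equal(pairwise_distance_matrix(ten)$values[1, 2], 0.1)
  gapped <- make_aln("AC-G", "AT-G")
  expect_equal(pairwise_distance_matrix(gapped)$values[1, 2], 1 / 3)
  expect_warning(nc <- pairwise_distance_matrix(make_aln("A-", "-A")),
                 "no comparable")
  expect_equal(nc$values[1, 2], 1)
})

test_that("p-distance satisfies the triangle inequality on gap-free fixtures", {
  set.seed(51)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    rows <- replicate(4, paste(sample(aas, 40, replace = TRUE), collapse = ""))
    d <- pairwise_distance_matrix(marker_alignment(paste0("s", 1:4), rows))$values
    for (i in 1:4) for (j in 1:4) for (k in 1:4) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("closest_relatives ranks by distance with lexicographic ties", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.1
  d[1, 3] <- d[3, 1] <- 0.3
  d[2, 3] <- d[3, 2] <- 0.2
  dm <- distance_matrix(c("A", "B", "C"), d)
  expect_equal(closest_relatives(dm, "A", 2), c("B", "C"))
  dt <- matrix(0, 3, 3)
  dt[1, 2] <- dt[2, 1] <- 0.2
  dt[1, 3] <- dt[3, 1] <- 0.2
  dt[2, 3] <- dt[3, 2] <- 0.4
  expect_equal(closest_relatives(distance_matrix(c("A", "B", "C"), dt), "A", 2),
               c("B", "C"))
  expect_error(closest_relatives(dm, "A", 3), "exceeds")
  expect_error(closest_relatives(dm, "Z", 1), "unknown")
})

test_that("best reciprocal hits honor identity and length thresholds", {
  set.seed(52)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aas, 100, replace = TRUE), collapse = "")
  same <- best_reciprocal_hits(c(x = p), c(y = p))
  expect_equal(nrow(same), 1L)
  expect_equal(same$identity, 1)

  ## identical prefix, lengths 100 vs 79: identity passes, length ratio fails
  short <- substr(p, 1, 79)
  none <- best_reciprocal_hits(c(x = p), c(y = short))
  expect_equal(nrow(none), 0L)
  ok <- best_reciprocal_hits(c(x = p), c(y = short),
                             min_length_conservation = 0.75)
  expect_equal(nrow(ok), 1L)
})

test_that("non-reciprocal best hits are excluded", {
  set.seed(53)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  b1 <- paste(sample(aas, 80, replace = TRUE), collapse = "")
  a2 <- b1                          # b1's best is a2
  a1 <- b1
  for (p in sample(80, 12)) substr(a1, p, p) <- sample(aas, 1)
  res <- best_reciprocal_hits(c(a1 = a1, a2 = a2), c(b1 = b1))
  expect_equal(res$id_a, "a2")
  expect_equal(res$id_b, "b1")
})

test_that("BRH output is symmetric and monotone in the thresholds", {
  set.seed(54)
  trio <- simulate_species_trio(6, gene_length = 240, identities = c(0.9, 0.9),
                                seed = 54)
  pa <- trio$species$focal$proteins
  pb <- trio$species$neighbor1$proteins
  ab <- best_reciprocal_hits(pa, pb, min_identity = 0.5)
  ba <- best_reciprocal_hits(pb, pa, min_identity = 0.5)
  expect_equal(ab[order(ab$id_a), c("id_a", "id_b")],
               setNames(ba[order(ba$id_b), c("id_b", "id_a")],
                        c("id_a", "id_b")),
               ignore_attr = TRUE)
  strict <- best_reciprocal_hits(pa, pb, min_identity = 0.9,
                                 min_length_conservation = 0.95)
  loose <- best_reciprocal_hits(pa, pb, min_identity = 0.5,
                                min_length_conservation = 0.5)
  expect_true(all(paste(strict$id_a, strict$id_b) %in%
                    paste(loose$id_a, loose$id_b)))
})

test_that("pseudo core is the BRH intersection over both neighbors", {
  set.seed(55)
  trio <- simulate_species_trio(5, gene_length = 240, identities = c(1, 1),
                                seed = 55)
  sp <- trio$species
  core <- build_pseudo_core("focal", sp$focal$genes, sp$focal$proteins,
                            list(n1 = sp$neighbor1$proteins,
                                 n2 = sp$neighbor2$proteins))
  expect_setequal(names(core$genes), names(sp$focal$genes))

  ## a gene present only in neighbor 1 is excluded
  n2_missing <- sp$neighbor2$proteins[-1L]
  core2 <- build_pseudo_core("focal", sp$focal$genes, sp$focal$proteins,
                             list(n1 = sp$neighbor1$proteins, n2 = n2_missing))
  expect_setequal(names(core2$genes), names(sp$focal$genes)[-1L])

  expect_error(build_pseudo_core("focal", sp$focal$genes,
                                 sp$focal$proteins[-1L],
                                 list(sp$neighbor1$proteins,
                                      sp$neighbor2$proteins)),
               "ids differ")
})

test_that("core recovery follows realized protein identity across divergence", {
  near <- simulate_species_trio(6, gene_length = 300, identities = c(0.93, 0.93),
                                seed = 56)
  far <- simulate_species_trio(6, gene_length = 300, identities = c(0.5, 0.5),
                               seed = 57)
  core_near <- build_pseudo_core("f", near$species$focal$genes,
                                 near$species$focal$proteins,
                                 list(near$species$neighbor1$proteins,
                                      near$species$neighbor2$proteins))
  high <- near$truth$gene_id[near$truth$identity_aa1 >= 0.75 &
                               near$truth$identity_aa2 >= 0.75]
  expect_true(all(high %in% names(core_near$genes)))
  suppressWarnings(
    core_far <- build_pseudo_core("f", far$species$focal$genes,
                                  far$species$focal$proteins,
                                  list(far$species$neighbor1$proteins,
                                       far$species$neighbor2$proteins)))
  expect_length(core_far$genes, 0L)
})
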