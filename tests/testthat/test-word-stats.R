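test_that("count_word counts overlaps, respects boundaries and N windows", {
  expect_equal(count_word("GCTGGTGGCTGGTGG", "GCTGGTGG"), 2L)
  expect_equal(count_word("AAAA", "AA"), 3L)
  expect_equal(count_word(c("GCTG", "GTGG"), "GCTGGTGG"), 0L)
  expect_equal(count_word("AANAA", "AA"), 2L)
  expect_error(count_word("ACGT", "AXA"), "A,C,G,T")
})

test_that("count_word agrees with the naive scan on random sequences", {
  set.seed(41)
  for (i in 1:30) {
    seqs <- replicate(3, random_dna(sample(50:500, 1), gc = runif(1, 0.3, 0.7)))
    word <- random_dna(sample(1:6, 1))
    expect_equal(count_word(seqs, word), naive_count(seqs, word))
  }
  ## sequences containing N
  s <- "ACGTNACGTACNGT"
  for (w in c("AC", "ACGT", "GT")) {
    expect_equal(count_word(s, w), naive_count(s, w))
  }
})

test_that("k-mer tables are complete and consistent with window counts", {
  k1 <- count_all_kmers("ACGT", 1)
  expect_equal(as.numeric(k1[c("A", "C", "G", "T")]), c(1, 1, 1, 1))
  k2 <- count_all_kmers("ACGT", 2)
  expect_equal(sum(k2), 3)
  expect_equal(as.numeric(k2[c("AC", "CG", "GT")]), c(1, 1, 1))
  expect_equal(sum(count_all_kmers("ANA", 2)), 0)
  expect_warning(empty <- count_all_kmers("ACG", 5), "exceeds")
  expect_length(empty, 0L)
  set.seed(42)
  for (k in c(1, 3, 5)) {
    seqs <- replicate(3, random_dna(sample(20:200, 1)))
    expect_equal(sum(count_all_kmers(seqs, k)),
                 sum(pmax(nchar(seqs) - k + 1, 0)))
    word <- random_dna(k)
    expect_equal(unname(count_all_kmers(seqs, k)[word]),
                 as.numeric(count_word(seqs, word)))
  }
})

test_that("fit_markov stores counts giving the right transition probabilities", {
  m0 <- fit_markov("AAAA", 0)
  expect_equal(unname(m0$counts_m1[["A"]] / sum(m0$counts_m1)), 1)
  m1 <- fit_markov("AACA", 1)
  expect_equal(unname(m1$counts_m1[["AA"]]), 1)
  expect_equal(unname(m1$counts_m1[["AC"]]), 1)
  ## p(A|A) = p(C|A) = 0.5
  pa <- m1$counts_m1[c("AA", "AC", "AG", "AT")]
  expect_equal(unname(pa / sum(pa)), c(0.5, 0.5, 0, 0))
  expect_error(suppressWarnings(fit_markov("ACGTA", 6)), "no valid windows")
})

test_that("plug-in expectation reproduces hand computations", {
  m <- fit_markov("ATATATAT", 0)
  expect_equal(expected_count(m, "AT"), 2)  # N(A) N(T) / N(eps) = 4*4/8
  ## order-1 on a designed sequence: E = N(AT) N(TG) / N(T)
  s <- "ATGATGTT"
  m1 <- fit_markov(s, 1)
  expect_equal(expected_count(m1, "ATG"),
               count_word(s, "AT") * count_word(s, "TG") / count_word(s, "T"))
  ## order-5 on an octamer: 3 hexamer factors over 2 pentamer factors
  core <- random_dna(5000)
  m5 <- fit_markov(core, 5)
  w <- "GCTGGTGG"
  parts <- function(k) vapply(1:(8 - k + 1), function(j) substr(w, j, j + k - 1), "")
  num <- prod(vapply(parts(6), function(x) count_word(core, x), numeric(1)))
  den <- prod(vapply(parts(5)[2:3], function(x) count_word(core, x), numeric(1)))
  expect_equal(expected_count(m5, w), num / den)
})

test_that("plug-in identity holds at word length = order + 1", {
  set.seed(43)
  core <- c(random_dna(3000), random_dna(2000))
  m3 <- fit_markov(core, 3)
  obs <- count_all_kmers(core, 4)
  for (w in names(obs)) {
    expect_equal(expected_count(m3, w), as.numeric(obs[[w]]))
  }
})

test_that("vectorized expectations equal the scalar path", {
  set.seed(44)
  core <- random_dna(4000)
  for (m in c(0, 1, 2)) {
    model <- fit_markov(core, m)
    all4 <- chiscan:::expected_count_all(model, 4)
    pick <- sample(names(all4), 25)
    scalar <- vapply(pick, function(w) expected_count(model, w), numeric(1))
    expect_equal(unname(all4[pick]), unname(scalar))
  }
})

test_that("model simulation is deterministic and matches model frequencies", {
  m <- fit_markov("AAAA", 0)
  expect_equal(simulate_from_model(m, 5, seed = 1), "AAAAA")
  mod <- fit_markov(random_dna(20000, gc = 0.6), 1)
  s1 <- simulate_from_model(mod, c(1000, 2000), seed = 7)
  s2 <- simulate_from_model(mod, c(1000, 2000), seed = 7)
  expect_identical(s1, s2)
  expect_equal(nchar(s1), c(1000, 2000))
  ## law of large numbers: dinucleotide frequencies near model frequencies
  long <- simulate_from_model(mod, 2e5, seed = 8)
  emp <- count_all_kmers(long, 2)
  emp_p <- emp / sum(emp)
  mod_p <- mod$counts_m1 / sum(mod$counts_m1)
  se <- sqrt(mod_p * (1 - mod_p) / sum(emp))
  expect_true(all(abs(emp_p - mod_p) <= 3 * se + 1e-4))
})

test_that("bootstrap null mean tracks the plug-in expectation", {
  ## degenerate chain: count is deterministic, sd must be 0
  m <- fit_markov("AAAA", 0)
  nd <- null_distribution(m, 2, c(10, 20), B = 5, seed = 1)
  expect_equal(unname(nd$mean[["AA"]]), 9 + 19)
  expect_equal(unname(nd$sd[["AA"]]), 0)
  ## stochastic: mean within 4 standard errors of the plug-in expectation
  mod <- fit_markov(random_dna(50000), 1)
  nd <- null_distribution(mod, 6, 50000, B = 200, seed = 2)
  for (w in c("ACGTAC", "GCTGGT", "AAAAAA")) {
    ex <- expected_count(mod, w)
    se <- nd$sd[[w]] / sqrt(200)
    expect_lt(abs(nd$mean[[w]] - ex), 4 * se + 1e-9)
  }
  a <- null_distribution(mod, 4, 1000, B = 10, seed = 5)
  b <- null_distribution(mod, 4, 1000, B = 10, seed = 5)
  expect_identical(a, b)
})

test_that("z-scores have the right sign and flag planted overrepresentation", {
  set.seed(45)
  ## 50 copies of an A/T-rich gene with the Chi site planted densely
  gene <- random_dna(900, gc = 0.3)
  for (p in seq(50, 850, by = 100)) {
    substr(gene, p, p + 7) <- "GCTGGTGG"
  }
  core <- rep(gene, 50)
  st <- zscore_word(core, "GCTGGTGG", order = 0, B = 200, seed = 9)
  expect_true(st$evaluable)
  expect_gt(st$z, 4)
  ## absent word with positive expectation scores negative
  absent <- zscore_word(rep(random_dna(20000), 3), "ACGTACGT", order = 0,
                        B = 100, seed = 10)
  expect_lt(absent$z, 0)
  expect_equal(sign(absent$z), sign(absent$observed - absent$expected))
})

test_that("score_all_models shares the observed count across orders", {
  set.seed(46)
  core <- random_dna(20000)
  res <- score_all_models(core, "GCTGGTGG", orders = 0:5, B = 50, seed = 11)
  expect_equal(nrow(res), 6L)
  expect_length(unique(res$observed), 1L)
  single <- score_all_models(core, "GCTGGTGG", orders = 0, B = 50, seed = 11)
  expect_equal(nrow(single), 1L)
  again <- score_all_models(core, "GCTGGTGG", orders = 0:5, B = 50, seed = 11)
  expect_identical(res, again)
})
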