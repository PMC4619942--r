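test_that("the FPR formula matches its closed form and limits", {
  expect_equal(bloom_fpr(4, 1e6, 4e6 / log(2)), 0.5^4)  # optimal load
  expect_identical(bloom_fpr(4, 0, 1000), 0)
  n <- seq(1e3, 1e5, length.out = 20)
  expect_true(all(diff(bloom_fpr(4, n, 1e6)) > 0))  # monotone in n
  expect_error(bloom_fpr(4, 10, 0), "positive")
})

test_that("optimal hash count is (m/n) ln 2", {
  expect_equal(bloom_optimal_h(4 / log(2) * 1e6, 1e6), 4)
  expect_equal(bloom_optimal_h(1e5, 1e5), log(2))
  expect_equal(bloom_optimal_h(2e6, 1e3), 2 * bloom_optimal_h(1e6, 1e3))
  expect_error(bloom_optimal_h(10, 0), "positive")
})

test_that("size_for inverts the FPR formula minimally", {
  # storing the human genome at h = 4, f = 6.25% costs about 2 GiB
  m <- bloom_size_for(3e9, 4, 0.0625)
  expect_equal(m, ceiling(4 * 3e9 / log(2)), tolerance = 1e-9)
  expect_identical(round(m / 8 / 2^30), 2)
  # tightness and validity over random inputs
  set.seed(301)
  for (i in 1:20) {
    n <- sample(1e3:1e6, 1)
    f <- runif(1, 1e-6, 0.5)
    m <- bloom_size_for(n, 4, f)
    expect_lte(bloom_fpr(4, n, m), f)
    if (m > 1) expect_gt(bloom_fpr(4, n, m - 1), f)
  }
  expect_gte(bloom_size_for(10, 4, 0.999), 1)
})

test_that("insert reports pre-insert hits and membership is strand-folded", {
  tpl <- seed_template(15, 20)
  bf <- seed_bloom(1e6, tpl)
  set.seed(302)
  s <- rand_dna(30)
  expect_identical(unname(bloom_query(bf, s)[1, ]), rep(FALSE, 4))
  expect_identical(unname(bloom_insert(bf, s)[1, ]), rep(FALSE, 4))
  expect_identical(unname(bloom_insert(bf, s)[1, ]), rep(TRUE, 4))
  expect_true(bloom_contains(bf, s))
  expect_true(bloom_contains(bf, revcomp(s)))  # automatic strand canonicity
  p <- bloom_params(bf)
  expect_identical(p$n_inserted, 2)
  expect_error(bloom_insert(bf, "ACGT"), "2k")
})

test_that("there are never false negatives, on either strand", {
  tpl <- seed_template(15, 10)
  bf <- seed_bloom(5e5, tpl)
  set.seed(303)
  seeds <- vapply(1:5000, function(i) rand_dna(30), character(1))
  bloom_insert(bf, seeds)
  expect_true(all(bloom_contains(bf, seeds)))
  expect_true(all(bloom_contains(bf, revcomp(seeds))))
})

test_that("a single-base edit at an even right-half position leaves the
           left and odd hash values hitting", {
  tpl <- seed_template(31, 0)
  bf <- seed_bloom(2^24, tpl)
  set.seed(304)
  s <- rand_dna(62)
  bloom_insert(bf, s)
  q <- s
  substr(q, 58, 58) <- setdiff(ORACLE_BASES, substr(s, 58, 58))[1]  # even, right
  hits <- bloom_query(bf, q)[1, ]
  expect_true(hits[["xL"]] && hits[["xO"]])
  expect_false(hits[["xR"]] || hits[["xE"]])  # whp in a large sparse filter
})

test_that("empirical FPR tracks the formula across loads", {
  tpl <- seed_template(31, 10)
  set.seed(305)
  n <- 5000
  train <- vapply(seq_len(n), function(i) rand_dna(62), character(1))
  probe <- vapply(seq_len(n), function(i) rand_dna(62), character(1))
  for (load in c(0.25, log(2), 1.0)) {
    m <- round(4 * n / load)
    bf <- seed_bloom(m, tpl)
    bloom_insert(bf, train)
    fpr_hat <- mean(bloom_contains(bf, probe))
    f <- bloom_fpr(4, n, m)
    expect_lt(abs(fpr_hat - f), 4 * sqrt(f * (1 - f) / n) + 1e-4)
  }
})

test_that("the lone k-mer sub-query supports the small length scale", {
  tpl <- seed_template(15, 30)
  bf <- seed_bloom(2^22, tpl)
  set.seed(306)
  s <- rand_dna(60)
  bloom_insert_read(bf, s)
  expect_true(bloom_kmer_contains(bf, substr(s, 1, 15)))
  expect_true(bloom_kmer_contains(bf, revcomp(substr(s, 1, 15))))
  expect_false(bloom_kmer_contains(bf, rand_dna(15)))
  expect_error(bloom_kmer_contains(bf, "ACGT"), "length")
})

test_that("serialization round-trips the filter bit for bit", {
  tpl <- seed_template(15, 20)
  bf <- seed_bloom(12345, tpl)
  set.seed(307)
  seeds <- vapply(1:200, function(i) rand_dna(30), character(1))
  bloom_insert(bf, seeds)
  path <- tempfile(fileext = ".ssbf")
  on.exit(unlink(path))
  bloom_save(bf, path)
  bf2 <- bloom_load(path)
  expect_identical(bloom_params(bf2), bloom_params(bf))
  expect_identical(bloom_query(bf2, seeds), bloom_query(bf, seeds))
  probes <- vapply(1:500, function(i) rand_dna(30), character(1))
  expect_identical(bloom_query(bf2, probes), bloom_query(bf, probes))
})
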