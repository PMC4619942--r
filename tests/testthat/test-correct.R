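test_that("hit patterns classify into the four action classes", {
  expect_identical(classify_pattern(c(TRUE, TRUE, TRUE, TRUE)), "present")
  singles <- list(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, FALSE, TRUE),
                  c(FALSE, TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE, TRUE))
  for (p in singles)
    expect_identical(classify_pattern(p), "single-correctable")
  # three hits, no hits, and the non-localising two-hit pairs are absent
  for (p in list(c(TRUE, TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE, TRUE),
                 c(TRUE, FALSE, TRUE, TRUE), c(FALSE, TRUE, TRUE, TRUE),
                 c(FALSE, FALSE, FALSE, FALSE),
                 c(TRUE, TRUE, FALSE, FALSE), c(FALSE, FALSE, TRUE, TRUE)))
    expect_identical(classify_pattern(p), "absent")
  for (p in list(c(TRUE, FALSE, FALSE, FALSE), c(FALSE, FALSE, TRUE, FALSE)))
    expect_identical(classify_pattern(p), "double-flagged")
  # matrix form classifies row-wise
  m <- rbind(rep(TRUE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(classify_pattern(m), c("present", "single-correctable"))
})

test_that("candidate positions are the missed half intersected with the
           missed parity", {
  expect_identical(locate_candidates(c(TRUE, FALSE, TRUE, FALSE), 8),
                   c(10L, 12L, 14L, 16L))  # right half, even
  expect_identical(locate_candidates(c(FALSE, TRUE, FALSE, TRUE), 8),
                   c(1L, 3L, 5L, 7L))      # left half, odd
  expect_identical(locate_candidates(c(TRUE, FALSE, FALSE, TRUE), 8),
                   c(9L, 11L, 13L, 15L))   # right half, odd
  for (k in c(4, 8, 15)) {
    cand <- locate_candidates(c(FALSE, TRUE, TRUE, FALSE), k)
    expect_identical(length(cand), as.integer(floor(k / 2)))
    expect_true(all(cand >= 1 & cand <= 2 * k))  # inside s2k, never the gap
  }
  expect_error(locate_candidates(c(TRUE, TRUE, TRUE, TRUE), 8),
               "single-correctable")
})

test_that("try_correct recovers a planted single-base error", {
  tpl <- seed_template(25, 0)
  bf <- seed_bloom(2^24, tpl)
  set.seed(701)
  s <- rand_dna(50)
  bloom_insert(bf, s)
  bad <- s
  substr(bad, 40, 40) <- setdiff(ORACLE_BASES, substr(s, 40, 40))[1]
  res <- try_correct(bad, bf)
  expect_identical(res$status, "corrected")
  expect_identical(res$s2k, s)
  expect_identical(res$pos, 40L)
  # a present seed is left untouched and updates the counter when given
  cc <- cascade_counter(2^22, tpl)
  cascade_add(cc, s)
  expect_identical(try_correct(s, bf, counter = cc)$status, "present")
  expect_identical(cascade_count(cc, s)$estimate, 2)
})

test_that("absent-class seeds are inserted rather than corrected", {
  tpl <- seed_template(25, 0)
  bf <- seed_bloom(2^24, tpl)
  set.seed(702)
  s <- rand_dna(50)
  res <- try_correct(s, bf)       # empty filter: pattern (0,0,0,0)
  expect_identical(res$status, "inserted")
  expect_true(bloom_contains(bf, s))
})

test_that("error-free reads pass through unchanged", {
  tpl <- seed_template(15, 20)
  set.seed(703)
  g <- sim_genome(2000)
  bf <- seed_bloom(2^22, tpl)
  bloom_insert_read(bf, g)
  r <- substr(g, 101, 250)
  res <- correct_read(r, tpl, bf)
  expect_identical(res$read, r)
  expect_identical(nrow(res$changes), 0L)
  # reads shorter than the span are returned untouched
  res <- correct_read("ACGT", tpl, bf)
  expect_identical(res$read, "ACGT")
})

test_that("an error in the gap does not disturb the window", {
  tpl <- seed_template(15, 20)  # span 50; gap positions 16..35
  set.seed(704)
  g <- rand_dna(50)
  bf <- seed_bloom(2^22, tpl)
  bloom_insert_read(bf, g)
  bad <- g
  substr(bad, 20, 20) <- setdiff(ORACLE_BASES, substr(g, 20, 20))[1]
  expect_identical(unname(bloom_query_read(bf, bad)$hits[1, ]), rep(TRUE, 4))
  res <- correct_read(bad, tpl, bf)
  expect_identical(res$read, bad)  # no action required, by construction
  expect_identical(nrow(res$changes), 0L)
})

test_that("single planted substitutions are corrected at high recall
           with no false changes", {
  tpl <- seed_template(25, 50)
  set.seed(705)
  g <- sim_genome(4000)
  bf <- seed_bloom(bloom_size_for(4000, 4, 1e-8), tpl)
  bloom_insert_read(bf, g)
  reads <- sim_reads(g, 150, 5, 0)
  n <- min(nrow(reads), 120)
  hits <- 0; false_changes <- 0
  for (i in seq_len(n)) {
    r <- reads$seq[i]
    p <- sample(150, 1)
    truth <- substr(r, p, p)
    bad <- r
    substr(bad, p, p) <- sample(setdiff(ORACLE_BASES, truth), 1)
    res <- correct_read(bad, tpl, bf)
    hits <- hits + (res$read == r)
    ok_change <- nrow(res$changes) >= 1 &&
      any(res$changes$pos == p - 1 & res$changes$to == truth)
    false_changes <- false_changes + nrow(res$changes) - ok_change
  }
  expect_gte(hits / n, 0.95)
  expect_lte(false_changes / n, 0.01)
})

test_that("quality gating blocks corrections at confident bases", {
  tpl <- seed_template(25, 0)
  bf <- seed_bloom(2^24, tpl)
  set.seed(706)
  g <- rand_dna(50)
  bloom_insert(bf, g)
  bad <- g
  substr(bad, 10, 10) <- setdiff(ORACLE_BASES, substr(g, 10, 10))[1]
  qual_hi <- rep(40L, 50)
  res <- correct_read(bad, tpl, bf, quality = qual_hi, quality_threshold = 20)
  expect_identical(res$read, bad)  # Q40 >= Q20: no commit
  qual_lo <- rep(10L, 50)
  bf2 <- seed_bloom(2^24, tpl)
  bloom_insert(bf2, g)
  res <- correct_read(bad, tpl, bf2, quality = qual_lo,
                      quality_threshold = 20)
  expect_identical(res$read, g)
})

test_that("foreign reads are inserted wholesale and left unchanged", {
  tpl <- seed_template(25, 20)
  set.seed(707)
  g <- sim_genome(2000)
  bf <- seed_bloom(2^22, tpl)
  bloom_insert_read(bf, g)
  alien <- rand_dna(150)
  res <- correct_read(alien, tpl, bf)
  expect_identical(res$read, alien)
  expect_identical(nrow(res$changes), 0L)
  expect_true(all(rowSums(bloom_query_read(bf, alien)$hits) == 4))
})

test_that("correct_reads aggregates per-read change logs", {
  tpl <- seed_template(25, 50)
  set.seed(708)
  g <- sim_genome(3000)
  bf <- seed_bloom(bloom_size_for(3000, 4, 1e-8), tpl)
  bloom_insert_read(bf, g)
  reads <- sim_reads(g, 150, 1, 0)[1:10, ]
  bad <- reads
  substr(bad$seq[3], 60, 60) <-
    setdiff(ORACLE_BASES, substr(reads$seq[3], 60, 60))[1]
  res <- correct_reads(bad, tpl, bf, quality_threshold = 50)
  expect_identical(res$reads$seq, reads$seq)
  expect_identical(unique(res$changes$id), reads$id[3])
})
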