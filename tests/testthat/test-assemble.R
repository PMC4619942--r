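test_that("a single read contributes two blunt edges", {
  tpl <- seed_template(15, 20)
  set.seed(801)
  r <- rand_dna(120)
  g <- build_graph(r, tpl)
  blunt <- g$aux[g$aux$type == "blunt", ]
  expect_identical(nrow(blunt), 2L)
  expect_identical(sort(blunt$side), c("left", "right"))
  expect_identical(blunt$seq[blunt$side == "left"], substr(r, 1, 50))
  expect_identical(blunt$seq[blunt$side == "right"], substr(r, 71, 120))
  # with no extensions in the filter, garbage collection keeps both
  expect_identical(nrow(garbage_collect(g$aux, g$filter)), 2L)
})

test_that("garbage collection prunes interior blunt ends of tiling reads", {
  tpl <- seed_template(15, 20)
  set.seed(802)
  genome <- rand_dna(300)
  reads <- c(substr(genome, 1, 180), substr(genome, 100, 300))
  g <- build_graph(reads, tpl)
  pruned <- garbage_collect(g$aux, g$filter)
  expect_identical(nrow(pruned), 2L)  # only the two true sequence ends
  expect_setequal(pruned$seq, c(substr(genome, 1, 50),
                                substr(genome, 251, 300)))
  # idempotent with no new reads; empty list passes through
  expect_identical(garbage_collect(pruned, g$filter), pruned)
  expect_identical(nrow(garbage_collect(g$aux[0, ], g$filter)), 0L)
})

test_that("the second sequence across a junction is caught as a branch", {
  tpl <- seed_template(15, 20)
  set.seed(803)
  A <- rand_dna(120); X <- rand_dna(80); Y <- rand_dna(80); B <- rand_dna(120)
  g <- build_graph(c(paste0(A, X), paste0(A, Y)), tpl)
  branches <- g$aux[g$aux$type == "branch", ]
  expect_gte(nrow(branches), 1L)
  # the captured junction window lies inside the shared prefix A
  expect_true(any(vapply(branches$seq, grepl, logical(1), x = paste0(A, Y),
                         fixed = TRUE) |
                  vapply(branches$seq, grepl, logical(1), x = paste0(A, X),
                         fixed = TRUE)))
})

test_that("extension reconstructs a clean linear genome exactly", {
  tpl <- seed_template(25, 20)  # 4^13 fold values: safely above ~1.5e3 seeds
  set.seed(804)
  genome <- rand_dna(1500)
  bf <- seed_bloom(bloom_size_for(1500, 4, 1e-12), tpl)
  bloom_insert_read(bf, genome)
  ct <- extend_contig(substr(genome, 1, tpl$span), bf)
  expect_identical(ct$seq, genome)
  expect_identical(ct$terminated_by, "blunt-end")
  expect_error(extend_contig(rand_dna(tpl$span), bf), "not present")
})

test_that("a circular sequence terminates the walk as circular", {
  tpl <- seed_template(25, 20)
  set.seed(805)
  genome <- rand_dna(800)
  wrapped <- paste0(genome, substr(genome, 1, tpl$span - 1))
  bf <- seed_bloom(bloom_size_for(1000, 4, 1e-12), tpl)
  bloom_insert_read(bf, wrapped)
  ct <- extend_contig(substr(wrapped, 1, tpl$span), bf)
  expect_identical(ct$terminated_by, "circular")
  expect_gte(ct$length, 800)
})

test_that("short dead-end branches are trimmed at the 2k - 1 default", {
  tpl <- seed_template(15, 20)
  ctgs <- data.frame(
    seq = c("x", "y", "z"), length = c(51, 80, 120),
    terminated_by = c("blunt-end", "blunt-end", "branch"),
    start_type = c("branch", "branch", "branch"),
    n_extended = c(1L, 30L, 5L))
  out <- trim_branches(ctgs, tpl)
  # the length-1 spur goes; the 30-base (>= 29) branch and the
  # branch-terminated contig stay
  expect_identical(out$n_extended, c(30L, 5L))
  expect_identical(trim_branches(ctgs, tpl, min_len = 40)$n_extended, 5L)
  expect_identical(nrow(trim_branches(ctgs[0, ], tpl)), 0L)
})

test_that("false branches die geometrically even genome-wide", {
  # at f = 6.25%, a false branch of length 10 survives 3e9 tests with
  # probability below 0.3%
  expect_lt(false_branch_prob(0.0625, 10, 3e9), 0.003)
  expect_identical(false_branch_prob(0.5, 1), 0.5)
  expect_true(all(diff(false_branch_prob(0.0625, 1:10)) < 0))
})

test_that("assembly of a clean genome yields one exact contig", {
  tpl <- seed_template(25, 50)
  g <- sim_genome(3000, seed = 806)
  reads <- sim_reads(g, 150, 30, 0, seed = 807)
  ctgs <- assemble_reads(reads, tpl, two_scale = TRUE)
  expect_identical(nrow(ctgs), 1L)
  expect_true(is_exact_substring(ctgs$seq[1], g))
  expect_gte(ctgs$length[1], 0.99 * nchar(g))
  expect_identical(nrow(assemble_reads(character(), tpl)), 0L)
})

test_that("contigs re-validate: every window is present in the filter", {
  tpl <- seed_template(25, 50)
  g <- sim_genome(2000, seed = 808)
  reads <- sim_reads(g, 150, 30, 0, seed = 809)
  gr <- build_graph(reads, tpl)
  aux <- garbage_collect(gr$aux, gr$filter)
  ct <- extend_contig(aux$seq[1], gr$filter)
  hits <- bloom_query_read(gr$filter, ct$seq)$hits
  expect_true(all(rowSums(hits) == 4L))
})

test_that("spaced seeds resolve repeats that break a plain 2k-mer DBG", {
  tpl <- seed_template(25, 50)  # resolves exact repeats of length < 99
  g <- sim_genome(4000,
                  repeat_spec = data.frame(count = 2, length = 70,
                                           divergence = 0),
                  seed = 810)
  reads <- sim_reads(g, 150, 30, 0, seed = 811)
  ctgs <- assemble_reads(reads, tpl, two_scale = TRUE)
  expect_identical(nrow(ctgs), 1L)
  expect_true(is_exact_substring(ctgs$seq[1], g))
  # the contiguous 50-mer oracle fragments at the 70-base repeat
  oracle <- plain_dbg_contigs(reads$seq, 2 * tpl$k)
  expect_gt(length(oracle), 1L)
  expect_lt(max(nchar(oracle)), 0.99 * nchar(g))
})

test_that("the scale-k fallback bridges a window-scale coverage dip", {
  tpl <- seed_template(25, 30)  # span 80
  set.seed(812)
  genome <- rand_dna(1200)
  # two read fragments leave a window-scale hole around position 620:
  # every k-mer there is observed, but no full span window is
  gap_reads <- c(substr(genome, 1, 640), substr(genome, 580, 1200))
  gr <- build_graph(gap_reads, tpl, m = 2^24)
  start <- substr(genome, 1, tpl$span)
  plain <- extend_contig(start, gr$filter, two_scale = FALSE)
  rescue <- extend_contig(start, gr$filter, two_scale = TRUE)
  expect_lt(plain$length, nchar(genome))
  expect_gt(rescue$length, plain$length)
})
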