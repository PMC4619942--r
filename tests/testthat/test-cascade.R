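# byte helpers for state construction
Z <- 0L          # +0
NEG0 <- 128L     # -0, the collision flag
CNT <- function(v, sign = 0L) bitwOr(mf_encode_exact(v), sign * 128L)

test_that("the stage-2 update rule reproduces the full 9-case truth table", {
  cases <- list(
    list(Z,         Z,         "set_x",          CNT(2),        Z),
    list(Z,         NEG0,      "set_x",          CNT(2),        NEG0),
    list(CNT(3),    Z,         "increment_x",    CNT(4),        Z),
    list(CNT(3),    NEG0,      "increment_x",    CNT(4),        NEG0),
    list(Z,         CNT(3),    "increment_xp",   Z,             CNT(4, 1L)),
    list(NEG0,      CNT(3),    "increment_xp",   NEG0,          CNT(4, 1L)),
    list(CNT(5),    CNT(9),    "flag_collision", NEG0,          NEG0),
    list(NEG0,      NEG0,      "flag_collision", NEG0,          NEG0),
    list(NEG0,      Z,         "set_xp",         NEG0,          CNT(2, 1L))
  )
  for (cs in cases) {
    res <- cascade_update_rule(cs[[1]], cs[[2]])
    expect_identical(res$action, cs[[3]])
    expect_identical(res$vx, cs[[4]])
    expect_identical(res$vxp, cs[[5]])
  }
  # an already-set strand sign survives an increment of x
  res <- cascade_update_rule(CNT(5, 1L), Z)
  expect_identical(res$vx, CNT(6, 1L))
})

test_that("seeds cascade to stage 2 only from the second observation", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(2^22, tpl)
  set.seed(501)
  s <- rand_dna(30)
  expect_identical(cascade_count(cc, s)$estimate, 0)      # never observed
  expect_identical(as.integer(cpp <- cascade_add(cc, s)), 1L)
  res <- cascade_count(cc, s)
  expect_identical(res$estimate, 1)                        # stage 1 only
  expect_false(res$both_strands)
  expect_identical(as.integer(cascade_add(cc, s)), 2L)
  # the byte at coordinate x now holds count 2, sign 0
  xy <- cascade_coords(cc, s)
  byte <- as.integer(spacedseeds:::cpp_cascade_bytes(cc$ptr)[xy[["x"]] + 1])
  expect_identical(byte, CNT(2))
  expect_identical(cascade_count(cc, s)$estimate, 2)
})

test_that("mixed-strand observations set the sticky both-strands sign", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(2^22, tpl)
  set.seed(502)
  s <- rand_dna(30)
  cascade_add(cc, s)             # stage 1
  cascade_add(cc, revcomp(s))    # cascades; populates the RC coordinate
  cascade_add(cc, s)             # finds x' nonzero -> increment, sign := 1
  res <- cascade_count(cc, s)
  expect_identical(res$estimate, 3)
  expect_true(res$both_strands)
  expect_false(res$collided)
})

test_that("counts up to 16 are exact; the coordinate pair is strand-symmetric", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(2^22, tpl)
  set.seed(503)
  s <- rand_dna(30)
  cascade_add(cc, rep(s, 20))
  res <- cascade_count(cc, s)
  expect_identical(res$estimate, 20)  # within the unit-gap range plus 18,20
  expect_identical(cascade_count(cc, revcomp(s))$estimate, 20)
  xy <- cascade_coords(cc, s)
  yx <- cascade_coords(cc, revcomp(s))
  expect_identical(unname(xy), unname(yx[c("xp", "x")]))
})

test_that("decoded counts equal a brute-force multiset oracle when
           collision-free", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(2^24, tpl, m2 = 2^20)
  set.seed(504)
  seeds <- vapply(1:60, function(i) rand_dna(30), character(1))
  truth <- sample(1:15, 60, replace = TRUE)
  # verify the collision-free regime by construction
  coords <- t(vapply(seeds, function(s) cascade_coords(cc, s), numeric(2)))
  expect_identical(anyDuplicated(as.vector(coords)), 0L)
  stream <- sample(rep(seeds, truth))
  for (s in stream) cascade_add(cc, s)
  res <- cascade_count(cc, seeds)
  expect_identical(res$estimate, as.numeric(truth))
  expect_true(!any(res$collided))
})

test_that("coordinate-pair collisions are flagged with negative zero", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(2^22, tpl, m2 = 2)  # two bytes force clashes
  set.seed(505)
  # a regular seed occupying both coordinates ...
  a <- NULL
  for (i in 1:200) {
    cand <- rand_dna(30)
    ca <- cascade_coords(cc, cand)
    if (ca[["x"]] != ca[["xp"]]) { a <- cand; break }
  }
  expect_false(is.null(a))
  ca <- cascade_coords(cc, a)
  # ... and an RC-palindromic seed whose single coordinate is a's x'
  d <- NULL
  for (i in 1:200) {
    w <- rand_dna(15)
    cand <- paste0(w, r_revcomp(w))
    if (cascade_coords(cc, cand)[["x"]] == ca[["xp"]]) { d <- cand; break }
  }
  expect_false(is.null(d))
  cascade_add(cc, c(a, a))  # byte at x(a) counts 2
  cascade_add(cc, c(d, d))  # byte at x'(a) counts 2 (palindromic path)
  cascade_add(cc, a)        # both coordinates nonzero: hash collision
  res <- cascade_count(cc, a)
  expect_true(res$collided)
  expect_true(is.na(res$estimate))
})

test_that("read-level adds agree with seed-level adds", {
  tpl <- seed_template(5, 4)
  cc1 <- cascade_counter(2^20, tpl)
  cc2 <- cascade_counter(2^20, tpl)
  set.seed(506)
  r <- rand_dna(40)
  cascade_add_read(cc1, r)
  cascade_add_read(cc1, r)
  seeds <- extract_seeds(r, tpl)
  cascade_add(cc2, seeds)
  cascade_add(cc2, seeds)
  expect_identical(cascade_count(cc1, seeds), cascade_count(cc2, seeds))
})

test_that("cascade serialization round-trips both stages", {
  tpl <- seed_template(15, 20)
  cc <- cascade_counter(40000, tpl, m2 = 5000)
  set.seed(507)
  seeds <- vapply(1:50, function(i) rand_dna(30), character(1))
  cascade_add(cc, c(seeds, seeds, seeds))
  path <- tempfile(fileext = ".sscc")
  on.exit(unlink(path))
  cascade_save(cc, path)
  cc2 <- cascade_load(path)
  expect_identical(cascade_params(cc2), cascade_params(cc))
  expect_identical(cascade_count(cc2, seeds), cascade_count(cc, seeds))
})
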