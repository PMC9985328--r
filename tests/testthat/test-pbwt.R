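# Positional Burrows-Wheeler transform and block enumeration.

test_that("pbwt_step reproduces hand-traced updates", {
  # identical rows: order unchanged, d stays minimal (all prefixes equal)
  st <- pbwt_init(3)
  for (j in 1:4) st <- pbwt_step(st, c(1, 1, 1))
  expect_equal(st$a, 1:3)
  expect_equal(st$d, c(5L, 1L, 1L))

  # first column (0,1,0): rows {1,3} sort before {2}, d marks the break
  st <- pbwt_step(pbwt_init(3), c(0, 1, 0))
  expect_equal(st$a, c(1L, 3L, 2L))
  expect_equal(st$d, c(2L, 1L, 2L))
})

test_that("pbwt divergence values delimit the longest common suffixes", {
  set.seed(11)
  m <- random_haplo_matrix(8, 12)
  st <- pbwt_init(8)
  for (j in 1:12) {
    st <- pbwt_step(st, m$alleles[, j])
    for (r in 2:8) {
      a1 <- st$a[r - 1]; a2 <- st$a[r]; d <- st$d[r]
      if (d <= j)
        expect_true(all(m$alleles[a1, d:j] == m$alleles[a2, d:j]))
      if (d > 1 && d <= j + 1)
        expect_false(isTRUE(m$alleles[a1, d - 1] == m$alleles[a2, d - 1]))
    }
  }
})

test_that("enumerate_blocks matches the worked examples", {
  m <- haplotype_matrix(rbind(c(0, 1, 0, 1), c(0, 1, 0, 0), c(1, 1, 0, 0)),
                        1:4, 0.01 * (1:4))
  b <- enumerate_blocks(m, materialize_rows = TRUE)
  b$rows <- lapply(b$rows, sort)
  expect_setequal(block_keys(b),
                  c("1|3|2|1,2", "2|3|3|1,2,3", "2|4|2|2,3"))

  # complementary rows share nothing
  m2 <- haplotype_matrix(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1:4, 0.01 * (1:4))
  expect_equal(nrow(enumerate_blocks(m2)), 0)

  # identical rows force the single full-matrix block
  m3 <- haplotype_matrix(matrix(c(0, 1, 1, 0, 1)[c(1:5, 1:5, 1:5)],
                                3, 5, byrow = TRUE), 1:5, 0.01 * (1:5))
  b3 <- enumerate_blocks(m3, materialize_rows = TRUE)
  expect_equal(nrow(b3), 1)
  expect_equal(c(b3$i, b3$j, b3$k_block), c(1, 5, 3))

  # single column, rows (0,0,1)
  m4 <- haplotype_matrix(matrix(c(0, 0, 1), 3, 1), 1, 0)
  b4 <- naive_blocks(m4)
  expect_equal(nrow(b4), 1)
  expect_equal(sort(b4$rows[[1]]), c(1, 2))
})

test_that("a two-block fixture in four sequences is found by both routes", {
  # three rows share one 6-site run, two rows share one 9-site run; the
  # pair's run must leave part of the trio's run uncovered, otherwise
  # row-maximality absorbs the fourth row into the trio block
  set.seed(42)
  for (try in 1:200) {
    fix <- planted_matrix(4, 11,
                          list(list(rows = 1:3, i = 1, j = 6),
                               list(rows = c(3, 4), i = 3, j = 11)),
                          seed = sample.int(1e6, 1))
    tr <- fix$truth
    has6 <- any(tr$k_block == 3 & tr$j - tr$i + 1 == 6)
    has9 <- any(tr$k_block == 2 & tr$j - tr$i + 1 == 9)
    if (has6 && has9) break
  }
  expect_true(has6 && has9)
  eb <- enumerate_blocks(fix$matrix, materialize_rows = TRUE)
  eb$rows <- lapply(eb$rows, sort)
  expect_setequal(block_keys(eb), block_keys(tr))
})

test_that("pBWT and naive enumeration agree on random matrices", {
  set.seed(7)
  for (t in 1:400) {
    k <- sample(2:12, 1); n <- sample(1:24, 1)
    p <- sample(c(0.1, 0.5), 1)
    m <- random_haplo_matrix(k, n, p)
    nb <- naive_blocks(m)
    eb <- enumerate_blocks(m, materialize_rows = TRUE)
    eb$rows <- lapply(eb$rows, sort)
    expect_setequal(block_keys(eb), block_keys(nb))
  }
})

test_that("per-column candidates stay below k and blocks are maximal", {
  set.seed(13)
  for (t in 1:25) {
    m <- random_haplo_matrix(sample(4:10, 1), sample(6:20, 1))
    eb <- enumerate_blocks(m, materialize_rows = TRUE)
    if (nrow(eb) == 0) next
    expect_true(all(table(eb$j) <= m$k))
    for (b in seq_len(nrow(eb)))
      expect_true(block_is_maximal(m, eb$i[b], eb$j[b], eb$rows[[b]]))
  }
})

test_that("min_sites excludes single-column blocks when requested", {
  set.seed(3)
  m <- random_haplo_matrix(6, 10)
  all_b <- enumerate_blocks(m, min_sites = 1L)
  multi <- enumerate_blocks(m, min_sites = 2L)
  expect_equal(multi, all_b[all_b$j - all_b$i + 1 >= 2, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("enumeration time grows about linearly in the number of sites", {
  set.seed(19)
  k <- 300
  m1 <- random_haplo_matrix(k, 2000)
  m2 <- haplotype_matrix(cbind(m1$alleles, m1$alleles,
                               matrix(rbinom(k * 4000, 1, 0.5), k)),
                         seq_len(8000), 0.01 * seq_len(8000))
  t1 <- system.time(for (i in 1:3) enumerate_blocks(m1))[3]
  t2 <- system.time(for (i in 1:3) enumerate_blocks(m2))[3]
  # 4x the sites: allow a generous factor over the proportional cost
  expect_lt(t2, 4 * max(t1, 0.05) * 4)
})

test_that("annotate_geometry fills frequency, map length and r", {
  m <- haplotype_matrix(rbind(c(0, 1, 0, 1), c(0, 1, 0, 0), c(1, 1, 0, 0)),
                        c(100, 250, 300, 900), c(0, 0.5, 0.5, 50.5))
  b <- annotate_geometry(enumerate_blocks(m), m)
  one <- b[b$i == 2 & b$j == 4, ]
  expect_equal(one$y_freq, 2 / 3)
  expect_equal(one$d_cm, 50)
  expect_equal(one$r, (1 - exp(-1)) / 2, tolerance = 1e-12)
  same <- b[b$i == b$j, ]
  if (nrow(same)) expect_true(all(same$d_cm == 0 & same$r == 0))
  expect_true(all(b$start_bp == m$pos_bp[b$i] & b$end_bp == m$pos_bp[b$j]))
})
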