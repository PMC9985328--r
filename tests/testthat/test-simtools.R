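# Simulation toolbox.

test_that("planted matrices carry their blocks and agree with the oracle", {
  fix <- planted_matrix(5, 12, list(list(rows = c(1, 2, 4), i = 3, j = 9)),
                        seed = 5)
  tr <- fix$truth
  # some truth block covers at least the planted rows and columns
  covered <- any(vapply(seq_len(nrow(tr)), function(b)
    all(c(1, 2, 4) %in% tr$rows[[b]]) && tr$i[b] <= 3 && tr$j[b] >= 9, TRUE))
  expect_true(covered)
  # truth is exactly the naive enumeration of the generated matrix
  expect_setequal(block_keys(tr), block_keys(naive_blocks(fix$matrix)))
  # no planted blocks: still oracle-defined
  fix0 <- planted_matrix(2, 4, seed = 9)
  expect_setequal(block_keys(fix0$truth), block_keys(naive_blocks(fix0$matrix)))
  # determinism
  expect_identical(planted_matrix(5, 12, seed = 5)$matrix$alleles,
                   planted_matrix(5, 12, seed = 5)$matrix$alleles)
})

test_that("neutral simulations match coalescent expectations", {
  spec <- sweep_sim_spec(region_bp = 2e5, n_sample_diploid = 5, maf_min = 0)
  nS <- numeric(8); npi <- numeric(8)
  for (i in 1:8) {
    sim <- simulate_neutral(spec, seed = 400 + i)
    al <- sim$matrix$alleles; k <- nrow(al)
    nS[i] <- sim$matrix$n
    npi[i] <- 2 * sum(colMeans(al) * (1 - colMeans(al))) * k / (k - 1) / 2e5
  }
  theta <- 4 * 1e4 * 2.5e-8
  ES <- theta * 2e5 * sum(1 / (1:9))
  expect_lt(abs(mean(nS) - ES), 3 * sd(nS) / sqrt(8) + 0.05 * ES)
  expect_lt(abs(mean(npi) - theta), 0.25 * theta)
  # reproducible from seed, map aligned with the matrix
  a <- simulate_neutral(spec, seed = 409)
  b <- simulate_neutral(spec, seed = 409)
  expect_identical(a$matrix$alleles, b$matrix$alleles)
  expect_equal(a$map$bp, a$matrix$pos_bp)
})

test_that("sweep simulations hit the conditioning target and are pure in the seed", {
  spec <- sweep_sim_spec(region_bp = 3e5, n_sample_diploid = 250,
                         s_true = 0.05, target_freq = 0.5)
  sw <- simulate_sweep(spec, seed = 21)
  expect_false(sw$lost)
  expect_lt(abs(sw$freq_sample - 0.5), 0.05)
  expect_equal(sw$sel_pos, 1.5e5)
  sw2 <- simulate_sweep(spec, seed = 21)
  expect_identical(sw$matrix$alleles, sw2$matrix$alleles)
  # the selected site is present at the conditioned frequency
  sel_col <- which(sw$matrix$pos_bp == sw$sel_pos)
  expect_length(sel_col, 1)
  expect_equal(mean(sw$matrix$alleles[, sel_col]), sw$freq_sample)
})

test_that("an exhausted retry budget labels the replicate as a loss", {
  spec <- sweep_sim_spec(region_bp = 1e5, n_sample_diploid = 50,
                         s_true = 0.005, target_freq = 0.9)
  set.seed(1)
  sw <- simulate_sweep(spec, seed = 3, max_tries = 2)
  expect_true(sw$lost)
  expect_equal(sw$freq_sample, 0)
  expect_s3_class(sw$matrix, "haplo_matrix")
})

test_that("SNP downsampling preserves order and matches a target spectrum", {
  spec <- sweep_sim_spec(region_bp = 1e5, n_sample_diploid = 50, maf_min = 0)
  sim <- simulate_neutral(spec, seed = 77)
  m <- sim$matrix
  expect_identical(downsample_snps(m, m$n), m)
  d1 <- downsample_snps(m, 50, seed = 3)
  d2 <- downsample_snps(m, 50, seed = 3)
  expect_identical(d1$alleles, d2$alleles)
  expect_true(all(diff(d1$pos_bp) > 0))
  expect_true(all(d1$pos_bp %in% m$pos_bp))
  # spectrum matching: use an achievable 20-bin target
  maf <- pmin(colMeans(m$alleles), 1 - colMeans(m$alleles))
  bins <- pmin(pmax(ceiling(maf / 0.5 * 20), 1), 20)
  w <- tabulate(bins, 20) / m$n
  target_n <- floor(m$n / 2)
  ds <- downsample_snps(m, target_n, afs_weights = w, seed = 11)
  maf2 <- pmin(colMeans(ds$alleles), 1 - colMeans(ds$alleles))
  bins2 <- pmin(pmax(ceiling(maf2 / 0.5 * 20), 1), 20)
  got <- tabulate(bins2, 20) / ds$n
  expect_lt(sum(abs(got - w)) / 2, 0.05)
})
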