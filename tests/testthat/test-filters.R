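# Drift and recent-common-ancestry filters.

test_that("allele age CDF behaves and inverts exactly", {
  expect_equal(allele_age_cdf(0, 0.5, 1000), 0.5^999)
  t <- sort(runif(40, 0, 5))
  expect_true(all(diff(allele_age_cdf(t, 0.3, 500)) >= 0))
  for (q in c(1e-4, 1e-3, 1e-2)) for (p in c(0.01, 0.5, 0.99))
    for (n in c(100, 2000)) {
      tq <- allele_age_quantile(q, p, n)
      if (tq > 0)
        expect_equal(allele_age_cdf(tq, p, n), q, tolerance = 1e-9)
    }
  # frozen direct evaluation
  expect_equal(allele_age_quantile(0.01, 0.5, 2000), 0.260648,
               tolerance = 1e-6)
  # limit: q -> (1-p) sends the quantile towards 1 - 2/n
  p <- 0.5; n <- 2000
  expect_equal(allele_age_quantile(1 - p - 1e-12, p, n), 1 - 2 / n,
               tolerance = 1e-3)
  # larger p at fixed q gives older quantiles
  ps <- c(0.05, 0.2, 0.5, 0.8)
  expect_true(all(diff(vapply(ps, function(p)
    allele_age_quantile(0.01, p, 2000), 0)) > 0))
  expect_error(allele_age_cdf(1, 1.5, 100), "p must be")
})

test_that("adaptive quantile follows the three-equation chain and clamps", {
  q <- adaptive_quantile(0.5, 2000, s_min = 0.005, Ne = 10000)
  # independent re-evaluation of the chain
  Ne <- 10000; y0 <- 1 / (2 * Ne)
  t_gen <- (1 / 0.005) * log(0.5 * (1 - y0) / (y0 * 0.5))
  q_direct <- (1 - 0.5)^(-1 + 2000 / (1 + 2000 * (t_gen / (2 * Ne)) / 2))
  expect_equal(q, min(0.01, max(1e-4, q_direct)))
  # always inside the advertised clamp
  set.seed(2)
  for (t in 1:50) {
    qq <- adaptive_quantile(runif(1, 0.001, 0.999), 2000,
                            s_min = runif(1, 0.001, 0.05), Ne = 10000)
    expect_gte(qq, 1e-4); expect_lte(qq, 0.01)
  }
  # tiny s_min makes drift ages huge, q' -> 1, clamped at the top
  expect_equal(adaptive_quantile(0.5, 2000, s_min = 1e-6, Ne = 10000), 0.01)
  # rarer than one population copy: most permissive level
  expect_equal(adaptive_quantile(1e-6, 2000, s_min = 0.005, Ne = 10000), 0.01)
})

test_that("drift filter keeps young blocks and rejects old ones", {
  cfg <- model_config(Ne = 10000)
  expect_false(drift_filter(Inf, 0.5, 2000, cfg)$pass)  # s_hat -> 0
  expect_true(drift_filter(0, 0.5, 2000, cfg)$pass)
  # end-to-end hand check: block at p = 0.5 with s_hat = 0.05
  t1 <- sweep_age(0.05, 0.5, 1 / 20000)
  res <- drift_filter(t1, 0.5, 2000, cfg)
  q <- adaptive_quantile(0.5, 2000, cfg$s_min, cfg$Ne)
  thr <- 2 * cfg$Ne * allele_age_quantile(q, 0.5, 2000)
  expect_equal(res$threshold, thr)
  expect_equal(res$pass, t1 < thr)
  expect_true(res$pass)  # a strong sweep at intermediate frequency is young
})

test_that("hypoexponential TMRCA CDF matches its defining properties", {
  # k = 2 reduces to a single exponential with rate 1/Ne at r = 0
  lam2 <- 1 / 10000
  t <- c(100, 1000, 10000)
  expect_equal(tmrca_exact_cdf(t, 0, 10000, 2), 1 - exp(-lam2 * t),
               tolerance = 1e-9)
  # mean identity: integral of the survival function equals sum(1/lambda_i)
  for (kk in c(3, 8)) for (rr in c(1e-4, 1e-2)) {
    lam <- (2:kk) * ((2:kk) - 1 + 2e4 * rr) / 2e4
    mean_exact <- sum(1 / lam)
    surv_int <- integrate(function(tt)
      1 - tmrca_exact_cdf(tt, rr, 1e4, kk), 0, Inf,
      rel.tol = 1e-7)$value
    expect_equal(surv_int, mean_exact, tolerance = 1e-4)
  }
  # stochastically smaller for larger r
  for (kk in c(3, 16)) {
    t <- c(10, 100, 500)
    lo <- tmrca_exact_cdf(t, 1e-4, 1e4, kk)
    hi <- tmrca_exact_cdf(t, 1e-2, 1e4, kk)
    expect_true(all(hi >= lo))
  }
  expect_error(tmrca_exact_cdf(1, 0, 1e4, 1), "k_block")
})

test_that("gamma approximation conserves the mean and tracks the exact tail", {
  g2 <- gamma_approx_params(1e-4, 1e4, 2)
  expect_equal(g2$shape, 1)
  expect_equal(g2$scale, 1 / (2 * (1 + 2e4 * 1e-4) / 2e4))
  for (kk in c(3, 8, 32)) for (rr in c(1e-6, 1e-4, 1e-2)) {
    gp <- gamma_approx_params(rr, 1e4, kk)
    lam <- (2:kk) * ((2:kk) - 1 + 2e4 * rr) / 2e4
    expect_equal(gp$shape * gp$scale, sum(1 / lam), tolerance = 1e-9)
    q_gamma <- qgamma(0.01, gp$shape, scale = gp$scale)
    q_exact <- tmrca_exact_quantile(0.01, rr, 1e4, kk)
    expect_lt(abs(q_gamma / q_exact - 1), 0.15)
  }
})

test_that("lookup tables are monotone, deterministic and serialize exactly", {
  tb <- build_lookup_table(10000, k_max = 64)
  # older MRCA with more lineages, younger with more recombination
  expect_true(all(apply(tb$q01, 2, function(col) all(diff(col) >= -1e-9))))
  expect_true(all(apply(tb$q01, 1, function(row) all(diff(row) <= 1e-9))))
  tb2 <- build_lookup_table(10000, k_max = 64)
  expect_identical(tb$q01, tb2$q01)
  path <- tempfile(fileext = ".tsv")
  write_lookup_table(tb, path)
  rt <- read_lookup_table(path)
  expect_identical(unname(rt$q01), unname(tb$q01))
  expect_equal(rt$Ne, tb$Ne); expect_equal(rt$r_grid, tb$r_grid)
  # grid nodes are returned exactly; off-grid queries interpolate within 5%
  for (ik in c(1, 3, 7)) for (ir in c(1, 10, 30)) {
    expect_equal(lookup_q01(tb, tb$k_grid[ik], tb$r_grid[ir]),
                 unname(tb$q01[ik, ir]))
  }
  set.seed(9)
  for (t in 1:100) {
    kq <- sample(3:64, 1)
    rq <- 10^runif(1, -7, log10(0.4))
    gp <- gamma_approx_params(rq, 10000, kq)
    direct <- qgamma(0.01, gp$shape, scale = gp$scale)
    expect_lt(abs(lookup_q01(tb, kq, rq) / direct - 1), 0.05)
  }
})

test_that("coalescent filter keeps implausibly young blocks only", {
  tb <- build_lookup_table(10000, k_max = 64)
  thr <- lookup_q01(tb, 10, 1e-3)
  expect_true(coalescent_filter(0, 10, 1e-3, tb)$pass)        # t2 = 0
  expect_false(coalescent_filter(Inf, 10, 1e-3, tb)$pass)     # s_hat -> 0
  # end-to-end re-evaluation for a synthetic block
  shat <- 0.05; y <- 0.3; Ne <- 1e4
  t2 <- sweep_age(shat, y, 1 / Ne)
  res <- coalescent_filter(t2, 10, 1e-3, tb)
  expect_equal(res$threshold, thr)
  expect_equal(res$pass, t2 < thr)
})

test_that("the two filters commute and compose", {
  cfg <- model_config(Ne = 10000)
  tb <- build_lookup_table(10000, k_max = 64)
  set.seed(21)
  t1 <- 10^runif(60, 0, 4); t2 <- t1 * runif(60, 0.5, 1)
  p <- runif(60, 0.01, 0.95); kb <- sample(2:64, 60, replace = TRUE)
  r <- 10^runif(60, -6, -1)
  d <- drift_filter(t1, p, 2000, cfg)$pass
  co <- coalescent_filter(t2, kb, r, tb)$pass
  expect_identical(d & co, co & d)
  reported <- which(d & co)
  # applying the filters in either order keeps the same set
  first_d <- which(d); after_c <- first_d[co[first_d]]
  expect_identical(reported, after_c)
})
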