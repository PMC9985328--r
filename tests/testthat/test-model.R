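# Sweep model: Haldane map function, sweep ages, composite likelihood and
# the closed-form MCL estimator.

test_that("haldane converts map distance to recombination fraction", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(50), (1 - exp(-1)) / 2, tolerance = 1e-12)
  expect_gt(haldane(1e6), 0.4999999)
  d <- sort(runif(50, 0, 200))
  expect_true(all(diff(haldane(d)) > 0))
  expect_error(haldane(-1), "negative")
})

test_that("sweep_age inverts the logistic trajectory", {
  # y chosen so that the frequency ratio equals exp(s): age is exactly 1
  s <- 0.05; y0 <- 1e-4
  y <- 1 / (1 + (1 - y0) / (y0 * exp(s)))
  expect_equal(sweep_age(s, y, y0), 1, tolerance = 1e-9)
  # frozen direct evaluation (s = 0.05, y = 0.5, y0 = 1/20000)
  expect_equal(sweep_age(0.05, 0.5, 1 / 20000), 198.0689, tolerance = 1e-6)
  # cross-check against the deterministic logistic recursion
  y0 <- 1 / 20000; s <- 0.05
  y <- y0
  gens <- 0
  while (y < 0.5) { y <- y * (1 + s) / (1 + y * s); gens <- gens + 1 }
  expect_lt(abs(gens - sweep_age(log(1 + s), 0.5, y0)), 2)
  # age decreases with s at fixed frequencies
  ss <- c(0.01, 0.02, 0.05, 0.1)
  expect_true(all(diff(sweep_age(ss, 0.5, 1e-4)) < 0))
  expect_error(sweep_age(0.05, 1e-5, 1e-4), "exceed")
})

test_that("no_recomb_prob equals its closed form and composition identity", {
  # C(s, r, y) = (y0/y)^(r/s) after substituting the sweep age
  set.seed(5)
  for (t in 1:50) {
    s <- runif(1, 0.005, 0.2); r <- runif(1, 1e-6, 0.4)
    y <- runif(1, 0.01, 0.99); y0 <- 10^runif(1, -6, -2) * y
    tt <- sweep_age(s, y, y0)
    direct <- exp(-r * tt) * (1 - y0 * (1 - exp(s * tt)))^(r / s)
    expect_equal(no_recomb_prob(s, r, y, y0), direct, tolerance = 1e-12)
  }
  expect_equal(no_recomb_prob(0.05, 0, 0.5, 1e-4), 1)
  expect_equal(no_recomb_prob(0.05, 0.01, 0.5, 5e-5), (1e-4)^0.2,
               tolerance = 1e-12)
})

test_that("log composite likelihood matches the product form", {
  cfg <- model_config(Ne = 10000, delta_r = 1e-4)
  # doubling the block size doubles the log-likelihood
  s <- seq(0.01, 0.2, by = 0.01)
  expect_equal(log_composite_likelihood(s, 0.01, 0.5, 20, cfg),
               2 * log_composite_likelihood(s, 0.01, 0.5, 10, cfg))
  # agreement with the direct product of per-haplotype factors
  set.seed(8)
  for (t in 1:40) {
    r <- runif(1, 1e-4, 0.3); y <- runif(1, 0.01, 0.99)
    s <- runif(1, 0.005, 0.3); kb <- sample(2:50, 1)
    C_in <- no_recomb_prob(s, r, y, cfg$y0_single)
    C_dr <- no_recomb_prob(s, cfg$delta_r, y, cfg$y0_single)
    direct <- 2 * kb * log(C_in * (1 - C_dr))
    expect_equal(log_composite_likelihood(s, r, y, kb, cfg), direct,
                 tolerance = 1e-9)
  }
  # decreasing beyond the optimum (limit -Inf as s grows)
  cfg2 <- model_config(Ne = 10000, delta_r = 1e-4)
  shat <- mcl_selection(0.01, 0.5, cfg2)$s_hat
  ll <- log_composite_likelihood(c(shat, 2 * shat, 10 * shat, 100 * shat),
                                 0.01, 0.5, 2, cfg2)
  expect_true(all(diff(ll) < 0))
})

test_that("closed-form MCL estimate maximizes the composite likelihood", {
  cfg <- model_config(Ne = 10000, delta_r = 1e-4)
  est <- mcl_selection(0.01, 0.5, cfg)
  expect_equal(est$s_hat, 0.09256316, tolerance = 1e-6)
  # independent grid + golden-section maximization
  opt <- optimize(function(s) log_composite_likelihood(s, 0.01, 0.5, 2, cfg),
                  c(1e-6, 1), maximum = TRUE, tol = 1e-12)
  expect_equal(est$s_hat, opt$maximum, tolerance = 1e-4)
  # monotone in r and in y
  rs <- c(0.001, 0.005, 0.02, 0.1)
  expect_true(all(diff(mcl_selection(rs, 0.5, cfg)$s_hat) > 0))
  ys <- c(0.05, 0.2, 0.5, 0.9)
  expect_true(all(diff(mcl_selection(0.01, ys, cfg)$s_hat) > 0))
  # degenerate blocks are flagged with zero estimate
  z1 <- mcl_selection(0, 0.5, cfg)
  expect_equal(z1$s_hat, 0); expect_false(z1$estimable)
  z2 <- mcl_selection(0.01, cfg$y0_single, cfg)
  expect_equal(z2$s_hat, 0); expect_false(z2$estimable)
})

test_that("age estimates order correctly and fixed blocks stay finite", {
  cfg <- model_config(Ne = 10000, delta_r = 1e-4)
  est <- mcl_selection(c(0.005, 0.01, 0.05), c(0.2, 0.5, 0.9), cfg)
  ok <- est$estimable
  expect_true(all(est$t_hat1[ok] > est$t_hat2[ok]))
  expect_true(all(est$t_hat2[ok] > 0))
  fixed <- mcl_selection(0.01, 1, cfg, k_sample = 2000)
  expect_true(is.finite(fixed$t_hat1) && fixed$s_hat > 0)
})
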