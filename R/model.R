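#' Model configuration for selection inference
#'
#' Bundles the population-genetic parameters shared by the estimator and the
#' filters. The initial haplotype frequency conventions follow the sweep
#' model: a single copy corresponds to `1/(2*Ne)` of the population, two
#' copies to `1/Ne` (diploid `Ne`).
#'
#' @param Ne Effective population size in diploid individuals. The default of
#'   10,000 is a conservative choice for humans; when demography is
#'   uncertain, prefer values at the lower end of the plausible range (lower
#'   `Ne` gives lower estimates and stricter filtering).
#' @param delta_r Recombination fraction between contiguous SNPs. If `NULL`
#'   it is derived by the scan from the mean genetic-map distance between
#'   consecutive retained SNPs.
#' @param s_min Minimum selection coefficient of interest; parametrizes the
#'   adaptive quantile of the drift filter.
#' @return An object of class `model_config`.
#' @export
model_config <- function(Ne = 10000, delta_r = NULL, s_min = 0.005) {
  stopifnot(is.numeric(Ne), length(Ne) == 1, Ne >= 2)
  stopifnot(is.null(delta_r) || (is.numeric(delta_r) && delta_r > 0 && delta_r < 0.5))
  stopifnot(is.numeric(s_min), length(s_min) == 1, s_min > 0)
  structure(list(
    Ne = Ne,
    y0_single = 1 / (2 * Ne),
    y0_pair = 1 / Ne,
    delta_r = delta_r,
    s_min = s_min
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config: Ne =", x$Ne,
      " y0(single) =", format(x$y0_single),
      " y0(pair) =", format(x$y0_pair),
      " delta_r =", if (is.null(x$delta_r)) "(from data)" else format(x$delta_r),
      " s_min =", x$s_min, "\n")
  invisible(x)
}

#' Haldane's map function
#'
#' Converts genetic distance in centimorgan to a recombination fraction,
#' `r = (1 - exp(-2 d / 100)) / 2`. The function is strictly increasing and
#' saturates at 1/2 for unlinked loci.
#'
#' @param d_cm Genetic distance in centimorgan (non-negative, vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cm) {
  if (any(d_cm < 0)) stop("haldane: negative map distance")
  -expm1(-2 * d_cm / 100) / 2
}

#' Deterministic sweep age of a haplotype
#'
#' Time, in generations, for a haplotype under genic selection `s` to rise
#' along the logistic sweep trajectory from initial frequency `y0` to
#' frequency `y`: `t = (1/s) * log(y (1 - y0) / (y0 (1 - y)))`.
#'
#' @param s Selection coefficient (> 0).
#' @param y Current haplotype frequency, `y0 < y < 1`.
#' @param y0 Initial haplotype frequency.
#' @return Age in generations.
#' @export
sweep_age <- function(s, y, y0) {
  if (any(s <= 0)) stop("sweep_age: s must be positive")
  if (any(y <= y0)) stop("sweep_age: y must exceed y0")
  if (any(y >= 1)) stop("sweep_age: y must be < 1 (substitute 1 - 1/(2k) for fixed blocks)")
  (1 / s) * log(y * (1 - y0) / (y0 * (1 - y)))
}

#' Probability that a haplotype escapes recombination during a sweep
#'
#' The probability of no effective recombination over map interval `r`
#' during a sweep from `y0` to `y` with coefficient `s`:
#' `C(s, r, y) = exp(-r t) (1 - y0 (1 - exp(s t)))^(r/s)` with `t` the sweep
#' age. Algebraically this collapses to `(y0 / y)^(r/s)`; the function
#' evaluates the collapsed form in log space for numerical robustness.
#'
#' @inheritParams sweep_age
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Probability in `(0, 1]`.
#' @export
no_recomb_prob <- function(s, r, y, y0) {
  if (any(s <= 0)) stop("no_recomb_prob: s must be positive")
  if (any(y <= y0)) stop("no_recomb_prob: y must exceed y0")
  if (any(r < 0 | r >= 0.5)) stop("no_recomb_prob: r must be in [0, 0.5)")
  exp((r / s) * log(y0 / y))
}

#' Log composite likelihood of a selection coefficient for a block
#'
#' For a block of `k_block` haplotypes at frequency `y` spanning
#' recombination fraction `r`, with inter-SNP fraction `delta_r`:
#' `ln L(s) = 2 k_block ( (r/s) ln(y0/y) + ln(1 - (y0/y)^(delta_r/s)) )`.
#' The composite likelihood treats haplotypes as independent (star
#' genealogy); each contributes no recombination inside the block and at
#' least one just outside each end.
#'
#' @param s Selection coefficient (> 0, vectorized).
#' @param r Block recombination fraction (> 0).
#' @param y Block frequency in the sample.
#' @param k_block Number of haplotypes in the block.
#' @param cfg A [model_config()]; `cfg$delta_r` must be set.
#' @return Log composite likelihood; `-Inf` where the outer-recombination
#'   term underflows, never `NaN`.
#' @export
log_composite_likelihood <- function(s, r, y, k_block, cfg) {
  if (any(s <= 0)) stop("log_composite_likelihood: s must be positive")
  stopifnot(inherits(cfg, "model_config"), !is.null(cfg$delta_r))
  y0 <- cfg$y0_single
  if (y <= y0) stop("log_composite_likelihood: y must exceed y0")
  lr <- log(y0 / y)                       # negative
  inner <- (r / s) * lr
  # log(1 - exp(x)) with x = (delta_r/s) * lr < 0, guarded against underflow
  x <- (cfg$delta_r / s) * lr
  outer <- ifelse(x == 0, -Inf, log(-expm1(x)))
  2 * k_block * (inner + outer)
}

#' Closed-form maximum composite likelihood selection estimate
#'
#' Maximizes the block composite likelihood analytically:
#' `s_hat = delta_r / log(r / (delta_r + r)) * log(y0 / y)`.
#' Degenerate blocks (`r = 0` or `y <= y0`) are returned with `s_hat = 0`
#' and flagged non-estimable; the estimator's limit as `r -> 0` is 0.
#' Sweep ages are attached: `t_hat1` uses the single-copy convention
#' `y0 = 1/(2 Ne)` (drift filter), `t_hat2` the two-copy convention
#' `y0 = 1/Ne` (common-ancestry filter). Fixed blocks (`y = 1`) are dated at
#' `y = 1 - 1/(2 k_sample)`, one sample chromosome short of fixation, which
#' keeps the ages finite at the frequency resolution of the sample.
#'
#' @param r Block recombination fraction (vectorized).
#' @param y Block frequency in the sample (vectorized).
#' @param cfg A [model_config()] with `delta_r` set.
#' @param k_block Number of haplotypes per block (vectorized; scales the
#'   attached log composite likelihood).
#' @param k_sample Number of sample chromosomes (used only to resolve
#'   `y = 1`).
#' @return A data.frame with columns `s_hat`, `log_cl`, `t_hat1`, `t_hat2`,
#'   `estimable`.
#' @export
mcl_selection <- function(r, y, cfg, k_block = 2, k_sample = NULL) {
  stopifnot(inherits(cfg, "model_config"), !is.null(cfg$delta_r))
  n <- max(length(r), length(y), length(k_block))
  r <- rep_len(r, n); y <- rep_len(y, n); k_block <- rep_len(k_block, n)
  y0s <- cfg$y0_single; y0p <- cfg$y0_pair
  y_eff <- y
  at_fix <- y >= 1
  if (any(at_fix)) {
    if (is.null(k_sample)) stop("mcl_selection: k_sample needed for fixed blocks")
    y_eff[at_fix] <- 1 - 1 / (2 * k_sample)
  }
  estimable <- r > 0 & y_eff > y0s
  s_hat <- numeric(n)
  dr <- cfg$delta_r
  s_hat[estimable] <- dr / log(r[estimable] / (dr + r[estimable])) *
    log(y0s / y_eff[estimable])
  t_hat1 <- rep(Inf, n); t_hat2 <- rep(Inf, n); log_cl <- rep(NA_real_, n)
  i <- estimable
  t_hat1[i] <- sweep_age(s_hat[i], y_eff[i], y0s)
  t_hat2[i] <- sweep_age(s_hat[i], y_eff[i], y0p)
  if (any(i)) {
    lr <- log(y0s / y_eff[i])
    x <- (dr / s_hat[i]) * lr
    log_cl[i] <- 2 * k_block[i] *
      ((r[i] / s_hat[i]) * lr + ifelse(x == 0, -Inf, log(-expm1(x))))
  }
  data.frame(s_hat = s_hat, log_cl = log_cl, t_hat1 = t_hat1,
             t_hat2 = t_hat2, estimable = estimable)
}
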