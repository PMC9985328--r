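# Simulation toolbox: planted-block fixtures, neutral coalescent samples
# (SMC' approximation) and sweep samples conditioned on the selected-allele
# frequency. Every generator is a pure function of (spec, seed).

#' Sweep / neutral simulation specification
#'
#' Parameters of the simulated study design: a Wright-Fisher population of
#' `Ne` diploids, a chromosome of `region_bp` bases with uniform
#' recombination and mutation rates, a beneficial allele of coefficient
#' `s_true` introduced at the centre, and output conditioned on the
#' selected allele reaching `target_freq`.
#'
#' @param Ne Diploid effective population size (default 10,000).
#' @param region_bp Region length in bp. The default 1 Mb is a scaled-down
#'   version of the 10 Mb design the method was validated on; see the
#'   methods vignette.
#' @param recomb_rate Recombination rate per bp per generation (1e-8).
#' @param mut_rate Mutation rate per bp per generation (2.5e-8).
#' @param s_true True selection coefficient (0 = neutral).
#' @param target_freq Selected-allele frequency at which the sample is
#'   taken.
#' @param n_sample_diploid Diploid sample size (default 1,000, i.e. 2,000
#'   chromosomes).
#' @param maf_min Minor-allele-frequency filter applied to the simulated
#'   sample. The default 0 keeps every segregating site, matching the
#'   validation design: simulated data carry no genotyping errors, and the
#'   rare variants are what fragments spurious rare long blocks (see the
#'   methods vignette). Raise it to emulate array-density or
#'   error-filtered data.
#' @return An object of class `sweep_sim_spec`.
#' @export
sweep_sim_spec <- function(Ne = 10000, region_bp = 1e6, recomb_rate = 1e-8,
                           mut_rate = 2.5e-8, s_true = 0, target_freq = 0.5,
                           n_sample_diploid = 1000, maf_min = 0) {
  stopifnot(Ne >= 2, region_bp > 0, recomb_rate >= 0, mut_rate >= 0,
            s_true >= 0, target_freq >= 0, target_freq <= 1,
            n_sample_diploid >= 1)
  structure(list(Ne = Ne, region_bp = region_bp, recomb_rate = recomb_rate,
                 mut_rate = mut_rate, s_true = s_true,
                 target_freq = target_freq,
                 n_sample_diploid = n_sample_diploid, maf_min = maf_min),
            class = "sweep_sim_spec")
}

#' Demographic models for the simulators
#'
#' Piecewise demographies matching the validation designs:
#' * `constant` — a single population of `Ne` diploids;
#' * `bottleneck` — 2`Ne` chromosomes reduced to 5\% for 10 generations,
#'   placed 1,120 generations before sampling;
#' * `migration` — two demes of `Ne` diploids each exchanging migrants at
#'   rate 3.11e-5 per lineage per generation for the 1,120 generations
#'   before sampling, a single ancestral population before that; samples
#'   come from the first deme;
#' * `out_of_africa` — the European lineage of the three-population
#'   Out-of-Africa model (ancestral 7,310; African expansion to 14,474 at
#'   5,920 generations; European bottleneck 1,861 at 2,040 generations;
#'   exponential growth at 0.38\%/generation from 1,032 after the
#'   European-Asian split 920 generations ago), collapsed to a single-deme
#'   size history (continental migration is ignored); growth is
#'   discretized into 16 piecewise-constant steps.
#'
#' @param model One of `"constant"`, `"bottleneck"`, `"migration"`,
#'   `"out_of_africa"`.
#' @param Ne Diploid size of the present-day population (for `constant`,
#'   `bottleneck`, `migration`).
#' @param split_gen Generations before sampling at which the
#'   bottleneck/migration structure starts (default 1,120).
#' @param mig_rate Per-lineage migration rate for the `migration` model.
#' @return An object of class `demography_spec` with the epoch table used
#'   by the simulators (`epoch_start` in generations, deme sizes in
#'   chromosomes, migration rate per epoch).
#' @export
demography_spec <- function(model = c("constant", "bottleneck", "migration",
                                      "out_of_africa"),
                            Ne = 10000, split_gen = 1120,
                            mig_rate = 3.11e-5) {
  model <- match.arg(model)
  chroms <- 2 * Ne
  if (model == "constant") {
    ep <- data.frame(start = 0, size1 = chroms, size2 = 0, mig = 0)
  } else if (model == "bottleneck") {
    ep <- data.frame(start = c(0, split_gen, split_gen + 10),
                     size1 = c(chroms, 0.05 * chroms, chroms),
                     size2 = 0, mig = 0)
  } else if (model == "migration") {
    ep <- data.frame(start = c(0, split_gen),
                     size1 = c(chroms, chroms),
                     size2 = c(chroms, 0),
                     mig = c(mig_rate, 0))
  } else {
    # European lineage sizes in chromosomes
    t_split <- 920; t_boot <- 2040; t_afr <- 5920
    growth <- 0.0038; n_eu0 <- 2 * 1032
    steps <- 16
    bounds <- seq(0, t_split, length.out = steps + 1)
    mids <- (head(bounds, -1) + tail(bounds, -1)) / 2
    sizes <- n_eu0 * exp(growth * (t_split - mids))
    ep <- data.frame(start = c(head(bounds, -1), t_split, t_boot, t_afr),
                     size1 = c(sizes, 2 * 1861, 2 * 14474, 2 * 7310),
                     size2 = 0, mig = 0)
  }
  structure(list(model = model, epochs = ep), class = "demography_spec")
}

# chromosome count of the sampled deme at generation g before sampling
deme_size_at <- function(dem, g) {
  ep <- dem$epochs
  e <- findInterval(g, ep$start)
  round(ep$size1[pmax(e, 1)])
}

#' Simulate a neutral sample
#'
#' Draws `2 * n_sample_diploid` haplotypes over `region_bp` bases under the
#' given demography using the SMC' approximation of the coalescent with
#' recombination, places infinite-sites mutations on the marginal
#' genealogies, and applies the spec's MAF filter. The genetic map is
#' uniform: `cM = 100 * recomb_rate * bp`.
#'
#' @param spec A [sweep_sim_spec()] with `s_true = 0`.
#' @param demography A [demography_spec()].
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, demography, seed).
#' @return A list with `matrix` (a [haplotype_matrix()]) and `map` (a
#'   `genetic_map` with one entry per site).
#' @export
simulate_neutral <- function(spec, demography = demography_spec("constant",
                                                                Ne = spec$Ne),
                             seed = NULL) {
  stopifnot(inherits(spec, "sweep_sim_spec"), inherits(demography, "demography_spec"))
  if (spec$s_true != 0) stop("simulate_neutral: spec has s_true > 0")
  if (!is.null(seed)) set.seed(seed)
  ep <- demography$epochs
  k <- 2 * spec$n_sample_diploid
  sim <- smc_simulate_cpp(k, spec$region_bp, spec$recomb_rate, spec$mut_rate,
                          ep$start, ep$size1, ep$size2, ep$mig, spec$maf_min)
  if (length(sim$pos_bp) == 0)
    stop("simulate_neutral: no segregating sites survived the MAF filter")
  cm <- 100 * spec$recomb_rate * sim$pos_bp
  m <- haplotype_matrix(sim$alleles, sim$pos_bp, cm, chrom = "chrSim")
  map <- data.frame(chrom = "chrSim", id = paste0("snp", seq_len(m$n)),
                    cm = cm, bp = sim$pos_bp, stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  list(matrix = m, map = map)
}

# Forward Wright-Fisher trajectory of a beneficial allele (genic selection
# s per haplotype), conditioned on reaching target_freq. Returns the
# frequency path indexed backwards from sampling (index 1 = generation 0),
# or NULL when the allele was lost in every attempt.
sweep_trajectory <- function(spec, demography, max_tries = 10000) {
  for (try in seq_len(max_tries)) {
    nchrom0 <- deme_size_at(demography, 0)
    y <- 1 / nchrom0
    path <- y
    repeat {
      g <- length(path) - 1          # generations since introduction
      nchrom <- deme_size_at(demography, 0)  # forward sim in present-size pop
      yp <- y * (1 + spec$s_true) / (1 + y * spec$s_true)
      y <- rbinom(1, nchrom, yp) / nchrom
      path <- c(path, y)
      if (y == 0) break
      if (y >= spec$target_freq) return(rev(path))
      if (length(path) > 200 / spec$s_true + 5000) break
    }
  }
  NULL
}

# Genealogy of the beneficial-allele class, backwards over the trajectory.
# y_back[g + 1] is the population frequency g generations before sampling.
# Returns nodes with children lists and integer times; leaves are 1..nB.
sweep_genealogy <- function(nB, y_back, demography) {
  n_nodes <- nB
  node_time <- rep(0, nB)
  children <- vector("list", nB)
  act <- seq_len(nB)
  T_end <- length(y_back) - 1
  for (g in seq_len(T_end)) {
    if (length(act) <= 1) break
    copies <- max(1, round(y_back[g + 1] * deme_size_at(demography, g)))
    par <- sample.int(copies, length(act), replace = TRUE)
    if (anyDuplicated(par)) {
      for (pp in unique(par[duplicated(par)])) {
        grp <- act[par == pp]
        n_nodes <- n_nodes + 1
        node_time[n_nodes] <- g
        children[[n_nodes]] <- grp
        act <- c(act[par != pp], n_nodes)
        par <- c(par[par != pp], pp)
      }
    }
  }
  if (length(act) > 1 || act[1] <= nB) {
    # force the MRCA at the origin of the allele (also for a single
    # sampled carrier, so its lineage is truncated along the trajectory)
    n_nodes <- n_nodes + 1
    node_time[n_nodes] <- T_end
    children[[n_nodes]] <- act
    act <- n_nodes
  }
  list(n_nodes = n_nodes, time = node_time, children = children, root = act)
}

#' Simulate a selective sweep sample
#'
#' Hybrid scheme: the selected-allele frequency trajectory is simulated
#' forward under Wright-Fisher dynamics with genic selection, conditioned
#' on reaching `target_freq`; the genealogy of the beneficial class is then
#' drawn backwards along that trajectory (coalescence rate inflated by the
#' class frequency); recombination events thinned by the non-beneficial
#' class frequency truncate the ancestral sweep haplotype along each
#' branch, and new mutations arise on the genealogy inside the surviving
#' extent. Neutral flanking diversity comes from an SMC' panel under the
#' same demography; non-carrier samples are neutral panel haplotypes.
#'
#' @inheritParams simulate_neutral
#' @param spec A [sweep_sim_spec()] with `s_true > 0`.
#' @param max_tries Retry budget for the conditioned trajectory; when the
#'   allele is lost in every attempt the replicate is labelled a loss, not
#'   an error.
#' @return A list with `matrix`, `map`, `s_true`, `target_freq`,
#'   `freq_sample` (realized selected-allele sample frequency), `sel_pos`
#'   (bp of the selected site) and `lost` (`TRUE` when the allele was lost
#'   within the retry budget; `matrix` is then the neutral panel).
#' @export
simulate_sweep <- function(spec, demography = demography_spec("constant",
                                                              Ne = spec$Ne),
                           seed = NULL, max_tries = 10000) {
  stopifnot(inherits(spec, "sweep_sim_spec"), spec$s_true > 0)
  if (!is.null(seed)) set.seed(seed)
  k <- 2 * spec$n_sample_diploid
  L <- spec$region_bp
  sel_pos <- round(L / 2)

  # neutral panel: sample haplotypes plus one origin haplotype
  ep <- demography$epochs
  panel <- smc_simulate_cpp(k + 1, L, spec$recomb_rate, spec$mut_rate,
                            ep$start, ep$size1, ep$size2, ep$mig, 0)
  pos <- panel$pos_bp
  al <- panel$alleles
  hstar <- al[k + 1, ]
  al <- al[seq_len(k), , drop = FALSE]

  y_back <- sweep_trajectory(spec, demography, max_tries = max_tries)
  if (is.null(y_back)) {
    keep <- pmin(colMeans(al), 1 - colMeans(al)) >= spec$maf_min
    m <- haplotype_matrix(al[, keep, drop = FALSE], pos[keep],
                          100 * spec$recomb_rate * pos[keep], chrom = "chrSim")
    return(list(matrix = m, map = NULL, s_true = spec$s_true,
                target_freq = spec$target_freq, freq_sample = 0,
                sel_pos = sel_pos, lost = TRUE))
  }
  y_T <- y_back[1]
  nB <- rbinom(1, k, y_T)
  nB <- max(nB, 1)
  gen <- sweep_genealogy(nB, y_back, demography)

  # walk the genealogy from the root down, truncating flanks by
  # recombination escapes (thinned by 1 - y(t)) and placing sweep-phase
  # mutations inside the surviving extent
  T_end <- length(y_back) - 1
  w <- 1 - y_back[pmin(seq_len(T_end) + 1, T_end + 1)]
  W <- c(0, cumsum(w))                   # W[g+1] = hazard weight of gens 1..g
  ext_a <- numeric(gen$n_nodes); ext_b <- numeric(gen$n_nodes)
  mut_pos <- numeric(0); mut_node <- integer(0)
  r_bp <- spec$recomb_rate; mu_bp <- spec$mut_rate
  add_muts <- function(ch, a, b, n_gens) {
    nm <- rpois(1, mu_bp * (b - a) * n_gens)
    if (nm > 0) {
      mut_pos <<- c(mut_pos, a + runif(nm) * (b - a))
      mut_node <<- c(mut_node, rep(ch, nm))
    }
  }
  ord <- order(gen$time, decreasing = TRUE)
  ext_a[gen$root] <- 0; ext_b[gen$root] <- L
  for (v in ord) {
    kids <- gen$children[[v]]
    if (is.null(kids) || length(kids) == 0) next
    for (ch in kids) {
      tp <- gen$time[v]; tc <- gen$time[ch]
      a <- ext_a[v]; b <- ext_b[v]
      g_cur <- tp
      while (g_cur > tc) {
        len_l <- sel_pos - a; len_r <- b - sel_pos
        haz <- r_bp * (len_l + len_r)
        if (haz <= 0) { add_muts(ch, a, b, g_cur - tc); break }
        target <- W[g_cur + 1] - rexp(1) / haz
        if (target < W[tc + 1]) {        # no escape before the child
          add_muts(ch, a, b, g_cur - tc)
          break
        }
        g_ev <- findInterval(target, W) - 1L
        g_ev <- max(tc, min(g_cur - 1L, g_ev))
        add_muts(ch, a, b, g_cur - g_ev)
        if (runif(1) < len_l / (len_l + len_r)) {
          a <- a + runif(1) * len_l
        } else {
          b <- b - runif(1) * len_r
        }
        g_cur <- g_ev
      }
      ext_a[ch] <- a; ext_b[ch] <- b
    }
  }

  # assemble the sample: carriers copy the origin haplotype inside their
  # extent, everyone keeps their own neutral background outside
  B_rows <- sample.int(k, nB)
  for (l in seq_len(nB)) {
    inside <- pos >= ext_a[l] & pos <= ext_b[l]
    al[B_rows[l], inside] <- hstar[inside]
  }

  # descendant leaves per internal node (for sweep-mutation carriers)
  desc <- function(v) {
    out <- integer(0); stack <- v
    while (length(stack)) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (u <= nB) out <- c(out, u)
      else stack <- c(stack, gen$children[[u]])
    }
    out
  }
  extra_pos <- round(mut_pos)
  extra_cols <- lapply(seq_along(mut_pos), function(i) {
    leaves <- desc(mut_node[i])
    leaves <- leaves[ext_a[leaves] <= mut_pos[i] & ext_b[leaves] >= mut_pos[i]]
    col <- integer(k)
    col[B_rows[leaves]] <- 1L
    col
  })
  # selected site itself
  sel_col <- integer(k); sel_col[B_rows] <- 1L
  extra_pos <- c(extra_pos, sel_pos)
  extra_cols <- c(extra_cols, list(sel_col))

  all_pos <- c(pos, extra_pos)
  all_al <- cbind(al, do.call(cbind, extra_cols))
  ordc <- order(all_pos)
  all_pos <- all_pos[ordc]; all_al <- all_al[, ordc, drop = FALSE]
  # make positions strictly increasing (rare integer collisions)
  dup <- which(diff(all_pos) <= 0)
  while (length(dup)) {
    all_pos[dup + 1] <- all_pos[dup] + 1
    dup <- which(diff(all_pos) <= 0)
  }
  af <- colMeans(all_al)
  keep <- pmin(af, 1 - af) >= spec$maf_min
  if (!any(keep)) stop("simulate_sweep: no sites survived the MAF filter")
  m <- haplotype_matrix(all_al[, keep, drop = FALSE], all_pos[keep],
                        100 * spec$recomb_rate * all_pos[keep],
                        chrom = "chrSim")
  map <- data.frame(chrom = "chrSim", id = paste0("snp", seq_len(m$n)),
                    cm = m$pos_cm, bp = m$pos_bp, stringsAsFactors = FALSE)
  class(map) <- c("genetic_map", "data.frame")
  list(matrix = m, map = map, s_true = spec$s_true,
       target_freq = spec$target_freq, freq_sample = nB / k,
       sel_pos = sel_pos, lost = FALSE)
}

#' Haplotype matrix with planted blocks (unit-test fixture)
#'
#' Generates an i.i.d. Bernoulli(0.5) background and forces the planted
#' regions to be identical across their row sets. The returned truth is
#' computed by the brute-force oracle on the finished matrix, so planted
#' blocks may legitimately extend or merge with background matches.
#'
#' @param k,n Matrix dimensions (small: the truth uses [naive_blocks()]).
#' @param planted List of `list(rows=, i=, j=)` plans; overlapping plans
#'   must agree on shared cells.
#' @param seed Integer seed.
#' @return A list with `matrix` (a [haplotype_matrix()]) and `truth` (the
#'   [naive_blocks()] table).
#' @export
planted_matrix <- function(k, n, planted = list(), seed = 1) {
  set.seed(seed)
  al <- matrix(rbinom(k * n, 1, 0.5), k, n)
  for (p in planted) {
    stopifnot(all(p$rows >= 1 & p$rows <= k), p$i >= 1, p$j <= n, p$i <= p$j)
    template <- al[min(p$rows), p$i:p$j]
    al[p$rows, p$i:p$j] <- matrix(template, length(p$rows), length(template),
                                  byrow = TRUE)
  }
  # consistency: planted plans sharing cells must agree (they do after the
  # sequential overwrite unless templates conflict; verify directly)
  for (p in planted) {
    block <- al[p$rows, p$i:p$j, drop = FALSE]
    if (any(apply(block, 2, function(col) length(unique(col)) != 1)))
      stop("planted_matrix: inconsistent planted blocks")
  }
  m <- haplotype_matrix(al, seq_len(n), 0.01 * seq_len(n))
  list(matrix = m, truth = naive_blocks(m))
}

#' Downsample SNP columns
#'
#' Uniform or allele-frequency-spectrum-matched subsampling of sites,
#' preserving column order. With `afs_weights`, sites are binned by minor
#' allele frequency into `length(afs_weights)` equal-width bins and sampled
#' to match the weight histogram; infeasible targets are met best-effort
#' (the deficit is redistributed over the remaining bins) with a message.
#'
#' @param m A [haplotype_matrix()].
#' @param target_n Number of sites to keep (`<= m$n`).
#' @param afs_weights Optional non-negative weights over minor-allele
#'   frequency bins (normalized internally).
#' @param seed Integer seed.
#' @return A [haplotype_matrix()] with `target_n` sites.
#' @export
downsample_snps <- function(m, target_n, afs_weights = NULL, seed = 1) {
  stopifnot(inherits(m, "haplo_matrix"), target_n >= 1, target_n <= m$n)
  set.seed(seed)
  if (target_n == m$n) return(m)
  if (is.null(afs_weights)) {
    keep <- sort(sample.int(m$n, target_n))
    return(subset_sites(m, keep))
  }
  nb <- length(afs_weights)
  wts <- afs_weights / sum(afs_weights)
  maf <- pmin(colMeans(m$alleles), 1 - colMeans(m$alleles))
  bin <- pmin(pmax(ceiling(maf / 0.5 * nb), 1L), nb)
  want <- round(target_n * wts)
  # fix rounding drift
  while (sum(want) != target_n) {
    i <- which.max(want)
    want[i] <- want[i] + sign(target_n - sum(want))
  }
  keep <- integer(0); deficit <- 0
  for (b in seq_len(nb)) {
    avail <- which(bin == b)
    take <- min(length(avail), want[b])
    deficit <- deficit + want[b] - take
    if (take > 0) keep <- c(keep, sample(avail, take))
  }
  if (deficit > 0) {
    rest <- setdiff(seq_len(m$n), keep)
    keep <- c(keep, sample(rest, min(deficit, length(rest))))
    message("downsample_snps: spectrum target infeasible; redistributed ",
            deficit, " sites uniformly")
  }
  subset_sites(m, sort(keep))
}
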