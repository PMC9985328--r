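# End-to-end scan: preprocess -> enumerate -> estimate -> filter ->
# postprocess -> tracks, with per-stage counts.

.haploscan_cache <- new.env(parent = emptyenv())

# lookup tables are expensive for large sample sizes; cache per (Ne, k).
cached_lookup <- function(Ne, k_max) {
  key <- paste0("Ne", Ne, "_k", k_max)
  if (is.null(.haploscan_cache[[key]]))
    .haploscan_cache[[key]] <- build_lookup_table(Ne, k_max = k_max)
  .haploscan_cache[[key]]
}

#' Scan configuration
#'
#' Aggregates file paths and model parameters for [run_scan()].
#'
#' @param vcf Path to the phased VCF (one chromosome).
#' @param map Path to the PLINK genetic map.
#' @param out_prefix Output prefix; when non-`NULL`, the block TSV, BED5,
#'   bedGraph and a JSON run summary are written.
#' @param mask_bed Optional BED of regions to mask (centromere/telomere):
#'   SNPs inside are removed before enumeration.
#' @param gaps_bed Optional BED of assembly gaps: blocks touching a gap are
#'   removed after estimation.
#' @param lookup_table Optional path to a serialized TMRCA lookup table; it
#'   must have been built for the same `Ne` (mismatch is an error). Built
#'   on the fly when omitted.
#' @param Ne,s_min,delta_r Model parameters, see [model_config()].
#' @param maf_min Minor-allele-frequency filter for the VCF.
#' @param min_sites Minimum sites per block (default 1).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(vcf, map, out_prefix = NULL, mask_bed = NULL,
                        gaps_bed = NULL, lookup_table = NULL, Ne = 10000,
                        maf_min = 0, s_min = 0.005, delta_r = NULL,
                        min_sites = 1L) {
  for (p in c(vcf, map, mask_bed, gaps_bed, lookup_table))
    if (!file.exists(p)) stop("scan_config: file not found: ", p)
  structure(list(vcf = vcf, map = map, out_prefix = out_prefix,
                 mask_bed = mask_bed, gaps_bed = gaps_bed,
                 lookup_table = lookup_table, Ne = Ne, maf_min = maf_min,
                 s_min = s_min, delta_r = delta_r, min_sites = min_sites),
            class = "scan_config")
}

#' Run the full selection scan from input files
#'
#' Reads the VCF and genetic map, then runs [scan_matrix()]:
#' mask -> enumerate -> annotate -> estimate -> drift filter -> coalescent
#' filter -> gap removal -> hidden-block removal -> track output. Output is
#' deterministic given the inputs.
#'
#' @param cfg A [scan_config()].
#' @param verbose Log per-stage counts to stderr.
#' @return See [scan_matrix()].
#' @export
run_scan <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "scan_config"))
  map <- read_plink_map(cfg$map)
  m <- read_phased_vcf(cfg$vcf, maf_min = cfg$maf_min, map = map)
  mask <- if (!is.null(cfg$mask_bed)) read_bed_mask(cfg$mask_bed) else NULL
  gaps <- if (!is.null(cfg$gaps_bed)) read_bed_mask(cfg$gaps_bed) else NULL
  lookup <- NULL
  if (!is.null(cfg$lookup_table)) {
    lookup <- read_lookup_table(cfg$lookup_table)
    if (lookup$Ne != cfg$Ne)
      stop("scan: lookup table was built for Ne = ", lookup$Ne,
           " but the scan uses Ne = ", cfg$Ne)
  }
  scan_matrix(m, model_config(Ne = cfg$Ne, delta_r = cfg$delta_r,
                              s_min = cfg$s_min),
              lookup = lookup, mask = mask, gaps = gaps,
              min_sites = cfg$min_sites, out_prefix = cfg$out_prefix,
              verbose = verbose)
}

#' Run the selection scan on an in-memory haplotype matrix
#'
#' @param m A [haplotype_matrix()] with genetic-map coordinates assigned.
#' @param cfg A [model_config()]; a `NULL` `delta_r` is filled with the
#'   Haldane-transformed mean map distance between consecutive retained
#'   SNPs.
#' @param lookup Optional `tmrca_lookup` (must match `cfg$Ne`); built and
#'   cached on demand.
#' @param mask,gaps Optional `interval_mask`s (0-based half-open bp).
#' @param min_sites Minimum sites per block.
#' @param out_prefix As in [scan_config()].
#' @param verbose Log per-stage counts to stderr.
#' @return A list of class `haploscan_scan` with `reported` (final block
#'   table: spans, `s_hat`, ages, filter thresholds), `counts` (per-stage
#'   block counts), `delta_r`, and `cfg`.
#' @export
scan_matrix <- function(m, cfg = model_config(), lookup = NULL, mask = NULL,
                        gaps = NULL, min_sites = 1L, out_prefix = NULL,
                        verbose = TRUE) {
  stopifnot(inherits(m, "haplo_matrix"), inherits(cfg, "model_config"))
  log_msg <- function(...) if (verbose) message("[scan] ", ...)
  if (!is.null(mask) && nrow(mask) > 0) {
    masked <- rep(FALSE, m$n)
    for (t in seq_len(nrow(mask)))
      masked <- masked | (m$pos_bp > mask$start_bp[t] &
                            m$pos_bp <= mask$end_bp[t])
    if (all(masked)) stop("scan_matrix: all sites masked")
    if (any(masked)) m <- subset_sites(m, !masked)
    log_msg("masked ", sum(masked), " sites, ", m$n, " left")
  }
  if (is.null(cfg$delta_r)) {
    if (m$n < 2) stop("scan_matrix: need >= 2 sites to derive delta_r")
    cfg$delta_r <- haldane(mean(diff(m$pos_cm)))
    if (cfg$delta_r <= 0)
      stop("scan_matrix: flat genetic map, delta_r = 0")
  }
  if (is.null(lookup)) {
    lookup <- cached_lookup(cfg$Ne, m$k)
  } else if (lookup$Ne != cfg$Ne) {
    stop("scan_matrix: lookup Ne mismatch")
  }

  blocks <- enumerate_blocks(m, materialize_rows = FALSE,
                             min_sites = min_sites)
  blocks <- annotate_geometry(blocks, m)
  n_total <- nrow(blocks)
  log_msg(n_total, " maximal perfect haplotype blocks")

  est <- mcl_selection(blocks$r, blocks$y_freq, cfg, k_block = blocks$k_block,
                       k_sample = m$k)
  blocks <- cbind(blocks, est)
  n_est <- sum(blocks$estimable)

  p_eff <- pmin(blocks$y_freq, 1 - 1 / (2 * m$k))
  dr <- drift_filter(blocks$t_hat1, p_eff, m$k, cfg)
  blocks$pass_drift <- dr$pass & blocks$estimable
  blocks$drift_threshold <- dr$threshold
  log_msg(sum(blocks$pass_drift), " blocks pass the drift filter")

  co <- coalescent_filter(blocks$t_hat2, blocks$k_block, blocks$r, lookup)
  blocks$pass_coalescent <- co$pass & blocks$estimable
  blocks$coalescent_threshold <- co$threshold
  n_both <- sum(blocks$pass_drift & blocks$pass_coalescent)
  log_msg(n_both, " blocks pass both filters")

  surv <- blocks[blocks$pass_drift & blocks$pass_coalescent, , drop = FALSE]
  if (!is.null(gaps)) {
    surv <- drop_gap_blocks(surv, gaps)
    log_msg(nrow(surv), " blocks after gap removal")
  }
  n_gap <- nrow(surv)
  reported <- drop_hidden_blocks(surv)
  log_msg(nrow(reported), " blocks reported after hidden-block removal")

  counts <- c(total = n_total, estimable = n_est,
              pass_drift = sum(blocks$pass_drift), pass_both = n_both,
              after_gaps = n_gap, reported = nrow(reported))
  out <- structure(list(reported = reported, counts = counts,
                        delta_r = cfg$delta_r, cfg = cfg, chrom = m$chrom,
                        k_sample = m$k, n_sites = m$n),
                   class = "haploscan_scan")
  if (!is.null(out_prefix)) {
    write.table(reported, paste0(out_prefix, ".blocks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rec <- data.frame(chrom = rep(m$chrom, nrow(reported)),
                      start_bp = reported$start_bp - 1,
                      end_bp = reported$end_bp, s_hat = reported$s_hat,
                      k_block = reported$k_block)
    write_track(rec, out_prefix)
    jsonlite::write_json(list(counts = as.list(counts),
                              delta_r = cfg$delta_r, Ne = cfg$Ne,
                              s_min = cfg$s_min, k_sample = m$k,
                              n_sites = m$n),
                         paste0(out_prefix, ".summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.haploscan_scan <- function(x, ...) {
  cat("haploscan scan of", x$chrom, "-", x$k_sample, "haplotypes,",
      x$n_sites, "sites\n")
  cat("  delta_r =", format(x$delta_r), " Ne =", x$cfg$Ne, "\n")
  for (nm in names(x$counts)) cat(sprintf("  %-12s %d\n", nm, x$counts[nm]))
  invisible(x)
}

#' Remove blocks overlapping assembly gaps
#'
#' Drops every block whose bp span (1-based, inclusive) intersects any gap
#' interval (0-based, half-open). A block that merely touches the half-open
#' gap end is kept.
#'
#' @param blocks Block table with `start_bp`, `end_bp`.
#' @param gaps An `interval_mask`.
#' @return The filtered block table.
#' @export
drop_gap_blocks <- function(blocks, gaps) {
  if (is.null(gaps) || nrow(gaps) == 0 || nrow(blocks) == 0) return(blocks)
  bl <- IRanges::IRanges(start = blocks$start_bp, end = blocks$end_bp)
  gp <- IRanges::IRanges(start = gaps$start_bp + 1, end = gaps$end_bp)
  blocks[IRanges::countOverlaps(bl, gp) == 0, , drop = FALSE]
}

#' Remove blocks hidden behind stronger blocks
#'
#' A block is hidden when its bp span is fully contained in the span of
#' another block with a selection coefficient at least as high; only the
#' highest coefficient is then visible at every position. Ties are broken
#' by keeping the longer block, then the earlier record.
#'
#' @param blocks Block table with `start_bp`, `end_bp`, `s_hat`.
#' @return The filtered block table.
#' @export
drop_hidden_blocks <- function(blocks) {
  n <- nrow(blocks)
  if (n <= 1) return(blocks)
  s <- blocks$s_hat; st <- blocks$start_bp; en <- blocks$end_bp
  len <- en - st
  # b is hidden iff some a with span(a) >= span(b) has lexicographically
  # higher (s, len, -index); since containment forces len_a >= len_b this
  # reproduces the documented tie-breaks exactly. Blocks are processed in
  # decreasing priority while a Fenwick tree over compressed start
  # positions holds the running prefix-maximum of end positions: a
  # processed block with st <= st[b] and en >= en[b] exists iff the
  # prefix maximum reaches en[b].
  ord <- order(-s, -len, seq_len(n))
  st_c <- match(st, sort(unique(st)))
  m <- max(st_c)
  fen <- rep(-Inf, m)
  fen_update <- function(i, val) {
    while (i <= m) { if (fen[i] < val) fen[i] <<- val; i <- i + bitwAnd(i, -i) }
  }
  fen_query <- function(i) {  # max over positions 1..i
    out <- -Inf
    while (i > 0) { if (fen[i] > out) out <- fen[i]; i <- i - bitwAnd(i, -i) }
    out
  }
  hidden <- logical(n)
  for (b in ord) {
    if (fen_query(st_c[b]) >= en[b]) hidden[b] <- TRUE
    fen_update(st_c[b], en[b])
  }
  blocks[!hidden, , drop = FALSE]
}
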