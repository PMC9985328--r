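# Readers and writers: phased VCF, PLINK genetic map, BED masks,
# genome-track output, lookup-table serialization.

#' Read a phased VCF into a haplotype matrix
#'
#' Reads a phased, fully imputed, single-chromosome VCF. Each sample
#' contributes one row per phased allele (a diploid sample contributes two
#' rows; mixed ploidy across samples is allowed). Only biallelic SNP
#' records are kept; sites with minor allele frequency below `maf_min` are
#' dropped. Alleles are used exactly as coded (REF = 0, ALT = 1): blocks
#' are polarization-independent, so no ancestral-allele handling is needed.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param maf_min Minor-allele-frequency threshold (default 0: keep all,
#'   appropriate for array data; 0.01 is recommended for sequencing data,
#'   as rare recent mutations fragment blocks that are identical by
#'   descent).
#' @param sample_exclude Character vector of sample IDs to drop.
#' @param map Optional [read_plink_map()] result; if supplied, cM positions
#'   are interpolated for every site, otherwise `pos_cm` is left at 0 and
#'   must be assigned with [assign_map()] before scanning.
#' @return A [haplotype_matrix()].
#' @export
read_phased_vcf <- function(path, maf_min = 0, sample_exclude = character(),
                            map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0) stop("read_phased_vcf: no records in ", path)
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1)
    stop("read_phased_vcf: expected one chromosome per file, found: ",
         paste(chroms, collapse = ", "))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!any(snp)) stop("read_phased_vcf: no biallelic SNP records")
  gt <- vcf@gt[snp, -1, drop = FALSE]
  pos <- as.numeric(fix[snp, "POS"])
  ids <- fix[snp, "ID"]
  samples <- colnames(gt)
  if (length(sample_exclude)) {
    keep <- !(samples %in% sample_exclude)
    gt <- gt[, keep, drop = FALSE]
    samples <- samples[keep]
  }
  if (ncol(gt) == 0) stop("read_phased_vcf: no samples left")
  # genotype field only
  gt[] <- sub(":.*$", "", gt)
  bad_mask <- grepl("/", gt, fixed = TRUE) | grepl(".", gt, fixed = TRUE)
  dim(bad_mask) <- dim(gt)
  bad <- which(bad_mask, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf(
      "read_phased_vcf: unphased or missing genotype '%s' (sample %s, %s:%s)",
      gt[b[1], b[2]], samples[b[2]], chroms, format(pos[b[1]], scientific = FALSE)))
  }
  if (anyDuplicated(pos))
    stop("read_phased_vcf: duplicate positions: ",
         paste(head(pos[duplicated(pos)], 5), collapse = ", "))
  # split each sample column into ploidy rows
  hap_rows <- list(); row_ids <- character()
  for (s in seq_along(samples)) {
    parts <- strsplit(gt[, s], "|", fixed = TRUE)
    pl <- lengths(parts)
    if (length(unique(pl)) != 1)
      stop("read_phased_vcf: inconsistent ploidy within sample ", samples[s])
    ph <- matrix(as.integer(unlist(parts)), nrow = pl[1])
    for (a in seq_len(pl[1])) {
      hap_rows[[length(hap_rows) + 1L]] <- ph[a, ]
      row_ids <- c(row_ids, paste0(samples[s], "_", a))
    }
  }
  al <- do.call(rbind, hap_rows)
  if (any(is.na(al)) || !all(al %in% c(0L, 1L)))
    stop("read_phased_vcf: non-biallelic allele index in genotypes")
  ord <- order(pos)
  al <- al[, ord, drop = FALSE]; pos <- pos[ord]
  af <- colMeans(al)
  keep <- pmin(af, 1 - af) >= maf_min
  if (!any(keep)) stop("read_phased_vcf: no sites left after MAF filter")
  al <- al[, keep, drop = FALSE]; pos <- pos[keep]
  cm <- if (!is.null(map)) interpolate_cm(map, pos) else rep(0, length(pos))
  haplotype_matrix(al, pos, cm, row_ids = row_ids, chrom = chroms)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Inverse of [read_phased_vcf()]; used to generate simulation output and
#' test fixtures that exercise the real reader. Consecutive rows are
#' grouped into samples of the given ploidy.
#'
#' @param m A [haplotype_matrix()].
#' @param path Output path.
#' @param ploidy Haplotypes per sample (default 2); must divide `k`.
#' @export
write_phased_vcf <- function(m, path, ploidy = 2) {
  stopifnot(inherits(m, "haplo_matrix"))
  if (m$k %% ploidy != 0)
    stop("write_phased_vcf: k is not a multiple of the ploidy")
  ns <- m$k %/% ploidy
  sample_ids <- paste0("S", seq_len(ns))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", m$chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  gt_cols <- vapply(seq_len(ns), function(s) {
    rows <- ((s - 1) * ploidy + 1):(s * ploidy)
    apply(m$alleles[rows, , drop = FALSE], 2, paste, collapse = "|")
  }, character(m$n))
  if (m$n == 1) gt_cols <- matrix(gt_cols, nrow = 1)
  lines <- paste(m$chrom, format(m$pos_bp, scientific = FALSE, trim = TRUE),
                 paste0("snp", seq_len(m$n)), "A", "C", ".", "PASS", ".", "GT",
                 apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a PLINK-format genetic map
#'
#' One whitespace-delimited line per variant: chromosome code, variant ID,
#' position in centimorgan, position in base pairs. Entries are returned
#' sorted by bp; a map whose cM column is non-monotone after sorting is
#' rejected as corrupt.
#'
#' @param path Path to the `.map` file.
#' @return A data.frame of class `genetic_map` with columns `chrom`, `id`,
#'   `cm`, `bp`.
#' @export
read_plink_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("read_plink_map: empty map file")
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 4))
    stop("read_plink_map: expected 4 fields, got ", nf[which(nf != 4)[1]],
         " at line ", which(nf != 4)[1])
  chrom <- vapply(parts, `[`, "", 1)
  id <- vapply(parts, `[`, "", 2)
  cm <- as.numeric(vapply(parts, `[`, "", 3))
  bp <- as.numeric(vapply(parts, `[`, "", 4))
  if (any(is.na(cm)) || any(is.na(bp)))
    stop("read_plink_map: non-numeric cM/bp at line ",
         which(is.na(cm) | is.na(bp))[1])
  ord <- order(chrom, bp)
  out <- data.frame(chrom = chrom[ord], id = id[ord], cm = cm[ord],
                    bp = bp[ord], stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    sel <- out$chrom == ch
    if (anyDuplicated(out$bp[sel]))
      stop("read_plink_map: duplicate bp positions on chromosome ", ch)
    if (any(diff(out$cm[sel]) < 0))
      stop("read_plink_map: cM positions decrease along chromosome ", ch,
           " (corrupt map)")
  }
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Write a PLINK-format genetic map
#'
#' @param map A `genetic_map` (or data.frame with `chrom`, `id`, `cm`,
#'   `bp`).
#' @param path Output path.
#' @export
write_plink_map <- function(map, path) {
  write.table(map[, c("chrom", "id", "cm", "bp")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate genetic-map position for arbitrary bp coordinates
#'
#' Linear interpolation between flanking map entries; queries before the
#' first or after the last entry are clamped to the terminal cM values, so
#' the result is monotone in `pos_bp`.
#'
#' @param map A `genetic_map` with at least 2 entries.
#' @param pos_bp Physical positions to interpolate (vectorized).
#' @return Genetic positions in centimorgan.
#' @export
interpolate_cm <- function(map, pos_bp) {
  if (is.null(map) || nrow(map) == 0) stop("interpolate_cm: empty map")
  if (nrow(map) < 2) stop("interpolate_cm: need at least 2 map entries")
  approx(map$bp, map$cm, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' Assign genetic-map coordinates to a haplotype matrix
#'
#' @param m A [haplotype_matrix()].
#' @param map A `genetic_map`.
#' @return The matrix with `pos_cm` interpolated from the map.
#' @export
assign_map <- function(m, map) {
  stopifnot(inherits(m, "haplo_matrix"))
  haplotype_matrix(m$alleles, m$pos_bp, interpolate_cm(map, m$pos_bp),
                   m$row_ids, m$chrom)
}

#' Read a BED mask
#'
#' Reads BED3+ intervals (0-based half-open), merges overlapping and
#' touching intervals and returns them sorted.
#'
#' @param path Path to a BED file; `track`/`browser`/comment lines are
#'   skipped.
#' @return A data.frame of class `interval_mask` with columns `start_bp`,
#'   `end_bp` (0-based half-open).
#' @export
read_bed_mask <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(interval_mask(numeric(), numeric()))
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) < 3))
    stop("read_bed_mask: fewer than 3 fields at line ",
         lineno[which(lengths(parts) < 3)[1]])
  start <- as.numeric(vapply(parts, `[`, "", 2))
  end <- as.numeric(vapply(parts, `[`, "", 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("read_bed_mask: invalid interval (start >= end) at line ", lineno[bad[1]])
  interval_mask(start, end)
}

#' Construct an interval mask
#'
#' @param start_bp,end_bp 0-based half-open interval bounds.
#' @return An `interval_mask`: merged, sorted, non-overlapping intervals.
#' @export
interval_mask <- function(start_bp, end_bp) {
  if (length(start_bp) == 0) {
    out <- data.frame(start_bp = numeric(), end_bp = numeric())
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(start = start_bp + 1, end = end_bp))
    out <- data.frame(start_bp = IRanges::start(ir) - 1,
                      end_bp = IRanges::end(ir))
  }
  class(out) <- c("interval_mask", "data.frame")
  out
}

#' Write genome-track files
#'
#' Writes (a) a BED5 file with one line per block — name `s=<s_hat>;k=<K>`,
#' score `min(1000, round(s_hat * 10000))` — and (b) a bedGraph of the
#' per-position maximum selection coefficient. Records are 0-based
#' half-open; unsorted input is sorted internally.
#'
#' @param records Data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open), `s_hat`, `k_block`.
#' @param out_prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.bedgraph`.
#' @return Invisibly, the two file paths.
#' @export
write_track <- function(records, out_prefix) {
  if (nrow(records) > 0 && any(records$s_hat < 0))
    stop("write_track: negative selection coefficient")
  bed_path <- paste0(out_prefix, ".bed")
  bg_path <- paste0(out_prefix, ".bedgraph")
  records <- records[order(records$chrom, records$start_bp, records$end_bp), ,
                     drop = FALSE]
  bed_con <- file(bed_path, "w"); on.exit(close(bed_con), add = TRUE)
  writeLines('track name="haploscan_blocks" description="selection coefficients per haplotype block"',
             bed_con)
  if (nrow(records) > 0) {
    writeLines(paste(records$chrom,
                     format(records$start_bp, scientific = FALSE, trim = TRUE),
                     format(records$end_bp, scientific = FALSE, trim = TRUE),
                     sprintf("s=%.4f;k=%d", records$s_hat, records$k_block),
                     pmin(1000, round(records$s_hat * 10000)),
                     sep = "\t"), bed_con)
  }
  bg_con <- file(bg_path, "w"); on.exit(close(bg_con), add = TRUE)
  writeLines('track type=bedGraph name="haploscan_shat" description="per-position maximum selection coefficient"',
             bg_con)
  if (nrow(records) > 0) {
    for (ch in unique(records$chrom)) {
      rec <- records[records$chrom == ch, , drop = FALSE]
      seg <- coverage_max(rec$start_bp, rec$end_bp, rec$s_hat)
      writeLines(paste(ch,
                       format(seg$start, scientific = FALSE, trim = TRUE),
                       format(seg$end, scientific = FALSE, trim = TRUE),
                       format(seg$value, trim = TRUE),
                       sep = "\t"), bg_con)
    }
  }
  invisible(c(bed = bed_path, bedgraph = bg_path))
}

# Per-position maximum of values over half-open intervals, returned as
# maximal constant segments.
coverage_max <- function(start, end, value) {
  bp <- sort(unique(c(start, end)))
  if (length(bp) < 2) return(data.frame(start = numeric(), end = numeric(),
                                        value = numeric()))
  seg_start <- bp[-length(bp)]; seg_end <- bp[-1]
  val <- rep(NA_real_, length(seg_start))
  for (t in seq_along(start)) {
    cover <- seg_start >= start[t] & seg_end <= end[t]
    val[cover] <- pmax(val[cover], value[t], na.rm = TRUE)
  }
  keep <- !is.na(val)
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]; val <- val[keep]
  # merge adjacent equal-valued segments
  if (length(val) > 1) {
    brk <- c(TRUE, val[-1] != val[-length(val)] |
               seg_start[-1] != seg_end[-length(val)])
    grp <- cumsum(brk)
    seg_start <- tapply(seg_start, grp, min)
    seg_end <- tapply(seg_end, grp, max)
    val <- tapply(val, grp, `[`, 1)
  }
  data.frame(start = as.numeric(seg_start), end = as.numeric(seg_end),
             value = as.numeric(val))
}

#' Serialize a TMRCA lookup table
#'
#' Self-describing tab-separated text: header lines `#Ne=`, `#level=`,
#' `#k_grid=`, `#r_grid=`, then the first-percentile matrix (rows = k,
#' columns = r) at full double precision, so the round-trip is exact.
#'
#' @param table A `tmrca_lookup` from [build_lookup_table()].
#' @param path Output path.
#' @export
write_lookup_table <- function(table, path) {
  stopifnot(inherits(table, "tmrca_lookup"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#Ne=", format(table$Ne, scientific = FALSE)),
               paste0("#level=", sprintf("%.17g", table$level)),
               paste0("#k_grid=", paste(table$k_grid, collapse = ",")),
               paste0("#r_grid=", paste(sprintf("%.17g", table$r_grid),
                                        collapse = ","))), con)
  writeLines(apply(table$q01, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_lookup_table
#' @return `read_lookup_table()` returns the `tmrca_lookup`.
#' @export
read_lookup_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^#", key, "="), "", grep(paste0("^#", key, "="),
                                                            hdr, value = TRUE))
  Ne <- as.numeric(get("Ne"))
  level <- as.numeric(get("level"))
  k_grid <- as.integer(strsplit(get("k_grid"), ",")[[1]])
  r_grid <- as.numeric(strsplit(get("r_grid"), ",")[[1]])
  body <- lines[!grepl("^#", lines)]
  q01 <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  dimnames(q01) <- list(k_grid, signif(r_grid, 8))
  structure(list(Ne = Ne, k_grid = k_grid, r_grid = r_grid, q01 = q01,
                 level = level), class = "tmrca_lookup")
}
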