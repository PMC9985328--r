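#' Binary haplotype matrix
#'
#' Container for `k` phased binary haplotypes over `n` biallelic sites with
#' physical (bp) and genetic-map (cM) coordinates. Rows are haplotypes
#' (one per sample chromosome), columns are sites ordered by position.
#'
#' @param alleles Integer matrix of 0/1 values, `k x n`.
#' @param pos_bp 1-based physical positions, strictly increasing, length `n`.
#' @param pos_cm Genetic-map positions in centimorgan, non-decreasing,
#'   length `n`.
#' @param row_ids Haplotype labels (default `hap1..hapk`).
#' @param chrom Chromosome name carried through to track output.
#' @return An object of class `haplo_matrix`.
#' @export
haplotype_matrix <- function(alleles, pos_bp, pos_cm, row_ids = NULL,
                             chrom = "chr1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  k <- nrow(alleles); n <- ncol(alleles)
  if (k < 2) stop("haplotype_matrix: need at least 2 haplotypes")
  if (n < 1) stop("haplotype_matrix: need at least 1 site")
  if (!all(alleles %in% c(0L, 1L))) stop("haplotype_matrix: alleles must be 0/1 with no missing values")
  if (length(pos_bp) != n || length(pos_cm) != n)
    stop("haplotype_matrix: positions must match the number of columns")
  if (any(diff(pos_bp) <= 0)) stop("haplotype_matrix: pos_bp must be strictly increasing")
  if (any(diff(pos_cm) < 0)) stop("haplotype_matrix: pos_cm must be non-decreasing")
  if (is.null(row_ids)) row_ids <- paste0("hap", seq_len(k))
  structure(list(alleles = alleles, pos_bp = as.numeric(pos_bp),
                 pos_cm = as.numeric(pos_cm), row_ids = as.character(row_ids),
                 chrom = chrom, k = k, n = n),
            class = "haplo_matrix")
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat("haplo_matrix:", x$k, "haplotypes x", x$n, "sites,",
      x$chrom, sprintf("[%d, %d] bp, [%.4g, %.4g] cM\n",
                       as.integer(x$pos_bp[1]), as.integer(x$pos_bp[x$n]),
                       x$pos_cm[1], x$pos_cm[x$n]))
  invisible(x)
}

#' Subset sites of a haplotype matrix
#'
#' @param m A `haplo_matrix`.
#' @param cols Column indices (logical or integer), kept in position order.
#' @return A `haplo_matrix` over the selected sites.
#' @export
subset_sites <- function(m, cols) {
  stopifnot(inherits(m, "haplo_matrix"))
  idx <- seq_len(m$n)[cols]
  idx <- sort(idx)
  if (length(idx) < 1) stop("subset_sites: no sites left")
  haplotype_matrix(m$alleles[, idx, drop = FALSE], m$pos_bp[idx],
                   m$pos_cm[idx], m$row_ids, m$chrom)
}
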