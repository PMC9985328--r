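#' One positional Burrows-Wheeler transform column update
#'
#' Advances the pBWT arrays from column `j-1` to column `j`. `a` orders the
#' rows by colexicographically sorted prefixes `s[a[r]][1..j]`; `d[r]` is
#' the start of the longest common suffix of the prefixes in sorted rows
#' `r-1` and `r`, with `d[1] = j + 1` by convention. Each call is O(k).
#'
#' @param prev A list with elements `a` (permutation of `1..k`), `d`
#'   (divergence values) and `j` (the column the arrays describe); use
#'   [pbwt_init()] for the state before the first column.
#' @param column_alleles Binary vector, one allele per row in original
#'   order.
#' @return A list `a`, `d`, `j` for the next column.
#' @export
pbwt_step <- function(prev, column_alleles) {
  stopifnot(length(prev$a) == length(column_alleles))
  if (!all(column_alleles %in% c(0L, 1L))) stop("pbwt_step: non-binary allele")
  pbwt_step_cpp(as.integer(prev$a), as.integer(prev$d),
                as.integer(column_alleles), as.integer(prev$j) + 1L)
}

#' @rdname pbwt_step
#' @param k Number of haplotype rows.
#' @export
pbwt_init <- function(k) {
  list(a = seq_len(k), d = rep(1L, k), j = 0L)
}

#' Enumerate all maximal perfect haplotype blocks
#'
#' A maximal perfect haplotype block is a set `K` of at least two haplotypes
#' identical over a column interval `[i, j]` that cannot be extended to the
#' left, to the right, or by an additional haplotype. All blocks are found
#' in O(nk + z) time via the positional Burrows-Wheeler transform. Blocks
#' are emitted grouped by end column `j`, within a column by decreasing
#' nesting (innermost lcp-interval first); the order is a stable convention.
#'
#' @param m A [haplotype_matrix()].
#' @param materialize_rows If `TRUE`, attach the exact haplotype row indices
#'   of every block (list column `rows`). Off by default: chromosome-scale
#'   scans can produce millions of blocks.
#' @param min_sites Minimum number of sites per block (default 1; the block
#'   definition permits single-column blocks).
#' @return A data.frame with columns `i`, `j` (1-based column interval) and
#'   `k_block` (number of haplotypes), plus `rows` when materialized.
#' @export
enumerate_blocks <- function(m, materialize_rows = FALSE, min_sites = 1L) {
  stopifnot(inherits(m, "haplo_matrix"))
  res <- pbwt_blocks_cpp(m$alleles, materialize_rows, as.integer(min_sites))
  out <- data.frame(i = res$i, j = res$j, k_block = res$k_block)
  if (materialize_rows) out$rows <- res$rows
  out
}

#' Brute-force haplotype block enumeration (testing oracle)
#'
#' Enumerates blocks directly from the definition: every column interval is
#' scanned, rows are grouped by their substring, and each group of size >= 2
#' is kept if it satisfies left-, right- and row-maximality. Exponentially
#' slower than [enumerate_blocks()]; guarded to small inputs.
#'
#' @param m A [haplotype_matrix()] with `k <= 16` and `n <= 32`.
#' @return A data.frame with columns `i`, `j`, `k_block`, `rows` (list of
#'   sorted row indices), sorted by `(j, i, first row)`.
#' @export
naive_blocks <- function(m) {
  stopifnot(inherits(m, "haplo_matrix"))
  if (m$k > 16 || m$n > 32) stop("naive_blocks: input too large (k <= 16, n <= 32)")
  al <- m$alleles
  res <- list(); nres <- 0L
  for (i in seq_len(m$n)) for (j in i:m$n) {
    key <- apply(al[, i:j, drop = FALSE], 1, paste, collapse = "")
    for (grp in split(seq_len(m$k), key)) {
      if (length(grp) < 2) next
      # row-maximality: grp holds all rows with this substring by construction
      if (i > 1 && length(unique(al[grp, i - 1])) == 1) next  # left-extensible
      if (j < m$n && length(unique(al[grp, j + 1])) == 1) next  # right-extensible
      nres <- nres + 1L
      res[[nres]] <- list(i = i, j = j, rows = sort(grp))
    }
  }
  if (nres == 0L)
    return(data.frame(i = integer(), j = integer(), k_block = integer(),
                      rows = I(list())))
  out <- data.frame(i = vapply(res, `[[`, 1L, "i"),
                    j = vapply(res, `[[`, 1L, "j"),
                    k_block = vapply(res, function(b) length(b$rows), 1L))
  out$rows <- lapply(res, `[[`, "rows")
  out[order(out$j, out$i, vapply(out$rows, `[`, 1L, 1)), , drop = FALSE]
}

#' Attach block geometry
#'
#' Adds the quantities the sweep model needs to a block table: sample
#' frequency `y_freq = k_block / k`, genetic length
#' `d_cm = pos_cm[j] - pos_cm[i]`, recombination fraction `r = haldane(d_cm)`
#' and the physical span `start_bp`, `end_bp`.
#'
#' @param blocks A block data.frame from [enumerate_blocks()].
#' @param m The [haplotype_matrix()] the blocks were enumerated from.
#' @return The block table with columns `y_freq`, `d_cm`, `r`, `start_bp`,
#'   `end_bp` added.
#' @export
annotate_geometry <- function(blocks, m) {
  stopifnot(inherits(m, "haplo_matrix"))
  blocks$y_freq <- blocks$k_block / m$k
  blocks$d_cm <- m$pos_cm[blocks$j] - m$pos_cm[blocks$i]
  blocks$r <- haldane(blocks$d_cm)
  blocks$start_bp <- m$pos_bp[blocks$i]
  blocks$end_bp <- m$pos_bp[blocks$j]
  blocks
}
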