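# Shared fixtures and small utilities for the suite.

random_haplo_matrix <- function(k, n, p = 0.5) {
  al <- matrix(rbinom(k * n, 1, p), k, n)
  haplotype_matrix(al, seq_len(n), 0.01 * seq_len(n))
}

# canonical key of a block set (rows must be materialized)
block_keys <- function(df) {
  if (nrow(df) == 0) return(character())
  apply(cbind(df$i, df$j, df$k_block,
              vapply(df$rows, function(r) paste(sort(r), collapse = ","), "")),
        1, paste, collapse = "|")
}

# direct maximality re-check of a materialized block
block_is_maximal <- function(m, i, j, rows) {
  al <- m$alleles
  sub <- al[rows, i:j, drop = FALSE]
  equal <- all(apply(sub, 2, function(col) length(unique(col)) == 1))
  others <- setdiff(seq_len(m$k), rows)
  row_max <- !any(vapply(others, function(o)
    all(al[o, i:j] == al[rows[1], i:j]), TRUE))
  left_max <- i == 1 || length(unique(al[rows, i - 1])) > 1
  right_max <- j == m$n || length(unique(al[rows, j + 1])) > 1
  equal && row_max && left_max && right_max
}

# write a minimal phased VCF from explicit genotype strings
write_fixture_vcf <- function(path, records, samples) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  writeLines(records, con)
  invisible(path)
}
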