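# Brute-force oracles, deliberately naive: per-bp set arithmetic and
# all-pairs loops, independent of the package's interval code paths.

# per-bp reciprocal overlap of two 1-based inclusive intervals
oracle_ro <- function(chrom1, s1, e1, chrom2, s2, e2) {
  if (chrom1 != chrom2) return(0)
  a <- s1:e1
  b <- s2:e2
  ov <- length(intersect(a, b))
  min(ov / length(a), ov / length(b))
}

# per-bp >= 1 bp overlap of an interval with any interval in a table
oracle_overlaps_any <- function(chrom, s, e, iv) {
  for (i in seq_len(nrow(iv))) {
    if (iv$chrom[i] != chrom) next
    if (length(intersect(s:e, iv$start[i]:iv$end[i])) > 0) return(TRUE)
  }
  FALSE
}

# per-bp union size of intervals within a chromosome set
oracle_union_bp <- function(iv, chroms) {
  iv <- iv[iv$chrom %in% chroms, , drop = FALSE]
  if (!nrow(iv)) return(0)
  sum(vapply(split(iv, iv$chrom), function(x) {
    length(unique(unlist(mapply(seq, x$start, x$end, SIMPLIFY = FALSE))))
  }, numeric(1)))
}

# random small call tables on a toy genome
random_calls <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                         max_len = 5000, samples = paste0("S", 1:5)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  cnv_calls(sample_id = sample(samples, n, replace = TRUE),
            chrom = sample(chroms, n, replace = TRUE),
            start = start, end = start + len - 1,
            copy_state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
            n_markers = sample(3:50, n, replace = TRUE))
}

# Rand index between two partitions given as label vectors (NA = singleton)
rand_index <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- paste0("singA", seq_along(a))[is.na(a)]
  b[is.na(b)] <- paste0("singB", seq_along(b))[is.na(b)]
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

toy_genome <- function() genome_def(c(chr1 = 2e5, chr2 = 2e5, chrX = 2e5))
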