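#' Pairwise SNP genetic distance
#'
#' For each sample pair, the distance is the fraction of loci at which both
#' samples have a genotype call and the genotypes differ (heterozygous AB
#' differs from both homozygotes). Loci where either sample is `NoCall` are
#' excluded from numerator and denominator, so shared no-calls are never a
#' difference; the normalization by co-called loci makes the distance
#' comparable across pairs and with the CNV distance.
#'
#' @param genotypes Character matrix (probe x sample) over
#'   `AA`/`AB`/`BB`/`NoCall`.
#' @return A `dist_matrix`: symmetric matrix with zero diagonal and
#'   attribute `kind = "snp"`.
#' @export
snp_distance <- function(genotypes) {
  if (ncol(genotypes) < 2) stop("need at least 2 samples")
  g <- matrix(match(genotypes, c("AA", "AB", "BB")), nrow(genotypes),
              dimnames = dimnames(genotypes))
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(g[, i]) & !is.na(g[, j])
      if (!any(both))
        stop("no co-called loci for pair ", colnames(g)[i], " / ", colnames(g)[j])
      d[i, j] <- d[j, i] <- mean(g[both, i] != g[both, j])
    }
  }
  dist_matrix(d, kind = "snp")
}

dist_matrix <- function(d, kind) {
  structure(d, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' Per-probe copy-state vectors for each sample
#'
#' Every autosomal probe receives the diploid baseline state 2 unless it lies
#' within one of the sample's calls, in which case it receives the collapsed
#' state (0, 1 or 3 for "3+"). When a probe falls inside two overlapping
#' same-sample calls with different states, the most extreme departure from 2
#' wins, ties resolving to the deletion; a warning is logged.
#'
#' @param calls QC-filtered call table.
#' @param probes Probe table; X/Y-chromosome probes are excluded (sex
#'   confounds the baseline).
#' @param samples Character vector of sample ids defining the columns.
#' @param genome A [genome_def()] (for the autosome set).
#' @return Integer matrix (probe x sample) of collapsed states.
#' @export
probe_state_matrix <- function(calls, probes, samples, genome) {
  probes <- probes[probes$chrom %in% genome$autosomes, , drop = FALSE]
  m <- matrix(2L, nrow(probes), length(samples),
              dimnames = list(probes$id, samples))
  calls <- calls[calls$sample_id %in% samples &
                 calls$chrom %in% genome$autosomes, , drop = FALSE]
  if (!nrow(calls)) return(m)
  collapsed <- pmin(calls$copy_state, 3L)
  conflict <- FALSE
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    pi <- which(probes$chrom == ch)
    if (!length(pi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(probes$pos[pi]), as.integer(probes$pos[pi])),
      IRanges::IRanges(as.integer(calls$start[ci]), as.integer(calls$end[ci])))
    if (!length(hits)) next
    p <- pi[S4Vectors::queryHits(hits)]
    k <- ci[S4Vectors::subjectHits(hits)]
    col <- match(calls$sample_id[k], samples)
    st <- collapsed[k]
    # extremeness from baseline 2; deletions win ties (rank 0,1 states above 3+)
    score <- abs(st - 2L) * 2L + (st < 2L)
    ord <- order(score)  # ascending: later (more extreme) assignments win
    idx <- cbind(p[ord], col[ord])
    key <- paste(p, col)
    if (any(tapply(st, key, function(s) length(unique(s))) > 1)) conflict <- TRUE
    m[idx] <- st[ord]
  }
  if (conflict)
    warning("probe(s) inside overlapping same-sample calls with different ",
            "states; most extreme departure from 2 kept (ties -> deletion)")
  m
}

#' Pairwise CNV genetic distance
#'
#' Each sample's calls are projected onto the probe map as collapsed copy
#' states (see [probe_state_matrix()]); the distance between two samples is
#' the number of probes at which their states differ divided by the total
#' number of probes.
#'
#' @inheritParams probe_state_matrix
#' @return A `dist_matrix` with attribute `kind = "cnv"`.
#' @export
cnv_distance <- function(calls, probes, samples, genome) {
  m <- probe_state_matrix(calls, probes, samples, genome)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(m[, i] != m[, j])
    }
  }
  dist_matrix(d, kind = "cnv")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (agglomeration by the Q-criterion).
#' Sample ids are sorted lexicographically before agglomeration so ties break
#' deterministically. Negative branch lengths, allowed by the NJ algorithm,
#' are retained and flagged with a warning.
#'
#' @param d A `dist_matrix` (or any symmetric matrix with labels).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 samples for a tree")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0))
    warning("tree contains negative branch lengths (NJ convention)")
  tr
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centered Gram-matrix eigendecomposition via `stats::cmdscale`,
#' returning the top-`k` coordinates ordered by eigenvalue. The sign of each
#' axis is fixed so that its largest-magnitude loading is positive, making
#' embeddings reproducible across platforms.
#'
#' @param d A `dist_matrix`.
#' @param k Number of dimensions (default 2).
#' @return Numeric matrix (sample x k) of coordinates.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (nrow(d) < k + 1) stop("need at least k + 1 samples")
  if (all(d == 0)) return(matrix(0, nrow(d), k, dimnames = list(rownames(d))))
  co <- stats::cmdscale(stats::as.dist(d), k = k)
  if (ncol(co) < k)  # degenerate configurations can drop axes
    co <- cbind(co, matrix(0, nrow(co), k - ncol(co)))
  for (a in seq_len(k)) {
    m <- which.max(abs(co[, a]))
    if (co[m, a] < 0) co[, a] <- -co[, a]
  }
  colnames(co) <- paste0("PCO", seq_len(k))
  co
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries. Significance comes from `n_perm` simultaneous row/column
#' permutations of the second matrix, one-sided for positive association:
#' `p = (1 + #{r_perm >= r}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist_matrix` objects over the same samples in the same order.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return List with `statistic` (r) and `p_value`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2))) stop("matrices must have the same samples")
  lt <- lower.tri(d1)
  x <- d1[lt]
  if (stats::sd(x) == 0 || stats::sd(d2[lt]) == 0)
    stop("constant distance matrix: correlation undefined")
  r_obs <- stats::cor(x, d2[lt])
  n <- nrow(d1)
  count <- 0L
  withr_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(n)
      r_p <- stats::cor(x, d2[perm, perm][lt])
      if (r_p >= r_obs) count <- count + 1L
    }
  })
  list(statistic = r_obs, p_value = (1 + count) / (1 + n_perm))
}

#' Exclude samples with extreme call counts
#'
#' Optional distance-analysis filter: removes samples whose call counts are
#' above the given percentile of the per-sample call-count distribution.
#'
#' @param calls Call table.
#' @param percentile Exclusion threshold (default 0.95).
#' @return Call table without the high-call-count samples.
#' @export
exclude_high_call_samples <- function(calls, percentile = 0.95) {
  counts <- table(calls$sample_id)
  cutoff <- stats::quantile(as.numeric(counts), percentile, names = FALSE)
  keep <- names(counts)[as.numeric(counts) <= cutoff]
  calls[calls$sample_id %in% keep, , drop = FALSE]
}
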