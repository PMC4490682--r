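#' Heterozygous fraction of SNP genotypes inside deletion calls
#'
#' Genotype calls for SNP markers inside a true deletion must be homozygous
#' (hemizygous DNA cannot produce AB), so the AB fraction among called SNP
#' probes inside each deletion gauges whether the call is genuine. `NoCall`
#' genotypes are excluded from the denominator; calls with no called SNP
#' probe inside are untestable and return `NA`.
#'
#' @param calls Deletion call table (`copy_state` 0 or 1).
#' @param genotypes Genotype matrix (probe x sample).
#' @param probes Probe table (SNP probes are used).
#' @return Numeric vector per call: AB fraction, or `NA` when untestable.
#' @export
call_het_fraction <- function(calls, genotypes, probes) {
  if (any(calls$copy_state >= 2))
    stop("heterozygosity testing applies to deletion calls only")
  snp <- probes[probes$type == "SNP" & probes$id %in% rownames(genotypes), ,
                drop = FALSE]
  out <- rep(NA_real_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    inside <- snp$chrom == calls$chrom[i] &
      snp$pos >= calls$start[i] & snp$pos <= calls$end[i]
    if (!any(inside)) next
    g <- genotypes[snp$id[inside], calls$sample_id[i]]
    called <- g != "NoCall"
    if (!any(called)) next
    out[i] <- mean(g[called] == "AB")
  }
  out
}

#' Heterozygosity-based false-discovery estimate for deletion calls
#'
#' Applies the rule that a deletion call is a putative false positive when
#' strictly more than `het_threshold` (default 10 %) of its called SNP
#' genotypes are heterozygous. Amplifications are never tested. Reports both
#' the pooled rate (flagged / testable) and the mean of per-sample rates.
#'
#' @param calls Call table (deletions are selected internally).
#' @param genotypes Genotype matrix.
#' @param probes Probe table.
#' @param het_threshold Flagging threshold on the AB fraction (strict `>`).
#' @return Object of class `fdr_report`: `n_deletions`, `n_testable`,
#'   `n_flagged`, `fdr` (pooled), `fdr_per_sample_mean`, `het_fraction`
#'   (per testable deletion), `flagged` (logical per testable deletion).
#' @export
estimate_fdr <- function(calls, genotypes, probes, het_threshold = 0.10) {
  dels <- calls[calls$copy_state < 2, , drop = FALSE]
  if (!nrow(dels)) stop("no deletion calls to test")
  het <- call_het_fraction(dels, genotypes, probes)
  testable <- !is.na(het)
  if (!any(testable)) stop("no testable deletions (no called SNP probes inside)")
  flagged <- het[testable] > het_threshold
  per_sample <- tapply(flagged, dels$sample_id[testable], mean)
  structure(list(
    n_deletions = nrow(dels),
    n_testable = sum(testable),
    n_flagged = sum(flagged),
    fdr = mean(flagged),
    fdr_per_sample_mean = mean(per_sample),
    het_fraction = het[testable],
    flagged = flagged,
    het_threshold = het_threshold
  ), class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("Deletion false-discovery estimate (het > %.0f%% rule)\n",
              100 * x$het_threshold))
  cat(sprintf("  deletions: %d; testable: %d; flagged: %d\n",
              x$n_deletions, x$n_testable, x$n_flagged))
  cat(sprintf("  pooled FDR: %.1f%%; per-sample mean: %.1f%%\n",
              100 * x$fdr, 100 * x$fdr_per_sample_mean))
  invisible(x)
}

#' Compare per-sample genotype rates inside calls between two groups
#'
#' For each sample, the rate is the fraction of genotype calls of the given
#' kind (`het` = AB among called genotypes, `nocall` = NoCall among all
#' genotypes) over SNP probes inside that sample's calls of the given region
#' type. The two groups are compared with a two-sided Wilcoxon rank-sum test.
#' Samples with no in-call SNP probes are omitted.
#'
#' @param calls Call table.
#' @param genotypes Genotype matrix.
#' @param probes Probe table.
#' @param group1,group2 Character vectors of sample ids.
#' @param rate `"het"` or `"nocall"`.
#' @param region `"deletions"` (states < 2) or `"amplifications"` (states > 2).
#' @return List with `rates1`, `rates2` (named per-sample rates) and
#'   `p_value`.
#' @export
group_rate_test <- function(calls, genotypes, probes, group1, group2,
                            rate = c("het", "nocall"),
                            region = c("deletions", "amplifications")) {
  rate <- match.arg(rate)
  region <- match.arg(region)
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  sub <- if (region == "deletions") calls[calls$copy_state < 2, , drop = FALSE]
         else calls[calls$copy_state > 2, , drop = FALSE]
  snp <- probes[probes$type == "SNP" & probes$id %in% rownames(genotypes), ,
                drop = FALSE]
  sample_rate <- function(s) {
    cs <- sub[sub$sample_id == s, , drop = FALSE]
    if (!nrow(cs)) return(NA_real_)
    inside <- overlaps_feature(
      data.frame(chrom = snp$chrom, start = snp$pos, end = snp$pos),
      cs[, c("chrom", "start", "end")])
    if (!any(inside)) return(NA_real_)
    g <- genotypes[snp$id[inside], s]
    if (rate == "nocall") mean(g == "NoCall")
    else {
      called <- g != "NoCall"
      if (!any(called)) NA_real_ else mean(g[called] == "AB")
    }
  }
  r1 <- vapply(group1, sample_rate, numeric(1))
  r2 <- vapply(group2, sample_rate, numeric(1))
  r1 <- r1[!is.na(r1)]; r2 <- r2[!is.na(r2)]
  if (!length(r1) || !length(r2))
    stop("a group has no sample with in-call SNP probes")
  p <- suppressWarnings(stats::wilcox.test(r1, r2)$p.value)
  list(rates1 = r1, rates2 = r2, p_value = p)
}
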