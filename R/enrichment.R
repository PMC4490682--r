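#' Does each call overlap a feature track by at least 1 bp?
#'
#' @param calls Call table (or any interval data.frame).
#' @param track A [feature_track()] or a plain interval data.frame.
#' @return Logical vector per call.
#' @export
overlaps_feature <- function(calls, track) {
  iv <- if (inherits(track, "feature_track")) track$intervals else track
  out <- logical(nrow(calls))
  if (!nrow(calls) || !nrow(iv)) return(out)
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    ri <- which(iv$chrom == ch)
    if (!length(ri)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(calls$start[ci]), as.integer(calls$end[ci])),
      IRanges::IRanges(as.integer(iv$start[ri]), as.integer(iv$end[ri])))
    out[ci[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  out
}

# per-permutation substream seed, kept inside 32-bit integer range
perm_seed <- function(seed, p) as.integer((as.numeric(seed) + p) %% 2147483647)

#' Randomly replace calls within their chromosomes
#'
#' Each call keeps its chromosome and exact length; its new start is drawn
#' uniformly from `[1, chrom_len - length + 1]`. Shuffled calls are placed
#' independently and may overlap one another -- the null preserves only the
#' chromosome assignment and the size distribution.
#'
#' @param calls Call table.
#' @param genome A [genome_def()].
#' @param seed Integer seed; the placement is a pure function of
#'   (`calls`, `seed`).
#' @return Call table with new `start`/`end`.
#' @export
shuffle_calls <- function(calls, genome, seed) {
  len <- cnv_length(calls)
  chrlen <- chrom_length(genome, calls$chrom)
  if (any(len > chrlen))
    stop("call longer than its chromosome (row ", which(len > chrlen)[1], ")")
  out <- calls
  withr_seed(perm_seed(seed, 0), {
    out$start <- floor(stats::runif(nrow(calls)) * (chrlen - len + 1)) + 1
  })
  out$end <- out$start + len - 1
  out
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Permutation test for feature enrichment or depletion
#'
#' The observed statistic is the number of calls sharing at least 1 bp with
#' the track. The null distribution reshuffles the calls `n_perm` times within
#' their chromosomes (size- and chromosome-preserving, see [shuffle_calls()])
#' and recounts. The 95 % interval is read off the ascending sorted null at
#' 1-based ranks 25 and 975 when `n_perm = 1000` (scaled as
#' `round(0.025 n)` / `round(0.975 n)` otherwise). The verdict is strict:
#' `enriched` iff observed > upper bound, `depleted` iff observed < lower
#' bound, otherwise `ns`. Each permutation uses its own derived RNG substream,
#' so the null is reproducible and order-independent.
#'
#' @param calls Call table (already subset to the set under test, e.g.
#'   deletions only or calls >= 10 kb).
#' @param track A [feature_track()].
#' @param genome A [genome_def()].
#' @param n_perm Number of shuffles (>= 40; default 1000).
#' @param seed Integer seed.
#' @param subset Label recorded in the result (default `"all"`).
#' @return Object of class `enrichment_result`: `feature`, `subset`,
#'   `observed`, `null` (integer vector), `ci_low`, `ci_high`, `verdict`.
#' @export
enrichment_test <- function(calls, track, genome, n_perm = 1000, seed = 1,
                            subset = "all") {
  if (!nrow(calls)) stop("empty call set")
  if (n_perm < 40) stop("n_perm must be at least 40")
  iv <- if (inherits(track, "feature_track")) track$intervals else track
  observed <- sum(overlaps_feature(calls, iv))

  len <- cnv_length(calls)
  chrlen <- chrom_length(genome, calls$chrom)
  if (any(len > chrlen)) stop("call longer than its chromosome")
  n <- nrow(calls)
  # all permutations' starts, one derived substream per permutation
  starts <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) {
    withr_seed(perm_seed(seed, p), {
      starts[, p] <- floor(stats::runif(n) * (chrlen - len + 1)) + 1
    })
  }
  null <- integer(n_perm)
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    ri <- which(iv$chrom == ch)
    if (!length(ri)) next
    st <- as.vector(starts[ci, , drop = FALSE])          # call-major per perm
    ln <- rep(len[ci], times = n_perm)
    q <- IRanges::IRanges(start = as.integer(st), width = as.integer(ln))
    s <- IRanges::IRanges(as.integer(iv$start[ri]), as.integer(iv$end[ri]))
    hit <- IRanges::overlapsAny(q, s)
    null <- null + colSums(matrix(hit, nrow = length(ci)))
  }
  null <- sort(null)
  lo <- null[round(0.025 * n_perm)]
  hi <- null[round(0.975 * n_perm)]
  verdict <- if (observed > hi) "enriched" else if (observed < lo) "depleted" else "ns"
  structure(list(
    feature = if (inherits(track, "feature_track")) track$name else "track",
    subset = subset, observed = observed, null = null,
    ci_low = lo, ci_high = hi, verdict = verdict,
    n_perm = n_perm, seed = seed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment test: feature '%s', subset '%s'\n", x$feature, x$subset))
  cat(sprintf("  observed %d overlaps; null 95%% CI [%d, %d] (%d shuffles) -> %s\n",
              x$observed, x$ci_low, x$ci_high, x$n_perm, x$verdict))
  invisible(x)
}

#' Breakpoint flank windows around call endpoints
#'
#' For each call, two windows of half-width `window/2` are centered on its
#' start and end positions and clipped to the chromosome. Calls short enough
#' for the two windows to overlap (length <= window) are dropped entirely so
#' the two breakpoints are assessed independently.
#'
#' @param calls Call table.
#' @param window Window width in bp (500, 1000 or 2000 in the standard
#'   analysis; must be even).
#' @param genome Optional [genome_def()] for clipping at chromosome ends.
#' @return Interval data.frame (`chrom`, `start`, `end`, `call_row`, `side`).
#' @export
breakpoint_flanks <- function(calls, window, genome = NULL) {
  if (window %% 2 != 0) stop("window must be even")
  keep <- cnv_length(calls) > window
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      call_row = integer(), side = character()))
  h <- window / 2
  out <- data.frame(
    chrom = rep(calls$chrom, 2),
    start = c(calls$start - h, calls$end - h),
    end = c(calls$start + h, calls$end + h),
    call_row = rep(which(keep), 2),
    side = rep(c("start", "end"), each = nrow(calls)),
    stringsAsFactors = FALSE
  )
  out$start <- pmax(out$start, 1)
  if (!is.null(genome))
    out$end <- pmin(out$end, chrom_length(genome, out$chrom))
  out[order(out$call_row, out$side), , drop = FALSE]
}
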