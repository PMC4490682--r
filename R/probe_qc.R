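#' Screen probe sequences for NspI / StyI restriction sites
#'
#' The genomic target is digested with NspI (recognition site `RCATGY`) and
#' StyI (`CCWWGG`) before hybridization, so a probe whose 25-mer target --
#' together with up to 12 bp of reference flank on either side -- contains
#' either palindromic site queries a fragment that may be cut and lost.
#' The scan runs on the concatenation `flank_5p + sequence + flank_3p`, so
#' sites split across the probe/flank boundary are caught. Both sites are
#' palindromic, so a single-strand scan suffices.
#'
#' @param sequence Character vector of probe sequences (A/C/G/T).
#' @param flank_5p,flank_3p Flanking reference sequence, each at most 12 bp
#'   (recycled against `sequence`). Empty by default, in which case the screen
#'   covers the probe alone.
#' @return Logical vector: `TRUE` where a site is present.
#' @export
flag_restriction_sites <- function(sequence, flank_5p = "", flank_3p = "") {
  if (any(is.na(sequence))) stop("sequence required")
  n <- length(sequence)
  flank_5p <- rep_len(flank_5p, n)
  flank_3p <- rep_len(flank_3p, n)
  if (any(nchar(flank_5p) > 12) || any(nchar(flank_3p) > 12))
    stop("flanks must be at most 12 bp")
  full <- toupper(paste0(flank_5p, sequence, flank_3p))
  if (any(grepl("[^ACGT]", full))) stop("sequences must be over {A,C,G,T}")
  grepl("[AG]CATG[CT]", full) | grepl("CC[AT][AT]GG", full)
}

#' Remove probes whose genomic targets overlap
#'
#' Two probes compete for the same genomic DNA template when their target
#' intervals `[pos, pos + probe_len - 1]` share at least 1 bp on the same
#' chromosome. Removal is symmetric: both members of every overlapping pair
#' are dropped, so a chain of mutually overlapping probes disappears entirely.
#'
#' @param probes Probe table (see [probe_table()]).
#' @param probe_len Probe target length in bp (default 25).
#' @return The probe table restricted to probes with pairwise disjoint targets.
#' @export
remove_overlapping_probes <- function(probes, probe_len = 25) {
  if (nrow(probes) < 2) return(probes)
  ord <- order(probes$chrom, probes$pos)
  p <- probes[ord, , drop = FALSE]
  drop <- logical(nrow(p))
  # sorted, equal target lengths: any overlapping pair implies an overlapping
  # adjacent pair, so adjacency flags suffice
  same_chrom <- p$chrom[-1] == p$chrom[-nrow(p)]
  close_pair <- (p$pos[-1] - p$pos[-nrow(p)]) <= probe_len - 1
  hit <- same_chrom & close_pair
  drop[c(which(hit), which(hit) + 1L)] <- TRUE
  out <- p[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median inter-probe distance with upper-quartile outlier trimming
#'
#' Gaps between consecutive probe positions are computed within each
#' chromosome only (large probe deserts dominate the raw distribution), gaps
#' strictly greater than the third quartile of the pooled gap distribution are
#' discarded, and the median of the remaining gaps is returned. Quartiles use
#' linear interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param probes Probe table.
#' @return Median gap in bp after trimming.
#' @export
interprobe_median <- function(probes) {
  if (nrow(probes) < 2) stop("need at least 2 probes")
  gaps <- unlist(lapply(split(probes$pos, probes$chrom), function(pos) {
    pos <- sort(pos)
    if (length(pos) >= 2) diff(pos) else numeric(0)
  }), use.names = FALSE)
  if (!length(gaps)) stop("no within-chromosome gaps")
  q3 <- stats::quantile(gaps, 0.75, names = FALSE)
  stats::median(gaps[gaps <= q3])
}

#' Run the full probe-suitability filter
#'
#' Applies, in order: sequence length check (25 bp where sequences are
#' present), restriction-site screen (where sequences are present),
#' duplicate-sequence removal, and positional-overlap removal. Each probe is
#' attributed to the first rule that removes it.
#'
#' @param probes Probe table.
#' @param flank_5p,flank_3p Optional per-probe reference flanks for the
#'   restriction-site screen.
#' @param probe_len Probe target length in bp.
#' @return A list of class `probe_filter_report`: `probes` (retained table),
#'   `removed` (named counts by reason), `n_input`, `n_retained`,
#'   `median_interprobe_bp`, `partial_screen` (TRUE when flanks were not
#'   supplied, so the restriction screen covered the probe alone).
#' @export
filter_probes <- function(probes, flank_5p = "", flank_3p = "", probe_len = 25) {
  n_input <- nrow(probes)
  removed <- c(bad_length = 0L, restriction_site = 0L,
               duplicate_sequence = 0L, overlaps_other = 0L)
  has_seq <- !is.na(probes$sequence)

  bad_len <- has_seq & nchar(probes$sequence) != probe_len
  removed["bad_length"] <- sum(bad_len)
  probes <- probes[!bad_len, , drop = FALSE]
  has_seq <- !is.na(probes$sequence)

  rs <- logical(nrow(probes))
  if (any(has_seq))
    rs[has_seq] <- flag_restriction_sites(probes$sequence[has_seq],
                                          rep_len(flank_5p, sum(has_seq)),
                                          rep_len(flank_3p, sum(has_seq)))
  probes$flag_restriction_site <- rs
  removed["restriction_site"] <- sum(rs)
  probes <- probes[!rs, , drop = FALSE]

  dup <- probes$flag_duplicate_sequence %in% TRUE
  removed["duplicate_sequence"] <- sum(dup)
  probes <- probes[!dup, , drop = FALSE]

  kept <- remove_overlapping_probes(probes, probe_len = probe_len)
  removed["overlaps_other"] <- nrow(probes) - nrow(kept)
  kept$flag_overlaps_other <- FALSE

  structure(list(
    probes = kept,
    removed = removed,
    n_input = n_input,
    n_retained = nrow(kept),
    median_interprobe_bp = if (nrow(kept) >= 2) interprobe_median(kept) else NA_real_,
    partial_screen = all(!nzchar(flank_5p)) && all(!nzchar(flank_3p))
  ), class = "probe_filter_report")
}

#' @export
print.probe_filter_report <- function(x, ...) {
  cat("Probe suitability filter:", x$n_input, "in,", x$n_retained, "retained\n")
  for (r in names(x$removed))
    cat(sprintf("  removed (%s): %d\n", r, x$removed[[r]]))
  cat("  median inter-probe distance (Q3-trimmed):",
      x$median_interprobe_bp, "bp\n")
  if (x$partial_screen)
    cat("  note: no reference flanks supplied; restriction screen covered the probe alone\n")
  invisible(x)
}
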