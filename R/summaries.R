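#' Round half-up to a fixed number of decimals
#'
#' Display arithmetic for summary tables: 0.845 rounds to 0.85, unlike
#' banker's rounding. Full precision is retained internally; only printed
#' ratios use this.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' One summary row from copy-state and sample counts
#'
#' The arithmetic backbone of the classification summary: given the number of
#' samples and the counts of calls per collapsed state, computes calls per
#' sample, the deletion/amplification ratio (states 0 + 1 over 3+) and
#' optionally the unique/recurrent ratio. Zero amplifications make the ratio
#' an `Inf` sentinel.
#'
#' @param group Group label.
#' @param n_samples Number of samples in the group.
#' @param n_state0,n_state1,n_state3plus Call counts per collapsed state.
#' @param n_unique,n_recurrent Optional uniqueness counts.
#' @return One-row data.frame with full-precision and rounded (2 dp,
#'   half-up) ratio columns.
#' @export
summary_row <- function(group, n_samples, n_state0, n_state1, n_state3plus,
                        n_unique = NA_integer_, n_recurrent = NA_integer_) {
  n_calls <- n_state0 + n_state1 + n_state3plus
  del_amp <- (n_state0 + n_state1) / n_state3plus
  uniq_rec <- n_unique / n_recurrent
  data.frame(
    group = group, n_samples = n_samples, n_calls = n_calls,
    calls_per_sample = round_half_up(n_calls / n_samples, 2),
    n_state0 = n_state0, n_state1 = n_state1, n_state3plus = n_state3plus,
    del_amp_ratio = round_half_up(del_amp, 2),
    n_unique = n_unique, n_recurrent = n_recurrent,
    unique_recurrent_ratio = round_half_up(uniq_rec, 2),
    del_amp_ratio_full = del_amp,
    unique_recurrent_ratio_full = uniq_rec,
    stringsAsFactors = FALSE
  )
}

#' Classification summary table of autosomal calls
#'
#' One row per classification group present in the metadata plus an `All`
#' row, tabulating call counts by collapsed copy state, per-sample means,
#' deletion/amplification ratios and unique/recurrent counts. Uniqueness must
#' be classified once on the full panel ([classify_uniqueness()]); subgroup
#' rows never re-evaluate it.
#'
#' @param calls Call table (typically autosomal calls from passing samples),
#'   aligned with `uniqueness`.
#' @param meta Sample metadata (defines group membership and sizes).
#' @param uniqueness Character vector `"unique"`/`"recurrent"` per call.
#' @param collapsed Optional collapsed states per call (`"0"`, `"1"`, `"3+"`);
#'   by default derived from `copy_state` against the autosomal baseline 2.
#' @return Data frame of summary rows (see [summary_row()]).
#' @export
summarize_calls <- function(calls, meta, uniqueness, collapsed = NULL) {
  if (length(uniqueness) != nrow(calls))
    stop("uniqueness must align with calls")
  if (is.null(collapsed))
    collapsed <- ifelse(calls$copy_state < 2,
                        as.character(pmin(calls$copy_state, 1L)), "3+")
  groups <- unique(meta$classification)
  rows <- list()
  mk <- function(label, sample_ids) {
    sel <- calls$sample_id %in% sample_ids
    summary_row(label, length(sample_ids),
                sum(sel & collapsed == "0"), sum(sel & collapsed == "1"),
                sum(sel & collapsed == "3+"),
                n_unique = sum(sel & uniqueness == "unique"),
                n_recurrent = sum(sel & uniqueness == "recurrent"))
  }
  rows[["All"]] <- mk("All", meta$sample_id)
  for (g in groups) {
    ids <- meta$sample_id[meta$classification == g]
    if (!length(ids)) {
      warning("classification group with zero samples omitted: ", g)
      next
    }
    rows[[g]] <- mk(g, ids)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of the genome covered by the union of calls
#'
#' The union of all call intervals within scope (merged across samples, so
#' two identical calls count once) divided by the total scope length. In
#' `per_sample` mode the union is taken within each sample and the resulting
#' fractions averaged.
#'
#' @param calls Call table.
#' @param genome A [genome_def()].
#' @param scope `"autosomes"` or `"autosomes_plus_X"`.
#' @param per_sample Average of per-sample fractions instead of the pooled
#'   union (default `FALSE`).
#' @return List with `fraction` and `mb` (megabases covered).
#' @export
genome_fraction_affected <- function(calls, genome,
                                     scope = c("autosomes", "autosomes_plus_X"),
                                     per_sample = FALSE) {
  scope <- match.arg(scope)
  chroms <- genome$autosomes
  if (scope == "autosomes_plus_X") chroms <- c(chroms, intersect("chrX", names(genome$lengths)))
  total <- sum(genome$lengths[chroms])
  union_bp <- function(df) {
    df <- df[df$chrom %in% chroms, , drop = FALSE]
    if (!nrow(df)) return(0)
    sum(vapply(split(df, df$chrom), function(x) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(as.integer(x$start), as.integer(x$end)))))
    }, numeric(1)))
  }
  bp <- if (per_sample) {
    mean(vapply(split(calls, calls$sample_id), union_bp, numeric(1)))
  } else union_bp(calls)
  list(fraction = bp / total, mb = bp / 1e6)
}

#' Length statistics and contrasts for call groups
#'
#' Reports median and mean call lengths per partition cell and two-sided
#' Mann-Whitney (Wilcoxon rank-sum) p-values for the standard contrasts:
#' amplifications vs deletions, and state-0 vs state-1 deletions. Empty
#' groups skip their contrast.
#'
#' @param calls Call table.
#' @param types Optional `"deletion"`/`"amplification"` per call (default:
#'   `copy_state` against autosomal baseline 2).
#' @return List with `table` (per-group median/mean/n) and `tests` (named
#'   p-values `amp_vs_del`, `state0_vs_state1`).
#' @export
length_stats <- function(calls, types = NULL) {
  len <- cnv_length(calls)
  if (is.null(types))
    types <- ifelse(calls$copy_state < 2, "deletion", "amplification")
  cells <- list(
    all = rep(TRUE, nrow(calls)),
    deletion = types == "deletion",
    amplification = types == "amplification",
    state0 = calls$copy_state == 0,
    state1 = types == "deletion" & calls$copy_state != 0
  )
  tab <- do.call(rbind, lapply(names(cells), function(nm) {
    x <- len[cells[[nm]]]
    data.frame(group = nm, n = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_)
  }))
  tests <- c(amp_vs_del = NA_real_, state0_vs_state1 = NA_real_)
  if (any(cells$amplification) && any(cells$deletion))
    tests["amp_vs_del"] <- suppressWarnings(
      stats::wilcox.test(len[cells$amplification], len[cells$deletion])$p.value)
  if (any(cells$state0) && any(cells$state1))
    tests["state0_vs_state1"] <- suppressWarnings(
      stats::wilcox.test(len[cells$state0], len[cells$state1])$p.value)
  list(table = tab, tests = tests)
}
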