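#' Quality-control thresholds for samples and calls
#'
#' Defaults follow the standard array-CNV filtering recipe: call length
#' between 500 bp and 1 Mb, at least 3 supporting markers, marker density at
#' least 0.00013 markers/bp (about one probe per 7700 bp), and per-sample
#' array-noise gates LRR_SD < 0.35 and BAF drift < 0.01. Length and density
#' bounds are inclusive; the sample-noise gates are strict.
#'
#' @param min_len,max_len Call length bounds in bp (inclusive).
#' @param min_markers Minimum supporting markers (inclusive).
#' @param min_density Minimum markers per bp (inclusive).
#' @param max_lrr_sd Maximum log-R-ratio standard deviation (strict).
#' @param max_baf_drift Maximum B-allele-frequency drift (strict).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_len = 500, max_len = 1e6, min_markers = 3,
                          min_density = 0.00013, max_lrr_sd = 0.35,
                          max_baf_drift = 0.01) {
  stopifnot(min_len < max_len, min_len > 0, min_markers > 0,
            min_density > 0, max_lrr_sd > 0, max_baf_drift > 0)
  structure(list(min_len = min_len, max_len = max_len,
                 min_markers = min_markers, min_density = min_density,
                 max_lrr_sd = max_lrr_sd, max_baf_drift = max_baf_drift),
            class = "qc_thresholds")
}

#' Sample-level quality control
#'
#' A sample passes when its log-R-ratio standard deviation and B-allele
#' frequency drift are both strictly below threshold.
#'
#' @param meta Sample metadata data.frame with `lrr_sd` and `baf_drift`.
#' @param thresholds A [qc_thresholds()].
#' @return Logical vector, one element per row of `meta`.
#' @export
sample_passes_qc <- function(meta, thresholds = qc_thresholds()) {
  if (!all(c("lrr_sd", "baf_drift") %in% names(meta)))
    stop("sample metadata must contain 'lrr_sd' and 'baf_drift'")
  if (anyNA(meta$lrr_sd) || anyNA(meta$baf_drift))
    stop("missing QC metric for sample ",
         meta$sample_id[is.na(meta$lrr_sd) | is.na(meta$baf_drift)][1])
  meta$lrr_sd < thresholds$max_lrr_sd & meta$baf_drift < thresholds$max_baf_drift
}

#' Call-level filtering
#'
#' Keeps calls satisfying the length, marker-count and marker-density gates.
#' Each removed call is attributed to the first failing rule in the fixed
#' order length, markers, density, so the removal report is deterministic.
#'
#' @param calls Call table.
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` (filtered call table) and `report` (named integer
#'   counts of removals by reason).
#' @export
filter_calls <- function(calls, thresholds = qc_thresholds()) {
  len <- cnv_length(calls)
  density <- calls$n_markers / len
  fail_len <- len < thresholds$min_len | len > thresholds$max_len
  fail_mark <- !fail_len & (is.na(calls$n_markers) |
                            calls$n_markers < thresholds$min_markers)
  fail_dens <- !fail_len & !fail_mark &
    (is.na(density) | density < thresholds$min_density)
  keep <- !(fail_len | fail_mark | fail_dens)
  kept <- calls[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = c(length = sum(fail_len), markers = sum(fail_mark),
                  density = sum(fail_dens)))
}

#' Classify a call as deletion or amplification against its baseline
#'
#' On autosomes the expected baseline is 2 copies; on the X chromosome it is 1
#' in males and 2 in females (so a male X state of 2 is an amplification).
#' States above the baseline are amplifications, below are deletions. The
#' collapsed state is `"0"`, `"1"` or `"3+"` relative to the diploid scale;
#' on male X the collapse is relative to baseline 1 (state 0 collapses to
#' `"0"`, states >= 2 to `"3+"`).
#'
#' @param calls Call table.
#' @param meta Sample metadata (for `sex`); alternatively a named character
#'   vector of sexes keyed by sample id.
#' @param genome A [genome_def()].
#' @return Data frame with columns `type` (`deletion`/`amplification`) and
#'   `collapsed_state` (`"0"`, `"1"`, `"3+"`).
#' @export
classify_calls <- function(calls, meta, genome) {
  sexes <- if (is.data.frame(meta))
    stats::setNames(meta$sex, meta$sample_id) else meta
  sex <- sexes[calls$sample_id]
  if (anyNA(sex)) stop("missing sex for sample ",
                       calls$sample_id[is.na(sex)][1])
  base <- baseline_copy_number(calls$chrom, sex, genome)
  if (any(calls$copy_state == base))
    stop("call with copy state equal to its baseline is not a CNV (row ",
         which(calls$copy_state == base)[1], ")")
  type <- ifelse(calls$copy_state < base, "deletion", "amplification")
  collapsed <- character(nrow(calls))
  del <- type == "deletion"
  # deletions: full loss collapses to "0", partial to "1"
  collapsed[del] <- ifelse(calls$copy_state[del] == 0, "0", "1")
  collapsed[!del] <- "3+"
  data.frame(type = type, collapsed_state = collapsed,
             stringsAsFactors = FALSE)
}
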