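#' Reciprocal overlap between interval pairs
#'
#' The reciprocal overlap of two intervals is `min(ov/len_a, ov/len_b)` where
#' `ov` is the shared length in bp (1-based inclusive coordinates), i.e. both
#' intervals must be covered at the stated fraction. Pairs on different
#' chromosomes or disjoint pairs return 0.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (recycled row-wise
#'   against each other).
#' @return Numeric vector of reciprocal-overlap fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  sa <- a$start[idx_a]; ea <- a$end[idx_a]
  sb <- b$start[idx_b]; eb <- b$end[idx_b]
  if (any(sa > ea) || any(sb > eb)) stop("invalid interval (start > end)")
  ov <- pmin(ea, eb) - pmax(sa, sb) + 1
  ov <- pmax(ov, 0)
  same <- a$chrom[idx_a] == b$chrom[idx_b]
  ro <- ifelse(same, pmin(ov / (ea - sa + 1), ov / (eb - sb + 1)), 0)
  as.numeric(ro)
}

#' Build the reciprocal-overlap recurrence graph
#'
#' Calls are nodes; an undirected edge joins every pair of calls (from any
#' samples, including the same sample) whose reciprocal overlap is at least
#' `fraction`. Calls are first sorted by (chrom, start, end, sample_id) and
#' assigned stable integer ids so downstream component labels are
#' deterministic. Candidate pairs come from an interval-overlap query per
#' chromosome; the reciprocal-fraction filter is applied to candidates.
#'
#' @param calls QC-filtered call table.
#' @param fraction Reciprocal-overlap threshold (default 0.40).
#' @return An object of class `recurrence_graph`: list with `calls` (sorted,
#'   with `call_id`), `edges` (data.frame `from`, `to`, `ro`), `degree`
#'   (integer per call), `fraction`.
#' @export
build_recurrence_graph <- function(calls, fraction = 0.40) {
  calls <- calls[order(calls$chrom, calls$start, calls$end, calls$sample_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls$call_id <- seq_len(nrow(calls))
  edges <- data.frame(from = integer(), to = integer(), ro = numeric())
  if (nrow(calls) >= 2) {
    per_chrom <- lapply(split(seq_len(nrow(calls)), calls$chrom), function(ix) {
      if (length(ix) < 2) return(NULL)
      ir <- IRanges::IRanges(start = as.integer(calls$start[ix]),
                             end = as.integer(calls$end[ix]))
      hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
      if (!length(hits)) return(NULL)
      i <- ix[S4Vectors::queryHits(hits)]
      j <- ix[S4Vectors::subjectHits(hits)]
      ro <- reciprocal_overlap(calls[i, c("chrom", "start", "end")],
                               calls[j, c("chrom", "start", "end")])
      keep <- ro >= fraction
      if (!any(keep)) return(NULL)
      data.frame(from = pmin(i[keep], j[keep]), to = pmax(i[keep], j[keep]),
                 ro = ro[keep])
    })
    per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
    if (length(per_chrom)) edges <- do.call(rbind, per_chrom)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  degree <- tabulate(c(edges$from, edges$to), nbins = nrow(calls))
  structure(list(calls = calls, edges = edges, degree = degree,
                 fraction = fraction),
            class = "recurrence_graph")
}

#' @export
print.recurrence_graph <- function(x, ...) {
  cat("Recurrence graph:", nrow(x$calls), "calls,", nrow(x$edges),
      "edges at >=", x$fraction, "reciprocal overlap\n")
  cat("  recurrent:", sum(x$degree >= 1), " unique:", sum(x$degree == 0), "\n")
  invisible(x)
}

#' Classify every call as unique or recurrent
#'
#' A call is recurrent when it has at least one reciprocal-overlap partner
#' anywhere in the full panel. Uniqueness is decided once on the entire
#' analysis and never re-evaluated within sample subgroups: a call whose only
#' partner sits in another subgroup is still recurrent in every subgroup
#' tabulation.
#'
#' @param graph A [build_recurrence_graph()] result over all samples.
#' @return Character vector (`"unique"`/`"recurrent"`) aligned with
#'   `graph$calls`.
#' @export
classify_uniqueness <- function(graph) {
  ifelse(graph$degree >= 1, "recurrent", "unique")
}

#' Mean pairwise boundary concordance of a region's member calls
#'
#' Boundary concordance of a set of calls is the mean reciprocal overlap over
#' all member pairs: identical boundaries give exactly 1, diffuse boundaries
#' approach the graph threshold. Regions below the `complex` threshold
#' (default 0.75) are classified complex.
#'
#' @param members Data frame of at least 2 member calls (`chrom`, `start`,
#'   `end`).
#' @return Mean pairwise reciprocal overlap in `[0, 1]`.
#' @export
boundary_concordance <- function(members) {
  n <- nrow(members)
  if (n < 2) stop("boundary concordance needs at least 2 member calls")
  pairs <- utils::combn(n, 2)
  mean(reciprocal_overlap(members[pairs[1, ], c("chrom", "start", "end")],
                          members[pairs[2, ], c("chrom", "start", "end")]))
}

#' Connected-component CNV regions with complexity classification
#'
#' Connected components of the recurrence graph with at least 2 member calls
#' are candidate CNV regions. Each region reports its span (min start to max
#' end of members), the number of distinct carrier samples, the copy-state mix
#' and its boundary concordance; regions whose concordance falls below
#' `complex_threshold` are flagged complex.
#'
#' @param graph A [build_recurrence_graph()] result.
#' @param types Optional character vector (`"deletion"`/`"amplification"`)
#'   aligned with `graph$calls`; by default inferred from `copy_state` against
#'   the autosomal baseline of 2.
#' @param complex_threshold Boundary-concordance threshold below which a
#'   region is complex (default 0.75).
#' @return List with `regions` (one row per region) and `membership` (integer
#'   region id per call, `NA` for unique calls).
#' @export
cnv_regions <- function(graph, types = NULL, complex_threshold = 0.75) {
  calls <- graph$calls
  if (is.null(types))
    types <- ifelse(calls$copy_state < 2, "deletion", "amplification")
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = calls$call_id))
  comp <- igraph::components(g)$membership[as.character(calls$call_id)]
  sizes <- table(comp)
  keep <- names(sizes)[sizes >= 2]
  membership <- rep(NA_integer_, nrow(calls))
  regions <- data.frame()
  if (length(keep)) {
    # stable region ids: order components by their span position
    rows <- lapply(keep, function(k) {
      ix <- which(comp == k)
      m <- calls[ix, , drop = FALSE]
      data.frame(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
                 n_members = nrow(m),
                 n_samples = length(unique(m$sample_id)),
                 state_mix = if (all(types[ix] == "deletion")) "all_deletion"
                             else if (all(types[ix] == "amplification")) "all_amplification"
                             else "mixed",
                 boundary_concordance = boundary_concordance(m),
                 comp_key = k, stringsAsFactors = FALSE)
    })
    regions <- do.call(rbind, rows)
    ord <- order(regions$chrom, regions$start, regions$end)
    regions <- regions[ord, , drop = FALSE]
    regions$region_id <- seq_len(nrow(regions))
    for (r in seq_len(nrow(regions)))
      membership[comp == regions$comp_key[r]] <- regions$region_id[r]
    regions$comp_key <- NULL
    regions$complex <- regions$boundary_concordance < complex_threshold
    rownames(regions) <- NULL
    regions <- regions[, c("region_id", "chrom", "start", "end", "n_members",
                           "n_samples", "state_mix", "boundary_concordance",
                           "complex")]
  }
  list(regions = regions, membership = membership)
}

#' Tally calls sharing exact start and end positions
#'
#' Groups calls by identical (chrom, start, end) and counts distinct carrier
#' samples per group; a sample carrying the same event twice is counted once.
#'
#' @param calls Call table.
#' @return Data frame (chrom, start, end, n_mice, states) sorted by
#'   descending carrier count, where `states` lists the copy states observed.
#' @export
most_common_cnvs <- function(calls) {
  if (!nrow(calls))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_mice = integer(), states = character()))
  key <- paste(calls$chrom, calls$start, calls$end, sep = ":")
  groups <- split(seq_len(nrow(calls)), key)
  out <- do.call(rbind, lapply(groups, function(ix) {
    data.frame(chrom = calls$chrom[ix[1]], start = calls$start[ix[1]],
               end = calls$end[ix[1]],
               n_mice = length(unique(calls$sample_id[ix])),
               states = paste(sort(unique(calls$copy_state[ix])),
                              collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_mice, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance of calls with a reference interval set
#'
#' A call is matched under `reciprocal_20` when it has at least 20 %
#' reciprocal overlap with any reference interval, and under `onebp` when it
#' shares at least 1 bp. Copy state is ignored: the presence of any reference
#' interval is taken as evidence that the region is variable.
#'
#' @param calls Call table.
#' @param reference Data frame of reference intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive), e.g. from [read_feature_track()].
#' @param mode `"reciprocal_20"` or `"onebp"`.
#' @param fraction Reciprocal fraction for `reciprocal_20` (default 0.20).
#' @return List with `matched` (logical per call) and `fraction_matched`.
#' @export
concordance_with_study <- function(calls, reference,
                                   mode = c("reciprocal_20", "onebp"),
                                   fraction = 0.20) {
  mode <- match.arg(mode)
  matched <- logical(nrow(calls))
  if (nrow(calls) && nrow(reference)) {
    for (ch in unique(calls$chrom)) {
      ci <- which(calls$chrom == ch)
      ri <- which(reference$chrom == ch)
      if (!length(ri)) next
      q <- IRanges::IRanges(as.integer(calls$start[ci]),
                            as.integer(calls$end[ci]))
      s <- IRanges::IRanges(as.integer(reference$start[ri]),
                            as.integer(reference$end[ri]))
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      if (mode == "onebp") {
        matched[ci[unique(S4Vectors::queryHits(hits))]] <- TRUE
      } else {
        i <- ci[S4Vectors::queryHits(hits)]
        j <- ri[S4Vectors::subjectHits(hits)]
        ro <- reciprocal_overlap(calls[i, c("chrom", "start", "end")],
                                 reference[j, c("chrom", "start", "end")])
        matched[unique(i[ro >= fraction])] <- TRUE
      }
    }
  }
  list(matched = matched,
       fraction_matched = if (nrow(calls)) mean(matched) else NA_real_)
}
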