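#' Construct a gene model table
#'
#' @param id,symbol,chrom,start,end,biotype Column vectors. `biotype` is one
#'   of `protein_coding`, `pseudogene`, `rna`, `antisense`, `other`; raw
#'   Ensembl biotype strings are mapped via [map_biotype()].
#' @return Validated gene data.frame.
#' @export
gene_table <- function(id, symbol, chrom, start, end, biotype) {
  df <- data.frame(id = as.character(id), symbol = as.character(symbol),
                   chrom = normalize_chrom(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   biotype = map_biotype(biotype), stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("invalid gene interval (start > end)")
  df
}

#' Map Ensembl biotype strings to the collapsed classification
#'
#' `protein_coding` stays; anything ending in `pseudogene` becomes
#' `pseudogene`; anything containing `RNA` becomes `rna`; `antisense` stays;
#' everything else is `other`. Already-collapsed values pass through.
#'
#' @param biotype Character vector of biotype strings.
#' @return Character vector over `{protein_coding, pseudogene, rna,
#'   antisense, other}`.
#' @export
map_biotype <- function(biotype) {
  out <- rep("other", length(biotype))
  out[biotype == "protein_coding"] <- "protein_coding"
  out[grepl("pseudogene$", biotype)] <- "pseudogene"
  out[grepl("RNA", biotype, ignore.case = FALSE)] <- "rna"
  out[grepl("^rna$", biotype)] <- "rna"
  out[biotype == "antisense"] <- "antisense"
  out
}

#' Classify call-gene overlap relations
#'
#' For every call-gene pair sharing at least 1 bp, the relation is
#' `encompasses_gene` when the call covers the whole gene, `inside_gene` when
#' the gene covers the whole call, and `partial` otherwise. Identical
#' intervals resolve to `encompasses_gene`.
#'
#' @param calls Call table (rows identified by position).
#' @param genes Gene table ([gene_table()]).
#' @return Data frame (`call_row`, `gene_id`, `relation`), one row per
#'   overlapping pair.
#' @export
classify_gene_overlap <- function(calls, genes) {
  out <- list()
  for (ch in unique(calls$chrom)) {
    ci <- which(calls$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(as.integer(calls$start[ci]), as.integer(calls$end[ci])),
      IRanges::IRanges(as.integer(genes$start[gi]), as.integer(genes$end[gi])))
    if (!length(hits)) next
    i <- ci[S4Vectors::queryHits(hits)]
    j <- gi[S4Vectors::subjectHits(hits)]
    enc <- calls$start[i] <= genes$start[j] & calls$end[i] >= genes$end[j]
    ins <- !enc & genes$start[j] <= calls$start[i] & genes$end[j] >= calls$end[i]
    rel <- ifelse(enc, "encompasses_gene", ifelse(ins, "inside_gene", "partial"))
    out[[ch]] <- data.frame(call_row = i, gene_id = genes$id[j],
                            relation = rel, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(call_row = integer(), gene_id = character(),
                      relation = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$call_row, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene lists under the complete-overlap rule
#'
#' Returns the genes that are completely encompassed by a call or completely
#' encompass a call (relations `encompasses_gene` / `inside_gene`); partial
#' overlaps are excluded. Pseudogenes that carry a protein-coding biotype
#' annotation are included like any other gene -- filtering by biotype is the
#' caller's choice. The list is suitable for export, one symbol per line, to
#' external ontology tools.
#'
#' @param calls Call table.
#' @param genes Gene table.
#' @param path Optional path; when given, symbols are written one per line.
#' @return Character vector of unique gene symbols (sorted).
#' @export
complete_overlap_gene_list <- function(calls, genes, path = NULL) {
  ov <- classify_gene_overlap(calls, genes)
  ov <- ov[ov$relation %in% c("encompasses_gene", "inside_gene"), , drop = FALSE]
  syms <- sort(unique(genes$symbol[match(ov$gene_id, genes$id)]))
  if (!is.null(path)) writeLines(syms, path)
  syms
}

#' Screen deletion calls against negative-control genes
#'
#' Conserved, dosage-sensitive genes are not expected to harbour deletions;
#' any deletion call overlapping a control gene by at least 1 bp is reported
#' with its copy state and the fraction of the gene lost. Zero-copy overlaps
#' are the highest-severity finding.
#'
#' @param calls Call table; only deletion states (`copy_state < 2`, or
#'   explicitly `copy_state == 0` with `mode = "state_zero"`) are screened.
#' @param control_genes Gene table of negative controls.
#' @param mode `"any_deletion"` (states 0 and 1) or `"state_zero"`.
#' @return Data frame (`sample_id`, `gene_symbol`, `copy_state`,
#'   `fraction_of_gene`, `severity`), empty when nothing overlaps.
#' @export
screen_negative_controls <- function(calls, control_genes,
                                     mode = c("any_deletion", "state_zero")) {
  mode <- match.arg(mode)
  dels <- if (mode == "state_zero") calls[calls$copy_state == 0, , drop = FALSE]
          else calls[calls$copy_state < 2, , drop = FALSE]
  empty <- data.frame(sample_id = character(), gene_symbol = character(),
                      copy_state = integer(), fraction_of_gene = numeric(),
                      severity = character())
  if (!nrow(dels) || !nrow(control_genes)) return(empty)
  ov <- classify_gene_overlap(dels, control_genes)
  if (!nrow(ov)) return(empty)
  i <- ov$call_row
  j <- match(ov$gene_id, control_genes$id)
  ov_len <- pmin(dels$end[i], control_genes$end[j]) -
    pmax(dels$start[i], control_genes$start[j]) + 1
  out <- data.frame(
    sample_id = dels$sample_id[i],
    gene_symbol = control_genes$symbol[j],
    copy_state = dels$copy_state[i],
    fraction_of_gene = ov_len / (control_genes$end[j] - control_genes$start[j] + 1),
    severity = ifelse(dels$copy_state[i] == 0, "state_zero", "single_copy"),
    stringsAsFactors = FALSE
  )
  out[order(out$severity != "state_zero", out$gene_symbol, out$sample_id), ,
      drop = FALSE]
}

#' Detect CNV regions private to one wild-caught subspecies
#'
#' A recurrence region is private to subspecies S (domesticus or musculus)
#' when at least `min_carriers` distinct wild-caught S samples carry member
#' calls of the region, and no wild-caught sample of the other subspecies has
#' any call overlapping the region span by >= 1 bp. For each private region
#' the table also reports whether any classical or wild-derived sample has a
#' call overlapping the span by >= 1 bp.
#'
#' @param graph Recurrence graph over the full panel
#'   ([build_recurrence_graph()]).
#' @param regions Result of [cnv_regions()] on that graph.
#' @param meta Sample metadata with `classification` and `subspecies` (the
#'   wild-caught samples must carry subspecies labels).
#' @param min_carriers Minimum distinct same-subspecies carriers (default 6,
#'   i.e. "more than five individuals").
#' @return Data frame, one row per private region: `region_id`, `chrom`,
#'   `start`, `end`, `subspecies`, `n_carriers`, `type`
#'   (del/amp/mixed among the carrier calls), `seen_in_classical`,
#'   `seen_in_wild_derived`.
#' @export
private_subspecies_cnvs <- function(graph, regions, meta, min_carriers = 6) {
  calls <- graph$calls
  cls <- stats::setNames(meta$classification, meta$sample_id)
  ssp <- stats::setNames(as.character(meta$subspecies), meta$sample_id)
  wc <- meta$sample_id[meta$classification == "wild_caught"]
  if (!length(wc) || all(is.na(ssp[wc]) | !nzchar(ssp[wc])))
    stop("wild-caught samples must carry subspecies labels")
  reg <- regions$regions
  memb <- regions$membership
  out <- list()
  for (r in seq_len(nrow(reg))) {
    ix <- which(memb == reg$region_id[r])
    m <- calls[ix, , drop = FALSE]
    wc_members <- m[cls[m$sample_id] == "wild_caught", , drop = FALSE]
    if (!nrow(wc_members)) next
    carriers <- tapply(wc_members$sample_id, ssp[wc_members$sample_id],
                       function(s) length(unique(s)))
    for (s in c("domesticus", "musculus")) {
      n_car <- if (s %in% names(carriers)) carriers[[s]] else 0L
      if (n_car < min_carriers) next
      other <- setdiff(c("domesticus", "musculus"), s)
      span <- reg[r, c("chrom", "start", "end")]
      touches_span <- function(samples) {
        sub <- calls[calls$sample_id %in% samples, , drop = FALSE]
        nrow(sub) > 0 && any(overlaps_feature(sub, span))
      }
      other_wc <- wc[ssp[wc] %in% other]
      if (touches_span(other_wc)) next
      carrier_calls <- wc_members[ssp[wc_members$sample_id] == s, , drop = FALSE]
      types <- ifelse(carrier_calls$copy_state < 2, "Del", "Amp")
      out[[length(out) + 1L]] <- data.frame(
        region_id = reg$region_id[r], chrom = reg$chrom[r],
        start = reg$start[r], end = reg$end[r],
        subspecies = s, n_carriers = n_car,
        type = if (length(unique(types)) == 1) unique(types) else "Mixed",
        seen_in_classical = touches_span(
          meta$sample_id[meta$classification == "classical"]),
        seen_in_wild_derived = touches_span(
          meta$sample_id[meta$classification == "wild_derived"]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      subspecies = character(), n_carriers = integer(),
                      type = character(), seen_in_classical = logical(),
                      seen_in_wild_derived = logical()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
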