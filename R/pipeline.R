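#' Read a directory of pipeline inputs
#'
#' Expects the file layout written by [write_sim_inputs()]: `calls.tsv`,
#' `probes.tsv`, `samples.tsv`, `genome.tsv`, optional `genotypes.tsv`,
#' `genes.tsv` and any number of `*.bed` feature tracks.
#'
#' @param dir Input directory.
#' @return List with `genome`, `probes`, `calls`, `meta`, and (when present)
#'   `genotypes`, `genes`, `tracks`.
#' @export
read_pipeline_inputs <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  genome <- read_genome_table(need("genome.tsv"))
  probes <- read_probe_annotation(need("probes.tsv"))
  inputs <- list(
    genome = genome,
    probes = probes,
    calls = read_cnv_calls(need("calls.tsv"), "tsv", genome = genome),
    meta = read_sample_meta(need("samples.tsv"))
  )
  gt <- file.path(dir, "genotypes.tsv")
  if (file.exists(gt)) inputs$genotypes <- read_genotype_matrix(gt, probes)
  gn <- file.path(dir, "genes.tsv")
  if (file.exists(gn)) {
    g <- read_tsv(gn)
    inputs$genes <- gene_table(g$id, g$symbol, g$chrom, g$start, g$end, g$biotype)
  }
  beds <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (length(beds))
    inputs$tracks <- stats::setNames(lapply(beds, read_feature_track),
                                     sub("\\.bed$", "", basename(beds)))
  inputs
}

#' Run the full analysis pipeline
#'
#' Stages run in order: sample and call QC, recurrence-graph construction and
#' region classification, feature enrichment, gene overlap, genetic distances
#' with tree/ordination/Mantel, deletion false-discovery estimation, and the
#' classification summary. Stages whose optional inputs (genotypes, genes,
#' tracks) are missing are skipped with a warning; the remaining stages still
#' run. All artifacts are TSV/Newick files under `out_dir`, and a manifest
#' records the package version, parameters and seed, so a re-run with the
#' same inputs and seed is bit-identical.
#'
#' @param inputs Either a directory path (see [read_pipeline_inputs()]), a
#'   `sim_panel`, or a list with the same element names.
#' @param out_dir Output directory (created if absent).
#' @param thresholds A [qc_thresholds()].
#' @param fraction Reciprocal-overlap threshold for recurrence (default 0.40).
#' @param n_perm Enrichment permutations (default 1000).
#' @param seed Integer seed for all stochastic stages.
#' @param mantel_perm Mantel permutations (default 999).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(inputs, out_dir, thresholds = qc_thresholds(),
                         fraction = 0.40, n_perm = 1000, seed = 1,
                         mantel_perm = 999) {
  if (is.character(inputs)) inputs <- read_pipeline_inputs(inputs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  log_line <- character()
  note <- function(...) log_line <<- c(log_line, paste0(...))

  ## qc
  pass <- sample_passes_qc(inputs$meta, thresholds)
  meta_pass <- inputs$meta[pass, , drop = FALSE]
  calls <- inputs$calls[inputs$calls$sample_id %in% meta_pass$sample_id, ,
                        drop = FALSE]
  fc <- filter_calls(calls, thresholds)
  res$qc <- list(samples_pass = sum(pass), samples_fail = sum(!pass),
                 removed = fc$report)
  calls <- fc$kept
  note("qc: ", sum(pass), "/", length(pass), " samples pass; ",
       nrow(calls), " calls kept")
  write_tsv(calls, file.path(out_dir, "calls_kept.tsv"))
  write_tsv(data.frame(reason = names(fc$report), n = as.integer(fc$report)),
            file.path(out_dir, "qc_report.tsv"))

  ## recurrence
  graph <- build_recurrence_graph(calls, fraction = fraction)
  uniq <- classify_uniqueness(graph)
  regions <- cnv_regions(graph)
  res$recurrence <- list(graph = graph, uniqueness = uniq, regions = regions)
  calls <- graph$calls  # sorted, with call_id
  write_tsv(graph$edges, file.path(out_dir, "graph_edges.tsv"))
  write_tsv(cbind(calls, uniqueness = uniq),
            file.path(out_dir, "calls_classified.tsv"))
  write_tsv(regions$regions, file.path(out_dir, "regions.tsv"))
  note("recurrence: ", nrow(graph$edges), " edges; ",
       nrow(regions$regions), " regions")

  ## enrichment
  if (!is.null(inputs$tracks) && length(inputs$tracks)) {
    enr <- lapply(names(inputs$tracks), function(nm)
      enrichment_test(calls, inputs$tracks[[nm]], inputs$genome,
                      n_perm = n_perm, seed = seed))
    res$enrichment <- enr
    write_tsv(do.call(rbind, lapply(enr, function(e)
      data.frame(feature = e$feature, subset = e$subset, observed = e$observed,
                 ci_low = e$ci_low, ci_high = e$ci_high, verdict = e$verdict))),
      file.path(out_dir, "enrichment.tsv"))
    note("enrichment: ", length(enr), " track(s) tested")
  } else {
    warning("no feature tracks supplied; enrichment stage skipped")
    note("enrichment: skipped (no tracks)")
  }

  ## genes
  if (!is.null(inputs$genes)) {
    ov <- classify_gene_overlap(calls, inputs$genes)
    gl <- complete_overlap_gene_list(calls, inputs$genes,
                                     path = file.path(out_dir, "gene_list.txt"))
    res$genes <- list(overlaps = ov, gene_list = gl)
    write_tsv(ov, file.path(out_dir, "gene_overlaps.tsv"))
    wc <- inputs$meta$classification == "wild_caught"
    if (any(wc) && any(!is.na(inputs$meta$subspecies[wc]))) {
      priv <- private_subspecies_cnvs(graph, regions, inputs$meta)
      res$genes$private <- priv
      write_tsv(priv, file.path(out_dir, "private_subspecies.tsv"))
    }
    note("genes: ", length(gl), " complete-overlap genes")
  } else {
    warning("no gene annotation supplied; gene stage skipped")
    note("genes: skipped (no annotation)")
  }

  ## distances
  samples <- sort(meta_pass$sample_id)
  dcnv <- cnv_distance(calls, inputs$probes, samples, inputs$genome)
  utils::write.table(as.matrix(dcnv), file.path(out_dir, "dist_cnv.tsv"),
                     sep = "\t", quote = FALSE)
  res$distance <- list(cnv = dcnv)
  if (length(samples) >= 3) {
    tr <- nj_tree(dcnv)
    ape::write.tree(tr, file.path(out_dir, "tree_cnv.nwk"))
    res$distance$tree_cnv <- tr
    mds <- classical_mds(dcnv)
    utils::write.table(mds, file.path(out_dir, "mds_cnv.tsv"),
                       sep = "\t", quote = FALSE)
  }
  if (!is.null(inputs$genotypes)) {
    dsnp <- snp_distance(inputs$genotypes[, samples, drop = FALSE])
    utils::write.table(as.matrix(dsnp), file.path(out_dir, "dist_snp.tsv"),
                       sep = "\t", quote = FALSE)
    res$distance$snp <- dsnp
    if (length(samples) >= 3) {
      trs <- nj_tree(dsnp)
      ape::write.tree(trs, file.path(out_dir, "tree_snp.nwk"))
      res$distance$tree_snp <- trs
      utils::write.table(classical_mds(dsnp), file.path(out_dir, "mds_snp.tsv"),
                         sep = "\t", quote = FALSE)
    }
    mt <- mantel_test(dsnp, dcnv, n_perm = mantel_perm, seed = seed)
    res$distance$mantel <- mt
    write_tsv(data.frame(statistic = mt$statistic, p_value = mt$p_value),
              file.path(out_dir, "mantel.tsv"))
    note("distance: Mantel r = ", round(mt$statistic, 3))
  } else {
    warning("no genotype matrix supplied; SNP distance and FDR stages skipped")
    note("distance: SNP stage skipped (no genotypes)")
  }

  ## fdr
  if (!is.null(inputs$genotypes) && any(calls$copy_state < 2)) {
    fdr <- estimate_fdr(calls, inputs$genotypes, inputs$probes)
    res$fdr <- fdr
    write_tsv(data.frame(n_deletions = fdr$n_deletions,
                         n_testable = fdr$n_testable,
                         n_flagged = fdr$n_flagged, fdr = fdr$fdr,
                         fdr_per_sample_mean = fdr$fdr_per_sample_mean),
              file.path(out_dir, "fdr.tsv"))
    note("fdr: ", sprintf("%.1f%%", 100 * fdr$fdr))
  }

  ## summaries
  summ <- summarize_calls(calls, meta_pass, uniq)
  write_tsv(summ, file.path(out_dir, "summary.tsv"))
  gfa <- genome_fraction_affected(calls, inputs$genome)
  ls <- length_stats(calls)
  write_tsv(ls$table, file.path(out_dir, "length_stats.tsv"))
  res$summary <- list(table = summ, genome_fraction = gfa, lengths = ls)
  note("summary: ", nrow(calls), " calls affect ",
       sprintf("%.2f%%", 100 * gfa$fraction), " of the autosomes")

  ## manifest
  params <- list(version = as.character(utils::packageVersion("popcnv")),
                 fraction = fraction, n_perm = n_perm, seed = seed,
                 mantel_perm = mantel_perm,
                 thresholds = unclass(thresholds))
  param_txt <- paste(deparse(params), collapse = "\n")
  writeLines(c(param_txt, "", log_line), file.path(out_dir, "manifest.txt"))
  invisible(res)
}

#' Run the demonstration panel end to end
#'
#' Generates the scaled demonstration panel ([demo_panel()]) and
#' runs [run_pipeline()] on it.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (drives both the panel and the pipeline).
#' @param n_perm Enrichment permutations.
#' @return Invisibly, the pipeline's stage results.
#' @export
demo_panel_run <- function(out_dir, seed = 1, n_perm = 1000) {
  sim <- demo_panel(seed = seed)
  run_pipeline(sim, out_dir, n_perm = n_perm, seed = seed)
}
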