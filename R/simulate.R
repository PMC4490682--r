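#' Configuration for the synthetic CNV panel generator
#'
#' Defaults emulate the scale and structure of a diverse laboratory/wild
#' mouse array panel, scaled to desk size: a few tens of Mb of genome, probe
#' spacing in the kb range, log-normal call lengths with deletion and
#' amplification medians of about 20 kb and 37 kb, roughly 60/40
#' deletion/amplification mix varying by group, planted recurrent CNV regions
#' with group-specific carrier frequencies, extra unique calls per sample
#' (more in wild groups), a 25 % planted false-positive deletion fraction
#' whose genotypes follow Hardy-Weinberg (heterozygote excess) while true
#' deletions are forced homozygous with elevated no-call, and a feature track
#' with a controlled enrichment factor inside the planted CNV zones.
#'
#' @param n_autosomes,autosome_length,x_length Genome shape (bp).
#' @param probe_spacing_median Median inter-probe gap in bp (exponential gaps).
#' @param snp_fraction Fraction of probes that are SNP (vs IGP) probes.
#' @param groups Named integer vector of samples per group; names from
#'   `classical`, `wild_derived`, `wild_caught_dom`, `wild_caught_mus`.
#' @param n_cnvr Number of planted recurrent CNV regions.
#' @param home_freq,away_freq Carrier-frequency ranges (min, max) in a
#'   region's home group and in the other groups.
#' @param private_cnvr Number of the planted regions made private to each
#'   wild-caught subspecies (zero carriers elsewhere).
#' @param unique_per_sample Named integer vector of unique calls per sample
#'   per group.
#' @param del_prob Named per-group probability that a call is a deletion.
#' @param state1_prob Probability a deletion has state 1 (else 0).
#' @param state3_prob Probability an amplification has state 3 (else 4).
#' @param len_meanlog_del,len_meanlog_amp,len_sdlog Log-normal length
#'   parameters (bp scale).
#' @param min_len,max_len Clipping bounds for generated lengths.
#' @param fp_deletion_fraction Fraction of deletion calls planted as false
#'   positives.
#' @param het_true,nocall_true AB and NoCall probabilities inside true
#'   deletions.
#' @param baseline_het,baseline_nocall Background AB and NoCall rates.
#' @param ind_flip Within-group allele flip probability (individual
#'   diversity).
#' @param group_divergence Named per-group allele divergence from the common
#'   base.
#' @param feature_factor Track density multiplier inside planted CNV zones.
#' @param n_track_intervals,track_len_range Feature-track shape.
#' @param n_genes,genic_fraction Gene-track shape: background gene count and
#'   the probability that an event locus gets an overlapping gene.
#' @param n_qc_fail Number of samples planted to fail array QC.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_autosomes = 3, autosome_length = 2e7, x_length = 2e7,
    probe_spacing_median = 1000, snp_fraction = 0.75,
    groups = c(classical = 20, wild_derived = 10,
               wild_caught_dom = 10, wild_caught_mus = 10),
    n_cnvr = 25,
    home_freq = c(0.5, 0.9), away_freq = c(0, 0.25),
    private_cnvr = 2,
    unique_per_sample = c(classical = 3, wild_derived = 8,
                          wild_caught_dom = 10, wild_caught_mus = 10),
    del_prob = c(classical = 0.457, wild_derived = 0.692,
                 wild_caught_dom = 0.745, wild_caught_mus = 0.745),
    state1_prob = 0.65, state3_prob = 0.9,
    len_meanlog_del = log(20091), len_meanlog_amp = log(36708),
    len_sdlog = 0.6,
    min_len = 8000, max_len = 5e5,
    fp_deletion_fraction = 0.25,
    het_true = 0.005, nocall_true = 0.10,
    baseline_het = 0.01, baseline_nocall = 0.02,
    ind_flip = 0.02,
    group_divergence = c(classical = 0.05, wild_derived = 0.15,
                         wild_caught_dom = 0.20, wild_caught_mus = 0.30),
    feature_factor = 2,
    n_track_intervals = 600, track_len_range = c(500, 1500),
    n_genes = 150, genic_fraction = 0.657,
    n_qc_fail = 0) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$groups >= 0), cfg$n_cnvr >= 0,
            all(unlist(cfg[c("home_freq", "away_freq")]) >= 0),
            all(unlist(cfg[c("home_freq", "away_freq")]) <= 1),
            cfg$fp_deletion_fraction >= 0, cfg$fp_deletion_fraction <= 1)
  structure(cfg, class = "sim_config")
}

sim_genome <- function(cfg) {
  lens <- stats::setNames(rep(cfg$autosome_length, cfg$n_autosomes),
                          paste0("chr", seq_len(cfg$n_autosomes)))
  genome_def(c(lens, chrX = cfg$x_length))
}

sim_probes <- function(cfg, genome) {
  rate <- log(2) / cfg$probe_spacing_median  # exponential gaps, given median
  dfs <- lapply(names(genome$lengths), function(ch) {
    len <- genome$lengths[[ch]]
    n_exp <- ceiling(len * rate * 1.3) + 10
    pos <- cumsum(ceiling(stats::rexp(n_exp, rate)))
    pos <- pos[pos <= len - 30]
    data.frame(chrom = ch, pos = pos)
  })
  df <- do.call(rbind, dfs)
  df$id <- sprintf("P%06d", seq_len(nrow(df)))
  df$type <- ifelse(stats::runif(nrow(df)) < cfg$snp_fraction, "SNP", "IGP")
  probe_table(df[, c("id", "chrom", "pos", "type")])
}

# number of probes within [s, e] given sorted positions
count_markers <- function(pos_sorted, s, e) {
  findInterval(e, pos_sorted) - findInterval(s - 1, pos_sorted)
}

draw_len <- function(n, meanlog, cfg) {
  pmin(pmax(round(stats::rlnorm(n, meanlog, cfg$len_sdlog)), cfg$min_len),
       cfg$max_len)
}

#' Generate a complete synthetic panel
#'
#' Emits every input the pipeline consumes -- genome, probe annotation, CNV
#' call table, genotype matrix, sample metadata, feature and gene tracks --
#' plus the generating truth. All randomness is driven by `seed`; a fixed
#' seed reproduces the panel bit for bit. Member calls of one planted region
#' are jittered within the window that keeps every pairwise reciprocal
#' overlap at least 0.45 (a margin above the 0.40 analysis threshold), and
#' planted unique calls are placed disjoint from everything else, so the
#' recurrence graph recovers the planted clustering exactly.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_panel` with elements `genome`, `probes`,
#'   `calls`, `genotypes`, `meta`, `tracks` (named list of
#'   [feature_track()]), `genes`, and `truth` (list: `cnvr`, `call_cnvr`,
#'   `call_is_fp`, `groups`, `feature_factor`).
#' @export
simulate_panel <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  genome <- sim_genome(cfg)
  probes <- sim_probes(cfg, genome)
  pos_by_chrom <- lapply(split(probes$pos, probes$chrom), sort)

  ## samples
  groups <- cfg$groups[cfg$groups > 0]
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(groups))),
    group = rep(names(groups), groups),
    stringsAsFactors = FALSE
  )
  meta$classification <- ifelse(grepl("^wild_caught", meta$group),
                                "wild_caught", meta$group)
  meta$subspecies <- ifelse(meta$group == "wild_caught_dom", "domesticus",
                     ifelse(meta$group == "wild_caught_mus", "musculus", NA))
  meta$sex <- sample(c("M", "F"), nrow(meta), replace = TRUE)
  meta$lrr_sd <- stats::runif(nrow(meta), 0.10, 0.30)
  meta$baf_drift <- stats::runif(nrow(meta), 0, 0.008)
  if (cfg$n_qc_fail > 0) {
    fail <- sample(nrow(meta), min(cfg$n_qc_fail, nrow(meta)))
    meta$lrr_sd[fail] <- stats::runif(length(fail), 0.36, 0.6)
  }

  ## planted CNVR anchors, packed with wide gaps so regions never merge
  occupied <- lapply(names(genome$lengths), function(ch)
    data.frame(start = numeric(), end = numeric()))
  names(occupied) <- names(genome$lengths)
  claim <- function(ch, s, e) {
    occupied[[ch]] <<- rbind(occupied[[ch]], data.frame(start = s, end = e))
  }
  is_free <- function(ch, s, e) {
    occ <- occupied[[ch]]
    !nrow(occ) || !any(s <= occ$end & e >= occ$start)
  }
  group_names <- names(groups)
  cnvr <- data.frame()
  for (r in seq_len(cfg$n_cnvr)) {
    placed <- FALSE
    for (attempt in 1:300) {
      ch <- sample(genome$autosomes, 1)
      home <- if (r <= cfg$private_cnvr && "wild_caught_dom" %in% group_names)
        "wild_caught_dom"
      else if (r <= 2 * cfg$private_cnvr && "wild_caught_mus" %in% group_names)
        "wild_caught_mus"
      else sample(group_names, 1)
      is_del <- stats::runif(1) < cfg$del_prob[[home]]
      L <- draw_len(1, if (is_del) cfg$len_meanlog_del else cfg$len_meanlog_amp, cfg)
      delta <- floor(0.18 * L)
      s <- floor(stats::runif(1) * (genome$lengths[[ch]] - L - 2 * delta - 2)) +
        delta + 1
      e <- s + L - 1
      gap <- max(2 * delta, 30000)  # zone margin keeps regions separable
      if (!is_free(ch, s - delta - gap, e + delta + gap)) next
      # every jittered member must retain >= 3 markers
      if (count_markers(pos_by_chrom[[ch]], s + delta, e - delta) < 4) next
      claim(ch, s - delta - gap, e + delta + gap)
      private <- r <= 2 * cfg$private_cnvr &&
        home %in% c("wild_caught_dom", "wild_caught_mus")
      freq <- stats::setNames(
        stats::runif(length(group_names), cfg$away_freq[1], cfg$away_freq[2]),
        group_names)
      freq[home] <- stats::runif(1, cfg$home_freq[1], cfg$home_freq[2])
      if (private) freq[setdiff(group_names, home)] <- 0
      cnvr <- rbind(cnvr, data.frame(
        cnvr_id = r, chrom = ch, start = s, end = e, delta = delta,
        home = home, is_del = is_del, private = private,
        t(freq), stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: planted regions exceed the genome")
  }

  draw_state <- function(is_del, n) {
    is_del <- rep_len(is_del, n)
    ifelse(is_del,
           ifelse(stats::runif(n) < cfg$state1_prob, 1L, 0L),
           ifelse(stats::runif(n) < cfg$state3_prob, 3L, 4L))
  }

  ## member calls
  calls <- list()
  call_cnvr <- integer()
  for (r in seq_len(nrow(cnvr))) {
    fr <- unlist(cnvr[r, group_names])
    carrier <- stats::runif(nrow(meta)) < fr[meta$group]
    if (!any(carrier)) next
    k <- sum(carrier)
    d <- cnvr$delta[r]
    st <- cnvr$start[r] + floor(stats::runif(k, -d, d + 1))
    en <- cnvr$end[r] + floor(stats::runif(k, -d, d + 1))
    # call type follows the carrier's group mix, so group-level
    # deletion/amplification ratios land on their configured targets
    carrier_del <- stats::runif(k) < cfg$del_prob[meta$group[carrier]]
    calls[[length(calls) + 1L]] <- data.frame(
      sample_id = meta$sample_id[carrier], chrom = cnvr$chrom[r],
      start = st, end = en,
      copy_state = draw_state(carrier_del, k),
      stringsAsFactors = FALSE)
    call_cnvr <- c(call_cnvr, rep(r, k))
  }

  ## unique calls: disjoint from every zone and from each other
  for (i in seq_len(nrow(meta))) {
    n_u <- cfg$unique_per_sample[[meta$group[i]]]
    placed <- 0
    attempt <- 0
    while (placed < n_u && attempt < 400 * n_u) {
      attempt <- attempt + 1
      ch <- sample(genome$autosomes, 1)
      is_del <- stats::runif(1) < cfg$del_prob[[meta$group[i]]]
      L <- draw_len(1, if (is_del) cfg$len_meanlog_del else cfg$len_meanlog_amp, cfg)
      s <- floor(stats::runif(1) * (genome$lengths[[ch]] - L)) + 1
      e <- s + L - 1
      if (!is_free(ch, s - 1, e + 1)) next
      nm <- count_markers(pos_by_chrom[[ch]], s, e)
      if (nm < 3 || nm / L < 0.00013) next
      claim(ch, s, e)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = meta$sample_id[i], chrom = ch, start = s, end = e,
        copy_state = draw_state(is_del, 1), stringsAsFactors = FALSE)
      call_cnvr <- c(call_cnvr, NA_integer_)
      placed <- placed + 1
    }
    if (placed < n_u) stop("infeasible packing: could not place unique calls")
  }

  if (!length(calls)) {
    calls <- cnv_calls(character(), character(), numeric(), numeric(),
                       integer())[0, ]
  } else {
    calls <- do.call(rbind, calls)
    # marker support from the probe map
    calls$n_markers <- mapply(function(ch, s, e)
      count_markers(pos_by_chrom[[ch]], s, e), calls$chrom, calls$start,
      calls$end, USE.NAMES = FALSE)
    calls$source <- "sim"
  }

  ## false-positive flags on deletions
  is_fp <- rep(FALSE, nrow(calls))
  del_rows <- which(calls$copy_state < 2)
  if (length(del_rows))
    is_fp[del_rows] <- stats::runif(length(del_rows)) < cfg$fp_deletion_fraction

  ## sort deterministically; keep truth aligned
  ord <- order(calls$chrom, calls$start, calls$end, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  call_cnvr <- call_cnvr[ord]
  is_fp <- is_fp[ord]
  calls <- validate_calls(calls)

  ## genotypes over SNP probes, with group structure
  snp <- probes[probes$type == "SNP", , drop = FALSE]
  np <- nrow(snp); ns <- nrow(meta)
  maf <- stats::runif(np, 0.05, 0.5)
  base_allele <- stats::runif(np) < 0.5
  gflip <- matrix(stats::runif(np * length(group_names)) <
                    rep(cfg$group_divergence[group_names], each = np),
                  np, length(group_names), dimnames = list(NULL, group_names))
  allele <- base_allele & !gflip[, meta$group] | (!base_allele) & gflip[, meta$group]
  allele <- xor(allele, matrix(stats::runif(np * ns) < cfg$ind_flip, np, ns))
  genotypes <- matrix(ifelse(allele, "AA", "BB"), np, ns,
                      dimnames = list(snp$id, meta$sample_id))
  u <- matrix(stats::runif(np * ns), np, ns)
  genotypes[u < cfg$baseline_het] <- "AB"
  genotypes[u >= cfg$baseline_het &
            u < cfg$baseline_het + cfg$baseline_nocall] <- "NoCall"

  ## overlay deletion genotype signatures
  snp_pos <- split(seq_len(np), snp$chrom)
  for (k in which(calls$copy_state < 2)) {
    pi <- snp_pos[[calls$chrom[k]]]
    if (is.null(pi)) next
    inside <- pi[snp$pos[pi] >= calls$start[k] & snp$pos[pi] <= calls$end[k]]
    if (!length(inside)) next
    col <- calls$sample_id[k]
    if (is_fp[k]) {
      # Hardy-Weinberg at the probe's minor-allele frequency: het excess
      p <- maf[inside]
      u2 <- stats::runif(length(inside))
      g <- ifelse(u2 < (1 - p)^2, "AA", ifelse(u2 < (1 - p)^2 + 2 * p * (1 - p),
                                               "AB", "BB"))
      u3 <- stats::runif(length(inside))
      g[u3 < cfg$baseline_nocall] <- "NoCall"
    } else {
      g <- ifelse(allele[inside, match(col, meta$sample_id)], "AA", "BB")
      u2 <- stats::runif(length(inside))
      g[u2 < cfg$het_true] <- "AB"
      g[u2 >= cfg$het_true & u2 < cfg$het_true + cfg$nocall_true] <- "NoCall"
    }
    genotypes[inside, col] <- g
  }

  ## feature track: density multiplied by feature_factor inside the event
  ## loci (planted region anchors plus unique-call footprints)
  zones <- rbind(if (nrow(cnvr)) cnvr[, c("chrom", "start", "end")],
                 calls[is.na(call_cnvr), c("chrom", "start", "end")])
  track <- sim_feature_track(genome, zones, cfg$feature_factor,
                             cfg$n_track_intervals, cfg$track_len_range)

  ## genes: one gene over a fraction of event loci, plus background genes
  genes <- sim_genes(genome, zones, cfg$genic_fraction, cfg$n_genes)

  structure(list(
    genome = genome, probes = probes, calls = calls, genotypes = genotypes,
    meta = meta[, c("sample_id", "classification", "subspecies", "sex",
                    "lrr_sd", "baf_drift")],
    tracks = list(featureA = track), genes = genes,
    truth = list(cnvr = cnvr, call_cnvr = call_cnvr, call_is_fp = is_fp,
                 groups = stats::setNames(meta$group, meta$sample_id),
                 track_zones = zones,
                 feature_factor = cfg$feature_factor),
    config = cfg, seed = seed
  ), class = "sim_panel")
}

# Track intervals with density inside the zones exactly `factor` times the
# density outside: an interval is a zone interval with probability
# f*Z / (f*Z + (T - Z)) and is placed uniformly inside a zone; background
# intervals are rejection-sampled into the zone complement.
sim_feature_track <- function(genome, zones, factor, n, len_range) {
  chroms <- genome$autosomes
  zones <- if (is.null(zones)) data.frame() else zones[zones$chrom %in% chroms, ,
                                                       drop = FALSE]
  zone_bp <- if (nrow(zones)) sum(zones$end - zones$start + 1) else 0
  total <- sum(genome$lengths[chroms])
  p_zone <- factor * zone_bp / (factor * zone_bp + (total - zone_bp))
  in_zone <- stats::runif(n) < p_zone & nrow(zones) > 0
  lens <- round(stats::runif(n, len_range[1], len_range[2]))
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    stringsAsFactors = FALSE)
  zone_w <- if (nrow(zones)) zones$end - zones$start + 1 else numeric()
  hits_zone <- function(ch, s) {
    z <- zones[zones$chrom == ch, , drop = FALSE]
    nrow(z) > 0 && any(s >= z$start & s <= z$end)
  }
  for (i in seq_len(n)) {
    if (in_zone[i]) {
      z <- sample.int(nrow(zones), 1, prob = zone_w)
      s <- floor(stats::runif(1, zones$start[z], zones$end[z] + 1))
      out[i, ] <- list(zones$chrom[z], s, s + lens[i] - 1)
    } else {
      repeat {
        ch <- sample(chroms, 1, prob = genome$lengths[chroms])
        s <- floor(stats::runif(1) * (genome$lengths[[ch]] - lens[i])) + 1
        if (!hits_zone(ch, s)) break
      }
      out[i, ] <- list(ch, s, s + lens[i] - 1)
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  feature_track("featureA", out)
}

sim_genes <- function(genome, loci, genic_fraction, n_background) {
  rows <- list()
  if (nrow(loci)) {
    hit <- stats::runif(nrow(loci)) < genic_fraction
    for (i in which(hit)) {
      L <- loci$end[i] - loci$start[i] + 1
      glen <- max(500, round(stats::runif(1, 0.2, 0.8) * L))
      gs <- max(1, loci$start[i] + floor(stats::runif(1, 0, L - glen)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = loci$chrom[i], start = gs, end = gs + glen - 1)
    }
  }
  chroms <- genome$autosomes
  for (i in seq_len(n_background)) {
    ch <- sample(chroms, 1, prob = genome$lengths[chroms])
    glen <- round(stats::runif(1, 5000, 50000))
    gs <- floor(stats::runif(1) * (genome$lengths[[ch]] - glen)) + 1
    rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = gs,
                                            end = gs + glen - 1)
  }
  if (!length(rows))
    return(gene_table(character(), character(), character(), numeric(),
                      numeric(), character()))
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  n <- nrow(df)
  gene_table(
    id = sprintf("G%05d", seq_len(n)),
    symbol = sprintf("Gene%05d", seq_len(n)),
    chrom = df$chrom, start = df$start, end = df$end,
    biotype = sample(c("protein_coding", "pseudogene", "rna", "antisense"),
                     n, replace = TRUE, prob = c(0.76, 0.11, 0.10, 0.03)))
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("Synthetic CNV panel:", nrow(x$meta), "samples,", nrow(x$calls),
      "calls,", nrow(x$probes), "probes, seed", x$seed, "\n")
  cat("  planted regions:", nrow(x$truth$cnvr),
      " planted FP deletions:", sum(x$truth$call_is_fp), "\n")
  invisible(x)
}

#' A scaled demonstration panel mirroring a diverse mouse array study
#'
#' About 50 samples and 1500 calls: classical laboratory strains with fewer,
#' more recurrent calls and a lower deletion/amplification ratio; wild-derived
#' and wild-caught groups with more calls per sample, more unique calls and a
#' deletion excess; wild-caught samples split between the domesticus and
#' musculus subspecies with a few subspecies-private planted regions.
#'
#' @param seed Integer seed.
#' @return A `sim_panel` (see [simulate_panel()]).
#' @export
demo_panel <- function(seed = 1) {
  cfg <- sim_config(
    groups = c(classical = 25, wild_derived = 10,
               wild_caught_dom = 8, wild_caught_mus = 8),
    n_cnvr = 40,
    home_freq = c(0.5, 0.9), away_freq = c(0.05, 0.35),
    private_cnvr = 2,
    unique_per_sample = c(classical = 3, wild_derived = 8,
                          wild_caught_dom = 10, wild_caught_mus = 10))
  simulate_panel(cfg, seed = seed)
}

#' Write a synthetic panel to disk in the pipeline's input formats
#'
#' Calls as TSV, probes as TSV, genotypes as TSV, metadata as TSV, genome as
#' a chromosome-length table, each feature track and the gene track as BED.
#'
#' @param sim A `sim_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(sim$calls, file.path(dir, "calls.tsv"))
  write_tsv(sim$probes[, c("id", "chrom", "pos", "type")],
            file.path(dir, "probes.tsv"))
  write_genotype_matrix(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(sim$meta, file.path(dir, "samples.tsv"))
  write_genome_table(sim$genome, file.path(dir, "genome.tsv"))
  for (nm in names(sim$tracks))
    write_bed(sim$tracks[[nm]]$intervals, file.path(dir, paste0(nm, ".bed")))
  write_tsv(sim$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}
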