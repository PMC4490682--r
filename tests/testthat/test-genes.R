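toy_genes <- function() {
  gene_table(id = c("g1", "g2", "g3"),
             symbol = c("Alpha", "Beta", "Gamma"),
             chrom = "chr1",
             start = c(2000, 2000, 50000), end = c(3000, 3000, 90000),
             biotype = c("protein_coding", "processed_pseudogene", "miRNA"))
}

test_that("overlap relations follow interval containment with ties to encompasses", {
  genes <- toy_genes()
  calls <- cnv_calls("S1", "chr1",
                     start = c(1, 2000, 500, 60000, 95000),
                     end = c(10000, 3000, 2500, 70000, 99000), copy_state = 1)
  ov <- classify_gene_overlap(calls, genes)
  rel <- function(cr, gid) ov$relation[ov$call_row == cr & ov$gene_id == gid]
  expect_equal(rel(1, "g1"), "encompasses_gene")
  expect_equal(rel(2, "g1"), "encompasses_gene")  # identical intervals
  expect_equal(rel(3, "g1"), "partial")
  expect_equal(rel(4, "g3"), "inside_gene")
  expect_equal(nrow(ov[ov$call_row == 5, ]), 0)
  # relations partition all >= 1 bp overlaps
  expect_true(all(ov$relation %in% c("encompasses_gene", "inside_gene", "partial")))
})

test_that("genic-fraction bookkeeping is a complement identity", {
  set.seed(61)
  calls <- random_calls(200, max_len = 5000)
  gstart <- sample.int(9e4, 30)
  genes <- gene_table(sprintf("g%02d", 1:30), sprintf("Sym%02d", 1:30),
                      sample(c("chr1", "chr2"), 30, TRUE),
                      start = gstart, end = gstart + 4000,
                      biotype = "protein_coding")
  ov <- classify_gene_overlap(calls, genes)
  frac_genic <- length(unique(ov$call_row)) / nrow(calls)
  frac_none <- mean(!seq_len(nrow(calls)) %in% ov$call_row)
  expect_equal(frac_genic, 1 - frac_none)
})

test_that("complete-overlap gene lists exclude partial hits and keep coded pseudogenes", {
  genes <- toy_genes()
  calls <- cnv_calls("S1", "chr1", start = c(1, 40000), end = c(10000, 45000),
                     copy_state = 1)
  syms <- complete_overlap_gene_list(calls, genes)
  expect_equal(syms, c("Alpha", "Beta"))   # pseudogene g2 included
  f <- withr::local_tempfile()
  complete_overlap_gene_list(calls, genes, path = f)
  expect_equal(readLines(f), c("Alpha", "Beta"))
  expect_equal(complete_overlap_gene_list(calls[0, ], genes), character(0))
  expect_equal(map_biotype(c("protein_coding", "processed_pseudogene",
                             "miRNA", "antisense", "TEC")),
               c("protein_coding", "pseudogene", "rna", "antisense", "other"))
})

test_that("negative-control screening reports deletion overlaps with severity", {
  controls <- gene_table("c1", "Cask", "chrX", 10000, 19999, "protein_coding")
  calls <- cnv_calls(c("m1", "m2", "m3"), "chrX",
                     start = c(8000, 12000, 30000),
                     end = c(11299, 13000, 40000),
                     copy_state = c(1, 0, 1))
  v <- screen_negative_controls(calls, controls)
  expect_equal(nrow(v), 2)
  expect_equal(v$severity[1], "state_zero")  # highest severity first
  m1 <- v[v$sample_id == "m1", ]
  expect_equal(m1$fraction_of_gene, 1300 / 10000)  # partial loss fraction
  # no overlapping deletions: empty table
  none <- screen_negative_controls(
    cnv_calls("m1", "chrX", 1, 100, 1), controls)
  expect_equal(nrow(none), 0)
  # amplifications are never reported
  amp <- screen_negative_controls(
    cnv_calls("m1", "chrX", 12000, 13000, 3), controls)
  expect_equal(nrow(amp), 0)
})

private_fixture <- function() {
  # 10 domesticus, 10 musculus wild-caught, plus classical/wild-derived
  meta <- data.frame(
    sample_id = c(sprintf("D%02d", 1:10), sprintf("M%02d", 1:10), "C01", "W01"),
    classification = c(rep("wild_caught", 20), "classical", "wild_derived"),
    subspecies = c(rep("domesticus", 10), rep("musculus", 10), NA, NA),
    sex = "F", lrr_sd = 0.1, baf_drift = 0.001, stringsAsFactors = FALSE)
  meta
}

test_that("private subspecies regions require six carriers and zero cross-subspecies overlap", {
  meta <- private_fixture()
  # region A: 7 domesticus carriers, nothing else
  a <- cnv_calls(sprintf("D%02d", 1:7), "chr1", 10000, 30000, 1)
  # region B: 6 domesticus carriers but one musculus overlap: disqualified
  b <- cnv_calls(c(sprintf("D%02d", 1:6), "M01"), "chr1",
                 c(rep(60000, 6), 61000), c(rep(80000, 6), 62000),
                 c(rep(1, 6), 3))
  # region C: 8 musculus carriers, also seen in wild-derived
  c_ <- cnv_calls(c(sprintf("M%02d", 1:8), "W01"), "chr2", 10000, 25000, 3)
  calls <- rbind(a, b, c_)
  g <- build_recurrence_graph(calls)
  reg <- cnv_regions(g)
  priv <- private_subspecies_cnvs(g, reg, meta)
  expect_equal(nrow(priv), 2)
  pa <- priv[priv$chrom == "chr1", ]
  expect_equal(pa$subspecies, "domesticus")
  expect_equal(pa$n_carriers, 7L)
  expect_equal(pa$type, "Del")
  expect_false(pa$seen_in_classical)
  pc <- priv[priv$chrom == "chr2", ]
  expect_equal(pc$subspecies, "musculus")
  expect_equal(pc$n_carriers, 8L)
  expect_true(pc$seen_in_wild_derived)
})

test_that("private-region output is invariant to sample order", {
  meta <- private_fixture()
  calls <- rbind(
    cnv_calls(sprintf("D%02d", 1:7), "chr1", 10000, 30000, 1),
    cnv_calls(sprintf("M%02d", 1:6), "chr2", 40000, 55000, 1))
  run <- function(cl) {
    g <- build_recurrence_graph(cl)
    private_subspecies_cnvs(g, cnv_regions(g), meta)
  }
  p1 <- run(calls)
  set.seed(67)
  p2 <- run(calls[sample.int(nrow(calls)), ])
  expect_equal(p1, p2)
  expect_error(
    private_subspecies_cnvs(build_recurrence_graph(calls),
                            cnv_regions(build_recurrence_graph(calls)),
                            within(meta, subspecies <- NA)),
    "subspecies labels")
})

test_that("planted subspecies-private regions are recovered from a synthetic panel", {
  cfg <- sim_config(groups = c(classical = 10, wild_derived = 5,
                               wild_caught_dom = 10, wild_caught_mus = 10),
                    n_cnvr = 12, private_cnvr = 3,
                    home_freq = c(0.8, 0.95), away_freq = c(0.1, 0.3))
  sim <- simulate_panel(cfg, seed = 11)
  g <- build_recurrence_graph(sim$calls)
  reg <- cnv_regions(g)
  priv <- private_subspecies_cnvs(g, reg, sim$meta)
  # independent recount of the privacy rule from the raw calls and truth:
  # for each planted region and subspecies, count realized wild-caught
  # carriers among its members and scan all other-subspecies wild-caught
  # calls for >= 1 bp overlap with the realized member span
  truth <- sim$truth
  grp_of <- truth$groups
  want <- list()
  for (p in seq_len(nrow(truth$cnvr))) {
    members <- which(truth$call_cnvr == truth$cnvr$cnvr_id[p])
    if (length(members) < 2) next
    span_s <- min(sim$calls$start[members])
    span_e <- max(sim$calls$end[members])
    ch <- truth$cnvr$chrom[p]
    for (ssp in c("wild_caught_dom", "wild_caught_mus")) {
      carriers <- unique(sim$calls$sample_id[members][
        grp_of[sim$calls$sample_id[members]] == ssp])
      if (length(carriers) < 6) next
      other <- setdiff(c("wild_caught_dom", "wild_caught_mus"), ssp)
      other_calls <- sim$calls[grp_of[sim$calls$sample_id] == other, ]
      touched <- any(other_calls$chrom == ch & other_calls$start <= span_e &
                     other_calls$end >= span_s)
      if (!touched)
        want[[length(want) + 1]] <- c(ch, ssp)
    }
  }
  got <- Map(c, priv$chrom,
             ifelse(priv$subspecies == "domesticus", "wild_caught_dom",
                    "wild_caught_mus"))
  expect_setequal(lapply(got, paste, collapse = ":"),
                  lapply(want, paste, collapse = ":"))
  # every planted-private region with enough realized carriers is among them
  planted <- truth$cnvr[truth$cnvr$private, ]
  for (p in seq_len(nrow(planted))) {
    members <- which(truth$call_cnvr == planted$cnvr_id[p])
    carriers <- unique(sim$calls$sample_id[members][
      grp_of[sim$calls$sample_id[members]] == planted$home[p]])
    if (length(carriers) >= 6)
      expect_true(any(priv$chrom == planted$chrom[p] &
                      priv$start <= planted$end[p] &
                      priv$end >= planted$start[p]))
  }
})
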