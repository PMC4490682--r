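het_fixture <- function(n_snp = 20, n_ab = 3, n_nocall = 0) {
  probes <- probe_table(data.frame(id = paste0("p", 1:n_snp), chrom = "chr1",
                                   pos = seq(1000, by = 500, length.out = n_snp),
                                   type = "SNP"))
  g <- matrix("AA", n_snp, 1, dimnames = list(probes$id, "s1"))
  if (n_ab) g[seq_len(n_ab), 1] <- "AB"
  if (n_nocall) g[n_snp - seq_len(n_nocall) + 1, 1] <- "NoCall"
  list(probes = probes, genotypes = g)
}

test_that("het fraction applies the strictly-more-than-10% rule at the boundary", {
  fx <- het_fixture(n_snp = 20, n_ab = 3)
  call <- cnv_calls("s1", "chr1", 1, 1e5, 1)
  expect_equal(call_het_fraction(call, fx$genotypes, fx$probes), 0.15)
  r <- estimate_fdr(call, fx$genotypes, fx$probes)
  expect_equal(r$n_flagged, 1L)           # 0.15 > 0.10: flagged
  fx2 <- het_fixture(n_snp = 20, n_ab = 2)
  r2 <- estimate_fdr(call, fx2$genotypes, fx2$probes)
  expect_equal(r2$n_flagged, 0L)          # exactly 0.10 is NOT flagged
  # no-calls leave the denominator
  fx3 <- het_fixture(n_snp = 20, n_ab = 2, n_nocall = 10)
  expect_equal(call_het_fraction(call, fx3$genotypes, fx3$probes), 0.2)
  # all no-call inside: untestable
  fx4 <- het_fixture(n_snp = 5, n_ab = 0, n_nocall = 5)
  expect_true(is.na(call_het_fraction(call, fx4$genotypes, fx4$probes)))
  expect_error(estimate_fdr(call, fx4$genotypes, fx4$probes), "no testable")
  expect_error(call_het_fraction(cnv_calls("s1", "chr1", 1, 10, 3),
                                 fx$genotypes, fx$probes), "deletion")
})

test_that("degenerate genotype panels give FDR 0 and 1", {
  fx <- het_fixture(n_snp = 10, n_ab = 0)
  calls <- cnv_calls("s1", "chr1", c(1, 3000), c(2500, 8000), c(1, 0))
  expect_equal(estimate_fdr(calls, fx$genotypes, fx$probes)$fdr, 0)
  all_ab <- het_fixture(n_snp = 10, n_ab = 10)
  expect_equal(estimate_fdr(calls, all_ab$genotypes, all_ab$probes)$fdr, 1)
})

test_that("het fractions match a per-probe brute force on random panels", {
  set.seed(101)
  probes <- probe_table(data.frame(id = sprintf("p%03d", 1:100),
                                   chrom = rep(c("chr1", "chr2"), each = 50),
                                   pos = rep(sort(sample.int(5e4, 50)), 2),
                                   type = sample(c("SNP", "IGP"), 100, TRUE,
                                                 prob = c(0.8, 0.2))))
  snp_ids <- probes$id[probes$type == "SNP"]
  g <- matrix(sample(c("AA", "AB", "BB", "NoCall"), length(snp_ids) * 3, TRUE),
              length(snp_ids), 3,
              dimnames = list(snp_ids, paste0("s", 1:3)))
  calls <- random_calls(50, chroms = c("chr1", "chr2"), max_pos = 4e4,
                        max_len = 10000, samples = paste0("s", 1:3))
  calls$copy_state <- sample(c(0L, 1L), nrow(calls), TRUE)
  got <- call_het_fraction(calls, g, probes)
  for (i in seq_len(nrow(calls))) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(probes))) {
      if (probes$type[k] != "SNP") next
      if (probes$chrom[k] != calls$chrom[i]) next
      if (probes$pos[k] < calls$start[i] || probes$pos[k] > calls$end[i]) next
      gt <- g[probes$id[k], calls$sample_id[i]]
      if (gt == "NoCall") next
      den <- den + 1
      if (gt == "AB") num <- num + 1
    }
    if (den == 0) expect_true(is.na(got[i])) else expect_equal(got[i], num / den)
  }
})

test_that("FDR estimate is invariant to call and sample order and monotone in threshold", {
  sim <- simulate_panel(sim_config(groups = c(classical = 10, wild_derived = 5,
                                              wild_caught_dom = 5,
                                              wild_caught_mus = 5),
                                   n_cnvr = 10), seed = 23)
  r <- estimate_fdr(sim$calls, sim$genotypes, sim$probes)
  set.seed(29)
  shuffled <- sim$calls[sample.int(nrow(sim$calls)), ]
  r2 <- estimate_fdr(shuffled, sim$genotypes, sim$probes)
  expect_equal(r2$fdr, r$fdr)
  expect_equal(r2$n_flagged, r$n_flagged)
  # raising the threshold never increases the flagged count
  thresholds <- c(0.05, 0.10, 0.20, 0.40)
  flagged <- vapply(thresholds, function(t)
    estimate_fdr(sim$calls, sim$genotypes, sim$probes, het_threshold = t)$n_flagged,
    integer(1))
  expect_true(all(diff(flagged) <= 0))
})

test_that("planted within-deletion het probability matches the binomial closed form", {
  # true deletions simulated with het probability p: the chance a call with m
  # called SNPs is flagged is the upper binomial tail beyond m/10
  p <- 0.005; m <- 15
  flag_prob <- 1 - pbinom(floor(0.10 * m), m, p)
  expect_lt(flag_prob, 0.01)   # honest deletions essentially never flagged
  p_fp <- 0.3
  flag_prob_fp <- 1 - pbinom(floor(0.10 * m), m, p_fp)
  expect_gt(flag_prob_fp, 0.95)  # Hardy-Weinberg het excess almost always flagged
})

test_that("group rate comparisons detect planted shifts and not null ones", {
  sim <- simulate_panel(sim_config(groups = c(classical = 12,
                                              wild_caught_dom = 6,
                                              wild_caught_mus = 6),
                                   n_cnvr = 12,
                                   nocall_true = 0.10), seed = 31)
  classical <- sim$meta$sample_id[sim$meta$classification == "classical"]
  wild <- sim$meta$sample_id[sim$meta$classification == "wild_caught"]
  # identical groups: p near 1
  same <- group_rate_test(sim$calls, sim$genotypes, sim$probes,
                          classical, classical, rate = "nocall")
  expect_gt(same$p_value, 0.99)
  # rate computation agrees with a direct per-sample recount
  s <- classical[1]
  dels <- sim$calls[sim$calls$sample_id == s & sim$calls$copy_state < 2, ]
  snp <- sim$probes[sim$probes$type == "SNP", ]
  inside <- rep(FALSE, nrow(snp))
  for (r in seq_len(nrow(dels)))
    inside <- inside | (snp$chrom == dels$chrom[r] & snp$pos >= dels$start[r] &
                        snp$pos <= dels$end[r])
  want <- mean(sim$genotypes[snp$id[inside], s] == "NoCall")
  expect_equal(unname(same$rates1[s]), want)
  expect_error(group_rate_test(sim$calls, sim$genotypes, sim$probes,
                               character(0), wild), "non-empty")
})

test_that("a planted het-rate shift between groups is detected", {
  # 50 samples per group, ~200 in-call SNPs each, het rates 3% vs 1%
  probes <- probe_table(data.frame(id = sprintf("p%03d", 1:200), chrom = "chr1",
                                   pos = seq(1000, by = 400, length.out = 200),
                                   type = "SNP"))
  samples <- c(paste0("w", 1:50), paste0("c", 1:50))
  calls <- cnv_calls(samples, "chr1", 1, 90000, 1)
  set.seed(37)
  detected <- 0
  for (rep in 1:10) {
    het_p <- rep(c(0.03, 0.01), each = 50)
    g <- vapply(seq_along(samples), function(i)
      ifelse(runif(200) < het_p[i], "AB", "AA"), character(200))
    dimnames(g) <- list(probes$id, samples)
    res <- group_rate_test(calls, g, probes, paste0("w", 1:50),
                           paste0("c", 1:50), rate = "het")
    if (res$p_value < 0.01) detected <- detected + 1
  }
  expect_gte(detected, 9)
})
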