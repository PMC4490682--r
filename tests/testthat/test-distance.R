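test_that("SNP distance excludes no-calls and matches a per-locus count", {
  g <- matrix(c("AA", "AB", "NoCall", "BB",
                "AA", "BB", "NoCall", "BB"), ncol = 2,
              dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  d <- snp_distance(g)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(diag(as.matrix(d)), c(s1 = 0, s2 = 0))
  # identical columns give zero
  g2 <- cbind(g, s3 = g[, "s1"])
  expect_equal(snp_distance(g2)["s1", "s3"], 0)
  # zero co-called loci is an error naming the pair
  g3 <- matrix(c("AA", "NoCall", "NoCall", "BB"), ncol = 2,
               dimnames = list(paste0("p", 1:2), c("x", "y")))
  expect_error(snp_distance(g3), "x / y")
})

test_that("SNP distance matches brute force on random matrices", {
  set.seed(71)
  for (rep in 1:20) {
    g <- matrix(sample(c("AA", "AB", "BB", "NoCall"), 40 * 6, TRUE,
                       prob = c(0.4, 0.2, 0.3, 0.1)),
                40, 6, dimnames = list(paste0("p", 1:40), paste0("s", 1:6)))
    d <- snp_distance(g)
    for (i in 1:5) for (j in (i + 1):6) {
      num <- 0; den <- 0
      for (k in 1:40) {
        if (g[k, i] == "NoCall" || g[k, j] == "NoCall") next
        den <- den + 1
        if (g[k, i] != g[k, j]) num <- num + 1
      }
      expect_equal(d[i, j], num / den)
      expect_equal(d[j, i], d[i, j])
    }
  }
})

cnv_dist_fixture <- function() {
  genome <- genome_def(c(chr1 = 1e5, chrX = 1e5))
  probes <- probe_table(data.frame(id = paste0("p", 1:4), chrom = "chr1",
                                   pos = c(1000, 2000, 3000, 4000),
                                   type = c("SNP", "IGP", "SNP", "IGP")))
  list(genome = genome, probes = probes)
}

test_that("CNV distance assigns collapsed probe states against baseline 2", {
  fx <- cnv_dist_fixture()
  # s1 carries a deletion over p3; s2 nothing; both carry a 4-state amp on p4
  calls <- cnv_calls(c("s1", "s1", "s2"), "chr1",
                     start = c(2900, 3900, 3900), end = c(3100, 4100, 4100),
                     copy_state = c(1, 4, 4))
  d <- cnv_distance(calls, fx$probes, c("s1", "s2"), fx$genome)
  # states s1: [2,2,1,3+], s2: [2,2,2,3+] -> differ at 1 of 4 probes
  expect_equal(d["s1", "s2"], 0.25)
  # no calls anywhere: all-zero matrix
  d0 <- cnv_distance(calls[0, ], fx$probes, c("s1", "s2"), fx$genome)
  expect_true(all(d0 == 0))
})

test_that("CNV distance matches per-probe brute force and X probes are excluded", {
  genome <- genome_def(c(chr1 = 5e4, chr2 = 5e4, chrX = 5e4))
  set.seed(73)
  probes <- probe_table(data.frame(
    id = sprintf("p%03d", 1:90),
    chrom = rep(c("chr1", "chr2", "chrX"), each = 30),
    pos = rep(sort(sample.int(5e4, 30)), 3), type = "IGP"))
  samples <- paste0("s", 1:4)
  calls <- random_calls(40, chroms = c("chr1", "chr2"), max_pos = 4e4,
                        max_len = 8000, samples = samples)
  # drop overlapping same-sample calls to keep the brute force unambiguous
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls) - 1)) for (j in (i + 1):nrow(calls)) {
    if (keep[j] && keep[i] && calls$sample_id[i] == calls$sample_id[j] &&
        oracle_ro(calls$chrom[i], calls$start[i], calls$end[i],
                  calls$chrom[j], calls$start[j], calls$end[j]) > 0)
      keep[j] <- FALSE
  }
  calls <- calls[keep, ]
  d <- cnv_distance(calls, probes, samples, genome)
  auto <- probes[probes$chrom != "chrX", ]
  state_of <- function(s, k) {
    st <- 2L
    for (r in which(calls$sample_id == s)) {
      if (calls$chrom[r] == auto$chrom[k] && calls$start[r] <= auto$pos[k] &&
          calls$end[r] >= auto$pos[k]) st <- min(calls$copy_state[r], 3L)
    }
    st
  }
  for (i in 1:3) for (j in (i + 1):4) {
    want <- mean(vapply(seq_len(nrow(auto)), function(k)
      state_of(samples[i], k) != state_of(samples[j], k), logical(1)))
    expect_equal(d[i, j], want)
  }
  # zero distance iff identical induced state vectors
  m <- probe_state_matrix(calls, probes, samples, genome)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j] == 0, identical(m[, i], m[, j]))
})

test_that("conflicting same-sample overlaps resolve to the extreme state with a warning", {
  fx <- cnv_dist_fixture()
  calls <- cnv_calls(c("s1", "s1"), "chr1", start = c(900, 900),
                     end = c(1100, 1100), copy_state = c(1, 3))
  expect_warning(
    m <- probe_state_matrix(calls, fx$probes, c("s1", "s2"), fx$genome),
    "most extreme")
  expect_equal(m["p1", "s1"], 1L)  # tie in extremeness: deletion wins
})

test_that("neighbor joining solves the 3-taxon closed form and additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # additive distances from random trees: exact topology and lengths
  set.seed(79)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- round(runif(nrow(true$edge), 0.1, 2), 3)
    dm <- ape::cophenetic.phylo(true)
    got <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(got, true)), 0)
    # recovered pairwise path lengths equal the generating distances
    expect_equal(ape::cophenetic.phylo(got)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "at least 3")
  asym <- d; asym[1, 2] <- 5
  expect_error(nj_tree(asym), "symmetric")
})

test_that("an identical pair forms a zero-length cherry", {
  d <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  tip_len <- tr$edge.length[match(match(c("A", "B"), tr$tip.label),
                                  tr$edge[, 2])]
  expect_equal(tip_len, c(0, 0))
})

test_that("classical MDS reproduces generating configurations", {
  # 3 collinear points: first axis carries the line, second nothing
  d <- as.matrix(dist(c(0, 1, 2)))
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  co <- classical_mds(d, k = 2)
  expect_equal(unname(abs(diff(co[, 1]))), c(1, 1), tolerance = 1e-7)
  # the second axis is a zero eigenvalue: only numerically zero
  expect_lt(max(abs(co[, 2])), 1e-6)
  # random 2-D configurations: embedded distances match inputs
  set.seed(83)
  for (rep in 1:5) {
    xy <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("s", 1:8)))
    dm <- as.matrix(dist(xy))
    co <- classical_mds(dm, k = 2)
    expect_equal(as.matrix(dist(co)), dm, tolerance = 1e-9, ignore_attr = TRUE)
    # sign convention: largest-magnitude loading on each axis is positive
    for (a in 1:2) expect_gt(co[which.max(abs(co[, a])), a], 0)
  }
  # duplicated samples land on identical coordinates
  dm <- as.matrix(dist(c(0, 0, 5, 9)))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  co <- classical_mds(dm)
  expect_equal(unname(co[1, ]), unname(co[2, ]), tolerance = 1e-6)
})

test_that("Mantel statistic and permutation p behave at the extremes", {
  set.seed(89)
  xy <- matrix(rnorm(20), 10, 2)
  d1 <- as.matrix(dist(xy))
  rownames(d1) <- colnames(d1) <- paste0("s", 1:10)
  m_self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(m_self$statistic, 1.0)
  expect_equal(m_self$p_value, 1 / 100)
  m_scaled <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(m_scaled$statistic, 1.0)
  expect_error(mantel_test(d1, matrix(1, 10, 10) - diag(10) * 0, 99),
               "constant")
})

test_that("Mantel agrees with an independent implementation and is calibrated under the null", {
  skip_if_not_installed("vegan")
  set.seed(97)
  d1 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  dimnames(d1) <- dimnames(d2) <- list(paste0("s", 1:12), paste0("s", 1:12))
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # null calibration: p below 0.05 in roughly 5 % of independent draws
  hits <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    a <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    b <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    dimnames(a) <- dimnames(b) <- list(paste0("s", 1:10), paste0("s", 1:10))
    if (mantel_test(a, b, n_perm = 199, seed = s)$p_value < 0.05)
      hits <- hits + 1
  }
  expect_lte(hits, 8)  # ~2.5 expected; generous upper bound
})

test_that("planted group structure yields correlated SNP and CNV distances", {
  sim <- simulate_panel(sim_config(groups = c(classical = 8, wild_derived = 6,
                                              wild_caught_dom = 6,
                                              wild_caught_mus = 6),
                                   n_cnvr = 15), seed = 19)
  samples <- sort(sim$meta$sample_id)
  dsnp <- snp_distance(sim$genotypes[, samples])
  dcnv <- cnv_distance(sim$calls, sim$probes, samples, sim$genome)
  # within-group CNV distance below between-group
  grp <- sim$truth$groups[samples]
  same <- outer(grp, grp, "==")[lower.tri(dcnv)]
  expect_lt(mean(as.matrix(dcnv)[lower.tri(dcnv)][same]),
            mean(as.matrix(dcnv)[lower.tri(dcnv)][!same]))
  mt <- mantel_test(dsnp, dcnv, n_perm = 499, seed = 3)
  expect_gt(mt$statistic, 0)
  expect_lt(mt$p_value, 0.05)
  # distances are bounded, symmetric, zero-diagonal
  for (d in list(dsnp, dcnv)) {
    m <- as.matrix(d)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
})

test_that("high-call-count sample exclusion drops only the extreme tail", {
  calls <- rbind(random_calls(10, samples = "low1"),
                 random_calls(10, samples = "low2"),
                 random_calls(80, samples = "high"))
  out <- exclude_high_call_samples(calls, percentile = 0.6)
  expect_setequal(unique(out$sample_id), c("low1", "low2"))
})
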