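test_that("constant probe input yields a single segment", {
  probes <- data.frame(contig = "c", pos = seq(0, 990, 10))
  set.seed(1)
  segs <- segment_probes(probes, rep(0.1, 100), n_perm = 200)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$mean_log2, 0.1)
  expect_identical(segs$n_probes, 100L)
  # fewer than 2 * min_probes probes: single segment, no test
  segs2 <- segment_probes(probes[1:4, ], c(0, 0, 5, 5), min_probes = 3)
  expect_identical(nrow(segs2), 1L)
})

test_that("a clear step is split at the right place with exact means", {
  set.seed(33)
  probes <- data.frame(contig = "c", pos = seq(0, 990, 10))
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  segs <- segment_probes(probes, x, n_perm = 500)
  expect_identical(nrow(segs), 2L)
  expect_lte(abs(segs$first_probe[2L] - 51L), 2L)
  # segment means equal brute-force means of the assigned probes
  for (i in seq_len(nrow(segs))) {
    idx <- segs$first_probe[i]:segs$last_probe[i]
    expect_equal(segs$mean_log2[i], mean(x[idx]))
  }
  # probe-sum conservation
  expect_equal(sum(segs$mean_log2 * segs$n_probes), sum(x),
               tolerance = 1e-9)
})

test_that("breakpoints are recovered across simulated single-step samples", {
  set.seed(55)
  probes <- data.frame(contig = "c", pos = seq(0, 990, 10))
  hits <- 0L
  n_trials <- 30L
  for (i in seq_len(n_trials)) {
    bp <- sample(20:80, 1L)
    x <- c(rnorm(bp, 0, 0.1), rnorm(100 - bp, 1, 0.1))
    segs <- segment_probes(probes, x, n_perm = 300)
    cuts <- segs$first_probe[-1L] - 1L
    if (any(abs(cuts - bp) <= 2L)) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("gene-level copy number is the mean of overlapping probes", {
  r <- tiny_reference()
  probes <- data.frame(contig = rep(names(r$ref), each = 50),
                       pos = rep(seq(0, 4900, 100), length(r$ref)))
  set.seed(3)
  x <- rnorm(nrow(probes))
  for (g in r$genes) {
    got <- gene_cn(probes, x, g)
    lo <- min(g$exons$start); hi <- max(g$exons$end)
    sel <- probes$contig == g$contig & probes$pos >= lo & probes$pos < hi
    expect_equal(got, mean(x[sel]))
  }
  # single overlapping probe returns its own value; none returns NA
  g1 <- r$genes[[1L]]
  lo <- min(g1$exons$start)
  one <- data.frame(contig = g1$contig, pos = lo)
  expect_equal(gene_cn(one, 0.7, g1), 0.7)
  off <- data.frame(contig = "elsewhere", pos = 0)
  expect_true(is.na(gene_cn(off, 0.7, g1)))
})

test_that("amplification calls use a strict log2 > 0.6 inequality", {
  cn <- matrix(c(0.6, 0.6000001, 1.2, -0.7), 4, 1,
               dimnames = list(paste0("g", 1:4), "T1"))
  expr <- matrix(rnorm(12, 8, 0.1), 4, 3,
                 dimnames = list(paste0("g", 1:4), c("T1", "N1", "N2")))
  classes <- c(T1 = "tumor", N1 = "normal", N2 = "normal")
  res <- integrate_cn_expr(cn, expr, classes)
  states <- res$states
  expect_false(states$amplified[states$gene_id == "g1"])   # exactly 0.6
  expect_true(states$amplified[states$gene_id == "g2"])
  expect_true(states$amplified[states$gene_id == "g3"])
  expect_true(states$lost[states$gene_id == "g4"])
})

test_that("integration ranking finds implanted amplicons and is permutation-invariant", {
  fx <- default_fixture()
  ex <- fx$expr
  truth <- fx$cohort$truth
  tumors <- colnames(truth$cn_gene_log2)
  qn <- quantile_normalize(ex$expr)
  cn_gene <- gene_cn_matrix(ex$cn_probes, ex$cn[, tumors], fx$reference$genes)
  res <- integrate_cn_expr(cn_gene, qn, ex$classes)
  # genes with true amplification in >= 2 tumors beat never-amplified genes
  true_amp_freq <- rowMeans(truth$cn_gene_log2 > 0.6)
  top <- res$ranking$gene_id[seq_len(sum(true_amp_freq > 0))]
  expect_gt(mean(true_amp_freq[top] > 0), 0.8)
  # sample-order permutation invariance
  set.seed(9)
  perm <- sample(tumors)
  res2 <- integrate_cn_expr(cn_gene[, perm], qn, ex$classes)
  expect_identical(res$ranking, res2$ranking)
})

test_that("recurrence summary equals a brute-force per-bin recount", {
  segs <- data.frame(
    sample = c("a", "a", "b", "c"), contig = c("c1", "c1", "c1", "c2"),
    start = c(0L, 3000L, 500L, 0L), end = c(2000L, 4000L, 2500L, 1000L),
    mean_log2 = c(1.0, -0.9, 0.8, 0.1))
  out <- recurrence_summary(segs, bin_size = 1000L,
                            contig_lengths = c(c1 = 4000L, c2 = 2000L))
  # brute force
  for (i in seq_len(nrow(out))) {
    g <- 0; l <- 0
    for (j in seq_len(nrow(segs))) {
      if (segs$contig[j] != out$contig[i]) next
      overlap <- segs$start[j] < out$bin_end[i] &&
        segs$end[j] > out$bin_start[i]
      if (!overlap) next
      if (segs$mean_log2[j] > 0.6) g <- g + segs$mean_log2[j]
      if (segs$mean_log2[j] < -0.6) l <- l + segs$mean_log2[j]
    }
    expect_equal(out$gain_sum[i], g)
    expect_equal(out$loss_sum[i], l)
  }
  # sub-threshold segments contribute nothing
  quiet <- segs; quiet$mean_log2 <- 0.1
  out0 <- recurrence_summary(quiet, 1000L,
                             contig_lengths = c(c1 = 4000L, c2 = 2000L))
  expect_true(all(out0$gain_sum == 0) && all(out0$loss_sum == 0))
})

test_that("profile matrix applies state precedence and counts actionability", {
  states <- data.frame(
    sample = c("s1", "s1", "s2", "s3", "s3"),
    gene_id = c("gA", "gB", "gA", "gB", "gC"),
    log2 = c(1, 0, -1, 0, 0.2),
    amplified = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    overexpressed = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    lost = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  mut <- data.frame(sample = c("s1", "s3"), gene_id = c("gA", "gC"),
                    consequence = c("nonsynonymous", "stop_gained"))
  prof <- build_profile(states, mut, confirmed = c(TRUE, FALSE),
                        actionable_features = c("gA", "gC"))
  m <- prof$matrix
  expect_identical(m["s1", "gA"], "mutation_confirmed")  # beats amp
  expect_identical(m["s1", "gB"], "overexpr_only")
  expect_identical(m["s2", "gA"], "dna_loss")
  expect_identical(m["s3", "gC"], "mutation_unconfirmed")
  expect_identical(m["s3", "gB"], "none")
  # actionable: s1 (gA mutation), s3 (gC mutation); s2 has only a loss
  expect_identical(prof$n_actionable, 2L)
  expect_identical(sum(apply(m[, c("gA", "gC"), drop = FALSE], 1,
                             function(r) any(r %in% c(
                               "amp_and_overexpr", "overexpr_only",
                               "mutation_confirmed",
                               "mutation_unconfirmed")))),
                   prof$n_actionable)
  # 11 actionable of 50 reports 22 percent
  states50 <- data.frame(sample = sprintf("p%02d", 1:11), gene_id = "gA",
                         log2 = 1, amplified = TRUE, overexpressed = TRUE,
                         lost = FALSE)
  prof50 <- build_profile(states50, mut[0, ],
                          actionable_features = "gA",
                          samples = sprintf("p%02d", 1:50))
  expect_identical(prof50$n_actionable, 11L)
  expect_identical(prof50$pct_actionable, 22L)
  # no events at all: all none, zero percent
  empty <- build_profile(states[0, ], mut[0, ], actionable_features = "gA",
                         samples = c("x", "y"))
  expect_true(all(empty$matrix == "none"))
  expect_identical(empty$pct_actionable, 0L)
})
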