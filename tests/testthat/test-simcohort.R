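test_that("sim_config validates its rates and ranges", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(somatic_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(mean_coverage = 0), "positive")
  expect_error(sim_config(purity_range = c(0, 0.9)))
})

test_that("reference simulation is reproducible and well-formed", {
  r1 <- simulate_reference(4, c(300, 600), seed = 9)
  r2 <- simulate_reference(4, c(300, 600), seed = 9)
  expect_identical(r1, r2)
  r3 <- simulate_reference(4, c(300, 600), seed = 10)
  expect_false(identical(r1$ref, r3$ref))
  # targets equal the exon union
  ex <- do.call(rbind, lapply(r1$genes, function(g) {
    data.frame(contig = g$contig, start = g$exons$start, end = g$exons$end)
  }))
  expect_identical(target_span(r1$targets), sum(ex$end - ex$start))
  # every CDS translates to protein ending in (and only in) a stop
  for (g in r1$genes) {
    aa <- translate_cds(spliced_cds(r1$ref, g))
    expect_identical(aa[1L], "M")
    expect_identical(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("cohort simulation is byte-reproducible under a fixed seed", {
  r <- simulate_reference(2, c(300, 450), seed = 5)
  cfg <- sim_config(n_pairs = 2L, n_tumor_only = 1L, n_array_loci = 20L,
                    seed = 77L)
  c1 <- simulate_cohort(cfg, r)
  c2 <- simulate_cohort(cfg, r)
  expect_identical(c1, c2)
  e1 <- simulate_expression(cfg, r, c1$truth)
  e2 <- simulate_expression(cfg, r, c2$truth)
  expect_identical(e1, e2)
  # byte-identical files from the same inputs
  f1 <- tempfile(); f2 <- tempfile()
  write_pileup_tsv(c1$pileups[[1L]], f1)
  write_pileup_tsv(c2$pileups[[1L]], f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("simulated depth matches the configured coverage", {
  r <- simulate_reference(8, c(1500, 2100), seed = 13)
  cfg <- sim_config(n_pairs = 1L, n_tumor_only = 0L, low_depth_prob = 0,
                    n_array_loci = 10L, seed = 21L)
  co <- simulate_cohort(cfg, r)
  depth <- rowSums(co$pileups[[1L]][, c("A", "C", "G", "T")])
  expect_gte(length(depth), 1e4)
  expect_lt(abs(mean(depth) - cfg$mean_coverage) / cfg$mean_coverage, 0.02)
  # with low-coverage dropout the expectation shifts accordingly
  fx <- small_cohort()
  d2 <- rowSums(fx$cohort$pileups[[1L]][, c("A", "C", "G", "T")])
  expected <- (1 - fx$cfg$low_depth_prob) * fx$cfg$mean_coverage +
    fx$cfg$low_depth_prob * fx$cfg$low_depth_mean
  se <- stats::sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - expected), 4 * se)
})

test_that("allele fractions and genotype classes behave as configured", {
  fx <- default_fixture()
  co <- fx$cohort
  cfg <- fx$cfg
  # het germline sites: pooled alt fraction near 0.5 (law of large numbers)
  s <- co$samples$sample[co$samples$type == "normal"][1L]
  ind <- co$samples$individual[co$samples$sample == s]
  pu <- co$pileups[[s]]
  g <- co$truth$germline[co$truth$germline$individual == ind &
                           co$truth$germline$dosage == 1L, ]
  idx <- match(paste(g$contig, g$pos), paste(pu$contig, pu$pos))
  m <- as.matrix(pu[idx, c("A", "C", "G", "T")])
  alt_reads <- m[cbind(seq_len(nrow(m)), match(g$alt, c("A", "C", "G", "T")))]
  depth <- rowSums(m)
  frac <- sum(alt_reads) / sum(depth)
  sigma <- 0.5 / sqrt(sum(depth))
  expect_lt(abs(frac - 0.5), 3 * sigma)
  # subclonal fraction among somatic truth within binomial 95% CI
  n_som <- nrow(co$truth$somatic)
  n_sub <- sum(!co$truth$somatic$clonal)
  ci <- stats::binom.test(n_sub, n_som)$conf.int
  expect_gte(cfg$subclone_prob, ci[1L])
  expect_lte(cfg$subclone_prob, ci[2L])
  # somatic sets are disjoint from the sample's own germline set
  ind_of <- stats::setNames(co$samples$individual, co$samples$sample)
  som_k <- paste(ind_of[co$truth$somatic$sample], co$truth$somatic$contig,
                 co$truth$somatic$pos)
  germ_k <- paste(co$truth$germline$individual, co$truth$germline$contig,
                  co$truth$germline$pos)
  expect_length(intersect(som_k, germ_k), 0L)
  # deleteriousness scores straddle the 0.05 damaging boundary
  expect_true(all(co$truth$somatic$score[co$truth$somatic$damaging] < 0.05))
  expect_true(all(co$truth$somatic$score[!co$truth$somatic$damaging] >= 0.05))
})

test_that("array genotype error matches the configured rate", {
  fx <- default_fixture()
  co <- fx$cohort
  # compare array genotypes to truth dosages at the shared loci
  poly_key <- paste(co$truth$panel$contig, co$truth$panel$pos)
  ind_of <- stats::setNames(co$samples$individual, co$samples$sample)
  arr <- co$array[co$array$genotype != "NoCall", ]
  pi_ <- match(paste(arr$contig, arr$pos), poly_key)
  germ <- co$truth$germline
  gk <- paste(germ$individual, germ$contig, germ$pos)
  dos <- germ$dosage[match(paste(ind_of[arr$sample], arr$contig, arr$pos),
                           gk)]
  dos[is.na(dos)] <- 0L
  truth_gt <- c("AA", "AB", "BB")[dos + 1L]
  n_err <- sum(arr$genotype != truth_gt)
  ci <- stats::binom.test(n_err, nrow(arr))$conf.int
  expect_gte(fx$cfg$array_error, ci[1L])
  expect_lte(fx$cfg$array_error, ci[2L])
})

test_that("extreme configurations produce the expected degenerate pileups", {
  r <- simulate_reference(1, c(300, 300), seed = 2)
  cfg <- sim_config(n_pairs = 0L, n_tumor_only = 1L, purity_range = c(1, 1),
                    base_error_phred = 1000, low_depth_prob = 0,
                    subclone_prob = 0, germline_rate = 0,
                    n_private_germline = 0L, somatic_rate = 0.02,
                    n_array_loci = 0L, seed = 8L)
  co <- simulate_cohort(cfg, r)
  pu <- co$pileups[[1L]]
  som <- co$truth$somatic
  expect_gt(nrow(som), 0L)
  expect_true(all(som$vaf == 0.5))  # purity 1, clonal het
  idx <- match(paste(som$contig, som$pos), paste(pu$contig, pu$pos))
  m <- as.matrix(pu[idx, c("A", "C", "G", "T"), drop = FALSE])
  alt_reads <- m[cbind(seq_len(nrow(m)), match(som$alt, c("A", "C", "G", "T")))]
  # error-free: alt reads are exactly Binomial(depth, 0.5) draws and
  # non-carrier bases are silent
  expect_equal(rowSums(m), alt_reads + m[cbind(seq_len(nrow(m)),
               match(som$ref, c("A", "C", "G", "T")))],
               ignore_attr = TRUE)
})

test_that("sanger re-test classification follows truth and VAF", {
  fx <- small_cohort()
  tr <- fx$cohort$truth
  som <- tr$somatic
  clonal_hi <- som[som$vaf >= 0.2, ][1L, ]
  sub_lo <- som[som$vaf < 0.2, ][1L, ]
  g <- tr$germline[1L, ]
  g_sample <- paste0(g$individual, "T")
  called <- data.frame(
    sample = c(clonal_hi$sample, sub_lo$sample, g_sample, clonal_hi$sample),
    contig = c(clonal_hi$contig, sub_lo$contig, g$contig, clonal_hi$contig),
    pos = c(clonal_hi$pos, sub_lo$pos, g$pos, 0L),
    alt = c(clonal_hi$alt, sub_lo$alt, g$alt, "N"),
    stringsAsFactors = FALSE)
  rec <- simulate_sanger_retest(tr, called)
  expect_identical(rec$outcome,
                   c("confirmed_somatic", "absent", "germline", "absent"))
  expect_error(simulate_sanger_retest(
    tr, data.frame(sample = "nope", contig = "c", pos = 1L, alt = "A")),
    "unknown sample")
})
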