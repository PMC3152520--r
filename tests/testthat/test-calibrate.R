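# hand-built fixture: 10 loci, 1 sample, explicit genotypes on both
# platforms
.hand_calibration <- function() {
  shared <- data.frame(locus_id = sprintf("L%02d", 1:10), contig = "c",
                       pos = 0:9, allele_a = "A", allele_b = "G",
                       stringsAsFactors = FALSE)
  # array: 5 hom-ref, 5 variant-bearing (AB notation); sequencing
  # genotypes are bases; locus 10 disagrees (array BB vs sequenced het)
  array_gt <- c(rep("AA", 5), "AB", "AB", "AB", "BB", "BB")
  seq_gt <- c(rep("AA", 5), "AG", "AG", "AG", "GG", "AG")
  calls <- data.frame(sample = "S1", contig = "c", pos = 0:9, ref = "A",
                      genotype = seq_gt,
                      cq = c(60, 60, 40, 60, 60, 60, 60, 30, 60, 60),
                      vq = ifelse(seq_gt == "AA", 0, 90),
                      depth = 100, stringsAsFactors = FALSE)
  array <- data.frame(sample = "S1", locus_id = shared$locus_id,
                      contig = "c", pos = 0:9, genotype = array_gt,
                      stringsAsFactors = FALSE)
  list(calls = calls, array = array, shared = shared)
}

test_that("concordance is exact arithmetic on hand-built genotypes", {
  h <- .hand_calibration()
  cc <- concordance(h$calls, h$array, h$shared)
  expect_equal(cc$overall, 0.9)
  expect_identical(cc$n, 10L)
  # identical platforms give 1
  h2 <- h
  h2$calls$genotype[10] <- "GG"
  expect_equal(concordance(h2$calls, h2$array, h2$shared)$overall, 1)
  # 97 of 100 worked example
  h3 <- list(
    shared = data.frame(locus_id = sprintf("L%03d", 1:100), contig = "c",
                        pos = 0:99, allele_a = "A", allele_b = "C"),
    calls = data.frame(sample = "S", contig = "c", pos = 0:99, ref = "A",
                       genotype = c(rep("AA", 97), rep("AC", 3)),
                       cq = 60, vq = c(rep(0, 97), rep(9, 3)), depth = 50),
    array = data.frame(sample = "S", locus_id = sprintf("L%03d", 1:100),
                       contig = "c", pos = 0:99, genotype = "AA"))
  expect_equal(concordance(h3$calls, h3$array, h3$shared)$overall, 0.97)
  # NoCall excluded, empty comparable set is NA not 0
  h4 <- h
  h4$array$genotype[] <- "NoCall"
  cc4 <- concordance(h4$calls, h4$array, h4$shared)
  expect_identical(cc4$overall, NA_real_)
  expect_identical(cc4$n, 0L)
})

test_that("threshold grid is exact and monotone in every cutoff", {
  h <- .hand_calibration()
  grid <- tabulate_grid(h$calls, h$array, h$shared,
                        cq_grid = c(0, 35, 50, 100), vq_grid = c(0, 95),
                        depth_grid = c(0, 50, 500))
  # all-zero cutoffs equal the unfiltered comparison
  r0 <- grid[grid$cq_cutoff == 0 & grid$vq_cutoff == 0 &
               grid$depth_cutoff == 0, ]
  expect_identical(r0$n_calls_retained, 10L)
  expect_equal(r0$concordance, 0.9)
  # cq 35 removes the cq=30 call, cq 50 also the cq=40 call
  r35 <- grid[grid$cq_cutoff == 35 & grid$vq_cutoff == 0 &
                grid$depth_cutoff == 0, ]
  expect_identical(r35$n_calls_retained, 9L)
  r50 <- grid[grid$cq_cutoff == 50 & grid$vq_cutoff == 0 &
                grid$depth_cutoff == 0, ]
  expect_identical(r50$n_calls_retained, 8L)
  # vq 95 keeps hom-ref calls but drops all variant calls (vq = 90)
  rv <- grid[grid$cq_cutoff == 0 & grid$vq_cutoff == 95 &
               grid$depth_cutoff == 0, ]
  expect_identical(rv$n_calls_retained, 5L)
  expect_equal(rv$concordance, 1)
  # cutoffs above everything retain nothing, concordance undefined
  rx <- grid[grid$cq_cutoff == 100 & grid$depth_cutoff == 500, ]
  expect_true(all(rx$n_calls_retained == 0L))
  expect_true(all(is.na(rx$concordance)))
  # retained-call monotonicity along each axis
  for (v in unique(grid$vq_cutoff)) for (d in unique(grid$depth_cutoff)) {
    sub <- grid[grid$vq_cutoff == v & grid$depth_cutoff == d, ]
    expect_true(all(diff(sub$n_calls_retained[order(sub$cq_cutoff)]) <= 0))
  }
  for (cq in unique(grid$cq_cutoff)) for (d in unique(grid$depth_cutoff)) {
    sub <- grid[grid$cq_cutoff == cq & grid$depth_cutoff == d, ]
    expect_true(all(diff(sub$n_calls_retained[order(sub$vq_cutoff)]) <= 0))
  }
})

test_that("threshold selection maximizes concordance above the floor", {
  h <- .hand_calibration()
  grid <- tabulate_grid(h$calls, h$array, h$shared,
                        cq_grid = c(0, 35, 50), vq_grid = c(0, 95),
                        depth_grid = 0)
  sel <- select_thresholds(grid, min_retained_fraction = 0.5)
  # exhaustive scan oracle
  floor_n <- 0.5 * max(grid$n_calls_retained)
  cand <- grid[grid$n_calls_retained >= floor_n & !is.na(grid$concordance), ]
  best <- max(cand$concordance)
  expect_equal(sel$concordance, best)
  oracle_rows <- cand[cand$concordance == best, ]
  expect_true(sel$n_calls_retained == max(oracle_rows$n_calls_retained))
  # dominating row is chosen when one dominates
  g2 <- data.frame(cq_cutoff = c(0, 50), vq_cutoff = 0, depth_cutoff = 0,
                   n_calls_retained = c(100L, 99L), n_concordant = c(90L, 99L),
                   concordance = c(0.90, 1.0))
  expect_identical(select_thresholds(g2, 0.85)$cq_cutoff, 50)
  # degenerate grid (nothing retained anywhere) -> NULL with warning
  g3 <- data.frame(cq_cutoff = c(256, 300), vq_cutoff = 0, depth_cutoff = 0,
                   n_calls_retained = c(0L, 0L), n_concordant = c(0L, 0L),
                   concordance = c(NA_real_, NA_real_))
  expect_warning(out <- select_thresholds(g3, 0.85), "retention floor")
  expect_null(out)
})

test_that("stratified FPR separates reference and variant array strata", {
  h <- .hand_calibration()
  fpr <- stratified_fpr(h$calls, h$array, h$shared)
  expect_equal(fpr$fpr_ref, 0)
  expect_equal(fpr$fpr_variant, 0.2)   # 1 of 5 variant loci discordant
  expect_identical(fpr$n_ref, 5L)
  expect_identical(fpr$n_variant, 5L)
  # perfect agreement gives (0, 0)
  h2 <- .hand_calibration()
  h2$calls$genotype[10] <- "GG"
  fpr2 <- stratified_fpr(h2$calls, h2$array, h2$shared)
  expect_equal(fpr2$fpr_ref, 0)
  expect_equal(fpr2$fpr_variant, 0)
  # empty stratum is NA
  h3 <- h
  h3$array$genotype[1:5] <- "NoCall"
  expect_identical(stratified_fpr(h3$calls, h3$array, h3$shared)$fpr_ref,
                   NA_real_)
})

test_that("sequencing genotypes with out-of-panel alleles count discordant", {
  shared <- data.frame(locus_id = "L1", contig = "c", pos = 0,
                       allele_a = "A", allele_b = "G")
  calls <- data.frame(sample = "S", contig = "c", pos = 0, ref = "A",
                      genotype = "AT", cq = 60, vq = 60, depth = 50)
  array <- data.frame(sample = "S", locus_id = "L1", contig = "c", pos = 0,
                      genotype = "AA")
  expect_equal(concordance(calls, array, shared)$overall, 0)
})

test_that("matched pairs outscore unrelated pairs and swaps are flagged", {
  fx <- small_cohort()
  lc <- fx$called$locus_calls
  pairs <- somaticpanel:::.expected_pairs(fx$cohort$samples)
  res <- mislabel_check(lc, pairs)
  expect_false(any(res$flagged))
  m <- attr(res, "matrix")
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
  # matched pairs sit above every unrelated tumor/normal combination
  unrelated <- m[pairs$tumor, pairs$normal]
  unrelated[cbind(pairs$tumor, pairs$normal)] <- NA
  expect_gt(min(res$concordance), max(unrelated, na.rm = TRUE))
  # replace one normal's data with an unrelated individual's: that pair,
  # and only that pair, is flagged
  victim <- pairs$normal[1L]
  donor <- pairs$normal[3L]
  swapped <- lc[lc$sample != victim, , drop = FALSE]
  dup <- lc[lc$sample == donor, , drop = FALSE]
  dup$sample <- victim
  res2 <- mislabel_check(rbind(swapped, dup), pairs)
  expect_identical(res2$normal[res2$flagged], victim)
})
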