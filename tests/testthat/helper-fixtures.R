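# Shared fixtures. Expensive objects (the default-scale cohort) are built
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small reference: 6 genes of 600-900 nt over 2 contigs
tiny_reference <- function() {
  .cached("tiny_reference", function() {
    simulate_reference(6, c(600, 900), seed = 3)
  })
}

# small cohort on the tiny reference: 4 pairs + 2 tumor-only
small_cohort <- function() {
  .cached("small_cohort", function() {
    r <- tiny_reference()
    cfg <- sim_config(n_pairs = 4L, n_tumor_only = 2L,
                      n_array_loci = 100L, seed = 11L)
    co <- simulate_cohort(cfg, r)
    called <- call_cohort(co$pileups, r$targets,
                          keep_loci = co$shared_loci)
    list(reference = r, cfg = cfg, cohort = co, called = called)
  })
}

# default-scale cohort (the study-condition configuration): 36 pairs + 8
# tumor-only, 20 genes, 110x. Built once and reused by acceptance tests.
default_fixture <- function() {
  .cached("default_fixture", function() {
    r <- simulate_reference(seed = 42)
    cfg <- sim_config(seed = 42)
    co <- simulate_cohort(cfg, r)
    ex <- simulate_expression(cfg, r, co$truth)
    called <- call_cohort(co$pileups, r$targets,
                          keep_loci = co$shared_loci)
    is_t <- called$variant_calls$sample %in%
      co$samples$sample[co$samples$type == "tumor"]
    tumor_variants <- calls_to_variants(
      filter_calls(called$variant_calls[is_t, , drop = FALSE], 50, 0, 0))
    normal_variants <- calls_to_variants(
      called$variant_calls[!is_t, , drop = FALSE])
    panel <- co$truth$panel[co$truth$panel$in_panel,
                            c("contig", "pos", "alt")]
    scores <- co$truth$somatic[, c("contig", "pos", "alt", "score")]
    somatic <- subtract_germline(tumor_variants, normal_variants, panel,
                                 r, scores)
    list(reference = r, cfg = cfg, cohort = co, expr = ex,
         called = called, tumor_variants = tumor_variants,
         normal_variants = normal_variants, panel = panel,
         scores = scores, somatic = somatic)
  })
}

variant_key <- function(d) paste(d$sample, d$contig, d$pos, d$alt)

# a single-interval plus-strand gene on a bespoke contig, from an explicit
# CDS sequence (used for hand-constructed annotation cases)
make_gene_from_cds <- function(cds_seq, strand = "+", flank = 10L,
                               gene_id = "GX") {
  n <- nchar(cds_seq)
  genomic <- if (strand == "-") reverse_complement(cds_seq) else cds_seq
  left <- paste(rep("A", flank), collapse = "")
  ref <- c(ctgX = paste0(left, genomic, left))
  iv <- data.frame(start = flank, end = flank + n)
  list(ref = ref,
       gene = gene_model(gene_id, "ctgX", strand, iv, iv),
       cds_start = flank)
}

# independent consequence oracle: retranslate the full mutated CDS and
# compare residue-by-residue with the original protein
oracle_consequence <- function(ref, gene, pos, ref_base, alt_base) {
  in_cds <- any(pos >= gene$cds$start & pos < gene$cds$end)
  if (!in_cds) return(list(category = "noncoding", aa_change = ""))
  ctg <- ref[[gene$contig]]
  mutated <- ctg
  sub_base <- alt_base
  substring(mutated, pos + 1L, pos + 1L) <- sub_base
  ref2 <- ref
  ref2[[gene$contig]] <- mutated
  aa_before <- translate_cds(spliced_cds(ref, gene))
  aa_after <- translate_cds(spliced_cds(ref2, gene))
  diff <- which(aa_before != aa_after)
  if (!length(diff)) return(list(category = "synonymous", aa_change = ""))
  i <- diff[1L]
  b <- aa_before[i]; a <- aa_after[i]
  fmt <- function(x) ifelse(x == "*", "X", x)
  if (a == "*") {
    list(category = "stop_gained", aa_change = paste0(fmt(b), i, "X"))
  } else if (b == "*") {
    list(category = "stop_lost", aa_change = paste0("X", i, fmt(a)))
  } else {
    list(category = "nonsynonymous", aa_change = paste0(b, i, a))
  }
}

# independent genotype-likelihood oracle: per-read product over the
# emission model, looped naively over the 10 genotypes
oracle_likelihoods <- function(counts, q) {
  e <- 10^(-q / 10)
  bases <- c("A", "C", "G", "T")
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  out <- numeric(10)
  names(out) <- gts
  for (g in gts) {
    alleles <- strsplit(g, "")[[1L]]
    ll <- 0
    for (b in bases) {
      w <- mean(alleles == b)
      p <- w * (1 - e) + (1 - w) * e / 3
      ll <- ll + counts[[b]] * log(p)
    }
    out[g] <- ll
  }
  out
}

# oracle posterior for call_genotype: brute-force normalization of
# likelihood x prior
oracle_posterior <- function(counts, ref_base, q, theta = 0.001) {
  ll <- oracle_likelihoods(counts, q)
  gts <- names(ll)
  hom_ref <- paste0(ref_base, ref_base)
  has_ref <- grepl(ref_base, gts, fixed = TRUE)
  prior <- ifelse(gts == hom_ref, 1 - theta - theta^2,
                  ifelse(has_ref, theta / 3, theta^2 / 6))
  w <- exp(ll - max(ll)) * prior
  w / sum(w)
}

random_pileup_counts <- function() {
  depth <- sample(1:200, 1L)
  f <- stats::runif(1)
  n1 <- stats::rbinom(1L, depth, f)
  picks <- sample(4L, 2L)
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  counts[picks[1L]] <- n1
  counts[picks[2L]] <- depth - n1
  # sprinkle error reads
  err <- sample(0:3, 1L)
  if (err > 0) {
    i <- sample(4L, 1L)
    counts[i] <- counts[i] + err
  }
  counts
}
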