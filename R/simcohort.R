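# Synthetic tumor/normal cohort generator with recorded ground truth.
# Every downstream stage (calling, calibration, somatic filtering, CNV and
# expression integration) is exercised on its output, so the whole pipeline
# is testable without external data.

.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults mirror the design of a deeply sequenced gastric-carcinoma panel
#' study: 36 matched tumor/normal pairs plus 8 tumor-only samples (44 tumors),
#' 110x mean targeted coverage, an SNP-array genotyping arm sharing ~1000
#' polymorphic loci with the sequenced targets, per-genotype array error of
#' 0.5%, tumor purity drawn uniformly from 0.4-0.9, and a subclonal somatic
#' class that falls below typical Sanger re-test sensitivity.
#'
#' @param n_pairs matched tumor/normal pairs (default 36).
#' @param n_tumor_only tumors without a matched normal (default 8).
#' @param mean_coverage mean reads per targeted site (default 110).
#' @param germline_rate per-bp density of polymorphic germline loci in the
#'   panel region (default 0.025; sized so the default desk-scale reference
#'   carries on the order of 1000 array-genotyped loci).
#' @param maf_range minor-allele-frequency range for polymorphic loci.
#' @param panel_capture_prob probability a polymorphic locus is present in
#'   the known-polymorphism panel (dbSNP/1000G stand-in; default 0.85).
#' @param n_private_germline novel private heterozygous germline variants per
#'   individual, absent from the panel (default 6).
#' @param somatic_rate somatic substitutions per bp per tumor (default 8e-4).
#' @param hot_gene_factor somatic-rate multiplier for the designated
#'   hot gene (first gene of the reference; default 8).
#' @param damaging_prob probability a somatic variant is truly damaging;
#'   damaging variants receive deleteriousness scores ~ U(0, 0.05), others
#'   ~ U(0.05, 1) (default 0.45).
#' @param purity_range tumor purity range, uniform draw (default 0.4-0.9).
#' @param subclone_prob fraction of somatic events restricted to a subclone.
#' @param subclone_ccf cancer-cell fraction of the subclone (default 0.3).
#' @param base_error_phred mean Phred base quality (default 30).
#' @param low_depth_prob probability a site in a sample drops to low
#'   coverage (default 0.02) -- the mechanism behind germline leak-through.
#' @param low_depth_mean mean depth at dropped sites (default 3).
#' @param array_error per-genotype array error rate (default 0.005).
#' @param array_nocall per-genotype array no-call rate (default 0.01).
#' @param n_array_loci number of polymorphic loci genotyped on the array arm.
#' @param cnv_segments_per_sample aberrant copy segments per tumor.
#' @param cnv_log2_sd probe-level log2-ratio noise SD (default 0.15).
#' @param cn_probe_spacing copy-number probe spacing in bp (default 200).
#' @param cn_expr_slope log2-expression change per unit log2 copy ratio.
#' @param expr_noise_sd expression noise SD on the log2 scale (default 0.3).
#' @param n_background_genes transcriptome background probes added to the
#'   expression matrix beyond the panel genes (default 200); expression
#'   arrays measure far more genes than a sequencing panel targets, and the
#'   background keeps rank-based normalization realistic.
#' @param signature_effect log2 expression shift of signature genes in
#'   signature-high tumors (default 1.5).
#' @param copa_effect log2 shift of the implanted outlier gene in its
#'   outlier tumors (default 6).
#' @param copa_tumor_frac fraction of tumors carrying the outlier (default
#'   0.25, echoing high expression in a minority of cancers).
#' @param qpcr_shift_sd per-sample global qPCR efficiency shift SD (log10).
#' @param qpcr_noise_sd per-assay qPCR noise SD (log10; default 0).
#' @param sanger_vaf_limit variant allele fraction below which a Sanger
#'   re-test cannot see a variant (default 0.20).
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pairs = 36L, n_tumor_only = 8L,
                       mean_coverage = 110,
                       germline_rate = 0.025,
                       maf_range = c(0.05, 0.5),
                       panel_capture_prob = 0.85,
                       n_private_germline = 6L,
                       somatic_rate = 8e-4,
                       hot_gene_factor = 8,
                       damaging_prob = 0.45,
                       purity_range = c(0.4, 0.9),
                       subclone_prob = 0.2,
                       subclone_ccf = 0.3,
                       base_error_phred = 30,
                       low_depth_prob = 0.02,
                       low_depth_mean = 3,
                       array_error = 0.005,
                       array_nocall = 0.01,
                       n_array_loci = 1000L,
                       cnv_segments_per_sample = 3L,
                       cnv_log2_sd = 0.15,
                       cn_probe_spacing = 200L,
                       cn_expr_slope = 1,
                       expr_noise_sd = 0.3,
                       n_background_genes = 200L,
                       signature_effect = 1.5,
                       copa_effect = 6,
                       copa_tumor_frac = 0.25,
                       qpcr_shift_sd = 0.3,
                       qpcr_noise_sd = 0,
                       sanger_vaf_limit = 0.20,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c("germline_rate", "panel_capture_prob", "somatic_rate",
             "subclone_prob", "subclone_ccf", "low_depth_prob",
             "array_error", "array_nocall", "damaging_prob",
             "copa_tumor_frac")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(r, " must lie in [0, 1]")
  }
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  stopifnot(length(purity_range) == 2L,
            purity_range[1] > 0, purity_range[2] <= 1,
            purity_range[1] <= purity_range[2])
  if (subclone_ccf <= 0) stop("subclone_ccf must be positive")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sense CDS: ATG + non-stop codons + stop
.rand_cds <- function(len_nt) {
  stopifnot(len_nt %% 3L == 0L, len_nt >= 9L)
  codons <- names(GENETIC_CODE_TABLE)
  nonstop <- codons[GENETIC_CODE_TABLE != "*"]
  stops <- codons[GENETIC_CODE_TABLE == "*"]
  paste(c("ATG", sample(nonstop, len_nt / 3L - 2L, replace = TRUE),
          sample(stops, 1L)), collapse = "")
}

#' Simulate a reference panel
#'
#' Generates synthetic contigs carrying single-transcript gene models (the
#' stand-in for a targeted panel of cancer genes), with target regions equal
#' to the exon union. CDS sequences start with ATG, contain no internal stop
#' and end with a stop codon; genes may be split over up to three exons and
#' fall on either strand.
#'
#' @param n_genes number of genes (default 20, desk scale).
#' @param gene_length_range CDS length range in nt (rounded to codons).
#' @param seed RNG seed.
#' @param genes_per_contig genes placed per contig (default 5).
#' @param intergenic intergenic/flank size in bp (default 300).
#' @param intron intron size in bp for split genes (default 120).
#' @return list with elements `ref` (named character vector of contigs),
#'   `genes` (list of [gene_model()]), `targets` ([target_regions()]) and
#'   `gene_ids`.
#' @export
simulate_reference <- function(n_genes = 20L,
                               gene_length_range = c(1500, 2400),
                               seed = 1L, genes_per_contig = 5L,
                               intergenic = 300L, intron = 120L) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  n_contigs <- ceiling(n_genes / genes_per_contig)
  contigs <- sprintf("chr%02d", seq_len(n_contigs))
  seqs <- stats::setNames(rep("", n_contigs), contigs)
  genes <- vector("list", n_genes)
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  for (i in seq_len(n_genes)) {
    ctg <- contigs[(i - 1L) %/% genes_per_contig + 1L]
    len <- round(stats::runif(1, gene_length_range[1], gene_length_range[2]))
    len <- max(9L, (len %/% 3L) * 3L)
    cds_seq <- .rand_cds(len)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(1:3, 1L)
    # split the sense CDS into n_ex chunks (translation order)
    cuts <- if (n_ex > 1L) sort(sample(seq_len(len - 1L), n_ex - 1L)) else integer()
    bounds <- c(0L, cuts, len)
    chunks <- substring(cds_seq, bounds[-length(bounds)] + 1L, bounds[-1L])
    # genomic (left-to-right) order of chunks
    gchunks <- if (strand == "-") {
      vapply(rev(chunks), reverse_complement, "")
    } else chunks
    cur <- nchar(seqs[[ctg]])
    pieces <- .rand_dna(intergenic)
    offset <- cur + intergenic
    iv <- matrix(0L, nrow = n_ex, ncol = 2L)
    for (j in seq_len(n_ex)) {
      iv[j, ] <- c(offset, offset + nchar(gchunks[j]))
      pieces <- c(pieces, gchunks[j])
      offset <- offset + nchar(gchunks[j])
      if (j < n_ex) {
        pieces <- c(pieces, .rand_dna(intron))
        offset <- offset + intron
      }
    }
    seqs[[ctg]] <- paste(c(seqs[[ctg]], pieces), collapse = "")
    cds <- data.frame(start = iv[, 1L], end = iv[, 2L])
    genes[[i]] <- gene_model(gene_ids[i], ctg, strand, cds, cds)
  }
  seqs <- vapply(seqs, function(s) paste0(s, .rand_dna(intergenic)), "")
  validate_reference(seqs)
  ex <- do.call(rbind, lapply(genes, function(g) {
    data.frame(contig = g$contig, start = g$exons$start, end = g$exons$end)
  }))
  list(ref = seqs, genes = genes, targets = target_regions(ex),
       gene_ids = gene_ids)
}

# base identity helpers
.BASES <- c("A", "C", "G", "T")

# lookup: for base-column pair (i, j), the remaining two of the four columns
.OTHER1 <- matrix(0L, 4L, 4L)
.OTHER2 <- matrix(0L, 4L, 4L)
for (.i in 1:4) for (.j in 1:4) {
  .rest <- setdiff(1:4, c(.i, .j))
  .OTHER1[.i, .j] <- .rest[1L]
  .OTHER2[.i, .j] <- .rest[if (length(.rest) > 1L) 2L else 1L]
}
rm(.i, .j, .rest)

.ref_base_at <- function(ref, contig, pos) {
  # vectorized single-base lookup
  vapply(seq_along(pos), function(i) {
    substring(ref[[contig[i]]], pos[i] + 1L, pos[i] + 1L)
  }, "")
}

.other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(.BASES, b), 1L), "")
}

#' Simulate a tumor/normal cohort
#'
#' For each sample, per-site read pileups are drawn over every targeted base:
#' depth ~ Poisson(`mean_coverage`) (with a small-probability low-coverage
#' dropout that mechanistically produces germline leak-through in normals),
#' and per-read base identity follows the true allele fraction with uniform
#' base errors at rate 10^(-Q/10). Array genotypes are generated at a
#' designated subset of polymorphic loci with error rate `array_error`.
#' Copy-number segment truth and expression signature labels are drawn here
#' and consumed by [simulate_expression()].
#'
#' @param cfg a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @return list with elements `samples` (data.frame: sample, individual,
#'   type, purity), `pileups` (named list of per-sample pileup data.frames
#'   with columns contig, pos, ref, A, C, G, T, q), `array` (long data.frame
#'   of array genotypes: sample, locus_id, contig, pos, genotype),
#'   `shared_loci` (locus_id, contig, pos, allele_a, allele_b) and `truth`
#'   (class `cohort_truth`).
#' @export
simulate_cohort <- function(cfg, reference) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.child_seed(cfg$seed, 1L))
  ref <- reference$ref
  targets <- reference$targets
  tp <- target_positions(targets)
  span <- nrow(tp)
  tp$ref <- .ref_base_at(ref, tp$contig, tp$pos)
  site_key <- paste(tp$contig, tp$pos)

  n_ind <- cfg$n_pairs + cfg$n_tumor_only
  individuals <- sprintf("I%02d", seq_len(n_ind))
  paired <- individuals[seq_len(cfg$n_pairs)]
  samples <- data.frame(sample = paste0(individuals, "T"),
                        individual = individuals,
                        type = rep("tumor", n_ind),
                        stringsAsFactors = FALSE)
  if (length(paired)) {
    samples <- rbind(samples, data.frame(
      sample = paste0(paired, "N"), individual = paired,
      type = rep("normal", length(paired)), stringsAsFactors = FALSE))
  }
  samples$purity <- ifelse(
    samples$type == "tumor",
    stats::runif(nrow(samples), cfg$purity_range[1], cfg$purity_range[2]),
    NA_real_)

  ## --- polymorphic germline loci ------------------------------------------
  n_poly <- stats::rbinom(1L, span, cfg$germline_rate)
  poly_idx <- sort(sample.int(span, n_poly))
  poly <- tp[poly_idx, c("contig", "pos", "ref")]
  poly$alt <- .other_base(poly$ref)
  poly$maf <- stats::runif(n_poly, cfg$maf_range[1], cfg$maf_range[2])
  poly$in_panel <- stats::runif(n_poly) < cfg$panel_capture_prob
  rownames(poly) <- NULL

  # per-individual dosages at polymorphic loci (HWE)
  dosage <- matrix(stats::rbinom(n_poly * n_ind, 2L,
                                 rep(poly$maf, n_ind)),
                   nrow = n_poly, ncol = n_ind,
                   dimnames = list(NULL, individuals))

  # private novel germline het variants, unique per individual
  taken <- poly_idx
  private <- do.call(rbind, lapply(individuals, function(ind) {
    avail <- setdiff(seq_len(span), taken)
    idx <- sort(sample(avail, cfg$n_private_germline))
    taken <<- c(taken, idx)
    data.frame(individual = rep(ind, length(idx)), contig = tp$contig[idx],
               pos = tp$pos[idx], ref = tp$ref[idx],
               alt = .other_base(tp$ref[idx]),
               dosage = rep(1L, length(idx)), stringsAsFactors = FALSE)
  }))

  germline <- rbind(
    do.call(rbind, lapply(individuals, function(ind) {
      d <- dosage[, ind]
      sel <- d > 0L
      if (!any(sel)) return(NULL)
      data.frame(individual = ind, contig = poly$contig[sel],
                 pos = poly$pos[sel], ref = poly$ref[sel],
                 alt = poly$alt[sel], dosage = d[sel],
                 stringsAsFactors = FALSE)
    })),
    private)

  ## --- somatic events ------------------------------------------------------
  hot_gene <- reference$genes[[1L]]
  hot_pos <- .cds_genomic_positions(hot_gene)
  weight <- rep(1, span)
  weight[site_key %in% paste(hot_gene$contig, hot_pos)] <- cfg$hot_gene_factor
  weight[taken] <- 0  # somatic sets disjoint from germline sets
  tumors <- samples$sample[samples$type == "tumor"]
  purity_of <- stats::setNames(samples$purity, samples$sample)
  eff_span <- sum(weight)
  somatic <- do.call(rbind, lapply(tumors, function(s) {
    n_som <- stats::rpois(1L, cfg$somatic_rate * eff_span)
    n_som <- min(n_som, sum(weight > 0))
    idx <- sample.int(span, n_som, prob = weight)
    clonal <- stats::runif(n_som) >= cfg$subclone_prob
    ccf <- ifelse(clonal, 1, cfg$subclone_ccf)
    damaging <- stats::runif(n_som) < cfg$damaging_prob
    data.frame(sample = rep(s, n_som), contig = tp$contig[idx],
               pos = tp$pos[idx],
               ref = tp$ref[idx], alt = .other_base(tp$ref[idx]),
               clonal = clonal,
               vaf = purity_of[[s]] * ccf * 0.5,
               damaging = damaging,
               score = ifelse(damaging, stats::runif(n_som, 0, 0.05),
                              stats::runif(n_som, 0.05, 1)),
               stringsAsFactors = FALSE)
  }))
  rownames(somatic) <- NULL
  # a deleteriousness prediction is a property of the substitution, not of
  # the sample: recurrent variants share one score
  vkey <- paste(somatic$contig, somatic$pos, somatic$alt)
  first <- match(vkey, vkey)
  somatic$damaging <- somatic$damaging[first]
  somatic$score <- somatic$score[first]
  somatic <- annotate_variants(ref, reference$genes, somatic)

  ## --- pileups -------------------------------------------------------------
  e <- 10^(-cfg$base_error_phred / 10)
  germ_by_ind <- split(germline, germline$individual)
  som_by_sample <- split(somatic, somatic$sample)
  pileups <- stats::setNames(vector("list", nrow(samples)), samples$sample)
  for (i in seq_len(nrow(samples))) {
    s <- samples$sample[i]
    ind <- samples$individual[i]
    f <- rep(0, span)           # alt fraction per site
    altbase <- rep(NA_character_, span)
    g <- germ_by_ind[[ind]]
    if (!is.null(g)) {
      gi <- match(paste(g$contig, g$pos), site_key)
      f[gi] <- ifelse(g$dosage == 2L, 1, 0.5)
      altbase[gi] <- g$alt
    }
    if (samples$type[i] == "tumor") {
      sm <- som_by_sample[[s]]
      if (!is.null(sm) && nrow(sm)) {
        si <- match(paste(sm$contig, sm$pos), site_key)
        f[si] <- sm$vaf
        altbase[si] <- sm$alt
      }
    }
    low <- stats::runif(span) < cfg$low_depth_prob
    depth <- ifelse(low, stats::rpois(span, cfg$low_depth_mean),
                    stats::rpois(span, cfg$mean_coverage))
    p_alt <- f * (1 - e) + (1 - f) * e / 3
    n_alt <- stats::rbinom(span, depth, p_alt)
    rest <- depth - n_alt
    p_oth <- (2 * e / 3) / pmax(1 - p_alt, 1e-12)
    n_oth <- stats::rbinom(span, rest, pmin(p_oth, 1))
    n_o1 <- stats::rbinom(span, n_oth, 0.5)
    counts <- matrix(0L, nrow = span, ncol = 4L,
                     dimnames = list(NULL, .BASES))
    ref_col <- match(tp$ref, .BASES)
    alt_col <- match(altbase, .BASES)
    alt_col[is.na(alt_col)] <- ((ref_col[is.na(alt_col)]) %% 4L) + 1L
    # the two "other" error bases: the remaining two of the four
    oth <- cbind(.OTHER1[cbind(ref_col, alt_col)],
                 .OTHER2[cbind(ref_col, alt_col)])
    idx <- cbind(seq_len(span), ref_col)
    counts[idx] <- rest - n_oth
    counts[cbind(seq_len(span), alt_col)] <-
      counts[cbind(seq_len(span), alt_col)] + n_alt
    counts[cbind(seq_len(span), oth[, 1L])] <-
      counts[cbind(seq_len(span), oth[, 1L])] + n_o1
    counts[cbind(seq_len(span), oth[, 2L])] <-
      counts[cbind(seq_len(span), oth[, 2L])] + (n_oth - n_o1)
    pileups[[s]] <- data.frame(
      contig = tp$contig, pos = tp$pos, ref = tp$ref,
      A = counts[, "A"], C = counts[, "C"],
      G = counts[, "G"], T = counts[, "T"],
      q = cfg$base_error_phred, stringsAsFactors = FALSE)
  }

  ## --- array genotypes at shared loci --------------------------------------
  n_arr <- min(cfg$n_array_loci, n_poly)
  arr_sel <- sort(sample.int(n_poly, n_arr))
  shared_loci <- data.frame(
    locus_id = sprintf("L%04d", seq_len(n_arr)),
    contig = poly$contig[arr_sel], pos = poly$pos[arr_sel],
    allele_a = poly$ref[arr_sel], allele_b = poly$alt[arr_sel],
    stringsAsFactors = FALSE)
  gts <- c("AA", "AB", "BB")
  array <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    d <- dosage[arr_sel, samples$individual[i]]
    g <- gts[d + 1L]
    err <- stats::runif(n_arr) < cfg$array_error
    g[err] <- vapply(g[err], function(x) sample(setdiff(gts, x), 1L), "")
    g[stats::runif(n_arr) < cfg$array_nocall] <- "NoCall"
    data.frame(sample = rep(samples$sample[i], n_arr),
               locus_id = shared_loci$locus_id,
               contig = shared_loci$contig, pos = shared_loci$pos,
               genotype = g, stringsAsFactors = FALSE)
  }))

  ## --- copy-number truth and signature labels ------------------------------
  cn <- .simulate_cn_truth(cfg, reference)
  n_tum <- length(tumors)
  labels <- data.frame(
    sample = tumors,
    wnt_high = stats::runif(n_tum) < 0.5,
    hh_high = stats::runif(n_tum) < 0.4,
    stringsAsFactors = FALSE)
  gene_ids <- reference$gene_ids
  pool <- setdiff(gene_ids, gene_ids[1L])   # keep the hot gene out of sets
  copa_gene <- if (length(pool)) sample(pool, 1L) else NA_character_
  pool <- setdiff(pool, copa_gene)
  wnt_set <- sample(pool, min(6L, length(pool)))
  pool <- setdiff(pool, wnt_set)
  hh_set <- sample(pool, min(4L, length(pool)))
  copa_samples <- sample(tumors, max(1L, round(cfg$copa_tumor_frac * n_tum)))

  truth <- structure(list(
    samples = samples, germline = germline, somatic = somatic,
    panel = poly, private = private,
    cn_segments = cn$segments, cn_probes = cn$probes,
    cn_gene_log2 = cn$gene_log2,
    labels = labels, gene_sets = list(wnt = wnt_set, hedgehog = hh_set),
    copa_gene = copa_gene, copa_samples = copa_samples,
    hot_gene = hot_gene$gene_id,
    config = cfg), class = "cohort_truth")

  list(samples = samples, pileups = pileups, array = array,
       shared_loci = shared_loci, truth = truth)
}

# true copy-number segments per tumor on a regular probe grid
.simulate_cn_truth <- function(cfg, reference) {
  contig_len <- vapply(reference$ref, nchar, 0L)
  probes <- do.call(rbind, lapply(names(contig_len), function(ctg) {
    data.frame(contig = ctg,
               pos = seq.int(0L, contig_len[[ctg]] - 1L,
                             by = cfg$cn_probe_spacing),
               stringsAsFactors = FALSE)
  }))
  probes$probe_id <- sprintf("P%04d", seq_len(nrow(probes)))
  n_probe <- nrow(probes)
  tumors <- paste0(sprintf("I%02d", seq_len(cfg$n_pairs + cfg$n_tumor_only)), "T")
  seg_list <- list()
  truth_log2 <- matrix(0, nrow = n_probe, ncol = length(tumors),
                       dimnames = list(probes$probe_id, tumors))
  for (s in tumors) {
    used <- rep(FALSE, n_probe)
    for (k in seq_len(cfg$cnv_segments_per_sample)) {
      len <- sample(5:30, 1L)
      if (n_probe <= len) next
      start <- sample.int(n_probe - len, 1L)
      idx <- start:(start + len - 1L)
      same_ctg <- probes$contig[idx] == probes$contig[idx[1L]]
      idx <- idx[same_ctg]
      if (any(used[idx]) || length(idx) < 3L) next
      used[idx] <- TRUE
      lr <- sample(c(-1, 1), 1L) * stats::runif(1, 0.7, 1.2)
      truth_log2[idx, s] <- lr
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        sample = s, contig = probes$contig[idx[1L]],
        start = probes$pos[idx[1L]],
        end = probes$pos[idx[length(idx)]] + cfg$cn_probe_spacing,
        log2 = lr, n_probes = length(idx), stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(sample = character(), contig = character(),
               start = integer(), end = integer(),
               log2 = numeric(), n_probes = integer())
  # gene-level true log2: mean of probes overlapping the gene span
  gene_log2 <- do.call(rbind, lapply(reference$genes, function(g) {
    lo <- min(g$exons$start); hi <- max(g$exons$end)
    sel <- probes$contig == g$contig & probes$pos >= lo & probes$pos < hi
    if (!any(sel)) rep(0, length(tumors)) else
      colMeans(truth_log2[sel, , drop = FALSE])
  }))
  rownames(gene_log2) <- reference$gene_ids
  list(segments = segments,
       probes = cbind(probes, as.data.frame(truth_log2)),
       gene_log2 = gene_log2)
}

#' Simulate expression, copy-number probe and qPCR data
#'
#' Gene expression couples to true copy number through `cn_expr_slope`,
#' signature gene sets are shifted in signature-high tumors, and one
#' implanted outlier gene is highly expressed in a minority of tumors while
#' near-absent in normals (the classic outlier-profile pattern). qPCR CT
#' values are generated so the abundance transform inverts exactly to the
#' recorded truth; a per-sample global shift (shared by housekeepers and
#' targets) emulates input/efficiency variation that housekeeper adjustment
#' removes.
#'
#' @param cfg a [sim_config()].
#' @param reference output of [simulate_reference()].
#' @param truth `cohort_truth` from [simulate_cohort()].
#' @return list with `expr` (genes x samples linear-intensity matrix),
#'   `classes` (named vector, tumor/normal per sample), `cn` (probes x
#'   samples observed log2 matrix), `cn_probes` (probe_id, contig, pos),
#'   `ct` (samples x assays CT matrix), `ct_truth` (true log10 abundances),
#'   `housekeepers` (assay names).
#' @export
simulate_expression <- function(cfg, reference, truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (is.null(truth$cn_segments)) stop("truth lacks CN segments")
  set.seed(.child_seed(cfg$seed, 2L))
  samples <- truth$samples
  gene_ids <- reference$gene_ids
  tumors <- samples$sample[samples$type == "tumor"]
  normals <- samples$sample[samples$type == "normal"]
  all_s <- c(tumors, normals)
  classes <- stats::setNames(
    ifelse(all_s %in% tumors, "tumor", "normal"), all_s)

  baseline <- stats::setNames(stats::rnorm(length(gene_ids), 7, 1), gene_ids)
  if (!is.na(truth$copa_gene)) baseline[truth$copa_gene] <- 4
  log2e <- matrix(rep(baseline, length(all_s)),
                  nrow = length(gene_ids), ncol = length(all_s),
                  dimnames = list(gene_ids, all_s))
  # copy-number coupling (tumors only)
  log2e[, tumors] <- log2e[, tumors] +
    cfg$cn_expr_slope * truth$cn_gene_log2[gene_ids, tumors]
  # signature effects
  for (set_name in names(truth$gene_sets)) {
    set_genes <- truth$gene_sets[[set_name]]
    col <- if (set_name == "wnt") "wnt_high" else "hh_high"
    high <- truth$labels$sample[truth$labels[[col]]]
    log2e[set_genes, high] <- log2e[set_genes, high] + cfg$signature_effect
  }
  # implanted outlier gene
  if (!is.na(truth$copa_gene)) {
    log2e[truth$copa_gene, truth$copa_samples] <-
      log2e[truth$copa_gene, truth$copa_samples] + cfg$copa_effect
  }
  log2e <- log2e + matrix(stats::rnorm(length(log2e), 0, cfg$expr_noise_sd),
                          nrow = nrow(log2e))
  # transcriptome background probes (measured by the array, outside the
  # sequencing panel)
  if (cfg$n_background_genes > 0L) {
    bg_ids <- sprintf("BG%03d", seq_len(cfg$n_background_genes))
    bg_base <- stats::rnorm(cfg$n_background_genes, 7, 1.5)
    bg <- matrix(bg_base, cfg$n_background_genes, length(all_s)) +
      matrix(stats::rnorm(cfg$n_background_genes * length(all_s), 0,
                          cfg$expr_noise_sd),
             nrow = cfg$n_background_genes)
    dimnames(bg) <- list(bg_ids, all_s)
    log2e <- rbind(log2e, bg)
  }
  expr <- 2^log2e   # linear intensities

  # observed CN probe matrix: truth plus noise; normals diploid
  pr <- truth$cn_probes
  probe_meta <- pr[, c("probe_id", "contig", "pos")]
  cn_true <- as.matrix(pr[, tumors, drop = FALSE])
  cn <- cbind(cn_true, matrix(0, nrow(cn_true), length(normals),
                              dimnames = list(NULL, normals)))
  cn <- cn + matrix(stats::rnorm(length(cn), 0, cfg$cnv_log2_sd),
                    nrow = nrow(cn))
  rownames(cn) <- probe_meta$probe_id

  # qPCR: housekeepers + a handful of target assays
  housekeepers <- c("GAPDH", "ACTB")
  targets <- unique(c(utils::head(setdiff(gene_ids, truth$copa_gene), 4L),
                      if (!is.na(truth$copa_gene)) truth$copa_gene))
  assays <- c(housekeepers, targets)
  shift <- stats::rnorm(length(all_s), 0, cfg$qpcr_shift_sd)
  base_ab <- c(GAPDH = 3.0, ACTB = 2.8,
               stats::setNames(stats::rnorm(length(targets), 2, 0.5), targets))
  ct_truth <- outer(rep(1, length(all_s)), base_ab)
  rownames(ct_truth) <- all_s
  # target abundances track the expression matrix (scaled to log10)
  ct_truth[, targets] <- t(log2e[targets, all_s]) * log10(2) - 1
  obs <- ct_truth + shift +
    matrix(stats::rnorm(length(ct_truth), 0, cfg$qpcr_noise_sd),
           nrow = nrow(ct_truth))
  # the instrument reports CT in [0, 40]; clamp the observed abundance so
  # the CT <-> abundance transform stays exactly invertible
  obs[] <- pmin(pmax(obs, 0), 40 / 3.5)
  ct <- 40 - 3.5 * obs

  list(expr = expr, classes = classes, cn = cn, cn_probes = probe_meta,
       ct = ct, ct_truth = obs, housekeepers = housekeepers)
}

#' Classify called somatic variants as a Sanger re-test would
#'
#' Each called variant is looked up in the simulator truth: a true somatic
#' event with VAF at or above the Sanger sensitivity limit is
#' `confirmed_somatic`; a variant that is germline for that individual is
#' `germline`; a true somatic event below the limit -- or a call at a site
#' that carries no variant in truth -- is `absent` (nothing for Sanger to
#' see).
#'
#' @param truth `cohort_truth` from [simulate_cohort()].
#' @param called data.frame of called somatic variants with columns
#'   `sample`, `contig`, `pos`, `alt`.
#' @param sanger_vaf_limit VAF detection limit of the re-test (default 0.20).
#' @return `called` with an added `outcome` column
#'   (`confirmed_somatic` / `germline` / `absent`).
#' @export
simulate_sanger_retest <- function(truth, called,
                                   sanger_vaf_limit = 0.20) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!nrow(called)) {
    called$outcome <- character(0)
    return(called)
  }
  ind_of <- stats::setNames(truth$samples$individual, truth$samples$sample)
  if (any(is.na(ind_of[called$sample]))) {
    stop("called set contains unknown sample(s)")
  }
  som_key <- with(truth$somatic, paste(sample, contig, pos, alt))
  germ_key <- with(truth$germline, paste(individual, contig, pos, alt))
  key_som <- with(called, paste(sample, contig, pos, alt))
  key_germ <- paste(ind_of[called$sample], called$contig, called$pos,
                    called$alt)
  mi <- match(key_som, som_key)
  outcome <- rep("absent", nrow(called))
  is_som <- !is.na(mi)
  outcome[is_som] <- ifelse(
    truth$somatic$vaf[mi[is_som]] >= sanger_vaf_limit,
    "confirmed_somatic", "absent")
  outcome[!is_som & key_germ %in% germ_key] <- "germline"
  called$outcome <- outcome
  called
}
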