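# Somatic filter cascade, deleteriousness-rate statistic, cohort
# frequencies and Sanger-validation accounting.
#
# A variant is accepted as somatic when it passes the calling-quality
# thresholds in the tumor, is absent from every normal sample's variant
# calls (not just the matched normal), and is absent from the known
# polymorphism panel. Matching is by position AND alternate allele.

#' Subtract germline evidence from tumor variant calls
#'
#' Removes every tumor variant whose (contig, pos, alt) appears in any
#' normal sample's variant calls or in the known-polymorphism panel, then
#' annotates the remainder (gene, consequence, amino-acid change) and
#' attaches deleteriousness scores where provided. Tumor-only samples flow
#' through the same cohort-wide subtraction.
#'
#' @param tumor_variants data.frame of threshold-passing tumor variant
#'   records (`sample`, `contig`, `pos`, `ref`, `alt`, ...), e.g. from
#'   [calls_to_variants()] after [filter_calls()].
#' @param normal_variants variant records pooled over all normal samples
#'   (only `contig`, `pos`, `alt` are used).
#' @param panel known polymorphism panel data.frame (`contig`, `pos`,
#'   `alt`).
#' @param reference reference list (`ref`, `genes`) used for consequence
#'   annotation, or `NULL` to skip annotation.
#' @param scores optional data.frame (`contig`, `pos`, `alt`, `score`)
#'   of deleteriousness predictions in [0, 1]; unmatched variants get `NA`.
#' @return data.frame of somatic variants with added columns `gene_id`,
#'   `consequence`, `aa_change` (if annotated) and `score`.
#' @export
subtract_germline <- function(tumor_variants, normal_variants, panel,
                              reference = NULL, scores = NULL) {
  key <- function(d) paste(d$contig, d$pos, d$alt)
  germ_keys <- unique(c(if (nrow(normal_variants)) key(normal_variants),
                        if (nrow(panel)) key(panel)))
  out <- tumor_variants[!(key(tumor_variants) %in% germ_keys), ,
                        drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(reference) && nrow(out)) {
    out <- annotate_variants(reference$ref, reference$genes, out)
  }
  if (!is.null(scores)) {
    out$score <- scores$score[match(key(out), key(scores))]
  } else if (!"score" %in% names(out)) {
    out$score <- NA_real_
  }
  out
}

#' Somatic filter-cascade counts
#'
#' Three nested counts over per-(sample, site) somatic events: all somatic
#' variants, the exonic nonsynonymous subset (stop gains/losses included),
#' and the deleterious subset (score below `cutoff`).
#'
#' @param variants somatic variant data.frame with columns `consequence`
#'   and `score`.
#' @param cutoff deleteriousness cutoff (default 0.05; scores below it are
#'   conventionally called damaging).
#' @return named integer vector: `total_somatic`, `exonic_nonsynonymous`,
#'   `deleterious`.
#' @export
count_cascade <- function(variants, cutoff = 0.05) {
  nonsyn <- .is_nonsyn(variants$consequence)
  del <- nonsyn & !is.na(variants$score) & variants$score < cutoff
  c(total_somatic = nrow(variants),
    exonic_nonsynonymous = sum(nonsyn),
    deleterious = sum(del))
}

# stop gains/losses count as nonsynonymous for cascade counts and rates
.is_nonsyn <- function(consequence) {
  consequence %in% c("nonsynonymous", "stop_gained", "stop_lost")
}

#' Per-gene deleterious mutation rate
#'
#' Number of nonsynonymous somatic mutations with deleteriousness score
#' below `cutoff`, divided by the CDS length of the gene in amino acids --
#' the length-corrected concentration of damaging mutations. Variants with
#' missing scores are excluded from the numerator and reported separately.
#'
#' @param gene a [gene_model()].
#' @param variants somatic variants of this gene (columns `consequence`,
#'   `score`).
#' @param cutoff deleteriousness cutoff (default 0.05).
#' @return list with `rate` (per amino acid), `n_deleterious`,
#'   `n_unscored`, `aa_length`.
#' @export
deleterious_rate <- function(gene, variants, cutoff = 0.05) {
  aa <- cds_aa_length(gene)
  nonsyn <- .is_nonsyn(variants$consequence)
  unscored <- nonsyn & is.na(variants$score)
  qualifying <- nonsyn & !is.na(variants$score) & variants$score < cutoff
  list(rate = sum(qualifying) / aa,
       n_deleterious = sum(qualifying),
       n_unscored = sum(unscored),
       aa_length = aa)
}

#' Rank genes by deleterious mutation rate
#'
#' @param genes list of [gene_model()] objects.
#' @param variants somatic variant data.frame with a `gene_id` column.
#' @param cutoff deleteriousness cutoff (default 0.05).
#' @return data.frame sorted by decreasing rate (ties broken by gene id):
#'   `gene_id`, `rate`, `n_deleterious`, `n_unscored`, `aa_length`.
#' @export
ranked_rates <- function(genes, variants, cutoff = 0.05) {
  rows <- lapply(genes, function(g) {
    v <- variants[!is.na(variants$gene_id) &
                    variants$gene_id == g$gene_id, , drop = FALSE]
    r <- deleterious_rate(g, v, cutoff)
    data.frame(gene_id = g$gene_id, rate = r$rate,
               n_deleterious = r$n_deleterious,
               n_unscored = r$n_unscored, aa_length = r$aa_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rate, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# integer percent, rounding halves away from zero (16/68 -> 24, 2/68 -> 3)
.pct <- function(num, den) {
  x <- 100 * num / den
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Cohort mutation frequency as an integer percentage
#'
#' @param n_mutated_samples number of samples carrying the event.
#' @param n_samples cohort size.
#' @return integer percent, halves rounded away from zero.
#' @export
cohort_frequency <- function(n_mutated_samples, n_samples) {
  stopifnot(n_samples >= 1L, n_mutated_samples >= 0L,
            n_mutated_samples <= n_samples)
  .pct(n_mutated_samples, n_samples)
}

#' Summarize Sanger re-test outcomes
#'
#' Accounts for attempted confirmations of called somatic variants:
#' confirmed somatic, germline (present in both tumor and normal by
#' re-test), or absent (seen in neither -- artifact or a subclonal event
#' below re-test sensitivity). Percentages are integer, halves away from
#' zero, with confirmed derived as attempted minus germline minus absent.
#'
#' @param records data.frame with an `outcome` column over
#'   `confirmed_somatic` / `germline` / `absent`.
#' @return list: `n_attempted`, `n_confirmed`, `n_germline`, `n_absent`,
#'   `pct_confirmed`, `pct_germline`, `pct_absent`.
#' @export
validation_summary <- function(records) {
  if (!nrow(records)) stop("no validation records: summary undefined")
  stopifnot(all(records$outcome %in%
                  c("confirmed_somatic", "germline", "absent")))
  n <- nrow(records)
  ng <- sum(records$outcome == "germline")
  na_ <- sum(records$outcome == "absent")
  nc <- n - ng - na_
  list(n_attempted = n, n_confirmed = nc, n_germline = ng, n_absent = na_,
       pct_confirmed = .pct(nc, n), pct_germline = .pct(ng, n),
       pct_absent = .pct(na_, n))
}
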