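# Calibration of sequencing genotype calls against orthogonal SNP-array
# genotypes: concordance, threshold grids, threshold selection, stratified
# false-positive rates and sample-mislabel screening.

# Map a sequencing genotype (two bases, e.g. "AC") into array {AA,AB,BB}
# space through the locus allele pair; any base outside the pair maps to
# "XX" and counts as discordant.
.to_ab <- function(genotype, allele_a, allele_b) {
  b1 <- substring(genotype, 1L, 1L)
  b2 <- substring(genotype, 2L, 2L)
  m1 <- ifelse(b1 == allele_a, "A", ifelse(b1 == allele_b, "B", "X"))
  m2 <- ifelse(b2 == allele_a, "A", ifelse(b2 == allele_b, "B", "X"))
  out <- paste0(pmin(m1, m2), pmax(m1, m2))
  ifelse(grepl("X", out, fixed = TRUE), "XX", out)
}

# Join sequencing calls with array genotypes at the shared loci.
# Returns one row per (sample, locus) present on both platforms
# (array NoCall and missing sequencing calls are excluded).
.shared_comparisons <- function(calls, array, shared) {
  key <- function(ctg, pos) paste(ctg, pos)
  li <- match(key(calls$contig, calls$pos), key(shared$contig, shared$pos))
  calls <- calls[!is.na(li), , drop = FALSE]
  li <- li[!is.na(li)]
  calls$locus_id <- shared$locus_id[li]
  calls$seq_ab <- .to_ab(calls$genotype, shared$allele_a[li],
                         shared$allele_b[li])
  arr <- array[array$genotype != "NoCall", c("sample", "locus_id", "genotype")]
  names(arr)[3L] <- "array_ab"
  out <- merge(calls, arr, by = c("sample", "locus_id"))
  out$match <- out$seq_ab == out$array_ab
  out
}

#' Sequencing/array genotype concordance
#'
#' @param calls data.frame of sequencing calls (`sample`, `contig`, `pos`,
#'   `ref`, `genotype`, `cq`, `vq`, `depth`), typically all calls at the
#'   shared loci.
#' @param array data.frame of array genotypes (`sample`, `locus_id`,
#'   `genotype` in AA/AB/BB/NoCall).
#' @param shared shared-locus table (`locus_id`, `contig`, `pos`,
#'   `allele_a`, `allele_b`).
#' @return list with `overall` (pooled fraction of matching genotypes),
#'   `n` (number of comparisons), and `per_sample` (data.frame: sample,
#'   concordance, n). An empty comparable set yields `NA` concordance.
#' @export
concordance <- function(calls, array, shared) {
  cmp <- .shared_comparisons(calls, array, shared)
  if (!nrow(cmp)) {
    return(list(overall = NA_real_, n = 0L,
                per_sample = data.frame(sample = character(),
                                        concordance = numeric(),
                                        n = integer())))
  }
  per <- stats::aggregate(match ~ sample, data = cmp,
                          FUN = function(x) mean(x))
  names(per)[2L] <- "concordance"
  per$n <- as.integer(table(cmp$sample)[per$sample])
  list(overall = mean(cmp$match), n = nrow(cmp), per_sample = per)
}

# retention rule: a call survives thresholds (cq_cut, vq_cut, depth_cut) if
# cq >= cq_cut, depth >= depth_cut, and -- for non-reference genotypes --
# vq > vq_cut. Hom-ref calls carry vq = 0 by construction and are not
# subject to the variant-quality threshold.
.retained <- function(cmp, cq_cut, vq_cut, depth_cut) {
  hom_ref <- cmp$genotype == paste0(cmp$ref, cmp$ref)
  cmp$cq >= cq_cut & cmp$depth >= depth_cut & (hom_ref | cmp$vq > vq_cut)
}

#' Apply quality thresholds to genotype calls
#'
#' @param calls data.frame of calls.
#' @param cq_cut consensus-quality threshold (retain `cq >= cq_cut`).
#' @param vq_cut variant-quality threshold applied to non-reference calls
#'   (retain `vq > vq_cut`; hom-ref calls are exempt).
#' @param depth_cut depth threshold (retain `depth >= depth_cut`).
#' @return the retained subset of `calls`.
#' @export
filter_calls <- function(calls, cq_cut = 50, vq_cut = 0, depth_cut = 0) {
  calls[.retained(calls, cq_cut, vq_cut, depth_cut), , drop = FALSE]
}

#' Tabulate concordance over a threshold grid
#'
#' One row per (cq, vq, depth) cutoff combination: number of retained
#' comparable calls, number concordant with the array, and the concordance
#' fraction (NA when nothing is retained).
#'
#' @inheritParams concordance
#' @param cq_grid,vq_grid,depth_grid numeric vectors of cutoffs.
#' @return data.frame of class `concordance_grid` with columns `cq_cutoff`,
#'   `vq_cutoff`, `depth_cutoff`, `n_calls_retained`, `n_concordant`,
#'   `concordance`.
#' @export
tabulate_grid <- function(calls, array, shared,
                          cq_grid = c(0, 20, 30, 40, 50, 60),
                          vq_grid = c(0, 10, 20),
                          depth_grid = c(0, 8, 20)) {
  stopifnot(length(cq_grid) >= 1L, length(vq_grid) >= 1L,
            length(depth_grid) >= 1L)
  cmp <- .shared_comparisons(calls, array, shared)
  grid <- expand.grid(cq_cutoff = cq_grid, vq_cutoff = vq_grid,
                      depth_cutoff = depth_grid, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    keep <- .retained(cmp, grid$cq_cutoff[i], grid$vq_cutoff[i],
                      grid$depth_cutoff[i])
    n <- sum(keep)
    nc <- sum(cmp$match[keep])
    data.frame(n_calls_retained = as.integer(n),
               n_concordant = as.integer(nc),
               concordance = if (n > 0L) nc / n else NA_real_)
  })
  out <- cbind(grid, do.call(rbind, res))
  class(out) <- c("concordance_grid", "data.frame")
  out
}

#' Select calling thresholds from a concordance grid
#'
#' Among grid rows retaining at least `min_retained_fraction` of the
#' maximum retained-call count (a hard retention floor standing in for
#' "minimize false negatives"), picks the cutoffs maximizing concordance;
#' ties are broken toward more retained calls, then lower cutoffs.
#'
#' @param grid a `concordance_grid` from [tabulate_grid()].
#' @param min_retained_fraction retention floor relative to the
#'   best-populated row (default 0.85, accepting the loss of roughly 10-15%
#'   of shared genotypes for a concordance gain).
#' @return the selected grid row (one-row data.frame), or `NULL` (with a
#'   warning) when no row meets the retention floor.
#' @export
select_thresholds <- function(grid, min_retained_fraction = 0.85) {
  stopifnot(nrow(grid) >= 1L)
  floor_n <- min_retained_fraction * max(grid$n_calls_retained)
  cand <- grid[grid$n_calls_retained >= floor_n &
                 !is.na(grid$concordance), , drop = FALSE]
  if (!nrow(cand)) {
    warning("no threshold combination meets the retention floor")
    return(NULL)
  }
  ord <- order(-cand$concordance, -cand$n_calls_retained,
               cand$cq_cutoff, cand$vq_cutoff, cand$depth_cutoff)
  out <- cand[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' False-positive rate stratified by array genotype class
#'
#' Discordance with the array computed separately for loci the array calls
#' homozygous for allele A (the reference allele of the shared-locus table)
#' and loci carrying the variant allele (AB or BB).
#'
#' @inheritParams concordance
#' @return list with `fpr_ref`, `fpr_variant` (NA for an empty stratum),
#'   and the stratum sizes `n_ref`, `n_variant`.
#' @export
stratified_fpr <- function(calls, array, shared) {
  cmp <- .shared_comparisons(calls, array, shared)
  is_ref <- cmp$array_ab == "AA"
  rate <- function(sel) {
    if (!any(sel)) NA_real_ else mean(!cmp$match[sel])
  }
  list(fpr_ref = rate(is_ref), fpr_variant = rate(!is_ref),
       n_ref = sum(is_ref), n_variant = sum(!is_ref))
}

#' Pairwise genotype-concordance matrix
#'
#' Fraction of loci with identical genotypes for every pair of samples,
#' over loci where both samples have a genotype. Used for sample-mislabel
#' screening: matched tumor/normal pairs share their germline and score far
#' above unrelated pairs.
#'
#' @param genotypes long data.frame with columns `sample`, a locus key
#'   (`locus_id`, or `contig` + `pos`), and `genotype`.
#' @return square numeric matrix (samples x samples); diagonal 1.
#' @export
concordance_matrix <- function(genotypes) {
  key <- if ("locus_id" %in% names(genotypes)) genotypes$locus_id else
    paste(genotypes$contig, genotypes$pos)
  samples <- sort(unique(genotypes$sample))
  loci <- sort(unique(key))
  wide <- matrix(NA_character_, length(loci), length(samples),
                 dimnames = list(loci, samples))
  wide[cbind(match(key, loci), match(genotypes$sample, samples))] <-
    genotypes$genotype
  n <- length(samples)
  out <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(out) <- 1
  for (i in seq_len(n - 1L)) {
    gi <- wide[, i]
    for (j in (i + 1L):n) {
      both <- !is.na(gi) & !is.na(wide[, j])
      out[i, j] <- out[j, i] <-
        if (any(both)) mean(gi[both] == wide[, j][both]) else NA_real_
    }
  }
  out
}

#' Screen expected tumor/normal pairs for sample mislabelling
#'
#' Each expected pair's concordance is compared with the background of
#' unrelated tumor/normal combinations; a pair is flagged when its
#' concordance falls below `median(unrelated) + margin_mads * MAD(unrelated)`
#' -- a matched pair should sit far above the unrelated background, so a
#' pair that looks unrelated indicates a swap or mislabel.
#'
#' @param genotypes long genotype data.frame (see [concordance_matrix()]).
#' @param pairs data.frame with columns `tumor`, `normal` naming the
#'   expected pairs.
#' @param margin_mads robust margin in MAD units (default 4).
#' @return data.frame: tumor, normal, concordance, threshold, flagged; the
#'   full concordance matrix is attached as attribute `"matrix"`.
#' @export
mislabel_check <- function(genotypes, pairs, margin_mads = 4) {
  m <- concordance_matrix(genotypes)
  stopifnot(all(pairs$tumor %in% rownames(m)),
            all(pairs$normal %in% rownames(m)))
  if (nrow(m) < 2L) stop("need at least 2 samples")
  pair_conc <- m[cbind(pairs$tumor, pairs$normal)]
  # unrelated background: tumor x normal combos that are not expected pairs
  tumors <- unique(pairs$tumor)
  normals <- unique(pairs$normal)
  bg <- m[tumors, normals, drop = FALSE]
  bg[cbind(pairs$tumor, pairs$normal)] <- NA
  bg <- bg[!is.na(bg)]
  thr <- stats::median(bg) + margin_mads * stats::mad(bg)
  out <- data.frame(tumor = pairs$tumor, normal = pairs$normal,
                    concordance = pair_conc, threshold = thr,
                    flagged = pair_conc < thr, stringsAsFactors = FALSE)
  attr(out, "matrix") <- m
  out
}
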