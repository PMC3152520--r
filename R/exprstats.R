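# Expression-matrix statistics: present-call filtering, quantile
# normalization, gene-set z-score signature scoring, cancer outlier profile
# analysis (COPA) and qPCR abundance conversion with housekeeper covariate
# adjustment.

#' Present-call filter
#'
#' A gene (probe set) is retained if its maximum intensity over samples is
#' strictly more than two standard deviations above background in at least
#' one sample.
#'
#' @param m genes x samples matrix of non-negative intensities.
#' @param background_mean,background_sd background distribution parameters.
#' @param n_sd number of standard deviations defining a present call
#'   (default 2).
#' @return character vector of retained gene (row) names.
#' @export
present_filter <- function(m, background_mean, background_sd, n_sd = 2) {
  thr <- background_mean + n_sd * background_sd
  rownames(m)[apply(m, 1L, max) > thr]
}

#' Log2 transform and quantile-normalize an expression matrix
#'
#' Intensities are shifted by +1 before the base-2 logarithm (to admit
#' zeros) and quantile-normalized so every column shares the same empirical
#' distribution (row-wise means of the sorted columns); ties receive the
#' mean over their rank range.
#'
#' @param m genes x samples matrix of non-negative intensities, or log2
#'   values if `log2_input = TRUE`.
#' @param log2_input is `m` already on the log2 scale? (default `FALSE`).
#' @return quantile-normalized log2 matrix with the input dimnames.
#' @export
quantile_normalize <- function(m, log2_input = FALSE) {
  if (!log2_input) {
    if (any(m < 0)) stop("negative intensities in a linear-scale matrix")
    m <- log2(m + 1)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Gene-set z-score signature scoring
#'
#' Each gene is z-scored across all samples; a sample's signature score is
#' the mean z over the set genes, and samples are ordered by score (the
#' heatmap column-order analogue, high scores last). Constant genes have no
#' z-score and are excluded with a message.
#'
#' @param m genes x samples expression matrix (normalized log2 scale).
#' @param gene_set character vector of gene ids.
#' @return list with `scores` (data.frame: sample, score, in ascending
#'   score order), `z` (set-genes x samples z matrix) and `excluded`
#'   (constant or absent set genes).
#' @export
zscore_signature <- function(m, gene_set) {
  present <- intersect(gene_set, rownames(m))
  absent <- setdiff(gene_set, present)
  sub <- m[present, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  constant <- present[sds == 0 | is.na(sds)]
  keep <- setdiff(present, constant)
  if (!length(keep)) stop("no scorable gene in the set")
  excluded <- c(absent, constant)
  if (length(excluded)) {
    message("zscore_signature: excluded ", length(excluded),
            " absent/constant gene(s)")
  }
  sub <- m[keep, , drop = FALSE]
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  score <- colMeans(z)
  scores <- data.frame(sample = names(score)[order(score)],
                       score = sort(score), stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  list(scores = scores, z = z, excluded = excluded)
}

#' Cancer outlier profile analysis (COPA)
#'
#' Each gene is median-centered and MAD-scaled over all samples; the COPA
#' score is the `r`-th percentile of the transformed values among tumor
#' samples. Genes highly expressed in only a minority of tumors -- too few
#' to move a mean -- rank at the top. Genes with zero MAD are excluded.
#'
#' @param m genes x samples expression matrix (normalized scale).
#' @param classes named character vector over `colnames(m)`:
#'   `"tumor"` / `"normal"`.
#' @param r percentile of the outlier statistic (default 90).
#' @return list with `ranking` (data.frame: gene_id, copa_score, rank;
#'   descending score, ties by gene id) and `excluded` (zero-MAD genes).
#' @export
copa <- function(m, classes, r = 90) {
  stopifnot(r > 0, r < 100)
  tumors <- names(classes)[classes == "tumor"]
  tumors <- intersect(tumors, colnames(m))
  if (!length(tumors)) stop("no tumor samples in matrix")
  med <- apply(m, 1L, stats::median)
  mads <- apply(m, 1L, stats::mad)
  keep <- mads > 0
  excluded <- rownames(m)[!keep]
  if (length(excluded)) {
    message("copa: excluded ", length(excluded), " zero-MAD gene(s)")
  }
  tr <- (m[keep, , drop = FALSE] - med[keep]) / mads[keep]
  score <- apply(tr[, tumors, drop = FALSE], 1L, stats::quantile,
                 probs = r / 100, names = FALSE)
  ord <- order(-score, rownames(tr))
  ranking <- data.frame(gene_id = rownames(tr)[ord],
                        copa_score = score[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  list(ranking = ranking, excluded = excluded)
}

#' Convert a qPCR CT value to abundance
#'
#' `abundance = 10^((40 - CT) / 3.5)`: CT 40 maps to abundance 1 and each
#' 3.5-cycle decrease multiplies abundance by ten (the behaviour expected
#' of an assay run near standard efficiency).
#'
#' @param ct CT value(s) in [0, 40].
#' @return abundance, same length as `ct`.
#' @export
qpcr_abundance <- function(ct) {
  if (any(ct < 0 | ct > 40)) stop("CT values must lie in [0, 40]")
  10^((40 - ct) / 3.5)
}

#' Housekeeper covariate adjustment of qPCR abundances
#'
#' Analysis-of-covariance style normalization: a per-sample robust score is
#' the median of the housekeeper log10 abundances; each target gene's log10
#' abundance is regressed on that score across samples and replaced by its
#' residual plus the gene's grand mean. Samples missing a housekeeper
#' measurement are dropped with a message; if the score has zero variance
#' the adjustment is skipped with a warning and raw abundances returned.
#'
#' @param ct samples x assays matrix of CT values in [0, 40].
#' @param housekeepers names of the (two) housekeeper assay columns.
#' @return samples x target-assays matrix of adjusted abundances (linear
#'   scale; housekeeper columns are not returned).
#' @export
housekeeper_adjust <- function(ct, housekeepers = c("GAPDH", "ACTB")) {
  stopifnot(all(housekeepers %in% colnames(ct)))
  ok <- stats::complete.cases(ct[, housekeepers, drop = FALSE])
  if (!all(ok)) {
    message("housekeeper_adjust: dropped ", sum(!ok),
            " sample(s) missing housekeeper CTs")
    ct <- ct[ok, , drop = FALSE]
  }
  log10ab <- (40 - ct) / 3.5
  score <- apply(log10ab[, housekeepers, drop = FALSE], 1L, stats::median)
  targets <- setdiff(colnames(ct), housekeepers)
  if (stats::var(score) == 0) {
    warning("housekeeper score has zero variance; returning raw abundances")
    return(10^log10ab[, targets, drop = FALSE])
  }
  adj <- vapply(targets, function(g) {
    y <- log10ab[, g]
    fit <- stats::lm(y ~ score)
    stats::residuals(fit) + mean(y)
  }, numeric(nrow(ct)))
  out <- 10^adj
  rownames(out) <- rownames(ct)
  out
}
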