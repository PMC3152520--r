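# Simplified Bayesian diploid genotype caller. Works from per-site base
# counts and a mean Phred base quality; produces, per site, the maximum-
# posterior diploid genotype with Phred-scaled consensus quality (confidence
# in the call) and variant quality (evidence against homozygous reference).
# This is deliberately NOT a SAMtools port: a closed-form multinomial
# likelihood over base counts keeps it desk-scale and fully testable, and
# the study thresholds (CQ >= 50, VQ > 0) are applied to these analogous
# quantities.

# the 10 unordered diploid genotypes, lexicographic
.GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

# per-genotype emission probability of each observed base, given error e:
# P(base | genotype) = (1 - e) * w + e/3 * (1 - w2), where a base in the
# genotype is emitted with weight 1 (hom) or 0.5 (het) and any base not in
# the genotype arises by error at rate e/3.
.emission_logprobs <- function(e) {
  # returns 10 x 4 matrix of log P(base | genotype)
  out <- matrix(NA_real_, 10L, 4L, dimnames = list(.GENOTYPES, .BASES))
  for (g in .GENOTYPES) {
    a1 <- substring(g, 1L, 1L); a2 <- substring(g, 2L, 2L)
    for (b in .BASES) {
      w <- (a1 == b) * 0.5 + (a2 == b) * 0.5
      out[g, b] <- log(w * (1 - e) + (1 - w) * e / 3)
    }
  }
  out
}

#' Genotype log-likelihoods for one site
#'
#' @param counts named numeric vector of read counts for A, C, G, T.
#' @param q mean Phred base quality of the site's reads.
#' @return named numeric vector: log-likelihood of each of the 10 unordered
#'   diploid genotypes (multinomial over base counts).
#' @export
genotype_likelihoods <- function(counts, q) {
  counts <- counts[.BASES]
  if (sum(counts) < 1L) stop("no reads at site (depth 0): no call")
  e <- 10^(-q / 10)
  lp <- .emission_logprobs(e)
  drop(lp %*% counts)
}

.genotype_prior_log <- function(theta) {
  # P(hom-ref) = 1 - theta - theta^2; the three ref-containing hets share
  # theta; the six genotypes without the reference allele share theta^2.
  stopifnot(theta > 0, theta + theta^2 < 1)
  c(hom_ref = log(1 - theta - theta^2),
    het_ref = log(theta / 3),
    non_ref = log(theta^2 / 6))
}

#' Call the genotype at one site
#'
#' Posterior over the 10 diploid genotypes with prior mass 1 - theta -
#' theta^2 on homozygous reference, theta shared by the three heterozygotes
#' containing the reference allele, and theta^2 shared by the six genotypes
#' without it. Consensus quality is `-10 log10(1 - P(best))`, variant
#' quality `-10 log10(P(hom-ref))` for non-reference calls (0 for
#' homozygous-reference calls); both are capped at 255. Ties are broken
#' toward homozygous reference, then lexicographically.
#'
#' @param counts named numeric vector of read counts for A, C, G, T.
#' @param ref_base the reference base at the site.
#' @param q mean Phred base quality.
#' @param theta heterozygosity prior (default 0.001).
#' @return list with `genotype` (two-character string, sorted),
#'   `consensus_quality`, `variant_quality`, `depth` and `posterior`
#'   (named vector over the 10 genotypes).
#' @export
call_genotype <- function(counts, ref_base, q, theta = 0.001) {
  if (!ref_base %in% .BASES) stop("ref_base must be one of A/C/G/T")
  ll <- genotype_likelihoods(counts, q)
  pri <- .genotype_prior_log(theta)
  has_ref <- vapply(.GENOTYPES, function(g) {
    grepl(ref_base, g, fixed = TRUE)
  }, TRUE)
  hom_ref <- paste0(ref_base, ref_base)
  lprior <- ifelse(.GENOTYPES == hom_ref, pri["hom_ref"],
                   ifelse(has_ref, pri["het_ref"], pri["non_ref"]))
  lpost <- ll + lprior
  lpost <- lpost - max(lpost)
  unnorm <- exp(lpost)
  post <- unnorm / sum(unnorm)
  names(post) <- names(unnorm) <- .GENOTYPES
  # argmax with ties toward hom-ref, then lexicographic
  best <- which(post >= max(post) - 1e-12)
  best <- if (any(.GENOTYPES[best] == hom_ref)) match(hom_ref, .GENOTYPES)
          else min(best)
  gt <- .GENOTYPES[best]
  # 1 - P(best) summed over the other genotypes (numerically stable)
  p_not_best <- sum(unnorm[-best]) / sum(unnorm)
  cq <- min(255, -10 * log10(max(p_not_best, 1e-300)))
  vq <- if (gt == hom_ref) 0 else
    min(255, -10 * log10(max(post[hom_ref], 1e-300)))
  list(genotype = gt, consensus_quality = unname(cq),
       variant_quality = unname(vq), depth = unname(sum(counts[.BASES])),
       posterior = post)
}

# Vectorized caller over a pileup data.frame (contig, pos, ref, A, C, G, T,
# q). Sites with depth 0 are dropped (no-call).
.call_pileup <- function(pileup, theta = 0.001) {
  counts <- as.matrix(pileup[, .BASES])
  depth <- rowSums(counts)
  keep <- depth >= 1L
  pileup <- pileup[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  depth <- depth[keep]
  n <- nrow(pileup)
  if (n == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), genotype = character(),
                      cq = numeric(), vq = numeric(), depth = numeric()))
  }
  e <- 10^(-pileup$q / 10)
  pri <- .genotype_prior_log(theta)
  ll <- matrix(NA_real_, n, 10L, dimnames = list(NULL, .GENOTYPES))
  for (g in .GENOTYPES) {
    a1 <- substring(g, 1L, 1L); a2 <- substring(g, 2L, 2L)
    lg <- 0
    for (b in .BASES) {
      w <- (a1 == b) * 0.5 + (a2 == b) * 0.5
      lg <- lg + counts[, b] * log(w * (1 - e) + (1 - w) * e / 3)
    }
    ll[, g] <- lg
  }
  ref_col <- match(pileup$ref, .BASES)
  hom_ref_idx <- match(paste0(pileup$ref, pileup$ref), .GENOTYPES)
  lprior <- matrix(pri["non_ref"], n, 10L)
  for (j in seq_len(10L)) {
    g <- .GENOTYPES[j]
    has <- substring(g, 1L, 1L) == pileup$ref |
      substring(g, 2L, 2L) == pileup$ref
    lprior[has, j] <- pri["het_ref"]
  }
  lprior[cbind(seq_len(n), hom_ref_idx)] <- pri["hom_ref"]
  lpost <- ll + lprior
  m <- lpost[cbind(seq_len(n), max.col(lpost, ties.method = "first"))]
  unnorm <- exp(lpost - m)
  total <- rowSums(unnorm)
  post <- unnorm / total
  # argmax with ties toward hom-ref then lexicographic ("first" is
  # lexicographic given column order)
  pmax_ <- do.call(pmax, as.data.frame(post))
  best <- max.col(post >= pmax_ - 1e-12, ties.method = "first")
  homref_post <- post[cbind(seq_len(n), hom_ref_idx)]
  tie_homref <- homref_post >= pmax_ - 1e-12
  best[tie_homref] <- hom_ref_idx[tie_homref]
  # 1 - P(best) as the explicit sum over the other genotypes (avoids
  # cancellation when the best posterior is within 1e-13 of 1)
  not_best <- unnorm
  not_best[cbind(seq_len(n), best)] <- 0
  p_not_best <- rowSums(not_best) / total
  cq <- pmin(255, -10 * log10(pmax(p_not_best, 1e-300)))
  is_homref <- best == hom_ref_idx
  vq <- ifelse(is_homref, 0,
               pmin(255, -10 * log10(pmax(homref_post, 1e-300))))
  data.frame(contig = pileup$contig, pos = pileup$pos, ref = pileup$ref,
             genotype = .GENOTYPES[best], cq = cq, vq = vq, depth = depth,
             stringsAsFactors = FALSE)
}

#' Call genotypes for one sample over targeted regions
#'
#' Calls every in-target pileup site (pileups outside the targets are
#' ignored) and reports a coverage summary: the fraction of targeted bases
#' with depth >= 1 and >= 20.
#'
#' @param pileup per-site pileup data.frame with columns `contig`, `pos`,
#'   `ref`, `A`, `C`, `G`, `T`, `q`.
#' @param targets a [target_regions()] object.
#' @param theta heterozygosity prior (default 0.001).
#' @return list with `calls` (data.frame: contig, pos, ref, genotype, cq,
#'   vq, depth) and `coverage` (list: frac_ge1, frac_ge20, n_target_bases).
#' @export
call_sample <- function(pileup, targets, theta = 0.001) {
  span <- target_span(targets)
  if (span == 0L || nrow(pileup) == 0L) {
    return(list(calls = .call_pileup(pileup[0, , drop = FALSE], theta),
                coverage = list(frac_ge1 = NA_real_, frac_ge20 = NA_real_,
                                n_target_bases = span)))
  }
  keep <- in_targets(targets, pileup$contig, pileup$pos)
  pileup <- pileup[keep, , drop = FALSE]
  depth <- rowSums(as.matrix(pileup[, .BASES]))
  cov <- list(frac_ge1 = sum(depth >= 1) / span,
              frac_ge20 = sum(depth >= 20) / span,
              n_target_bases = span)
  list(calls = .call_pileup(pileup, theta), coverage = cov)
}

#' Call genotypes across a cohort
#'
#' Memory-conscious wrapper over [call_sample()]: for each sample only the
#' variant (non-reference) calls and the calls at a designated locus subset
#' (typically the array-shared loci) are kept, along with per-sample
#' coverage summaries.
#'
#' @param pileups named list of per-sample pileup data.frames.
#' @param targets a [target_regions()] object.
#' @param keep_loci optional data.frame with columns `contig`, `pos`: sites
#'   whose calls are retained regardless of genotype.
#' @param theta heterozygosity prior.
#' @return list with `variant_calls` (long data.frame with a `sample`
#'   column; non-hom-ref calls only), `locus_calls` (calls at `keep_loci`,
#'   all genotypes) and `coverage` (per-sample data.frame).
#' @export
call_cohort <- function(pileups, targets, keep_loci = NULL, theta = 0.001) {
  vc <- list(); lc <- list(); cov <- list()
  keep_key <- if (!is.null(keep_loci)) {
    paste(keep_loci$contig, keep_loci$pos)
  } else character()
  for (s in names(pileups)) {
    res <- call_sample(pileups[[s]], targets, theta)
    calls <- res$calls
    hom_ref <- calls$genotype == paste0(calls$ref, calls$ref)
    v <- calls[!hom_ref, , drop = FALSE]
    if (nrow(v)) vc[[s]] <- cbind(sample = s, v)
    if (length(keep_key)) {
      l <- calls[paste(calls$contig, calls$pos) %in% keep_key, ,
                 drop = FALSE]
      if (nrow(l)) lc[[s]] <- cbind(sample = s, l)
    }
    cov[[s]] <- data.frame(sample = s, frac_ge1 = res$coverage$frac_ge1,
                           frac_ge20 = res$coverage$frac_ge20,
                           stringsAsFactors = FALSE)
  }
  empty <- data.frame(sample = character(), contig = character(),
                      pos = integer(), ref = character(),
                      genotype = character(), cq = numeric(),
                      vq = numeric(), depth = numeric())
  list(variant_calls = if (length(vc)) do.call(rbind, vc) else empty,
       locus_calls = if (length(lc)) do.call(rbind, lc) else empty,
       coverage = do.call(rbind, cov))
}

#' Expand genotype calls into variant records
#'
#' Every allele of a non-reference genotype that differs from the reference
#' base becomes one variant record (a het non-reference genotype yields two).
#'
#' @param calls data.frame of calls with columns `sample`, `contig`, `pos`,
#'   `ref`, `genotype`, `cq`, `vq`, `depth`.
#' @return data.frame with one row per (call, alternate allele), adding an
#'   `alt` column.
#' @export
calls_to_variants <- function(calls) {
  a1 <- substring(calls$genotype, 1L, 1L)
  a2 <- substring(calls$genotype, 2L, 2L)
  out <- rbind(
    cbind(calls, alt = a1)[a1 != calls$ref, , drop = FALSE],
    cbind(calls, alt = a2)[a2 != calls$ref & a2 != a1, , drop = FALSE])
  out <- out[order(out$sample, out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$alt <- as.character(out$alt)
  out
}
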