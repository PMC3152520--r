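# Copy-number segmentation (simplified recursive binary segmentation with
# permutation testing), gene-level DNA/RNA integration, recurrence summary
# and the per-sample mutational/actionability profile matrix.

# maximal two-sample t statistic over all interior split points of x,
# computed via cumulative sums. Returns list(t, split) where the left
# segment is x[1:split].
.max_t_split <- function(x, min_probes) {
  n <- length(x)
  ks <- seq.int(min_probes, n - min_probes)
  if (length(ks) < 1L) return(list(t = -Inf, split = NA_integer_))
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  nl <- ks
  nr <- n - ks
  ml <- cs[ks] / nl
  mr <- (cs[n] - cs[ks]) / nr
  ssl <- cs2[ks] - nl * ml^2
  ssr <- (cs2[n] - cs2[ks]) - nr * mr^2
  sp2 <- (ssl + ssr) / pmax(n - 2L, 1L)
  tt <- abs(ml - mr) / sqrt(pmax(sp2, 1e-300) * (1 / nl + 1 / nr))
  i <- which.max(tt)
  list(t = tt[i], split = ks[i])
}

# recursive segmentation of one probe vector; returns integer vector of
# segment ids per probe (1, 2, ... left to right)
.segment_vector <- function(x, alpha, min_probes, n_perm) {
  bounds <- list()
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len >= 2L * min_probes) {
      seg <- x[lo:hi]
      obs <- .max_t_split(seg, min_probes)
      if (is.finite(obs$t)) {
        null_t <- vapply(seq_len(n_perm), function(i) {
          .max_t_split(sample(seg), min_probes)$t
        }, 0)
        p <- (1 + sum(null_t >= obs$t)) / (n_perm + 1)
        if (p <= alpha) {
          cut <- lo + obs$split - 1L
          recurse(lo, cut)
          recurse(cut + 1L, hi)
          return(invisible(NULL))
        }
      }
    }
    bounds[[length(bounds) + 1L]] <<- c(lo, hi)
    invisible(NULL)
  }
  recurse(1L, length(x))
  ids <- integer(length(x))
  ord <- order(vapply(bounds, `[[`, 0, 1L))
  for (k in seq_along(ord)) {
    b <- bounds[[ord[k]]]
    ids[b[1L]:b[2L]] <- k
  }
  ids
}

#' Segment copy-number probe log2 ratios
#'
#' Simplified circular-binary-segmentation style change-point detection:
#' within each contig, the maximal two-sample t statistic over split points
#' is tested against a within-segment permutation null; significant splits
#' recurse until no further change-point is supported. Segment means are
#' arithmetic means of member probes.
#'
#' @param probes data.frame with columns `contig`, `pos` (sorted within
#'   contig) and optionally `probe_id`.
#' @param log2 numeric vector of probe log2 ratios, parallel to `probes`.
#' @param alpha permutation p-value threshold for a split (default 0.01).
#' @param min_probes minimum probes per segment (default 3).
#' @param n_perm permutations per tested split (default 1000).
#' @return data.frame of segments: `contig`, `start`, `end` (half-open,
#'   probe positions; `end` is the last probe position + 1), `mean_log2`,
#'   `n_probes`, `first_probe`, `last_probe` (indices into `probes`).
#' @export
segment_probes <- function(probes, log2, alpha = 0.01, min_probes = 3L,
                           n_perm = 1000L) {
  stopifnot(nrow(probes) == length(log2))
  out <- list()
  for (ctg in unique(probes$contig)) {
    sel <- which(probes$contig == ctg)
    if (is.unsorted(probes$pos[sel])) stop("probes must be position-sorted")
    x <- log2[sel]
    ids <- if (length(x) < 2L * min_probes) rep(1L, length(x)) else
      .segment_vector(x, alpha, min_probes, n_perm)
    for (id in unique(ids)) {
      idx <- sel[ids == id]
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg,
        start = probes$pos[idx[1L]],
        end = probes$pos[idx[length(idx)]] + 1L,
        mean_log2 = mean(log2[idx]),
        n_probes = length(idx),
        first_probe = idx[1L], last_probe = idx[length(idx)],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Segment every sample of a copy-number matrix
#'
#' @param probes probe table (`contig`, `pos`).
#' @param log2_matrix probes x samples matrix of log2 ratios.
#' @inheritParams segment_probes
#' @return data.frame of segments with a leading `sample` column.
#' @export
segment_cohort <- function(probes, log2_matrix, alpha = 0.01,
                           min_probes = 3L, n_perm = 1000L) {
  segs <- lapply(colnames(log2_matrix), function(s) {
    cbind(sample = s,
          segment_probes(probes, log2_matrix[, s], alpha, min_probes,
                         n_perm))
  })
  do.call(rbind, segs)
}

#' Gene-level copy-number value
#'
#' Mean probe log2 ratio over the gene span (probe-level integration).
#'
#' @param probes probe table (`contig`, `pos`).
#' @param log2 probe log2 values, parallel to `probes`.
#' @param gene a [gene_model()].
#' @return mean log2 of overlapping probes, or `NA` if no probe overlaps.
#' @export
gene_cn <- function(probes, log2, gene) {
  lo <- min(gene$exons$start); hi <- max(gene$exons$end)
  sel <- probes$contig == gene$contig & probes$pos >= lo & probes$pos < hi
  if (!any(sel)) return(NA_real_)
  mean(log2[sel])
}

#' Gene x sample copy-number matrix
#'
#' @param probes probe table (`contig`, `pos`).
#' @param log2_matrix probes x samples log2 matrix.
#' @param genes list of [gene_model()] objects.
#' @return genes x samples matrix of mean probe log2 values.
#' @export
gene_cn_matrix <- function(probes, log2_matrix, genes) {
  out <- t(vapply(genes, function(g) {
    lo <- min(g$exons$start); hi <- max(g$exons$end)
    sel <- probes$contig == g$contig & probes$pos >= lo & probes$pos < hi
    if (!any(sel)) rep(NA_real_, ncol(log2_matrix)) else
      colMeans(log2_matrix[sel, , drop = FALSE])
  }, numeric(ncol(log2_matrix))))
  rownames(out) <- vapply(genes, `[[`, "", "gene_id")
  colnames(out) <- colnames(log2_matrix)
  out
}

#' Integrate gene-level copy number with expression
#'
#' A gene is amplified in a tumor when its log2 copy ratio strictly exceeds
#' `amp_threshold`, lost when below `-amp_threshold`, and overexpressed when
#' its expression z-score against the normal-sample distribution exceeds
#' `overexpr_z`. Genes are ranked by (amplification frequency across
#' tumors, mean tumor z) -- the "frequently amplified and concordantly
#' overexpressed" ordering.
#'
#' @param cn genes x tumor-samples matrix of log2 copy ratios.
#' @param expr genes x samples expression matrix (log2 scale recommended).
#' @param classes named character vector over `colnames(expr)`:
#'   `"tumor"` / `"normal"`.
#' @param amp_threshold log2 amplification cutoff (default 0.6, strict
#'   inequality).
#' @param overexpr_z z-score cutoff vs normals (default 2, strict).
#' @param top_n size of the returned concordant ranking (default 200).
#' @return list with `states` (data.frame: sample, gene_id, log2,
#'   amplified, overexpressed, lost), `ranking` (data.frame: gene_id,
#'   amp_freq, mean_z, rank) truncated to `top_n`, and `excluded`
#'   (genes missing from either data type).
#' @export
integrate_cn_expr <- function(cn, expr, classes, amp_threshold = 0.6,
                              overexpr_z = 2, top_n = 200L) {
  tumors <- names(classes)[classes == "tumor"]
  normals <- names(classes)[classes == "normal"]
  tumors <- intersect(tumors, colnames(cn))
  common <- intersect(rownames(cn), rownames(expr))
  excluded <- setdiff(union(rownames(cn), rownames(expr)), common)
  cn <- cn[common, tumors, drop = FALSE]
  nm <- expr[common, normals, drop = FALSE]
  mu <- rowMeans(nm)
  sdev <- apply(nm, 1L, stats::sd)
  z <- (expr[common, tumors, drop = FALSE] - mu) / sdev
  states <- do.call(rbind, lapply(tumors, function(s) {
    data.frame(sample = s, gene_id = common, log2 = cn[, s],
               amplified = !is.na(cn[, s]) & cn[, s] > amp_threshold,
               overexpressed = is.finite(z[, s]) & z[, s] > overexpr_z,
               lost = !is.na(cn[, s]) & cn[, s] < -amp_threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(states) <- NULL
  amp_freq <- rowMeans(cn > amp_threshold, na.rm = TRUE)
  mean_z <- rowMeans(z, na.rm = TRUE)
  ord <- order(-amp_freq, -mean_z, common)
  ranking <- data.frame(gene_id = common[ord], amp_freq = amp_freq[ord],
                        mean_z = mean_z[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  list(states = states, ranking = utils::head(ranking, top_n),
       excluded = excluded)
}

#' Cohort copy-number recurrence summary
#'
#' Per genomic bin, the sum over samples of segment mean log2 ratios for
#' segments exceeding the gain threshold and (separately) falling below the
#' loss threshold -- large values mark regions recurrently gained or lost,
#' or strongly changed in a few samples.
#'
#' @param segments segment data.frame (`sample`, `contig`, `start`, `end`,
#'   `mean_log2`).
#' @param bin_size bin width in bp (default 1000).
#' @param gain_threshold,loss_threshold log2 cutoffs (default +0.6 / -0.6).
#' @param contig_lengths named vector of contig lengths (optional; inferred
#'   from segment ends otherwise).
#' @return data.frame: `contig`, `bin_start`, `bin_end`, `gain_sum`
#'   (>= 0), `loss_sum` (<= 0).
#' @export
recurrence_summary <- function(segments, bin_size = 1000L,
                               gain_threshold = 0.6,
                               loss_threshold = -0.6,
                               contig_lengths = NULL) {
  contigs <- if (!is.null(contig_lengths)) names(contig_lengths) else
    unique(segments$contig)
  out <- list()
  for (ctg in contigs) {
    len <- if (!is.null(contig_lengths)) contig_lengths[[ctg]] else
      max(segments$end[segments$contig == ctg], bin_size)
    starts <- seq.int(0L, len - 1L, by = bin_size)
    gain <- numeric(length(starts)); loss <- numeric(length(starts))
    seg <- segments[segments$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      hit <- starts < seg$end[i] & (starts + bin_size) > seg$start[i]
      if (seg$mean_log2[i] > gain_threshold) {
        gain[hit] <- gain[hit] + seg$mean_log2[i]
      } else if (seg$mean_log2[i] < loss_threshold) {
        loss[hit] <- loss[hit] + seg$mean_log2[i]
      }
    }
    out[[ctg]] <- data.frame(contig = ctg, bin_start = starts,
                             bin_end = pmin(starts + bin_size, len),
                             gain_sum = gain, loss_sum = loss,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.PROFILE_STATES <- c("none", "dna_loss", "overexpr_only",
                     "amp_and_overexpr", "mutation_unconfirmed",
                     "mutation_confirmed")

#' Build the per-sample mutational/actionability profile matrix
#'
#' One cell per (sample, gene), holding the highest-precedence event:
#' confirmed mutation > unconfirmed mutation > amplification with
#' concordant overexpression > overexpression only > DNA loss > none.
#' A sample is actionable when any gene on the actionable-feature list is
#' in a non-none, non-loss state.
#'
#' @param states `states` data.frame from [integrate_cn_expr()].
#' @param mutations somatic variant data.frame (`sample`, `gene_id`,
#'   `consequence`) restricted to the events to display; only
#'   nonsynonymous-class variants are profiled.
#' @param confirmed logical vector parallel to `mutations` rows: Sanger
#'   confirmed? (default all `FALSE`).
#' @param actionable_features character vector of gene ids with an approved
#'   or in-development targeted therapy (configuration, not code).
#' @param samples optional sample universe (default: union seen in inputs).
#' @return list with `matrix` (samples x genes character matrix of states),
#'   `actionable` (named logical per sample), `n_actionable` and
#'   `pct_actionable` (integer percent of the sample universe).
#' @export
build_profile <- function(states, mutations,
                          confirmed = rep(FALSE, nrow(mutations)),
                          actionable_features = character(),
                          samples = NULL) {
  if (is.null(samples)) {
    samples <- sort(unique(c(states$sample, mutations$sample)))
  }
  genes <- sort(unique(c(states$gene_id,
                         mutations$gene_id[!is.na(mutations$gene_id)])))
  prof <- matrix("none", length(samples), length(genes),
                 dimnames = list(samples, genes))
  rank_of <- stats::setNames(seq_along(.PROFILE_STATES), .PROFILE_STATES)
  set_state <- function(s, g, state) {
    cur <- prof[s, g]
    if (rank_of[[state]] > rank_of[[cur]]) prof[s, g] <<- state
  }
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    if (!(st$sample %in% samples)) next
    state <- if (st$amplified && st$overexpressed) "amp_and_overexpr"
      else if (st$overexpressed) "overexpr_only"
      else if (st$lost) "dna_loss"
      else "none"
    if (state != "none") set_state(st$sample, st$gene_id, state)
  }
  if (nrow(mutations)) {
    keep <- .is_nonsyn(mutations$consequence) & !is.na(mutations$gene_id)
    for (i in which(keep)) {
      if (!(mutations$sample[i] %in% samples)) next
      set_state(mutations$sample[i], mutations$gene_id[i],
                if (confirmed[i]) "mutation_confirmed"
                else "mutation_unconfirmed")
    }
  }
  act_genes <- intersect(actionable_features, genes)
  act_states <- c("amp_and_overexpr", "overexpr_only",
                  "mutation_confirmed", "mutation_unconfirmed")
  actionable <- apply(prof[, act_genes, drop = FALSE], 1L,
                      function(r) any(r %in% act_states))
  list(matrix = prof, actionable = actionable,
       n_actionable = sum(actionable),
       pct_actionable = cohort_frequency(sum(actionable), length(samples)))
}
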