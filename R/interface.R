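# Pipeline driver: configuration, end-to-end execution (simulate -> call ->
# calibrate -> somatic -> cnv/expr -> report) and the run report.

#' Pipeline configuration
#'
#' All thresholds are surfaced here and none are hard-coded downstream;
#' defaults are the study values (consensus quality >= 50, variant quality
#' > 0, amplification log2 > 0.6, deleteriousness score < 0.05).
#'
#' @param sim a [sim_config()] (carries the root seed).
#' @param n_genes,gene_length_range reference panel size (desk scale:
#'   20 genes of ~2 kb; a full-scale panel is a configuration choice).
#' @param cq,vq,depth calling-quality thresholds for the final variant set.
#' @param amp_threshold log2 amplification cutoff (strict `>`).
#' @param overexpr_z overexpression z cutoff vs normals (strict `>`).
#' @param score_cutoff deleteriousness cutoff for the damaging class.
#' @param sanger_vaf_limit Sanger re-test sensitivity limit (VAF).
#' @param n_sanger_attempts number of called somatic variants submitted to
#'   the simulated re-test (default 68).
#' @param actionable_features gene ids with a targeted therapy
#'   (configuration; default: the first five panel genes of the simulated
#'   reference).
#' @param cq_grid,vq_grid,depth_grid calibration threshold grids.
#' @param min_retained_fraction retention floor for threshold selection.
#' @param seg_n_perm permutations per segmentation split test.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_genes = 20L,
                            gene_length_range = c(1500, 2400),
                            cq = 50, vq = 0, depth = 0,
                            amp_threshold = 0.6, overexpr_z = 2,
                            score_cutoff = 0.05,
                            sanger_vaf_limit = 0.20,
                            n_sanger_attempts = 68L,
                            actionable_features = NULL,
                            cq_grid = c(0, 20, 30, 40, 50, 60),
                            vq_grid = c(0, 10, 20),
                            depth_grid = c(0, 8, 20),
                            min_retained_fraction = 0.85,
                            seg_n_perm = 500L) {
  stopifnot(inherits(sim, "sim_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with top-level keys matching [pipeline_config()]
#'   arguments; the `sim` key holds [sim_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  do.call(pipeline_config, c(list(sim = sim), y))
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output YAML file.
#' @export
write_pipeline_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path)
  invisible(path)
}

# deterministic hash of the configuration (md5 of its YAML serialization)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on a simulated cohort
#'
#' Chains: reference + cohort + expression simulation, genotype calling,
#' array calibration (threshold grid, selection, stratified FPR, mislabel
#' screen), germline subtraction and the somatic cascade, simulated Sanger
#' re-testing, copy-number segmentation and DNA/RNA integration into the
#' actionability profile, and expression statistics (signatures, COPA,
#' qPCR adjustment).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, key artifacts are written
#'   (grid TSV, somatic variants TSV, profile TSV, report JSON).
#' @param verbose emit per-stage progress messages (default `FALSE`).
#' @return a `run_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message("[somaticpanel] ", ...)
  seed <- cfg$sim$seed

  say("stage simulate: reference (", cfg$n_genes, " genes)")
  reference <- simulate_reference(cfg$n_genes, cfg$gene_length_range,
                                  seed = .child_seed(seed, 10L))
  say("stage simulate: cohort")
  cohort <- simulate_cohort(cfg$sim, reference)
  truth <- cohort$truth
  say("stage simulate: expression/CN/qPCR")
  exprdata <- simulate_expression(cfg$sim, reference, truth)

  say("stage call: ", length(cohort$pileups), " samples")
  called <- call_cohort(cohort$pileups, reference$targets,
                        keep_loci = cohort$shared_loci)

  say("stage calibrate")
  conc_raw <- concordance(called$locus_calls, cohort$array,
                          cohort$shared_loci)
  grid <- tabulate_grid(called$locus_calls, cohort$array,
                        cohort$shared_loci, cfg$cq_grid, cfg$vq_grid,
                        cfg$depth_grid)
  selected <- select_thresholds(grid, cfg$min_retained_fraction)
  filtered_locus <- filter_calls(called$locus_calls, cfg$cq, cfg$vq,
                                 cfg$depth)
  conc_filtered <- concordance(filtered_locus, cohort$array,
                               cohort$shared_loci)
  fpr <- stratified_fpr(filtered_locus, cohort$array, cohort$shared_loci)
  pairs <- .expected_pairs(cohort$samples)
  mislabel <- mislabel_check(called$locus_calls, pairs)

  say("stage somatic")
  is_tumor <- called$variant_calls$sample %in%
    cohort$samples$sample[cohort$samples$type == "tumor"]
  tumor_variants <- calls_to_variants(
    filter_calls(called$variant_calls[is_tumor, , drop = FALSE],
                 cfg$cq, cfg$vq, cfg$depth))
  normal_variants <- calls_to_variants(
    called$variant_calls[!is_tumor, , drop = FALSE])
  panel <- truth$panel[truth$panel$in_panel, c("contig", "pos", "alt")]
  scores <- truth$somatic[, c("contig", "pos", "alt", "score")]
  somatic <- subtract_germline(tumor_variants, normal_variants, panel,
                               reference, scores)
  cascade <- count_cascade(somatic, cfg$score_cutoff)
  rates <- ranked_rates(reference$genes, somatic, cfg$score_cutoff)

  say("stage sanger")
  nonsyn <- somatic[.is_nonsyn(somatic$consequence), , drop = FALSE]
  n_att <- min(cfg$n_sanger_attempts, nrow(nonsyn))
  set.seed(.child_seed(seed, 3L))
  attempted <- nonsyn[sample.int(nrow(nonsyn), n_att), , drop = FALSE]
  records <- simulate_sanger_retest(truth, attempted,
                                    cfg$sanger_vaf_limit)
  vsum <- if (nrow(records)) validation_summary(records) else NULL

  say("stage cnv")
  tumors <- cohort$samples$sample[cohort$samples$type == "tumor"]
  set.seed(.child_seed(seed, 4L))
  segments <- segment_cohort(exprdata$cn_probes,
                             exprdata$cn[, tumors, drop = FALSE],
                             n_perm = cfg$seg_n_perm)
  recurrence <- recurrence_summary(
    segments, bin_size = 1000L,
    gain_threshold = cfg$amp_threshold,
    loss_threshold = -cfg$amp_threshold,
    contig_lengths = vapply(reference$ref, nchar, 0L))
  cn_gene <- gene_cn_matrix(exprdata$cn_probes,
                            exprdata$cn[, tumors, drop = FALSE],
                            reference$genes)

  say("stage expr")
  qn <- quantile_normalize(exprdata$expr)
  integ <- integrate_cn_expr(cn_gene, qn, exprdata$classes,
                             cfg$amp_threshold, cfg$overexpr_z)
  act <- cfg$actionable_features
  if (is.null(act)) act <- utils::head(reference$gene_ids, 5L)
  confirmed_key <- with(records[records$outcome == "confirmed_somatic", ,
                                drop = FALSE],
                        paste(sample, contig, pos, alt))
  profile <- build_profile(
    integ$states, somatic,
    confirmed = with(somatic, paste(sample, contig, pos, alt)) %in%
      confirmed_key,
    actionable_features = act)
  signatures <- lapply(truth$gene_sets, function(set) {
    if (!length(set)) return(NULL)
    suppressMessages(zscore_signature(qn, set))
  })
  copa_res <- suppressMessages(copa(qn, exprdata$classes))
  adjusted_ab <- housekeeper_adjust(exprdata$ct, exprdata$housekeepers)

  report <- structure(list(
    version = as.character(utils::packageVersion("somaticpanel")),
    config_hash = config_hash(cfg),
    seed = seed,
    n_samples = nrow(cohort$samples),
    n_tumors = length(tumors),
    target_span = target_span(reference$targets),
    coverage = called$coverage,
    n_shared_loci = nrow(cohort$shared_loci),
    concordance_unfiltered = conc_raw$overall,
    concordance_filtered = conc_filtered$overall,
    grid = grid,
    selected_thresholds = selected,
    fpr = fpr,
    mislabel_flags = sum(mislabel$flagged),
    cascade = cascade,
    rates = rates,
    validation = vsum,
    n_segments = nrow(segments),
    top_concordant = utils::head(integ$ranking, 10L),
    n_actionable = profile$n_actionable,
    pct_actionable = profile$pct_actionable,
    copa_top = utils::head(copa_res$ranking, 5L),
    signature_scores = lapply(signatures, function(s) s$scores)
  ), class = "run_report")

  result <- list(report = report, reference = reference, cohort = cohort,
                 exprdata = exprdata, called = called, grid = grid,
                 somatic = somatic, records = records,
                 segments = segments, recurrence = recurrence,
                 integration = integ, profile = profile,
                 mislabel = mislabel, copa = copa_res,
                 signatures = signatures, adjusted_abundance = adjusted_ab)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(grid, file.path(out_dir, "concordance_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(somatic, file.path(out_dir, "somatic_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(segments, file.path(out_dir, "cn_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(profile$matrix, file.path(out_dir, "profile.tsv"),
                     "sample")
    jsonlite::write_json(.report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

.expected_pairs <- function(samples) {
  normals <- samples[samples$type == "normal", , drop = FALSE]
  tumors <- samples[samples$type == "tumor", , drop = FALSE]
  data.frame(
    tumor = tumors$sample[match(normals$individual, tumors$individual)],
    normal = normals$sample, stringsAsFactors = FALSE)
}

.report_json <- function(report) {
  list(version = report$version, config_hash = report$config_hash,
       seed = report$seed, n_samples = report$n_samples,
       n_tumors = report$n_tumors, target_span = report$target_span,
       n_shared_loci = report$n_shared_loci,
       concordance_unfiltered = report$concordance_unfiltered,
       concordance_filtered = report$concordance_filtered,
       fpr_ref = report$fpr$fpr_ref, fpr_variant = report$fpr$fpr_variant,
       mislabel_flags = report$mislabel_flags,
       cascade = as.list(report$cascade),
       validation = report$validation,
       n_segments = report$n_segments,
       n_actionable = report$n_actionable,
       pct_actionable = report$pct_actionable)
}

#' @export
print.run_report <- function(x, ...) {
  cat("somaticpanel run report\n")
  cat(sprintf("  samples: %d (%d tumors); target span %d bp; %d shared loci\n",
              x$n_samples, x$n_tumors, x$target_span, x$n_shared_loci))
  cat(sprintf("  concordance: %.4f unfiltered -> %.4f filtered\n",
              x$concordance_unfiltered, x$concordance_filtered))
  cat(sprintf("  FPR: %.4f (ref) / %.4f (variant); mislabel flags: %d\n",
              x$fpr$fpr_ref, x$fpr$fpr_variant, x$mislabel_flags))
  cat(sprintf("  cascade: %d somatic, %d nonsynonymous, %d deleterious\n",
              x$cascade["total_somatic"], x$cascade["exonic_nonsynonymous"],
              x$cascade["deleterious"]))
  if (!is.null(x$validation)) {
    cat(sprintf("  validation: %d attempted -> %d%% / %d%% / %d%% (confirmed/germline/absent)\n",
                x$validation$n_attempted, x$validation$pct_confirmed,
                x$validation$pct_germline, x$validation$pct_absent))
  }
  cat(sprintf("  actionable: %d samples (%d%%)\n",
              x$n_actionable, x$pct_actionable))
  invisible(x)
}
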