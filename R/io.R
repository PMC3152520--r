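# Readers and writers for the standard interchange formats: FASTA contigs,
# GFF3-subset gene models, BED target regions, per-sample VCF genotype
# calls, and the simulator's TSV dialects. FASTA/GFF3/BED go through
# Biostrings/rtracklayer; the VCF writer emits minimal VCF 4.2 with the
# caller's CQ/VQ annotations.

#' Read reference contigs from FASTA
#' @param path FASTA file.
#' @return named character vector of uppercase contig sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ref <- toupper(as.character(x))
  names(ref) <- sub("\\s.*$", "", names(ref))
  validate_reference(ref)
  ref
}

#' Write reference contigs to FASTA
#' @param ref named character vector of contig sequences.
#' @param path output FASTA file.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' Write gene models to a GFF3 subset
#'
#' One `gene` feature plus `CDS` children per gene model (internal 0-based
#' half-open coordinates become standard 1-based inclusive GFF3).
#'
#' @param genes list of [gene_model()] objects.
#' @param path output GFF3 file.
#' @export
write_genes_gff3 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    span <- c(min(g$cds$start), max(g$cds$end))
    lens <- g$cds$end - g$cds$start
    # CDS phase in translation order (genomic order for +, reversed for -)
    ord <- if (g$strand == "-") rev(seq_along(lens)) else seq_along(lens)
    phase <- integer(length(lens))
    phase[ord] <- (3L - c(0L, cumsum(lens[ord]))[seq_along(lens)] %% 3L) %% 3L
    GenomicRanges::GRanges(
      g$contig,
      IRanges::IRanges(start = c(span[1L], g$cds$start) + 1L,
                       end = c(span[2L], g$cds$end)),
      strand = g$strand,
      type = c("gene", rep("CDS", nrow(g$cds))),
      phase = c(NA_integer_, phase),
      ID = c(g$gene_id, sprintf("%s.cds%d", g$gene_id,
                                seq_len(nrow(g$cds)))),
      Parent = c(NA_character_, rep(g$gene_id, nrow(g$cds))))
  })
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 subset
#' @param path GFF3 file written by [write_genes_gff3()] (gene + CDS
#'   features; one transcript per gene).
#' @return list of [gene_model()] objects.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  parent <- as.character(unlist(cds$Parent))
  out <- lapply(unique(parent), function(gid) {
    sub <- cds[parent == gid]
    iv <- data.frame(start = GenomicRanges::start(sub) - 1L,
                     end = GenomicRanges::end(sub))
    gene_model(gid, as.character(GenomicRanges::seqnames(sub))[1L],
               as.character(GenomicRanges::strand(sub))[1L], iv, iv)
  })
  out
}

#' Write target regions to BED
#' @param targets a [target_regions()] object.
#' @param path output BED file (0-based half-open, as BED).
#' @export
write_targets_bed <- function(targets, path) {
  gr <- GenomicRanges::GRanges(
    targets$contig,
    IRanges::IRanges(start = targets$start + 1L, end = targets$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read target regions from BED
#' @param path BED file.
#' @return a [target_regions()] object (0-based half-open).
#' @export
read_targets_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  target_regions(data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)))
}

#' Write a per-site pileup table
#' @param pileup pileup data.frame (`contig`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `q`).
#' @param path output TSV.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-site pileup table
#' @param path TSV written by [write_pileup_tsv()].
#' @return pileup data.frame.
#' @export
read_pileup_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "integer", "integer", "integer",
                                   "integer", "numeric"))
}

#' Write genotype calls as minimal VCF 4.2
#'
#' One sample per file. Positions become 1-based; INFO carries the caller's
#' consensus (CQ) and variant (VQ) qualities, FORMAT carries GT and DP.
#' Homozygous-reference calls are emitted with ALT "." and GT 0/0.
#'
#' @param calls calls data.frame (`contig`, `pos`, `ref`, `genotype`,
#'   `cq`, `vq`, `depth`).
#' @param path output VCF path.
#' @param sample sample name for the genotype column.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE") {
  a1 <- substring(calls$genotype, 1L, 1L)
  a2 <- substring(calls$genotype, 2L, 2L)
  alt <- mapply(function(x, y, r) {
    u <- setdiff(unique(c(x, y)), r)
    if (!length(u)) "." else paste(u, collapse = ",")
  }, a1, a2, calls$ref, USE.NAMES = FALSE)
  gt_idx <- function(allele, ref, alt_str) {
    alleles <- c(ref, strsplit(alt_str, ",", fixed = TRUE)[[1L]])
    match(allele, alleles) - 1L
  }
  gt <- vapply(seq_len(nrow(calls)), function(i) {
    paste(sort(c(gt_idx(a1[i], calls$ref[i], alt[i]),
                 gt_idx(a2[i], calls$ref[i], alt[i]))), collapse = "/")
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CQ,Number=1,Type=Float,Description=\"Consensus quality (Phred)\">",
    "##INFO=<ID=VQ,Number=1,Type=Float,Description=\"Variant quality (Phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- paste(calls$contig, calls$pos + 1L, ".", calls$ref, alt, ".",
                ".", sprintf("CQ=%.6g;VQ=%.6g", calls$cq, calls$vq),
                "GT:DP", paste0(gt, ":", calls$depth), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls from a VCF written by [write_vcf()]
#' @param path VCF file.
#' @return calls data.frame (`sample`, `contig`, `pos`, `ref`, `genotype`,
#'   `cq`, `vq`, `depth`); positions 0-based.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  sample <- utils::tail(strsplit(hdr, "\t", fixed = TRUE)[[1L]], 1L)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(sample = character(), contig = character(),
                      pos = integer(), ref = character(),
                      genotype = character(), cq = numeric(),
                      vq = numeric(), depth = integer()))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- f[, 8L]
  cq <- as.numeric(sub(".*CQ=([^;]+).*", "\\1", info))
  vq <- as.numeric(sub(".*VQ=([^;]+).*", "\\1", info))
  fmt <- strsplit(f[, 10L], ":", fixed = TRUE)
  gt <- vapply(fmt, `[[`, "", 1L)
  dp <- as.integer(vapply(fmt, `[[`, "", 2L))
  geno <- vapply(seq_len(nrow(f)), function(i) {
    alleles <- c(f[i, 4L],
                 if (f[i, 5L] != ".") strsplit(f[i, 5L], ",")[[1L]])
    idx <- as.integer(strsplit(gt[i], "/", fixed = TRUE)[[1L]]) + 1L
    paste(sort(alleles[idx]), collapse = "")
  }, "")
  data.frame(sample = sample, contig = f[, 1L],
             pos = as.integer(f[, 2L]) - 1L, ref = f[, 4L],
             genotype = geno, cq = cq, vq = vq, depth = dp,
             stringsAsFactors = FALSE)
}

#' Write a generic matrix as TSV (row names in first column)
#' @param m matrix.
#' @param path output TSV.
#' @param rowname_col header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE)
  names(d)[1L] <- rowname_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV file.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
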