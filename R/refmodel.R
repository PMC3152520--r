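# Reference model: contigs, gene/CDS structures, codon translation and
# point-substitution consequence annotation. All coordinates are 0-based,
# half-open internally; VCF output is 1-based.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Validate a reference sequence set
#'
#' A reference is a named character vector of uppercase DNA sequences
#' (one element per contig, A/C/G/T only).
#'
#' @param ref named character vector of contig sequences.
#' @return `ref`, invisibly, after validation.
#' @export
validate_reference <- function(ref) {
  stopifnot(is.character(ref), length(ref) >= 1L, !is.null(names(ref)))
  if (anyDuplicated(names(ref))) stop("duplicate contig names")
  bad <- grepl("[^ACGT]", ref)
  if (any(bad)) {
    stop("contig(s) contain non-ACGT characters: ",
         paste(names(ref)[bad], collapse = ", "))
  }
  if (any(nchar(ref) == 0L)) stop("empty contig sequence")
  invisible(ref)
}

#' Construct a gene model
#'
#' A single-transcript gene model: exon and CDS intervals on one contig.
#' Intervals are 0-based half-open, stored in genomic order, non-overlapping.
#' The stop codon is part of the stored CDS.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open).
#' @param cds data.frame with columns `start`, `end`; total length must be a
#'   multiple of 3 and every CDS interval must lie within an exon.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  exons <- .check_intervals(exons, "exons")
  cds <- .check_intervals(cds, "cds")
  if (sum(cds$end - cds$start) %% 3L != 0L) {
    stop("gene ", gene_id, ": total CDS length not divisible by 3")
  }
  # every CDS interval must be contained in some exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    if (!inside) stop("gene ", gene_id, ": CDS interval outside exons")
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons, cds = cds),
            class = "gene_model")
}

.check_intervals <- function(x, what) {
  x <- as.data.frame(x)[, c("start", "end")]
  stopifnot(nrow(x) >= 1L, all(x$end > x$start))
  x <- x[order(x$start), , drop = FALSE]
  if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)])) {
    stop(what, " intervals overlap")
  }
  rownames(x) <- NULL
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s(%s)  %d exon(s), CDS %d nt\n",
              x$gene_id, x$contig, x$strand, nrow(x$exons),
              sum(x$cds$end - x$cds$start)))
  invisible(x)
}

#' Construct a target-region set
#'
#' @param regions data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @return an object of class `target_regions` (a data.frame).
#' @export
target_regions <- function(regions) {
  regions <- as.data.frame(regions)[, c("contig", "start", "end")]
  stopifnot(all(regions$end > regions$start))
  regions <- regions[order(regions$contig, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  class(regions) <- c("target_regions", "data.frame")
  regions
}

#' Total targeted span in bases
#' @param targets a `target_regions` object.
#' @return integer, total number of targeted bases.
#' @export
target_span <- function(targets) sum(targets$end - targets$start)

#' Test positions for target membership
#'
#' @param targets a `target_regions` object.
#' @param contig,pos parallel vectors of contig names and 0-based positions.
#' @return logical vector: is each position inside a target interval?
#' @export
in_targets <- function(targets, contig, pos) {
  stopifnot(length(contig) == length(pos))
  out <- logical(length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    iv <- targets[targets$contig == ctg, , drop = FALSE]
    if (nrow(iv) == 0L) next
    p <- pos[sel]
    hit <- rep(FALSE, length(p))
    for (i in seq_len(nrow(iv))) {
      hit <- hit | (p >= iv$start[i] & p < iv$end[i])
    }
    out[sel] <- hit
  }
  out
}

#' Enumerate all targeted positions
#' @param targets a `target_regions` object.
#' @return data.frame with columns `contig`, `pos` (0-based), one row per base.
#' @export
target_positions <- function(targets) {
  pos <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                    targets$start, targets$end), use.names = FALSE)
  data.frame(
    contig = rep(targets$contig, targets$end - targets$start),
    pos = pos, stringsAsFactors = FALSE)
}

#' CDS length in amino acids
#'
#' By package convention the stop codon is stored as part of the CDS and is
#' excluded from the amino-acid count, so a 1062-nt CDS encodes 353 residues.
#'
#' @param gene a `gene_model`.
#' @param stop_codon_included does the stored CDS include the stop codon?
#'   Default `TRUE` (the package convention).
#' @return positive integer, number of encoded amino acids.
#' @export
cds_aa_length <- function(gene, stop_codon_included = TRUE) {
  nt <- sum(gene$cds$end - gene$cds$start)
  if (nt %% 3L != 0L) stop("CDS length not divisible by 3")
  nt %/% 3L - as.integer(stop_codon_included)
}

# Genomic positions of the CDS in translation order (5' -> 3' of the mRNA).
.cds_genomic_positions <- function(gene) {
  pos <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                    gene$cds$start, gene$cds$end), use.names = FALSE)
  if (gene$strand == "-") rev(pos) else pos
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a DNA string
#' @param x character scalar of A/C/G/T.
#' @return reverse complement as a character scalar.
#' @export
reverse_complement <- function(x) {
  paste(rev(.COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Spliced CDS sequence of a gene
#'
#' @param ref named character vector of contig sequences.
#' @param gene a `gene_model`.
#' @return the CDS in translation orientation (reverse-complemented for
#'   minus-strand genes) as a character scalar.
#' @export
spliced_cds <- function(ref, gene) {
  seqs <- substring(ref[[gene$contig]], gene$cds$start + 1L, gene$cds$end)
  s <- paste(seqs, collapse = "")
  if (gene$strand == "-") reverse_complement(s) else s
}

#' Translate a DNA coding sequence
#'
#' @param dna character scalar, length a multiple of 3.
#' @return character vector of single-letter amino acids (`"*"` = stop).
#' @export
translate_cds <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  codons <- substring(dna, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  unname(GENETIC_CODE_TABLE[codons])
}

#' Annotate a point substitution
#'
#' Classifies a single-nucleotide substitution against one gene model:
#' `noncoding` outside the CDS, otherwise the affected codon is translated
#' before and after the change (reverse-complementing minus-strand genes) and
#' classified as `synonymous`, `nonsynonymous`, `stop_gained` or `stop_lost`.
#'
#' @param ref named character vector of contig sequences.
#' @param gene a `gene_model`.
#' @param pos 0-based genomic position of the substitution.
#' @param ref_base,alt_base reference and alternate base (must differ;
#'   `ref_base` must match the contig sequence at `pos`).
#' @return list with elements `category` and `aa_change` (e.g. `"G12D"`;
#'   stop codons are written `X`, so a truncating change reads `"Y140X"`;
#'   empty for synonymous/noncoding).
#' @export
annotate_variant <- function(ref, gene, pos, ref_base, alt_base) {
  seqlen <- nchar(ref[[gene$contig]])
  if (pos < 0L || pos >= seqlen) stop("position outside contig bounds")
  have <- substring(ref[[gene$contig]], pos + 1L, pos + 1L)
  if (have != ref_base) {
    stop(sprintf("ref base mismatch at %s:%d (have %s, given %s)",
                 gene$contig, pos, have, ref_base))
  }
  if (alt_base == ref_base) stop("alt_base equals ref_base")
  map <- .cds_genomic_positions(gene)
  idx <- match(pos, map)
  if (is.na(idx)) {
    return(list(category = "noncoding", aa_change = ""))
  }
  cds <- spliced_cds(ref, gene)
  codon_num <- (idx - 1L) %/% 3L + 1L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substring(cds, (codon_num - 1L) * 3L + 1L, codon_num * 3L)
  alt_in_cds <- if (gene$strand == "-") .COMPLEMENT[[alt_base]] else alt_base
  mut <- codon
  substring(mut, within, within) <- alt_in_cds
  ref_aa <- GENETIC_CODE_TABLE[[codon]]
  alt_aa <- GENETIC_CODE_TABLE[[mut]]
  fmt <- function(a) ifelse(a == "*", "X", a)
  if (ref_aa == alt_aa) {
    list(category = "synonymous", aa_change = "")
  } else if (alt_aa == "*") {
    list(category = "stop_gained",
         aa_change = paste0(fmt(ref_aa), codon_num, "X"))
  } else if (ref_aa == "*") {
    list(category = "stop_lost",
         aa_change = paste0("X", codon_num, fmt(alt_aa)))
  } else {
    list(category = "nonsynonymous",
         aa_change = paste0(ref_aa, codon_num, alt_aa))
  }
}

#' Annotate variants against a gene set
#'
#' Vectorized convenience wrapper: each variant is annotated against the gene
#' whose CDS contains it (or `noncoding` with empty `gene_id` if none does).
#'
#' @param ref named character vector of contig sequences.
#' @param genes list of `gene_model` objects.
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @return `variants` with added columns `gene_id`, `consequence`, `aa_change`.
#' @export
annotate_variants <- function(ref, genes, variants) {
  n <- nrow(variants)
  gene_id <- character(n); cons <- character(n); aa <- character(n)
  # index: per contig, a lookup from position to gene
  gene_of <- list()
  for (g in genes) {
    p <- .cds_genomic_positions(g)
    key <- g$contig
    m <- gene_of[[key]]
    if (is.null(m)) m <- new.env(parent = emptyenv())
    for (pp in p) assign(as.character(pp), g$gene_id, envir = m)
    gene_of[[key]] <- m
  }
  by_id <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  for (i in seq_len(n)) {
    m <- gene_of[[variants$contig[i]]]
    gid <- if (!is.null(m)) {
      get0(as.character(variants$pos[i]), envir = m, ifnotfound = NA_character_)
    } else NA_character_
    if (is.na(gid)) {
      gene_id[i] <- NA_character_; cons[i] <- "noncoding"; aa[i] <- ""
    } else {
      ann <- annotate_variant(ref, by_id[[gid]], variants$pos[i],
                              variants$ref[i], variants$alt[i])
      gene_id[i] <- gid; cons[i] <- ann$category; aa[i] <- ann$aa_change
    }
  }
  variants$gene_id <- gene_id
  variants$consequence <- cons
  variants$aa_change <- aa
  variants
}
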