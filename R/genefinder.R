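# Map selected chromosomal bins to the genes they contain, using a local
# GFF3 annotation (offline; the user supplies the annotation file).

# Normalize chromosome names across VCF / GFF3 dialects: strip a leading
# "Chr"/"chr" prefix and leading zeros ("Chr01" == "chr1" == "1").
normalize_chrom <- function(x) {
  x <- sub("^[Cc]hr", "", as.character(x))
  sub("^0+(?=.)", "", x, perl = TRUE)
}

#' Find genes overlapping selected chromosomal bins
#'
#' Reads `gene` features from a GFF3 file and pairs each selected bin with
#' every gene whose interval overlaps it by at least 1 bp (closed
#' intervals). Chromosome names are normalized on both sides before
#' matching; if the two files share no chromosome names after
#' normalization, the error lists both vocabularies.
#'
#' @param bins list of `chromosomal_bin` objects (e.g. the bins of the
#'   columns surviving [intersect_filters()]).
#' @param gff path to a GFF3 annotation file.
#' @return Data frame sorted by bin then gene start, with columns
#'   `bin_label`, `gene_id`, `chrom`, `start`, `end`, `annotation`.
#' @export
genes_in_regions <- function(bins, gff) {
  stopifnot(length(bins) > 0L, file.exists(gff))
  ann <- rtracklayer::readGFF(gff)
  ann <- ann[ann$type == "gene", , drop = FALSE]
  if (nrow(ann) == 0L) stop("no gene features in ", gff)
  gene_chr <- normalize_chrom(ann$seqid)
  bin_chr <- normalize_chrom(vapply(bins, `[[`, character(1), "chrom"))
  if (length(intersect(unique(gene_chr), unique(bin_chr))) == 0L) {
    stop("no shared chromosome names after normalization.\n  bins: ",
         paste(unique(bin_chr), collapse = ", "), "\n  GFF3: ",
         paste(unique(gene_chr), collapse = ", "))
  }
  gene_id <- if (!is.null(ann$ID)) ann$ID else ann$Name
  note <- if (!is.null(ann$Note)) {
    vapply(ann$Note, function(x) paste(unlist(x), collapse = "; "),
           character(1))
  } else if (!is.null(ann$description)) {
    as.character(ann$description)
  } else rep("", nrow(ann))
  genes_gr <- GenomicRanges::GRanges(
    seqnames = gene_chr,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end))
  bins_gr <- GenomicRanges::GRanges(
    seqnames = bin_chr,
    ranges = IRanges::IRanges(
      start = vapply(bins, `[[`, numeric(1), "start_bp"),
      end = vapply(bins, `[[`, numeric(1), "end_bp")))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(bins_gr, genes_gr, minoverlap = 1L))
  bi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    bin_label = bin_labels(bins)[bi],
    gene_id = as.character(gene_id[gi]),
    chrom = as.character(ann$seqid[gi]),
    start = ann$start[gi], end = ann$end[gi],
    annotation = note[gi],
    stringsAsFactors = FALSE)
  out[order(bi, out$start), , drop = FALSE]
}
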