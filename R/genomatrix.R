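# Genotype ingestion and LD-binned design matrix construction ("sum method").

#' Construct a variant table
#'
#' Low-level constructor used by [read_vcf()] and the synthetic-genotype
#' generator. Validates the invariants every downstream step relies on:
#' positions strictly increasing within each chromosome and reference-allele
#' counts in \{0, 1, 2\} where not missing.
#'
#' @param accession_ids character vector of accession labels (rows).
#' @param chrom character vector, per-SNP chromosome label (columns).
#' @param pos integer vector, per-SNP 1-based coordinate in bp.
#' @param ref_count accession x SNP integer matrix of reference-allele counts.
#' @param missing_mask accession x SNP logical matrix; `TRUE` marks a missing
#'   genotype call.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(accession_ids, chrom, pos, ref_count,
                          missing_mask = NULL) {
  ref_count <- as.matrix(ref_count)
  if (is.null(missing_mask)) {
    missing_mask <- is.na(ref_count)
  }
  missing_mask <- as.matrix(missing_mask)
  n_acc <- length(accession_ids)
  n_snp <- length(pos)
  if (n_acc < 1L || n_snp < 1L) {
    stop("variant_table needs at least 1 accession and 1 SNP")
  }
  stopifnot(
    length(chrom) == n_snp,
    nrow(ref_count) == n_acc, ncol(ref_count) == n_snp,
    all(dim(missing_mask) == dim(ref_count))
  )
  ok <- ref_count[!missing_mask]
  if (any(!ok %in% 0:2)) {
    stop("ref_count must lie in {0,1,2} where not missing")
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  dimnames(ref_count) <- list(accession_ids, NULL)
  structure(
    list(accession_ids = as.character(accession_ids),
         chrom = as.character(chrom), pos = as.integer(pos),
         ref_count = ref_count, missing_mask = missing_mask),
    class = "variant_table")
}

#' @method print variant_table
#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d accessions x %d biallelic SNPs on %d chromosome(s)\n",
              length(x$accession_ids), length(x$pos), length(unique(x$chrom))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(x$missing_mask)))
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped), keeps only biallelic SNP
#' records (single-base REF and ALT), and converts diploid genotypes to
#' reference-allele counts. Missing genotypes are flagged, never imputed.
#' Multiallelic and non-SNP records are dropped and the drop count reported
#' with a message.
#'
#' @param path path to a VCF file.
#' @param accession_subset optional character vector of sample names to
#'   retain; an error is raised if any is absent from the VCF header.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, accession_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (!is.null(accession_subset)) {
    missing <- setdiff(accession_subset, samples)
    if (length(missing) > 0L) {
      stop("accessions not in VCF header: ", paste(missing, collapse = ", "))
    }
  }
  ref <- vcfR::getREF(vcf)
  alt <- vcfR::getALT(vcf)
  keep <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(n_drop, " non-biallelic-SNP record(s) dropped")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")          # SNP x sample
  if (!is.null(accession_subset)) {
    gt <- gt[, accession_subset, drop = FALSE]
    samples <- accession_subset
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  miss <- is.na(gt) | a1 == "." | a2 == "." | a2 == ""
  rc <- (a1 == "0") + (a2 == "0")
  rc[miss] <- NA_integer_
  chrom <- vcfR::getCHROM(vcf)
  pos <- vcfR::getPOS(vcf)
  ord <- order(chrom, pos)
  variant_table(
    accession_ids = samples,
    chrom = chrom[ord], pos = pos[ord],
    ref_count = t(rc[ord, , drop = FALSE]),
    missing_mask = t(miss[ord, , drop = FALSE]))
}

#' Bin adjacent SNPs into chromosomal regions of at least a minimum span
#'
#' Implements the "sum method" region construction: per chromosome, a
#' left-to-right greedy scan opens a bin at the next unassigned SNP and
#' extends it with adjacent SNPs until the spanned region (last position
#' minus first position plus one) reaches `min_span_bp`. The final bin of a
#' chromosome may fall short of the minimum span; it is kept as-is and
#' flagged with a message. The default 50 kb exceeds the 3.5--35.5 kb range
#' over which linkage disequilibrium decays in *Sorghum bicolor*, so distinct
#' bins are unlikely to be in LD through linkage.
#'
#' @param vt a [variant_table()].
#' @param min_span_bp minimum bin span in bp (default 50,000).
#' @return A list of `chromosomal_bin` objects (fields `chrom`, `start_bp`,
#'   `end_bp`, `snp_indices`), genome-ordered.
#' @export
bin_variants <- function(vt, min_span_bp = 50000L) {
  stopifnot(inherits(vt, "variant_table"), min_span_bp >= 1)
  bins <- list()
  for (ch in unique(vt$chrom)) {
    idx <- which(vt$chrom == ch)
    if (length(idx) == 0L) {
      message("chromosome ", ch, " has no SNPs; skipped")
      next
    }
    pos <- vt$pos[idx]
    i <- 1L
    n <- length(idx)
    while (i <= n) {
      j <- i
      while (pos[j] - pos[i] + 1L < min_span_bp && j < n) j <- j + 1L
      if (pos[j] - pos[i] + 1L < min_span_bp) {
        message("trailing bin on chromosome ", ch, " spans ",
                pos[j] - pos[i] + 1L, " bp (< ", min_span_bp, ")")
      }
      bins[[length(bins) + 1L]] <- structure(
        list(chrom = ch, start_bp = pos[i], end_bp = pos[j],
             snp_indices = idx[i:j]),
        class = "chromosomal_bin")
      i <- j + 1L
    }
  }
  bins
}

bin_labels <- function(bins) {
  vapply(bins, function(b) sprintf("%s:%d-%d", b$chrom, b$start_bp, b$end_bp),
         character(1))
}

#' Build the normalized reference-allele dosage design matrix
#'
#' Entry (i, j) is the reference-allele count summed over the non-missing
#' SNPs of bin j in accession i, divided by twice the number of those SNPs:
#' a mean reference-allele dosage in \[0, 1\]. A cell whose SNPs are all
#' missing for an accession takes the bin's column mean over the remaining
#' accessions.
#'
#' @param vt a [variant_table()].
#' @param bins output of [bin_variants()]; the bins must partition `vt`'s SNPs.
#' @return An object of class `design_matrix` with fields `row_ids`, `bins`,
#'   `values` (rows x bins numeric matrix) and `level` (`"accession"`).
#' @export
build_design_matrix <- function(vt, bins) {
  stopifnot(inherits(vt, "variant_table"), length(bins) > 0L)
  covered <- sort(unlist(lapply(bins, `[[`, "snp_indices")))
  if (!identical(covered, seq_along(vt$pos))) {
    stop("bins must partition the variant table's SNPs")
  }
  n_acc <- length(vt$accession_ids)
  vals <- matrix(NA_real_, n_acc, length(bins),
                 dimnames = list(vt$accession_ids, bin_labels(bins)))
  for (j in seq_along(bins)) {
    idx <- bins[[j]]$snp_indices
    if (length(idx) == 0L) stop("bin ", j, " contains no SNPs")
    rc <- vt$ref_count[, idx, drop = FALSE]
    obs <- !vt$missing_mask[, idx, drop = FALSE]
    rc[!obs] <- 0
    n_obs <- rowSums(obs)
    v <- rowSums(rc) / (2 * n_obs)        # NaN where n_obs == 0
    if (anyNA(v) || any(is.nan(v))) {
      v[is.nan(v)] <- NA_real_
      v[is.na(v)] <- mean(v, na.rm = TRUE)
    }
    vals[, j] <- v
  }
  structure(
    list(row_ids = vt$accession_ids, bins = bins, values = vals,
         level = "accession"),
    class = "design_matrix")
}

#' @method print design_matrix
#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d %s rows x %d chromosomal bins\n",
              nrow(x$values), x$level, ncol(x$values)))
  invisible(x)
}

#' Join per-chromosome design matrices into one genome-wide matrix
#'
#' @param per_chrom list of `design_matrix` objects with identical `row_ids`
#'   in identical order.
#' @return A single `design_matrix` with columns concatenated in input
#'   (genome) order; bin provenance is preserved.
#' @export
join_chromosomes <- function(per_chrom) {
  stopifnot(length(per_chrom) >= 1L)
  ref_ids <- per_chrom[[1L]]$row_ids
  for (k in seq_along(per_chrom)) {
    ids <- per_chrom[[k]]$row_ids
    if (!identical(ids, ref_ids)) {
      bad <- unique(c(setdiff(ids, ref_ids), setdiff(ref_ids, ids)))
      if (length(bad) == 0L) bad <- ids[ids != ref_ids]  # same set, wrong order
      stop("row ids differ between matrices (offending rows: ",
           paste(utils::head(bad, 5), collapse = ", "), ")")
    }
  }
  structure(
    list(row_ids = ref_ids,
         bins = do.call(c, lapply(per_chrom, `[[`, "bins")),
         values = do.call(cbind, lapply(per_chrom, `[[`, "values")),
         level = per_chrom[[1L]]$level),
    class = "design_matrix")
}

#' Expand an accession-level design matrix to plant-level rows
#'
#' Each plant row is a copy of its accession's row, so the matrix rows align
#' with a per-plant observation vector.
#'
#' @param dm accession-level `design_matrix`.
#' @param plant_map named character vector mapping plant id (names) to
#'   accession id (values).
#' @return A plant-level `design_matrix` (possibly with zero rows).
#' @export
expand_to_plants <- function(dm, plant_map) {
  stopifnot(inherits(dm, "design_matrix"))
  if (length(plant_map) == 0L) {
    out <- dm
    out$row_ids <- character(0)
    out$values <- dm$values[0L, , drop = FALSE]
    out$level <- "plant"
    return(out)
  }
  unknown <- setdiff(unname(plant_map), dm$row_ids)
  if (length(unknown) > 0L) {
    stop("accessions not present in design matrix: ",
         paste(unique(unknown), collapse = ", "))
  }
  ridx <- match(unname(plant_map), dm$row_ids)
  structure(
    list(row_ids = names(plant_map), bins = dm$bins,
         values = `rownames<-`(dm$values[ridx, , drop = FALSE], names(plant_map)),
         level = "plant"),
    class = "design_matrix")
}

#' Write a design matrix and its bin manifest as TSV
#'
#' @param dm a `design_matrix`.
#' @param out_prefix path prefix; writes `<prefix>_design.tsv` (rows =
#'   row ids, columns = `chrom:start-end` bin labels) and `<prefix>_bins.tsv`
#'   (chrom, start, end, n_snps).
#' @return Invisibly, the two file paths.
#' @export
write_design_matrix <- function(dm, out_prefix) {
  f1 <- paste0(out_prefix, "_design.tsv")
  f2 <- paste0(out_prefix, "_bins.tsv")
  df <- data.frame(row_id = dm$row_ids, dm$values, check.names = FALSE)
  write.table(df, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    chrom = vapply(dm$bins, `[[`, character(1), "chrom"),
    start = vapply(dm$bins, `[[`, numeric(1), "start_bp"),
    end = vapply(dm$bins, `[[`, numeric(1), "end_bp"),
    n_snps = vapply(dm$bins, function(b) length(b$snp_indices), integer(1)))
  write.table(manifest, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read a design matrix written by [write_design_matrix()]
#'
#' @param design_tsv path to the `*_design.tsv` file.
#' @param bins_tsv optional path to the `*_bins.tsv` manifest; when given,
#'   bin provenance is restored.
#' @param level `"accession"` or `"plant"`.
#' @return A `design_matrix`.
#' @export
read_design_matrix <- function(design_tsv, bins_tsv = NULL,
                               level = "accession") {
  df <- read.table(design_tsv, sep = "\t", header = TRUE, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  bins <- vector("list", ncol(vals))
  if (!is.null(bins_tsv)) {
    mf <- read.table(bins_tsv, sep = "\t", header = TRUE)
    bins <- lapply(seq_len(nrow(mf)), function(i) {
      structure(list(chrom = as.character(mf$chrom[i]),
                     start_bp = mf$start[i], end_bp = mf$end[i],
                     snp_indices = integer(0)),
                class = "chromosomal_bin")
    })
  }
  structure(list(row_ids = df[[1L]], bins = bins, values = vals,
                 level = level),
            class = "design_matrix")
}
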