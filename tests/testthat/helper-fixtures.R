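# Shared fixture builders: everything is generated in code at test time.

# Identity-like fixed covariance structure over n observations.
diag_cov <- function(d) {
  structure(list(form = "fixed_blockdiag", d = d, matrix = NULL),
            class = "cov_structure")
}

dense_cov <- function(M) {
  structure(list(form = "mixed_dense", d = NULL, matrix = M),
            class = "cov_structure")
}

# Trait data with one plant per observation (accessions optionally shared).
make_td <- function(y, accession_ids = paste0("a", seq_along(y))) {
  trait_data(y, paste0("plant", seq_along(y)), accession_ids)
}

# A minimal ensemble object around a given sample matrix.
make_ensemble <- function(samples, hamiltonians = NULL, model = "linear") {
  samples <- as.matrix(samples)
  if (is.null(colnames(samples))) {
    colnames(samples) <- paste0("bin", seq_len(ncol(samples)))
  }
  if (is.null(hamiltonians)) hamiltonians <- rep(0, nrow(samples))
  structure(
    list(samples = samples, sigma_samples = NULL,
         hamiltonians = hamiltonians,
         traces = list(hamiltonian = hamiltonians, rates = NULL),
         config = NULL, model = model,
         accession_levels = NULL, n_obs = NA_integer_),
    class = "mine_ensemble")
}

# Random candidate pool with labelled rows.
make_pool <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("ACC%02d", seq_len(n)), NULL))
  candidate_pool(X)
}

# Hand-written VCF with 3 samples: two biallelic SNPs, one multiallelic
# record (must be dropped) and one missing call.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=Chr01,length=100000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("Chr01", "100", "s1", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("Chr01", "200", "s2", "C", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", sep = "\t"),
    paste("Chr01", "300", "s3", "T", "C", ".", "PASS", ".", "GT",
          "0/0", "./.", "0/1", sep = "\t")), path)
  path
}

# Independent recursive binning oracle (left-to-right, same contract as
# bin_variants but written as recursion over positions).
recursive_bins <- function(pos, min_span) {
  if (length(pos) == 0L) return(list())
  j <- 1L
  while (pos[j] - pos[1L] + 1L < min_span && j < length(pos)) j <- j + 1L
  c(list(seq_len(j)),
    lapply(recursive_bins(pos[-seq_len(j)], min_span),
           function(idx) idx + j))
}

# Random variant table (no missing data unless requested).
random_vt <- function(n_acc, n_snp, seed = 1, missing_rate = 0,
                      max_pos = 200000L) {
  set.seed(seed)
  pos <- sort(sample.int(max_pos, n_snp))
  rc <- matrix(sample(0:2, n_acc * n_snp, replace = TRUE), n_acc, n_snp)
  miss <- matrix(runif(n_acc * n_snp) < missing_rate, n_acc, n_snp)
  rc[miss] <- NA_integer_
  variant_table(paste0("A", seq_len(n_acc)), rep("Chr01", n_snp), pos,
                rc, miss)
}

# Batch-means Monte Carlo standard error per column (honest under the
# residual autocorrelation of a thinned chain).
batch_mcse <- function(samples, n_batch = 20L) {
  M <- nrow(samples)
  bsize <- floor(M / n_batch)
  bm <- sapply(seq_len(n_batch), function(b) {
    colMeans(samples[((b - 1L) * bsize + 1L):(b * bsize), , drop = FALSE])
  })
  if (is.null(dim(bm))) bm <- matrix(bm, nrow = 1L)
  apply(bm, 1L, sd) / sqrt(n_batch)
}

# Small GFF3 with gene features.
write_toy_gff <- function(path, df) {
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(df)), function(i) {
               paste(df$chrom[i], "phytozome", "gene", df$start[i],
                     df$end[i], ".", "+", ".",
                     sprintf("ID=%s;Note=%s", df$gene_id[i], df$note[i]),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}
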