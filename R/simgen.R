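# Synthetic genotypes, field panels and traits with the statistical
# structure the models assume, so every pipeline stage is exercisable
# without external downloads.

#' Simulation configuration
#'
#' Defaults mirror the organism and field protocol the toolkit targets:
#' SNPs every ~2.5 kb along each chromosome, a selfing rate of 0.85 (so
#' heterozygosity is strongly depressed relative to Hardy-Weinberg), and
#' accessions replicated as 6 plants in each of 3 randomized blocks.
#'
#' @param n_accessions number of accessions in the panel.
#' @param n_chrom number of chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param mean_snp_spacing_bp mean spacing between adjacent SNPs (bp);
#'   spacings are drawn exponential with this mean.
#' @param allele_freq_law function(n) returning n reference-allele
#'   frequencies (default uniform on \[0.1, 0.9\]).
#' @param selfing_rate selfing rate s in \[0, 1\]; genotypes carry the
#'   equilibrium inbreeding excess homozygosity F = s / (2 - s).
#' @param missing_rate per-call probability of a missing genotype.
#' @param n_causal_bins number of causal chromosomal bins.
#' @param effect_sizes causal-bin effects in trait-standard-deviation
#'   units; default `n_causal_bins` values evenly spaced in \[0.5, 2\] with
#'   alternating sign.
#' @param sigma_acc_law function(n) drawing per-accession variance-component
#'   scales (default uniform on \[0.1, 0.3\]).
#' @param sigma_resid residual standard deviation (trait units).
#' @param replicates_per_accession,n_blocks,n_years field layout.
#' @param seed RNG seed used by the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 50L, n_chrom = 2L,
                       snps_per_chrom = 60L, mean_snp_spacing_bp = 2500,
                       allele_freq_law = function(n) runif(n, 0.1, 0.9),
                       selfing_rate = 0.85, missing_rate = 0,
                       n_causal_bins = 3L, effect_sizes = NULL,
                       sigma_acc_law = function(n) runif(n, 0.1, 0.3),
                       sigma_resid = 0.5,
                       replicates_per_accession = 6L, n_blocks = 3L,
                       n_years = 1L, seed = 1L) {
  if (is.null(effect_sizes)) {
    effect_sizes <- seq(0.5, 2, length.out = n_causal_bins) *
      rep_len(c(1, -1), n_causal_bins)
  }
  stopifnot(n_accessions > 0, n_chrom > 0, snps_per_chrom > 0,
            mean_snp_spacing_bp > 0, selfing_rate >= 0, selfing_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            length(effect_sizes) == n_causal_bins,
            sigma_resid > 0, replicates_per_accession > 0, n_blocks > 0,
            n_years > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate biallelic SNP genotypes for a selfing population
#'
#' SNP positions are laid down with exponential spacings of the configured
#' mean; per accession and SNP, genotypes are drawn from the inbreeding
#' equilibrium with excess homozygosity `F = s / (2 - s)` implied by the
#' selfing rate s: P(het) = 2f(1-f)(1-F), with the remaining mass split
#' between the homozygotes in proportion to the allele frequencies.
#'
#' @param cfg a [sim_config()].
#' @param vcf_path optional path; when given, the genotypes are also
#'   written as a VCF 4.2 file readable by [read_vcf()].
#' @return A [variant_table()].
#' @export
simulate_genotypes <- function(cfg, vcf_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  acc <- sprintf("ACC%03d", seq_len(cfg$n_accessions))
  chrom <- rep(sprintf("Chr%02d", seq_len(cfg$n_chrom)),
               each = cfg$snps_per_chrom)
  pos <- unlist(lapply(seq_len(cfg$n_chrom), function(ch) {
    cumsum(1 + stats::rexp(cfg$snps_per_chrom,
                           1 / cfg$mean_snp_spacing_bp))
  }))
  pos <- as.integer(round(pos))
  # enforce strict increase after rounding
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- pos[i] + cumsum(c(0L, as.integer(diff(pos[i]) <= 0)))
  }
  n_snp <- length(pos)
  f <- cfg$allele_freq_law(n_snp)
  Fcoef <- cfg$selfing_rate / (2 - cfg$selfing_rate)
  p_het <- 2 * f * (1 - f) * (1 - Fcoef)
  p_homref <- f^2 + Fcoef * f * (1 - f)
  u <- matrix(runif(cfg$n_accessions * n_snp), cfg$n_accessions, n_snp)
  rc <- matrix(0L, cfg$n_accessions, n_snp)
  rc[sweep(u, 2L, p_homref, `<`)] <- 2L
  het <- !sweep(u, 2L, p_homref, `<`) &
    sweep(u, 2L, p_homref + p_het, `<`)
  rc[het] <- 1L
  miss <- matrix(runif(cfg$n_accessions * n_snp) < cfg$missing_rate,
                 cfg$n_accessions, n_snp)
  rc_na <- rc
  rc_na[miss] <- NA_integer_
  vt <- variant_table(acc, chrom, pos, rc_na, miss)
  if (!is.null(vcf_path)) write_vcf(vt, vcf_path)
  vt
}

#' Write a variant table as a VCF 4.2 text file
#'
#' @param vt a [variant_table()].
#' @param path output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path) {
  bases <- c("A", "C", "G", "T")
  n_snp <- length(vt$pos)
  ref <- rep_len(bases, n_snp)
  alt <- rep_len(bases[c(3, 4, 1, 2)], n_snp)
  gt_code <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
  gt <- matrix("./.", nrow(vt$ref_count), n_snp)
  obs <- !vt$missing_mask
  gt[obs] <- gt_code[as.character(vt$ref_count[obs])]
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    vapply(unique(vt$chrom), function(ch) {
      sprintf("##contig=<ID=%s,length=%d>",
              ch, max(vt$pos[vt$chrom == ch]) + 1000L)
    }, character(1)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$accession_ids), collapse = "\t"))
  body <- vapply(seq_len(n_snp), function(i) {
    paste(c(vt$chrom[i], vt$pos[i], sprintf("snp%d", i), ref[i], alt[i],
            ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Build the replicated field layout for a simulated panel
#'
#' @param cfg a [sim_config()].
#' @param accession_ids accession labels to replicate.
#' @return Data frame with columns `plant_id`, `accession_id`, `year`,
#'   `block` (one row per plant observation).
#' @export
field_layout <- function(cfg, accession_ids) {
  grid <- expand.grid(accession_id = accession_ids,
                      rep = seq_len(cfg$replicates_per_accession),
                      block = seq_len(cfg$n_blocks),
                      year = seq_len(cfg$n_years),
                      stringsAsFactors = FALSE)
  grid$plant_id <- sprintf("Y%d_B%d_%s_r%d", grid$year, grid$block,
                           grid$accession_id, grid$rep)
  grid[, c("plant_id", "accession_id", "year", "block")]
}

#' Simulate trait observations over a design matrix
#'
#' Chooses `n_causal_bins` causal columns, assigns them the configured
#' effects (scaled so one effect unit is one standard deviation of the
#' column-dosage spread), and draws
#' `Y = X beta + (mixed only: accession-structured random contribution
#' with the mixed-model covariance) + N(0, sigma_resid^2)` noise.
#'
#' @param cfg a [sim_config()].
#' @param X plant-level `design_matrix`.
#' @param td_frame data frame from [field_layout()] aligned with the rows
#'   of `X`.
#' @param model `"linear"` or `"mixed"`.
#' @param causal_bins optional integer indices of the causal columns;
#'   drawn at random by default.
#' @return List with `td` (a [trait_data()]) and `truth` (causal bin
#'   indices, effect vector beta, variance components).
#' @export
simulate_traits <- function(cfg, X, td_frame, model = c("linear", "mixed"),
                            causal_bins = NULL) {
  model <- match.arg(model)
  Xm <- design_values(X)
  p <- ncol(Xm)
  set.seed(cfg$seed + 1L)
  if (is.null(causal_bins)) {
    causal_bins <- sort(sample.int(p, cfg$n_causal_bins))
  }
  if (any(causal_bins < 1L | causal_bins > p)) {
    stop("causal bin index out of range")
  }
  beta <- numeric(p)
  # effect unit = sd of the dosage column, so effects are comparable
  col_sd <- apply(Xm[, causal_bins, drop = FALSE], 2L, sd)
  col_sd[col_sd == 0] <- 1
  beta[causal_bins] <- cfg$effect_sizes / col_sd
  n <- nrow(Xm)
  mean_part <- drop(Xm %*% beta)
  sigma_acc <- NULL
  acc_part <- 0
  if (model == "mixed") {
    acc_levels <- unique(td_frame$accession_id)
    acc_index <- match(td_frame$accession_id, acc_levels)
    sigma_acc <- cfg$sigma_acc_law(length(acc_levels))
    # random contribution with covariance G diag(sigma^2) G (G = XX')
    G <- tcrossprod(Xm)
    s_obs <- sigma_acc[acc_index]
    acc_part <- drop(G %*% (s_obs * rnorm(n)))
  }
  y <- mean_part + acc_part + rnorm(n, sd = cfg$sigma_resid)
  td <- trait_data(y, td_frame$plant_id, td_frame$accession_id,
                   year = td_frame$year, block = td_frame$block)
  list(td = td,
       truth = list(causal_bins = causal_bins, beta = beta,
                    sigma_acc = sigma_acc, sigma_resid = cfg$sigma_resid,
                    model = model))
}

#' Power / false-positive-rate study over simulated replicates
#'
#' Per replicate: simulate genotypes, bin them, build the plant-level
#' design matrix, simulate a trait with known causal bins, fit the linear
#' model ensemble, apply the Bayesian-interval and Benjamini-Hochberg
#' filters, and compare the surviving bins to the truth. Power is the
#' fraction of causal bins detected; FPR the fraction of non-causal bins
#' kept.
#'
#' @param cfg a [sim_config()] (its `seed` is offset per replicate).
#' @param n_replicates number of simulation replicates.
#' @param mcmc_cfg sampler configuration for the per-replicate fits.
#' @param alpha,level filter settings.
#' @return Data frame with one row per replicate: `replicate`, `power`,
#'   `fpr`, `n_bins`, `n_causal`. Replicates with no causal bins report
#'   `power = NA`.
#' @export
power_fpr_study <- function(cfg, n_replicates = 10L,
                            mcmc_cfg = mcmc_config(
                              n_equil_sweeps = 4000L, n_decorr_sweeps = 5L,
                              n_accumulate = 400L, adjust_every = 500L,
                              rate_window = 500L),
                            alpha = 0.05, level = 0.95) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * r
    vt <- simulate_genotypes(cfg_r)
    bins <- bin_variants(vt)
    dm <- build_design_matrix(vt, bins)
    layout <- field_layout(cfg_r, dm$row_ids)
    pm <- setNames(layout$accession_id, layout$plant_id)
    Xp <- expand_to_plants(dm, pm)
    sim <- simulate_traits(cfg_r, Xp, layout, model = "linear")
    V <- v_fixed(sim$td)
    mcmc_cfg$seed <- cfg_r$seed + 7L
    e <- run_chain("linear", Xp, sim$td, mcmc_cfg, V = V)
    keep <- bayesian_interval(e, level = level) &
      benjamini_hochberg(e, alpha = alpha)
    causal <- seq_len(ncol(Xp$values)) %in% sim$truth$causal_bins
    n_causal <- sum(causal)
    rows[[r]] <- data.frame(
      replicate = r,
      power = if (n_causal > 0) sum(keep & causal) / n_causal else NA_real_,
      fpr = sum(keep & !causal) / sum(!causal),
      n_bins = length(keep), n_causal = n_causal)
  }
  do.call(rbind, rows)
}
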