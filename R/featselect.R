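# Feature selection on parameter ensembles: linear projection, Bayesian
# interval, Benjamini-Hochberg, their intersection, the single-column
# negative control, and the year-effect likelihood-ratio machinery.

#' Project ensemble coefficients onto the data-constrained subspace
#'
#' With fewer observations than bins (n < p), coefficient directions in the
#' null space of \eqn{X'V^{-1}X} are unconstrained by the data and wander
#' during the random walk. This filter eigendecomposes \eqn{X'V^{-1}X},
#' rotates each stored coefficient vector into the eigenbasis, zeroes the
#' coordinates whose eigenvalue falls below `rel_tol` times the largest
#' eigenvalue (exactly the components "from n+1 on" when X has rank n), and
#' rotates back. Fitted values \eqn{X\beta} are unchanged, so for the
#' linear model the stored Hamiltonians remain valid.
#'
#' @param e a `mine_ensemble`.
#' @param X the plant-level design matrix the ensemble was fitted on.
#' @param V the residual `cov_structure` used in the fit.
#' @param rel_tol eigenvalues below `rel_tol * lambda_max` are treated as
#'   zero (default 1e-10).
#' @return The ensemble with projected `samples`; the number of retained
#'   eigendirections is stored as attribute `"rank_kept"`.
#' @export
linear_projection <- function(e, X, V, rel_tol = 1e-10) {
  Xm <- design_values(X)
  Vm <- cov_matrix(V)
  A <- crossprod(Xm, solve(Vm, Xm))
  A <- (A + t(A)) / 2
  ed <- eigen(A, symmetric = TRUE)        # eigenvalues descending
  keep <- ed$values >= rel_tol * max(ed$values)
  R_keep <- ed$vectors[, keep, drop = FALSE]
  proj <- tcrossprod(R_keep)              # R_keep R_keep'
  out <- e
  out$samples <- e$samples %*% proj
  colnames(out$samples) <- colnames(e$samples)
  attr(out, "rank_kept") <- sum(keep)
  out
}

#' Bayesian interval filter
#'
#' Keeps a parameter only when its equal-tailed ensemble interval excludes
#' zero: per parameter the M stored values are sorted and the empirical
#' 2.5% and 97.5% quantiles taken as the values at indices
#' `ceil(0.025 M)` and `ceil(0.975 M)`; the parameter is removed when the
#' lower bound is below zero and the upper bound above.
#'
#' @param e a `mine_ensemble` with at least 40 stored samples.
#' @param level interval coverage (default 0.95).
#' @return Logical keep mask with attributes `"lower"` and `"upper"`
#'   (the interval bounds per parameter).
#' @export
bayesian_interval <- function(e, level = 0.95) {
  B <- e$samples
  M <- nrow(B)
  stopifnot(M >= 40L, level > 0, level < 1)
  q <- (1 - level) / 2
  i_lo <- ceiling(q * M)
  i_hi <- ceiling((1 - q) * M)
  sorted <- apply(B, 2L, sort)
  lower <- sorted[i_lo, ]
  upper <- sorted[i_hi, ]
  keep <- !(lower < 0 & upper > 0)
  names(keep) <- colnames(B)
  attr(keep, "lower") <- lower
  attr(keep, "upper") <- upper
  keep
}

#' Benjamini-Hochberg filter on ensemble z-scores
#'
#' Per parameter, z = ensemble mean / ensemble standard deviation and a
#' two-sided p-value from the standard normal. The default `"step-up"`
#' variant is the standard Benjamini-Hochberg rule (keep all parameters of
#' rank up to the largest k with \eqn{p_{(k)} \le (k/m)\alpha}); the
#' `"literal"` variant compares each sorted p-value to its own critical
#' value independently, which keeps a subset of the step-up survivors.
#' Zero-variance parameters are excluded with a warning.
#'
#' @param e a `mine_ensemble`.
#' @param alpha false discovery rate (default 0.05).
#' @param variant `"step-up"` or `"literal"`.
#' @return Logical keep mask with attributes `"z"` and `"p"`.
#' @export
benjamini_hochberg <- function(e, alpha = 0.05,
                               variant = c("step-up", "literal")) {
  variant <- match.arg(variant)
  B <- e$samples
  mu <- colMeans(B)
  sdv <- apply(B, 2L, sd)
  z <- rep(NA_real_, ncol(B))
  ok <- sdv > 0
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance parameter(s) excluded from BH")
  }
  z[ok] <- mu[ok] / sdv[ok]
  p <- 2 * pnorm(-abs(z))
  keep <- rep(FALSE, ncol(B))
  if (any(ok)) {
    if (variant == "step-up") {
      keep[ok] <- p.adjust(p[ok], method = "BH") <= alpha
    } else {
      m <- sum(ok)
      ord <- order(p[ok])
      crit <- (seq_len(m) / m) * alpha
      lit <- logical(m)
      lit[ord] <- p[ok][ord] < crit
      keep[ok] <- lit
    }
  }
  names(keep) <- colnames(B)
  attr(keep, "z") <- z
  attr(keep, "p") <- p
  keep
}

#' Assemble the three-filter feature report for one fitted model
#'
#' Applies the linear projection followed by the Bayesian interval (the
#' "projection" selection), the Bayesian interval on the raw ensemble, and
#' the Benjamini-Hochberg filter on the raw ensemble. Markers passing all
#' three filters form the final set.
#'
#' @param e a `mine_ensemble`.
#' @param X,V design matrix and residual covariance used in the fit
#'   (needed for the projection).
#' @param alpha FDR level for the BH filter.
#' @param level coverage for the Bayesian interval.
#' @return A `feature_report`: per-bin masks `kept_projection`,
#'   `kept_bayes`, `kept_bh`, the `z`/`p` vectors, interval bounds, and the
#'   model tag.
#' @export
feature_report <- function(e, X, V, alpha = 0.05, level = 0.95) {
  proj <- linear_projection(e, X, V)
  kp <- bayesian_interval(proj, level = level)
  kb <- bayesian_interval(e, level = level)
  kh <- benjamini_hochberg(e, alpha = alpha)
  labels <- colnames(e$samples)
  if (is.null(labels)) labels <- paste0("bin", seq_len(ncol(e$samples)))
  structure(
    list(bin_labels = labels,
         kept_projection = as.logical(kp),
         kept_bayes = as.logical(kb),
         kept_bh = as.logical(kh),
         z = attr(kh, "z"), p = attr(kh, "p"),
         lower = attr(kb, "lower"), upper = attr(kb, "upper"),
         model = e$model),
    class = "feature_report")
}

#' Intersect the three filters and count the Venn regions
#'
#' @param fr a [feature_report()] (or any list carrying the three masks).
#' @return List with `final` (AND of the masks) and `venn`, the seven
#'   region counts named by filter membership (`"projection"`,
#'   `"projection+bayes"`, ...).
#' @export
intersect_filters <- function(fr) {
  a <- fr$kept_projection
  b <- fr$kept_bayes
  c_ <- fr$kept_bh
  if (length(a) != length(b) || length(b) != length(c_)) {
    stop("filter mask length mismatch")
  }
  venn <- c(
    "projection" = sum(a & !b & !c_),
    "bayes" = sum(!a & b & !c_),
    "bh" = sum(!a & !b & c_),
    "projection+bayes" = sum(a & b & !c_),
    "projection+bh" = sum(a & !b & c_),
    "bayes+bh" = sum(!a & b & c_),
    "projection+bayes+bh" = sum(a & b & c_))
  list(final = a & b & c_, venn = venn)
}

#' Write a feature report as TSV
#'
#' One row per bin: label, z, p, interval bounds, the three filter flags
#' and the final (intersection) flag.
#'
#' @param fr a [feature_report()].
#' @param path output TSV path.
#' @return Invisibly, the data frame written.
#' @export
write_feature_report <- function(fr, path) {
  final <- intersect_filters(fr)$final
  df <- data.frame(
    bin = fr$bin_labels, z = fr$z, p = fr$p,
    lower_2.5 = fr$lower, upper_97.5 = fr$upper,
    kept_projection = fr$kept_projection,
    kept_bayes = fr$kept_bayes, kept_bh = fr$kept_bh,
    final = final)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Single-column regression scan (negative control)
#'
#' Regresses the trait on each design-matrix column separately by
#' generalized least squares (V-weighted, with intercept), converts each
#' slope to a z-score, and applies the Benjamini-Hochberg step-up across
#' columns. Because binned genotype columns are correlated, this
#' one-at-a-time scan overfits and keeps far more columns than the joint
#' ensemble filters -- it is provided as the comparison baseline, not a
#' recommended analysis.
#'
#' @param X plant-level design matrix.
#' @param td a [trait_data()].
#' @param V residual `cov_structure` (block-diagonal form).
#' @param alpha FDR level.
#' @return Logical keep mask with attributes `"z"` and `"p"`. Constant
#'   columns are excluded with a warning.
#' @export
one_at_a_time <- function(X, td, V, alpha = 0.05) {
  Xm <- design_values(X)
  y <- td$y
  w <- if (V$form == "fixed_blockdiag") 1 / V$d else 1 / diag(cov_matrix(V))
  p <- ncol(Xm)
  z <- rep(NA_real_, p)
  sw <- sum(w)
  yw <- sum(w * y) / sw
  for (j in seq_len(p)) {
    x <- Xm[, j]
    xw <- sum(w * x) / sw
    sxx <- sum(w * (x - xw)^2)
    if (sxx < .Machine$double.eps * sw) next   # constant column
    b <- sum(w * (x - xw) * (y - yw)) / sxx
    res <- y - yw - b * (x - xw)
    df_res <- length(y) - 2L
    s2 <- sum(w * res^2) / df_res
    z[j] <- b / sqrt(s2 / sxx)
  }
  if (anyNA(z)) warning(sum(is.na(z)), " constant column(s) excluded")
  pv <- 2 * pnorm(-abs(z))
  keep <- rep(FALSE, p)
  ok <- !is.na(pv)
  keep[ok] <- p.adjust(pv[ok], method = "BH") <= alpha
  names(keep) <- colnames(Xm)
  attr(keep, "z") <- z
  attr(keep, "p") <- pv
  keep
}

#' Year-effect likelihood-ratio test from ensemble Hamiltonians
#'
#' Compares a pooled (no-year) model fit against separate per-year fits:
#' the statistic is \eqn{2 (H_{noyear} - \sum_y H_y)} using each chain's
#' final stored Hamiltonian (since H = -ln Q, a better-fitting year model
#' makes the statistic positive). Because any single MCMC run's final
#' Hamiltonian is one draw from its ensemble, the statistic is also
#' resampled: each draw picks one stored Hamiltonian uniformly from every
#' ensemble, and the fraction of resampled statistics below zero counts the
#' votes for the no-year-effect hypothesis.
#'
#' @param e_noyear the pooled-model `mine_ensemble`.
#' @param e_years list of per-year `mine_ensemble`s (at least 2).
#' @param df degrees of freedom to report (the parameter-count difference,
#'   declared by the caller).
#' @param n_draws resampling draws (default 1000).
#' @return An `lrt_result`: `lambda_stat`, `df`, `hamiltonians`,
#'   `resample_histogram` (the draws), `frac_below_zero`.
#' @export
lrt_year_effect <- function(e_noyear, e_years, df = NA_integer_,
                            n_draws = 1000L) {
  stopifnot(length(e_years) >= 2L)
  tags <- vapply(e_years, `[[`, character(1), "model")
  if (length(unique(c(e_noyear$model, tags))) != 1L) {
    stop("model tags differ across ensembles: ",
         paste(unique(c(e_noyear$model, tags)), collapse = ", "))
  }
  h_no <- e_noyear$hamiltonians
  h_last_no <- h_no[length(h_no)]
  h_last_years <- vapply(e_years, function(e) {
    e$hamiltonians[length(e$hamiltonians)]
  }, numeric(1))
  stat <- 2 * (h_last_no - sum(h_last_years))
  draws <- replicate(n_draws, {
    hn <- h_no[sample.int(length(h_no), 1L)]
    hy <- vapply(e_years, function(e) {
      e$hamiltonians[sample.int(length(e$hamiltonians), 1L)]
    }, numeric(1))
    2 * (hn - sum(hy))
  })
  structure(
    list(lambda_stat = stat, df = df,
         hamiltonians = c(noyear = h_last_no, h_last_years),
         resample_histogram = draws,
         frac_below_zero = mean(draws < 0)),
    class = "lrt_result")
}

#' @method print lrt_result
#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("year-effect LRT: -2lnLambda = %.4f (df = %s), %.1f%% of %d resampled statistics below zero\n",
              x$lambda_stat, x$df, 100 * x$frac_below_zero,
              length(x$resample_histogram)))
  invisible(x)
}
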