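# Linear and mixed linear model machinery: covariance structures,
# Hamiltonians, ensemble log-probability and trait prediction.

#' Construct a trait-observation table
#'
#' One row per plant observation, paired with a plant-level design matrix.
#'
#' @param y numeric observation vector (trait units, e.g. log grams).
#' @param plant_ids,accession_ids character vectors, one entry per
#'   observation.
#' @param year,block optional per-observation factors.
#' @return An object of class `trait_data`.
#' @export
trait_data <- function(y, plant_ids, accession_ids, year = NULL,
                       block = NULL) {
  n <- length(y)
  stopifnot(all(is.finite(y)), length(plant_ids) == n,
            length(accession_ids) == n)
  if (is.null(year)) year <- rep(NA_integer_, n)
  if (is.null(block)) block <- rep(NA_integer_, n)
  structure(
    list(y = as.numeric(y), plant_ids = as.character(plant_ids),
         accession_ids = as.character(accession_ids),
         year = year, block = block),
    class = "trait_data")
}

#' Read a phenotype table from delimited text
#'
#' Expects a header with columns `plant_id`, `accession_id`, `year`, `block`
#' and one or more trait columns; the trait is chosen by name.
#'
#' @param path TSV/CSV file path (separator sniffed from the extension).
#' @param trait name of the trait column to use as the observation vector.
#' @return A [trait_data()] object.
#' @export
read_phenotypes <- function(path, trait) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  need <- c("plant_id", "accession_id", trait)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  keep <- is.finite(df[[trait]])
  df <- df[keep, , drop = FALSE]
  trait_data(df[[trait]], df$plant_id, df$accession_id,
             year = if ("year" %in% names(df)) df$year else NULL,
             block = if ("block" %in% names(df)) df$block else NULL)
}

#' Fixed block-diagonal residual covariance from accession sample variances
#'
#' For the linear fixed-effects model the residual covariance V is held
#' fixed: each observation's diagonal entry is the sample variance (n-1
#' denominator) of its accession's trait values. Accessions with a single
#' observation, or with sample variance below `floor`, take
#' `max(pooled within-accession variance, floor)` so V stays invertible.
#' If every accession is a singleton the global sample variance is used,
#' with a warning.
#'
#' @param td a [trait_data()].
#' @param floor variance floor in squared trait units (default 1e-6).
#' @return A `cov_structure` with `form = "fixed_blockdiag"`; the matrix is
#'   diagonal and stored as its diagonal vector `d`.
#' @export
v_fixed <- function(td, floor = 1e-6) {
  stopifnot(inherits(td, "trait_data"))
  acc <- td$accession_ids
  vs <- tapply(td$y, acc, stats::var)            # NA for singletons
  ns <- tapply(td$y, acc, length)
  multi <- !is.na(vs) & ns >= 2
  if (!any(multi)) {
    warning("all accessions are singletons; using global sample variance")
    pooled <- stats::var(td$y)
  } else {
    pooled <- sum((ns[multi] - 1) * vs[multi]) / sum(ns[multi] - 1)
  }
  fallback <- max(pooled, floor)
  vs[is.na(vs) | vs < floor] <- fallback
  d <- as.numeric(vs[acc])
  structure(list(form = "fixed_blockdiag", d = d, matrix = NULL),
            class = "cov_structure")
}

cov_matrix <- function(V) {
  if (!is.null(V$matrix)) V$matrix else diag(V$d, length(V$d))
}

#' Linear-model Hamiltonian (V-weighted sum of squared errors)
#'
#' Returns \eqn{(Y - X\beta)' V^{-1} (Y - X\beta)}: a distance between model
#' prediction and observation, zero exactly when the residual vanishes. Note
#' the fixed-effects Hamiltonian carries no 1/2 factor, so the stationary
#' ensemble of the Metropolis sampler has covariance
#' \eqn{\frac{1}{2}(X'V^{-1}X)^{-1}}.
#'
#' @param beta coefficient vector (one entry per design-matrix column).
#' @param X plant-level `design_matrix` or plain numeric matrix.
#' @param td a [trait_data()].
#' @param V a `cov_structure` from [v_fixed()] (or any SPD matrix form).
#' @return Nonnegative scalar.
#' @export
hamiltonian_linear <- function(beta, X, td, V) {
  Xm <- design_values(X)
  if (length(beta) != ncol(Xm) || nrow(Xm) != length(td$y)) {
    stop("nonconforming dimensions: beta ", length(beta), ", X ",
         nrow(Xm), "x", ncol(Xm), ", y ", length(td$y))
  }
  r <- td$y - drop(Xm %*% beta)
  if (V$form == "fixed_blockdiag") {
    sum(r * r / V$d)
  } else {
    drop(crossprod(r, solve(cov_matrix(V), r)))
  }
}

design_values <- function(X) {
  if (inherits(X, "design_matrix")) X$values else as.matrix(X)
}

#' Mixed-model observation covariance
#'
#' Builds the n x n covariance
#' \eqn{V = \sum_i (X x_i)(X x_i)' \sigma^2_{j(i)} + \sigma^2 I}
#' where the sum runs over the n plant observations, \eqn{x_i} is row i of
#' the plant-level design matrix and \eqn{j(i)} indexes the observation's
#' accession; equivalently \eqn{V = G \,\mathrm{diag}(\sigma^2_{j(i)})\, G +
#' \sigma^2 I} with the Gram matrix \eqn{G = XX'}. Replicate observations of
#' an accession each contribute a term, per the model's literal
#' per-observation sum.
#'
#' @param sigma_acc nonnegative numeric vector of per-accession scales
#'   (square roots of the variance components), named or ordered by
#'   `unique(acc_index)` levels.
#' @param sigma_resid residual scale (> 0).
#' @param X plant-level design matrix.
#' @param acc_index integer or character vector mapping each observation to
#'   its accession (position in `sigma_acc`).
#' @return A `cov_structure` with `form = "mixed_dense"`.
#' @export
v_mixed <- function(sigma_acc, sigma_resid, X, acc_index) {
  if (any(sigma_acc < 0)) stop("sigma_acc must be nonnegative")
  if (sigma_resid <= 0) stop("sigma_resid must be positive")
  Xm <- design_values(X)
  n <- nrow(Xm)
  stopifnot(length(acc_index) == n)
  if (is.character(acc_index)) {
    acc_index <- match(acc_index, names(sigma_acc))
    if (anyNA(acc_index)) stop("accession without a variance component")
  }
  s2 <- (sigma_acc[acc_index])^2
  G <- tcrossprod(Xm)
  V <- G %*% (s2 * G) + diag(sigma_resid^2, n)
  V <- (V + t(V)) / 2
  structure(list(form = "mixed_dense", d = NULL, matrix = V),
            class = "cov_structure")
}

#' Mixed-model Hamiltonian (negative multivariate-normal log density)
#'
#' Returns \eqn{\frac12 (Y-X\beta)'V^{-1}(Y-X\beta) + \frac{n}{2}\ln 2\pi +
#' \frac12 \ln|V|}, the negative log density of \eqn{N(X\beta, V)} at Y.
#' Unlike the fixed-effects Hamiltonian it can be negative when |V| is small.
#'
#' @inheritParams hamiltonian_linear
#' @param V a `cov_structure` from [v_mixed()] (must be positive definite).
#' @return Scalar.
#' @export
hamiltonian_mixed <- function(beta, X, td, V) {
  Xm <- design_values(X)
  if (length(beta) != ncol(Xm) || nrow(Xm) != length(td$y)) {
    stop("nonconforming dimensions")
  }
  Vm <- cov_matrix(V)
  n <- length(td$y)
  L <- tryCatch(chol(Vm), error = function(e) {
    stop("covariance not positive definite: ", conditionMessage(e))
  })
  r <- td$y - drop(Xm %*% beta)
  z <- backsolve(L, r, transpose = TRUE)
  0.5 * sum(z * z) + 0.5 * n * log(2 * pi) + sum(log(diag(L)))
}

#' Log ensemble probability up to normalization
#'
#' The Boltzmann ensemble is \eqn{Q(\beta, X) \propto e^{-H(\beta, X)}}; the
#' normalization cancels in every Metropolis ratio and is never computed.
#'
#' @param h finite Hamiltonian value.
#' @return `-h`.
#' @export
log_ensemble_prob <- function(h) {
  stopifnot(is.finite(h))
  -h
}

#' Model-averaged point predictions for candidate rows
#'
#' The predicted sample statistic for candidate k is its design row times
#' the coefficient vector.
#'
#' @param beta coefficient vector.
#' @param X_cand candidate `design_matrix` (accession level) or matrix.
#' @return Numeric vector, one prediction per candidate row.
#' @export
predict_trait <- function(beta, X_cand) {
  Xm <- design_values(X_cand)
  if (ncol(Xm) != length(beta)) stop("dimension mismatch")
  drop(Xm %*% beta)
}
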