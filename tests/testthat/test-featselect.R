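# Projection, interval and FDR filters, the negative control and the
# year-effect likelihood ratio.

test_that("linear projection is the identity on full-column-rank designs", {
  set.seed(1)
  X <- matrix(rnorm(40), 10, 4)                # n > p, full rank
  e <- make_ensemble(matrix(rnorm(80), 20, 4))
  proj <- linear_projection(e, X, diag_cov(rep(1, 10)))
  expect_equal(proj$samples, e$samples, tolerance = 1e-10)
  expect_equal(attr(proj, "rank_kept"), 4L)
})

test_that("linear projection zeroes null-space directions without changing fitted values", {
  # p = 2, n = 1, X = [[1, 0]]: X'X has eigenvalues (1, 0); the second
  # rotated coordinate is zeroed, so beta_p = (beta_1, 0)
  X <- matrix(c(1, 0), 1, 2)
  e <- make_ensemble(matrix(c(1, 5, -2, 7), 2, 2))
  proj <- linear_projection(e, X, diag_cov(1))
  expect_equal(attr(proj, "rank_kept"), 1L)
  expect_equal(unname(proj$samples), cbind(e$samples[, 1L], c(0, 0)))
  expect_equal(e$samples %*% t(X), proj$samples %*% t(X))
  # random rank-deficient X: fits are invariant for every ensemble member
  set.seed(2)
  n <- 6; p <- 12
  Xr <- matrix(rnorm(n * p), n, p)
  er <- make_ensemble(matrix(rnorm(50 * p, sd = 3), 50, p))
  pr <- linear_projection(er, Xr, diag_cov(runif(n, 0.5, 2)))
  expect_equal(attr(pr, "rank_kept"), n)
  fit0 <- er$samples %*% t(Xr)
  fit1 <- pr$samples %*% t(Xr)
  expect_lt(max(abs(fit1 - fit0)) / max(abs(fit0)), 1e-8)
})

test_that("the Bayesian interval filter keeps parameters whose ensemble interval excludes zero", {
  e <- make_ensemble(cbind(seq(0.5, 1.5, length.out = 100),
                           seq(-0.5, 0.5, length.out = 100)))
  keep <- bayesian_interval(e)
  expect_true(keep[[1L]])                      # all-positive: kept
  expect_false(keep[[2L]])                     # straddles zero: removed
  # calibration: ensemble centers ~ N(0,1) across parameters with unit
  # ensemble spread keep about 5% at level 0.95
  set.seed(3)
  n_par <- 200L; M <- 1000L
  mu <- rnorm(n_par)
  B <- sweep(matrix(rnorm(M * n_par), M, n_par), 2L, mu, `+`)
  kept <- sum(bayesian_interval(make_ensemble(B)))
  band <- qbinom(c(0.005, 0.995), n_par, 0.05)
  expect_gte(kept, band[1L])
  expect_lte(kept, band[2L])
})

test_that("the BH filter reproduces the hand-worked step-up example and dominates the literal variant", {
  # build two-point ensembles whose z-scores give the target p-values
  p_target <- c(0.001, 0.012, 0.014, 0.30, 0.90)
  M <- 1000L
  z <- qnorm(1 - p_target / 2)
  sd_fac <- sqrt(M / (M - 1))                  # two-point sample sd factor
  B <- sapply(z, function(zz) rep(c(-1, 1), M / 2) / sd_fac + zz)
  e <- make_ensemble(B)
  keep <- benjamini_hochberg(e, alpha = 0.05)
  expect_equal(as.logical(keep), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(keep, "p"), p_target, tolerance = 1e-10)
  # all p = 1: nothing kept
  e1 <- make_ensemble(matrix(rep(c(-1, 1), 50), 100, 4))
  expect_false(any(benjamini_hochberg(e1)))
  # single parameter with p = 0.04 at alpha = 0.05: kept
  e_one <- make_ensemble(matrix(rep(c(-1, 1), M / 2) / sd_fac +
                                  qnorm(1 - 0.02), M, 1))
  expect_true(all(benjamini_hochberg(e_one)))
  # step-up keeps a superset of the literal variant on random p-sets
  set.seed(4)
  for (rep_i in 1:10) {
    mu <- rnorm(30, sd = 1.5)
    Br <- sweep(matrix(rnorm(200 * 30), 200, 30), 2L, mu, `+`)
    er <- make_ensemble(Br)
    up <- benjamini_hochberg(er, variant = "step-up")
    lit <- benjamini_hochberg(er, variant = "literal")
    expect_true(all(up[lit]))                  # literal => step-up
  }
  # zero-variance parameters are excluded with a warning
  e_const <- make_ensemble(cbind(rep(1, 100), rnorm(100)))
  expect_warning(kc <- benjamini_hochberg(e_const), "zero-variance")
  expect_false(kc[[1L]])
})

test_that("filter intersection produces consistent Venn region counts", {
  fr <- list(kept_projection = c(TRUE, FALSE, FALSE),
             kept_bayes = c(FALSE, TRUE, FALSE),
             kept_bh = c(FALSE, FALSE, TRUE))
  out <- intersect_filters(fr)
  expect_false(any(out$final))                 # disjoint masks
  fr2 <- list(kept_projection = c(TRUE, FALSE), kept_bayes = c(TRUE, FALSE),
              kept_bh = c(TRUE, FALSE))
  expect_equal(intersect_filters(fr2)$final, c(TRUE, FALSE))
  # random masks vs set-algebra oracle
  set.seed(5)
  a <- runif(100) < 0.4; b <- runif(100) < 0.4; cc <- runif(100) < 0.4
  out3 <- intersect_filters(list(kept_projection = a, kept_bayes = b,
                                 kept_bh = cc))
  sets <- list(A = which(a), B = which(b), C = which(cc))
  oracle <- c(
    length(setdiff(sets$A, union(sets$B, sets$C))),
    length(setdiff(sets$B, union(sets$A, sets$C))),
    length(setdiff(sets$C, union(sets$A, sets$B))),
    length(setdiff(intersect(sets$A, sets$B), sets$C)),
    length(setdiff(intersect(sets$A, sets$C), sets$B)),
    length(setdiff(intersect(sets$B, sets$C), sets$A)),
    length(intersect(sets$A, intersect(sets$B, sets$C))))
  expect_equal(unname(out3$venn), oracle)
  expect_equal(sum(out3$final), oracle[7L])
  expect_error(intersect_filters(list(kept_projection = a, kept_bayes = b,
                                      kept_bh = cc[1:10])), "mismatch")
})

test_that("the one-at-a-time scan keeps strong signals, duplicates them, and stays near alpha under the null", {
  set.seed(6)
  n <- 120
  X <- matrix(runif(n * 20), n, 20)
  td_sig <- make_td(5 * X[, 1L] + rnorm(n, sd = 0.1))
  keep <- one_at_a_time(X, td_sig, diag_cov(rep(1, n)))
  expect_true(keep[[1L]])
  # duplicated causal column: both copies survive (the overfit this
  # control is meant to exhibit)
  Xd <- cbind(X, X[, 1L])
  keep_d <- one_at_a_time(Xd, td_sig, diag_cov(rep(1, n)))
  expect_true(keep_d[[1L]] && keep_d[[21L]])
  # null simulation: survivors average at most alpha * n_bins
  survivors <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(runif(60 * 200), 60, 200)
    tdn <- make_td(rnorm(60))
    sum(one_at_a_time(Xn, tdn, diag_cov(rep(1, 60)), alpha = 0.05))
  }, numeric(1))
  expect_lte(mean(survivors), 0.05 * 200)
  # constant columns are excluded with a warning
  Xc <- cbind(rep(1, n), X[, 1:3])
  expect_warning(kc <- one_at_a_time(Xc, td_sig, diag_cov(rep(1, n))),
                 "constant")
  expect_false(kc[[1L]])
})

test_that("the year-effect statistic and its resampled distribution behave as designed", {
  e_no <- make_ensemble(matrix(0, 50, 2), hamiltonians = rep(10, 50))
  e_y1 <- make_ensemble(matrix(0, 50, 2), hamiltonians = rep(4, 50))
  e_y2 <- make_ensemble(matrix(0, 50, 2), hamiltonians = rep(6, 50))
  out <- lrt_year_effect(e_no, list(e_y1, e_y2), df = 1L, n_draws = 100L)
  expect_equal(out$lambda_stat, 0)             # 2 * (10 - 4 - 6)
  expect_equal(out$frac_below_zero, 0)         # draws are exactly 0
  # all pooled Hamiltonians below the per-year sum: every draw negative
  e_no2 <- make_ensemble(matrix(0, 50, 2), hamiltonians = rep(5, 50))
  out2 <- lrt_year_effect(e_no2, list(e_y1, e_y2), n_draws = 200L)
  expect_equal(out2$frac_below_zero, 1)
  # small-set resampling matches full enumeration of draw combinations
  h_no <- c(9, 11, 13); h_a <- c(4, 6); h_b <- c(5, 7)
  grid <- expand.grid(h_no, h_a, h_b)
  oracle_frac <- mean(2 * (grid[, 1] - grid[, 2] - grid[, 3]) < 0)
  e_no3 <- make_ensemble(matrix(0, 3, 2), hamiltonians = h_no)
  e_a <- make_ensemble(matrix(0, 2, 2), hamiltonians = h_a)
  e_b <- make_ensemble(matrix(0, 2, 2), hamiltonians = h_b)
  set.seed(7)
  out3 <- lrt_year_effect(e_no3, list(e_a, e_b), n_draws = 1000L)
  expect_equal(out3$frac_below_zero, oracle_frac, tolerance = 0.03)
  # model tags must agree
  e_mix <- make_ensemble(matrix(0, 2, 2), hamiltonians = h_a,
                         model = "mixed")
  expect_error(lrt_year_effect(e_no3, list(e_a, e_mix)), "model tags")
})

test_that("feature_report wires the three filters together over a fitted ensemble", {
  set.seed(8)
  n <- 60; p <- 10
  X <- matrix(runif(n * p), n, p)
  beta <- numeric(p); beta[3L] <- 4
  y <- drop(X %*% beta) + rnorm(n, sd = 0.3)
  acc <- rep(sprintf("a%02d", 1:(n / 3)), each = 3)
  td <- trait_data(y, paste0("pl", 1:n), acc)
  V <- v_fixed(td)
  cfg <- mcmc_config(n_equil_sweeps = 800L, n_decorr_sweeps = 2L,
                     n_accumulate = 300L, adjust_every = 200L,
                     rate_window = 200L, seed = 5L)
  e <- run_chain("linear", X, td, cfg, V = V)
  fr <- feature_report(e, X, V)
  expect_s3_class(fr, "feature_report")
  out <- intersect_filters(fr)
  expect_true(out$final[3L])                   # the causal bin survives
  expect_equal(length(out$final), p)
  expect_equal(sum(out$venn), sum(fr$kept_projection | fr$kept_bayes |
                                    fr$kept_bh))
  df <- write_feature_report(fr, tempfile(fileext = ".tsv"))
  expect_equal(nrow(df), p)
})
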