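# MINE scoring (prediction-covariance determinants) and panel selectors.

# Exhaustive search oracle for the best p_a-subset by log-determinant.
exhaustive_best <- function(e, pool, p_a, criterion = "covariance") {
  combos <- combn(length(pool$accession_ids), p_a)
  scores <- apply(combos, 2L, function(idx) {
    score_subset(e, pool, pool$accession_ids[idx],
                 criterion = criterion)$log_det
  })
  list(score = max(scores), scores = scores,
       subset = pool$accession_ids[combos[, which.max(scores)]])
}

test_that("prediction moments are ensemble averages of candidate predictions", {
  # degenerate ensemble of identical members: second moments factorize
  pool <- make_pool(4, 3, seed = 1)
  e_const <- make_ensemble(matrix(rep(c(1, 2, -1), each = 10), 10, 3))
  mom <- prediction_moments(e_const, pool, pool$accession_ids[1:3])
  expect_equal(unname(mom$second), unname(tcrossprod(mom$first)),
               tolerance = 1e-12)
  # two-member ensemble with predictions {1, 3}: E[G] = 2, E[G^2] = 5
  pool1 <- candidate_pool(matrix(1, 1, 1, dimnames = list("A", NULL)))
  e2 <- make_ensemble(matrix(c(1, 3), 2, 1))
  mom2 <- prediction_moments(e2, pool1, "A")
  expect_equal(unname(mom2$first), 2)
  expect_equal(unname(mom2$second[1, 1]), 5)
  # random 5-member x 3-candidate case vs a double loop
  set.seed(2)
  pool3 <- make_pool(3, 4, seed = 3)
  e5 <- make_ensemble(matrix(rnorm(20), 5, 4))
  mom3 <- prediction_moments(e5, pool3, pool3$accession_ids)
  P <- matrix(NA_real_, 3, 5)
  for (i in 1:5) for (k in 1:3) P[k, i] <- sum(pool3$X[k, ] * e5$samples[i, ])
  first <- rowMeans(P)
  second <- matrix(0, 3, 3)
  for (k in 1:3) for (j in 1:3) second[k, j] <- mean(P[k, ] * P[j, ])
  expect_equal(unname(mom3$first), first)
  expect_equal(unname(mom3$second), second)
  expect_error(prediction_moments(e5, pool3, "NOPE"), "NOPE")
})

test_that("subset scores are covariance/correlation log-determinants with an eigenvalue floor", {
  pool <- make_pool(5, 3, seed = 4)
  set.seed(5)
  e <- make_ensemble(matrix(rnorm(60), 20, 3))
  # K = 1 under correlation: matrix [1], log det 0
  s1 <- score_subset(e, pool, pool$accession_ids[1L],
                     criterion = "correlation")
  expect_equal(s1$matrix, matrix(1, 1, 1,
                                 dimnames = list(pool$accession_ids[1L],
                                                 pool$accession_ids[1L])))
  expect_equal(s1$log_det, 0)
  # identical ensemble members: zero covariance, log det at the floor
  e0 <- make_ensemble(matrix(1, 10, 3))
  s0 <- score_subset(e0, pool, pool$accession_ids[1:2])
  expect_true(all(abs(s0$matrix) < 1e-12))
  expect_true(s0$log_det < -40)                # 2 * log(1e-12)
  expect_error(score_subset(e0, pool, pool$accession_ids[1:2],
                            criterion = "correlation"),
               "zero prediction variance")
  # permutation invariance of the score
  sub <- pool$accession_ids[c(1, 3, 4)]
  expect_equal(score_subset(e, pool, sub)$log_det,
               score_subset(e, pool, rev(sub))$log_det, tolerance = 1e-12)
})

test_that("eigenvalue-product determinants match LU determinants on random PSD matrices", {
  set.seed(6)
  for (K in c(2, 10, 50)) {
    A <- matrix(rnorm(K * (K + 5)), K + 5, K)
    D <- crossprod(A) / (K + 5)                # full-rank PSD
    ld <- minegwas:::log_det_psd(D)$log_det
    expect_equal(ld, determinant(D, logarithm = TRUE)$modulus[[1]],
                 tolerance = 1e-8)
  }
})

test_that("suboptimal tuple selection equals an enumerate-sort-harvest oracle", {
  set.seed(7)
  pool4 <- make_pool(4, 3, seed = 7)
  e <- make_ensemble(matrix(rnorm(30), 10, 3))
  # p_t = p_a = 3: the answer is the argmax triple over all 4 triples
  res <- select_suboptimal(e, pool4, p_t = 3L, p_a = 3L)
  best <- exhaustive_best(e, pool4, 3L)
  expect_setequal(res$selected, best$subset)
  # pool of 8, p_t = 2, p_a = 4 vs independent oracle
  pool8 <- make_pool(8, 4, seed = 8)
  e8 <- make_ensemble(matrix(rnorm(60), 15, 4))
  res8 <- select_suboptimal(e8, pool8, p_t = 2L, p_a = 4L)
  combos <- combn(8, 2)
  scores <- apply(combos, 2L, function(idx) {
    score_subset(e8, pool8, pool8$accession_ids[idx])$log_det
  })
  harvest <- character(0)
  for (t in order(-scores)) {
    for (lab in pool8$accession_ids[combos[, t]]) {
      if (!(lab %in% harvest) && length(harvest) < 4L) {
        harvest <- c(harvest, lab)
      }
    }
  }
  expect_equal(res8$selected, harvest)
  # p_t must divide p_a; enumeration budget enforced
  expect_error(select_suboptimal(e8, pool8, p_t = 3L, p_a = 4L), "divide")
  expect_error(select_suboptimal(e8, pool8, p_t = 2L, p_a = 4L,
                                 max_tuples = 3), "budget")
  # total tie (identical candidate rows) is still deterministic
  Xsame <- matrix(1, 5, 3, dimnames = list(paste0("T", 5:1), NULL))
  pool_t <- candidate_pool(Xsame)
  res_t1 <- select_suboptimal(e, pool_t, p_t = 1L, p_a = 2L)
  res_t2 <- select_suboptimal(e, pool_t, p_t = 1L, p_a = 2L)
  expect_identical(res_t1$selected, res_t2$selected)
  expect_equal(res_t1$selected, c("T1", "T2"))  # lexicographic tie-break
})

test_that("Monte Carlo selection is a Metropolis swap search returning the best-seen subset", {
  pool <- make_pool(10, 3, seed = 9)
  set.seed(9)
  e <- make_ensemble(matrix(rnorm(36), 12, 3))
  # m = 0 returns the scored initial subset
  r0 <- select_monte_carlo(e, pool, 3L, m = 0L, seed = 1L)
  expect_length(r0$selected, 3L)
  expect_length(r0$score_trace, 1L)
  # best-seen trace is non-decreasing by construction
  r1 <- select_monte_carlo(e, pool, 3L, m = 500L, seed = 2L)
  expect_true(all(diff(r1$score_trace) >= 0))
  # hits the exhaustive optimum in >= 4/5 seeds
  best <- exhaustive_best(e, pool, 3L)
  hits <- vapply(1:5, function(s) {
    r <- select_monte_carlo(e, pool, 3L, m = 2000L, seed = s)
    isTRUE(all.equal(r$score_trace[length(r$score_trace)], best$score,
                     tolerance = 1e-10))
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("the combined tuple selector matches per-round brute force", {
  pool6 <- make_pool(6, 3, seed = 10)
  set.seed(10)
  e <- make_ensemble(matrix(rnorm(45), 15, 3))
  res <- select_nc3plus2(e, pool6, p_a = 5L)
  # round 1: best triple; round 2: best doublet given the triple
  b1 <- exhaustive_best(e, pool6, 3L)
  expect_setequal(res$selected[1:3], b1$subset)
  rest <- setdiff(pool6$accession_ids, b1$subset)
  pairs <- combn(rest, 2)
  s2 <- apply(pairs, 2L, function(pr) {
    score_subset(e, pool6, c(b1$subset, pr))$log_det
  })
  expect_setequal(res$selected[4:5], pairs[, which.max(s2)])
  # p_a = p_t1 reduces to the top tuple alone
  res3 <- select_nc3plus2(e, pool6, p_a = 3L)
  expect_setequal(res3$selected, b1$subset)
  # infeasible panel size errors
  expect_error(select_nc3plus2(e, pool6, p_a = 7L), "p_a")
})

test_that("greedy selection equals a one-step-lookahead oracle and nears the exhaustive optimum", {
  pool5 <- make_pool(5, 3, seed = 11)
  set.seed(11)
  e <- make_ensemble(matrix(rnorm(30), 10, 3))
  res <- select_greedy(e, pool5, p_a = 4L)
  b1 <- exhaustive_best(e, pool5, 3L)
  expect_setequal(res$selected[1:3], b1$subset)
  rest <- setdiff(pool5$accession_ids, b1$subset)
  s_add <- vapply(rest, function(a) {
    score_subset(e, pool5, c(b1$subset, a))$log_det
  }, numeric(1))
  expect_equal(res$selected[4L], names(which.max(s_add)))
  # p_a = 3 is exactly the top triple
  expect_setequal(select_greedy(e, pool5, p_a = 3L)$selected, b1$subset)
  # across 20 random ensembles on pools <= 10: greedy gap <= 5% of range
  ok <- 0L
  for (seed in 1:20) {
    pool <- make_pool(8, 3, seed = 100 + seed)
    set.seed(200 + seed)
    er <- make_ensemble(matrix(rnorm(30), 10, 3))
    best <- exhaustive_best(er, pool, 3L)
    g <- select_greedy(er, pool, p_a = 3L)
    gap <- best$score - g$score_trace[length(g$score_trace)]
    range_ <- max(best$scores) - min(best$scores)
    if (gap <= 0.05 * range_) ok <- ok + 1L
  }
  expect_equal(ok, 20L)
})

test_that("selector comparison tables are reproducible and bounded by the exhaustive optimum", {
  pool <- make_pool(8, 3, seed = 12)
  set.seed(12)
  e <- make_ensemble(matrix(rnorm(24), 8, 3))
  tab <- compare_selectors(e, pool, p_a = 3L, selectors = "greedy",
                           n_repeats = 3L)
  expect_equal(length(unique(tab$log_det)), 1L)  # deterministic selector
  tab2 <- compare_selectors(e, pool, p_a = 3L,
                            selectors = c("greedy", "random"),
                            n_repeats = 10L)
  m <- tapply(tab2$log_det, tab2$algorithm, mean)
  expect_gte(m[["greedy"]], m[["random"]])
  best <- exhaustive_best(e, pool, 3L)
  expect_true(all(tab2$log_det <= best$score + 1e-10))
})

test_that("adding a prediction-orthogonal candidate multiplies det(D) by its prediction variance", {
  # ensemble with independent coordinates and identity candidate rows:
  # predictions are the coordinates themselves, so D is diagonal
  set.seed(13)
  B <- cbind(rnorm(200, sd = 1), rnorm(200, sd = 2), rnorm(200, sd = 0.5))
  B <- scale(B, center = TRUE, scale = FALSE)
  B[, 3] <- lm.fit(B[, 1:2], B[, 3])$residuals  # exact sample orthogonality
  e <- make_ensemble(B)
  pool <- candidate_pool(diag(3), accession_ids = c("A", "B", "C"))
  s2 <- score_subset(e, pool, c("A", "B"))
  s3 <- score_subset(e, pool, c("A", "B", "C"))
  var_c <- mean(B[, 3]^2) - mean(B[, 3])^2
  expect_equal(s3$log_det, s2$log_det + log(var_c), tolerance = 1e-8)
})
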