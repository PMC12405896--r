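# MINE criterion: covariance / correlation determinants of ensemble trait
# predictions, and the four accession-panel selection algorithms.

#' Candidate pool of selectable accessions
#'
#' @param X_cand accession-level `design_matrix` (or matrix with rownames)
#'   holding one row per selectable accession.
#' @param accession_ids optional labels; defaults to the matrix row ids.
#' @return An object of class `candidate_pool`.
#' @export
candidate_pool <- function(X_cand, accession_ids = NULL) {
  Xm <- design_values(X_cand)
  if (is.null(accession_ids)) {
    accession_ids <- if (inherits(X_cand, "design_matrix")) {
      X_cand$row_ids
    } else rownames(Xm)
  }
  stopifnot(!is.null(accession_ids), length(accession_ids) == nrow(Xm),
            !anyDuplicated(accession_ids))
  rownames(Xm) <- accession_ids
  structure(list(accession_ids = as.character(accession_ids), X = Xm),
            class = "candidate_pool")
}

# Prediction matrix over the whole pool: pool accessions x ensemble members.
pool_predictions <- function(e, pool) {
  stopifnot(inherits(e, "mine_ensemble") || is.matrix(e$samples))
  pool$X %*% t(e$samples)
}

#' First and second moments of ensemble predictions for a subset
#'
#' Ensemble averages over the N stored parameter vectors of the predicted
#' trait value `G_k` of each subset accession, and of the pairwise products
#' `G_k G_j`.
#'
#' @param e a `mine_ensemble`.
#' @param pool a [candidate_pool()].
#' @param subset character vector of accession labels (within the pool).
#' @return List with `first` (length K) and `second` (K x K matrix).
#' @export
prediction_moments <- function(e, pool, subset) {
  idx <- match(subset, pool$accession_ids)
  if (anyNA(idx)) {
    stop("unknown accession label(s): ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  P <- pool$X[idx, , drop = FALSE] %*% t(e$samples)   # K x N
  N <- ncol(P)
  first <- rowMeans(P)
  second <- tcrossprod(P) / N
  dimnames(second) <- list(subset, subset)
  list(first = setNames(first, subset), second = second)
}

log_det_psd <- function(M, eig_floor_rel = 1e-12) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  floor_v <- eig_floor_rel * max(ev[1L], 1)
  list(log_det = sum(log(pmax(ev, floor_v))), eigenvalues = ev)
}

#' Score a candidate subset by the MINE criterion
#'
#' Assembles the K x K ensemble prediction-covariance matrix D (or its
#' correlation normalization E) for the subset and returns its
#' log-determinant, computed from eigenvalues with a relative floor of
#' 1e-12 so positive-semidefinite rank deficiency does not produce
#' `-Inf`. The determinant is the prediction-uncertainty ellipsoid volume:
#' larger means a more informative subset.
#'
#' @inheritParams prediction_moments
#' @param criterion `"covariance"` (D) or `"correlation"` (E).
#' @return A `mine_score`: `criterion`, `matrix`, `log_det`, `eigenvalues`
#'   (descending).
#' @export
score_subset <- function(e, pool, subset,
                         criterion = c("covariance", "correlation")) {
  criterion <- match.arg(criterion)
  mom <- prediction_moments(e, pool, subset)
  D <- mom$second - tcrossprod(mom$first)
  D <- (D + t(D)) / 2
  if (criterion == "correlation") {
    dkk <- diag(D)
    if (any(dkk <= 0)) {
      stop("zero prediction variance for candidate(s): ",
           paste(subset[dkk <= 0], collapse = ", "),
           " (correlation criterion undefined)")
    }
    D <- D / sqrt(tcrossprod(dkk))
    diag(D) <- 1
  }
  ld <- log_det_psd(D)
  structure(list(criterion = criterion, matrix = D,
                 log_det = ld$log_det, eigenvalues = ld$eigenvalues),
            class = "mine_score")
}

#' @method print mine_score
#' @export
print.mine_score <- function(x, ...) {
  cat(sprintf("mine_score (%s): K = %d, log det = %.4f\n",
              x$criterion, nrow(x$matrix), x$log_det))
  invisible(x)
}

# Shared fast path: full pool prediction covariance, subsets score by
# submatrix log-determinant (D depends only on pairwise covariances).
pool_cov <- function(e, pool, criterion) {
  P <- pool_predictions(e, pool)
  N <- ncol(P)
  m1 <- rowMeans(P)
  C <- tcrossprod(P) / N - tcrossprod(m1)
  C <- (C + t(C)) / 2
  if (criterion == "correlation") {
    dkk <- diag(C)
    if (any(dkk <= 0)) {
      stop("zero prediction variance for candidate(s): ",
           paste(pool$accession_ids[dkk <= 0], collapse = ", "))
    }
    C <- C / sqrt(tcrossprod(dkk))
    diag(C) <- 1
  }
  C
}

subset_log_det <- function(C, idx) {
  log_det_psd(C[idx, idx, drop = FALSE])$log_det
}

# Deterministic ordering: descending score, exact ties broken by the
# lexicographically smallest label vector.
order_tuples <- function(scores, label_keys) {
  order(-scores, label_keys, method = "radix")
}

selection_result <- function(selected, score_trace, algorithm, seed = NA) {
  stopifnot(!anyDuplicated(selected))
  structure(list(selected = selected, score_trace = score_trace,
                 algorithm = algorithm, seed = seed),
            class = "selection_result")
}

#' @method print selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d accessions, final log det = %.4f\n",
              x$algorithm, length(x$selected),
              x$score_trace[length(x$score_trace)]))
  invisible(x)
}

#' Suboptimal (exhaustive tuple) selection
#'
#' Scores every `p_t`-tuple of pool accessions, sorts tuples by score
#' descending, and harvests individual accessions from the top tuple
#' downward (within-tuple in input order, duplicates skipped) until `p_a`
#' accessions are collected. Exact score ties are broken by lexicographic
#' label order so the selection is deterministic.
#'
#' @param e a `mine_ensemble`.
#' @param pool a [candidate_pool()].
#' @param p_t tuple size (a number that divides `p_a`).
#' @param p_a number of accessions to select.
#' @param criterion `"covariance"` or `"correlation"`.
#' @param max_tuples enumeration budget; exceeding it is an error
#'   suggesting the cheaper selectors (override with `force = TRUE`).
#' @param force allow enumerations above `max_tuples`.
#' @return A `selection_result`.
#' @export
select_suboptimal <- function(e, pool, p_t = 3L, p_a = p_t,
                              criterion = c("covariance", "correlation"),
                              max_tuples = 2e6, force = FALSE) {
  criterion <- match.arg(criterion)
  n <- length(pool$accession_ids)
  stopifnot(p_t >= 1L, p_a >= p_t, p_a <= n)
  if (p_a %% p_t != 0L) {
    stop("p_t (", p_t, ") must divide p_a (", p_a, ")")
  }
  n_tuples <- choose(n, p_t)
  if (n_tuples > max_tuples && !force) {
    stop("enumeration of ", format(n_tuples, big.mark = ","),
         " tuples exceeds the budget; consider select_monte_carlo(), ",
         "select_nc3plus2() or select_greedy(), or set force = TRUE")
  }
  C <- pool_cov(e, pool, criterion)
  tuples <- combn(n, p_t)
  scores <- apply(tuples, 2L, function(idx) subset_log_det(C, idx))
  keys <- apply(tuples, 2L, function(idx) {
    paste(pool$accession_ids[idx], collapse = "\r")
  })
  ord <- order_tuples(scores, keys)
  selected <- character(0)
  trace <- numeric(0)
  for (t in ord) {
    for (lab in pool$accession_ids[tuples[, t]]) {
      if (!(lab %in% selected) && length(selected) < p_a) {
        selected <- c(selected, lab)
        trace <- c(trace, subset_log_det(
          C, match(selected, pool$accession_ids)))
      }
    }
    if (length(selected) >= p_a) break
  }
  selection_result(selected, trace, "suboptimal")
}

#' Monte Carlo (Metropolis swap) selection
#'
#' Starts from a random `p_a`-subset and performs `m` single-accession
#' swaps with the remaining pool, accepting a swap with probability
#' `min(1, exp((logdet_new - logdet_old) / temperature))` -- i.e. the
#' negated MINE log-determinant plays the role of a Hamiltonian. The
#' best-seen subset is returned.
#'
#' @inheritParams select_suboptimal
#' @param m number of swap steps.
#' @param temperature Metropolis temperature (default 1).
#' @param seed optional RNG seed.
#' @return A `selection_result` with the per-step best-seen score trace.
#' @export
select_monte_carlo <- function(e, pool, p_a, m = 1000L, temperature = 1,
                               criterion = c("covariance", "correlation"),
                               seed = NULL) {
  criterion <- match.arg(criterion)
  n <- length(pool$accession_ids)
  stopifnot(p_a >= 1L, p_a < n, m >= 0L)
  if (!is.null(seed)) set.seed(seed)
  C <- pool_cov(e, pool, criterion)
  current <- sample.int(n, p_a)
  cur_score <- subset_log_det(C, current)
  best <- current
  best_score <- cur_score
  trace <- cur_score
  for (step in seq_len(m)) {
    out_i <- sample.int(p_a, 1L)
    candidates <- setdiff(seq_len(n), current)
    in_lab <- candidates[sample.int(length(candidates), 1L)]
    prop <- current
    prop[out_i] <- in_lab
    prop_score <- subset_log_det(C, prop)
    if (prop_score >= cur_score ||
        runif(1) < exp((prop_score - cur_score) / temperature)) {
      current <- prop
      cur_score <- prop_score
      if (cur_score > best_score) {
        best <- current
        best_score <- cur_score
      }
    }
    trace <- c(trace, best_score)
  }
  selection_result(sort_by_label(pool$accession_ids[best]), trace,
                   "monte_carlo", seed = if (is.null(seed)) NA else seed)
}

sort_by_label <- function(x) x[order(x, method = "radix")]

# Best tuple of size p_t from `avail` (indices into C), maximizing the
# log-determinant of base ∪ tuple; ties broken lexicographically.
best_tuple <- function(C, labels, avail, base, p_t) {
  tuples <- combn(avail, p_t)
  scores <- apply(tuples, 2L, function(idx) {
    subset_log_det(C, c(base, idx))
  })
  keys <- apply(tuples, 2L, function(idx) {
    paste(labels[idx], collapse = "\r")
  })
  t <- order_tuples(scores, keys)[1L]
  list(idx = tuples[, t], score = scores[t])
}

#' Combined suboptimal selection (one large tuple, then small tuples)
#'
#' Seeds the panel with the best `p_t1`-tuple, removes it from the pool,
#' then repeatedly adds the best `p_t2`-tuple until `p_a` accessions are
#' selected. Each round's tuple maximizes the MINE score of the already
#' selected panel plus the tuple (joint scoring). With `p_t1 = 3`,
#' `p_t2 = 2` this is the "N choose 3 plus 2" selector. Set `cycle = TRUE`
#' to alternate `p_t1`- and `p_t2`-tuples after the seed instead.
#'
#' @inheritParams select_suboptimal
#' @param p_t1,p_t2 sizes of the seeding tuple and the subsequent tuples.
#' @param cycle alternate tuple sizes after the seed round.
#' @return A `selection_result` with per-round score trace.
#' @export
select_nc3plus2 <- function(e, pool, p_a, p_t1 = 3L, p_t2 = 2L,
                            criterion = c("covariance", "correlation"),
                            cycle = FALSE) {
  criterion <- match.arg(criterion)
  n <- length(pool$accession_ids)
  stopifnot(p_t1 >= 1L, p_t2 >= 1L, p_a >= p_t1, p_a <= n)
  C <- pool_cov(e, pool, criterion)
  labels <- pool$accession_ids
  avail <- seq_len(n)
  sel <- integer(0)
  trace <- numeric(0)
  sizes <- p_t1
  round_i <- 1L
  while (length(sel) < p_a) {
    want <- if (round_i == 1L) {
      p_t1
    } else if (cycle && round_i %% 2L == 1L) p_t1 else p_t2
    want <- min(want, p_a - length(sel))
    if (length(avail) < want) {
      stop("pool exhausted before reaching p_a = ", p_a)
    }
    bt <- best_tuple(C, labels, avail, sel, want)
    sel <- c(sel, bt$idx)
    avail <- setdiff(avail, bt$idx)
    trace <- c(trace, bt$score)
    round_i <- round_i + 1L
  }
  selection_result(labels[sel], trace, "nc3plus2")
}

#' Greedy selection
#'
#' Seeds with the best `p_t`-tuple, then repeatedly adds the single
#' accession that maximizes the MINE score of the augmented panel until
#' `p_a` accessions are selected. The score trace is recorded but is not
#' guaranteed monotone under the correlation criterion.
#'
#' @inheritParams select_suboptimal
#' @return A `selection_result` with per-addition score trace.
#' @export
select_greedy <- function(e, pool, p_a, p_t = 3L,
                          criterion = c("covariance", "correlation")) {
  criterion <- match.arg(criterion)
  n <- length(pool$accession_ids)
  stopifnot(p_t >= 1L, p_a >= p_t, p_a <= n)
  C <- pool_cov(e, pool, criterion)
  labels <- pool$accession_ids
  avail <- seq_len(n)
  bt <- best_tuple(C, labels, avail, integer(0), p_t)
  sel <- bt$idx
  avail <- setdiff(avail, sel)
  trace <- bt$score
  while (length(sel) < p_a) {
    scores <- vapply(avail, function(i) subset_log_det(C, c(sel, i)),
                     numeric(1))
    j <- order_tuples(scores, labels[avail])[1L]
    sel <- c(sel, avail[j])
    trace <- c(trace, scores[j])
    avail <- avail[-j]
  }
  selection_result(labels[sel], trace, "greedy")
}

#' Compare panel-selection algorithms across seeds
#'
#' Runs each configured selector `n_repeats` times (one run per seed; the
#' deterministic selectors simply repeat) and tabulates the final MINE
#' log-determinant of each selected panel.
#'
#' @inheritParams select_suboptimal
#' @param selectors character subset of
#'   `c("suboptimal", "monte_carlo", "nc3plus2", "greedy")`.
#' @param n_repeats runs per selector.
#' @param seeds integer vector of length `n_repeats` (defaults to
#'   `seq_len(n_repeats)`).
#' @param ... passed to the individual selectors.
#' @return Data frame with columns `algorithm`, `seed`, `log_det`.
#' @export
compare_selectors <- function(e, pool, p_a,
                              selectors = c("greedy", "monte_carlo"),
                              criterion = c("covariance", "correlation"),
                              n_repeats = 10L, seeds = NULL, ...) {
  criterion <- match.arg(criterion)
  stopifnot(length(selectors) >= 1L)
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  rows <- list()
  for (alg in selectors) {
    for (s in seeds) {
      res <- switch(
        alg,
        suboptimal = select_suboptimal(e, pool,
                                       p_t = if (p_a %% 3L == 0L) 3L else 1L,
                                       p_a = p_a, criterion = criterion, ...),
        monte_carlo = select_monte_carlo(e, pool, p_a, seed = s,
                                         criterion = criterion, ...),
        nc3plus2 = select_nc3plus2(e, pool, p_a, criterion = criterion, ...),
        greedy = select_greedy(e, pool, p_a, criterion = criterion, ...),
        random = {
          set.seed(s)
          idx <- sample.int(length(pool$accession_ids), p_a)
          C <- pool_cov(e, pool, criterion)
          selection_result(pool$accession_ids[idx],
                           subset_log_det(C, idx), "random", seed = s)
        },
        stop("unknown selector: ", alg))
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, seed = s,
        log_det = res$score_trace[length(res$score_trace)])
    }
  }
  do.call(rbind, rows)
}
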