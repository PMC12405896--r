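# Customized Metropolis sampler: configuration, single-step primitives,
# the dynamic stepwidth adjuster, and the chain driver built on the
# compiled sweep kernels.

#' Sampler configuration
#'
#' Defaults follow the study protocol: 10,000 equilibration sweeps, 1,000
#' decorrelation sweeps between stored samples, 1,000 stored parameter
#' vectors, target acceptance band \[0.3, 0.7\], stepwidth updated from a
#' moving acceptance average every 1,000 sweeps. Scaled-down profiles
#' override these for tests and small problems.
#'
#' @param n_equil_sweeps,n_decorr_sweeps,n_accumulate burn-in sweeps,
#'   decorrelation sweeps per stored sample, and ensemble size M.
#' @param stepwidth_init named list with initial stepwidths for the two
#'   parameter classes, `beta` and `sigma`.
#' @param r_min,r_max acceptance-rate band targeted by the adjuster.
#' @param E_S stepwidth-band constant (in \[1e-6, 1e-4\]): the stepwidth is
#'   only adjusted while within `[E_S * S_bar, S_bar / E_S]` of its running
#'   mean `S_bar`.
#' @param adjust_every sweeps between stepwidth updates.
#' @param rate_window sweeps in the acceptance moving average.
#' @param seed optional integer; when non-NULL, `run_chain()` seeds R's RNG.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_equil_sweeps = 10000L, n_decorr_sweeps = 1000L,
                        n_accumulate = 1000L,
                        stepwidth_init = list(beta = 0.1, sigma = 0.05),
                        r_min = 0.3, r_max = 0.7, E_S = 1e-5,
                        adjust_every = 1000L, rate_window = 1000L,
                        seed = NULL) {
  stopifnot(r_min > 0, r_min < r_max, r_max < 1,
            E_S >= 1e-6, E_S <= 1e-4,
            n_equil_sweeps > 0, n_decorr_sweeps > 0, n_accumulate > 0,
            adjust_every > 0, rate_window > 0,
            stepwidth_init$beta > 0, stepwidth_init$sigma > 0)
  structure(
    list(n_equil_sweeps = as.integer(n_equil_sweeps),
         n_decorr_sweeps = as.integer(n_decorr_sweeps),
         n_accumulate = as.integer(n_accumulate),
         stepwidth_init = stepwidth_init,
         r_min = r_min, r_max = r_max, E_S = E_S,
         adjust_every = as.integer(adjust_every),
         rate_window = as.integer(rate_window), seed = seed),
    class = "mcmc_config")
}

#' Propose a single-parameter Metropolis update
#'
#' Perturbs component `k` by `stepwidth * U(-1, 1)`. For mixed-model scale
#' parameters, a proposal driving the scale negative is returned flagged
#' invalid; the caller rejects it outright (which counts as a rejection in
#' the acceptance rate).
#'
#' @param params numeric parameter vector.
#' @param k index of the component to perturb.
#' @param stepwidth positive proposal half-width.
#' @param is_scale logical vector (recycled) marking nonnegative scale
#'   components.
#' @return List with `params` (proposed vector), `k`, and `valid`.
#' @export
propose_update <- function(params, k, stepwidth, is_scale = FALSE) {
  if (k < 1L || k > length(params)) stop("parameter index out of range")
  stopifnot(stepwidth >= 0)
  prop <- params
  prop[k] <- prop[k] + stepwidth * runif(1, -1, 1)
  is_scale <- rep_len(is_scale, length(params))
  list(params = prop, k = k, valid = !(is_scale[k] && prop[k] < 0))
}

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(h_current - h_proposed))`; downhill
#' moves (lower Hamiltonian) are always accepted.
#'
#' @param h_current,h_proposed finite Hamiltonian values.
#' @return Logical.
#' @export
accept_step <- function(h_current, h_proposed) {
  stopifnot(is.finite(h_current), is.finite(h_proposed))
  if (h_proposed <= h_current) return(TRUE)
  runif(1) < exp(h_current - h_proposed)
}

#' Initialize stepwidth-adjuster state
#'
#' @param s_init initial stepwidth.
#' @return A `stepwidth_state` list with fields `S_current`, `f_prev`,
#'   `S_sum`/`S_n` (for the running mean of past stepwidths) and `r_prev`.
#' @export
stepwidth_state <- function(s_init) {
  stopifnot(s_init > 0)
  structure(list(S_current = s_init, f_prev = 1, S_sum = 0, S_n = 0L,
                 r_prev = NA_real_),
            class = "stepwidth_state")
}

#' Dynamic stepwidth adjustment
#'
#' Multiplies the stepwidth by a factor chosen from the windowed acceptance
#' rate `r_i`: unchanged while the rate is inside `[r_min, r_max]` or the
#' stepwidth has left the band `[E_S * S_bar, S_bar / E_S]` around its
#' running mean; shrink by 2/3 on first falling below `r_min` (acceptance
#' too low means steps too large); grow by 3/2 on first exceeding `r_max`;
#' reuse the previous factor when out of range on the same side twice; use
#' its reciprocal when the band was crossed.
#'
#' @param st a [stepwidth_state()].
#' @param r_i acceptance rate over the last window, in \[0, 1\].
#' @param cfg an [mcmc_config()] supplying `r_min`, `r_max`, `E_S`.
#' @return Updated `stepwidth_state`.
#' @export
adjust_stepwidth <- function(st, r_i, cfg) {
  stopifnot(r_i >= 0, r_i <= 1)
  s_prev <- st$S_current
  # running mean of past stepwidths, including the current one
  S_sum <- st$S_sum + s_prev
  S_n <- st$S_n + 1L
  s_bar <- S_sum / S_n
  s_min <- cfg$E_S * s_bar
  s_max <- s_bar / cfg$E_S
  r_prev <- st$r_prev
  in_range <- r_i >= cfg$r_min && r_i <= cfg$r_max
  first <- is.na(r_prev)
  f <- if (in_range || s_prev < s_min || s_prev > s_max) {
    1
  } else if (!first && ((r_prev < cfg$r_min && r_i < cfg$r_min) ||
                        (r_prev > cfg$r_max && r_i > cfg$r_max))) {
    st$f_prev
  } else if (!first && ((r_prev < cfg$r_min && r_i > cfg$r_max) ||
                        (r_prev > cfg$r_max && r_i < cfg$r_min))) {
    1 / st$f_prev
  } else if (r_i < cfg$r_min) {   # first excursion below the band
    2 / 3
  } else {                        # first excursion above the band
    3 / 2
  }
  structure(list(S_current = f * s_prev, f_prev = f,
                 S_sum = S_sum, S_n = S_n, r_prev = r_i),
            class = "stepwidth_state")
}

#' Run the Metropolis chain and accumulate a parameter ensemble
#'
#' Two phases: `n_equil_sweeps` of equilibration with the stepwidth
#' adjuster active (one adjustment per `adjust_every` sweeps, from the
#' acceptance rate of the last `rate_window` sweeps, separately for the
#' `beta` and `sigma` parameter classes), then `n_accumulate` blocks of
#' `n_decorr_sweeps` decorrelation sweeps each, storing one parameter
#' vector per block at frozen stepwidths. Beta coordinates are initialized
#' i.i.d. uniform on (-0.1, 0.1); mixed-model scales at the trait's overall
#' sample standard deviation. The linear-model kernel tracks the
#' Hamiltonian through rank-1 residual updates and is re-synchronized
#' against a full recomputation at every phase boundary.
#'
#' @param model `"linear"` or `"mixed"`.
#' @param X plant-level `design_matrix` (or plain matrix).
#' @param td a [trait_data()].
#' @param cfg an [mcmc_config()].
#' @param V fixed residual covariance for the linear model; defaults to
#'   [v_fixed()] of `td`.
#' @param sample_sigma,sample_resid mixed model only: whether accession
#'   scales and the residual scale are sampled (set `FALSE` to freeze them
#'   at their initial values).
#' @param sigma_acc_init,sigma_resid_init mixed model only: initial scales.
#' @return An object of class `mine_ensemble`: `samples` (M x p beta
#'   matrix), `sigma_samples` (mixed model), `hamiltonians`, `traces`
#'   (per-sweep Hamiltonian and per-window acceptance/stepwidth), `config`,
#'   `model`, and the accession index used.
#' @export
run_chain <- function(model = c("linear", "mixed"), X, td,
                      cfg = mcmc_config(), V = NULL,
                      sample_sigma = TRUE, sample_resid = TRUE,
                      sigma_acc_init = NULL, sigma_resid_init = NULL) {
  model <- match.arg(model)
  Xm <- design_values(X)
  stopifnot(inherits(td, "trait_data"), nrow(Xm) == length(td$y))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- ncol(Xm)
  beta <- runif(p, -0.1, 0.1)
  acc_levels <- unique(td$accession_ids)
  acc_index <- match(td$accession_ids, acc_levels)

  st_beta <- stepwidth_state(cfg$stepwidth_init$beta)
  st_sigma <- stepwidth_state(cfg$stepwidth_init$sigma)
  h_trace <- numeric(0)
  rate_rows <- list()

  if (model == "linear") {
    if (is.null(V)) V <- v_fixed(td)
    if (V$form != "fixed_blockdiag") {
      stop("linear model requires a fixed block-diagonal covariance")
    }
    run_block <- function(ns) {
      out <- sweep_linear_cpp(Xm, V$d, td$y, beta, ns, st_beta$S_current)
      beta <<- drop(out$beta)
      h_trace <<- c(h_trace, out$h_trace)
      c(acc_beta = sum(out$acc_trace) / (ns * p), acc_sigma = NA_real_)
    }
    recompute_h <- function() hamiltonian_linear(beta, Xm, td, V)
    get_sample <- function() list(beta = beta, sigma = NULL)
  } else {
    sd_y <- stats::sd(td$y)
    sigma_acc <- if (is.null(sigma_acc_init)) {
      rep(sd_y, length(acc_levels))
    } else rep_len(sigma_acc_init, length(acc_levels))
    sigma_resid <- if (is.null(sigma_resid_init)) sd_y else sigma_resid_init
    G <- tcrossprod(Xm)
    run_block <- function(ns) {
      out <- sweep_mixed_cpp(Xm, G, acc_index - 1L, td$y, beta,
                             sigma_acc, sigma_resid, ns,
                             st_beta$S_current, st_sigma$S_current,
                             sample_sigma, sample_resid)
      beta <<- drop(out$beta)
      sigma_acc <<- drop(out$sigma_acc)
      sigma_resid <<- out$sigma_resid
      h_trace <<- c(h_trace, out$h_trace)
      c(acc_beta = sum(out$acc_beta) / max(1, sum(out$att_beta)),
        acc_sigma = if (sum(out$att_sigma) > 0) {
          sum(out$acc_sigma) / sum(out$att_sigma)
        } else NA_real_)
    }
    recompute_h <- function() {
      hamiltonian_mixed(beta, Xm, td,
                        v_mixed(sigma_acc, sigma_resid, Xm, acc_index))
    }
    get_sample <- function() {
      list(beta = beta, sigma = c(sigma_acc, resid = sigma_resid))
    }
  }

  h0 <- recompute_h()
  if (!is.finite(h0)) stop("non-finite Hamiltonian at initialization")

  # --- equilibration with stepwidth adjustment -------------------------
  left <- cfg$n_equil_sweeps
  sweep_at <- 0L
  while (left > 0L) {
    ns <- min(cfg$adjust_every, left)
    rates <- run_block(ns)
    sweep_at <- sweep_at + ns
    left <- left - ns
    rate_rows[[length(rate_rows) + 1L]] <- data.frame(
      sweep = sweep_at, phase = "equilibration",
      acc_beta = rates[["acc_beta"]], acc_sigma = rates[["acc_sigma"]],
      step_beta = st_beta$S_current, step_sigma = st_sigma$S_current)
    st_beta <- adjust_stepwidth(st_beta, rates[["acc_beta"]], cfg)
    if (model == "mixed" && sample_sigma && is.finite(rates[["acc_sigma"]])) {
      st_sigma <- adjust_stepwidth(st_sigma, rates[["acc_sigma"]], cfg)
    }
  }
  h_check <- recompute_h()
  if (length(h_trace) > 0 &&
      abs(h_check - h_trace[length(h_trace)]) >
      1e-6 * max(1, abs(h_check))) {
    stop("incremental Hamiltonian drifted from full recomputation")
  }

  # --- accumulation ----------------------------------------------------
  M <- cfg$n_accumulate
  samples <- matrix(NA_real_, M, p,
                    dimnames = list(NULL, colnames(Xm)))
  sigma_samples <- NULL
  hamiltonians <- numeric(M)
  for (m in seq_len(M)) {
    rates <- run_block(cfg$n_decorr_sweeps)
    sweep_at <- sweep_at + cfg$n_decorr_sweeps
    smp <- get_sample()
    samples[m, ] <- smp$beta
    if (!is.null(smp$sigma)) {
      if (is.null(sigma_samples)) {
        sigma_samples <- matrix(NA_real_, M, length(smp$sigma),
                                dimnames = list(NULL, names(smp$sigma)))
      }
      sigma_samples[m, ] <- smp$sigma
    }
    hamiltonians[m] <- h_trace[length(h_trace)]
  }
  h_final <- recompute_h()
  if (abs(h_final - hamiltonians[M]) > 1e-6 * max(1, abs(h_final))) {
    stop("stored Hamiltonian disagrees with recomputation")
  }

  structure(
    list(samples = samples, sigma_samples = sigma_samples,
         hamiltonians = hamiltonians,
         traces = list(hamiltonian = h_trace,
                       rates = do.call(rbind, rate_rows)),
         config = cfg, model = model,
         accession_levels = acc_levels,
         n_obs = nrow(Xm)),
    class = "mine_ensemble")
}

#' @method print mine_ensemble
#' @export
print.mine_ensemble <- function(x, ...) {
  cat(sprintf("mine_ensemble: %d %s-model parameter vectors (p = %d), final H = %.4f\n",
              nrow(x$samples), x$model, ncol(x$samples),
              x$hamiltonians[length(x$hamiltonians)]))
  invisible(x)
}

#' Chain diagnostics: traces and an equilibration flag
#'
#' Summarizes the per-sweep Hamiltonian trace and the per-window acceptance
#' rates and stepwidths; flags non-equilibration when the least-squares
#' slope of the Hamiltonian over its last quartile of sweeps exceeds
#' `slope_tol` in absolute value.
#'
#' @param e a `mine_ensemble` from [run_chain()].
#' @param slope_tol tolerance on the last-quartile Hamiltonian slope
#'   (Hamiltonian units per sweep).
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_htrace.tsv` and `<prefix>_rates.tsv`.
#' @return List with `slope`, `equilibrated`, `acceptance` (last recorded
#'   rates) and the trace data frames.
#' @export
diagnostics <- function(e, slope_tol = 0.05, out_prefix = NULL) {
  h <- e$traces$hamiltonian
  stopifnot(length(h) > 0)
  q4 <- h[seq.int(floor(3 * length(h) / 4) + 1L, length(h))]
  slope <- if (length(q4) >= 2L) {
    unname(coef(lm(q4 ~ seq_along(q4)))[2L])
  } else 0
  rates <- e$traces$rates
  out <- list(
    slope = slope,
    equilibrated = abs(slope) <= slope_tol,
    acceptance = rates[nrow(rates), , drop = FALSE],
    h_trace = data.frame(sweep = seq_along(h), hamiltonian = h),
    rates = rates)
  if (!is.null(out_prefix)) {
    write.table(out$h_trace, paste0(out_prefix, "_htrace.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rates, paste0(out_prefix, "_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Persist an ensemble as plain-text arrays plus a JSON sidecar
#'
#' @param e a `mine_ensemble`.
#' @param out_prefix path prefix for `<prefix>_samples.tsv`,
#'   `<prefix>_sigma.tsv` (mixed model), `<prefix>_hamiltonians.tsv` and
#'   `<prefix>_meta.json`.
#' @return Invisibly, the files written.
#' @export
write_ensemble <- function(e, out_prefix) {
  files <- character(0)
  f <- paste0(out_prefix, "_samples.tsv")
  write.table(e$samples, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(e$sigma_samples)) {
    f <- paste0(out_prefix, "_sigma.tsv")
    write.table(e$sigma_samples, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  f <- paste0(out_prefix, "_hamiltonians.tsv")
  write.table(data.frame(hamiltonian = e$hamiltonians), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  meta <- list(model = e$model, config = unclass(e$config),
               accession_levels = e$accession_levels, n_obs = e$n_obs)
  f <- paste0(out_prefix, "_meta.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Load an ensemble written by [write_ensemble()]
#'
#' @param out_prefix the prefix passed to [write_ensemble()].
#' @return A `mine_ensemble` (traces are not persisted).
#' @export
read_ensemble <- function(out_prefix) {
  samples <- as.matrix(read.table(paste0(out_prefix, "_samples.tsv"),
                                  sep = "\t", header = TRUE,
                                  check.names = FALSE))
  sig_f <- paste0(out_prefix, "_sigma.tsv")
  sigma_samples <- if (file.exists(sig_f)) {
    as.matrix(read.table(sig_f, sep = "\t", header = TRUE,
                         check.names = FALSE))
  } else NULL
  h <- read.table(paste0(out_prefix, "_hamiltonians.tsv"),
                  sep = "\t", header = TRUE)$hamiltonian
  meta <- jsonlite::read_json(paste0(out_prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(
    list(samples = samples, sigma_samples = sigma_samples,
         hamiltonians = h,
         traces = list(hamiltonian = numeric(0), rates = NULL),
         config = meta$config, model = meta$model,
         accession_levels = meta$accession_levels, n_obs = meta$n_obs),
    class = "mine_ensemble")
}
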