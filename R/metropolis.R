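#' Random-walk Metropolis sampler
#'
#' Samples a log-density with multi-chain random-walk Metropolis on the
#' (already transformed) parameter scale. Proposals are multivariate normal
#' increments whose covariance is adapted during burn-in only: a running
#' estimate of the chain covariance (regularized, refreshed every 100
#' steps once enough burn-in history exists) scaled by a global step size
#' tuned toward the target acceptance rate. Both are frozen after burn-in,
#' so the post-burn-in kernel preserves detailed balance. Chains are seeded
#' deterministically from `seed`, so identical inputs give bitwise-identical
#' output.
#'
#' @param logpost function mapping a parameter vector to a log density
#'   (finite at `init`).
#' @param init named numeric initial vector.
#' @param n_chains number of chains (default 6).
#' @param n_steps post-burn-in steps per chain (default 10000).
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param burn_steps burn-in steps discarded per chain (default `n_steps`,
#'   i.e. the first 50% of the total run).
#' @param target_accept target acceptance rate during adaptation.
#' @param init_scale initial proposal step size.
#' @param jitter_sd spread of the chain-specific jitter around `init`.
#' @return an object of class `posterior_chains` with elements `samples`
#'   (array step x parameter x chain, post-burn-in), `acceptance` (per
#'   chain), `rhat` (split-chain potential scale reduction per parameter),
#'   `seed`, and `param_names`.
#' @export
#' @examples
#' ch <- metropolis_sample(function(x) -x^2 / 2, c(mu = 0),
#'                         n_chains = 2, n_steps = 500, seed = 1)
#' mean(pooled_samples(ch))
metropolis_sample <- function(logpost, init, n_chains = 6L, n_steps = 10000L,
                              seed = 1L, burn_steps = n_steps,
                              target_accept = 0.3, init_scale = 0.2,
                              jitter_sd = 0.1) {
  d <- length(init)
  nm <- names(init)
  if (is.null(nm)) nm <- paste0("p", seq_len(d))
  lp0 <- logpost(init)
  if (!is.finite(lp0)) stop("logpost not finite at init")
  total <- burn_steps + n_steps
  samples <- array(NA_real_, c(n_steps, d, n_chains),
                   dimnames = list(NULL, nm, NULL))
  acc_rate <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch)
    x <- init + rnorm(d, 0, jitter_sd)
    lp <- logpost(x)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      x <- init + rnorm(d, 0, jitter_sd)
      lp <- logpost(x)
      tries <- tries + 1
    }
    if (!is.finite(lp)) { x <- init; lp <- lp0 }
    log_step <- log(init_scale)
    L <- diag(d)                       # Cholesky factor of proposal shape
    run_m <- x                         # Welford running moments (burn-in)
    run_C <- matrix(0, d, d)
    n_acc_post <- 0L
    acc_win <- 0L
    for (s in seq_len(total)) {
      prop <- x + exp(log_step) * as.vector(L %*% rnorm(d))
      lpp <- logpost(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        x <- prop; lp <- lpp
        acc_win <- acc_win + 1L
        if (s > burn_steps) n_acc_post <- n_acc_post + 1L
      }
      if (s <= burn_steps) {
        delta <- x - run_m
        run_m <- run_m + delta / s
        run_C <- run_C + tcrossprod(delta, x - run_m)
        if (s %% 50L == 0L) {
          log_step <- log_step +
            min(1, 5 / sqrt(s)) * (acc_win / 50 - target_accept)
          acc_win <- 0L
        }
        if (s %% 100L == 0L && s >= max(200L, 10L * d)) {
          C <- run_C / (s - 1) + diag(1e-8, d)
          Lc <- tryCatch(t(chol(C)), error = function(e) NULL)
          if (!is.null(Lc)) {
            # renormalize so the global step keeps its meaning
            L <- Lc / exp(mean(log(pmax(diag(Lc), 1e-12))))
          }
        }
      } else {
        samples[s - burn_steps, , ch] <- x
      }
    }
    acc_rate[ch] <- n_acc_post / n_steps
  }
  if (all(acc_rate == 0))
    stop("all chains rejected every post-burn-in proposal")
  structure(list(samples = samples, acceptance = acc_rate,
                 rhat = split_rhat(samples), seed = seed,
                 n_steps = n_steps, burn_steps = burn_steps,
                 param_names = nm),
            class = "posterior_chains")
}

# split-chain potential scale reduction factor per parameter
split_rhat <- function(samples) {
  n <- dim(samples)[1]; d <- dim(samples)[2]; m <- dim(samples)[3]
  half <- n %/% 2L
  out <- numeric(d); names(out) <- dimnames(samples)[[2]]
  for (k in seq_len(d)) {
    halves <- matrix(NA_real_, half, 2L * m)
    for (ch in seq_len(m)) {
      halves[, 2 * ch - 1] <- samples[seq_len(half), k, ch]
      halves[, 2 * ch] <- samples[half + seq_len(half), k, ch]
    }
    mns <- colMeans(halves)
    vrs <- apply(halves, 2, stats::var)
    W <- mean(vrs)
    B <- half * stats::var(mns)
    out[k] <- if (W < 1e-300) 1 else sqrt(((half - 1) / half * W + B / half) / W)
  }
  out
}

#' Pool post-burn-in samples across chains
#'
#' @param chains a `posterior_chains` object.
#' @param parameter optional parameter name; if given, returns a vector.
#' @return matrix (rows = pooled draws) or numeric vector.
#' @export
pooled_samples <- function(chains, parameter = NULL) {
  stopifnot(inherits(chains, "posterior_chains"))
  s <- chains$samples
  m <- matrix(aperm(s, c(1, 3, 2)), ncol = dim(s)[2],
              dimnames = list(NULL, chains$param_names))
  if (is.null(parameter)) m else m[, parameter]
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat("posterior_chains:", dim(x$samples)[3], "chains x",
      dim(x$samples)[1], "steps,", dim(x$samples)[2], "parameters\n")
  cat("acceptance:", paste(sprintf("%.2f", x$acceptance), collapse = " "), "\n")
  cat("split-Rhat:", paste(sprintf("%s=%.3f", names(x$rhat), x$rhat),
                           collapse = " "), "\n")
  invisible(x)
}
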