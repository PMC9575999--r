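#' Posterior summary metrics
#'
#' Inference metrics computed directly from posterior samples: expected
#' value, highest-posterior-density credible interval, one-sided lower
#' credible limit, and the probability of exceeding zero. The default
#' credible level is 90.9% = 10/(10+1), the mass at which the evidence
#' ratio of interval membership equals 10 ("strong" evidence).
#'
#' @param x numeric vector of posterior samples (pooled across chains).
#' @param level credible mass, default `10/11`.
#' @name posterior-metrics
NULL

#' @rdname posterior-metrics
#' @return `ev`: the posterior mean.
#' @export
ev <- function(x) mean(x)

#' @rdname posterior-metrics
#' @return `hpd_interval`: length-2 vector, the shortest interval containing
#'   `level` of the samples (shortest-single-interval rule under
#'   multimodality).
#' @export
hpd_interval <- function(x, level = 10 / 11) {
  stopifnot(level > 0, level < 1, length(x) >= 2)
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  width <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(width)
  c(lower = xs[i], upper = xs[i + k])
}

#' @rdname posterior-metrics
#' @return `lcl0`: lower end of the one-sided interval holding `level` mass,
#'   i.e. the `1 - level` sample quantile.
#' @export
lcl0 <- function(x, level = 10 / 11) {
  unname(quantile(x, probs = 1 - level, names = FALSE))
}

#' @rdname posterior-metrics
#' @return `pr_gt0`: fraction of samples greater than zero.
#' @export
pr_gt0 <- function(x) mean(x > 0)

#' Evidence ratio and its base-10 logarithm
#'
#' A probability statement about a parameter is compared to its complement
#' in an evidence ratio ER = Pr/(1 - Pr); LER = log10(ER). LERs of 0.5, 1.0,
#' 1.5 and 2.0 are read as substantial, strong, very strong and decisive
#' evidence respectively.
#'
#' @param pr probability in (0, 1). Values of exactly 0 or 1 (possible with
#'   finite samples) are clamped to the resolution limit `1/(n+1)` implied
#'   by `n`, and flagged.
#' @param n optional sample count behind `pr`, used only for the clamp.
#' @return `evidence_ratio`: ER.
#' @export
#' @examples
#' evidence_ratio(10 / 11)       # 10
#' log_evidence_ratio(10 / 11)   # 1 ("strong")
evidence_ratio <- function(pr, n = NULL) {
  if (pr < 0 || pr > 1) stop("pr must be in [0,1]")
  if (pr == 0 || pr == 1) {
    if (is.null(n)) stop("pr at 0 or 1: supply n to report a resolution bound")
    eps <- 1 / (n + 1)
    pr <- if (pr == 0) eps else 1 - eps
  }
  pr / (1 - pr)
}

#' @rdname evidence_ratio
#' @return `log_evidence_ratio`: LER = log10(ER).
#' @export
log_evidence_ratio <- function(pr, n = NULL) log10(evidence_ratio(pr, n))

#' @rdname evidence_ratio
#' @param ler a LER value.
#' @return `ler_label`: the interpretation band of a LER.
#' @export
ler_label <- function(ler) {
  cut(ler, c(-Inf, 0.5, 1, 1.5, 2, Inf), right = FALSE,
      labels = c("weak", "substantial", "strong", "very strong", "decisive"))
}

#' Interannual hazard ratios
#'
#' For a vector of per-year hazard levels `h`, the maximum ratio between any
#' two years is `maxR = exp(range of ln h)` and the mean ratio is
#' `meanR = exp(mean |ln h_i - ln h_j|)` over all unordered year pairs.
#' Both are invariant to multiplying all hazards by a constant, so they do
#' not depend on the year-effect identifiability constraint. Applied per
#' posterior draw they yield posterior distributions of the ratios.
#'
#' @param h positive numeric vector of per-year hazards (length >= 2), or a
#'   matrix with one row per posterior draw and one column per year.
#' @return named vector `c(maxR, meanR)`, or a 2-column matrix for matrix
#'   input.
#' @export
#' @examples
#' interannual_ratios(c(1, 2, 4))  # maxR 4, meanR exp(mean pairwise |dln|)
interannual_ratios <- function(h) {
  if (is.matrix(h)) {
    out <- t(apply(h, 1, interannual_ratios))
    colnames(out) <- c("maxR", "meanR")
    return(out)
  }
  if (length(h) < 2) stop("need hazards for at least 2 years")
  if (any(h <= 0)) stop("hazards must be positive")
  lh <- log(h)
  mad <- mean(abs(outer(lh, lh, "-"))[lower.tri(diag(length(lh)))])
  c(maxR = exp(max(lh) - min(lh)), meanR = exp(mad))
}

#' First-year hazard from first-year survivorship
#'
#' `h1 = -ln(S1)`, the mean first-year hazard implied by survivorship to age
#' 1; used to place calf and adult interannual variation on a common hazard
#' scale (the adult analogue is `hA = exp(beta_Y)`).
#'
#' @param S1 survivorship to age 1, in (0, 1).
#' @return hazard (1/yr).
#' @export
h1_from_S1 <- function(S1) {
  stopifnot(all(S1 > 0), all(S1 < 1))
  -log(S1)
}
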