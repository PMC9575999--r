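#' @name model-stages
#' @title Staged sequential Bayesian fitting
#'
#' @description
#' The three observation streams are fitted in sequence: the collared-cow
#' survival model (CC) and its single-effect extensions (CC.S season, CC.L
#' location, CC.Y year), then the herd-count model (HC, HC.Y), then the
#' calf-detection model (CD, CD.Y). Each stage samples its free parameters
#' by random-walk Metropolis on a transformed scale (log for positive
#' parameters, logit for probabilities, identity for signed effects);
#' parameters carried forward from an earlier stage receive independent
#' normal priors on the transformed scale moment-matched to that stage's
#' posterior, and parameters needed but not sampled are fixed at the carried
#' posterior mean.
NULL

# transformation registry -------------------------------------------------

transform_of <- function(name) {
  if (name %in% c("a1", "b1", "a2", "a3", "b3", "gamma_D")) return("log")
  if (name == "f" || startsWith(name, "f.") || name %in% c("p", "q"))
    return("logit")
  "identity"  # beta_S, beta_L100, beta_Y.<year>
}

to_transformed <- function(x, tr) {
  switch(tr, log = log(x), logit = log(x / (1 - x)), identity = x)
}

from_transformed <- function(z, tr) {
  switch(tr, log = exp(z), logit = 1 / (1 + exp(-z)), identity = z)
}

natural_vec <- function(z) {
  setNames(vapply(names(z), function(nm)
    from_transformed(z[[nm]], transform_of(nm)), numeric(1)), names(z))
}

# assemble a named natural-scale value vector into model objects.
# beta_L is sampled per 100 km ("beta_L100") for conditioning; beta_Y values
# are centered to the sum-to-zero identifiability constraint.
assemble_params <- function(vals) {
  nm <- names(vals)
  need <- c("a1", "b1", "a2", "a3", "b3")
  if (!all(need %in% nm)) stop("missing Siler parameter(s): ",
                               paste(setdiff(need, nm), collapse = ", "))
  params <- siler_params(vals[["a1"]], vals[["b1"]], vals[["a2"]],
                         vals[["a3"]], vals[["b3"]])
  by <- vals[startsWith(nm, "beta_Y.")]
  if (length(by)) {
    names(by) <- sub("^beta_Y\\.", "", names(by))
    by <- by - mean(by)
  }
  mods <- hazard_modifiers(
    beta_S = if ("beta_S" %in% nm) vals[["beta_S"]] else 0,
    beta_L = if ("beta_L100" %in% nm) vals[["beta_L100"]] / 100 else 0,
    beta_Y = by,
    gamma_D = if ("gamma_D" %in% nm) vals[["gamma_D"]] else 0)
  fv <- vals[startsWith(nm, "f.")]
  if (length(fv)) names(fv) <- sub("^f\\.", "", names(fv))
  list(params = params, mods = mods,
       f = if (length(fv)) fv else if ("f" %in% nm) vals[["f"]] else NULL,
       p = if ("p" %in% nm) vals[["p"]] else NULL,
       q = if ("q" %in% nm) vals[["q"]] else NULL)
}

#' Define a model stage
#'
#' @param label stage label (e.g. `"CC"`, `"HC.Y"`).
#' @param data which stream the stage is fitted to: `"cc"`, `"hc"` or
#'   `"cd"`.
#' @param free names of parameters sampled in this stage.
#' @param fixed named natural-scale values for parameters held fixed (used
#'   when neither carried nor defaulted).
#' @param prior_from label of the earlier stage whose posterior supplies
#'   moment-matched priors and fixed values for carried parameters, or
#'   `NULL` for none.
#' @param init named natural-scale starting values for free parameters not
#'   carried from an earlier stage.
#' @param fresh free parameters that take the default weak prior even when
#'   an earlier stage estimated them (used where a stage is meant to give
#'   an independent estimate, e.g. fecundity from the calf-detection
#'   stream).
#' @param n_steps optional per-stage override of the sampler's post-burn-in
#'   step count (stages with cheap likelihoods can afford longer chains).
#' @return a `model_stage` list.
#' @export
model_stage <- function(label, data, free, fixed = c(), prior_from = NULL,
                        init = c(), fresh = character(), n_steps = NULL) {
  stopifnot(data %in% c("cc", "hc", "cd"))
  structure(list(label = label, data = data, free = free, fixed = fixed,
                 prior_from = prior_from, init = init, fresh = fresh,
                 n_steps = n_steps),
            class = "model_stage")
}

#' Default stage sequence
#'
#' CC estimates the adult Siler components (a2, a3, b3; the immature scale
#' is pinned to zero because collared animals enter as adults). CC.S, CC.L
#' and CC.Y are parallel single-effect extensions fitted to the same data
#' set with fresh base priors: posterior-to-prior chaining passes
#' information between data sets, and carrying CC's posterior into a refit
#' of the same records would count them twice (narrowing the effect
#' intervals below nominal coverage). HC adds fecundity
#' and the immature parameters (a1, b1), with the senescent components and
#' the season effect carry-priored from CC.S (the season effect stays in
#' the calf model: first-year survival is strongly season-structured);
#' HC.Y estimates per-year fecundities. CD estimates fecundity, the calf
#' hazard's immature parameters, detection probabilities p and q, and the
#' dissociation slope from the calf-detection stream with fresh weak priors
#' on fecundity and the immature parameters (so the calf-detection stream
#' yields an estimate independent of the herd counts, with only the
#' senescent components and the season effect taken from earlier stages);
#' CD.Y estimates its per-year fecundities.
#'
#' @param years integer vector of complete study years (used for the
#'   year-effect stages).
#' @return named list of [model_stage()] definitions, in running order.
#' @export
default_stages <- function(years) {
  yl <- as.character(years)
  adult_fixed <- c(a1 = 0, b1 = 1)
  adult_init <- c(a2 = 0.1, a3 = 0.02, b3 = 0.3)
  st <- list(
    model_stage("CC", "cc", free = c("a2", "a3", "b3"),
                fixed = adult_fixed, init = adult_init),
    model_stage("CC.S", "cc", free = c("beta_S", "a2", "a3", "b3"),
                fixed = adult_fixed,
                init = c(beta_S = 0, adult_init)),
    model_stage("CC.L", "cc", free = c("beta_L100", "a2", "a3", "b3"),
                fixed = adult_fixed,
                init = c(beta_L100 = 0, adult_init)),
    model_stage("CC.Y", "cc",
                free = c(paste0("beta_Y.", yl), "a2", "a3", "b3"),
                fixed = adult_fixed,
                init = c(setNames(rep(0, length(yl)), paste0("beta_Y.", yl)),
                         adult_init)),
    model_stage("HC", "hc",
                free = c("f", "a1", "b1", "a2", "a3", "b3", "beta_S"),
                prior_from = "CC.S", init = c(f = 0.5, a1 = 1, b1 = 2)),
    model_stage("HC.Y", "hc", free = paste0("f.", yl),
                prior_from = "HC",
                init = setNames(rep(0.5, length(yl)), paste0("f.", yl))),
    model_stage("CD", "cd", free = c("f", "p", "q", "gamma_D", "a1", "b1"),
                prior_from = "HC", fresh = c("f", "a1", "b1"),
                init = c(f = 0.5, p = 0.8, q = 0.05, gamma_D = 2,
                         a1 = 1, b1 = 2)),
    model_stage("CD.Y", "cd",
                free = c(paste0("f.", yl), "p", "q", "gamma_D"),
                prior_from = "CD",
                init = setNames(rep(0.5, length(yl)), paste0("f.", yl)))
  )
  names(st) <- vapply(st, `[[`, "", "label")
  st
}

stage_loglik <- function(stage, data, model) {
  switch(stage$data,
    cc = cc_loglik(data$cc, model$params, model$mods),
    hc = hc_loglik(data$hc, model$f, model$params, model$mods),
    cd = cd_loglik(data$cd, model$f, model$p, model$q, model$params,
                   model$mods))
}

#' Run a sequence of model stages with posterior-to-prior chaining
#'
#' Runs each stage's Metropolis fit in order. For every free parameter the
#' prior on the transformed scale is either a moment-matched normal built
#' from the `prior_from` stage's posterior (when that stage sampled it) or
#' the default weak normal(0, 10). Parameters a stage needs but does not
#' sample are fixed at the carried posterior mean (or the stage's declared
#' fixed value). Each stage records the priors and fixed values it used.
#'
#' @param stages named list of [model_stage()] definitions in running order.
#' @param data list with elements `cc`, `hc`, `cd` as produced by
#'   [make_cc_data()], [make_hc_data()], [make_cd_data()] (only the streams
#'   the stages use are required).
#' @param seed integer seed; stage `i` uses `seed + 1000 * i`.
#' @param n_chains,n_steps,burn_steps passed to [metropolis_sample()].
#' @param prior_sd default prior standard deviation on the transformed
#'   scale.
#' @return named list of stage results, each with elements `chains`
#'   (`posterior_chains`), `prior` (data.frame), `fixed` (named vector),
#'   `summary` (EV and HPD per free parameter on the natural scale).
#' @export
sequential_fit <- function(stages, data, seed = 1L, n_chains = 6L,
                           n_steps = 10000L, burn_steps = n_steps,
                           prior_sd = 10) {
  results <- list()
  carries <- list()   # per-stage carry environment: named list mean/sd (transformed)
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    carry <- if (!is.null(st$prior_from)) {
      if (is.null(carries[[st$prior_from]]))
        stop("stage ", st$label, " references unfitted stage ", st$prior_from)
      carries[[st$prior_from]]
    } else list()
    prior_mean <- numeric(length(st$free)); prior_s <- numeric(length(st$free))
    init_z <- numeric(length(st$free))
    names(prior_mean) <- names(prior_s) <- names(init_z) <- st$free
    for (nm in st$free) {
      if (!is.null(carry[[nm]]) && !nm %in% st$fresh) {
        prior_mean[nm] <- carry[[nm]]["mean"]
        prior_s[nm] <- max(carry[[nm]]["sd"], 1e-6)
        init_z[nm] <- prior_mean[nm]
      } else {
        prior_mean[nm] <- 0
        prior_s[nm] <- prior_sd
        if (!nm %in% names(st$init))
          stop("stage ", st$label, ": no init or carried prior for ", nm)
        init_z[nm] <- to_transformed(st$init[[nm]], transform_of(nm))
      }
    }
    # fixed values: declared fixed first, then carried means
    fixed <- st$fixed
    for (nm in setdiff(names(carry), c(st$free, names(fixed))))
      fixed[nm] <- from_transformed(carry[[nm]]["mean"], transform_of(nm))
    logpost <- local({
      st_ <- st; fixed_ <- fixed; pm <- prior_mean; ps <- prior_s
      function(z) {
        vals <- c(natural_vec(setNames(z, names(pm))), fixed_)
        model <- assemble_params(vals)
        ll <- tryCatch(stage_loglik(st_, data, model),
                       error = function(e) -Inf)
        if (!is.finite(ll)) return(-Inf)
        ll + sum(stats::dnorm(z, pm, ps, log = TRUE))
      }
    })
    ns <- if (!is.null(st$n_steps)) st$n_steps else n_steps
    bs <- if (!is.null(st$n_steps)) st$n_steps else burn_steps
    chains <- metropolis_sample(logpost, init_z, n_chains = n_chains,
                                n_steps = ns, seed = seed + 1000L * i,
                                burn_steps = bs)
    pooled <- pooled_samples(chains)
    post <- lapply(st$free, function(nm)
      c(mean = mean(pooled[, nm]), sd = stats::sd(pooled[, nm])))
    names(post) <- st$free
    carries[[st$label]] <- utils::modifyList(carry, post)
    # intervals: HPD on the sampling (transformed) scale, endpoints mapped
    # back -- stable under the ridge-skewed posteriors of the hazard scales
    summ <- do.call(rbind, lapply(st$free, function(nm) {
      tr <- transform_of(nm)
      h <- from_transformed(hpd_interval(pooled[, nm]), tr)
      data.frame(parameter = nm, ev = mean(from_transformed(pooled[, nm], tr)),
                 lower = h[1], upper = h[2],
                 rhat = chains$rhat[nm], row.names = NULL)
    }))
    results[[st$label]] <- list(label = st$label, chains = chains,
                                prior = data.frame(parameter = st$free,
                                                   mean = prior_mean,
                                                   sd = prior_s,
                                                   row.names = NULL),
                                fixed = fixed, summary = summ)
  }
  results
}

#' Natural-scale posterior draws of a stage, with fixed parameters attached
#'
#' @param stage_result one element of the [sequential_fit()] return value.
#' @return data.frame of pooled posterior draws on the natural scale; fixed
#'   parameters appear as constant columns.
#' @export
stage_draws <- function(stage_result) {
  pooled <- pooled_samples(stage_result$chains)
  out <- as.data.frame(sapply(colnames(pooled), function(nm)
    from_transformed(pooled[, nm], transform_of(nm)), simplify = FALSE))
  for (nm in names(stage_result$fixed)) out[[nm]] <- stage_result$fixed[[nm]]
  out
}
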