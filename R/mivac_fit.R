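# Simulation-based likelihood and estimation: grid search plus bounded
# simplex refinement, BIC model comparison with evidence categories, and
# generalization to held-out trials.

#' Configuration of the simulation-based fit
#'
#' Likelihoods are relative frequencies over repeated simulations of each
#' trial, truncated to `[prob_floor, prob_ceiling]`.  Estimation combines a
#' per-parameter grid search with bounded Nelder-Mead restarts seeded from
#' the best grid point, random draws from the best fraction of grid fits,
#' and (optionally) the best fits of nested variants.  The full-scale
#' settings are a 31-step grid with 100 simulations per trial; the defaults
#' here are desk-scale (7 steps, 50 simulations), with predictions based on
#' fresh out-of-sample simulations.
#'
#' @param sims_per_trial_fit Simulations per trial in the likelihood
#'   (full-scale 100; default 50).
#' @param sims_per_trial_predict Simulations per trial for out-of-sample
#'   predictions (full-scale 10000).
#' @param grid_steps Grid points per free parameter (full-scale 31; default
#'   7; a 1-step grid sits at the bounds' midpoints).
#' @param n_best_starts Simplex restarts from the best grid point.
#' @param n_random_starts Simplex restarts drawn from the best
#'   `best_frac` of grid fits (`best_frac_baseline` for the baseline
#'   variant, whose grid is tiny).
#' @param best_frac,best_frac_baseline Fractions defining the restart pool.
#' @param prob_floor,prob_ceiling Truncation of trial-wise predicted
#'   probabilities (no renormalization after clipping).
#' @param simplex_maxit Iteration cap per simplex run.
#' @param seed Seed for the simulation-based likelihood (common random
#'   numbers across parameter values) and the restart draws.
#' @return An object of class `mivac_fit_config`.
#' @export
fit_config <- function(sims_per_trial_fit = 50, sims_per_trial_predict = 10000,
                       grid_steps = 7, n_best_starts = 3, n_random_starts = 10,
                       best_frac = 0.01, best_frac_baseline = 0.2,
                       prob_floor = 0.01, prob_ceiling = 0.99,
                       simplex_maxit = 150, seed = 1) {
  stopifnot(prob_floor > 0, prob_floor < prob_ceiling, prob_ceiling < 1)
  structure(list(sims_per_trial_fit = sims_per_trial_fit,
                 sims_per_trial_predict = sims_per_trial_predict,
                 grid_steps = grid_steps, n_best_starts = n_best_starts,
                 n_random_starts = n_random_starts, best_frac = best_frac,
                 best_frac_baseline = best_frac_baseline,
                 prob_floor = prob_floor, prob_ceiling = prob_ceiling,
                 simplex_maxit = simplex_maxit, seed = seed),
            class = "mivac_fit_config")
}

full_par_matrix <- function(par_mat_free, free, params) {
  full <- matrix(rep(c(params$sigma, params$gamma, params$beta, params$pi),
                     each = nrow(par_mat_free)),
                 nrow(par_mat_free), 4,
                 dimnames = list(NULL, c("sigma", "gamma", "beta", "pi")))
  full[, free] <- par_mat_free
  full
}

loglik_engine <- function(par_mat_free, free, params, mats, d_present,
                          observed, config, nsims, seed) {
  cpp_loglik_batch(full_par_matrix(par_mat_free, free, params),
                   mats$inputs, mats$fixvals, d_present,
                   as.integer(observed), dyn_vector(params),
                   as.integer(nsims), config$prob_floor, config$prob_ceiling,
                   as.double(seed), TRUE)
}

#' Simulation-based likelihood of one trial's observed response
#'
#' Relative frequency of the observed response category over
#' `sims_per_trial_fit` simulations, clipped to the configured floor and
#' ceiling (without renormalization).
#'
#' @param trial Single-row `mivac_trials` data frame.
#' @param observed Observed response (`"HV"`, `"LV"`, `"D"`, `"EMPTY"`,
#'   `"MISS"`).
#' @param params A `mivac_params` object.
#' @param config A `mivac_fit_config`.
#' @param seed Simulation seed (defaults to `config$seed`).
#' @return The clipped probability.
#' @export
trial_likelihood <- function(trial, observed, params, config = fit_config(),
                             seed = config$seed) {
  mats <- sim_matrices(trial[1, , drop = FALSE])
  counts <- cpp_outcome_counts(mats$inputs, mats$fixvals, trial$d_present[1],
                               c(params$sigma, params$gamma, params$beta,
                                 params$pi),
                               dyn_vector(params),
                               as.integer(config$sims_per_trial_fit),
                               as.double(seed), TRUE)
  p <- counts[1, response_code(observed) + 1L] / config$sims_per_trial_fit
  min(max(p, config$prob_floor), config$prob_ceiling)
}

#' Simulation-based log-likelihood of a choice set
#'
#' @param choices Data frame with `trial_id` and `response`.
#' @param trials A `mivac_trials` data frame.
#' @param params A `mivac_params` object.
#' @param config A `mivac_fit_config`.
#' @param n_sims Simulations per trial (defaults to
#'   `config$sims_per_trial_fit`).
#' @return Total log-likelihood over the clipped trial-wise probabilities.
#' @export
mivac_loglik <- function(choices, trials, params, config = fit_config(),
                         n_sims = config$sims_per_trial_fit) {
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  mats <- sim_matrices(dat)
  free <- c("sigma", "gamma", "beta", "pi")
  par <- matrix(c(params$sigma, params$gamma, params$beta, params$pi), 1, 4)
  loglik_engine(par, free, params, mats, dat$d_present,
                response_code(dat$response), config, n_sims, config$seed)[1]
}

grid_values <- function(bounds, steps) {
  if (steps == 1) mean(bounds) else seq(bounds[1], bounds[2],
                                        length.out = steps)
}

# bounded Nelder-Mead on a logit-transformed parameter space
simplex_refine <- function(start, free, bounds, objective, maxit) {
  lo <- vapply(bounds[free], `[`, numeric(1), 1)
  hi <- vapply(bounds[free], `[`, numeric(1), 2)
  eps <- 1e-6 * (hi - lo)
  to_z <- function(x) qlogis((pmin(pmax(x, lo + eps), hi - eps) - lo) / (hi - lo))
  to_x <- function(z) lo + (hi - lo) * plogis(z)
  if (length(free) == 1) {
    fit <- optim(to_z(start), function(z) objective(to_x(z)),
                 method = "Brent", lower = -15, upper = 15,
                 control = list(maxit = maxit))
  } else {
    fit <- optim(to_z(start), function(z) objective(to_x(z)),
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-6))
  }
  list(par = to_x(fit$par), value = fit$value)
}

#' Fit one participant's distractor-trial choices
#'
#' Grid search over the free parameters of the requested variant within the
#' fitting bounds, followed by bounded simplex refinements started from the
#' best grid point, random draws from the best grid fraction, and any
#' supplied nested-model solutions.  Only distractor-present trials enter
#' the likelihood; all five response categories (HV, LV, D, empty, miss) are
#' distinct likelihood categories.
#'
#' @param choices Data frame with `trial_id` and `response`.
#' @param trials A `mivac_trials` data frame; only `d_present` trials are
#'   used.
#' @param variant Model variant (see [variant_free_params()]).
#' @param config A `mivac_fit_config`.
#' @param nested_starts Optional list of named parameter vectors used as
#'   additional simplex starts (e.g. best fits of nested variants).
#' @param template Optional `mivac_params` supplying the fixed constants.
#' @return A list of class `mivac_fit`: `participant`-agnostic estimates
#'   (`params`), `variant`, `loglik`, `bic`, `n_trials`, `free`.
#' @export
fit_participant <- function(choices, trials, variant = "mivac",
                            config = fit_config(), nested_starts = NULL,
                            template = NULL) {
  trials <- trials[trials$d_present, , drop = FALSE]
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  if (nrow(dat) == 0) stop("no distractor-present trials to fit")
  if (is.null(template)) template <- mivac_params(sigma = 20)
  template <- apply_variant(template, variant)
  free <- variant_free_params(variant)
  bounds <- mivac_bounds()
  # rare response categories first: they discriminate parameter values most
  # strongly, which lets the grid search abandon poor candidates early
  observed <- response_code(dat$response)
  tab <- tabulate(observed + 1L, nbins = 5L)
  dat <- dat[order(tab[observed + 1L]), , drop = FALSE]
  observed <- response_code(dat$response)
  mats <- sim_matrices(dat)

  grid <- as.matrix(expand.grid(lapply(bounds[free], grid_values,
                                       steps = config$grid_steps)))
  frac <- if (variant == "baseline") config$best_frac_baseline else
    config$best_frac
  n_pool <- max(1L, ceiling(frac * nrow(grid)))
  # cheap prescreen orders the grid so that strong candidates fill the
  # pruning pool first; the ordering is a pure scheduling heuristic and does
  # not enter the retained likelihood values
  n_pre <- min(nrow(dat), 60L)
  pre <- cpp_loglik_batch(full_par_matrix(grid, free, template),
                          mats$inputs[seq_len(n_pre), , drop = FALSE],
                          mats$fixvals[seq_len(n_pre), , drop = FALSE],
                          dat$d_present[seq_len(n_pre)],
                          as.integer(observed[seq_len(n_pre)]),
                          dyn_vector(template), 5L, config$prob_floor,
                          config$prob_ceiling, as.double(config$seed + 77),
                          TRUE)
  ord <- order(pre, decreasing = TRUE)
  ll <- numeric(nrow(grid))
  ll[ord] <- cpp_grid_search(full_par_matrix(grid[ord, , drop = FALSE], free,
                                             template),
                             mats$inputs, mats$fixvals, dat$d_present,
                             as.integer(observed), dyn_vector(template),
                             as.integer(config$sims_per_trial_fit),
                             config$prob_floor, config$prob_ceiling,
                             as.double(config$seed), TRUE,
                             as.integer(n_pool))
  pool <- order(ll, decreasing = TRUE)[seq_len(n_pool)]
  set.seed(config$seed)
  starts <- grid[c(rep(pool[1], config$n_best_starts),
                   sample(pool, config$n_random_starts, replace = TRUE)), ,
                 drop = FALSE]
  for (ns in nested_starts) starts <- rbind(starts, ns[free])

  objective <- function(x) {
    -loglik_engine(matrix(x, 1), free, template, mats, dat$d_present,
                   observed, config, config$sims_per_trial_fit, config$seed)[1]
  }
  best <- list(par = grid[pool[1], ], value = -max(ll))
  for (s in seq_len(nrow(starts))) {
    res <- simplex_refine(starts[s, ], free, bounds, objective,
                          config$simplex_maxit)
    if (res$value < best$value) best <- res
  }
  params <- template
  for (i in seq_along(free)) params[[free[i]]] <- unname(best$par[i])
  loglik <- -best$value
  structure(list(params = params, variant = variant, free = free,
                 loglik = loglik, n_trials = nrow(dat),
                 bic = -2 * loglik + length(free) * log(nrow(dat))),
            class = "mivac_fit")
}

#' Fit all nested variants to one participant
#'
#' Fits the baseline first and passes each solution on as extra simplex
#' starts for the models it is nested in, mirroring the restart schedule of
#' the estimation procedure.
#'
#' @inheritParams fit_participant
#' @param variants Variants to fit.
#' @return Named list of `mivac_fit` objects.
#' @export
fit_variants <- function(choices, trials, variants = MIVAC_VARIANTS,
                         config = fit_config(), template = NULL) {
  order_v <- intersect(c("baseline", "no_vac", "no_ae", "no_dd", "mivac"),
                       variants)
  fits <- list()
  for (v in order_v) {
    nested <- lapply(fits, function(f) {
      p <- f$params
      c(sigma = p$sigma, gamma = p$gamma, beta = p$beta, pi = p$pi)
    })
    # only pass parameter sets that respect the target variant's constraints
    fixed <- setdiff(c("gamma", "beta", "pi"), variant_free_params(v))
    nested <- Filter(function(x) all(x[fixed] == 0), nested)
    fits[[v]] <- fit_participant(choices, trials, v, config,
                                 nested_starts = nested, template = template)
  }
  fits[variants]
}

#' BIC evidence category
#'
#' Maps a BIC difference between the best and second-best model onto the
#' conventional evidence labels; boundary differences (exactly 2, 6, 10)
#' fall into the weaker category since the intervals are open.
#'
#' @param bic_gap Non-negative BIC difference(s).
#' @return Character vector: `"weak"` (gap <= 2), `"positive"` (2-6),
#'   `"strong"` (6-10), or `"very strong"` (> 10).
#' @export
#' @examples
#' evidence_category(c(1, 4, 7, 12))
evidence_category <- function(bic_gap) {
  stopifnot(all(bic_gap >= 0))
  cut(bic_gap, c(-Inf, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"),
      right = TRUE) |> as.character()
}

#' Compare fitted variants across participants
#'
#' @param fits Data frame with columns `participant`, `variant`, `bic` (one
#'   row per participant and variant; see [fits_table()]).
#' @return List with `mean_bic` (per variant), `best` (per participant:
#'   winning variant, BIC gap to the runner-up, evidence category), and
#'   `pairwise` (paired t-tests of BIC differences against the best mean-BIC
#'   variant).
#' @export
compare_models <- function(fits) {
  mean_bic <- aggregate(bic ~ variant, fits, mean)
  mean_bic <- mean_bic[order(mean_bic$bic), ]
  best_v <- mean_bic$variant[1]
  per_part <- lapply(split(fits, fits$participant), function(d) {
    d <- d[order(d$bic), ]
    gap <- d$bic[2] - d$bic[1]
    data.frame(participant = d$participant[1], best_model = d$variant[1],
               bic_gap = gap, evidence = evidence_category(gap))
  })
  best <- do.call(rbind, per_part)
  rownames(best) <- NULL
  others <- setdiff(unique(fits$variant), best_v)
  pairwise <- do.call(rbind, lapply(others, function(v) {
    m <- merge(fits[fits$variant == best_v, c("participant", "bic")],
               fits[fits$variant == v, c("participant", "bic")],
               by = "participant", suffixes = c("_best", "_other"))
    tt <- t.test(m$bic_other, m$bic_best, paired = TRUE)
    data.frame(variant = v, mean_diff = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  list(mean_bic = mean_bic, best = best, pairwise = pairwise)
}

#' Flatten a list of fits into a table
#'
#' @param fit_list Named list (participants) of named lists (variants) of
#'   `mivac_fit` objects.
#' @return Data frame with participant, variant, parameter estimates,
#'   `loglik` and `bic`.
#' @export
fits_table <- function(fit_list) {
  rows <- list()
  for (pid in names(fit_list)) {
    for (v in names(fit_list[[pid]])) {
      f <- fit_list[[pid]][[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant = pid, variant = v, sigma = f$params$sigma,
        gamma = f$params$gamma, beta = f$params$beta, pi = f$params$pi,
        loglik = f$loglik, bic = f$bic)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Out-of-sample predicted response probabilities
#'
#' Fresh simulations (default `sims_per_trial_predict`) of each trial under
#' fixed parameters; used for generalization tests and qualitative
#' signatures.
#'
#' @param params A `mivac_params` object.
#' @param trials A `mivac_trials` data frame.
#' @param config A `mivac_fit_config`.
#' @param n_sims Simulations per trial.
#' @param seed Simulation seed.
#' @return Matrix `n_trials x 5` of response probabilities (columns HV, LV,
#'   D, EMPTY, MISS), not clipped.
#' @export
predict_response_probs <- function(params, trials, config = fit_config(),
                                   n_sims = config$sims_per_trial_predict,
                                   seed = config$seed + 1) {
  mats <- sim_matrices(trials)
  counts <- cpp_outcome_counts(mats$inputs, mats$fixvals, trials$d_present,
                               c(params$sigma, params$gamma, params$beta,
                                 params$pi),
                               dyn_vector(params), as.integer(n_sims),
                               as.double(seed), TRUE)
  p <- counts / n_sims
  colnames(p) <- RESPONSE_LEVELS
  p
}

#' Generalization deviance on held-out trials
#'
#' Deviance `-2 * sum(log p)` of held-out observations under clipped
#' out-of-sample predicted probabilities from fresh simulations.
#'
#' @param fit A `mivac_fit` (or a `mivac_params` object).
#' @param choices Held-out choices (`trial_id`, `response`).
#' @param trials Held-out `mivac_trials`.
#' @param config A `mivac_fit_config`.
#' @param n_sims Simulations per trial (defaults to
#'   `config$sims_per_trial_predict`).
#' @param seed Simulation seed.
#' @return The deviance (numeric scalar).
#' @export
generalize <- function(fit, choices, trials, config = fit_config(),
                       n_sims = config$sims_per_trial_predict,
                       seed = config$seed + 1) {
  params <- if (inherits(fit, "mivac_fit")) fit$params else fit
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  p <- predict_response_probs(params, dat, config, n_sims, seed)
  obs <- response_code(dat$response) + 1L
  pr <- pmin(pmax(p[cbind(seq_len(nrow(dat)), obs)], config$prob_floor),
             config$prob_ceiling)
  -2 * sum(log(pr))
}
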