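# The MIVAC simulator: mutual-inhibition accumulator dynamics with
# value-based attentional capture, attended-input enhancement, and
# probabilistic distractor identification, plus the multi-attribute
# comparison extension and the empirical fixation-duration variant.

MIVAC_VARIANTS <- c("mivac", "no_vac", "no_ae", "no_dd", "baseline")

#' MIVAC parameters
#'
#' Free parameters of the accumulator model together with its fixed dynamics
#' constants.  The free parameters are the per-step accumulation-noise SD
#' `sigma`, the attentional-capture weight `gamma` (value-dependence of
#' fixation probabilities), the attended-input boost `beta`, and the
#' per-check distractor-identification probability `pi`.  The constants fix
#' leakage at 0.96, mutual inhibition at -0.036, the collapsing bound at
#' 1000 falling linearly to 200 over the decision horizon (1400 ms under
#' high time pressure), a 200 ms non-decision time, a 10 ms step, a 200 ms
#' fixation period, and a 100 ms distractor-identification period.  Noise is
#' per 10 ms step; the step size is part of the model definition.
#'
#' @param sigma Accumulation-noise SD, in `[5, 50]` when fitted.
#' @param gamma Attentional-capture weight, in `[-1.12, 3.08]` when fitted.
#' @param beta Attended-input boost, in `[-2.1, 18.9]` when fitted.
#' @param pi Distractor-identification probability per 100 ms check, in
#'   `[0, 1]`.
#' @param leak,inhibition,theta0,theta_end,nondecision_ms,dt_ms Fixed
#'   dynamics constants (overridable for exploration).
#' @param fixation_period_ms,detection_period_ms Fixation and
#'   identification periods.
#' @param horizon_ms Decision horizon (1400 ms high pressure; 5800 ms when
#'   emulating the 6 s low-pressure deadline net of non-decision time).
#' @return An object of class `mivac_params`.
#' @export
#' @examples
#' mivac_params(sigma = 15, gamma = 1, beta = 8, pi = 0.3)
mivac_params <- function(sigma, gamma = 0, beta = 0, pi = 0,
                         leak = 0.96, inhibition = -0.036,
                         theta0 = 1000, theta_end = 200,
                         nondecision_ms = 200, dt_ms = 10,
                         fixation_period_ms = 200, detection_period_ms = 100,
                         horizon_ms = 1400) {
  stopifnot(sigma >= 0, pi >= 0, pi <= 1, horizon_ms > 0, dt_ms > 0)
  structure(list(sigma = sigma, gamma = gamma, beta = beta, pi = pi,
                 leak = leak, inhibition = inhibition, theta0 = theta0,
                 theta_end = theta_end, nondecision_ms = nondecision_ms,
                 dt_ms = dt_ms, fixation_period_ms = fixation_period_ms,
                 detection_period_ms = detection_period_ms,
                 horizon_ms = horizon_ms),
            class = "mivac_params")
}

#' Fitting bounds of the free MIVAC parameters
#'
#' @return Named list of `c(lower, upper)` bounds for `sigma`, `gamma`,
#'   `beta` and `pi`.
#' @export
mivac_bounds <- function() {
  list(sigma = c(5, 50), gamma = c(-1.12, 3.08),
       beta = c(-2.1, 18.9), pi = c(0, 1))
}

#' Free parameters of a model variant
#'
#' The nested variants fix some mechanisms at zero: `no_vac` removes
#' value-based attentional capture (`gamma = 0`), `no_ae` the attended-input
#' boost (`beta = 0`), `no_dd` distractor detection (`pi = 0`), and
#' `baseline` all three.
#'
#' @param variant One of `"mivac"`, `"no_vac"`, `"no_ae"`, `"no_dd"`,
#'   `"baseline"`.
#' @return Character vector of free-parameter names.
#' @export
variant_free_params <- function(variant = MIVAC_VARIANTS) {
  variant <- match.arg(variant)
  switch(variant,
    mivac = c("sigma", "gamma", "beta", "pi"),
    no_vac = c("sigma", "beta", "pi"),
    no_ae = c("sigma", "gamma", "pi"),
    no_dd = c("sigma", "gamma", "beta"),
    baseline = "sigma")
}

apply_variant <- function(params, variant) {
  fixed <- setdiff(c("gamma", "beta", "pi"), variant_free_params(variant))
  for (nm in fixed) params[[nm]] <- 0
  params
}

dyn_vector <- function(params, horizon_ms = NULL) {
  c(params$leak, params$inhibition, params$theta0, params$theta_end,
    params$dt_ms, params$fixation_period_ms, params$detection_period_ms,
    if (is.null(horizon_ms)) params$horizon_ms else horizon_ms,
    params$nondecision_ms)
}

#' Value-dependent fixation probabilities
#'
#' Probability of fixating each of the four quadrant targets: a softmax of
#' `gamma` times the expected values normalized by their sum over all
#' currently presented options (empty quadrants contribute 0; once the
#' distractor is identified its normalized value is 0).  With `gamma = 0`,
#' or when all values are zero, fixations are uniform.
#'
#' @param evs Numeric vector of four non-negative values (HV, LV, D, empty).
#' @param gamma Attentional-capture weight.
#' @param d_identified Has the distractor been identified?
#' @return Numeric vector of four probabilities summing to 1.
#' @export
#' @examples
#' fixation_probabilities(c(5, 1.5, 4.5, 0), gamma = 3.08)
fixation_probabilities <- function(evs, gamma, d_identified = FALSE) {
  stopifnot(length(evs) == 4, all(evs >= 0))
  if (d_identified) evs[3] <- 0
  s <- sum(evs)
  if (s <= 0 || gamma == 0) return(rep(0.25, 4))
  w <- gamma * evs / s
  e <- exp(w - max(w))
  e / sum(e)
}

# accumulator inputs and fixation values (n x 4 matrices) for a trial set
sim_matrices <- function(trials, values = c("ev", "eu"), alpha = 1) {
  values <- match.arg(values)
  if (values == "ev") {
    v_hv <- trials$hv_mag * trials$hv_prob
    v_lv <- trials$lv_mag * trials$lv_prob
    v_d <- ifelse(trials$d_present, trials$d_mag * trials$d_prob, 0)
  } else {
    r_eu <- eu_grid_range(alpha)
    tr <- function(m, p) transform_eu_to_ev_range(
      subjective_value(m, p, "EU", alpha = alpha),
      r_eu[1], r_eu[2], 0.25, 10.5)
    v_hv <- tr(trials$hv_mag, trials$hv_prob)
    v_lv <- tr(trials$lv_mag, trials$lv_prob)
    v_d <- ifelse(trials$d_present, tr(trials$d_mag, trials$d_prob), 0)
    v_d[!trials$d_present] <- 0
  }
  m <- cbind(v_hv, v_lv, v_d, 0)
  list(inputs = m, fixvals = m)
}

#' Simulate behavior from MIVAC or one of its nested variants
#'
#' Runs the accumulator race for each trial: every 10 ms step the four
#' accumulators leak, inhibit each other, and integrate their inputs (the
#' option values, plus `beta` for the fixated target) with Gaussian noise;
#' a new fixation is drawn every 200 ms with value-dependent probabilities;
#' from 100 ms onward the distractor can be identified at each 100 ms check,
#' after which its input and fixation value are 0.  The first accumulator to
#' reach the collapsing bound determines the response; no crossing within
#' the horizon is a miss.
#'
#' @param trials A `mivac_trials` data frame.
#' @param params A `mivac_params` object.
#' @param n_reps Simulations per trial.
#' @param seed Integer seed (deterministic engine-side generator).
#' @param variant Model variant; forces the corresponding parameters to 0.
#' @param values Accumulator inputs: `"ev"` (default) or `"eu"` (power
#'   utilities rescaled onto the EV range).
#' @param alpha Utility curvature when `values = "eu"`.
#' @param record_fixations Record the fixation stream?
#' @param fixation_model Optional `fixation_duration_model`; when supplied,
#'   fixation durations are sampled from its log-normal cells instead of the
#'   fixed 200 ms schedule.
#' @param beta_on_empty Does the attended-input boost also apply when an
#'   empty quadrant is fixated?  Default `TRUE`.
#' @return Data frame with `trial_id`, `rep`, `response`, `rt_ms` (including
#'   the 200 ms non-decision time; `NA` for misses).  When
#'   `record_fixations` is `TRUE` the fixation stream is attached as
#'   attribute `"fixations"` (`trial_id`, `rep`, `fix_index`, `target`,
#'   `onset_ms`, `duration_ms`, `fixation_type`).
#' @export
simulate_trials <- function(trials, params, n_reps = 1, seed = 1,
                            variant = "mivac", values = "ev", alpha = 1,
                            record_fixations = FALSE, fixation_model = NULL,
                            beta_on_empty = TRUE) {
  params <- apply_variant(params, variant)
  mats <- sim_matrices(trials, values, alpha)
  fixdur <- if (is.null(fixation_model)) NULL else
    fixation_model_matrix(fixation_model)
  res <- cpp_simulate(mats$inputs, mats$fixvals, trials$d_present,
                      c(params$sigma, params$gamma, params$beta, params$pi),
                      dyn_vector(params), as.integer(n_reps), as.double(seed),
                      beta_on_empty, record_fixations, fixdur)
  out <- data.frame(
    trial_id = trials$trial_id[res$trial],
    rep = res$rep,
    response = response_factor(res$response),
    rt_ms = res$rt_ms
  )
  if (record_fixations) {
    fx <- res$fixations
    target <- c("HV", "LV", "D", "EMPTY")[fx$target + 1L]
    target[fx$target == 2L & !trials$d_present[fx$trial]] <- "EMPTY"
    attr(out, "fixations") <- data.frame(
      trial_id = trials$trial_id[fx$trial],
      rep = fx$rep,
      fix_index = fx$fix_index,
      target = target,
      quadrant = fx$target + 1L,
      onset_ms = fx$onset_ms,
      duration_ms = fx$duration_ms,
      fixation_type = ifelse(fx$fix_index == 1L, "first", "middle")
    )
  }
  out
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_trials()] for one trial.
#'
#' @inheritParams simulate_trials
#' @param trial A single-row `mivac_trials` data frame.
#' @return One-row data frame (`response`, `rt_ms`), with the fixation
#'   sequence attached as attribute `"fixations"`.
#' @export
simulate_trial <- function(trial, params, seed = 1, ...) {
  simulate_trials(trial[1, , drop = FALSE], params, n_reps = 1, seed = seed,
                  record_fixations = TRUE, ...)
}

# ------------------------------------------------------------------ MLBA ----

#' Parameters of the multi-attribute comparison extension
#'
#' The extension replaces the plain value inputs by sums of pairwise
#' attribute comparisons in the style of multi-attribute linear ballistic
#' accumulation: `I_i = sum_j V_ij + i0`, where
#' `V_ij = w^M (u_i^M - u_j^M) + w^P (u_i^P - u_j^P)` on the objective
#' magnitude and probability scales.  The attribute weight decays with
#' attribute distance, fast (`lambda1 = 3`) on attributes where the
#' comparing option i is at least as good as j and slowly
#' (`lambda2 = 0.05`) where it is worse.  Advantages are therefore heavily
#' discounted while disadvantages count almost fully at any distance, so
#' an option adjacent to the distractor in attribute space carries only
#' small penalties from that comparison while the dissimilar option is
#' penalized by its large attribute disadvantages; relative accuracy rises
#' when the distractor neighbors HV, whether it dominates or is dominated
#' (the combined attraction and phantom-decoy pattern).
#'
#' @param i0 Baseline input to every option accumulator (default 20).
#' @param lambda1 Weight decay on attributes where the comparing option is
#'   at least as good (default 3).
#' @param lambda2 Weight decay on attributes where the comparing option is
#'   worse (default 0.05).
#' @return An object of class `mlba_params`.
#' @export
mlba_params <- function(i0 = 20, lambda1 = 3, lambda2 = 0.05) {
  stopifnot(i0 >= 0, lambda1 > 0, lambda2 > 0)
  structure(list(i0 = i0, lambda1 = lambda1, lambda2 = lambda2),
            class = "mlba_params")
}

#' Pairwise comparison value between two options
#'
#' @param mag_i,prob_i,mag_j,prob_j Attribute values of options i and j.
#' @param ext An `mlba_params` object.
#' @return The comparison value `V_ij` (vectorized).
#' @export
mlba_comparison <- function(mag_i, prob_i, mag_j, prob_j,
                            ext = mlba_params()) {
  wgt <- function(ui, uj) {
    d <- abs(ui - uj)
    ifelse(ui >= uj, exp(-ext$lambda1 * d), exp(-ext$lambda2 * d))
  }
  wgt(mag_i, mag_j) * (mag_i - mag_j) + wgt(prob_i, prob_j) * (prob_i - prob_j)
}

mlba_inputs <- function(trials, ext) {
  n <- nrow(trials)
  mags <- cbind(trials$hv_mag, trials$lv_mag, trials$d_mag)
  probs <- cbind(trials$hv_prob, trials$lv_prob, trials$d_prob)
  inputs <- matrix(0, n, 4)
  for (i in 1:3) {
    acc <- rep(ext$i0, n)
    for (j in setdiff(1:3, i))
      acc <- acc + mlba_comparison(mags[, i], probs[, i], mags[, j], probs[, j],
                                   ext)
    inputs[, i] <- acc
  }
  inputs
}

#' Simulate trials under the multi-attribute comparison extension
#'
#' As [simulate_trials()], but accumulator inputs come from pairwise
#' attribute comparisons (see [mlba_params()]) and the default horizon is
#' the 6 s low-time-pressure deadline.  Fixation probabilities still follow
#' the expected values.  After identification the distractor's own input is
#' set to 0, but its attributes keep entering the other options' comparison
#' sums, which carries the phantom-decoy influence.
#'
#' @inheritParams simulate_trials
#' @param ext An `mlba_params` object.
#' @param horizon_ms Decision horizon (default `6000 - nondecision`).
#' @return As [simulate_trials()].
#' @export
simulate_trials_mlba <- function(trials, params, ext = mlba_params(),
                                 n_reps = 1, seed = 1, variant = "mivac",
                                 horizon_ms = NULL, record_fixations = FALSE,
                                 beta_on_empty = TRUE) {
  stopifnot(all(trials$d_present))
  params <- apply_variant(params, variant)
  if (is.null(horizon_ms)) horizon_ms <- 6000 - params$nondecision_ms
  inputs <- mlba_inputs(trials, ext)
  fixvals <- sim_matrices(trials)$fixvals
  res <- cpp_simulate(inputs, fixvals, trials$d_present,
                      c(params$sigma, params$gamma, params$beta, params$pi),
                      dyn_vector(params, horizon_ms), as.integer(n_reps),
                      as.double(seed), beta_on_empty, record_fixations, NULL)
  data.frame(
    trial_id = trials$trial_id[res$trial],
    rep = res$rep,
    response = response_factor(res$response),
    rt_ms = res$rt_ms
  )
}

# ------------------------------------------- fixation-duration model --------

#' Log-normal fixation-duration model
#'
#' Cellwise log-normal fixation durations by option type (HV, LV, D, empty)
#' and fixation type (first vs middle), replacing the fixed 200 ms fixation
#' schedule when passed to [simulate_trials()].
#'
#' @param cells Data frame with columns `option_type`
#'   (`"HV"`, `"LV"`, `"D"`, `"EMPTY"`), `fixation_type`
#'   (`"first"`, `"middle"`), `meanlog`, `sdlog`.
#' @return An object of class `fixation_duration_model`.
#' @seealso [default_fixation_model()]
#' @export
fixation_duration_model <- function(cells) {
  need <- expand.grid(option_type = c("HV", "LV", "D", "EMPTY"),
                      fixation_type = c("first", "middle"),
                      stringsAsFactors = FALSE)
  key <- paste(cells$option_type, cells$fixation_type)
  if (!all(paste(need$option_type, need$fixation_type) %in% key))
    stop("missing cell in fixation-duration model")
  if (any(cells$sdlog < 0)) stop("sdlog must be non-negative")
  structure(list(cells = cells), class = "fixation_duration_model")
}

#' Default synthetic fixation-duration model
#'
#' A plausible stand-in for empirically fitted cells: median durations
#' around 250 ms for first and 200 ms for middle fixations (first fixations
#' longer than middle ones), slightly longer on options than on empty
#' quadrants, with log-scale SD 0.4.
#'
#' @return A `fixation_duration_model`.
#' @export
default_fixation_model <- function() {
  cells <- expand.grid(option_type = c("HV", "LV", "D", "EMPTY"),
                       fixation_type = c("first", "middle"),
                       stringsAsFactors = FALSE)
  med <- ifelse(cells$fixation_type == "first", 250, 200) *
    ifelse(cells$option_type == "EMPTY", 0.8, 1)
  cells$meanlog <- log(med)
  cells$sdlog <- 0.4
  fixation_duration_model(cells)
}

fixation_model_matrix <- function(model) {
  cells <- model$cells
  m <- matrix(NA_real_, 4, 4)
  opts <- c("HV", "LV", "D", "EMPTY")
  for (i in 1:4) {
    f <- cells[cells$option_type == opts[i] & cells$fixation_type == "first", ]
    mid <- cells[cells$option_type == opts[i] & cells$fixation_type == "middle", ]
    m[i, ] <- c(f$meanlog[1], f$sdlog[1], mid$meanlog[1], mid$sdlog[1])
  }
  m
}

#' Sample fixation durations from a log-normal cell
#'
#' @param model A `fixation_duration_model`.
#' @param option_type,fixation_type Cell selectors.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Positive durations in ms.
#' @export
sample_fixation_duration <- function(model, option_type, fixation_type, n = 1,
                                     seed = NULL) {
  cells <- model$cells
  row <- cells[cells$option_type == option_type &
                 cells$fixation_type == fixation_type, ]
  if (nrow(row) == 0) stop("missing cell: ", option_type, "/", fixation_type)
  if (!is.null(seed)) set.seed(seed)
  rlnorm(n, row$meanlog[1], row$sdlog[1])
}
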