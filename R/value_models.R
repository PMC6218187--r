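# Static choice models used to test whether choosers integrate magnitude and
# probability: single-attribute models (OM, OP), expected value (EV),
# expected utility (EU) with a power utility, and prospect theory (PT) with a
# one-parameter probability-weighting function, all combined with a logistic
# choice rule.

SIMPLE_MODELS <- c("OM", "OP", "EV", "EU", "PT")

#' Subjective value of a gamble under a static choice model
#'
#' * `OM` uses only the magnitude, `OP` only the probability.
#' * `EV` is `probability * magnitude`.
#' * `EU` is `magnitude^alpha * probability` (power utility).
#' * `PT` is `magnitude^alpha * w(probability)` with the one-parameter
#'   weighting function `w(p) = p^tau / (p^tau + (1 - p)^tau)^(1/tau)`,
#'   applied to the single win probability of these two-outcome gambles.
#'
#' @param magnitude,probability Gamble attributes (vectorized).
#' @param model One of `"OM"`, `"OP"`, `"EV"`, `"EU"`, `"PT"`.
#' @param alpha Utility curvature (> 0), used by EU and PT.
#' @param tau Probability-weighting exponent (> 0), used by PT.
#' @return Numeric vector of subjective values.
#' @export
#' @examples
#' subjective_value(8, 5 / 8, "EU", alpha = 1)    # 5, identical to EV
#' subjective_value(8, 5 / 8, "EU", alpha = 0.5)  # 1.76777
subjective_value <- function(magnitude, probability,
                             model = c("EV", "OM", "OP", "EU", "PT"),
                             alpha = 1, tau = 1) {
  model <- match.arg(model)
  if (model %in% c("EU", "PT") && (!is.finite(alpha) || alpha <= 0))
    stop("invalid parameter: alpha must be positive")
  if (model == "PT" && (!is.finite(tau) || tau <= 0))
    stop("invalid parameter: tau must be positive")
  switch(model,
    OM = magnitude,
    OP = probability,
    EV = magnitude * probability,
    EU = magnitude^alpha * probability,
    PT = magnitude^alpha *
      probability^tau / (probability^tau + (1 - probability)^tau)^(1 / tau)
  )
}

#' Logistic choice rule
#'
#' Probability of choosing option a over option b given their subjective
#' values: `1 / (1 + exp(-sensitivity * (sv_a - sv_b)))`.
#'
#' @param sv_a,sv_b Subjective values (vectorized).
#' @param sensitivity Non-negative sensitivity to value differences.
#' @return Choice probabilities in (0, 1).
#' @export
#' @examples
#' choice_probability(5, 1.5, 0.5)  # 0.85195
choice_probability <- function(sv_a, sv_b, sensitivity) {
  if (any(sensitivity < 0)) stop("sensitivity must be non-negative")
  plogis(sensitivity * (sv_a - sv_b))
}

#' Affine rescaling of expected utilities onto the expected-value range
#'
#' When EU-based subjective values replace EVs as accumulator inputs, they
#' are rescaled onto the EV range so that model dynamics stay comparable:
#' `ev_min + (eu - eu_min) * (ev_max - ev_min) / (eu_max - eu_min)`.
#'
#' @param eu Value(s) to transform.
#' @param eu_min,eu_max Range of the EU values (max must exceed min).
#' @param ev_min,ev_max Target EV range.
#' @return Transformed values.
#' @export
transform_eu_to_ev_range <- function(eu, eu_min, eu_max, ev_min, ev_max) {
  if (eu_max <= eu_min || ev_max <= ev_min)
    stop("degenerate range in EU-to-EV transformation")
  ev_min + (eu - eu_min) * (ev_max - ev_min) / (eu_max - eu_min)
}

#' Range of EU values over the full stimulus grid
#'
#' @param alpha Utility curvature.
#' @param tau Probability-weighting exponent (1 for plain EU).
#' @return Numeric vector `c(min, max)` of subjective values over the grid.
#' @export
eu_grid_range <- function(alpha, tau = 1) {
  g <- stimulus_grid()
  grid <- expand.grid(m = g$magnitudes, p = g$probabilities)
  v <- subjective_value(grid$m, grid$p, if (tau == 1) "EU" else "PT",
                        alpha = alpha, tau = tau)
  range(v)
}

simple_model_npar <- function(model) {
  switch(model, OM = 1L, OP = 1L, EV = 1L, EU = 2L, PT = 3L)
}

simple_model_sv <- function(trials, model, alpha, tau) {
  sv_hv <- subjective_value(trials$hv_mag, trials$hv_prob, model, alpha, tau)
  sv_lv <- subjective_value(trials$lv_mag, trials$lv_prob, model, alpha, tau)
  cbind(hv = sv_hv, lv = sv_lv)
}

simple_model_loglik <- function(par, chose_hv, trials, model,
                                floor_p = 1e-12) {
  alpha <- if (model %in% c("EU", "PT")) par[["alpha"]] else 1
  tau <- if (model == "PT") par[["tau"]] else 1
  sv <- simple_model_sv(trials, model, alpha, tau)
  p_hv <- choice_probability(sv[, "hv"], sv[, "lv"], par[["sensitivity"]])
  p <- ifelse(chose_hv, p_hv, 1 - p_hv)
  sum(log(pmax(p, floor_p)))
}

#' Maximum-likelihood fits of the static choice models
#'
#' Fits each requested model to one participant's HV-vs-LV choices by
#' bounded multi-start optimization and compares them by BIC.  Only trials
#' with an HV or LV response enter the likelihood.
#'
#' @param choices Data frame with columns `trial_id` and `response`.
#' @param trials A `mivac_trials` data frame.
#' @param models Models to fit (default all five).
#' @param sensitivity_bounds,alpha_bounds,tau_bounds Optimizer bounds.
#' @param n_starts Number of multi-start points per model.
#' @param seed Seed for the start-point draws.
#' @return Data frame with one row per model: parameter estimates, `loglik`,
#'   `bic`, `n_trials`, ranked by BIC (best first).
#' @export
fit_simple_models <- function(choices, trials, models = SIMPLE_MODELS,
                              sensitivity_bounds = c(0, 20),
                              alpha_bounds = c(1e-3, 5),
                              tau_bounds = c(1e-3, 5),
                              n_starts = 8, seed = 1) {
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  dat <- dat[dat$response %in% c("HV", "LV"), , drop = FALSE]
  if (nrow(dat) < 1) stop("no HV/LV responses to fit")
  chose_hv <- dat$response == "HV"
  n <- nrow(dat)

  set.seed(seed)
  fits <- lapply(models, function(model) {
    par_names <- c("sensitivity",
                   if (model %in% c("EU", "PT")) "alpha",
                   if (model == "PT") "tau")
    lo <- c(sensitivity = sensitivity_bounds[1], alpha = alpha_bounds[1],
            tau = tau_bounds[1])[par_names]
    hi <- c(sensitivity = sensitivity_bounds[2], alpha = alpha_bounds[2],
            tau = tau_bounds[2])[par_names]
    obj <- function(p) {
      names(p) <- par_names
      -simple_model_loglik(p, chose_hv, dat, model)
    }
    starts <- rbind(
      (lo + hi) / 2,
      matrix(runif(length(par_names) * (n_starts - 1), lo, hi),
             ncol = length(par_names), byrow = TRUE)
    )
    # mildly informative default start for the sensitivity scale
    starts[1, 1] <- min(1, hi[1])
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo, upper = hi),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    par <- setNames(best$par, par_names)
    k <- simple_model_npar(model)
    loglik <- -best$value
    data.frame(
      model = model,
      alpha = if ("alpha" %in% par_names) par[["alpha"]] else NA_real_,
      tau = if ("tau" %in% par_names) par[["tau"]] else NA_real_,
      sensitivity = par[["sensitivity"]],
      loglik = loglik,
      bic = -2 * loglik + k * log(n),
      n_trials = n
    )
  })
  out <- do.call(rbind, fits)
  out[order(out$bic), , drop = FALSE]
}

#' Simulate HV-vs-LV choices from a static choice model
#'
#' @param trials A `mivac_trials` data frame.
#' @param model Static model name.
#' @param sensitivity,alpha,tau Model parameters.
#' @param seed Integer seed.
#' @return Data frame with `trial_id` and `response` (`"HV"` or `"LV"`).
#' @export
simulate_simple_choices <- function(trials, model = "EV", sensitivity = 0.5,
                                    alpha = 1, tau = 1, seed = 1) {
  sv <- simple_model_sv(trials, model, alpha, tau)
  p_hv <- choice_probability(sv[, "hv"], sv[, "lv"], sensitivity)
  set.seed(seed)
  data.frame(
    trial_id = trials$trial_id,
    response = ifelse(rbinom(nrow(trials), 1, p_hv) == 1, "HV", "LV")
  )
}
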