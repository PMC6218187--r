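# Multinomial-logit baselines: a chooser that perfectly excludes the
# distractor, one that treats it as a regular option, and one that adds a
# "frame value" for choosable options.

LOGIT_MODELS <- c("exclude_d", "include_d", "frame_value")

#' Choice probability under the distractor-excluding logit model
#'
#' The probability of choosing HV is a logistic function of the expected
#' value difference between HV and LV; the distractor plays no role, so the
#' prediction is identical whether it is present or absent.
#'
#' @param trials A `mivac_trials` data frame.
#' @param sensitivity Non-negative value-difference sensitivity.
#' @return Numeric vector `P(HV among HV, LV)` per trial.
#' @export
#' @examples
#' tr <- enumerate_novel_trials()[1, ]
#' exclude_d_probability(tr, 0.5)
exclude_d_probability <- function(trials, sensitivity) {
  if (sensitivity < 0) stop("sensitivity must be non-negative")
  plogis(sensitivity * (trials$hv_mag * trials$hv_prob -
                          trials$lv_mag * trials$lv_prob))
}

#' Choice probabilities under the distractor-including logit model
#'
#' Softmax of `sensitivity * EV` over HV, LV and D; the distractor competes
#' as a regular option.
#'
#' @inheritParams exclude_d_probability
#' @return Matrix `n x 3` of probabilities (columns HV, LV, D) summing to 1.
#' @export
include_d_probabilities <- function(trials, sensitivity) {
  frame_value_probabilities(trials, sensitivity, frame_value = 0)
}

#' Choice probabilities under the frame-value logit model
#'
#' As [include_d_probabilities()], but each choosable option's subjective
#' value is its EV plus a non-negative frame value attached to the target
#' frame; the distractor's frame value is 0.  With `frame_value = 0` the
#' model reduces exactly to the distractor-including model.
#'
#' @inheritParams exclude_d_probability
#' @param frame_value Non-negative frame value of the choosable options.
#' @return Matrix `n x 3` of probabilities (columns HV, LV, D) summing to 1.
#' @export
frame_value_probabilities <- function(trials, sensitivity, frame_value) {
  if (sensitivity < 0) stop("sensitivity must be non-negative")
  if (frame_value < 0) stop("invalid parameter: frame_value must be >= 0")
  if (!all(trials$d_present))
    stop("model undefined for binary trials (no distractor)")
  sv <- cbind(HV = trials$hv_mag * trials$hv_prob + frame_value,
              LV = trials$lv_mag * trials$lv_prob + frame_value,
              D = trials$d_mag * trials$d_prob)
  z <- sensitivity * sv
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Maximum-likelihood fit of a multinomial-logit baseline
#'
#' Data subsets follow the models' scope: the distractor-excluding model is
#' fitted on HV/LV-choice trials only, the other two on HV/LV/D-choice
#' trials of distractor-present trials.  Empty-quadrant choices and misses
#' have no category under these models and are excluded.
#'
#' @param choices Data frame with `trial_id`, `response`.
#' @param trials A `mivac_trials` data frame.
#' @param model One of `"exclude_d"`, `"include_d"`, `"frame_value"`.
#' @param sensitivity_bounds,frame_value_bounds Optimizer bounds.
#' @return List with `model`, `sensitivity`, `frame_value` (or `NA`),
#'   `loglik`, `n_trials`, and `predicted` choice proportions per category.
#' @export
fit_logit_model <- function(choices, trials,
                            model = c("exclude_d", "include_d", "frame_value"),
                            sensitivity_bounds = c(0, 20),
                            frame_value_bounds = c(0, 50)) {
  model <- match.arg(model)
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  if (model == "exclude_d") {
    dat <- dat[dat$response %in% c("HV", "LV"), , drop = FALSE]
  } else {
    dat <- dat[dat$d_present & dat$response %in% c("HV", "LV", "D"), ,
               drop = FALSE]
  }
  if (nrow(dat) == 0) stop("no usable trials for this model")

  negll <- function(par) {
    if (model == "exclude_d") {
      p_hv <- exclude_d_probability(dat, par[1])
      p <- ifelse(dat$response == "HV", p_hv, 1 - p_hv)
    } else {
      fv <- if (model == "frame_value") par[2] else 0
      pm <- frame_value_probabilities(dat, par[1], fv)
      p <- pm[cbind(seq_len(nrow(dat)),
                    match(dat$response, c("HV", "LV", "D")))]
    }
    -sum(log(pmax(p, 1e-12)))
  }
  npar <- if (model == "frame_value") 2L else 1L
  lo <- c(sensitivity_bounds[1], frame_value_bounds[1])[seq_len(npar)]
  hi <- c(sensitivity_bounds[2], frame_value_bounds[2])[seq_len(npar)]
  best <- NULL
  for (start in list((lo + hi) / 2, lo + 0.1 * (hi - lo),
                     lo + 0.9 * (hi - lo))) {
    fit <- tryCatch(optim(start, negll, method = "L-BFGS-B",
                          lower = lo, upper = hi),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  sens <- best$par[1]
  fv <- if (model == "frame_value") best$par[2] else NA_real_
  pred <- if (model == "exclude_d") {
    p_hv <- exclude_d_probability(dat, sens)
    c(HV = mean(p_hv), LV = mean(1 - p_hv), D = 0)
  } else {
    colMeans(frame_value_probabilities(dat, sens,
                                       if (is.na(fv)) 0 else fv))
  }
  list(model = model, sensitivity = sens, frame_value = fv,
       loglik = -best$value, n_trials = nrow(dat), predicted = pred)
}
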