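# Complete synthetic studies: per-participant trial sets, accumulator-model
# parameters drawn from truncated normals, and simulated choices, response
# times and fixation streams, so that every pipeline stage is testable
# without external data.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the high-time-pressure study conditions: 150 distractor
#' and 150 binary trials per participant plus the 56-trial Dominance x
#' Similarity set, a 1400 ms decision horizon, and participant-level
#' parameters drawn from truncated normals inside the fitting bounds.
#' The parameter location/spread defaults were chosen once so that
#' simulated aggregates sit in the empirically reported ranges (distractor
#' chosen in a few percent of distractor trials, misses rare, relative
#' accuracy well above chance); see the package vignette.
#'
#' @param n_participants Number of simulated participants.
#' @param n_distractor,n_binary Trials per participant in the
#'   rejection-sampled choice set.
#' @param include_novel Append the 56-trial Dominance x Similarity set?
#' @param param_means,param_sds Named means and SDs (sigma, gamma, beta,
#'   pi) of the truncated-normal parameter population.
#' @param horizon_ms Decision horizon (1400 high pressure).
#' @param fixation_model Optional `fixation_duration_model` replacing the
#'   fixed 200 ms fixation schedule.
#' @param seed Master seed; everything derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20, n_distractor = 150,
                          n_binary = 150, include_novel = TRUE,
                          param_means = c(sigma = 18, gamma = 1.2,
                                          beta = 8, pi = 0.35),
                          param_sds = c(sigma = 6, gamma = 0.7,
                                        beta = 4, pi = 0.18),
                          horizon_ms = 1400, fixation_model = NULL,
                          seed = 1) {
  structure(list(n_participants = n_participants,
                 n_distractor = n_distractor, n_binary = n_binary,
                 include_novel = include_novel, param_means = param_means,
                 param_sds = param_sds, horizon_ms = horizon_ms,
                 fixation_model = fixation_model, seed = seed),
            class = "cohort_config")
}

rtnorm_bounded <- function(n, mean, sd, bounds) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= bounds[1] && x <= bounds[2]) break
    }
    out[i] <- x
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' For each participant: a fresh rejection-sampled choice set (plus,
#' optionally, the fixed novel set), parameters drawn from the configured
#' truncated normals, and a full behavioral simulation with recorded
#' fixation streams.
#'
#' @param config A `cohort_config`.
#' @return List of data frames: `trials` (with `participant`), `behavior`
#'   (`participant`, `trial_id`, `response`, `rt_ms`), `fixations`, and
#'   `true_params` (the data-generating parameters per participant).
#' @export
generate_cohort <- function(config = cohort_config()) {
  bounds <- mivac_bounds()
  set.seed(config$seed)
  pm <- config$param_means
  ps <- config$param_sds
  pars <- data.frame(
    participant = sprintf("P%02d", seq_len(config$n_participants)),
    sigma = rtnorm_bounded(config$n_participants, pm["sigma"], ps["sigma"],
                           bounds$sigma),
    gamma = rtnorm_bounded(config$n_participants, pm["gamma"], ps["gamma"],
                           bounds$gamma),
    beta = rtnorm_bounded(config$n_participants, pm["beta"], ps["beta"],
                          bounds$beta),
    pi = rtnorm_bounded(config$n_participants, pm["pi"], ps["pi"],
                        bounds$pi))
  seeds <- derive_seeds(config$seed, 2 * config$n_participants)

  trials_all <- list()
  behavior_all <- list()
  fix_all <- list()
  novel <- if (config$include_novel) enumerate_novel_trials() else NULL
  for (i in seq_len(config$n_participants)) {
    tr <- sample_chau_trialset(config$n_distractor, config$n_binary,
                               seed = seeds[2 * i - 1])
    if (!is.null(novel)) {
      nv <- novel
      nv$trial_id <- nv$trial_id + max(tr$trial_id)
      tr <- new_trialset(rbind(tr, nv))
    }
    params <- mivac_params(sigma = pars$sigma[i], gamma = pars$gamma[i],
                           beta = pars$beta[i], pi = pars$pi[i],
                           horizon_ms = config$horizon_ms)
    beh <- simulate_trials(tr, params, n_reps = 1, seed = seeds[2 * i],
                           record_fixations = TRUE,
                           fixation_model = config$fixation_model)
    fx <- attr(beh, "fixations")
    tr$participant <- pars$participant[i]
    beh$participant <- pars$participant[i]
    fx$participant <- pars$participant[i]
    trials_all[[i]] <- as.data.frame(tr)
    behavior_all[[i]] <- beh[, c("participant", "trial_id", "response",
                                 "rt_ms")]
    fix_all[[i]] <- fx[, c("participant", "trial_id", "fix_index", "target",
                           "quadrant", "onset_ms", "duration_ms",
                           "fixation_type")]
  }
  list(trials = do.call(rbind, trials_all),
       behavior = do.call(rbind, behavior_all),
       fixations = do.call(rbind, fix_all),
       true_params = pars)
}

#' Write a cohort to CSV files
#'
#' Writes `trials.csv`, `behavior.csv`, `fixations.csv` and
#' `true_params.csv` under `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("trials", "behavior", "fixations", "true_params"))
    write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the CSV files.
#' @return List as returned by [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  out <- lapply(c(trials = "trials", behavior = "behavior",
                  fixations = "fixations", true_params = "true_params"),
                function(nm) read.csv(file.path(dir, paste0(nm, ".csv")),
                                      stringsAsFactors = FALSE))
  out$trials$d_present <- as.logical(out$trials$d_present)
  out$behavior$response <- factor(out$behavior$response,
                                  levels = RESPONSE_LEVELS)
  out
}
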