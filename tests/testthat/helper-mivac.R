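# shared fixtures and independent oracles, built in code

# hand-built trial set (no sampling)
make_trials <- function(hv_mag, hv_prob, lv_mag, lv_prob,
                        d_mag = NA, d_prob = NA) {
  n <- length(hv_mag)
  d_present <- !is.na(d_mag)
  df <- data.frame(
    trial_id = seq_len(n), kind = ifelse(d_present, "distractor", "binary"),
    hv_mag = hv_mag, hv_prob = hv_prob, lv_mag = lv_mag, lv_prob = lv_prob,
    d_mag = d_mag, d_prob = d_prob, d_present = d_present,
    dominance = NA_character_, similarity = NA_character_
  )
  class(df) <- c("mivac_trials", "data.frame")
  df
}

# independent exact-arithmetic oracle for the noise-free linear dynamics
# (requires beta = 0 so fixations cannot influence the inputs, and pi in
# {0, 1} so identification is deterministic)
oracle_noise_free <- function(trial, params) {
  stopifnot(params$sigma == 0, params$beta == 0, params$pi %in% c(0, 1))
  evs <- c(trial$hv_mag * trial$hv_prob,
           trial$lv_mag * trial$lv_prob,
           if (trial$d_present) trial$d_mag * trial$d_prob else 0,
           0)
  n_steps <- round(params$horizon_ms / params$dt_ms)
  det_step <- round(params$detection_period_ms / params$dt_ms)
  A <- rep(0, 4)
  identified <- FALSE
  for (k in seq_len(n_steps) - 1L) {
    if (params$pi == 1 && trial$d_present && k > 0 && k %% det_step == 0)
      identified <- TRUE
    I <- evs
    if (identified) I[3] <- 0
    A <- params$leak * A + params$inhibition * (sum(A) - A) + I
    theta <- params$theta0 -
      (params$theta0 - params$theta_end) * ((k + 1) * params$dt_ms) /
        params$horizon_ms
    if (max(A) >= theta) {
      w <- which.max(A)
      resp <- if (w == 3 && !trial$d_present) "EMPTY" else
        c("HV", "LV", "D", "EMPTY")[w]
      return(list(response = resp,
                  rt_ms = (k + 1) * params$dt_ms + params$nondecision_ms,
                  step = k + 1L, activations = A))
    }
  }
  list(response = "MISS", rt_ms = NA_real_, step = NA_integer_,
       activations = A)
}

# brute-force log-likelihood of a logistic chooser on a grid of sensitivity
# values (independent oracle for the maximum-likelihood fits)
grid_best_sensitivity <- function(sv_diff, chose_hv, grid) {
  ll <- vapply(grid, function(s) {
    p <- plogis(s * sv_diff)
    sum(log(ifelse(chose_hv, p, 1 - p)))
  }, numeric(1))
  list(sensitivity = grid[which.max(ll)], loglik = max(ll))
}
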