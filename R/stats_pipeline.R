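# Within-participant regression battery, group-level tests, the
# Dominance x Similarity ANOVA, path analysis, the interaction-artifact
# simulation, the binned value-difference analysis, and the test of
# detectability.

# per-trial predictor frame for one participant; predictors standardized
# over the distractor trials, with binary trials receiving the
# distractor-trial means for the distractor-dependent terms
build_predictors <- function(choices, trials,
                             interaction_mode = "standardized_components") {
  dat <- merge(as.data.frame(choices), as.data.frame(trials), by = "trial_id")
  dat$ev_hv <- dat$hv_mag * dat$hv_prob
  dat$ev_lv <- dat$lv_mag * dat$lv_prob
  dat$ev_d <- ifelse(dat$d_present, dat$d_mag * dat$d_prob, NA_real_)
  dat$hvmlv_raw <- dat$ev_hv - dat$ev_lv
  dat$hvplv_raw <- dat$ev_hv + dat$ev_lv
  dat$hvmd_raw <- dat$ev_hv - dat$ev_d

  dd <- dat$d_present
  zstat <- function(x) {
    m <- mean(x[dd])
    s <- sd(x[dd])
    list(m = m, s = if (is.na(s) || s == 0) 1 else s)
  }
  z1 <- zstat(dat$hvmlv_raw); z2 <- zstat(dat$hvplv_raw)
  z3 <- zstat(dat$hvmd_raw);  z4 <- zstat(dat$ev_d)
  dat$hvmlv <- (dat$hvmlv_raw - z1$m) / z1$s
  dat$hvplv <- (dat$hvplv_raw - z2$m) / z2$s
  dat$hvmd <- (dat$hvmd_raw - z3$m) / z3$s
  dat$d_value <- (dat$ev_d - z4$m) / z4$s
  # binary trials: distractor-dependent predictors held at distractor means
  dat$hvmd[!dd] <- 0
  dat$hvmd_raw[!dd] <- z3$m
  dat$d_value[!dd] <- 0

  dat$interaction <- switch(interaction_mode,
    standardized_components = dat$hvmlv * dat$hvmd,
    uncentered_components = dat$hvmlv_raw * dat$hvmd_raw,
    excluded = NULL,
    stop("unknown interaction_mode"))
  if (!is.null(dat$interaction))
    dat$interaction[!dd] <- mean(dat$interaction[dd])
  dat$trial_z <- as.numeric(scale(dat$trial_id))
  dat
}

fit_flagged_glm <- function(formula, data, family = binomial()) {
  y <- model.response(model.frame(formula, data))
  flagged <- FALSE
  fit <- withCallingHandlers(
    tryCatch(glm(formula, data = data, family = family),
             error = function(e) NULL),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || !fit$converged || var(as.numeric(y)) == 0 ||
      any(abs(coef(fit)[-1]) > 50, na.rm = TRUE))
    flagged <- TRUE
  list(fit = fit, flagged = flagged)
}

#' Within-participant regression of the behavioral battery
#'
#' Estimates one participant's intra-individual regression for a given
#' outcome.  Relative choice accuracy (HV vs LV, HV/LV-choice trials only)
#' and absolute choice accuracy (HV vs anything, all trials) are logistic
#' regressions on the standardized value difference HV-LV, value sum HV+LV,
#' distractor difference HV-D, their interaction, and distractor presence.
#' The distractor-choice, empty-choice and miss outcomes are logistic
#' regressions on the standardized distractor value over distractor trials.
#' Response time (HV/LV choices, linear model) is regressed on HV-LV,
#' HV+LV, distractor value and distractor presence.  Standardization is
#' within participant over the distractor trials; the interaction term is
#' built after standardization (unless a different `interaction_mode` is
#' requested) and is itself never restandardized.
#'
#' @param choices Data frame with `trial_id`, `response` and (for the RT
#'   outcome) `rt_ms`.
#' @param trials A `mivac_trials` data frame.
#' @param outcome One of `"relative_accuracy"`, `"absolute_accuracy"`,
#'   `"chose_D"`, `"chose_empty"`, `"miss"`, `"rt"`.
#' @param interaction_mode `"standardized_components"` (default),
#'   `"uncentered_components"`, or `"excluded"`.
#' @param include_trial_number Add a standardized trial-number covariate?
#' @return A list with `coef` (named coefficients), `flagged` (degenerate or
#'   non-converged fits are flagged and excluded from group tests), `n`.
#' @export
run_participant_regression <- function(choices, trials,
                                       outcome = c("relative_accuracy",
                                                   "absolute_accuracy",
                                                   "chose_D", "chose_empty",
                                                   "miss", "rt"),
                                       interaction_mode =
                                         "standardized_components",
                                       include_trial_number = FALSE) {
  outcome <- match.arg(outcome)
  dat <- build_predictors(choices, trials, interaction_mode)

  if (outcome %in% c("chose_D", "chose_empty", "miss")) {
    dat <- dat[dat$d_present, , drop = FALSE]
    dat$y <- as.integer(dat$response == switch(outcome, chose_D = "D",
                                               chose_empty = "EMPTY",
                                               miss = "MISS"))
    rhs <- c("d_value", if (include_trial_number) "trial_z")
    fam <- binomial()
  } else if (outcome == "rt") {
    dat <- dat[dat$response %in% c("HV", "LV") & !is.na(dat$rt_ms), ,
               drop = FALSE]
    dat$y <- dat$rt_ms
    rhs <- c("hvmlv", "hvplv", "d_value", "d_present",
             if (include_trial_number) "trial_z")
    fam <- NULL
  } else {
    if (outcome == "relative_accuracy")
      dat <- dat[dat$response %in% c("HV", "LV"), , drop = FALSE]
    dat$y <- as.integer(dat$response == "HV")
    rhs <- c("hvmlv", "hvplv", "hvmd",
             if (interaction_mode != "excluded") "interaction",
             "d_present", if (include_trial_number) "trial_z")
    fam <- binomial()
  }
  if (all(dat$d_present)) rhs <- setdiff(rhs, "d_present")
  if (nrow(dat) == 0 || var(dat$y) == 0)
    return(list(coef = NULL, flagged = TRUE, n = nrow(dat)))
  fml <- stats::reformulate(rhs, response = "y")
  if (is.null(fam)) {
    fit <- lm(fml, data = dat)
    list(coef = coef(fit), flagged = anyNA(coef(fit)), n = nrow(dat))
  } else {
    res <- fit_flagged_glm(fml, dat, fam)
    list(coef = if (is.null(res$fit)) NULL else coef(res$fit),
         flagged = res$flagged, n = nrow(dat))
  }
}

#' Group-level test of per-participant coefficients
#'
#' Two-sided one-sample t-test of the coefficients against 0, with Cohen's
#' d as mean over SD across participants.  Participants with flagged fits
#' should be excluded before calling (listwise per test, which is why group
#' degrees of freedom can vary between tests).
#'
#' @param coefficients Numeric vector, one value per participant.
#' @return Data frame with `mean_coef`, `t`, `df`, `p`, `d`, `n`.
#' @export
group_test <- function(coefficients) {
  coefficients <- coefficients[is.finite(coefficients)]
  n <- length(coefficients)
  if (n < 2) stop("need at least 2 valid participants")
  s <- sd(coefficients)
  if (s == 0)
    return(data.frame(mean_coef = mean(coefficients), t = Inf, df = n - 1,
                      p = 0, d = Inf, n = n))
  tt <- t.test(coefficients)
  data.frame(mean_coef = mean(coefficients), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             d = mean(coefficients) / s, n = n)
}

#' Repeated-measures 2 x 2 ANOVA on the Dominance x Similarity cell means
#'
#' Both factors have two levels, so each effect has one numerator degree of
#' freedom and its F equals the squared paired t of the corresponding
#' within-participant contrast; partial eta squared is
#' `SS_effect / (SS_effect + SS_error) = F / (F + df_error)`.
#'
#' @param cell_means Data frame with columns `participant`, `dominance`,
#'   `similarity`, `accuracy` (one row per participant and cell).
#' @return Data frame with one row per effect (`dominance`, `similarity`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `pes` (partial eta squared).
#' @export
novel_trial_anova <- function(cell_means) {
  cell_means$cell <- paste(cell_means$dominance, cell_means$similarity,
                           sep = ".")
  m <- tapply(cell_means$accuracy,
              list(cell_means$participant, cell_means$cell), mean)
  doms <- sort(unique(cell_means$dominance))
  sims <- sort(unique(cell_means$similarity))
  if (length(doms) != 2 || length(sims) != 2 || ncol(m) != 4 || anyNA(m))
    stop("missing cells in the Dominance x Similarity design")
  cn <- colnames(m)
  g <- function(d, s) m[, cn == paste(d, s, sep = ".")]
  contr <- list(
    dominance = (g(doms[1], sims[1]) + g(doms[1], sims[2]) -
                   g(doms[2], sims[1]) - g(doms[2], sims[2])) / 2,
    similarity = (g(doms[1], sims[1]) - g(doms[1], sims[2]) +
                    g(doms[2], sims[1]) - g(doms[2], sims[2])) / 2,
    interaction = (g(doms[1], sims[1]) - g(doms[1], sims[2]) -
                     g(doms[2], sims[1]) + g(doms[2], sims[2])) / 2)
  n <- nrow(m)
  out <- do.call(rbind, lapply(names(contr), function(e) {
    x <- contr[[e]]
    if (var(x) == 0 && mean(x) == 0) {
      f <- 0
    } else if (var(x) == 0) {
      f <- Inf
    } else {
      f <- (mean(x) / (sd(x) / sqrt(n)))^2
    }
    data.frame(effect = e, F = f, df1 = 1, df2 = n - 1,
               p = pf(f, 1, n - 1, lower.tail = FALSE),
               pes = ifelse(is.infinite(f), 1, f / (f + (n - 1))))
  }))
  rownames(out) <- NULL
  out
}

#' Per-participant cell means for the Dominance x Similarity set
#'
#' @param behavior Data frame with `participant`, `trial_id`, `response`.
#' @param trials Novel `mivac_trials` (with `dominance`, `similarity`).
#' @param measure `"relative"` (HV among HV/LV choices) or `"absolute"`
#'   (HV among all trials).
#' @return Data frame `participant`, `dominance`, `similarity`, `accuracy`.
#' @export
novel_cell_means <- function(behavior, trials, measure = c("relative",
                                                           "absolute")) {
  measure <- match.arg(measure)
  dat <- merge(as.data.frame(behavior), as.data.frame(trials), by = "trial_id")
  if (measure == "relative")
    dat <- dat[dat$response %in% c("HV", "LV"), , drop = FALSE]
  dat$acc <- as.integer(dat$response == "HV")
  out <- aggregate(acc ~ participant + dominance + similarity, dat, mean)
  names(out)[names(out) == "acc"] <- "accuracy"
  out
}

#' Within-participant path analysis of value, attention and accuracy
#'
#' For each participant: path a regresses attention to the distractor
#' (its relative fixation duration) on the standardized distractor value
#' (least squares); paths b and c' come from a joint logistic regression of
#' absolute choice accuracy on attention and distractor value.  Each path
#' coefficient is then tested against zero across participants.  Full
#' mediation corresponds to significant a and b with a non-significant
#' direct path c'.
#'
#' @param data Data frame with columns `participant`, `d_value` (expected
#'   value of the distractor), `d_attention` (relative fixation duration on
#'   the distractor), `accuracy` (0/1, chose HV), one row per distractor
#'   trial.
#' @return List with `paths` (per-participant a, b, c_prime, flagged) and
#'   `tests` (group-level [group_test()] per path).
#' @export
path_analysis <- function(data) {
  per <- lapply(split(data, data$participant), function(d) {
    if (nrow(d) < 5 || var(d$d_attention) == 0 || var(d$d_value) == 0)
      return(data.frame(participant = d$participant[1], a = NA, b = NA,
                        c_prime = NA, flagged = TRUE))
    zd <- as.numeric(scale(d$d_value))
    za <- as.numeric(scale(d$d_attention))
    a <- coef(lm(za ~ zd))[2]
    res <- fit_flagged_glm(accuracy ~ za + zd,
                           data.frame(accuracy = d$accuracy, za = za, zd = zd))
    if (is.null(res$fit))
      return(data.frame(participant = d$participant[1], a = unname(a), b = NA,
                        c_prime = NA, flagged = TRUE))
    cf <- coef(res$fit)
    data.frame(participant = d$participant[1], a = unname(a),
               b = unname(cf["za"]), c_prime = unname(cf["zd"]),
               flagged = res$flagged)
  })
  paths <- do.call(rbind, per)
  rownames(paths) <- NULL
  ok <- !paths$flagged
  tests <- rbind(
    cbind(path = "a", group_test(paths$a[ok])),
    cbind(path = "b", group_test(paths$b[ok])),
    cbind(path = "c_prime", group_test(paths$c_prime[ok])))
  list(paths = paths, tests = tests)
}

#' The interaction-artifact simulation
#'
#' Demonstrates that an uncentered product term induces a spurious
#' distractor-value effect through nonessential multicollinearity.
#' Hypothetical participants choose between HV and LV via a logistic rule
#' on the raw value difference HV-LV alone, so their behavior is
#' independent of the distractor by construction.  Per replication,
#' `n_participants` such choosers are simulated on the distractor trials of
#' a rejection-sampled choice set and each participant's relative-accuracy
#' logistic regression (HV-LV, HV+LV, HV-D and, depending on the variant,
#' their product) is fitted under four variants that share the simulated
#' choices: the product term included with standardized or with raw
#' (uncentered) predictors, and the product excluded with standardized or
#' raw predictors.  The per-replication average HV-D coefficient is then
#' tested against zero across replications.  Each replication draws a
#' fresh rejection-sampled trial set shared by its participants (one
#' simulated experiment); pass `trials` to reanalyze a fixed set instead.
#' Because standardizing main effects without a product term is an affine
#' reparameterization, the two excluded-product variants are exactly
#' equivalent once coefficients are expressed per SD of HV-D, and all
#' raw-basis coefficients are reported on that common scale.
#'
#' @param n_participants Simulated participants per replication (21, the
#'   original sample size).
#' @param n_reps Number of replications (1000).
#' @param sensitivity Logistic choice sensitivity (0.5).
#' @param n_trials Distractor trials per generated set (150).
#' @param trials Optional `mivac_trials` used for every replication instead
#'   of per-replication sets.
#' @param seed Master seed.
#' @return List with `tests` (per variant: mean HV-D coefficient, t, df, p)
#'   and `coef_means` (the replication-wise averages, n_reps x 4).
#' @export
artifact_simulation <- function(n_participants = 21, n_reps = 1000,
                                sensitivity = 0.5, n_trials = 150,
                                trials = NULL, seed = 1) {
  # the uncentered and standardized bases span the same model when the
  # product is included (the product of centered components lies in the
  # span of 1, r1, r3, r1*r3); what changes is the meaning of the HV-D
  # coefficient, which is the artifact under study
  variant_names <- c("interaction_uncentered", "interaction_standardized",
                     "excluded_standardized", "excluded_uncentered")
  raw_scale <- c(TRUE, FALSE, FALSE, TRUE)
  hvmd_col <- 4L
  set_seeds <- derive_seeds(seed, n_reps)

  fixed <- !is.null(trials)
  if (fixed) trials <- trials[trials$d_present, , drop = FALSE]
  coef_means <- matrix(NA_real_, n_reps, 4,
                       dimnames = list(NULL, variant_names))
  for (r in seq_len(n_reps)) {
    tr <- if (fixed) trials else
      sample_chau_trialset(n_trials, 0, seed = set_seeds[r])
    ev_hv <- tr$hv_mag * tr$hv_prob
    ev_lv <- tr$lv_mag * tr$lv_prob
    ev_d <- tr$d_mag * tr$d_prob
    r1 <- ev_hv - ev_lv
    r2 <- ev_hv + ev_lv
    r3 <- ev_hv - ev_d
    z <- function(x) (x - mean(x)) / sd(x)
    z1 <- z(r1); z2 <- z(r2); z3 <- z(r3)
    designs <- list(cbind(1, r1, r2, r3, r1 * r3),
                    cbind(1, z1, z2, z3, z1 * z3),
                    cbind(1, z1, z2, z3),
                    cbind(1, r1, r2, r3))
    p_hv <- plogis(sensitivity * r1)
    n <- length(p_hv)
    set.seed(set_seeds[r] + 1)
    sums <- numeric(4)
    counts <- integer(4)
    for (pp in seq_len(n_participants)) {
      y <- rbinom(n, 1, p_hv)
      for (v in 1:4) {
        fit <- tryCatch(
          suppressWarnings(glm.fit(designs[[v]], y, family = binomial())),
          error = function(e) NULL)
        if (!is.null(fit) && fit$converged) {
          b <- fit$coefficients[hvmd_col]
          # raw-basis coefficients rescaled to per-SD units so variants are
          # comparable; t-tests are scale-invariant per variant
          if (raw_scale[v]) b <- b * sd(r3)
          sums[v] <- sums[v] + b
          counts[v] <- counts[v] + 1L
        }
      }
    }
    coef_means[r, ] <- sums / counts
  }
  tests <- do.call(rbind, lapply(1:4, function(v) {
    gt <- group_test(coef_means[, v])
    cbind(variant = variant_names[v], gt)
  }))
  names(tests)[1] <- "variant"
  rownames(tests) <- NULL
  list(tests = tests, coef_means = coef_means)
}

#' Binned distractor-difference analysis
#'
#' Splits the distractor trials by the discrete levels of the raw value
#' difference HV-LV and, within each bin, fits each participant's
#' relative-accuracy logistic regression on the within-bin standardized
#' HV+LV and HV-D (no HV-LV term and no product term, since HV-LV is
#' constant within a bin), then tests the HV-D coefficients across
#' participants per bin.
#'
#' @param behavior Data frame with `participant`, `trial_id`, `response`.
#' @param trials A `mivac_trials` data frame (distractor trials used).
#' @param min_trials Bins in which a participant has fewer usable trials
#'   are flagged for that participant.
#' @return Data frame, one row per bin: `hvmlv_level`, `n_trials`,
#'   `n_participants`, `mean_coef`, `t`, `df`, `p`.
#' @export
binned_hvd_analysis <- function(behavior, trials, min_trials = 8) {
  trials <- trials[trials$d_present, , drop = FALSE]
  trial_key <- if ("participant" %in% names(trials))
    c("participant", "trial_id") else "trial_id"
  dat <- merge(as.data.frame(behavior), as.data.frame(trials), by = trial_key)
  dat <- dat[dat$response %in% c("HV", "LV"), , drop = FALSE]
  dat$hvmlv_raw <- dat$hv_mag * dat$hv_prob - dat$lv_mag * dat$lv_prob
  dat$hvplv_raw <- dat$hv_mag * dat$hv_prob + dat$lv_mag * dat$lv_prob
  dat$hvmd_raw <- dat$hv_mag * dat$hv_prob - dat$d_mag * dat$d_prob
  dat$y <- as.integer(dat$response == "HV")
  levels_raw <- sort(unique(round(dat$hvmlv_raw, 9)))
  out <- lapply(levels_raw, function(lev) {
    b <- dat[abs(dat$hvmlv_raw - lev) < 1e-9, , drop = FALSE]
    coefs <- vapply(split(b, b$participant), function(d) {
      if (nrow(d) < min_trials || var(d$y) == 0 || var(d$hvmd_raw) == 0)
        return(NA_real_)
      zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
        (x - mean(x)) / sd(x)
      res <- fit_flagged_glm(y ~ hvplv + hvmd,
                             data.frame(y = d$y, hvplv = zs(d$hvplv_raw),
                                        hvmd = zs(d$hvmd_raw)))
      if (is.null(res$fit) || res$flagged) NA_real_ else
        unname(coef(res$fit)["hvmd"])
    }, numeric(1))
    coefs <- coefs[is.finite(coefs)]
    if (length(coefs) < 2)
      return(data.frame(hvmlv_level = lev, n_trials = nrow(b),
                        n_participants = length(coefs), mean_coef = NA,
                        t = NA, df = NA, p = NA))
    gt <- group_test(coefs)
    data.frame(hvmlv_level = lev, n_trials = nrow(b),
               n_participants = gt$n, mean_coef = gt$mean_coef, t = gt$t,
               df = gt$df, p = gt$p)
  })
  do.call(rbind, out)
}

#' Effect size detectable with a given power (test of detectability)
#'
#' The hypothetical effect size d at which a two-sided one-sample t-test
#' with `n` participants attains exactly the stated power; originals whose
#' reproduced effects fall significantly below the d at 33% power were not
#' detectably large with the original sample size.  Solved by root finding
#' on the noncentral-t power function; decreasing in `n`.
#'
#' @param n Sample size (>= 2).
#' @param alpha Two-sided alpha level.
#' @param power Target power (default 1/3).
#' @return The effect size d (Cohen's d units).
#' @export
#' @examples
#' detectability_threshold(21)
detectability_threshold <- function(n, alpha = 0.05, power = 1 / 3) {
  stopifnot(n >= 2, power > alpha, power < 1)
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  pw <- function(d) {
    ncp <- d * sqrt(n)
    pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
  }
  uniroot(function(d) pw(d) - power, c(1e-8, 10), tol = 1e-9)$root
}

#' Relative fixation durations per trial
#'
#' Sum of fixation durations on each quadrant target divided by the summed
#' duration over all quadrants of that trial.
#'
#' @param fixations Data frame with `participant`, `trial_id`, `target`,
#'   `duration_ms`.
#' @return Data frame `participant`, `trial_id`, `rel_HV`, `rel_LV`,
#'   `rel_D`, `rel_EMPTY` (rows sum to 1).
#' @export
relative_fixation_durations <- function(fixations) {
  f <- as.data.frame(fixations)
  tot <- aggregate(duration_ms ~ participant + trial_id, f, sum)
  names(tot)[3] <- "total"
  out <- tot
  for (tg in c("HV", "LV", "D", "EMPTY")) {
    s <- aggregate(duration_ms ~ participant + trial_id,
                   f[f$target == tg, , drop = FALSE], sum)
    names(s)[3] <- "dur"
    out <- merge(out, s, by = c("participant", "trial_id"), all.x = TRUE)
    out$dur[is.na(out$dur)] <- 0
    names(out)[names(out) == "dur"] <- paste0("rel_", tg)
  }
  for (tg in c("HV", "LV", "D", "EMPTY"))
    out[[paste0("rel_", tg)]] <- out[[paste0("rel_", tg)]] / out$total
  out$total <- NULL
  out
}

#' Value-attention correlations and first-fixation regressions
#'
#' Within each participant, the Pearson correlation between an option's
#' expected value and its relative fixation duration across distractor
#' trials, Fisher z-transformed and tested against zero at the group level,
#' for HV, LV and D.  Additionally, first-fixation logistic regressions:
#' the probability that an option is fixated first as a function of its
#' value, and the probability that it is chosen as a function of whether it
#' was fixated first, the first-fixation duration, and value.
#'
#' @param fixations Data frame with `participant`, `trial_id`, `fix_index`,
#'   `target`, `duration_ms`.
#' @param trials A `mivac_trials` data frame.
#' @param behavior Data frame with `participant`, `trial_id`, `response`.
#' @return List with `value_attention` (per-option group tests of the
#'   Fisher-z correlations), `first_fixation_value` and
#'   `choice_on_first_fixation` (per-option group tests of regression
#'   coefficients), plus `per_participant` correlations.
#' @export
fixation_value_correlations <- function(fixations, trials, behavior) {
  trials <- as.data.frame(trials)
  trials$ev_hv <- trials$hv_mag * trials$hv_prob
  trials$ev_lv <- trials$lv_mag * trials$lv_prob
  trials$ev_d <- ifelse(trials$d_present, trials$d_mag * trials$d_prob,
                        NA_real_)
  trial_key <- if ("participant" %in% names(trials))
    c("participant", "trial_id") else "trial_id"
  rel <- relative_fixation_durations(fixations)
  dat <- merge(rel, trials, by = trial_key)
  dat <- dat[dat$d_present, , drop = FALSE]

  per <- do.call(rbind, lapply(split(dat, dat$participant), function(d) {
    corz <- function(v, rf) {
      if (var(v) == 0 || var(rf) == 0) return(NA_real_)
      r <- cor(v, rf)
      atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    }
    data.frame(participant = d$participant[1],
               z_HV = corz(d$ev_hv, d$rel_HV),
               z_LV = corz(d$ev_lv, d$rel_LV),
               z_D = corz(d$ev_d, d$rel_D))
  }))
  rownames(per) <- NULL
  value_attention <- do.call(rbind, lapply(c("HV", "LV", "D"), function(o) {
    cbind(option = o, group_test(per[[paste0("z_", o)]]))
  }))

  # first-fixation analyses
  f <- as.data.frame(fixations)
  first <- f[f$fix_index == 1, c("participant", "trial_id", "target",
                                 "duration_ms")]
  names(first)[3:4] <- c("first_target", "first_duration")
  fdat <- merge(merge(first, trials, by = trial_key),
                as.data.frame(behavior), by = c("participant", "trial_id"))
  fdat <- fdat[fdat$d_present, , drop = FALSE]
  ffx <- function(o, value_col, chose) {
    coefs <- vapply(split(fdat, fdat$participant), function(d) {
      d$y <- if (chose) as.integer(d$response == o) else
        as.integer(d$first_target == o)
      if (var(d$y) == 0) return(NA_real_)
      zs <- function(x) if (sd(x) == 0) rep(0, length(x)) else
        as.numeric(scale(x))
      if (chose) {
        d$ff <- as.integer(d$first_target == o)
        d$fd <- zs(ifelse(d$ff == 1, d$first_duration, 0))
        res <- fit_flagged_glm(y ~ ff + fd + v,
                               data.frame(y = d$y, ff = d$ff, fd = d$fd,
                                          v = zs(d[[value_col]])))
        if (is.null(res$fit) || res$flagged) NA_real_ else
          unname(coef(res$fit)["ff"])
      } else {
        res <- fit_flagged_glm(y ~ v, data.frame(y = d$y,
                                                 v = zs(d[[value_col]])))
        if (is.null(res$fit) || res$flagged) NA_real_ else
          unname(coef(res$fit)["v"])
      }
    }, numeric(1))
    coefs[is.finite(coefs)]
  }
  opts <- c(HV = "ev_hv", LV = "ev_lv", D = "ev_d")
  first_fixation_value <- do.call(rbind, lapply(names(opts), function(o) {
    cbind(option = o, group_test(ffx(o, opts[[o]], chose = FALSE)))
  }))
  choice_on_first <- do.call(rbind, lapply(names(opts), function(o) {
    cbind(option = o, group_test(ffx(o, opts[[o]], chose = TRUE)))
  }))
  list(value_attention = value_attention,
       first_fixation_value = first_fixation_value,
       choice_on_first_fixation = choice_on_first,
       per_participant = per)
}
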