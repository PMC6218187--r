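test_that("standardization is anchored to the distractor trials", {
  tr <- sample_chau_trialset(80, 40, seed = 33)
  ch <- simulate_simple_choices(tr, "EV", sensitivity = 0.5, seed = 1)
  dat <- mivac:::build_predictors(ch, tr)
  dd <- dat$d_present
  for (col in c("hvmlv", "hvplv", "hvmd")) {
    expect_equal(mean(dat[[col]][dd]), 0, tolerance = 1e-12)
    expect_equal(sd(dat[[col]][dd]), 1, tolerance = 1e-12)
  }
  # binary trials carry the distractor-trial means of the distractor terms
  expect_true(all(dat$hvmd[!dd] == 0))
  expect_equal(unique(dat$interaction[!dd]),
               mean((dat$hvmlv * dat$hvmd)[dd]))
})

test_that("the standardized product is far less collinear than the raw one", {
  tr <- sample_chau_trialset(150, 0, seed = 44)
  r1 <- tr$hv_mag * tr$hv_prob - tr$lv_mag * tr$lv_prob
  r3 <- tr$hv_mag * tr$hv_prob - tr$d_mag * tr$d_prob
  z1 <- as.numeric(scale(r1)); z3 <- as.numeric(scale(r3))
  expect_lt(abs(cor(z1 * z3, z3)), abs(cor(r1 * r3, r3)) - 0.3)
})

test_that("degenerate outcomes are flagged, valid regressions recover an oracle", {
  tr <- sample_chau_trialset(30, 0, seed = 3)
  all_hv <- data.frame(trial_id = tr$trial_id, response = "HV")
  res <- run_participant_regression(all_hv, tr, "relative_accuracy")
  expect_true(res$flagged)
  # small dataset: logistic coefficients match a direct likelihood search
  tr12 <- sample_chau_trialset(12, 0, seed = 9)
  set.seed(2)
  ch12 <- data.frame(trial_id = tr12$trial_id,
                     response = sample(c("HV", "LV"), 12, replace = TRUE,
                                       prob = c(0.7, 0.3)))
  dat <- mivac:::build_predictors(ch12, tr12)
  res12 <- run_participant_regression(ch12, tr12, "relative_accuracy",
                                      interaction_mode = "excluded")
  nll <- function(b) {
    eta <- b[1] + b[2] * dat$hvmlv + b[3] * dat$hvplv + b[4] * dat$hvmd
    -sum(ifelse(dat$response == "HV", plogis(eta, log.p = TRUE),
                plogis(-eta, log.p = TRUE)))
  }
  oracle <- optim(rep(0, 4), nll, method = "BFGS")
  expect_equal(unname(res12$coef), oracle$par, tolerance = 1e-3)
})

test_that("value-difference choosers show no distractor effect", {
  set.seed(10)
  coefs <- vapply(1:12, function(pp) {
    tr <- sample_chau_trialset(100, 50, seed = 100 + pp)
    ch <- simulate_simple_choices(tr, "EV", sensitivity = 0.5, seed = pp)
    r <- run_participant_regression(ch, tr, "relative_accuracy")
    if (r$flagged) NA_real_ else r$coef[["hvmd"]]
  }, numeric(1))
  gt <- group_test(coefs)
  expect_gt(gt$p, 0.05)
})

test_that("group tests behave at the edges and under the null", {
  expect_error(group_test(1), "at least 2")
  const <- group_test(rep(0.4, 6))
  expect_true(is.infinite(const$t))
  x <- c(0, 2, 1)  # mean 1, sd 1, so d = mean / sd = 1
  expect_equal(group_test(x)$d, 1)
  # type-I error rate of the group test under a standard-normal null
  set.seed(77)
  rej <- mean(replicate(600, group_test(rnorm(123))$p < 0.05))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.08)
})

test_that("the 2x2 repeated-measures ANOVA matches a least-squares oracle", {
  set.seed(5)
  cells <- expand.grid(participant = sprintf("P%02d", 1:31),
                       dominance = c("D_dominates", "D_dominated"),
                       similarity = c("near_HV", "near_LV"))
  cells$accuracy <- runif(nrow(cells))
  res <- novel_trial_anova(cells)
  # independent oracle: aov with within-participant error strata
  oa <- summary(aov(accuracy ~ dominance * similarity +
                      Error(participant / (dominance * similarity)),
                    data = cells))
  f_or <- c(oa[["Error: participant:dominance"]][[1]]["dominance", "F value"],
            oa[["Error: participant:similarity"]][[1]]["similarity", "F value"],
            oa[["Error: participant:dominance:similarity"]][[1]][
              "dominance:similarity", "F value"])
  expect_equal(res$F, unname(f_or), tolerance = 1e-8)
  expect_true(all(res$df1 == 1) && all(res$df2 == 30))
  # degenerate patterns
  flat <- cells; flat$accuracy <- 0.5
  expect_true(all(novel_trial_anova(flat)$F == 0))
  shifted <- flat
  shifted$accuracy <- 0.5 + 0.2 * (shifted$dominance == "D_dominates")
  res2 <- novel_trial_anova(shifted)
  expect_equal(res2$pes[res2$effect == "dominance"], 1)
  expect_error(novel_trial_anova(cells[cells$similarity == "near_HV", ]),
               "missing cells")
})

test_that("path analysis recovers built-in full mediation", {
  set.seed(21)
  gen <- function(pid, mediated) {
    n <- 150
    d_value <- runif(n, 0.25, 9)
    att <- if (mediated) 0.05 + 0.04 * d_value + rnorm(n, 0, 0.05) else
      runif(n, 0, 0.4)
    att <- pmin(pmax(att, 0), 1)
    eta <- 1.5 - (if (mediated) 6 else 0) * att
    data.frame(participant = pid, d_value = d_value, d_attention = att,
               accuracy = rbinom(n, 1, plogis(eta)))
  }
  med <- do.call(rbind, lapply(sprintf("M%02d", 1:14), gen, mediated = TRUE))
  res <- path_analysis(med)
  tests <- res$tests
  expect_lt(tests$p[tests$path == "a"], 0.001)
  expect_gt(tests$mean_coef[tests$path == "a"], 0)
  expect_lt(tests$p[tests$path == "b"], 0.001)
  expect_lt(tests$mean_coef[tests$path == "b"], 0)
  expect_gt(tests$p[tests$path == "c_prime"], 0.05)
  # attention unrelated to value: path a centered on zero
  unm <- do.call(rbind, lapply(sprintf("U%02d", 1:14), gen, mediated = FALSE))
  res2 <- path_analysis(unm)
  expect_gt(res2$tests$p[res2$tests$path == "a"], 0.05)
})

test_that("relative fixation durations sum to one over the quadrants", {
  tr <- make_trials(8, 5 / 8, 4, 3 / 8, 6, 6 / 8)
  params <- mivac_params(sigma = 15, gamma = 1, beta = 5, pi = 0.3)
  sim <- simulate_trials(tr[rep(1, 30), ], params, record_fixations = TRUE,
                         seed = 2)
  fx <- attr(sim, "fixations")
  fx$participant <- "P1"
  fx$trial_id <- fx$rep  # treat repetitions as trials
  rel <- relative_fixation_durations(fx)
  sums <- rowSums(rel[, c("rel_HV", "rel_LV", "rel_D", "rel_EMPTY")])
  expect_equal(sums, rep(1, nrow(rel)))
})

test_that("the artifact appears only with the uncentered product", {
  res <- artifact_simulation(n_participants = 8, n_reps = 60, n_trials = 100,
                             seed = 15)
  tests <- res$tests
  t_unc <- tests$t[tests$variant == "interaction_uncentered"]
  p_unc <- tests$p[tests$variant == "interaction_uncentered"]
  expect_lt(t_unc, 0)
  expect_lt(p_unc, 0.05)
  # the two excluded-product variants agree to numerical precision
  expect_equal(res$coef_means[, "excluded_standardized"],
               res$coef_means[, "excluded_uncentered"], tolerance = 1e-8)
  # the standardized product shows a far weaker distortion
  expect_lt(abs(tests$mean_coef[tests$variant == "interaction_standardized"]),
            abs(tests$mean_coef[tests$variant == "interaction_uncentered"]) / 3)
})

test_that("binned analyses isolate the distractor difference per level", {
  set.seed(31)
  trials <- do.call(rbind, lapply(1:8, function(pp) {
    tr <- sample_chau_trialset(120, 0, seed = 400 + pp)
    tr$participant <- sprintf("P%02d", pp)
    tr
  }))
  beh <- do.call(rbind, lapply(split(trials, trials$participant), function(tr) {
    ch <- simulate_simple_choices(tr, "EV", sensitivity = 0.5,
                                  seed = as.integer(substr(tr$participant[1], 2, 3)))
    ch$participant <- tr$participant[1]
    ch
  }))
  res <- binned_hvd_analysis(beh, trials, min_trials = 3)
  lv <- sort(unique(round(trials$hv_mag * trials$hv_prob -
                            trials$lv_mag * trials$lv_prob, 9)))
  expect_equal(res$hvmlv_level, lv)
  # distractor-blind choosers: few bins reach significance
  ok <- res[!is.na(res$p), ]
  expect_lt(mean(ok$p < 0.05), 0.2)
})

test_that("the detectability threshold solves the power equation", {
  d33 <- detectability_threshold(21)
  # Monte-Carlo oracle at the root: rejection rate of the one-sample t-test
  set.seed(3)
  rej <- mean(replicate(4000, {
    x <- rnorm(21, mean = d33)
    t.test(x)$p.value < 0.05
  }))
  expect_equal(rej, 1 / 3, tolerance = 0.025)
  # monotone decreasing in n, and smaller than the original effect size
  expect_gt(detectability_threshold(10), detectability_threshold(21))
  expect_gt(detectability_threshold(21), detectability_threshold(100))
  expect_lt(d33, abs(-0.495))
})

test_that("value-dependent fixations yield positive value-attention coupling", {
  co <- generate_cohort(cohort_config(
    n_participants = 8, n_distractor = 100, n_binary = 0,
    include_novel = FALSE,
    param_means = c(sigma = 15, gamma = 2.5, beta = 8, pi = 0.3),
    param_sds = c(sigma = 2, gamma = 1e-6, beta = 2, pi = 0.05), seed = 30))
  res <- fixation_value_correlations(co$fixations, co$trials, co$behavior)
  va <- res$value_attention
  expect_true(all(va$mean_coef > 0))
  expect_true(all(va$p < 0.05))
  # first fixations are drawn to value, and a first fixation on an
  # available option predicts choosing it (distractor choices are too rare
  # at this cohort size for a stable per-participant estimate)
  expect_true(all(res$first_fixation_value$mean_coef > 0))
  cff <- res$choice_on_first_fixation
  expect_true(all(cff$mean_coef[cff$option %in% c("HV", "LV")] > 0))
})
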