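test_that("fixation probabilities follow the normalized-value softmax", {
  expect_equal(fixation_probabilities(c(5, 1.5, 4.5, 0), gamma = 0),
               rep(0.25, 4))
  expect_equal(fixation_probabilities(c(3, 3, 3, 3), gamma = 2), rep(0.25, 4))
  # direct evaluation: softmax of gamma * sum-normalized values
  evs <- c(5, 1.5, 4.5, 0)
  w <- exp(3.08 * evs / sum(evs))
  expect_equal(fixation_probabilities(evs, gamma = 3.08), w / sum(w))
  expect_equal(fixation_probabilities(evs, gamma = 3.08),
               c(0.4014, 0.1507, 0.3490, 0.0990), tolerance = 1e-3)
  # identified distractor loses its value-based draw
  p_id <- fixation_probabilities(evs, gamma = 3.08, d_identified = TRUE)
  expect_equal(p_id[3], p_id[4])
  # sums to 1 and invariant under relabeling of equal-value options
  set.seed(2)
  for (i in 1:20) {
    v <- c(runif(3, 0, 10), 0)
    g <- runif(1, -1.12, 3.08)
    p <- fixation_probabilities(v, g)
    expect_equal(sum(p), 1)
    expect_equal(fixation_probabilities(v[c(2, 1, 3, 4)], g), p[c(2, 1, 3, 4)])
  }
})

test_that("noise-free dynamics match the exact linear-map oracle", {
  trials <- make_trials(
    hv_mag = c(12, 8, 6, 10), hv_prob = c(7 / 8, 5 / 8, 6 / 8, 4 / 8),
    lv_mag = c(2, 4, 4, 2), lv_prob = c(1 / 8, 3 / 8, 2 / 8, 3 / 8),
    d_mag = c(NA, 6, 8, 12), d_prob = c(NA, 6 / 8, 7 / 8, 6 / 8))
  for (pi_val in c(0, 1)) {
    params <- mivac_params(sigma = 0, gamma = 0, beta = 0, pi = pi_val)
    sim <- simulate_trials(trials, params, n_reps = 1, seed = 99)
    for (i in seq_len(nrow(trials))) {
      orc <- oracle_noise_free(trials[i, ], params)
      expect_equal(as.character(sim$response[i]), orc$response,
                   info = sprintf("trial %d pi %g", i, pi_val))
      expect_equal(sim$rt_ms[i], orc$rt_ms,
                   info = sprintf("trial %d pi %g", i, pi_val))
    }
  }
})

test_that("deterministic race is won by the largest-input option", {
  tr <- make_trials(12, 7 / 8, 2, 1 / 8)
  params <- mivac_params(sigma = 0, gamma = 0, beta = 0, pi = 0)
  sim <- simulate_trials(tr, params, n_reps = 3, seed = 1)
  expect_true(all(sim$response == "HV"))
  expect_true(all(sim$rt_ms == sim$rt_ms[1]))
})

test_that("the collapsing bound runs from 1000 to 200 over the horizon", {
  p <- mivac_params(sigma = 20)
  expect_equal(p$theta0, 1000)
  expect_equal(p$theta_end, 200)
  expect_equal(p$horizon_ms, 1400)
  expect_equal(p$nondecision_ms, 200)
  # a noise-free race with tiny inputs never reaches the terminal bound
  tr <- make_trials(4, 1 / 8, 2, 1 / 8)
  params <- mivac_params(sigma = 0, gamma = 0, beta = 0, pi = 0)
  orc <- oracle_noise_free(tr[1, ], params)
  # steady-state activation of the winning accumulator stays below 200
  expect_equal(orc$response, "MISS")
  sim <- simulate_trials(tr, params, n_reps = 1, seed = 5)
  expect_equal(as.character(sim$response[1]), "MISS")
  expect_true(is.na(sim$rt_ms[1]))
})

test_that("large noise produces misses and empty-quadrant choices", {
  tr <- make_trials(8, 5 / 8, 4, 3 / 8, 6, 6 / 8)
  params <- mivac_params(sigma = 50, gamma = 0, beta = 0, pi = 0)
  sim <- simulate_trials(tr, params, n_reps = 10000, seed = 17)
  tab <- table(sim$response)
  expect_gt(tab[["EMPTY"]], 0)
  expect_gt(tab[["MISS"]], 0)
})

test_that("zeroed mechanisms reproduce the nested variants exactly", {
  tr <- make_trials(c(8, 6), c(5 / 8, 6 / 8), c(4, 4), c(3 / 8, 2 / 8),
                    c(6, 12), c(6 / 8, 6 / 8))
  base <- mivac_params(sigma = 12, gamma = 1.5, beta = 6, pi = 0.4)
  # paired-seed trajectory equality of explicit zeroing vs variant switches
  for (v in c("no_vac", "no_ae", "no_dd", "baseline")) {
    zeroed <- base
    for (nm in setdiff(c("gamma", "beta", "pi"), variant_free_params(v)))
      zeroed[[nm]] <- 0
    a <- simulate_trials(tr, zeroed, n_reps = 50, seed = 7, variant = "mivac")
    b <- simulate_trials(tr, base, n_reps = 50, seed = 7, variant = v)
    expect_identical(a, b, info = v)
  }
})

test_that("immediate identification suppresses value-driven distractor wins", {
  tr <- make_trials(6, 5 / 8, 4, 3 / 8, 12, 6 / 8)
  fast <- mivac_params(sigma = 10, gamma = 0, beta = 0, pi = 1)
  never <- mivac_params(sigma = 10, gamma = 0, beta = 0, pi = 0)
  s_fast <- simulate_trials(tr, fast, n_reps = 4000, seed = 3)
  s_never <- simulate_trials(tr, never, n_reps = 4000, seed = 3)
  expect_lt(mean(s_fast$response == "D"), 0.05)
  expect_gt(mean(s_never$response == "D"), 0.5)
})

test_that("choice and RT shift monotonically with the distractor's value", {
  lowd <- make_trials(8, 5 / 8, 4, 3 / 8, 2, 1 / 8)
  highd <- make_trials(8, 5 / 8, 4, 3 / 8, 12, 6 / 8)
  params <- mivac_params(sigma = 18, gamma = 1.2, beta = 8, pi = 0.35)
  a <- simulate_trials(lowd, params, n_reps = 6000, seed = 11)
  b <- simulate_trials(highd, params, n_reps = 6000, seed = 12)
  expect_gt(mean(b$response == "D"), mean(a$response == "D"))
  rt_a <- mean(a$rt_ms[a$response %in% c("HV", "LV")], na.rm = TRUE)
  rt_b <- mean(b$rt_ms[b$response %in% c("HV", "LV")], na.rm = TRUE)
  expect_gt(rt_b, rt_a)
  # a wider value difference raises relative accuracy
  narrow <- make_trials(8, 4 / 8, 8, 3 / 8, 6, 4 / 8)
  wide <- make_trials(12, 6 / 8, 2, 2 / 8, 6, 4 / 8)
  sn <- simulate_trials(narrow, params, n_reps = 6000, seed = 13)
  sw <- simulate_trials(wide, params, n_reps = 6000, seed = 14)
  racc <- function(s) mean(s$response[s$response %in% c("HV", "LV")] == "HV")
  expect_gt(racc(sw), racc(sn))
})

test_that("recorded fixation streams are consistent with the schedule", {
  tr <- make_trials(8, 5 / 8, 4, 3 / 8, 6, 6 / 8)
  params <- mivac_params(sigma = 15, gamma = 1, beta = 5, pi = 0.3)
  sim <- simulate_trials(tr, params, n_reps = 200, seed = 21,
                         record_fixations = TRUE)
  fx <- attr(sim, "fixations")
  expect_true(all(fx$duration_ms > 0))
  expect_true(all(fx$duration_ms <= 200))
  expect_true(all(fx$fixation_type[fx$fix_index == 1] == "first"))
  # per simulation, fixations tile the decision time without gaps
  one <- fx[fx$rep == 1, ]
  expect_equal(one$onset_ms, c(0, cumsum(one$duration_ms))[seq_len(nrow(one))])
})

test_that("pairwise attribute comparisons have the stated symmetries", {
  ext_sym <- mlba_params(lambda1 = 0.5, lambda2 = 0.5)
  v_ij <- mlba_comparison(8, 5 / 8, 6, 6 / 8, ext_sym)
  v_ji <- mlba_comparison(6, 6 / 8, 8, 5 / 8, ext_sym)
  expect_equal(v_ij, -v_ji)
  expect_equal(mlba_comparison(8, 5 / 8, 8, 5 / 8, mlba_params()), 0)
  # with asymmetric decay, disadvantages outweigh advantages in a pair's
  # mutual comparisons, and the penalty borne by the option dissimilar to a
  # third neighbor exceeds the similar option's
  ext <- mlba_params()
  expect_lt(mlba_comparison(8, 5 / 8, 6, 4 / 8, ext) +
              mlba_comparison(6, 4 / 8, 8, 5 / 8, ext), 0)
  nov <- enumerate_novel_trials()
  inp <- mivac:::mlba_inputs(nov, ext)
  di <- inp[, 1] - inp[, 2]
  cell <- tapply(di, list(nov$dominance, nov$similarity), mean)
  expect_true(all(cell[, "near_HV"] > cell[, "near_LV"]))
})

test_that("fixation durations follow their log-normal cells", {
  m <- default_fixation_model()
  x <- sample_fixation_duration(m, "HV", "first", n = 10000, seed = 5)
  cell <- m$cells[m$cells$option_type == "HV" &
                    m$cells$fixation_type == "first", ]
  mu <- exp(cell$meanlog + cell$sdlog^2 / 2)
  sdv <- mu * sqrt(exp(cell$sdlog^2) - 1)
  expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(10000))
  # zero scale collapses to the point mass at exp(location)
  m0 <- fixation_duration_model(within(m$cells, sdlog <- 0))
  expect_equal(sample_fixation_duration(m0, "LV", "middle", n = 3),
               rep(exp(m0$cells$meanlog[m0$cells$option_type == "LV" &
                                          m0$cells$fixation_type == "middle"]),
                   3))
  expect_error(sample_fixation_duration(m, "HV", "nope"), "missing cell")
  expect_error(fixation_duration_model(m$cells[-1, ]), "missing cell")
})

test_that("empirical fixation durations keep the value-capture signature", {
  lowd <- make_trials(8, 5 / 8, 4, 3 / 8, 2, 1 / 8)
  highd <- make_trials(8, 5 / 8, 4, 3 / 8, 12, 6 / 8)
  params <- mivac_params(sigma = 18, gamma = 1.2, beta = 8, pi = 0.35)
  fm <- default_fixation_model()
  a <- simulate_trials(lowd, params, n_reps = 5000, seed = 31,
                       fixation_model = fm)
  b <- simulate_trials(highd, params, n_reps = 5000, seed = 32,
                       fixation_model = fm)
  expect_gt(mean(b$response == "D"), mean(a$response == "D"))
})
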