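test_that("expected value follows the stimulus grid", {
  expect_equal(expected_value(8, 5 / 8), 5)
  expect_equal(expected_value(2, 6 / 8), 1.5)
  expect_equal(expected_value(2, 1 / 8), 0.25)
  expect_equal(expected_value(12, 7 / 8), 10.5)
  expect_error(expected_value(3, 5 / 8), "off the stimulus grid")
  expect_error(expected_value(8, 0.5001), "off the stimulus grid")
})

test_that("dominance classification distinguishes the four relations", {
  expect_equal(classify_dominance(6, 6 / 8, 4, 3 / 8), "a_dominates")
  expect_equal(classify_dominance(6, 6 / 8, 8, 5 / 8), "trade_off")
  expect_equal(classify_dominance(4, 3 / 8, 6, 6 / 8), "b_dominates")
  expect_equal(classify_dominance(6, 6 / 8, 6, 6 / 8), "equal")
  # weak dominance: equal on one attribute, strictly better on the other
  expect_equal(classify_dominance(6, 6 / 8, 6, 5 / 8), "a_dominates")
})

test_that("novel-trial enumeration yields 14 combinations and 56 trials", {
  nov <- enumerate_novel_trials()
  expect_equal(nrow(nov), 56)
  combos <- unique(nov[, c("hv_mag", "hv_prob", "lv_mag", "lv_prob")])
  expect_equal(nrow(combos), 14)
  # crossed factors: 14 trials per Dominance x Similarity cell
  expect_true(all(table(nov$dominance, nov$similarity) == 14))
  # deterministic and order-stable
  expect_identical(nov, enumerate_novel_trials())
})

test_that("novel trials satisfy their structural invariants", {
  nov <- enumerate_novel_trials()
  # HV has the higher EV and trades off with LV in every trial
  ev_hv <- nov$hv_mag * nov$hv_prob
  ev_lv <- nov$lv_mag * nov$lv_prob
  expect_true(all(ev_hv > ev_lv))
  expect_true(all(classify_dominance(nov$hv_mag, nov$hv_prob,
                                     nov$lv_mag, nov$lv_prob) == "trade_off"))
  # the Dominance label agrees with the relation between D and its adjacent
  # option, and D never stands in a dominance relation to the other option
  adj_mag <- ifelse(nov$similarity == "near_HV", nov$hv_mag, nov$lv_mag)
  adj_prob <- ifelse(nov$similarity == "near_HV", nov$hv_prob, nov$lv_prob)
  oth_mag <- ifelse(nov$similarity == "near_HV", nov$lv_mag, nov$hv_mag)
  oth_prob <- ifelse(nov$similarity == "near_HV", nov$lv_prob, nov$hv_prob)
  rel_adj <- classify_dominance(nov$d_mag, nov$d_prob, adj_mag, adj_prob)
  expect_true(all(rel_adj[nov$dominance == "D_dominates"] == "a_dominates"))
  expect_true(all(rel_adj[nov$dominance == "D_dominated"] == "b_dominates"))
  expect_true(all(classify_dominance(nov$d_mag, nov$d_prob,
                                     oth_mag, oth_prob) == "trade_off"))
  # every option on the grid
  g <- stimulus_grid()
  for (col in c("hv_mag", "lv_mag", "d_mag"))
    expect_true(all(nov[[col]] %in% g$magnitudes))
  for (col in c("hv_prob", "lv_prob", "d_prob"))
    expect_true(all(vapply(nov[[col]],
                           function(p) any(abs(g$probabilities - p) < 1e-9),
                           logical(1))))
})

test_that("rejection sampling enforces the shared-variance criterion", {
  tr <- sample_chau_trialset(150, 150, seed = 7)
  expect_equal(nrow(tr), 300)
  d <- tr[tr$d_present, ]
  hvmlv <- d$hv_mag * d$hv_prob - d$lv_mag * d$lv_prob
  hvmd <- d$hv_mag * d$hv_prob - d$d_mag * d$d_prob
  expect_lt(cor(hvmlv, hvmd)^2, 0.25)
  # labeling and grid invariants
  expect_true(all(tr$hv_mag * tr$hv_prob > tr$lv_mag * tr$lv_prob))
  ev_all <- c(tr$hv_mag * tr$hv_prob, tr$lv_mag * tr$lv_prob,
              d$d_mag * d$d_prob)
  expect_true(all(ev_all >= 0.25 & ev_all <= 10.5))
  # same seed reproduces the identical set
  expect_identical(tr, sample_chau_trialset(150, 150, seed = 7))
  expect_error(sample_chau_trialset(2, 0, seed = 1), "at least 3")
})

test_that("pooled role-wise EV ranges match the achievable extremes", {
  evs <- do.call(rbind, lapply(1:8, function(s) {
    tr <- sample_chau_trialset(120, 0, seed = s)
    cbind(hv = tr$hv_mag * tr$hv_prob, lv = tr$lv_mag * tr$lv_prob,
          d = tr$d_mag * tr$d_prob)
  }))
  # HV >= 0.5 (something must lie strictly below it), LV and D <= 9
  expect_gte(min(evs[, "hv"]), 0.5)
  expect_lte(max(evs[, "lv"]), 9)
  expect_lte(max(evs[, "d"]), 9)
  expect_gte(min(evs[, "lv"]), 0.25)
  expect_gte(min(evs[, "d"]), 0.25)
})

test_that("optional nondominance constraint shapes the sampled trials", {
  tr <- sample_chau_trialset(60, 30, seed = 3, nondominant_frac = 2 / 3)
  rel <- classify_dominance(tr$hv_mag, tr$hv_prob, tr$lv_mag, tr$lv_prob)
  d <- rel[tr$d_present]
  expect_equal(mean(d == "trade_off"), 2 / 3, tolerance = 0.02)
})

test_that("trial sets round-trip through CSV with exact fractions", {
  tr <- sample_chau_trialset(20, 10, seed = 5)
  nov <- enumerate_novel_trials()
  nov$trial_id <- nov$trial_id + 30L
  both <- rbind(as.data.frame(tr), as.data.frame(nov))
  class(both) <- class(tr)
  path <- tempfile(fileext = ".csv")
  write_trials(both, path)
  back <- read_trials(path)
  for (col in c("trial_id", "hv_mag", "hv_prob", "lv_mag", "lv_prob",
                "d_mag", "d_prob", "d_present", "dominance", "similarity"))
    expect_equal(back[[col]], both[[col]], ignore_attr = TRUE)
  expect_false(any(grepl("0\\.", readLines(path)[1])))
})

test_that("trial-set summary reports per-role EV statistics", {
  tr <- make_trials(c(8, 12), c(5 / 8, 7 / 8), c(4, 2), c(3 / 8, 1 / 8),
                    c(6, 2), c(6 / 8, 1 / 8))
  s <- trialset_summary(tr)
  expect_equal(s$mean[s$role == "HV"], mean(c(5, 10.5)))
  expect_equal(s$min[s$role == "D"], 0.25)
  expect_equal(s$max[s$role == "D"], 4.5)
})
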