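# Stimulus space and trial-set construction for the two-attribute gamble task:
# a 6 x 7 grid of outcome magnitudes (CHF 2..12 in steps of 2) and win
# probabilities (1/8..7/8 in steps of 1/8).

#' Stimulus grids of the gamble task
#'
#' The task presents two-outcome gambles whose magnitude and probability lie
#' on fixed grids: magnitudes CHF 2 to 12 in steps of 2, probabilities 1/8 to
#' 7/8 in steps of 1/8.  All expected values therefore lie on the 42-value
#' product grid between 0.25 and 10.5.
#'
#' @return A list with numeric vectors `magnitudes` and `probabilities`.
#' @export
#' @examples
#' stimulus_grid()
stimulus_grid <- function() {
  list(magnitudes = seq(2, 12, by = 2), probabilities = (1:7) / 8)
}

on_grid <- function(magnitude, probability) {
  g <- stimulus_grid()
  ok_m <- !is.na(magnitude) &
    vapply(magnitude, function(m) any(abs(g$magnitudes - m) < 1e-9), logical(1))
  ok_p <- !is.na(probability) &
    vapply(probability, function(p) any(abs(g$probabilities - p) < 1e-9),
           logical(1))
  ok_m & ok_p
}

#' Expected value of a gamble on the stimulus grid
#'
#' @param magnitude Outcome magnitude in CHF; must lie on the magnitude grid.
#' @param probability Win probability; must lie on the probability grid.
#' @return `probability * magnitude`, vectorized.
#' @export
#' @examples
#' expected_value(8, 5 / 8)   # 5
#' expected_value(2, 6 / 8)   # 1.5
expected_value <- function(magnitude, probability) {
  if (!all(on_grid(magnitude, probability)))
    stop("invalid option: magnitude or probability off the stimulus grid")
  probability * magnitude
}

#' Dominance relation between two options
#'
#' Option a dominates option b when it is at least as good on both attributes
#' and strictly better on at least one; options that are each better on
#' exactly one attribute trade off.
#'
#' @param mag_a,prob_a,mag_b,prob_b Attribute values of the two options
#'   (vectorized).
#' @return Character vector with elements `"a_dominates"`, `"b_dominates"`,
#'   `"trade_off"`, or `"equal"`.
#' @export
#' @examples
#' classify_dominance(6, 6 / 8, 4, 3 / 8)  # a_dominates
#' classify_dominance(6, 6 / 8, 8, 5 / 8)  # trade_off
classify_dominance <- function(mag_a, prob_a, mag_b, prob_b) {
  a_ge <- mag_a >= mag_b & prob_a >= prob_b
  b_ge <- mag_b >= mag_a & prob_b >= prob_a
  eq <- mag_a == mag_b & prob_a == prob_b
  out <- rep("trade_off", length(mag_a))
  out[a_ge & !eq] <- "a_dominates"
  out[b_ge & !eq] <- "b_dominates"
  out[eq] <- "equal"
  out
}

new_trialset <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("mivac_trials", "data.frame")
  df
}

#' Rejection-sampled choice sets with a bounded shared-variance criterion
#'
#' Samples a set of distractor (three-option) and binary (two-option) trials.
#' For each trial, magnitudes and probabilities of the candidate options are
#' drawn independently and uniformly from the stimulus grids; the two
#' available options are labelled HV and LV by expected-value rank (ties
#' resampled), and the distractor D is the third draw.  Whole candidate sets
#' are regenerated until the squared Pearson correlation between the
#' trial-level HV-LV and HV-D expected-value differences across the
#' distractor trials falls below `r2_max`, so that the two regressors of the
#' core behavioral analysis share less than 25% variance by construction.
#'
#' @param n_distractor Number of distractor trials (at least 3, so the
#'   correlation is defined).
#' @param n_binary Number of binary trials.
#' @param seed Integer seed; the same seed reproduces the identical set.
#' @param r2_max Shared-variance bound (default 0.25).
#' @param max_rounds Maximum number of whole-set resampling rounds before a
#'   sampling-failure error.
#' @param nondominant_frac Optional fraction of trials constrained to have no
#'   dominance relation between HV and LV (the training phase used 2/3);
#'   `NULL` (default) leaves trials unconstrained.
#' @return A `mivac_trials` data frame with columns `trial_id`, `kind`,
#'   `hv_mag`, `hv_prob`, `lv_mag`, `lv_prob`, `d_mag`, `d_prob`,
#'   `d_present`, `dominance`, `similarity`.
#' @export
sample_chau_trialset <- function(n_distractor, n_binary, seed,
                                 r2_max = 0.25, max_rounds = 1000,
                                 nondominant_frac = NULL) {
  if (n_distractor < 3) stop("n_distractor must be at least 3")
  g <- stimulus_grid()
  set.seed(seed)

  sample_pairs <- function(n, with_d) {
    k <- if (with_d) 3L else 2L
    mag <- matrix(sample(g$magnitudes, n * k, replace = TRUE), n, k)
    prob <- matrix(sample(g$probabilities, n * k, replace = TRUE), n, k)
    ev <- mag * prob
    # resample trials whose two available options tie in EV, or whose
    # distractor is the grid's single most extreme gamble (the distractor's
    # achievable expected-value range is [0.25, 9], like LV's)
    repeat {
      bad <- ev[, 1] == ev[, 2]
      if (with_d) bad <- bad | ev[, 3] > 9
      if (!is.null(nondominant_frac)) {
        want_nd <- seq_len(n) <= round(nondominant_frac * n)
        rel <- classify_dominance(mag[, 1], prob[, 1], mag[, 2], prob[, 2])
        bad <- bad | (want_nd & rel != "trade_off") |
          (!want_nd & rel == "trade_off")
      }
      if (!any(bad)) break
      nb <- sum(bad)
      mag[bad, ] <- sample(g$magnitudes, nb * k, replace = TRUE)
      prob[bad, ] <- sample(g$probabilities, nb * k, replace = TRUE)
      ev <- mag * prob
    }
    hv_first <- ev[, 1] >= ev[, 2]
    hv <- ifelse(hv_first, 1L, 2L)
    lv <- 3L - hv
    idx <- seq_len(n)
    data.frame(
      hv_mag = mag[cbind(idx, hv)], hv_prob = prob[cbind(idx, hv)],
      lv_mag = mag[cbind(idx, lv)], lv_prob = prob[cbind(idx, lv)],
      d_mag = if (with_d) mag[, 3] else NA_real_,
      d_prob = if (with_d) prob[, 3] else NA_real_
    )
  }

  for (round in seq_len(max_rounds)) {
    dtr <- sample_pairs(n_distractor, with_d = TRUE)
    hvmlv <- dtr$hv_mag * dtr$hv_prob - dtr$lv_mag * dtr$lv_prob
    hvmd <- dtr$hv_mag * dtr$hv_prob - dtr$d_mag * dtr$d_prob
    if (cor(hvmlv, hvmd)^2 < r2_max) {
      df <- cbind(dtr, kind = "distractor", d_present = TRUE)
      if (n_binary > 0) {
        btr <- sample_pairs(n_binary, with_d = FALSE)
        df <- rbind(df, cbind(btr, kind = "binary", d_present = FALSE))
      }
      df$trial_id <- seq_len(nrow(df))
      df$dominance <- NA_character_
      df$similarity <- NA_character_
      return(new_trialset(df[, c("trial_id", "kind", "hv_mag", "hv_prob",
                                 "lv_mag", "lv_prob", "d_mag", "d_prob",
                                 "d_present", "dominance", "similarity")]))
    }
  }
  stop("sampling failure: shared-variance criterion not met within ",
       max_rounds, " rounds")
}

# HV/LV combinations eligible for the Dominance x Similarity set: an
# attribute trade-off between HV and LV such that a distractor placed one
# grid step away from either option on both attributes (i) fully dominates or
# is fully dominated by that adjacent option, (ii) stands in no dominance
# relation to the non-adjacent option, and (iii) stays on the grid for all
# four placements.  Exhaustive enumeration of the grid under this rule yields
# exactly 14 combinations.
enumerate_novel_pairs <- function() {
  g <- stimulus_grid()
  opts <- expand.grid(m = g$magnitudes, p = g$probabilities)
  dm <- 2
  dp <- 1 / 8
  keep <- list()
  for (i in seq_len(nrow(opts))) {
    for (j in seq_len(nrow(opts))) {
      a <- opts[i, ]
      b <- opts[j, ]
      if (!(a$m > b$m && a$p < b$p)) next  # one orientation covers each pair
      ev_a <- a$m * a$p
      ev_b <- b$m * b$p
      if (ev_a == ev_b) next
      hv <- if (ev_a > ev_b) a else b
      lv <- if (ev_a > ev_b) b else a
      ok <- TRUE
      for (role in c("hv", "lv")) {
        adj <- if (role == "hv") hv else lv
        oth <- if (role == "hv") lv else hv
        for (s in c(1, -1)) {
          d_m <- adj$m + s * dm
          d_p <- adj$p + s * dp
          if (!on_grid(d_m, d_p)) { ok <- FALSE; break }
          rel_oth <- classify_dominance(d_m, d_p, oth$m, oth$p)
          if (rel_oth != "trade_off") { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) keep[[length(keep) + 1L]] <-
          data.frame(hv_mag = hv$m, hv_prob = hv$p,
                     lv_mag = lv$m, lv_prob = lv$p)
    }
  }
  out <- do.call(rbind, keep)
  out[order(out$hv_mag, out$hv_prob, out$lv_mag, out$lv_prob), , drop = FALSE]
}

#' Enumerate the Dominance x Similarity distractor set
#'
#' Deterministically enumerates the novel distractor trials: all HV/LV pairs
#' on the stimulus grid with an attribute trade-off such that a distractor
#' can be placed one grid step above or below HV or LV on both attributes,
#' fully dominating (or fully dominated by) the adjacent option while having
#' no dominance relation with the other option.  Each of the 14 eligible
#' combinations yields four trials (D above HV, below HV, above LV, below
#' LV), labelled by the crossed factors Dominance (`D_dominates` /
#' `D_dominated`, relative to the adjacent option) and Similarity (`near_HV`
#' / `near_LV`), for 56 trials in total.
#'
#' @return A `mivac_trials` data frame of 56 distractor trials.
#' @export
#' @examples
#' nov <- enumerate_novel_trials()
#' nrow(nov)                       # 56
#' table(nov$dominance, nov$similarity)
enumerate_novel_trials <- function() {
  pairs <- enumerate_novel_pairs()
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    for (role in c("HV", "LV")) {
      adj_m <- if (role == "HV") pr$hv_mag else pr$lv_mag
      adj_p <- if (role == "HV") pr$hv_prob else pr$lv_prob
      for (s in c(1, -1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "novel",
          hv_mag = pr$hv_mag, hv_prob = pr$hv_prob,
          lv_mag = pr$lv_mag, lv_prob = pr$lv_prob,
          d_mag = adj_m + s * 2, d_prob = adj_p + s / 8,
          d_present = TRUE,
          dominance = if (s > 0) "D_dominates" else "D_dominated",
          similarity = if (role == "HV") "near_HV" else "near_LV"
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  df$trial_id <- seq_len(nrow(df))
  new_trialset(df[, c("trial_id", "kind", "hv_mag", "hv_prob", "lv_mag",
                      "lv_prob", "d_mag", "d_prob", "d_present", "dominance",
                      "similarity")])
}

#' Per-role expected-value summary of a trial set
#'
#' @param trials A `mivac_trials` data frame.
#' @return Data frame with mean, SD, min and max expected value for the HV,
#'   LV and D roles (D over distractor trials only).
#' @export
trialset_summary <- function(trials) {
  ev_hv <- trials$hv_mag * trials$hv_prob
  ev_lv <- trials$lv_mag * trials$lv_prob
  ev_d <- (trials$d_mag * trials$d_prob)[trials$d_present]
  summ <- function(x) c(mean = mean(x), sd = sd(x), min = min(x), max = max(x))
  out <- as.data.frame(rbind(HV = summ(ev_hv), LV = summ(ev_lv), D = summ(ev_d)))
  out$role <- rownames(out)
  rownames(out) <- NULL
  out[, c("role", "mean", "sd", "min", "max")]
}

#' Write and read trial sets as CSV
#'
#' Probabilities are written as exact eighths (`"k/8"`), so files round-trip
#' without floating-point loss.
#'
#' @param trials A `mivac_trials` data frame.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   `mivac_trials` data frame.
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(trials)
  for (col in c("hv_prob", "lv_prob", "d_prob")) {
    k <- round(df[[col]] * 8)
    df[[col]] <- ifelse(is.na(k), "", paste0(k, "/8"))
  }
  df$d_present <- as.integer(df$d_present)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  parse_frac <- function(x) {
    x[x == ""] <- NA
    vapply(x, function(s) {
      if (is.na(s)) return(NA_real_)
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      as.numeric(parts[1]) / as.numeric(parts[2])
    }, numeric(1), USE.NAMES = FALSE)
  }
  for (col in c("hv_prob", "lv_prob", "d_prob"))
    df[[col]] <- parse_frac(as.character(df[[col]]))
  df$d_present <- as.logical(df$d_present)
  df$d_mag[!df$d_present] <- NA_real_
  for (col in c("dominance", "similarity"))
    if (!is.null(df[[col]])) df[[col]][df[[col]] == ""] <- NA_character_
  new_trialset(df)
}
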