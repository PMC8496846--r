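# Build a synthetic trajectory object around a given infiltrating-CD8 series.
fake_traj <- function(cd8) {
  n <- length(cd8)
  counts <- data.frame(tick = 0:(n - 1), week = (0:(n - 1)) / 168,
                       n_healthy_beta = 100, n_apoptotic_beta = 0,
                       n_dead_beta = 0, births = 0,
                       n_infiltrating_cd8 = cd8, n_dc_islet = 0, n_apc_pln = 0)
  structure(list(counts = counts, onset_week = 32, onset_hour = NA_real_,
                 censored = TRUE, onset_threshold_frac = 0.2,
                 beta_init = 100, seed = 1L),
            class = "t1d_trajectory")
}

test_that("LHS designs are stratified exactly", {
  rng <- parameter_ranges()
  des <- lhs_sample(rng, n_strata = 100, seed = 3)
  expect_identical(dim(des$samples), c(100L, 21L))
  for (j in seq_len(ncol(des$samples))) {
    lo <- rng$low[j]; hi <- rng$high[j]
    stratum <- floor((des$samples[, j] - lo) / ((hi - lo) / 100))
    expect_identical(as.integer(sort(stratum)), 0:99)  # occupancy is a permutation
  }
  # binning oracle on a single (0, 10) range with 10 strata
  des10 <- lhs_sample(list(p = c(0, 10)), n_strata = 10, seed = 1)
  s <- sort(des10$samples$p)
  expect_true(all(s >= 0:9 & s < 1:10))
  # single stratum: one draw on the full range
  des1 <- lhs_sample(list(p = c(2, 4)), n_strata = 1, seed = 1)
  expect_identical(nrow(des1$samples), 1L)
  expect_true(des1$samples$p >= 2 && des1$samples$p <= 4)
  expect_error(lhs_sample(list(p = c(1, 1)), 10, 1), "degenerate")
})

test_that("weekly means read the count at each week's tick", {
  const <- fake_traj(rep(7, 14 * 168 + 1))
  expect_identical(unname(weekly_means(const, c(4, 6, 8, 10, 12, 14))),
                   rep(7, 6))
  ramp <- fake_traj(0:(14 * 168))  # count(t) = t
  wm <- weekly_means(ramp, c(4, 6, 8, 10, 12, 14))
  expect_identical(length(wm), 6L)
  expect_equal(unname(wm["week4"]), 672)
  expect_error(weekly_means(ramp, 20), "cover")
})

test_that("fit score decomposes into discrepancy and R-squared", {
  perfect <- fit_score(c(1, 2, 3), c(1, 2, 3))
  expect_identical(perfect$discrepancy, 0)
  expect_identical(perfect$r2, 1)
  mid <- fit_score(c(2, 2, 2), c(1, 2, 3))
  expect_identical(mid$discrepancy, 2)
  expect_identical(mid$r2, 0)
  expect_identical(fit_score(c(1, 2, 4), c(1, 2, 3))$discrepancy, 1)
  expect_warning(out <- fit_score(c(1, 2), c(5, 5)), "zero-variance")
  expect_true(is.na(out$r2))
  expect_error(fit_score(1:3, 1:4), "equal length")
  # SEM weighting rescales the discrepancy only
  wtd <- fit_score(c(2, 2, 2), c(1, 2, 3), sem = c(1, 1, 2))
  expect_identical(wtd$discrepancy, 1 + 0.25)
  expect_identical(wtd$r2, 0)
})

test_that("candidate selection returns the argmin with a full leaderboard", {
  cfg <- aggressive_cfg()
  cand <- data.frame(ctl_kill_prob = c(0.2, 0.15))
  # cheap two-week fit window keeps this a shape/contract check
  traj <- run_simulation(cfg, seed = 77, horizon_weeks = 2,
                         stop_at_onset = FALSE)
  dm <- weekly_means(traj, c(1, 2))
  sel <- suppressWarnings(
    select_default(cand, cfg, dm, weeks = c(1, 2), n_reps = 1, seed = 5))
  expect_identical(nrow(sel$leaderboard), 2L)
  expect_true(all(diff(sel$leaderboard$discrepancy) >= 0))
  expect_identical(sel$best$ctl_kill_prob,
                   sel$leaderboard$ctl_kill_prob[1])
  expect_identical(sel$best_config$params$ctl_kill_prob,
                   sel$best$ctl_kill_prob)
  # single candidate, n_reps = 1: that candidate comes back
  one <- suppressWarnings(
    select_default(cand[1, , drop = FALSE], cfg, dm, weeks = c(1, 2),
                   n_reps = 1, seed = 5))
  expect_identical(one$best$ctl_kill_prob, 0.2)
})
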