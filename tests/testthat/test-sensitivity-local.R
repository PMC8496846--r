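test_that("OAT levels span the default +/- 20 percent in 5 percent steps", {
  expect_equal(oat_levels(100), seq(80, 120, by = 5))
  expect_equal(oat_levels(100, step_frac = 0), rep(100, 9))
  lv <- oat_levels(37)
  expect_identical(length(lv), 9L)
  expect_equal(range(lv), c(37 * 0.8, 37 * 1.2))
  expect_error(oat_levels(-1), "positive")
})

test_that("level jitter follows the truncated normal contract", {
  expect_identical(sample_level(50, 0), 50)
  set.seed(4)
  draws <- replicate(1e4, sample_level(100, 6))
  expect_lt(abs(mean(draws) - 100), 0.2)
  expect_lt(abs(sd(draws) - 6), 0.2)
  set.seed(4)
  trunc <- replicate(500, sample_level(1, 2, range = c(0.5, Inf)))
  expect_true(all(trunc >= 0.5))
})

test_that("quartiles follow the ceiling-index formulas", {
  q <- quartiles(1:20)
  expect_identical(unname(q), c(5, 10.5, 15))  # x(5), median, x(15)
  expect_identical(unname(quartiles(rep(3, 7))), c(3, 3, 3))
  expect_identical(unname(quartiles(1:21)[["q2"]]), 11)
  set.seed(2)
  x <- rnorm(37)
  expect_identical(quartiles(x), quartiles(sample(x)))
  expect_error(quartiles(numeric(0)), "empty")
})

test_that("one-way ANOVA matches a brute-force sums-of-squares oracle", {
  res <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$SSR, 6)
  expect_equal(res$SSE, 6)
  expect_equal(res$F, 3)
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 6L)

  ident <- anova_oneway(list(rep(2, 5), rep(2, 5)))
  expect_identical(ident$F, 0)
  expect_identical(ident$p, 1)

  shifted <- anova_oneway(list(rnorm(10), rnorm(10) + 1000))
  expect_lt(shifted$p, 0.05)
  expect_true(shifted$significant)

  # brute-force two-pass oracle on random groups
  set.seed(8)
  for (rep in 1:5) {
    groups <- lapply(sample(2:6, 4, replace = TRUE) + 1, rnorm)
    y <- unlist(groups); gm <- mean(y)
    means <- vapply(groups, mean, numeric(1))
    nk <- vapply(groups, length, integer(1))
    SSR_o <- sum(nk * (means - gm)^2)
    SSE_o <- sum(unlist(Map(function(g, m) (g - m)^2, groups, means)))
    SST_o <- sum((y - gm)^2)
    M <- length(groups); N <- length(y)
    F_o <- (SSR_o / (M - 1)) / (SSE_o / (N - M))
    res <- anova_oneway(groups)
    expect_equal(res$SSR, SSR_o, tolerance = 1e-9)
    expect_equal(res$SSE, SSE_o, tolerance = 1e-9)
    expect_equal(res$SSR + res$SSE, SST_o, tolerance = 1e-9)
    expect_equal(res$F, F_o, tolerance = 1e-9)
    expect_equal(res$p, stats::pf(F_o, M - 1, N - M, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("the OAT screen separates driving from inert parameters", {
  cfg <- aggressive_cfg()
  # small design (N = 3) keeps this a structural check; seeds fixed
  scr <- local_screen(cfg, param_names = c("not_a_parameter",
                                           "init_apoptotic_beta"),
                      N = 3, seed = 42)
  expect_identical(nrow(scr$summary), 2L)
  expect_identical(nrow(scr$raw), 2L * 9L * 3L)
  # censored runs enter the response as the 32-week censoring value
  expect_true(all(scr$raw$onset_week <= 32))
  # the inert control must not be flagged
  inert_row <- scr$summary[scr$summary$parameter == "not_a_parameter", ]
  expect_false(inert_row$significant)
  # jittered values stay within the physical range of the real parameter
  real <- scr$raw[scr$raw$parameter == "init_apoptotic_beta", ]
  expect_true(all(real$value >= 50 & real$value <= 400))
})
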