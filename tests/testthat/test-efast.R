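test_that("the search curve stays in the unit interval and hits anchors", {
  expect_equal(search_curve(1, 0), 0.5)
  expect_equal(search_curve(5, 0), 0.5)
  expect_equal(search_curve(1, pi / 2), 1.0)
  s <- seq(-pi, pi, length.out = 4001)
  for (om in c(1, 3, 24)) {
    q <- search_curve(om, s)
    expect_true(all(q >= 0 & q <= 1))
  }
  expect_error(search_curve(0, 1), "omega")
})

test_that("frequency selection follows the interference rules", {
  fr <- select_frequencies(200, 4, 5)
  expect_identical(fr$driver, 24L)
  expect_true(all(fr$complementary <= 3))
  expect_identical(length(fr$complementary), 4L)
  # harmonics of complementary frequencies stay below the driver
  expect_true(all(fr$complementary * 4 < 24))
  single <- select_frequencies(200, 4, 1)
  expect_identical(length(single$complementary), 0L)
  expect_error(select_frequencies(10, 4, 2), "exceed")
})

test_that("quantile transforms invert the factor distributions", {
  expect_equal(quantile_transform(0.5, list(dist = "normal", mean = 100,
                                            sd = 20)), 100)
  expect_equal(quantile_transform(pnorm(1), list(dist = "normal", mean = 100,
                                                 sd = 20)), 120)
  expect_equal(quantile_transform(0.25, list(dist = "uniform", min = 0,
                                             max = 8)), 2)
  expect_error(quantile_transform(1.2, list(dist = "uniform", min = 0,
                                            max = 1)), "\\[0, 1\\]")
  expect_error(quantile_transform(0.5, list(dist = "beta")), "unsupported")
})

test_that("eFAST indices recover analytic variance fractions", {
  # constant output: zero variance, flagged, all indices 0
  zero <- efast_indices(rep(5, 200), 24, 4)
  expect_true(zero$zero_variance)
  expect_identical(zero$S_i, 0)
  expect_identical(zero$S_T, 0)

  # additive linear model y = sum(a_i q_i): with independent near-uniform
  # factors the analytic shares are a_i^2 / sum(a^2); Monte-Carlo oracle
  # computed first from independent uniform draws
  a <- c(2, 1, 0.5, 0.25, 1.5)
  set.seed(30)
  qmc <- matrix(runif(2e5 * 5), ncol = 5)
  ymc <- qmc %*% a
  oracle <- vapply(1:5, function(i) {
    a[i]^2 * var(qmc[, i]) / var(as.vector(ymc))
  }, numeric(1))

  factors <- stats::setNames(
    rep(list(list(dist = "uniform", min = 0, max = 1)), 5),
    paste0("f", 1:5))
  des <- efast_design(factors, n = 200, m = 4)
  res <- efast_run(function(x) sum(a * x), des)
  for (i in 1:5) {
    expect_lt(abs(res$S_i[i] - oracle[i]), 0.05)
    expect_lt(abs(res$S_T[i] - oracle[i]), 0.1)  # no interactions: S_T ~ S_i
    expect_lte(res$S_i[i], res$S_T[i] + 0.02)
  }

  # output driven only by the driven factor
  des1 <- efast_design(factors, n = 200, m = 4)
  only <- efast_run(function(x) x[["f1"]], des1)
  expect_gt(only$S_i[1], 0.95)
})

test_that("design rotations drive each factor once without aliasing", {
  factors <- stats::setNames(
    rep(list(list(dist = "uniform", min = 0, max = 1)), 5), letters[1:5])
  des <- efast_design(factors, n = 200, m = 4)
  expect_identical(length(des$X), 5L)
  for (i in 1:5) {
    expect_identical(unname(des$omegas[i, i]), 24L)
    expect_true(all(des$omegas[i, -i] <= 3))
    expect_identical(dim(des$X[[i]]), c(200L, 5L))
    expect_true(all(des$Q[[i]] >= 0 & des$Q[[i]] <= 1))
  }
  # reproducibility: the design is deterministic
  des2 <- efast_design(factors, n = 200, m = 4)
  expect_identical(des$X, des2$X)
})

test_that("a reduced-scale eFAST campaign returns coherent indices", {
  cfg <- aggressive_cfg()
  mu0 <- cfg$params$dc_recruit_mu
  factors <- list(
    ctl_lifespan_h = list(dist = "uniform", min = 96, max = 144),
    init_apoptotic_beta = list(dist = "uniform", min = 10, max = 40),
    dc_move_interval_h = list(dist = "uniform", min = 1, max = 6),
    max_naive_binding = list(dist = "uniform", min = 1, max = 6),
    dc_recruit_mu = list(dist = "uniform", min = 0.5 * mu0, max = 1.5 * mu0))
  res <- efast_campaign(cfg, factors, n = 33, m = 2, mode = "full", seed = 2)
  expect_identical(nrow(res), 5L)
  expect_true(all(res$S_i >= 0 & res$S_i <= 1))
  expect_true(all(res$S_T >= 0 & res$S_T <= 1.02))
  expect_true(all(res$S_i <= res$S_T + 0.02))
  expect_identical(unique(res$n_used), 33L)

  # reduced mode keeps only onset cases; with guaranteed onsets it exists
  red <- efast_campaign(cfg, factors, n = 33, m = 2, mode = "reduced",
                        seed = 2)
  expect_identical(nrow(red), 5L)
  expect_true(all(red$n_used <= 33L))
})
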