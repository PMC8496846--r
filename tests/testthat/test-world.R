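test_that("grid scale converts islet diameter to patch length", {
  expect_equal(grid_scale(100, 38), 1.32)
  expect_equal(grid_scale(76, 38), 1.00)
  expect_equal(grid_scale(110, 38), 1.45)
  expect_error(grid_scale(0, 38), "positive")
  expect_error(grid_scale(100, -1), "positive")
})

test_that("the region map partitions the whole grid into three bands", {
  cfg <- micro_cfg()
  w <- build_world(cfg, 1)
  expect_setequal(unique(as.vector(w$region)), c(1L, 2L, 3L))
  expect_identical(length(w$region), cfg$grid_width * cfg$grid_height)
  expect_identical(sort(c(w$islet_cells, w$pln_cells, w$circ_cells)),
                   seq_len(cfg$grid_width * cfg$grid_height))
})

test_that("beta placement honours count, islet disks, and the seed", {
  cfg <- t1d_config(grid_width = 60, grid_height = 60, n_islets = 5,
                    islet_radius = 10, n_beta_cells = 320)
  w <- build_world(cfg, 7)
  expect_identical(length(w$bx), 320L)
  # every beta patch within the radius of at least one centre
  d2min <- sapply(seq_along(w$bx), function(i)
    min((w$bx[i] - w$islet_centers[, 1])^2 + (w$by[i] - w$islet_centers[, 2])^2))
  expect_true(all(d2min <= 10^2))
  expect_true(all(w$region[w$bx + (w$by - 1) * cfg$grid_width] == 1L))
  # initial apoptotic relabelling
  expect_identical(sum(w$bstatus == 1L),
                   as.integer(round(cfg$params$init_apoptotic_beta)))
  # same seed -> identical world
  w2 <- build_world(cfg, 7)
  expect_identical(w[c("region", "bx", "by", "bstatus", "islet_centers")],
                   w2[c("region", "bx", "by", "bstatus", "islet_centers")])
  # different seed -> different placement
  w3 <- build_world(cfg, 8)
  expect_false(identical(w$bx, w3$bx))
})

test_that("degenerate worlds are rejected or empty as appropriate", {
  cfg0 <- t1d_config(n_islets = 0, n_beta_cells = 0,
                     params = modifyList(default_parameters(),
                                         list(init_apoptotic_beta = 0)))
  w <- build_world(cfg0, 1)
  expect_identical(length(w$bx), 0L)
  expect_error(t1d_config(n_islets = 0, n_beta_cells = 100), "no islets")
  expect_error(
    build_world(t1d_config(grid_width = 30, grid_height = 30, n_islets = 1,
                           islet_radius = 3, n_beta_cells = 5000), 1),
    "available")
  expect_error(t1d_config(onset_fraction_low = 0.4, onset_fraction_high = 0.3),
               "onset fractions")
})

test_that("per-run draws land inside their stated ranges", {
  for (s in 1:20) {
    w <- build_world(micro_cfg(), s)
    expect_gte(w$onset_threshold_frac, 0.10)
    expect_lte(w$onset_threshold_frac, 0.30)
    expect_gte(w$prolif_fraction, 0.154)
    expect_lte(w$prolif_fraction, 0.238)
    expect_gte(w$k_r, 0)
    nv <- w$agents$nv
    expect_true(all(nv[, "life"] >= 72 & nv[, "life"] <= 120))
    expect_true(all(w$q_el >= 0 & w$q_el < 168))
  }
})

test_that("world snapshots serialize with an RLE region map", {
  w <- build_world(micro_cfg(), 3)
  path <- tempfile(fileext = ".json")
  write_world(w, path)
  snap <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(
    as.integer(inverse.rle(list(lengths = snap$region_rle$lengths,
                                values = snap$region_rle$values))),
    as.integer(w$region))
  expect_identical(as.integer(snap$beta$x), as.integer(w$bx))
  unlink(path)
})
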