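#' Reduced desk-scale configuration
#'
#' Produces a configuration with the full rule structure at a fraction of
#' the full-scale arena, in the same spirit as the model's own one-percent
#' downscaling of the in-vivo beta-cell mass. Beta-cell geometry shrinks to
#' `n_islets` islets of `cells_per_islet` beta cells; the immune-cell pools
#' (naive pool, circulating and resident DCs, replenishment) scale by
#' `pool_scale`; the initial apoptotic count scales with the beta-cell
#' ratio; and the mean/SD of the DC recruitment rate are rescaled by the
#' inverse of the population scale factors so per-capita mass-action
#' recruitment is preserved (the recruitment term is a product of two
#' scaled populations).
#'
#' @param n_islets Number of islets (default 5).
#' @param cells_per_islet Beta cells per islet (default 64).
#' @param pool_scale Immune-pool scale relative to full scale (default 0.1).
#' @param params Full-scale parameter list to rescale.
#' @param seed Seed recorded in the configuration.
#' @return A [t1d_config()] whose 20-week run completes in seconds on one
#'   CPU.
#' @export
mini_world <- function(n_islets = 5, cells_per_islet = 64, pool_scale = 0.1,
                       params = default_parameters(), seed = 1L) {
  if (n_islets <= 0 || cells_per_islet <= 0 || pool_scale <= 0)
    stop("mini_world() sizes must be positive")
  n_beta <- n_islets * cells_per_islet
  # generous disk headroom: islets may overlap and clip at region borders,
  # yet the union of disks must still hold all beta cells
  radius <- ceiling(sqrt(2.4 * cells_per_islet / pi))
  side <- max(40, ceiling(4.2 * radius * sqrt(n_islets)))
  beta_ratio <- n_beta / 8080
  p <- params
  p$init_apoptotic_beta <- max(1, round(p$init_apoptotic_beta * beta_ratio))
  p$n_naive_pool <- max(4, round(p$n_naive_pool * pool_scale))
  p$dc_c <- max(2, round(p$dc_c * pool_scale))
  p$n_resident_dc <- max(1, round(p$n_resident_dc * pool_scale))
  p$naive_replenish_per_h <- p$naive_replenish_per_h * pool_scale
  p$dc_recruit_mu <- p$dc_recruit_mu / beta_ratio
  p$dc_recruit_sigma <- p$dc_recruit_sigma / beta_ratio
  t1d_config(grid_width = side, grid_height = side,
             n_islets = n_islets, islet_radius = radius,
             n_beta_cells = n_beta, params = p, seed = seed)
}

#' Surrogate weekly infiltrating-CD8 series
#'
#' A stand-in for the (unpublished) weekly NOD-mouse infiltrating-CD8
#' counts used for calibration: a sigmoidal rise centred near week 8 with a
#' superimposed oscillation — low counts before week 8, a marked increase
#' around week 8, and a continued rise through week 14 — with per-week SEM
#' derived from the replicate counts of the validation experiment
#' (7, 6, 5, 6, 7, 12 mice at weeks 4, 6, 8, 10, 12, 14). This is a
#' synthetic series shaped by qualitative constraints, not experimental
#' data.
#'
#' @param seed Integer seed.
#' @param plateau Asymptotic count of the sigmoid (default 400).
#' @param midpoint_week Week of the half-rise (default 8).
#' @param rise_rate Sigmoid steepness in 1/weeks (default 0.9).
#' @param osc_amp Relative amplitude of the oscillation (default 0.10).
#' @param osc_period Oscillation period in weeks (default 5).
#' @param noise_scale Relative SD of the multiplicative per-week noise;
#'   0 gives the deterministic shape (default 0.08).
#' @return Object of class `t1d_cd8_series`: data.frame with `week`,
#'   `mean`, `sem`, `n_rep`, plus attributes `seed` and `shape`.
#' @export
surrogate_cd8_series <- function(seed = 1L, plateau = 400, midpoint_week = 8,
                                 rise_rate = 0.9, osc_amp = 0.10,
                                 osc_period = 5, noise_scale = 0.08) {
  weeks <- c(4, 6, 8, 10, 12, 14)
  n_rep <- c(7, 6, 5, 6, 7, 12)
  set.seed(as.integer(seed))
  shape <- plateau / (1 + exp(-rise_rate * (weeks - midpoint_week))) *
    (1 + osc_amp * sin(2 * pi * weeks / osc_period))
  m <- shape * exp(stats::rnorm(length(weeks), 0, noise_scale))
  # enforce the qualitative constraints: increase through the rise
  post <- weeks >= 6
  m[post] <- cummax(m[post])
  if (m[weeks == 10] <= m[weeks == 6])
    m[weeks == 10] <- m[weeks == 6] * 1.05
  sem <- noise_scale * m / sqrt(n_rep) + m * 0.05 / sqrt(n_rep)
  out <- data.frame(week = weeks, mean = m, sem = sem, n_rep = n_rep)
  attr(out, "seed") <- seed
  attr(out, "shape") <- shape
  class(out) <- c("t1d_cd8_series", "data.frame")
  out
}

#' Write / read a trajectory
#'
#' The per-hour counts go to a tidy CSV; onset and run metadata go to a
#' JSON manifest next to it (same path with extension `.json`). Reading
#' reproduces the trajectory exactly (counts are integers; metadata is
#' written at full precision).
#'
#' @param traj A `t1d_trajectory`.
#' @param path CSV path.
#' @return `read_trajectory()` returns the `t1d_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "t1d_trajectory"))
  utils::write.csv(traj$counts, path, row.names = FALSE)
  meta <- traj[setdiff(names(traj), "counts")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  counts <- utils::read.csv(path)
  expected <- c("tick", "week", "n_healthy_beta", "n_apoptotic_beta",
                "n_dead_beta", "births", "n_infiltrating_cd8", "n_dc_islet",
                "n_apc_pln")
  if (!identical(names(counts), expected))
    stop("malformed trajectory CSV '", path, "': header is [",
         paste(names(counts), collapse = ", "), "]")
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  traj <- c(list(counts = counts), meta)
  traj$onset_week <- as.numeric(meta$onset_week)
  oh <- suppressWarnings(as.numeric(meta$onset_hour))  # censored: null/NA
  traj$onset_hour <- if (length(oh) != 1 || is.na(oh)) NA_real_ else oh
  traj <- traj[c("counts", "onset_week", "onset_hour", "censored",
                 "onset_threshold_frac", "beta_init", "seed")]
  class(traj) <- "t1d_trajectory"
  traj
}

#' Run manifest for exact re-execution
#'
#' @param config The run's [t1d_config()].
#' @param seed The run seed.
#' @return List with the package version, seed, and an md5 hash of the
#'   canonical JSON serialization of the configuration.
#' @export
run_manifest <- function(config, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  list(package = "t1dsim",
       version = as.character(utils::packageVersion("t1dsim")),
       seed = as.integer(seed),
       config_md5 = unname(tools::md5sum(tmp)))
}
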