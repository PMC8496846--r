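#' Simulation configuration
#'
#' Builds the single source of truth for one simulation run: world geometry,
#' region layout, the unknown-parameter set, and run control. The default
#' geometry is the full-scale arena: a 201 x 201 patch grid whose lower band
#' holds the pancreatic islets (25 islet centres, radius 38 patches, 8080
#' beta cells, i.e. about one percent of the ~900,000 beta cells of a NOD
#' mouse pancreas), with the upper band split between PLN and circulation.
#'
#' @param grid_width,grid_height Grid dimensions in patches.
#' @param n_islets Number of islet centres.
#' @param islet_radius Islet radius in patches.
#' @param n_beta_cells Total beta cells placed at step 0.
#' @param islet_diameter_um Mean islet diameter in micrometres (sets the
#'   physical patch length via [grid_scale()]).
#' @param max_weeks Censoring horizon in weeks reported for runs without
#'   onset (default 32).
#' @param onset_window_weeks Onset is only scored within this many weeks of
#'   autoimmunity (default 20).
#' @param onset_fraction_low,onset_fraction_high Bounds of the per-run
#'   uniform draw of the onset threshold (fraction of initial healthy beta
#'   cells; defaults 0.10 and 0.30).
#' @param region_layout List with `top_frac` (fraction of rows forming the
#'   PLN/circulation band) and `pln_col_frac` (fraction of columns of that
#'   band assigned to the PLN).
#' @param scale_factor Fraction of in-vivo cell numbers represented.
#' @param params Named list of unknown parameters; see [default_parameters()].
#' @param seed Default RNG seed recorded with the configuration.
#' @return An object of class `t1d_config`.
#' @seealso [mini_world()] for reduced desk-scale configurations.
#' @export
t1d_config <- function(grid_width = 201, grid_height = 201,
                       n_islets = 25, islet_radius = 38,
                       n_beta_cells = 8080, islet_diameter_um = 100,
                       max_weeks = 32, onset_window_weeks = 20,
                       onset_fraction_low = 0.10, onset_fraction_high = 0.30,
                       region_layout = list(top_frac = 0.3, pln_col_frac = 0.5),
                       scale_factor = 0.01,
                       params = default_parameters(),
                       seed = 1L) {
  cfg <- list(
    grid_width = as.integer(grid_width),
    grid_height = as.integer(grid_height),
    n_islets = as.integer(n_islets),
    islet_radius = islet_radius,
    n_beta_cells = as.integer(n_beta_cells),
    islet_diameter_um = islet_diameter_um,
    tick_hours = 1L,
    max_weeks = max_weeks,
    onset_window_weeks = onset_window_weeks,
    onset_fraction_low = onset_fraction_low,
    onset_fraction_high = onset_fraction_high,
    region_layout = region_layout,
    scale_factor = scale_factor,
    params = params,
    constants = behavior_constants(),
    seed = as.integer(seed)
  )
  class(cfg) <- "t1d_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg A `t1d_config`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "t1d_config"))
  if (cfg$n_islets > 0 && (cfg$grid_width < 2 * cfg$islet_radius ||
                           cfg$grid_height < 2 * cfg$islet_radius))
    stop("grid dimensions must be at least twice the islet radius")
  if (!(cfg$onset_fraction_low > 0 &&
        cfg$onset_fraction_low < cfg$onset_fraction_high &&
        cfg$onset_fraction_high < 1))
    stop("onset fractions must satisfy 0 < low < high < 1")
  if (cfg$n_beta_cells > 0 && cfg$n_islets <= 0)
    stop("beta cells requested but no islets configured")
  if (cfg$n_beta_cells < 0) stop("n_beta_cells must be non-negative")
  rl <- cfg$region_layout
  if (!(rl$top_frac > 0 && rl$top_frac < 1 &&
        rl$pln_col_frac > 0 && rl$pln_col_frac < 1))
    stop("region layout fractions must lie strictly in (0, 1)")
  validate_parameters(cfg$params)
  invisible(TRUE)
}

#' @export
print.t1d_config <- function(x, ...) {
  cat("t1d_config:", x$grid_width, "x", x$grid_height, "grid,",
      x$n_islets, "islets (radius", x$islet_radius, "),",
      x$n_beta_cells, "beta cells\n")
  cat("  onset threshold U(", x$onset_fraction_low, ",",
      x$onset_fraction_high, "), window", x$onset_window_weeks,
      "weeks, censor at", x$max_weeks, "weeks\n")
  invisible(x)
}

#' Write / read a configuration as structured text
#'
#' Configurations serialize to YAML (every field of the configuration and of
#' the parameter set is addressable). Reading reproduces the object exactly.
#'
#' @param cfg A `t1d_config`.
#' @param path File path.
#' @return `read_config()` returns the `t1d_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "t1d_config"))
  out <- unclass(cfg)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("failed to parse config '", path,
                                           "': ", conditionMessage(e)))
  cfg <- t1d_config(
    grid_width = raw$grid_width, grid_height = raw$grid_height,
    n_islets = raw$n_islets, islet_radius = raw$islet_radius,
    n_beta_cells = raw$n_beta_cells, islet_diameter_um = raw$islet_diameter_um,
    max_weeks = raw$max_weeks, onset_window_weeks = raw$onset_window_weeks,
    onset_fraction_low = raw$onset_fraction_low,
    onset_fraction_high = raw$onset_fraction_high,
    region_layout = raw$region_layout,
    scale_factor = raw$scale_factor,
    params = raw$params,
    seed = raw$seed
  )
  cfg
}
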