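#' Table of unknown model parameters
#'
#' The model carries 21 tunable ("unknown") parameters whose values are not
#' fixed by experimental measurement. Each has a repository default and a
#' range used by Latin hypercube calibration and the sensitivity analyses.
#' The first five rows are the sensitive set identified by local screening:
#' CTL lifespan in islets, initial apoptotic beta-cell count, DC movement
#' interval in islets, APC binding capacity for naive CD8+ T cells, and the
#' mean DC recruitment rate.
#'
#' Defaults are repository defaults chosen inside the stated ranges (the CTL
#' lifespan default of 120 h is anchored by the therapy worked example that
#' reduces it to 114 h); they are not values published with the model.
#'
#' @return A data.frame with columns `name`, `default`, `low`, `high`,
#'   `integer` (whether the parameter is used as an integer count).
#' @export
parameter_ranges <- function() {
  tab <- rbind(
    c("ctl_lifespan_h",        120,    96,     144,   0),
    c("init_apoptotic_beta",   200,    50,     400,   1),
    c("dc_move_interval_h",    2,      1,      6,     1),
    c("max_naive_binding",     2,      1,      6,     1),
    c("dc_recruit_mu",         3e-5,   5e-6,   8e-5,  0),
    c("dc_recruit_sigma",      5e-6,   5e-7,   2e-5,  0),
    c("dc_c",                  100,    50,     200,   1),
    c("gamma",                 1,      0.5,    2,     0),
    c("n_naive_pool",          300,    100,    500,   1),
    c("n_resident_dc",         20,     5,      50,    1),
    c("antigen_lifespan_h",    24,     6,      48,    1),
    c("apoptotic_duration_h",  72,     24,     96,    1),
    c("naive_binding_sites",   2,      1,      4,     1),
    c("ctl_step_cells",        4,      2,      8,     0),
    c("restim_prob",           0.3,    0.1,    0.6,   0),
    c("ctl_kill_prob",         0.05,   0.02,   0.2,   0),
    c("dc_islet_lifespan_h",   96,     48,     168,   1),
    c("antigen_per_apoptosis", 1,      1,      3,     1),
    c("naive_replenish_per_h", 4,      1,      10,    0),
    c("dc_migration_trigger",  1,      1,      4,     1),
    c("apc_move_interval_h",   2,      1,      6,     1)
  )
  data.frame(
    name    = tab[, 1],
    default = as.numeric(tab[, 2]),
    low     = as.numeric(tab[, 3]),
    high    = as.numeric(tab[, 4]),
    integer = as.numeric(tab[, 5]) == 1,
    stringsAsFactors = FALSE
  )
}

#' Default unknown-parameter set
#'
#' @return Named list of the 21 unknown parameters at their repository
#'   defaults (see [parameter_ranges()]).
#' @export
default_parameters <- function() {
  tab <- parameter_ranges()
  as.list(stats::setNames(tab$default, tab$name))
}

# Behavioural constants measured in NOD-mouse experiments (hours unless
# noted). Ranges are sampled per agent at creation; scalars are fixed.
behavior_constants <- function() {
  list(
    apc_lifespan_h            = c(48, 72),    # APC lifespan in PLN
    apc_short_contact_h       = c(6, 8),      # short APC/naive contact
    naive_activation_h        = c(2, 24),     # stable contact to activation
    naive_diff_cycle_h        = c(4, 8),      # differentiation cycle
    naive_lifespan_h          = c(72, 120),   # naive CD8 lifespan in PLN (3-5 d)
    pln_residence_h           = c(72, 120),   # activated cells egress after 3-5 d
    dc_islet_to_pln_h         = c(360, 432),  # DC migration islets -> PLN (15-18 d)
    activated_transit_h       = 120,          # PLN -> islet transit
    ctl_prolif_interval_h     = 120,          # CTL proliferation clock
    ctl_prolif_offspring      = c(4, 7),      # offspring per proliferation
    ctl_prolif_fraction       = c(0.154, 0.238), # fraction of CTLs proliferating
    beta_replication_h        = 24,           # beta-cell division duration
    quiescence_T0_h           = 168           # baseline beta quiescence (7 d)
  )
}

validate_parameters <- function(params) {
  tab <- parameter_ranges()
  missing <- setdiff(tab$name, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  for (nm in tab$name) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("parameter '", nm, "' must be a single number")
    if (v < 0) stop("parameter '", nm, "' must be non-negative")
  }
  invisible(TRUE)
}
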