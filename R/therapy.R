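#' Specify a therapeutic intervention
#'
#' Three single-target strategies are modelled, each a persistent fractional
#' reduction of its parameter from the administration week onward:
#' \itemize{
#'   \item T1 — reduce CTL longevity in islets (`ctl_lifespan_h`);
#'   \item T2 — inhibit DC infiltration into islets (mean recruitment rate
#'     `dc_recruit_mu`, i.e. the drawn rate k_r);
#'   \item T3 — mitigate naive CD8+ binding to DCs (`max_naive_binding`).
#' }
#' At most two strategies may be combined. The anchor dose for T1 is 0.05
#' (lifespan 120 h reduced to 114 h).
#'
#' @param components Character vector drawn from `c("T1", "T2", "T3")`,
#'   length 1 or 2.
#' @param admin_week Administration week (single dose; the reduction
#'   persists for the rest of the run).
#' @param dose Fractional reduction in `[0, 1]` applied to each targeted
#'   parameter.
#' @return Object of class `t1d_therapy`.
#' @export
therapy_spec <- function(components, admin_week, dose) {
  components <- unique(as.character(components))
  if (!length(components) || length(components) > 2 ||
      !all(components %in% c("T1", "T2", "T3")))
    stop("components must be 1 or 2 of 'T1', 'T2', 'T3'")
  if (dose < 0 || dose > 1) stop("dose must lie in [0, 1]")
  if (admin_week < 0) stop("admin_week must be >= 0")
  structure(list(components = components, admin_week = admin_week,
                 dose = dose), class = "t1d_therapy")
}

therapy_targets <- c(T1 = "ctl_lifespan_h", T2 = "dc_recruit_mu",
                     T3 = "max_naive_binding")

#' Effective parameters under a therapy
#'
#' Pure view of the intervention: before the administration week the
#' parameters are unchanged; at and after it each targeted parameter is
#' multiplied by `1 - dose`.
#'
#' @param params Named parameter list (see [default_parameters()]).
#' @param spec A [therapy_spec()].
#' @param current_week Simulation week at which the parameters are queried.
#' @return The effective parameter list.
#' @export
apply_therapy <- function(params, spec, current_week) {
  stopifnot(inherits(spec, "t1d_therapy"))
  if (current_week < spec$admin_week) return(params)
  for (comp in spec$components) {
    nm <- therapy_targets[[comp]]
    params[[nm]] <- params[[nm]] * (1 - spec$dose)
  }
  params
}

# In-run application: scales the effective engine parameters once, at the
# administration tick. Lifespans already drawn are kept (therapy affects
# newly created CTLs); the drawn recruitment rate k_r is scaled directly.
apply_therapy_env <- function(E, spec) {
  for (comp in spec$components) {
    switch(comp,
           T1 = { E$eff_ctl_lifespan <- E$eff_ctl_lifespan * (1 - spec$dose) },
           T2 = { E$eff_k_r <- E$eff_k_r * (1 - spec$dose) },
           T3 = { E$eff_max_naive_binding <-
                    E$eff_max_naive_binding * (1 - spec$dose) })
  }
  invisible(E)
}

#' Estimate the probability of developing T1D under a therapy
#'
#' Runs `n_runs` seeded simulations with the intervention applied and
#' reports `P_T1D = onsets within the scoring window / n_runs`.
#'
#' @param config A [t1d_config()].
#' @param spec A [therapy_spec()], or `NULL` for the untreated baseline.
#' @param n_runs Replicate simulations (default 50).
#' @param seed Integer seed; run r uses seed `seed + r - 1`, so paired-seed
#'   comparisons across specs are obtained by reusing `seed`.
#' @return Object of class `t1d_therapy_outcome`: list with `spec`,
#'   `n_runs`, `n_onsets`, `p_t1d`, `onset_weeks`, `seeds`.
#' @export
estimate_p_t1d <- function(config, spec = NULL, n_runs = 50, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  seeds <- seed + seq_len(n_runs) - 1L
  onset_weeks <- numeric(n_runs)
  onsets <- 0L
  for (r in seq_len(n_runs)) {
    traj <- run_simulation(config, seed = seeds[r], therapy = spec)
    onset_weeks[r] <- traj$onset_week
    if (!traj$censored) onsets <- onsets + 1L
  }
  structure(list(spec = spec, n_runs = n_runs, n_onsets = onsets,
                 p_t1d = onsets / n_runs, onset_weeks = onset_weeks,
                 seeds = seeds),
            class = "t1d_therapy_outcome")
}

#' @export
print.t1d_therapy_outcome <- function(x, ...) {
  comp <- if (is.null(x$spec)) "baseline" else
    paste(x$spec$components, collapse = "+")
  cat("P(T1D) =", x$p_t1d, "(", x$n_onsets, "/", x$n_runs, "runs ) [",
      comp, "]\n")
  invisible(x)
}

#' Therapy campaign over administration week and dose
#'
#' Estimates `P_T1D` for every (week, dose) cell of a single- or
#' two-component strategy, with shared run seeds across cells so that
#' week/dose contrasts are paired.
#'
#' @param config A [t1d_config()].
#' @param components Components of the strategy (see [therapy_spec()]).
#' @param weeks Administration weeks (e.g. `seq(4, 16, 2)`).
#' @param doses Dose grid (fractional reductions).
#' @param n_runs Replicates per cell (default 50).
#' @param seed Base seed shared across cells.
#' @return Tidy data.frame: `components`, `admin_week`, `dose`, `n_runs`,
#'   `n_onsets`, `p_t1d` — one row per cell, suitable for heatmap rendering.
#' @export
therapy_grid <- function(config, components, weeks, doses, n_runs = 50,
                         seed = 1L) {
  if (!length(weeks) || !length(doses)) stop("empty week or dose grid")
  grid <- expand.grid(admin_week = weeks, dose = doses)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- if (grid$dose[i] == 0) NULL else
      therapy_spec(components, grid$admin_week[i], grid$dose[i])
    out <- estimate_p_t1d(config, spec, n_runs = n_runs, seed = seed)
    data.frame(components = paste(components, collapse = "+"),
               admin_week = grid$admin_week[i], dose = grid$dose[i],
               n_runs = n_runs, n_onsets = out$n_onsets, p_t1d = out$p_t1d)
  })
  do.call(rbind, res)
}
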