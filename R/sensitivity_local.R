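#' One-at-a-time perturbation levels
#'
#' Level means for the local sensitivity design: `n_side` values on each
#' side of the default, spaced by `step_frac` of the default (M = 9 levels
#' spanning the default +/- 20 percent with the defaults).
#'
#' @param P_d Default (baseline) parameter value, > 0.
#' @param step_frac Spacing as a fraction of `P_d` (default 0.05).
#' @param n_side Levels on each side of the default (default 4).
#' @return Numeric vector of `2 * n_side + 1` level means.
#' @examples
#' oat_levels(100)  # 80 85 ... 120
#' @export
oat_levels <- function(P_d, step_frac = 0.05, n_side = 4) {
  if (P_d <= 0) stop("P_d must be positive")
  P_d * (1 + step_frac * (-n_side:n_side))
}

#' Draw a perturbed parameter value around a level mean
#'
#' Values follow Normal(level_mean, sd) with sd defaulting to 6 percent of
#' the baseline, extending coverage toward the default +/- 30 percent.
#' Draws outside the physical range are redrawn (then clamped as a last
#' resort).
#'
#' @param level_mean Mean of the perturbation distribution.
#' @param sd Standard deviation (>= 0).
#' @param range Physical range `c(min, max)` for truncation.
#' @return A single perturbed value inside `range`.
#' @export
sample_level <- function(level_mean, sd, range = c(-Inf, Inf)) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(min(max(level_mean, range[1]), range[2]))
  for (i in 1:100) {
    v <- stats::rnorm(1, level_mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  min(max(level_mean, range[1]), range[2])
}

#' Quartiles by the ceiling-index order-statistic convention
#'
#' Q1 and Q3 are the order statistics at index `ceiling(0.25 N)` and
#' `ceiling(0.75 N)` of the ascending sort (equivalently type-1 sample
#' quantiles); Q2 is the standard median (the mean of the two central order
#' statistics for even N).
#'
#' @param x Numeric vector (length >= 1).
#' @return Named vector `c(q1, q2, q3)`.
#' @export
quartiles <- function(x) {
  if (length(x) == 0) stop("empty vector")
  c(q1 = unname(stats::quantile(x, 0.25, type = 1)),
    q2 = stats::median(x),
    q3 = unname(stats::quantile(x, 0.75, type = 1)))
}

#' One-way ANOVA across perturbation levels
#'
#' Standard decomposition of the total sum of squares into between-group
#' (SSR) and within-group (SSE) components with
#' `F = (SSR/(M-1)) / (SSE/(N_total-M))` and the p-value from the
#' F(M-1, N_total-M) distribution; the null is equality of all level means.
#' The degenerate all-constant case is reported as F = 0, p = 1.
#'
#' @param groups List of M numeric vectors (M >= 2, each of length >= 2).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return List with `F`, `df_between`, `df_within`, `p`, `SSR`, `SSE`,
#'   `significant`.
#' @export
anova_oneway <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  M <- length(groups); N <- length(y)
  if (stats::var(y) == 0) {
    return(list(F = 0, df_between = M - 1L, df_within = N - M, p = 1,
                SSR = 0, SSE = 0, significant = FALSE))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  SSR <- tab$`Sum Sq`[1]; SSE <- tab$`Sum Sq`[2]
  Fv <- if (SSE == 0) Inf else tab$`F value`[1]
  p <- if (SSE == 0) 0 else tab$`Pr(>F)`[1]
  list(F = Fv, df_between = M - 1L, df_within = N - M, p = p,
       SSR = SSR, SSE = SSE, significant = p < alpha)
}

#' Local (OAT + ANOVA) sensitivity screen of onset time
#'
#' For each named parameter, runs the M x N one-at-a-time design: M level
#' means at the default +/- 20 percent in 5 percent steps, each level
#' jittered by Normal(level, 6 percent of default) and truncated to the
#' parameter's physical range, N replicate simulations per level recording
#' the week of overt T1D (censored runs enter as the censoring value, 32
#' weeks by default). A one-way ANOVA across levels gives the sensitivity
#' verdict. A parameter name absent from the configuration is treated as an
#' inert negative control (the draws do not enter the model).
#'
#' @param config Base [t1d_config()] holding the calibrated defaults.
#' @param param_names Parameters to screen (default: all 21 unknowns).
#' @param N Replicates per level (default 20).
#' @param step_frac,n_side,sd_frac Design constants (5 percent spacing, 4
#'   levels per side, jitter SD 6 percent of the default).
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return List with `summary` (data.frame: parameter, F, p, significant)
#'   and `raw` (data.frame: parameter, level, rep, value, onset_week) for
#'   boxplot-style summaries via [quartiles()].
#' @export
local_screen <- function(config, param_names = parameter_ranges()$name,
                         N = 20, step_frac = 0.05, n_side = 4,
                         sd_frac = 0.06, seed = 1L, alpha = 0.05) {
  rng_tab <- parameter_ranges()
  raw <- list()
  summ <- list()
  run_i <- 0L
  for (pn in param_names) {
    inert <- !(pn %in% names(config$params))
    P_d <- if (inert) 1 else config$params[[pn]]
    phys <- if (pn %in% rng_tab$name) {
      r <- rng_tab[rng_tab$name == pn, ]
      c(r$low, r$high)
    } else c(0, Inf)
    levels <- oat_levels(P_d, step_frac, n_side)
    M <- length(levels)
    onset <- matrix(0, N, M)
    vals <- matrix(0, N, M)
    for (j in seq_len(M)) {
      for (r in seq_len(N)) {
        run_i <- run_i + 1L
        set.seed(seed * 100003L + run_i)
        v <- sample_level(levels[j], sd_frac * P_d, range = phys)
        vals[r, j] <- v
        cfg <- config
        if (!inert) cfg$params[[pn]] <- v
        traj <- run_simulation(cfg, seed = seed * 1009L + run_i)
        onset[r, j] <- traj$onset_week
      }
    }
    a <- anova_oneway(split(as.vector(onset), rep(seq_len(M), each = N)),
                      alpha = alpha)
    summ[[pn]] <- data.frame(parameter = pn, F = a$F, p = a$p,
                             significant = a$significant)
    raw[[pn]] <- data.frame(parameter = pn,
                            level = rep(levels, each = N),
                            rep = rep(seq_len(N), M),
                            value = as.vector(vals),
                            onset_week = as.vector(onset))
  }
  list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
       raw = do.call(rbind, c(raw, make.row.names = FALSE)))
}
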