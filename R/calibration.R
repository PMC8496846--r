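#' Latin hypercube sample of the unknown-parameter space
#'
#' Each parameter's range is divided into `n_strata` equal-width strata and
#' each stratum is sampled exactly once (per-parameter stratum occupancy is a
#' permutation). The default design follows the calibration procedure:
#' 100 strata over the 21 unknown parameters.
#'
#' @param ranges Either a data.frame with columns `name`, `low`, `high`
#'   (e.g. [parameter_ranges()]) or a named list of `c(low, high)` pairs.
#' @param n_strata Number of strata / parameter combinations (default 100).
#' @param seed Integer seed.
#' @return An object of class `t1d_lhs`: list with `samples` (an
#'   `n_strata` x k data.frame of parameter values), `ranges`, `n_strata`,
#'   `seed`.
#' @export
lhs_sample <- function(ranges, n_strata = 100, seed = 1L) {
  rng <- as_range_table(ranges)
  if (any(rng$low >= rng$high))
    stop("degenerate range for parameter(s): ",
         paste(rng$name[rng$low >= rng$high], collapse = ", "))
  if (n_strata < 1) stop("n_strata must be >= 1")
  set.seed(as.integer(seed))
  u <- lhs::randomLHS(n_strata, nrow(rng))
  samples <- as.data.frame(
    sweep(sweep(u, 2, rng$high - rng$low, "*"), 2, rng$low, "+"))
  names(samples) <- rng$name
  structure(list(samples = samples, ranges = rng,
                 n_strata = as.integer(n_strata), seed = as.integer(seed)),
            class = "t1d_lhs")
}

as_range_table <- function(ranges) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("name", "low", "high") %in% names(ranges)))
    return(ranges[, c("name", "low", "high")])
  }
  data.frame(name = names(ranges),
             low = vapply(ranges, `[`, numeric(1), 1),
             high = vapply(ranges, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

#' Weekly infiltrating-CD8 counts from a trajectory
#'
#' The value at week w is the infiltrating-CD8 count at that week's tick
#' (w x 168 hours), matching the weekly sampling of the validation data
#' (weeks 4, 6, 8, 10, 12, 14 by default elsewhere in the package).
#'
#' @param traj A `t1d_trajectory`.
#' @param weeks Integer vector of weeks.
#' @return Named numeric vector of counts, one per requested week.
#' @export
weekly_means <- function(traj, weeks) {
  stopifnot(inherits(traj, "t1d_trajectory"))
  ticks <- weeks * 168
  if (any(ticks > max(traj$counts$tick)))
    stop("trajectory does not cover requested week(s): ",
         paste(weeks[ticks > max(traj$counts$tick)], collapse = ", "))
  stats::setNames(traj$counts$n_infiltrating_cd8[ticks + 1],
                  paste0("week", weeks))
}

#' Discrepancy and R-squared between simulated and observed weekly means
#'
#' Discrepancy is the (optionally SEM-weighted) sum of squared differences;
#' R-squared is computed about the data mean: `1 - SS_res / SS_tot`.
#'
#' @param sim_means,data_means Equal-length numeric vectors (length >= 2).
#' @param sem Optional per-week SEM; when given, squared differences are
#'   weighted by `1/sem^2`.
#' @return List with `discrepancy` and `r2`. Zero-variance data give
#'   `r2 = NA` with a warning.
#' @export
fit_score <- function(sim_means, data_means, sem = NULL) {
  if (length(sim_means) != length(data_means) || length(sim_means) < 2)
    stop("sim_means and data_means must have equal length >= 2")
  d2 <- (sim_means - data_means)^2
  w <- if (is.null(sem)) rep(1, length(d2)) else 1 / sem^2
  ss_res <- sum(d2)
  ss_tot <- sum((data_means - mean(data_means))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance data: R-squared undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  list(discrepancy = sum(w * d2), r2 = r2)
}

#' Select default parameter values by fit to weekly CD8 data
#'
#' Runs `n_reps` replicate simulations per candidate parameter set, averages
#' the infiltrating-CD8 counts at the requested weeks, scores each candidate
#' by its discrepancy to the data means, and returns the best candidate
#' together with the full leaderboard.
#'
#' @param candidates A `t1d_lhs` design or a data.frame whose columns are a
#'   subset of the unknown-parameter names (one candidate per row).
#' @param config Base [t1d_config()]; candidate values overwrite its params.
#' @param data_means Observed weekly means (same order as `weeks`).
#' @param weeks Weeks at which the data were measured.
#' @param n_reps Replicate runs per candidate (default 20).
#' @param seed Integer seed; replicate run seeds are derived from it.
#' @param sem Optional SEM weights passed to [fit_score()].
#' @return List with `best` (named list of winning parameter values),
#'   `best_config`, and `leaderboard` (a data.frame: candidate index,
#'   parameter values, discrepancy, r2, ranked best first).
#' @export
select_default <- function(candidates, config, data_means,
                           weeks = c(4, 6, 8, 10, 12, 14),
                           n_reps = 20, seed = 1L, sem = NULL) {
  cand <- if (inherits(candidates, "t1d_lhs")) candidates$samples else candidates
  stopifnot(is.data.frame(cand), nrow(cand) >= 1)
  horizon <- max(weeks)
  n_cand <- nrow(cand)
  disc <- r2 <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    cfg <- config
    for (nm in names(cand)) cfg$params[[nm]] <- cand[i, nm]
    sims <- matrix(0, n_reps, length(weeks))
    for (r in seq_len(n_reps)) {
      traj <- run_simulation(cfg, seed = seed * 10000L + i * 100L + r,
                             horizon_weeks = horizon, stop_at_onset = FALSE)
      sims[r, ] <- weekly_means(traj, weeks)
    }
    sc <- fit_score(colMeans(sims), data_means, sem = sem)
    disc[i] <- sc$discrepancy; r2[i] <- sc$r2
  }
  lb <- cbind(data.frame(candidate = seq_len(n_cand)), cand,
              data.frame(discrepancy = disc, r2 = r2))
  lb <- lb[order(lb$discrepancy), ]
  best_row <- lb$candidate[1]
  best <- as.list(cand[best_row, , drop = FALSE])
  best_config <- config
  for (nm in names(best)) best_config$params[[nm]] <- best[[nm]]
  list(best = best, best_config = best_config, leaderboard = lb)
}
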