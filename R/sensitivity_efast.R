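#' eFAST search curve
#'
#' Encodes a factor on the unit interval along the scalar search variable s:
#' `q = 1/2 + (1/pi) * arcsin(sin(omega * s + phase))`.
#'
#' @param omega Integer driving frequency (>= 1).
#' @param s Search variable, in radians.
#' @param phase Optional phase shift (resampling curve), default 0.
#' @return Values in `[0, 1]`.
#' @export
search_curve <- function(omega, s, phase = 0) {
  if (omega < 1) stop("omega must be >= 1")
  0.5 + asin(sin(omega * s + phase)) / pi
}

#' Frequency assignment for an eFAST design
#'
#' The driven factor receives the maximum frequency
#' `omega_max = floor((n - 1) / (2 m))`; the complementary factors receive
#' integer frequencies at most `max(1, floor(omega_max / (2 m)))`, assigned
#' by cycling 1, 2, ..., so that every harmonic `p * omega_c` with
#' `p <= m` stays below `omega_max` (no aliasing into the driver's band).
#' With n = 200 samples and interference factor m = 4 the driving frequency
#' is 24 and complementary frequencies are at most 3. In a full analysis the
#' assignment is rotated so each factor is driven once.
#'
#' @param n Samples per search curve.
#' @param m Interference factor (default 4).
#' @param N_l Number of factors.
#' @return List with `driver` (the maximum frequency), `complementary`
#'   (frequencies for the other `N_l - 1` factors), and `m`, `n`.
#' @examples
#' select_frequencies(200, 4, 5)$driver  # 24
#' @export
select_frequencies <- function(n, m = 4, N_l = 5) {
  if (n <= 4 * m) stop("n must exceed 4 * m")
  driver <- as.integer(floor((n - 1) / (2 * m)))
  if (driver < 1) stop("n too small for interference factor m")
  comp_max <- max(1L, as.integer(floor(driver / (2 * m))))
  complementary <- if (N_l > 1)
    rep(seq_len(comp_max), length.out = N_l - 1) else integer(0)
  # aliasing guard: all harmonics p * omega_c (p <= m) stay below the driver
  stopifnot(all(complementary * m < driver) || driver == 1)
  list(driver = driver, complementary = complementary, m = m, n = n)
}

#' Inverse-CDF transform of a unit factor
#'
#' Maps a search-curve value `q` in `[0, 1]` to a factor value through the
#' quantile function of the factor's distribution.
#'
#' @param q Values in `[0, 1]`.
#' @param spec Distribution spec: `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "normal", mean=, sd=)`.
#' @return Factor values.
#' @examples
#' quantile_transform(0.5, list(dist = "normal", mean = 100, sd = 20))  # 100
#' @export
quantile_transform <- function(q, spec) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  qc <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  switch(spec$dist,
         uniform = stats::qunif(q, spec$min, spec$max),
         normal = stats::qnorm(qc, spec$mean, spec$sd),
         stop("unsupported distribution: ", spec$dist))
}

#' eFAST variance decomposition of one driven rotation
#'
#' Fourier analysis of the model output along the search variable: with
#' `A_j` and `B_j` the discrete cosine/sine coefficients and
#' `Lambda_j = A_j^2 + B_j^2`, the driven factor's variance share is
#' `D_i = 2 * sum(Lambda at harmonics p*omega, p = 1..m)`, total variance is
#' `D = 2 * sum(Lambda_j, j = 1..(n-1)/2)`, and the total-order term is the
#' total minus the complementary low-frequency band:
#' `D_T = D - 2 * sum(Lambda_j, j <= omega/2)`. First- and total-order
#' indices are `S_i = D_i / D` and `S_T = D_T / D`.
#'
#' @param y Model outputs along the s grid (length n).
#' @param omega Driving frequency of the analysed factor.
#' @param m Interference factor.
#' @return List with `S_i`, `S_T`, `D_i`, `D_T`, `D`, `lambda`, and
#'   `zero_variance` (TRUE when the output is constant; indices then 0).
#' @export
efast_indices <- function(y, omega, m = 4) {
  n <- length(y)
  s <- pi * (2 * seq_len(n) - n - 1) / n
  jmax <- floor((n - 1) / 2)
  j <- seq_len(jmax)
  A <- vapply(j, function(jj) mean(y * cos(jj * s)), numeric(1))
  B <- vapply(j, function(jj) mean(y * sin(jj * s)), numeric(1))
  lambda <- A^2 + B^2
  D <- 2 * sum(lambda)
  if (D < 1e-12 * max(1, mean(y)^2)) {
    return(list(S_i = 0, S_T = 0, D_i = 0, D_T = 0, D = 0,
                lambda = lambda, zero_variance = TRUE))
  }
  harm <- (seq_len(m)) * omega
  harm <- harm[harm <= jmax]
  D_i <- 2 * sum(lambda[harm])
  low <- seq_len(max(0, floor(omega / 2)))
  D_T <- D - 2 * sum(lambda[low])
  list(S_i = D_i / D, S_T = D_T / D, D_i = D_i, D_T = D_T, D = D,
       lambda = lambda, zero_variance = FALSE)
}

#' Build an eFAST sample design
#'
#' For each rotation (each factor driven once at the maximum frequency,
#' the others at low complementary frequencies), evaluates the search
#' curves on the n-point s grid and transforms them through each factor's
#' quantile function.
#'
#' @param factors Named list of distribution specs (see
#'   [quantile_transform()]).
#' @param n Samples per curve (default 200).
#' @param m Interference factor (default 4).
#' @param phases Optional per-factor phase shifts. By default, within each
#'   rotation the factors that share a complementary frequency receive
#'   quarter-period offsets (0, pi/2, ...): the triangle-wave search curves
#'   of two factors at the same frequency are exactly decorrelated by a
#'   quarter-period lag, keeping the factors independent along the curve
#'   (frequency repeats are unavoidable when there are more complementary
#'   factors than allowed frequencies; with three or more factors on one
#'   frequency some residual correlation remains).
#' @return Object of class `t1d_efast_design`: list with `X` (list of
#'   n x N_l value matrices, one per rotation), `Q` (unit-interval
#'   matrices), `omegas` (per-rotation frequency vectors), `factors`, `n`,
#'   `m`, `s`.
#' @export
efast_design <- function(factors, n = 200, m = 4, phases = NULL) {
  k <- length(factors)
  fr <- select_frequencies(n, m, k)
  s <- pi * (2 * seq_len(n) - n - 1) / n
  X <- Q <- vector("list", k)
  omegas <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    om <- integer(k)
    om[i] <- fr$driver
    om[-i] <- fr$complementary
    omegas[i, ] <- om
    ph <- if (is.null(phases)) {
      # quarter-period offsets among factors sharing a frequency
      vapply(seq_len(k),
             function(jj) (sum(om[seq_len(jj)] == om[jj]) - 1) * pi / 2,
             numeric(1))
    } else phases
    q <- vapply(seq_len(k),
                function(jj) search_curve(om[jj], s, ph[jj]), numeric(n))
    x <- vapply(seq_len(k),
                function(jj) quantile_transform(q[, jj], factors[[jj]]),
                numeric(n))
    colnames(q) <- colnames(x) <- names(factors)
    Q[[i]] <- q; X[[i]] <- x
  }
  structure(list(X = X, Q = Q, omegas = omegas, factors = factors,
                 n = n, m = m, s = s, driver = fr$driver),
            class = "t1d_efast_design")
}

#' eFAST indices of an arbitrary model function
#'
#' Convenience wrapper: evaluates `f` row-wise on each rotation of the
#' design and computes the driven factor's first- and total-order indices.
#'
#' @param f Function taking a named numeric vector of factor values and
#'   returning a scalar output.
#' @param design A [efast_design()].
#' @return data.frame with columns `factor`, `S_i`, `S_T`.
#' @export
efast_run <- function(f, design) {
  k <- length(design$factors)
  out <- data.frame(factor = names(design$factors),
                    S_i = numeric(k), S_T = numeric(k))
  for (i in seq_len(k)) {
    y <- apply(design$X[[i]], 1, f)
    idx <- efast_indices(y, design$omegas[i, i], design$m)
    out$S_i[i] <- idx$S_i; out$S_T[i] <- idx$S_T
  }
  out
}

#' eFAST campaign over the simulator
#'
#' Runs the agent-based simulator at every design point of every rotation,
#' recording the week of overt T1D (censored runs enter as the censoring
#' value), and computes per-factor first- and total-order indices. In
#' `mode = "reduced"` only runs with T1D occurrence are kept and the
#' filtered output series is re-indexed on its own equispaced s grid before
#' the Fourier analysis (the equi-spacing of the original grid is broken by
#' the filtering; indices in this mode are approximate).
#'
#' @param config Base [t1d_config()] holding calibrated defaults for the
#'   parameters not varied.
#' @param factors Named list of distribution specs over the varied
#'   parameters (names must be unknown-parameter names).
#' @param n Samples per curve.
#' @param m Interference factor.
#' @param mode `"full"` or `"reduced"`.
#' @param seed Integer seed (one simulation per design point).
#' @return data.frame with `factor`, `S_i`, `S_T`, `mode`, `n_used`.
#' @export
efast_campaign <- function(config, factors, n = 200, m = 4,
                           mode = c("full", "reduced"), seed = 1L) {
  mode <- match.arg(mode)
  design <- efast_design(factors, n = n, m = m)
  k <- length(factors)
  out <- data.frame(factor = names(factors), S_i = numeric(k),
                    S_T = numeric(k), mode = mode, n_used = 0L)
  for (i in seq_len(k)) {
    X <- design$X[[i]]
    onset <- censored <- numeric(n)
    for (r in seq_len(n)) {
      cfg <- config
      for (nm in colnames(X)) cfg$params[[nm]] <- max(0, X[r, nm])
      traj <- run_simulation(cfg, seed = seed * 100000L + i * 1000L + r)
      onset[r] <- traj$onset_week
      censored[r] <- traj$censored
    }
    if (mode == "reduced") {
      keep <- !censored
      if (!any(keep)) stop("reduced mode: no T1D occurrences in rotation ", i)
      y <- onset[keep]
    } else y <- onset
    idx <- efast_indices(y, design$omegas[i, i], m)
    out$S_i[i] <- idx$S_i; out$S_T[i] <- idx$S_T; out$n_used[i] <- length(y)
  }
  out
}
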