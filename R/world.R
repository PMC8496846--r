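# Region codes used throughout the engine.
REGION_ISLET <- 1L
REGION_CIRC  <- 2L
REGION_PLN   <- 3L

# Beta-cell status codes.
BETA_HEALTHY   <- 0L
BETA_APOPTOTIC <- 1L
BETA_DEAD      <- 2L

#' Physical patch length
#'
#' The grid is scaled so an islet of the configured diameter spans one islet
#' radius on each side of its centre: patch length = diameter / (2 * radius).
#' With the default 100 um islet diameter and 38-patch radius each patch is
#' 1.32 um long.
#'
#' @param islet_diameter_um Islet diameter in micrometres.
#' @param islet_radius_cells Islet radius in patches.
#' @return Patch length in micrometres per patch, rounded to 2 decimals.
#' @examples
#' grid_scale(100, 38)  # 1.32
#' @export
grid_scale <- function(islet_diameter_um, islet_radius_cells) {
  if (!is.numeric(islet_diameter_um) || islet_diameter_um <= 0 ||
      !is.numeric(islet_radius_cells) || islet_radius_cells <= 0)
    stop("grid_scale() requires positive diameter and radius")
  round(islet_diameter_um / (2 * islet_radius_cells), 2)
}

# Partition the grid into islet / circulation / PLN bands. Rows are indexed
# bottom-to-top; the bottom (1 - top_frac) of rows is the islet band, the top
# band splits into PLN (left pln_col_frac of columns) and circulation.
region_map <- function(cfg) {
  gw <- cfg$grid_width; gh <- cfg$grid_height
  reg <- matrix(REGION_ISLET, nrow = gw, ncol = gh)
  y_top <- floor((1 - cfg$region_layout$top_frac) * gh)
  if (y_top < gh) {
    x_pln <- floor(cfg$region_layout$pln_col_frac * gw)
    reg[, (y_top + 1):gh] <- REGION_CIRC
    if (x_pln >= 1) reg[1:x_pln, (y_top + 1):gh] <- REGION_PLN
  }
  reg
}

# Empty agent pools; each pool is a numeric matrix with named columns.
empty_agents <- function() {
  mk <- function(cols) matrix(numeric(0), nrow = 0, ncol = length(cols),
                              dimnames = list(NULL, cols))
  list(
    ag  = mk(c("x", "y", "age", "life")),
    dc  = mk(c("x", "y", "age", "life", "mvt", "eng")),
    apc = mk(c("id", "x", "y", "phase", "age", "life", "mig", "nb")),
    nv  = mk(c("x", "y", "age", "life", "stage", "timer", "apc", "sites")),
    tc  = mk(c("x", "y", "phase", "cyc_t", "cycles", "egress", "transit")),
    ctl = mk(c("x", "y", "age", "life", "pt"))
  )
}

runifr <- function(n, range) stats::runif(n, range[1], range[2])

#' Construct the simulation world
#'
#' Partitions the grid into islet, circulation, and PLN regions, picks
#' `n_islets` random islet centres inside the islet band, and furnishes the
#' islet disks (radius `islet_radius`, disks may overlap and form clusters)
#' with exactly `n_beta_cells` beta-cell patches sampled uniformly without
#' replacement from the union of the disks. `init_apoptotic_beta` of them are
#' re-labelled apoptotic and release autoantigens; resident DCs and the naive
#' CD8+ T-cell pool are placed; per-run draws (onset threshold, DC
#' recruitment rate k_r, CTL proliferation fraction) are made.
#'
#' Rebuilding with the same seed yields an identical world.
#'
#' @param config A [t1d_config()].
#' @param rng_seed Integer seed for all construction randomness.
#' @return An object of class `t1d_world`.
#' @export
build_world <- function(config, rng_seed = config$seed) {
  validate_config(config)
  set.seed(as.integer(rng_seed))
  p <- config$params; cons <- config$constants
  gw <- config$grid_width; gh <- config$grid_height
  reg <- region_map(config)

  islet_cells <- which(reg == REGION_ISLET)
  pln_cells   <- which(reg == REGION_PLN)
  circ_cells  <- which(reg == REGION_CIRC)

  n_beta <- config$n_beta_cells
  centers <- matrix(integer(0), 0, 2)
  beta_cells <- integer(0)
  if (config$n_islets > 0) {
    ctr_idx <- sample(islet_cells, config$n_islets,
                      replace = config$n_islets > length(islet_cells))
    centers <- cbind(((ctr_idx - 1L) %% gw) + 1L, ((ctr_idx - 1L) %/% gw) + 1L)
    r <- config$islet_radius
    off <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    xs <- rep(centers[, 1], each = nrow(off)) + off$dx
    ys <- rep(centers[, 2], each = nrow(off)) + off$dy
    ok <- xs >= 1 & xs <= gw & ys >= 1 & ys <= gh
    idx <- unique(xs[ok] + (ys[ok] - 1L) * gw)
    idx <- idx[reg[idx] == REGION_ISLET]
    if (n_beta > length(idx))
      stop("requested ", n_beta, " beta cells but only ", length(idx),
           " patches are available inside the islet disks")
    beta_cells <- if (n_beta > 0) sample(idx, n_beta) else integer(0)
  } else if (n_beta > 0) {
    stop("requested ", n_beta, " beta cells but no islets configured")
  }

  bx <- ((beta_cells - 1L) %% gw) + 1L
  by <- ((beta_cells - 1L) %/% gw) + 1L
  bstatus <- rep(BETA_HEALTHY, n_beta)
  n_ap0 <- min(round(p$init_apoptotic_beta), n_beta)
  if (n_ap0 > 0) bstatus[sample.int(n_beta, n_ap0)] <- BETA_APOPTOTIC

  occ <- matrix(0L, gw, gh)
  occ[beta_cells] <- seq_len(n_beta)

  ag_count <- matrix(0L, gw, gh)
  agents <- empty_agents()

  # Autoantigen release from the initially apoptotic cells.
  ap_idx <- which(bstatus == BETA_APOPTOTIC)
  k <- max(1L, round(p$antigen_per_apoptosis))
  if (length(ap_idx) > 0) {
    ax <- rep(bx[ap_idx], each = k); ay <- rep(by[ap_idx], each = k)
    n_ag <- length(ax)
    agents$ag <- cbind(x = ax, y = ay, age = 0,
                       life = rep(p$antigen_lifespan_h, n_ag))
    tb <- table(ax + (ay - 1L) * gw)
    ag_count[as.integer(names(tb))] <- as.integer(tb)
  }

  # Resident DCs live inside the islets proper (on/near beta-cell patches).
  n_dc <- round(p$n_resident_dc)
  if (n_dc > 0 && length(islet_cells) > 0) {
    home <- if (length(beta_cells) > 0) beta_cells else islet_cells
    idx <- sample(home, n_dc, replace = n_dc > length(home))
    agents$dc <- cbind(x = ((idx - 1L) %% gw) + 1L,
                       y = ((idx - 1L) %/% gw) + 1L,
                       age = 0, life = rep(p$dc_islet_lifespan_h, n_dc),
                       mvt = sample.int(max(1L, round(p$dc_move_interval_h)),
                                        n_dc, replace = TRUE),
                       eng = rep(0, n_dc))
  }

  # Naive CD8+ T-cell pool in the PLN.
  n_nv <- round(p$n_naive_pool)
  if (n_nv > 0 && length(pln_cells) > 0) {
    idx <- sample(pln_cells, n_nv, replace = n_nv > length(pln_cells))
    agents$nv <- cbind(x = ((idx - 1L) %% gw) + 1L,
                       y = ((idx - 1L) %/% gw) + 1L,
                       age = 0, life = runifr(n_nv, cons$naive_lifespan_h),
                       stage = rep(0, n_nv), timer = rep(0, n_nv),
                       apc = rep(0, n_nv),
                       sites = rep(round(p$naive_binding_sites), n_nv))
  }

  world <- list(
    cfg = config,
    region = reg,
    islet_centers = centers,
    islet_cells = islet_cells,
    pln_cells = pln_cells,
    circ_cells = circ_cells,
    bx = bx, by = by, bstatus = bstatus,
    q_el = floor(stats::runif(n_beta, 0, cons$quiescence_T0_h)),
    q_base = rep(cons$quiescence_T0_h, n_beta),
    rep_t = rep(0, n_beta),
    ap_el = rep(0, n_beta),
    occ = occ,
    ag_count = ag_count,
    agents = agents,
    k_r = max(0, stats::rnorm(1, p$dc_recruit_mu, p$dc_recruit_sigma)),
    prolif_fraction = runifr(1, cons$ctl_prolif_fraction),
    onset_threshold_frac = stats::runif(1, config$onset_fraction_low,
                                        config$onset_fraction_high),
    beta_init = sum(bstatus == BETA_HEALTHY),
    births = 0L,
    apc_next_id = 1,
    clock_h = 0L,
    seed = as.integer(rng_seed)
  )
  class(world) <- "t1d_world"
  world
}

#' @export
print.t1d_world <- function(x, ...) {
  cat("t1d_world at t =", x$clock_h, "h:",
      sum(x$bstatus == BETA_HEALTHY), "healthy /",
      sum(x$bstatus == BETA_APOPTOTIC), "apoptotic /",
      sum(x$bstatus == BETA_DEAD), "dead beta cells;",
      nrow(x$agents$ctl), "CTLs,", nrow(x$agents$dc), "islet DCs\n")
  invisible(x)
}

#' Count mobile agents by class
#'
#' @param world A `t1d_world`.
#' @return Named integer vector of pool sizes.
#' @export
agent_counts <- function(world) {
  vapply(world$agents, nrow, integer(1))
}

#' Write a world snapshot as JSON
#'
#' The region map is run-length encoded; beta-cell state and mobile agent
#' pools are stored as plain arrays.
#'
#' @param world A `t1d_world`.
#' @param path Output file.
#' @export
write_world <- function(world, path) {
  rle_reg <- rle(as.integer(world$region))
  snap <- list(
    clock_h = world$clock_h,
    seed = world$seed,
    grid = c(world$cfg$grid_width, world$cfg$grid_height),
    region_rle = list(lengths = rle_reg$lengths, values = rle_reg$values),
    onset_threshold_frac = world$onset_threshold_frac,
    k_r = world$k_r,
    beta = list(x = world$bx, y = world$by, status = world$bstatus),
    agents = lapply(world$agents, function(m) as.data.frame(m))
  )
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
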