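# Moore neighbourhood offsets (centre patch included where noted).
OFF9_X <- c(0L, -1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
OFF9_Y <- c(0L, -1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)

# The engine mutates an environment holding the world state; step() and
# run_simulation() wrap this. All randomness flows through the R RNG, seeded
# once per run, so identical (config, seed) gives identical trajectories.

world_to_env <- function(world) {
  E <- new.env(parent = emptyenv())
  for (nm in names(world)) assign(nm, world[[nm]], envir = E)
  E$gw <- world$cfg$grid_width; E$gh <- world$cfg$grid_height
  E$p <- world$cfg$params; E$cons <- world$cfg$constants
  E$nv_acc <- 0
  # effective (therapy-adjustable) parameters
  E$eff_ctl_lifespan <- E$p$ctl_lifespan_h
  E$eff_k_r <- world$k_r
  E$eff_max_naive_binding <- E$p$max_naive_binding
  E$tick_births <- 0L
  E
}

env_to_world <- function(E) {
  w <- mget(c("cfg", "region", "islet_centers", "islet_cells", "pln_cells",
              "circ_cells", "bx", "by", "bstatus", "q_el", "q_base", "rep_t",
              "ap_el", "occ", "ag_count", "agents", "k_r", "prolif_fraction",
              "onset_threshold_frac", "beta_init", "births", "apc_next_id",
              "clock_h", "seed"), envir = E)
  class(w) <- "t1d_world"
  w
}

# Random Moore step constrained to a region; agents that would leave the
# region or the grid stay put.
moore_step <- function(x, y, E, regcode) {
  n <- length(x)
  if (n == 0) return(list(x = x, y = y))
  nx <- x + sample(c(-1L, 0L, 1L), n, replace = TRUE)
  ny <- y + sample(c(-1L, 0L, 1L), n, replace = TRUE)
  ok <- nx >= 1 & nx <= E$gw & ny >= 1 & ny <= E$gh
  ok[ok] <- E$region[nx[ok] + (ny[ok] - 1L) * E$gw] == regcode
  x[ok] <- nx[ok]; y[ok] <- ny[ok]
  list(x = x, y = y)
}

# Neighbourhood lookup: for agent positions return an n x 9 matrix of a
# per-patch integer field (0 outside the grid).
lookup9 <- function(x, y, field, E) {
  n <- length(x)
  out <- matrix(0L, n, 9)
  for (j in 1:9) {
    nx <- x + OFF9_X[j]; ny <- y + OFF9_Y[j]
    ok <- which(nx >= 1 & nx <= E$gw & ny >= 1 & ny <= E$gh)
    if (length(ok)) out[ok, j] <- field[nx[ok] + (ny[ok] - 1L) * E$gw]
  }
  out
}

add_count <- function(m, idx, E) {
  if (length(idx) == 0) return(m)
  tb <- tabulate(idx, nbins = E$gw * E$gh)
  hit <- which(tb > 0L)
  m[hit] <- m[hit] + tb[hit]
  m
}

spawn_antigens <- function(E, beta_idx) {
  if (length(beta_idx) == 0) return(invisible())
  k <- max(1L, round(E$p$antigen_per_apoptosis))
  ax <- rep(E$bx[beta_idx], each = k); ay <- rep(E$by[beta_idx], each = k)
  E$agents$ag <- rbind(E$agents$ag,
                       cbind(x = ax, y = ay, age = 0,
                             life = rep(E$p$antigen_lifespan_h, length(ax))))
  E$ag_count <- add_count(E$ag_count, ax + (ay - 1L) * E$gw, E)
  invisible()
}

tick_env <- function(E) {
  p <- E$p; cons <- E$cons; gw <- E$gw
  E$tick_births <- 0L

  ## (2) DC movement within islets and antigen engulfment
  dc <- E$agents$dc
  if (nrow(dc) > 0) {
    dc[, "mvt"] <- dc[, "mvt"] - 1
    mv <- which(dc[, "mvt"] <= 0)
    if (length(mv)) {
      st <- moore_step(dc[mv, "x"], dc[mv, "y"], E, REGION_ISLET)
      dc[mv, "x"] <- st$x; dc[mv, "y"] <- st$y
      dc[mv, "mvt"] <- max(1, round(p$dc_move_interval_h))
    }
    ag <- E$agents$ag
    if (nrow(ag) > 0) {
      # phagocytosis reaches the Moore neighbourhood of the DC
      agk <- ag[, "x"] + (ag[, "y"] - 1L) * gw
      ndc <- nrow(dc)
      dck9 <- numeric(ndc * 9)
      for (j in 1:9) {
        nx <- dc[, "x"] + OFF9_X[j]; ny <- dc[, "y"] + OFF9_Y[j]
        key <- nx + (ny - 1L) * gw
        key[nx < 1 | nx > gw | ny < 1 | ny > E$gh] <- NA
        dck9[(j - 1L) * ndc + seq_len(ndc)] <- key
      }
      hit <- match(agk, dck9)
      eaten <- which(!is.na(hit))
      if (length(eaten)) {
        dcidx <- ((hit[eaten] - 1L) %% ndc) + 1L
        cnt <- tabulate(dcidx, nbins = ndc)
        dc[, "eng"] <- dc[, "eng"] + cnt
        tb <- tabulate(agk[eaten], nbins = gw * E$gh)
        nz <- which(tb > 0L)
        E$ag_count[nz] <- E$ag_count[nz] - tb[nz]
        E$agents$ag <- ag[-eaten, , drop = FALSE]
      }
    }
    # DCs that engulfed enough antigen become APCs and schedule migration
    ripe <- which(dc[, "eng"] >= max(1, round(p$dc_migration_trigger)))
    if (length(ripe)) {
      n <- length(ripe)
      ids <- E$apc_next_id + seq_len(n) - 1
      E$apc_next_id <- E$apc_next_id + n
      E$agents$apc <- rbind(E$agents$apc,
        cbind(id = ids, x = dc[ripe, "x"], y = dc[ripe, "y"], phase = 1,
              age = 0, life = Inf,
              mig = runifr(n, cons$dc_islet_to_pln_h), nb = 0))
      dc <- dc[-ripe, , drop = FALSE]
    }
    E$agents$dc <- dc
  }

  ## (3) APC migration islet -> PLN
  apc <- E$agents$apc
  if (nrow(apc) > 0) {
    ph1 <- which(apc[, "phase"] == 1)
    if (length(ph1)) {
      apc[ph1, "mig"] <- apc[ph1, "mig"] - 1
      arr <- ph1[apc[ph1, "mig"] <= 0]
      if (length(arr) && length(E$pln_cells)) {
        idx <- sample(E$pln_cells, length(arr),
                      replace = length(arr) > length(E$pln_cells))
        apc[arr, "x"] <- ((idx - 1L) %% gw) + 1L
        apc[arr, "y"] <- ((idx - 1L) %/% gw) + 1L
        apc[arr, "phase"] <- 2
        apc[arr, "age"] <- 0
        apc[arr, "life"] <- runifr(length(arr), cons$apc_lifespan_h)
        apc[arr, "mig"] <- max(1, round(p$apc_move_interval_h))
      }
    }
    E$agents$apc <- apc
  }

  ## (4) PLN: contact progression, movement, new bindings
  nv <- E$agents$nv
  apc <- E$agents$apc
  if (nrow(nv) > 0) {
    s1 <- which(nv[, "stage"] == 1)
    if (length(s1)) {
      nv[s1, "timer"] <- nv[s1, "timer"] - 1
      adv <- s1[nv[s1, "timer"] <= 0]
      if (length(adv)) {
        nv[adv, "stage"] <- 2
        nv[adv, "timer"] <- runifr(length(adv), cons$naive_activation_h)
      }
    }
    s2 <- which(nv[, "stage"] == 2)
    act <- integer(0)
    if (length(s2)) {
      nv[s2, "timer"] <- nv[s2, "timer"] - 1
      act <- s2[nv[s2, "timer"] <= 0]
    }
    if (length(act)) {
      # activation: naive cell becomes an activated CD8+ T cell in the PLN
      n <- length(act)
      E$agents$tc <- rbind(E$agents$tc,
        cbind(x = nv[act, "x"], y = nv[act, "y"], phase = 1,
              cyc_t = runifr(n, cons$naive_diff_cycle_h), cycles = 0,
              egress = runifr(n, cons$pln_residence_h), transit = 0))
      if (nrow(apc) > 0) {
        rel <- match(nv[act, "apc"], apc[, "id"])
        rel <- rel[!is.na(rel)]
        if (length(rel)) {
          cnt <- tabulate(rel, nbins = nrow(apc))
          apc[, "nb"] <- pmax(0, apc[, "nb"] - cnt)
        }
      }
      nv <- nv[-act, , drop = FALSE]
    }
    free <- which(nv[, "stage"] == 0)
    if (length(free)) {
      st <- moore_step(nv[free, "x"], nv[free, "y"], E, REGION_PLN)
      nv[free, "x"] <- st$x; nv[free, "y"] <- st$y
    }
  }
  if (nrow(apc) > 0) {
    ph2 <- which(apc[, "phase"] == 2)
    if (length(ph2)) {
      unb <- ph2[apc[ph2, "nb"] == 0]
      if (length(unb)) {
        apc[unb, "mig"] <- apc[unb, "mig"] - 1
        mv <- unb[apc[unb, "mig"] <= 0]
        if (length(mv)) {
          st <- moore_step(apc[mv, "x"], apc[mv, "y"], E, REGION_PLN)
          apc[mv, "x"] <- st$x; apc[mv, "y"] <- st$y
          apc[mv, "mig"] <- max(1, round(p$apc_move_interval_h))
        }
      }
      # new short-span contacts: APCs probe the surrounding eight patches
      cap <- E$eff_max_naive_binding
      cand_apc <- ph2[apc[ph2, "nb"] < cap]
      if (length(cand_apc) && nrow(nv) > 0) {
        avail <- nv[, "stage"] == 0 & nv[, "sites"] > 0
        if (any(avail)) {
          nvk <- nv[, "x"] + (nv[, "y"] - 1L) * gw
          for (i in cand_apc) {
            if (!any(avail)) break
            spare <- floor(cap - apc[i, "nb"])
            if (spare <= 0) next
            keys <- (apc[i, "x"] + OFF9_X) + (apc[i, "y"] + OFF9_Y - 1L) * gw
            hits <- which(avail & nvk %in% keys)
            if (!length(hits)) next
            take <- hits[seq_len(min(spare, length(hits)))]
            nv[take, "stage"] <- 1
            nv[take, "timer"] <- runifr(length(take), cons$apc_short_contact_h)
            nv[take, "apc"] <- apc[i, "id"]
            nv[take, "sites"] <- nv[take, "sites"] - 1
            apc[i, "nb"] <- apc[i, "nb"] + length(take)
            avail[take] <- FALSE
          }
        }
      }
    }
  }
  E$agents$nv <- nv
  E$agents$apc <- apc

  ## (5) activated CD8+ T cells: differentiation, egress, transit, arrival
  tc <- E$agents$tc
  if (nrow(tc) > 0) {
    ph1 <- which(tc[, "phase"] == 1)
    if (length(ph1)) {
      tc[ph1, "cyc_t"] <- tc[ph1, "cyc_t"] - 1
      done <- ph1[tc[ph1, "cyc_t"] <= 0]
      if (length(done)) {
        tc[done, "cycles"] <- tc[done, "cycles"] + 1
        tc[done, "cyc_t"] <- runifr(length(done), cons$naive_diff_cycle_h)
      }
      tc[ph1, "egress"] <- tc[ph1, "egress"] - 1
      out <- ph1[tc[ph1, "egress"] <= 0]
      if (length(out)) {
        tc[out, "phase"] <- 2
        tc[out, "transit"] <- cons$activated_transit_h
      }
    }
    ph2 <- which(tc[, "phase"] == 2)
    if (length(ph2)) {
      tc[ph2, "transit"] <- tc[ph2, "transit"] - 1
      arr <- ph2[tc[ph2, "transit"] <= 0]
      if (length(arr) && length(E$islet_cells)) {
        idx <- sample(E$islet_cells, length(arr),
                      replace = length(arr) > length(E$islet_cells))
        tc[arr, "x"] <- ((idx - 1L) %% gw) + 1L
        tc[arr, "y"] <- ((idx - 1L) %/% gw) + 1L
        tc[arr, "phase"] <- 3
        # effector lifespan once resident in islets (reuses the transit slot)
        tc[arr, "transit"] <- E$eff_ctl_lifespan
      }
    }
    ph3 <- which(tc[, "phase"] == 3)
    if (length(ph3)) {
      st <- walk_step(tc[ph3, "x"], tc[ph3, "y"], p$ctl_step_cells, E)
      tc[ph3, "x"] <- st$x; tc[ph3, "y"] <- st$y
      # restimulation by autoantigen -> CTL; free antigen or the residual
      # deposits at sites of beta-cell destruction both stimulate
      ag9 <- lookup9(tc[ph3, "x"], tc[ph3, "y"], E$ag_count, E)
      near <- rowSums(ag9) > 0
      if (!all(near)) {
        occ9 <- lookup9(tc[ph3, "x"], tc[ph3, "y"], E$occ, E)
        dam <- occ9 > 0
        dam[dam] <- E$bstatus[occ9[dam]] != BETA_HEALTHY
        near <- near | rowSums(dam) > 0
      }
      go <- ph3[near & stats::runif(length(ph3)) < p$restim_prob]
      if (length(go)) {
        n <- length(go)
        E$agents$ctl <- rbind(E$agents$ctl,
          cbind(x = tc[go, "x"], y = tc[go, "y"], age = 0,
                life = rep(E$eff_ctl_lifespan, n), pt = 0))
        tc <- tc[-go, , drop = FALSE]
      }
      # islet-resident activated cells age out on the effector lifespan
      ph3 <- which(tc[, "phase"] == 3)
      if (length(ph3)) {
        tc[ph3, "transit"] <- tc[ph3, "transit"] - 1
        dead <- ph3[tc[ph3, "transit"] <= 0]
        if (length(dead)) tc <- tc[-dead, , drop = FALSE]
      }
    }
    E$agents$tc <- tc
  }

  ## (6) CTLs: random walk and contact killing
  ctl <- E$agents$ctl
  new_ap <- integer(0)
  if (nrow(ctl) > 0) {
    st <- walk_step(ctl[, "x"], ctl[, "y"], p$ctl_step_cells, E)
    ctl[, "x"] <- st$x; ctl[, "y"] <- st$y
    n <- nrow(ctl)
    nb9 <- lookup9(ctl[, "x"], ctl[, "y"], E$occ, E)
    healthy <- nb9 > 0
    healthy[healthy] <- E$bstatus[nb9[healthy]] == BETA_HEALTHY
    has <- rowSums(healthy) > 0
    if (any(has)) {
      w <- matrix(stats::runif(n * 9), n, 9) * healthy
      pick <- max.col(w)
      target <- nb9[cbind(seq_len(n), pick)]
      kill <- has & stats::runif(n) < p$ctl_kill_prob
      new_ap <- unique(target[kill])
    }
    E$agents$ctl <- ctl
  }
  if (length(new_ap)) {
    E$bstatus[new_ap] <- BETA_APOPTOTIC
    E$ap_el[new_ap] <- 0
    E$rep_t[new_ap] <- 0
    spawn_antigens(E, new_ap)   # (1) antigen release from apoptotic cells
  }

  ## (7) CTL proliferation: a drawn fraction divides every 120 h
  ctl <- E$agents$ctl
  if (nrow(ctl) > 0) {
    ctl[, "pt"] <- ctl[, "pt"] + 1
    due <- which(ctl[, "pt"] >= cons$ctl_prolif_interval_h)
    if (length(due)) {
      ctl[due, "pt"] <- 0
      div <- due[stats::runif(length(due)) < E$prolif_fraction]
      if (length(div)) {
        off <- sample(cons$ctl_prolif_offspring[1]:cons$ctl_prolif_offspring[2],
                      length(div), replace = TRUE)
        px <- rep(ctl[div, "x"], off); py <- rep(ctl[div, "y"], off)
        E$agents$ctl <- rbind(ctl,
          cbind(x = px, y = py, age = 0,
                life = rep(E$eff_ctl_lifespan, length(px)), pt = 0))
      } else E$agents$ctl <- ctl
    } else E$agents$ctl <- ctl
  }

  ## (8) DC recruitment from circulation (mass-action kinetics); recruited
  ## DCs extravasate at sites of insulitis (apoptotic beta-cell patches)
  ap_sites <- which(E$bstatus == BETA_APOPTOTIC)
  beta_ap <- length(ap_sites)
  n_new <- dc_recruited(E$eff_k_r, beta_ap, p$dc_c)
  if (n_new > 0 && length(E$islet_cells)) {
    idx <- if (beta_ap > 0) {
      pickb <- if (beta_ap == 1) rep(ap_sites, n_new) else
        sample(ap_sites, n_new, replace = TRUE)
      E$bx[pickb] + (E$by[pickb] - 1L) * gw
    } else
      sample(E$islet_cells, n_new, replace = n_new > length(E$islet_cells))
    E$agents$dc <- rbind(E$agents$dc,
      cbind(x = ((idx - 1L) %% gw) + 1L, y = ((idx - 1L) %/% gw) + 1L,
            age = 0, life = rep(p$dc_islet_lifespan_h, n_new),
            mvt = rep(max(1, round(p$dc_move_interval_h)), n_new),
            eng = rep(0, n_new)))
  }

  ## (9) beta-cell quiescence, replication, apoptotic -> dead
  ap_now <- which(E$bstatus == BETA_APOPTOTIC)
  if (length(ap_now)) {
    E$ap_el[ap_now] <- E$ap_el[ap_now] + 1
    # cells in programmed death keep shedding autoantigen every 12 h
    emit <- ap_now[E$ap_el[ap_now] %% 12 == 0]
    if (length(emit)) spawn_antigens(E, emit)
    gone <- ap_now[E$ap_el[ap_now] >= p$apoptotic_duration_h]
    if (length(gone)) E$bstatus[gone] <- BETA_DEAD
  }
  frac <- min(1, beta_ap / E$beta_init)
  factor <- (1 - frac)^p$gamma
  healthy_i <- which(E$bstatus == BETA_HEALTHY)
  # regeneration fills the islet niche back toward its initial capacity
  n_healthy <- length(healthy_i)
  capacity_left <- E$beta_init - n_healthy
  if (length(healthy_i)) {
    repl <- healthy_i[E$rep_t[healthy_i] > 0]
    if (length(repl)) {
      E$rep_t[repl] <- E$rep_t[repl] - 1
      born <- repl[E$rep_t[repl] <= 0]
      if (length(born) > max(0, capacity_left))
        born <- born[seq_len(max(0, capacity_left))]
      for (i in born) {
        nx <- E$bx[i] + OFF9_X[-1]; ny <- E$by[i] + OFF9_Y[-1]
        ok <- nx >= 1 & nx <= gw & ny >= 1 & ny <= E$gh
        k <- nx[ok] + (ny[ok] - 1L) * gw
        k <- k[E$region[k] == REGION_ISLET & E$occ[k] == 0L]
        E$q_el[i] <- 0
        if (length(k)) {
          pk <- if (length(k) == 1) k else sample(k, 1)
          j <- length(E$bx) + 1L
          E$bx <- c(E$bx, ((pk - 1L) %% gw) + 1L)
          E$by <- c(E$by, ((pk - 1L) %/% gw) + 1L)
          E$bstatus <- c(E$bstatus, BETA_HEALTHY)
          E$q_el <- c(E$q_el, 0)
          E$q_base <- c(E$q_base, cons$quiescence_T0_h)
          E$rep_t <- c(E$rep_t, 0)
          E$ap_el <- c(E$ap_el, 0)
          E$occ[pk] <- j
          E$tick_births <- E$tick_births + 1L
        }
      }
    }
    idle <- healthy_i[E$rep_t[healthy_i] <= 0]
    if (length(idle)) {
      E$q_el[idle] <- E$q_el[idle] + 1
      if (capacity_left > 0) {
        thr <- factor * E$q_base[idle]
        start <- idle[E$q_el[idle] >= thr]
        if (length(start)) E$rep_t[start] <- cons$beta_replication_h
      }
    }
  }
  E$births <- E$births + E$tick_births

  ## (10) ageing and lifespan bookkeeping
  ag <- E$agents$ag
  if (nrow(ag) > 0) {
    ag[, "age"] <- ag[, "age"] + 1
    dead <- which(ag[, "age"] > ag[, "life"])
    if (length(dead)) {
      dk <- ag[dead, "x"] + (ag[dead, "y"] - 1L) * gw
      tb <- tabulate(dk, nbins = gw * E$gh); nz <- which(tb > 0L)
      E$ag_count[nz] <- E$ag_count[nz] - tb[nz]
      ag <- ag[-dead, , drop = FALSE]
    }
    E$agents$ag <- ag
  }
  dc <- E$agents$dc
  if (nrow(dc) > 0) {
    dc[, "age"] <- dc[, "age"] + 1
    dead <- which(dc[, "age"] > dc[, "life"])
    if (length(dead)) dc <- dc[-dead, , drop = FALSE]
    E$agents$dc <- dc
  }
  apc <- E$agents$apc
  if (nrow(apc) > 0) {
    ph2 <- apc[, "phase"] == 2
    apc[ph2, "age"] <- apc[ph2, "age"] + 1
    dead <- which(apc[, "age"] > apc[, "life"])
    if (length(dead)) {
      dead_ids <- apc[dead, "id"]
      nv <- E$agents$nv
      if (nrow(nv) > 0) {
        held <- which(nv[, "stage"] > 0 & nv[, "apc"] %in% dead_ids)
        if (length(held)) {   # released naive cells return to the free pool
          nv[held, "stage"] <- 0; nv[held, "timer"] <- 0; nv[held, "apc"] <- 0
          E$agents$nv <- nv
        }
      }
      apc <- apc[-dead, , drop = FALSE]
    }
    E$agents$apc <- apc
  }
  nv <- E$agents$nv
  if (nrow(nv) > 0) {
    nv[, "age"] <- nv[, "age"] + 1
    dead <- which(nv[, "age"] > nv[, "life"])
    if (length(dead)) {
      apc <- E$agents$apc
      if (nrow(apc) > 0) {
        rel <- match(nv[dead, "apc"][nv[dead, "stage"] > 0], apc[, "id"])
        rel <- rel[!is.na(rel)]
        if (length(rel)) {
          cnt <- tabulate(rel, nbins = nrow(apc))
          apc[, "nb"] <- pmax(0, apc[, "nb"] - cnt)
          E$agents$apc <- apc
        }
      }
      nv <- nv[-dead, , drop = FALSE]
    }
    E$agents$nv <- nv
  }
  ctl <- E$agents$ctl
  if (nrow(ctl) > 0) {
    ctl[, "age"] <- ctl[, "age"] + 1
    dead <- which(ctl[, "age"] > ctl[, "life"])
    if (length(dead)) ctl <- ctl[-dead, , drop = FALSE]
    E$agents$ctl <- ctl
  }

  # naive pool replenishment (thymic output into the PLN)
  deficit <- round(E$p$n_naive_pool) - nrow(E$agents$nv)
  if (deficit > 0 && length(E$pln_cells)) {
    E$nv_acc <- E$nv_acc + p$naive_replenish_per_h
    k <- min(floor(E$nv_acc), deficit)
    if (k > 0) {
      E$nv_acc <- E$nv_acc - k
      idx <- sample(E$pln_cells, k, replace = k > length(E$pln_cells))
      E$agents$nv <- rbind(E$agents$nv,
        cbind(x = ((idx - 1L) %% gw) + 1L, y = ((idx - 1L) %/% gw) + 1L,
              age = 0, life = runifr(k, cons$naive_lifespan_h),
              stage = rep(0, k), timer = rep(0, k), apc = rep(0, k),
              sites = rep(round(p$naive_binding_sites), k)))
    }
  }

  E$clock_h <- E$clock_h + 1L
  invisible(E)
}

# Displacement of a fast cell (CTL or islet-resident activated cell): a
# uniform random direction with the configured effective step length in
# patches per hour, confined to the islet region.
walk_step <- function(x, y, step_cells, E) {
  n <- length(x)
  if (n == 0) return(list(x = x, y = y))
  th <- stats::runif(n, 0, 2 * pi)
  nx <- x + round(step_cells * cos(th))
  ny <- y + round(step_cells * sin(th))
  ok <- nx >= 1 & nx <= E$gw & ny >= 1 & ny <= E$gh
  ok[ok] <- E$region[nx[ok] + (ny[ok] - 1L) * E$gw] == REGION_ISLET
  x[ok] <- nx[ok]; y[ok] <- ny[ok]
  list(x = x, y = y)
}

count_state <- function(E) {
  tc <- E$agents$tc
  reg_at <- function(m) {
    if (nrow(m) == 0) return(integer(0))
    E$region[m[, "x"] + (m[, "y"] - 1L) * E$gw]
  }
  n_inf <- sum(tc[, "phase"] == 3) + nrow(E$agents$ctl)
  apc <- E$agents$apc
  c(n_healthy_beta = sum(E$bstatus == BETA_HEALTHY),
    n_apoptotic_beta = sum(E$bstatus == BETA_APOPTOTIC),
    n_dead_beta = sum(E$bstatus == BETA_DEAD),
    births = E$tick_births,
    n_infiltrating_cd8 = n_inf,
    n_dc_islet = nrow(E$agents$dc) + sum(apc[, "phase"] == 1),
    n_apc_pln = sum(apc[, "phase"] == 2))
}

#' Advance the world by one hour
#'
#' Fires all agent rules once, in order: antigen release from apoptotic beta
#' cells; DC movement/engulfment; APC migration to the PLN; APC binding and
#' naive CD8+ activation in the PLN; activated-cell differentiation, egress
#' and transit; CTL restimulation, random walk, killing and proliferation;
#' mass-action DC recruitment; beta-cell quiescence/replication; lifespan
#' bookkeeping. Uses the current global RNG stream; call `set.seed()` first
#' for a reproducible single step.
#'
#' @param world A `t1d_world`.
#' @return The advanced `t1d_world` (clock incremented by one hour).
#' @export
step <- function(world) {
  stopifnot(inherits(world, "t1d_world"))
  E <- world_to_env(world)
  tick_env(E)
  env_to_world(E)
}

#' Detect disease onset in a healthy-beta series
#'
#' Overt T1D is scored at the first hour at which the surviving healthy
#' beta-cell fraction drops to or below the per-run threshold. Onset is only
#' scored within `window_weeks` weeks; later (or absent) crossings are
#' censored and reported as `censor_weeks` weeks.
#'
#' @param healthy_series Per-hour healthy beta-cell counts, starting at hour 0.
#' @param beta_init Initial healthy beta-cell count.
#' @param threshold_frac Onset threshold as a fraction of `beta_init`.
#' @param window_weeks Scoring window (default 20 weeks).
#' @param censor_weeks Value reported for censored runs (default 32 weeks).
#' @return List with `onset_week` (numeric weeks; `censor_weeks` when
#'   censored), `onset_hour` (NA when censored), and `censored` (logical).
#' @export
detect_onset <- function(healthy_series, beta_init, threshold_frac,
                         window_weeks = 20, censor_weeks = 32) {
  if (length(healthy_series) == 0) stop("empty healthy-beta series")
  if (!(threshold_frac > 0 && threshold_frac < 1))
    stop("threshold_frac must lie in (0, 1)")
  cross <- which(healthy_series / beta_init <= threshold_frac)
  if (length(cross) == 0)
    return(list(onset_week = censor_weeks, onset_hour = NA_real_,
                censored = TRUE))
  hour <- cross[1] - 1
  week <- hour / 168
  if (week > window_weeks)
    return(list(onset_week = censor_weeks, onset_hour = NA_real_,
                censored = TRUE))
  list(onset_week = week, onset_hour = hour, censored = FALSE)
}

#' Run a full simulation
#'
#' Builds the world from `config` with `seed` and iterates the hourly rules,
#' recording per-hour population counts. The run stops at onset (unless
#' `stop_at_onset = FALSE`, used e.g. when weekly counts beyond onset are
#' needed for calibration) or at the horizon. Identical (config, seed) give
#' identical trajectories.
#'
#' @param config A [t1d_config()].
#' @param seed Integer run seed.
#' @param horizon_weeks Simulated horizon; defaults to the onset window.
#' @param stop_at_onset Stop stepping once onset is detected (default TRUE).
#' @param therapy Optional [therapy_spec()] applied during the run.
#' @return An object of class `t1d_trajectory`: a list with `counts` (a
#'   data.frame of per-hour series), `onset_week`, `onset_hour`, `censored`,
#'   `onset_threshold_frac`, `beta_init`, and `seed`.
#' @export
run_simulation <- function(config, seed, horizon_weeks = NULL,
                           stop_at_onset = TRUE, therapy = NULL) {
  validate_config(config)
  if (is.null(horizon_weeks)) horizon_weeks <- config$onset_window_weeks
  world <- build_world(config, seed)
  E <- world_to_env(world)
  n_ticks <- ceiling(horizon_weeks * 168)
  rec <- matrix(0, n_ticks + 1, 7,
                dimnames = list(NULL, c("n_healthy_beta", "n_apoptotic_beta",
                                        "n_dead_beta", "births",
                                        "n_infiltrating_cd8", "n_dc_islet",
                                        "n_apc_pln")))
  rec[1, ] <- count_state(E)
  thr_abs <- E$onset_threshold_frac * E$beta_init
  onset_hour <- NA_real_
  last <- n_ticks
  admin_tick <- if (!is.null(therapy)) therapy$admin_week * 168 else Inf
  for (t in seq_len(n_ticks)) {
    if (t >= admin_tick && is.finite(admin_tick)) {
      apply_therapy_env(E, therapy)
      admin_tick <- Inf
    }
    tick_env(E)
    rec[t + 1, ] <- count_state(E)
    if (is.na(onset_hour) && rec[t + 1, "n_healthy_beta"] <= thr_abs)
      onset_hour <- t
    if (!is.na(onset_hour) && stop_at_onset) { last <- t; break }
  }
  rec <- rec[seq_len(last + 1), , drop = FALSE]
  counts <- data.frame(tick = 0:last, week = (0:last) / 168, rec)
  ons <- detect_onset(counts$n_healthy_beta, E$beta_init,
                      E$onset_threshold_frac,
                      window_weeks = config$onset_window_weeks,
                      censor_weeks = config$max_weeks)
  traj <- list(counts = counts,
               onset_week = ons$onset_week,
               onset_hour = ons$onset_hour,
               censored = ons$censored,
               onset_threshold_frac = E$onset_threshold_frac,
               beta_init = E$beta_init,
               seed = as.integer(seed))
  class(traj) <- "t1d_trajectory"
  traj
}

#' @export
print.t1d_trajectory <- function(x, ...) {
  cat("t1d_trajectory:", nrow(x$counts) - 1, "hours simulated;",
      if (x$censored) paste0("censored (reported ", x$onset_week, " weeks)")
      else paste0("onset at week ", signif(x$onset_week, 4)),
      "| threshold", signif(x$onset_threshold_frac, 3), "\n")
  invisible(x)
}
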