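# Shared reduced-scale configurations. All fixtures are built in code.

# Desk-scale world used by the distribution-level checks (5 islets x 64
# beta cells, immune pools at 10 percent of full scale).
mini_cfg <- function() mini_world()

# Smallest world that still runs the full rule set; used by unit tests.
micro_cfg <- function() mini_world(3, 36, 0.05)

# Aggressive micro configuration: a large initial apoptotic insult and fast
# effector kinetics so onset occurs within a 10-week window in nearly every
# seed. Used where a test needs guaranteed, fast disease progression.
aggressive_cfg <- function() {
  cfg <- micro_cfg()
  cfg$params$init_apoptotic_beta <- 25
  cfg$params$ctl_kill_prob <- 0.2
  cfg$params$restim_prob <- 0.6
  cfg$params$dc_recruit_mu <- 8e-5 / (cfg$n_beta_cells / 8080)
  cfg$onset_window_weeks <- 10
  cfg
}

# A configuration in which autoimmunity can never initiate.
inert_cfg <- function() {
  cfg <- micro_cfg()
  cfg$params$init_apoptotic_beta <- 0
  cfg$params$n_naive_pool <- 0
  cfg$params$naive_replenish_per_h <- 0
  cfg
}
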