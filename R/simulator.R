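#' Simulation configuration
#'
#' Bundles the model profile and experiment geometry for one two-population
#' simulation. Population sizes, degrees and conductance scales come from
#' `profile`; the inter-areal coupling from `coupling`; the optional
#' stimulus from `protocol`.
#'
#' @param profile a model profile, see [default_profile()]
#' @param coupling a [coupling_spec()]
#' @param protocol optional [stimulus_protocol()]
#' @param record_v_ids global indices of neurons whose membrane voltage is
#'   recorded (downsampled), for diagnostics
#' @return a `sim_config` list
#' @export
sim_config <- function(profile = default_profile(), coupling = coupling_spec(),
                       protocol = NULL, record_v_ids = integer(0)) {
  sim <- profile$sim
  if (sim$dt <= 0 || sim$duration <= 0) {
    stop("sim_config: dt and duration must be positive")
  }
  rec_every <- (1000 / sim$fs_record) / sim$dt
  if (abs(rec_every - round(rec_every)) > 1e-9) {
    stop("sim_config: dt must divide the recording interval 1/fs_record")
  }
  if (!is.null(protocol) && protocol$window[2] > sim$duration) {
    stop("sim_config: stimulus window extends beyond the analysed span")
  }
  structure(list(profile = profile, coupling = coupling,
                 protocol = protocol, record_v_ids = record_v_ids),
            class = "sim_config")
}

# gating-rate lookup table handed to the compiled core; the R-level
# gating_rates() stays the single definition of the kinetics
gating_rate_table <- function(vmin = -130, vmax = 90, dv = 0.02) {
  V <- seq(vmin, vmax, by = dv)
  r <- gating_rates(V)
  list(vmin = vmin, dv = dv,
       rates = cbind(r$alpha_n, r$beta_n, r$alpha_m, r$beta_m,
                     r$alpha_h, r$beta_h))
}

# round a delay (ms) to integration steps, ties rounding up; delivery is
# never earlier than one step after the spike
delay_to_steps <- function(delay_ms, dt) {
  pmax(1L, as.integer(floor(delay_ms / dt + 0.5)))
}

#' Run one simulation trial
#'
#' Builds fresh connectivity, initial conditions and noise from `seed`,
#' integrates the two delay-coupled populations with the Heun scheme, and
#' returns the trial record: per-neuron spike times, per-population traces
#' of the summed absolute excitatory and inhibitory synaptic currents onto
#' excitatory cells (the LFP ingredients), and bookkeeping metadata.
#'
#' Spikes are detected as upward crossings of the configured threshold with
#' a refractory lockout; each spike is delivered to every outgoing edge
#' after that edge's conduction delay (rounded to the nearest integration
#' step, ties up, minimum one step). The warm-up period is integrated but
#' trimmed from the recorded traces and spike times.
#'
#' @param cfg a [sim_config()]
#' @param seed integer trial seed; identical (cfg, seed) gives bit-identical
#'   records
#' @param stimulus_index optional 1-based index into the protocol's rate
#'   increments; `NULL` runs the baseline drive
#' @return a `simulation_record` list with elements `spikes` (list, ms,
#'   warm-up removed), `I_exc_abs`, `I_inh_abs` (matrices, one column per
#'   population, summed over that population's excitatory cells, uA/cm^2),
#'   `V_rec`, `fs`, `exc_mask`, `pop_of`, `n_exc`, `config_hash`, `seed`
#' @export
run_trial <- function(cfg, seed = 1, stimulus_index = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  prof <- cfg$profile
  sim <- prof$sim
  net <- prof$network
  dt <- sim$dt

  # fresh connectivity per trial
  spec_A <- build_small_world(net$N, net$mean_degree, net$rewiring_p,
                              net$frac_exc, seed = sub_seed(seed, 1L))
  spec_B <- build_small_world(net$N, net$mean_degree, net$rewiring_p,
                              net$frac_exc, seed = sub_seed(seed, 50L))
  inter <- build_inter_coupling(spec_A, spec_B, cfg$coupling,
                                seed = sub_seed(seed, 90L))

  N <- spec_A$N + spec_B$N
  exc_mask <- c(spec_A$exc_mask, spec_B$exc_mask)
  pop_of <- rep(0:1, c(spec_A$N, spec_B$N))

  edges <- rbind(
    data.frame(pre = spec_A$edges$pre, post = spec_A$edges$post,
               delay = spec_A$edges$delay, class = spec_A$edges$class),
    data.frame(pre = spec_B$edges$pre + spec_A$N,
               post = spec_B$edges$post + spec_A$N,
               delay = spec_B$edges$delay, class = spec_B$edges$class),
    inter[, c("pre", "post", "delay", "class")]
  )

  p_exc <- as_neuron_params(prof$neuron_exc)
  p_inh <- as_neuron_params(prof$neuron_inh)
  # one parameter column per neuron: C_m, g_Na, g_K, g_L, E_Na, E_K, E_L
  np <- matrix(0, 7, N)
  np[, exc_mask] <- unlist(p_exc)
  np[, !exc_mask] <- unlist(p_inh)

  sa <- as_synapse_params(prof$syn_ampa)
  sg <- as_synapse_params(prof$syn_gaba)
  se <- as_synapse_params(prof$syn_ext)
  syn_tau_d <- c(sa$tau_d, sg$tau_d, se$tau_d)
  syn_tau_r <- c(sa$tau_r, sg$tau_r, se$tau_r)
  syn_w <- c(sa$g_max * sa$norm_c, sg$g_max * sg$norm_c,
             se$g_max * se$norm_c)
  syn_E <- c(sa$E_syn, sg$E_syn, se$E_syn)

  span <- sim$duration + sim$warmup
  n_steps <- round(span * 1000 / dt)
  rec_every <- as.integer(round((1000 / sim$fs_record) / dt))

  # background drive: one OU trace per population (shared mode) with
  # independent per-neuron Poisson thinning inside the core
  dp <- do.call(ou_params, prof$drive[names(prof$drive) %in%
    c("nu0", "sigma", "tau_ou", "clip_at_zero")])
  shared <- isTRUE(prof$drive$shared_ou)
  if (shared) {
    r1 <- ou_rate_trace(dp, dt, span, seed = sub_seed(seed, 91L))
    r2 <- ou_rate_trace(dp, dt, span, seed = sub_seed(seed, 92L))
    rate_pop <- cbind(as.numeric(r1), as.numeric(r2))
  } else {
    rate_pop <- matrix(0, 1, 2) # unused in independent mode
  }
  ou_a <- exp(-dt / dp$tau_ou)
  ou_s <- dp$sigma * sqrt(1 - ou_a^2)

  # stimulus targets: long-range projecting excitatory neurons of pop 1
  stim_ids <- integer(0)
  stim_on <- -1L
  stim_off <- -1L
  stim_inc <- 0
  if (!is.null(cfg$protocol) && !is.null(stimulus_index)) {
    proto <- cfg$protocol
    if (stimulus_index < 1 || stimulus_index > length(proto$rate_increments))
      stop("run_trial: stimulus_index out of range")
    emitters <- sort(unique(inter$pre[inter$pre <= spec_A$N]))
    if (length(emitters) == 0) {
      stop("run_trial: no long-range emitters to stimulate")
    }
    set.seed(sub_seed(seed, 93L))
    n_t <- min(proto$n_target_neurons, length(emitters))
    stim_ids <- sort(sample(emitters, n_t))
    # protocol window is expressed in analysis time (post warm-up)
    stim_on <- as.integer(round((proto$window[1] + sim$warmup) * 1000 / dt))
    stim_off <- as.integer(round((proto$window[2] + sim$warmup) * 1000 / dt))
    stim_inc <- proto$rate_increments[stimulus_index]
  }

  # initial conditions: V uniform near rest, gates at steady state
  set.seed(sub_seed(seed, 94L))
  Vr_e <- resting_voltage(p_exc)
  V0 <- Vr_e + stats::runif(N, -5, 5)
  gi <- gating_inf(V0)

  tab <- gating_rate_table()
  set.seed(sub_seed(seed, 95L)) # RNG state consumed by the compiled core
  res <- .sim_core(
    N, as.integer(exc_mask), np, syn_tau_d, syn_tau_r, syn_w, syn_E,
    as.integer(edges$pre - 1L), as.integer(edges$post - 1L),
    delay_to_steps(edges$delay, dt),
    as.integer(edges$class == "gaba"), rate_pop, as.integer(pop_of),
    as.integer(stim_ids - 1L), stim_on, stim_off, stim_inc, dt, n_steps,
    rec_every, sim$v_thresh, as.integer(round(sim$refractory / dt)), V0,
    gi$n, gi$h, tab$vmin, tab$dv, tab$rates, !shared, dp$nu0, dp$sigma,
    ou_a, ou_s, dp$clip_at_zero,
    if (is.null(prof$drive$inh_drive_gain)) 1 else
      prof$drive$inh_drive_gain,
    as.integer(cfg$record_v_ids - 1L)
  )

  warm_ms <- sim$warmup * 1000
  n_warm_rec <- round(warm_ms / 1000 * sim$fs_record)
  keep <- seq_len(nrow(res$I_exc_abs)) > n_warm_rec
  spikes <- lapply(res$spikes, function(s) s[s > warm_ms] - warm_ms)
  structure(list(
    spikes = spikes,
    I_exc_abs = res$I_exc_abs[keep, , drop = FALSE],
    I_inh_abs = res$I_inh_abs[keep, , drop = FALSE],
    V_rec = if (length(cfg$record_v_ids))
      res$V_rec[keep, , drop = FALSE] else NULL,
    fs = sim$fs_record, dt = dt, duration = sim$duration,
    exc_mask = exc_mask, pop_of = pop_of,
    n_exc = c(sum(spec_A$exc_mask), sum(spec_B$exc_mask)),
    N = c(spec_A$N, spec_B$N),
    n_ou_clipped = res$n_ou_clipped,
    stim_ids = stim_ids, stimulus_index = stimulus_index,
    config_hash = config_hash(cfg), seed = as.integer(seed)
  ), class = "simulation_record")
}

# stable hash of a configuration: polynomial rolling hash of its serialised
# bytes; enough to detect config drift in manifests without a cryptographic
# dependency
config_hash <- function(cfg) {
  b <- as.integer(serialize(cfg, NULL, version = 2))
  m <- 2^48
  h <- 0
  # vectorised Horner scheme in blocks to stay in exact double range
  for (chunk in split(b, ceiling(seq_along(b) / 4096))) {
    for (x in chunk) h <- (h * 257 + x) %% m
  }
  as.integer64ish(h)
}

# format a [0, 2^48) double as fixed-width hex without bit64
as.integer64ish <- function(h) {
  hi <- floor(h / 2^24)
  lo <- h - hi * 2^24
  sprintf("%06x%06x", hi, lo)
}

#' Run a delay/stimulus sweep experiment
#'
#' Runs independent trials over a grid of inter-areal delays and (optionally)
#' stimuli. Results are returned as a nested list and, when `out_dir` is
#' given, persisted incrementally (one JSON+CSV bundle per record plus a
#' manifest) so an interrupted sweep can be resumed: records already on disk
#' are loaded, not recomputed.
#'
#' @param cfg a [sim_config()]; its coupling's `tau_inter` is overridden by
#'   the grid values
#' @param tau_grid inter-areal mean delays (ms)
#' @param stimulus_set stimulus indices (or `NULL` for unstimulated trials)
#' @param n_trials trials per (tau, stimulus) cell
#' @param master_seed base seed; each cell/trial gets a distinct derived seed
#' @param out_dir optional directory for incremental persistence
#' @return list of records; each element carries attributes `tau`,
#'   `stimulus`, `trial`
#' @export
run_experiment <- function(cfg, tau_grid, stimulus_set = NULL, n_trials = 1,
                           master_seed = 1, out_dir = NULL) {
  stopifnot(length(tau_grid) >= 1, n_trials >= 1)
  if (is.null(stimulus_set)) stimulus_set <- NA_integer_
  grid <- expand.grid(trial = seq_len(n_trials), s = stimulus_set,
                      tau = tau_grid)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tau <- grid$tau[i]
    s <- grid$s[i]
    trial <- grid$trial[i]
    seed <- derive_seed(master_seed, tau, s, trial)
    key <- sprintf("tau%g_s%s_t%d", tau, ifelse(is.na(s), "none", s), trial)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, paste0(key, ".rec.json"))
      if (file.exists(f)) {
        out[[i]] <- read_record(f)
        next
      }
    }
    cfg_i <- cfg
    cfg_i$coupling$tau_inter <- tau
    rec <- run_trial(cfg_i, seed = seed,
                     stimulus_index = if (is.na(s)) NULL else s)
    attr(rec, "tau") <- tau
    attr(rec, "stimulus") <- if (is.na(s)) NULL else s
    attr(rec, "trial") <- trial
    if (!is.null(out_dir)) {
      write_record(rec, file.path(out_dir, paste0(key, ".rec.json")))
    }
    out[[i]] <- rec
  }
  attr(out, "grid") <- grid
  if (!is.null(out_dir)) {
    manifest <- list(
      grid = grid, master_seed = master_seed,
      config_hash = config_hash(cfg),
      package_version = as.character(utils::packageVersion("gammalink"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# reproducible sub-seed for one component of a trial (kept under 2^31,
# overflow-safe for any 32-bit master seed)
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %%
               2147483629) + 1L
}

# distinct, reproducible sub-seed per grid cell (kept under 2^31)
derive_seed <- function(master_seed, tau, s, trial) {
  v <- c(master_seed, round(tau * 1000), ifelse(is.na(s), 0, s), trial)
  h <- 0
  for (x in v) h <- (h * 7919 + x + 1) %% 2147483629
  as.integer(h + 1)
}

#' Persist / load a simulation record (plain-text bundle)
#'
#' Records are stored as a JSON file holding metadata and spike times plus
#' the current traces inline; everything round-trips exactly at double
#' precision.
#'
#' @param rec a `simulation_record`
#' @param path file path (`.rec.json`)
#' @return `read_record` returns the record; `write_record` the path,
#'   invisibly
#' @export
write_record <- function(rec, path) {
  obj <- unclass(rec)
  obj$spikes <- lapply(obj$spikes, as.numeric)
  for (a in c("tau", "stimulus", "trial")) obj[[paste0(".attr_", a)]] <-
    attr(rec, a)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spikes <- lapply(obj$spikes, as.numeric)
  obj$I_exc_abs <- as.matrix(obj$I_exc_abs)
  obj$I_inh_abs <- as.matrix(obj$I_inh_abs)
  obj$exc_mask <- as.logical(obj$exc_mask)
  rec <- obj[!startsWith(names(obj), ".attr_")]
  class(rec) <- "simulation_record"
  for (a in c("tau", "stimulus", "trial")) {
    v <- obj[[paste0(".attr_", a)]]
    if (!is.null(v)) attr(rec, a) <- v
  }
  rec
}
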