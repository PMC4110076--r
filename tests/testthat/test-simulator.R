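test_that("identical (config, seed) reproduces bit-identical rasters and
           traces", {
  cfg <- fixture_network("tiny")
  a <- suppressMessages(run_trial(cfg, seed = 3))
  b <- suppressMessages(run_trial(cfg, seed = 3))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$I_exc_abs, b$I_exc_abs)
  expect_identical(a$I_inh_abs, b$I_inh_abs)
  c2 <- suppressMessages(run_trial(cfg, seed = 4))
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("the tiny fixture simulates end-to-end with sane statistics", {
  rec <- cached("tiny_rec", suppressMessages(run_trial(fixture_network("tiny"),
                                                       seed = 1)))
  expect_s3_class(rec, "simulation_record")
  expect_true(all(is.finite(rec$I_exc_abs)))
  expect_true(all(is.finite(rec$I_inh_abs)))
  # spike times strictly increasing per neuron, inside the trimmed span
  for (s in rec$spikes) {
    if (length(s) > 1) expect_true(all(diff(s) > 0))
    if (length(s) > 0) expect_true(all(s > 0 & s <= rec$duration * 1000))
  }
  # some activity in both populations
  expect_gt(mean(firing_rates(rec, 1)), 0.5)
  expect_gt(mean(firing_rates(rec, 2)), 0.5)
})

test_that("event delivery on a 3-neuron chain matches spike time + edge
           delay", {
  # hand-built core call: neuron 1 (pop 1) drives neurons 2 and 3 (pop 2)
  # through delays of 3 and 7 ms; drive reaches only neuron 1
  dt <- 0.05
  tab <- gammalink:::gating_rate_table()
  p <- neuron_params()
  Vr <- resting_voltage(p)
  g0 <- gating_inf(Vr)
  n_steps <- round(100 / dt)
  rate_pop <- matrix(c(rep(8000, n_steps), rep(0, n_steps)), ncol = 2)
  np <- matrix(rep(unlist(p), 3), nrow = 7)
  # edges: neuron 1 -> 2 with 3 ms delay, 1 -> 3 with 7 ms delay
  set.seed(42)
  res <- gammalink:::.sim_core(
    3L, c(1L, 1L, 1L), np,
    c(2, 4.5, 2), c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.05), c(0, -80, 0),
    c(0L, 0L), c(1L, 2L), as.integer(c(3 / dt, 7 / dt)), c(0L, 0L),
    rate_pop, c(0L, 1L, 1L),
    integer(0), -1L, -1L, 0, dt, n_steps, 1L, 0, as.integer(2 / dt),
    rep(Vr, 3), rep(g0$n, 3), rep(g0$h, 3),
    tab$vmin, tab$dv, tab$rates, FALSE, 0, 0, 1, 0, FALSE, 1,
    c(1L, 2L)
  )
  spikes1 <- res$spikes[[1]]
  expect_gt(length(spikes1), 0)
  t1 <- spikes1[1]
  # V of neurons 2 and 3 (columns of V_rec) starts deflecting upward at
  # t1 + delay, within one recording step
  dev2 <- which(res$V_rec[, 1] > Vr + 0.05)[1] * dt
  dev3 <- which(res$V_rec[, 2] > Vr + 0.05)[1] * dt
  expect_equal(dev2 - t1, 3, tolerance = 0.5)
  expect_equal(dev3 - t1, 7, tolerance = 0.5)
  # causality: no deflection before spike + delay
  expect_gt(dev2, t1 + 3 - 2 * dt - 0.5)
})

test_that("uncoupled populations show only chance-level coherence", {
  recs <- cached("tiny_uncoupled", {
    cfg <- fixture_network("tiny")
    cfg$coupling$degree_per_source <- 0
    suppressMessages(run_experiment(cfg, tau_grid = 0, n_trials = 4,
                                    master_seed = 11))
  })
  co <- phase_coherence(lapply(recs, compute_lfp, population = 1),
                        lapply(recs, compute_lfp, population = 2),
                        nperseg = 250)
  chance <- sqrt(pi) / (2 * sqrt(co$K))
  sel <- co$freqs >= 10 & co$freqs <= 120
  expect_lt(mean(co$coherence[sel]), 2.5 * chance)
  # and the trial-averaged LFP cross-correlation at zero lag is weak
  ccs <- vapply(recs, function(r) {
    x <- as.numeric(compute_lfp(r, 1))
    y <- as.numeric(compute_lfp(r, 2))
    abs(cor(x, y))
  }, numeric(1))
  expect_lt(median(ccs), 0.35)
})

test_that("run_experiment enumerates the grid with distinct seeds and
           labels", {
  cfg <- fixture_network("tiny")
  recs <- cached("tiny_grid", suppressMessages(
    run_experiment(cfg, tau_grid = c(0, 4, 8), n_trials = 3,
                   master_seed = 5)))
  expect_length(recs, 9)
  grid <- attr(recs, "grid")
  expect_equal(nrow(grid), 9)
  seeds <- vapply(recs, `[[`, integer(1), "seed")
  expect_equal(length(unique(seeds)), 9)
  taus <- vapply(recs, function(r) attr(r, "tau"), numeric(1))
  expect_equal(sort(unique(taus)), c(0, 4, 8))
})

test_that("an interrupted sweep resumes to the same set of records", {
  cfg <- fixture_network("tiny")
  d1 <- tempfile("sweep_full")
  full <- suppressMessages(run_experiment(cfg, tau_grid = c(0, 3),
                                          n_trials = 2, master_seed = 9,
                                          out_dir = d1))
  # simulate a kill after the first record: keep only one file
  d2 <- tempfile("sweep_partial")
  dir.create(d2)
  fs <- list.files(d1, pattern = "rec.json$", full.names = TRUE)
  file.copy(fs[1], file.path(d2, basename(fs[1])))
  resumed <- suppressMessages(run_experiment(cfg, tau_grid = c(0, 3),
                                             n_trials = 2, master_seed = 9,
                                             out_dir = d2))
  for (i in seq_along(full)) {
    expect_equal(resumed[[i]]$spikes, full[[i]]$spikes)
    expect_equal(resumed[[i]]$I_exc_abs, full[[i]]$I_exc_abs,
                 tolerance = 1e-12)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("records round-trip through the plain-text serialisation", {
  rec <- cached("tiny_rec", suppressMessages(run_trial(fixture_network("tiny"),
                                                       seed = 1)))
  f <- tempfile(fileext = ".rec.json")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$spikes, rec$spikes)
  expect_equal(back$I_exc_abs, rec$I_exc_abs, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$seed, rec$seed)
  unlink(f)
})

test_that("membrane voltage stays sub-threshold on average in the
           network (fluctuation-driven regime)", {
  cfg <- fixture_network("tiny")
  cfg$record_v_ids <- 1:5
  rec <- suppressMessages(run_trial(cfg, seed = 21))
  mv <- colMeans(rec$V_rec)
  expect_true(all(mv < 0)) # mean V below the spike threshold
  expect_true(all(mv > -90) && all(mv < -20)) # and physiological
})
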