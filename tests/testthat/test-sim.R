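mini_protocol <- function() dg_protocol(onset = 5, n_gc = 6, n_bc = 1, n_mc = 1)

test_that("an unstimulated network stays silent", {
  net <- mini_network(seed = 1)
  sim <- run_simulation(net, protocol = NULL,
                        config = dg_sim_config(duration = 50))
  expect_equal(nrow(sim$raster), 0)
})

test_that("spike detection interpolates crossings and merges within refractory", {
  expect_equal(detect_spikes(rep(-60, 100), 0.1), numeric(0))

  # synthetic spike crossing 0 mV exactly at 14.0 ms
  tt <- seq(0, 20, by = 0.1)
  v <- -60 + 80 * exp(-((tt - 14.35) / 0.7)^2)
  v[tt == 13.9] <- -10; v[tt == 14.0] <- 0; v[tt == 14.1] <- 10
  got <- detect_spikes(v, 0.1)
  expect_equal(length(got), 1)
  expect_equal(got, 14.0, tolerance = 1e-8)

  # two crossings 0.5 ms apart merge into one event
  w <- rep(-60, 200)
  w[51:53] <- c(-10, 10, -10)   # crossing near 5.0
  w[56:58] <- c(-10, 10, -10)   # crossing near 5.5
  expect_equal(length(detect_spikes(w, 0.1)), 1)
  expect_equal(length(detect_spikes(w, 0.1, refractory = 0.2)), 2)
})

test_that("identical configuration and seed give a bit-identical raster", {
  net <- mini_network(seed = 4)
  a <- run_simulation(net, protocol = mini_protocol(), seed = 4)
  b <- run_simulation(net, protocol = mini_protocol(), seed = 4)
  expect_identical(a$raster, b$raster)
  expect_identical(a$traces, b$traces)
  expect_gt(nrow(a$raster), 0)
})

test_that("no postsynaptic effect arrives before spike plus delay", {
  counts <- c(GC = 1, MC = 1, BC = 1, HIPP = 1)
  rules <- list(dg_rule("GC", "MC", 1L, 1L))
  with_edge <- generate_network(counts = counts, rules = rules, seed = 1)
  without <- generate_network(counts = counts, rules = list(), seed = 1)
  inj <- data.frame(cell = "GC0", comp = "soma", amp = 0.4,
                    t_on = 10, t_off = 30)
  cfg <- dg_sim_config(duration = 40,
                       record = data.frame(cell = "MC0", comp = "soma"))
  sa <- run_simulation(with_edge, protocol = NULL, config = cfg, inject = inj)
  sb <- run_simulation(without, protocol = NULL, config = cfg, inject = inj)
  gc_spike <- sa$raster$time[sa$raster$cell == "GC0"][1]
  delay <- dg_synapse_table()["GC_MC", "delay"]
  t <- sa$traces$time
  pre_window <- t <= gc_spike + delay
  expect_identical(sa$traces$MC0.soma[pre_window], sb$traces$MC0.soma[pre_window])
  expect_false(identical(sa$traces$MC0.soma, sb$traces$MC0.soma))
})

test_that("halving the step shifts spike times by less than 0.5 ms", {
  net <- mini_network(seed = 6)
  coarse <- run_simulation(net, protocol = mini_protocol(),
                           config = dg_sim_config(dt = 0.1), seed = 6)
  fine <- run_simulation(net, protocol = mini_protocol(),
                         config = dg_sim_config(dt = 0.05), seed = 6)
  rc <- coarse$raster; rf <- fine$raster
  shared <- intersect(unique(rc$cell), unique(rf$cell))
  expect_gt(length(shared), 0)
  for (cc in shared) {
    tc <- rc$time[rc$cell == cc]
    tf <- rf$time[rf$cell == cc]
    n <- min(length(tc), length(tf))
    expect_lt(max(abs(tc[seq_len(n)] - tf[seq_len(n)])), 0.5)
  }
})

test_that("missing synapse parameters are caught before integration", {
  net <- mini_network(seed = 1)
  tbl <- dg_synapse_table()
  tbl <- tbl[tbl$synapse_ref != "HIPP_BC", ]
  expect_error(run_simulation(net, protocol = mini_protocol(), synapses = tbl),
               "HIPP_BC")
})

test_that("basket cells fire network-driven spikes only in the sprouted circuit", {
  healthy <- generate_network(seed = 8)
  hs <- run_simulation(healthy, seed = 8)
  stim_bc <- hs$stimulated[grepl("^BC", hs$stimulated)]
  bc_spikes <- hs$raster[hs$raster$type == "BC", ]
  # healthy: every BC spike is the direct response of a stimulated cell
  expect_true(all(bc_spikes$cell %in% stim_bc))
  expect_true(all(bc_spikes$time < 11))

  sprouted <- generate_network(seed = 8, mode = "pathological",
                               sprouting_degree = 10)
  ps <- run_simulation(sprouted, seed = 8)
  late_bc <- ps$raster[ps$raster$type == "BC" & ps$raster$time > 11, ]
  expect_gt(nrow(late_bc), 0)
})

test_that("simulation configuration is validated", {
  expect_error(dg_sim_config(duration = 0), "positive")
  expect_error(dg_sim_config(dt = 0.3, duration = 100.05), "multiple")
  net <- mini_network(seed = 1)
  expect_error(run_simulation(net, protocol = dg_protocol(onset = 500,
                                                          n_gc = 5, n_bc = 1,
                                                          n_mc = 1)),
               "onset")
})
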