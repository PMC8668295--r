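#' Default synapse parameter table
#'
#' One row per synapse class.  Classes named `"<PRE>_<POST>"` are the
#' network projections (matching the rules' `synapse_ref`);
#' `"GC_GC_sprouted"` is the recurrent mossy-fiber-sprouting synapse of the
#' pathological mode and `"stim_<TYPE>"` are the artificial
#' (perforant-path-like) stimulation synapses.
#'
#' Columns: `tau_rise` / `tau_decay` (ms) of the double-exponential
#' conductance, `gmax` (uS, peak conductance per contact), `e_rev` (mV;
#' about 0 for excitatory GC/MC sources, hyperpolarized for BC/HIPP
#' sources), `delay` (ms; lumped axonal + synaptic latency) and `target`,
#' the postsynaptic compartment selector: `soma`, `prox` (section 1),
#' `mid` (section 2), `dist` (sections 3 and 4) — basket cells contact the
#' soma, mossy fibers and sprouted collaterals proximal dendrites, HIPP
#' cells and the perforant-path stimulus distal dendrites.  The stimulus
#' delay (3 ms) plus synaptic rise is what makes directly stimulated cells
#' fire about 4 ms after the stimulus.
#'
#' @return Data frame keyed by `synapse_ref`.
#' @export
dg_synapse_table <- function() {
  tbl <- rbind(
    data.frame(synapse_ref = "GC_MC",   tau_rise = 0.5, tau_decay = 4,  gmax = 0.0035, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "GC_BC",   tau_rise = 0.3, tau_decay = 3,  gmax = 0.00022, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "GC_HIPP", tau_rise = 0.5, tau_decay = 5,  gmax = 0.0035, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "MC_GC",   tau_rise = 0.5, tau_decay = 4,  gmax = 0.0006, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "MC_MC",   tau_rise = 0.5, tau_decay = 4,  gmax = 0.0015, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "MC_BC",   tau_rise = 0.5, tau_decay = 4,  gmax = 0.0002, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "MC_HIPP", tau_rise = 0.5, tau_decay = 4,  gmax = 0.0010, e_rev = 0,   delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "BC_GC",   tau_rise = 0.3, tau_decay = 6,  gmax = 0.0030, e_rev = -70, delay = 0.8, target = "soma"),
    data.frame(synapse_ref = "BC_MC",   tau_rise = 0.3, tau_decay = 6,  gmax = 0.0020, e_rev = -70, delay = 0.8, target = "soma"),
    data.frame(synapse_ref = "BC_BC",   tau_rise = 0.3, tau_decay = 8,  gmax = 0.0050, e_rev = -70, delay = 0.8, target = "soma"),
    data.frame(synapse_ref = "HIPP_GC", tau_rise = 0.5, tau_decay = 8,  gmax = 0.0015, e_rev = -75, delay = 1.2, target = "dist"),
    data.frame(synapse_ref = "HIPP_MC", tau_rise = 0.5, tau_decay = 8,  gmax = 0.0015, e_rev = -75, delay = 1.2, target = "mid"),
    data.frame(synapse_ref = "HIPP_BC", tau_rise = 0.5, tau_decay = 8,  gmax = 0.0012, e_rev = -75, delay = 1.2, target = "mid"),
    data.frame(synapse_ref = "GC_GC_sprouted", tau_rise = 0.5, tau_decay = 5, gmax = 0.015, e_rev = 0, delay = 1.0, target = "prox"),
    data.frame(synapse_ref = "stim_GC",   tau_rise = 0.3, tau_decay = 4, gmax = 0.010, e_rev = 0, delay = 3.0, target = "dist"),
    data.frame(synapse_ref = "stim_MC",   tau_rise = 0.3, tau_decay = 4, gmax = 0.012, e_rev = 0, delay = 3.0, target = "prox"),
    data.frame(synapse_ref = "stim_BC",   tau_rise = 0.3, tau_decay = 4, gmax = 0.012, e_rev = 0, delay = 3.0, target = "prox")
  )
  rownames(tbl) <- tbl$synapse_ref
  tbl
}

# Exp2Syn-style normalization: with unit weight the conductance peaks at 1.
syn_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
}

syn_norm_factor <- function(tau_rise, tau_decay) {
  tp <- syn_peak_time(tau_rise, tau_decay)
  1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Double-exponential synaptic conductance
#'
#' Closed-form conductance of one synapse: each presynaptic spike at time
#' `t_s` contributes, starting `delay` after the spike,
#' `gmax * f * (exp(-(t - t_s - delay)/tau_decay) - exp(-(t - t_s - delay)/tau_rise))`
#' with `f` normalizing the peak of a single event to `gmax`.
#' Contributions sum linearly; the conductance is never negative and is
#' exactly zero before `t_s + delay` (causality).
#'
#' @param spike_times Sorted presynaptic spike times (ms).
#' @param t Evaluation times (ms), scalar or vector.
#' @param tau_rise,tau_decay Time constants (ms), `0 < tau_rise < tau_decay`.
#' @param gmax Peak conductance per event (uS).
#' @param delay Latency between spike and conductance onset (ms).
#' @return Conductance (uS) at each `t`.
#' @export
synaptic_conductance <- function(spike_times, t, tau_rise, tau_decay,
                                 gmax = 1, delay = 0) {
  if (!(tau_rise > 0 && tau_rise < tau_decay)) {
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  }
  if (is.unsorted(spike_times)) stop("spike_times must be sorted", call. = FALSE)
  f <- gmax * syn_norm_factor(tau_rise, tau_decay)
  g <- numeric(length(t))
  for (ts in spike_times) {
    dtm <- t - ts - delay
    on <- dtm > 0
    g[on] <- g[on] + f * (exp(-dtm[on] / tau_decay) - exp(-dtm[on] / tau_rise))
  }
  g
}

#' Synaptic current
#'
#' Current through a conductance-based synapse,
#' `I = g(t) * (e_rev - V_post)` (nA, with g in uS and potentials in mV;
#' positive values depolarize the postsynaptic compartment).
#'
#' @inheritParams synaptic_conductance
#' @param V_post Postsynaptic membrane potential (mV) at each `t`.
#' @param e_rev Synaptic reversal potential (mV).
#' @return Current (nA) at each `t`.
#' @export
synaptic_current <- function(spike_times, t, V_post, tau_rise, tau_decay,
                             gmax, e_rev, delay = 0) {
  g <- synaptic_conductance(spike_times, t, tau_rise, tau_decay, gmax, delay)
  g * (e_rev - V_post)
}

#' Read a spike-time stimulus file
#'
#' Parses a plain-text stimulus file with one spike time (ms) per line —
#' the file-driven continuous-stimulation source.  Blank lines are
#' ignored; times are returned sorted.
#'
#' @param path File path.
#' @return Sorted numeric vector of non-negative times (ms).
#' @export
load_spike_times <- function(path) {
  if (!file.exists(path)) stop("spike-time file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines)
  if (!any(keep)) return(numeric(0))
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    stop(sprintf("non-numeric spike time at line %d of %s", bad, path), call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("spike times must be non-negative in ", path, call. = FALSE)
  }
  sort(vals)
}

#' Stimulation protocol
#'
#' The default protocol delivers a single pulse at `onset` through
#' excitatory synapses to 100 granule cells (a contiguous block at the
#' center of the septotemporal axis), 2 basket cells and 2 randomly chosen
#' mossy cells — the reduced circuit's analogue of a perforant-path volley.
#' A spike-time file (see [load_spike_times()]) may replace the single
#' pulse as the source.
#'
#' @param onset Stimulus time (ms) for the single-pulse source.
#' @param n_gc,n_bc,n_mc Number of stimulated cells per type.
#' @param spike_file Optional path to a spike-time file; when given, its
#'   times replace the single pulse.
#' @return An object of class `dg_protocol`.
#' @export
dg_protocol <- function(onset = 5, n_gc = 100L, n_bc = 2L, n_mc = 2L,
                        spike_file = NULL) {
  structure(list(onset = onset, n_gc = as.integer(n_gc),
                 n_bc = as.integer(n_bc), n_mc = as.integer(n_mc),
                 spike_file = spike_file),
            class = "dg_protocol")
}

#' Wire the stimulation source to its target cells
#'
#' Selects the stimulated cells: `n_gc` granule cells as a contiguous block
#' centered on the axis, `n_bc` basket cells as a contiguous central block,
#' and `n_mc` mossy cells drawn at random (reproducibly under `seed`).
#'
#' @param protocol A [dg_protocol].
#' @param network A `dg_network`.
#' @param seed Integer seed for the random mossy-cell choice.
#' @return Data frame with columns `cell`, `type` and `source`
#'   (`"stim"`), plus attribute `"times"` holding the source spike times.
#' @export
build_stimulation <- function(protocol, network, seed = 1L) {
  stopifnot(inherits(protocol, "dg_protocol"), inherits(network, "dg_network"))
  cts <- network$counts
  if (protocol$n_gc > cts[["GC"]] || protocol$n_bc > cts[["BC"]] ||
      protocol$n_mc > cts[["MC"]]) {
    stop("protocol stimulates more cells than the population holds", call. = FALSE)
  }
  central_block <- function(n_pop, n_take) {
    if (n_take == 0L) return(integer(0))
    start <- (n_pop - n_take) %/% 2L
    start + seq_len(n_take) - 1L
  }
  gc_idx <- central_block(cts[["GC"]], protocol$n_gc)
  bc_idx <- central_block(cts[["BC"]], protocol$n_bc)
  mc_idx <- integer(0)
  if (protocol$n_mc > 0L) {
    set.seed(rule_seed(seed, "stim_MC"))
    mc_idx <- sort(sample.int(cts[["MC"]], protocol$n_mc)) - 1L
  }
  ids <- function(tp, idx) if (length(idx)) paste0(tp, idx) else character(0)
  cells <- c(ids("GC", gc_idx), ids("BC", bc_idx), ids("MC", mc_idx))
  types <- c(rep("GC", length(gc_idx)), rep("BC", length(bc_idx)),
             rep("MC", length(mc_idx)))
  times <- if (!is.null(protocol$spike_file)) {
    load_spike_times(protocol$spike_file)
  } else {
    protocol$onset
  }
  out <- data.frame(cell = cells, type = types,
                    source = rep("stim", length(cells)),
                    stringsAsFactors = FALSE)
  attr(out, "times") <- times
  out
}
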