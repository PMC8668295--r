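#' Membrane-potential landmarks of the four cell types
#'
#' The calibration targets for the single-cell models: resting potential,
#' spike threshold and somatic spike peak (mV) for each cell type.
#'
#' @return Data frame with rownames `GC`, `MC`, `BC`, `HIPP` and columns
#'   `rest`, `threshold`, `peak` (mV).
#' @export
membrane_targets <- function() {
  data.frame(
    rest      = c(GC = -70.44, MC = -60.11, BC = -60.00, HIPP = -70.67),
    threshold = c(GC = -39.44, MC = -39.05, BC = -38.86, HIPP = -42.67),
    peak      = c(GC =  37.14, MC =  46.72, BC =  46.87, HIPP =  76.53)
  )
}

# Compartment layout per type: soma + n_branch dendrites x 4 sections.
# Section 1 is proximal, section 4 distal.  GC somata are ~10 um spheres;
# the remaining geometry is a uniform-diameter default (each section is one
# isopotential cylinder).
cell_geometry <- function(type) {
  switch(type,
    GC   = list(n_branch = 2L, soma_L = 10, soma_diam = 10, sec_L = 75, sec_diam = 1.5),
    MC   = list(n_branch = 4L, soma_L = 20, soma_diam = 20, sec_L = 80, sec_diam = 2.0),
    BC   = list(n_branch = 4L, soma_L = 15, soma_diam = 15, sec_L = 60, sec_diam = 1.5),
    HIPP = list(n_branch = 3L, soma_L = 10, soma_diam = 10, sec_L = 75, sec_diam = 1.5),
    stop("unknown cell type: ", type, call. = FALSE)
  )
}

#' Biophysical parameters of a cell type
#'
#' Returns the calibrated default parameter set for one cell type:
#' passive properties (specific capacitance `cm` in uF/cm2, axial
#' resistivity `ra` in ohm cm, leak density `g_pas` in S/cm2), active
#' somatic Na/K maximal conductance densities (`gna`, `gk`, S/cm2) with
#' reversals `ena`/`ek` (mV), the kinetics voltage shift `shift` (mV, a
#' rightward shift of the activation curves that sets the spike threshold)
#' and the type's resting potential `rest` (mV).  The leak reversal is not
#' stored: it is solved exactly at build time so that `rest` is a fixed
#' point of the membrane equations (passive dendrites rest at `rest`
#' trivially; the somatic leak reversal compensates the small standing
#' Na/K window currents).
#'
#' The defaults reproduce each type's landmark rest/threshold/peak within
#' the calibration tolerances; [calibrate_cell()] regenerates them from
#' scratch.
#'
#' @param type Cell type.
#' @return Named list of parameters.
#' @export
dg_cell_params <- function(type) {
  type <- match.arg(type, DG_TYPES)
  base <- list(cm = 1, ra = 210, gna = 0.12, gk = 0.036, ek = -77)
  tuned <- switch(type,
    GC   = list(rest = -70.44, g_pas = 1 / 30000, ena = 54.48, shift = 6.14),
    MC   = list(rest = -60.11, g_pas = 1 / 20000, ena = 76.84, shift = 5.46),
    BC   = list(rest = -60.00, g_pas = 1 / 5000, ena = 92.66, shift = 4.64),
    HIPP = list(rest = -70.67, g_pas = 1 / 30000, ena = 120.99, shift = 3.27)
  )
  c(list(type = type), base, tuned)
}

# --- HH-type kinetics -------------------------------------------------------
# Classic Na/K formalism expressed relative to a per-type voltage shift `s`:
# the rate functions are evaluated at u = V - s, so increasing `s` moves the
# activation range (and hence the spike threshold) to more depolarized
# potentials without touching the reversals.

vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))

hh_rates <- function(V, shift) {
  u <- V - shift
  list(
    am = 0.1 * vtrap(-(u + 40), 10),
    bm = 4 * exp(-(u + 65) / 18),
    ah = 0.07 * exp(-(u + 65) / 20),
    bh = 1 / (1 + exp(-(u + 35) / 10)),
    an = 0.01 * vtrap(-(u + 55), 10),
    bn = 0.125 * exp(-(u + 65) / 80)
  )
}

hh_steady <- function(V, shift) {
  r <- hh_rates(V, shift)
  list(m = r$am / (r$am + r$bm),
       h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

# Somatic leak reversal that makes `rest` an exact fixed point (density
# space; areas cancel).
solve_el_soma <- function(p) {
  s <- hh_steady(p$rest, p$shift)
  ina <- p$gna * s$m^3 * s$h * (p$rest - p$ena)
  ik  <- p$gk * s$n^4 * (p$rest - p$ek)
  p$rest + (ina + ik) / p$g_pas
}

#' Build a multicompartment cell
#'
#' Constructs the compartment tree for one cell: a cylindrical somatic
#' compartment plus `n_branch` dendrites of four serially coupled sections
#' each (section 1 proximal, section 4 distal), all rooted at the soma.
#' Granule cells have 9 compartments, mossy and basket cells 17, HIPP
#' cells 13.  The soma carries active Na/K conductances; dendrites are
#' passive.  Axial coupling between a compartment and its parent is
#' `1 / (ra * (L1/(2 A1) + L2/(2 A2)))` with cross-sections `A` (the
#' standard cable discretization).
#'
#' @param type Cell type.
#' @param params Parameter list, defaults to [dg_cell_params()].
#' @return An object of class `dg_cell`: list with `type`, `params` and a
#'   compartment data frame `comps` (columns `comp`, `role`, `branch`,
#'   `section`, `L`, `diam`, `area_cm2`, `C_nF`, `g_pas_uS`, `E_L`,
#'   `parent`, `g_axial_uS`, `active`).
#' @examples
#' nrow(build_cell("GC")$comps)   # 9
#' nrow(build_cell("MC")$comps)   # 17
#' nrow(build_cell("HIPP")$comps) # 13
#' @export
build_cell <- function(type, params = dg_cell_params(type)) {
  type <- match.arg(type, DG_TYPES)
  geo <- cell_geometry(type)
  ncomp <- 1L + 4L * geo$n_branch
  role <- c("soma", rep("dendrite", ncomp - 1L))
  branch <- c(0L, rep(seq_len(geo$n_branch), each = 4L))
  section <- c(0L, rep(1:4, geo$n_branch))
  L <- c(geo$soma_L, rep(geo$sec_L, ncomp - 1L))
  diam <- c(geo$soma_diam, rep(geo$sec_diam, ncomp - 1L))
  # parent: soma has none; section 1 attaches to soma, section s to s-1
  parent <- integer(ncomp)
  for (i in 2:ncomp) parent[i] <- if (section[i] == 1L) 1L else i - 1L

  area_cm2 <- pi * diam * L * 1e-8          # lateral cylinder surface
  C_nF <- params$cm * area_cm2 * 1e3        # uF/cm2 * cm2 -> nF
  g_pas_uS <- params$g_pas * area_cm2 * 1e6 # S -> uS

  xsec <- pi * (diam * 1e-4)^2 / 4          # cm2
  half_res <- (L * 1e-4) / (2 * xsec) * params$ra  # ohm, center to end
  g_axial_uS <- numeric(ncomp)
  for (i in 2:ncomp) {
    g_axial_uS[i] <- 1e6 / (half_res[i] + half_res[parent[i]])
  }

  el_soma <- solve_el_soma(params)
  comps <- data.frame(
    comp = seq_len(ncomp), role = role, branch = branch, section = section,
    L = L, diam = diam, area_cm2 = area_cm2, C_nF = C_nF,
    g_pas_uS = g_pas_uS,
    E_L = c(el_soma, rep(params$rest, ncomp - 1L)),
    parent = parent, g_axial_uS = g_axial_uS,
    active = c(TRUE, rep(FALSE, ncomp - 1L)),
    stringsAsFactors = FALSE
  )
  structure(list(type = type, params = params, comps = comps), class = "dg_cell")
}

#' @export
print.dg_cell <- function(x, ...) {
  geo <- cell_geometry(x$type)
  cat(sprintf("<dg_cell> %s: %d compartments (soma + %d dendrites x 4 sections)\n",
              x$type, nrow(x$comps), geo$n_branch))
  invisible(x)
}

#' Initial gating state of a cell
#'
#' Steady-state HH gating variables of the somatic compartment at a given
#' membrane potential.
#'
#' @param cell A `dg_cell`.
#' @param V Membrane potential (mV).
#' @return List with `m`, `h`, `n`.
#' @export
init_gates <- function(cell, V) {
  hh_steady(V, cell$params$shift)
}

#' Membrane and gating derivatives of one cell
#'
#' Right-hand side of the compartmental membrane equations: for each
#' compartment, `C dV/dt` equals the sum of leak, active Na/K (somatic
#' only), axial, synaptic and injected currents; axial currents between a
#' parent and a child are equal and opposite (charge conservation).  Gating
#' derivatives follow the HH formalism `dx/dt = a (1 - x) - b x`.
#'
#' @param cell A `dg_cell`.
#' @param V Numeric vector of per-compartment potentials (mV).
#' @param gates List with somatic `m`, `h`, `n` (see [init_gates()]).
#' @param I_inj Per-compartment injected current (nA), scalar or vector.
#' @param g_syn Optional data frame `comp`, `g` (uS), `E` (mV) of synaptic
#'   conductances.
#' @return List with `dV` (mV/ms per compartment) and `dgates`
#'   (`dm`, `dh`, `dn`).
#' @export
membrane_derivatives <- function(cell, V, gates, I_inj = 0, g_syn = NULL) {
  comps <- cell$comps
  n <- nrow(comps)
  if (length(V) != n) stop("V must have one entry per compartment", call. = FALSE)
  if (any(!is.finite(V))) {
    stop(sprintf("non-finite membrane state in %s cell", cell$type), call. = FALSE)
  }
  p <- cell$params
  I <- rep_len(I_inj, n)
  # leak
  I <- I + comps$g_pas_uS * (comps$E_L - V)
  # active soma
  area_soma <- comps$area_cm2[1]
  gna <- p$gna * area_soma * 1e6 * gates$m^3 * gates$h
  gk <- p$gk * area_soma * 1e6 * gates$n^4
  I[1] <- I[1] + gna * (p$ena - V[1]) + gk * (p$ek - V[1])
  # axial (conservative pairwise exchange)
  for (i in seq_len(n)[-1]) {
    j <- comps$parent[i]
    ax <- comps$g_axial_uS[i] * (V[j] - V[i])
    I[i] <- I[i] + ax
    I[j] <- I[j] - ax
  }
  if (!is.null(g_syn)) {
    for (k in seq_len(nrow(g_syn))) {
      ck <- g_syn$comp[k]
      I[ck] <- I[ck] + g_syn$g[k] * (g_syn$E[k] - V[ck])
    }
  }
  r <- hh_rates(V[1], p$shift)
  list(
    dV = I / comps$C_nF,
    dgates = list(dm = r$am * (1 - gates$m) - r$bm * gates$m,
                  dh = r$ah * (1 - gates$h) - r$bh * gates$h,
                  dn = r$an * (1 - gates$n) - r$bn * gates$n)
  )
}

#' Estimate the spike threshold from a somatic voltage trace
#'
#' Returns the membrane potential at spike onset for the first spike of a
#' trace, using the standard rate-of-rise criterion: onset is the first
#' sample of the upstroke at which `dV/dt` exceeds `dvdt_crit` on its way
#' to the first suprathreshold peak.
#'
#' @param v Voltage trace (mV), uniformly sampled.
#' @param dt Sampling step (ms).
#' @param peak_thresh Peaks must exceed this value (mV) to count as spikes.
#' @param dvdt_crit Onset criterion (mV/ms), default 20.
#' @return Onset potential (mV), or `NA` if the trace has no spike.
#' @export
spike_threshold <- function(v, dt, peak_thresh = 0, dvdt_crit = 20) {
  pk <- which(v > peak_thresh)
  if (!length(pk)) return(NA_real_)
  # first local maximum above peak_thresh
  p <- pk[1]
  while (p < length(v) && v[p + 1] > v[p]) p <- p + 1
  dv <- diff(v) / dt                              # aligned with v[1:(n-1)]
  fast <- which(dv[seq_len(p - 1)] >= dvdt_crit)
  if (!length(fast)) return(NA_real_)
  # walk back to the start of the contiguous fast-rise run ending at the peak
  i <- max(fast)
  while (i > 1 && dv[i - 1] >= dvdt_crit) i <- i - 1
  v[i]
}

#' Calibrate a cell model to its membrane landmarks
#'
#' Adjusts the kinetics voltage shift (which sets the spike threshold) and
#' the Na reversal (which sets the spike peak) until a somatic
#' current-clamp protocol reproduces the target landmarks: resting
#' potential within 2 mV, spike-onset potential within 5 mV and spike peak
#' within 10 mV.  The resting potential is met by construction (the leak
#' reversal is solved for it exactly, see [dg_cell_params()]); iteration is
#' only needed for threshold and peak.
#'
#' @param type Cell type.
#' @param targets Numeric vector or one-row data frame with `rest`,
#'   `threshold`, `peak` (mV); defaults to the type's row of
#'   [membrane_targets()].  Must satisfy rest < threshold < peak.
#' @param params Starting parameter set.
#' @param amp Clamp amplitude (nA); raised automatically if subthreshold.
#' @param max_iter Iteration bound.
#' @return Calibrated parameter list with attribute `"residuals"` (named
#'   vector: rest, threshold, peak errors in mV).
#' @export
calibrate_cell <- function(type, targets = membrane_targets()[type, ],
                           params = dg_cell_params(type), amp = 0.25,
                           max_iter = 12L) {
  type <- match.arg(type, DG_TYPES)
  tg <- as.list(targets)
  if (!(tg$rest < tg$threshold && tg$threshold < tg$peak)) {
    stop("targets must satisfy rest < threshold < peak", call. = FALSE)
  }
  params$rest <- tg$rest
  resid <- c(rest = NA_real_, threshold = NA_real_, peak = NA_real_)
  for (iter in seq_len(max_iter)) {
    meas <- clamp_landmarks(type, params, amp)
    if (is.na(meas["peak"])) { amp <- amp * 2; next }  # subthreshold: stronger clamp
    resid <- c(rest = meas[["rest"]] - tg$rest,
               threshold = meas[["threshold"]] - tg$threshold,
               peak = meas[["peak"]] - tg$peak)
    if (abs(resid["threshold"]) < 2 && abs(resid["peak"]) < 3) break
    params$shift <- params$shift - 0.8 * resid[["threshold"]]
    params$ena <- params$ena - 0.9 * resid[["peak"]]
  }
  if (any(is.na(resid)) ||
      abs(resid["rest"]) > 2 || abs(resid["threshold"]) > 5 || abs(resid["peak"]) > 10) {
    stop(sprintf("calibration for %s did not converge; residuals: %s", type,
                 paste(sprintf("%s %.2f", names(resid), resid), collapse = ", ")),
         call. = FALSE)
  }
  attr(params, "residuals") <- resid
  params
}

# One current-clamp run; returns measured rest / threshold / peak (mV).
clamp_landmarks <- function(type, params, amp) {
  sim <- simulate_cell(type, params = params, amp = amp,
                       t_on = 40, t_off = 90, duration = 100,
                       v_init = params$rest)
  v <- sim$traces[, 2]
  dt <- sim$config$dt
  rest <- v[round(39.5 / dt)]
  pk <- if (any(v > 0)) max(v) else NA_real_
  c(rest = rest, threshold = spike_threshold(v, dt), peak = pk)
}
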