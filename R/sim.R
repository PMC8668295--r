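#' Simulation configuration
#'
#' @param dt Integration step (ms), default 0.1.
#' @param duration Simulated time (ms), default 100; must be a multiple of
#'   `dt`.
#' @param v_init Initial membrane potential (mV) of every compartment,
#'   default -60; cells relax to their own resting potentials within the
#'   first milliseconds.
#' @param substeps Integer number of internal integration substeps per
#'   `dt` (default 2): the two-stage exponential update runs at `dt /
#'   substeps` while synaptic deliveries, traces and the spike raster stay
#'   on the `dt` grid.
#' @param record Recording set: data frame with columns `cell` and `comp`
#'   (compartment label, `"soma"` or `"d<branch>s<section>"`), or `NULL`
#'   for the default set (granule cell 0 and the first stimulated granule
#'   cell, each with soma and the four sections of dendrite 1).
#' @return An object of class `dg_sim_config`.
#' @export
dg_sim_config <- function(dt = 0.1, duration = 100, v_init = -60,
                          substeps = 2L, record = NULL) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  substeps <- as.integer(substeps)
  if (is.na(substeps) || substeps < 1L) {
    stop("substeps must be a positive integer", call. = FALSE)
  }
  nsteps <- duration / dt
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop("duration must be a multiple of dt", call. = FALSE)
  }
  structure(list(dt = dt, duration = duration, v_init = v_init,
                 substeps = substeps, record = record),
            class = "dg_sim_config")
}

comp_label_to_index <- function(label, type) {
  geo <- cell_geometry(type)
  if (label == "soma") return(1L)
  m <- regmatches(label, regexec("^d([0-9]+)s([0-9]+)$", label))[[1]]
  if (length(m) != 3) stop("bad compartment label: ", label, call. = FALSE)
  b <- as.integer(m[2]); s <- as.integer(m[3])
  if (b < 1 || b > geo$n_branch || s < 1 || s > 4) {
    stop(sprintf("compartment %s does not exist on a %s cell", label, type),
         call. = FALSE)
  }
  1L + (b - 1L) * 4L + s
}

# Compartments contacted by a synapse class on one postsynaptic cell
# (local indices).  "dist" spreads the contact over sections 3 and 4 of the
# chosen branch.
target_comps <- function(target, type, branch) {
  switch(target,
    soma = 1L,
    prox = 1L + (branch - 1L) * 4L + 1L,
    mid  = 1L + (branch - 1L) * 4L + 2L,
    dist = 1L + (branch - 1L) * 4L + 3:4,
    stop("unknown synapse target selector: ", target, call. = FALSE)
  )
}

# Flatten one prototype cell per type into global state arrays for a list
# of cell instances.
flatten_cells <- function(types, protos) {
  per <- lapply(protos, function(cl) {
    cp <- cl$comps
    p <- cl$params
    area_soma <- cp$area_cm2[1]
    list(ncomp = nrow(cp), C = cp$C_nF, gpas = cp$g_pas_uS, EL = cp$E_L,
         parent = cp$parent, gax = cp$g_axial_uS,
         gna = p$gna * area_soma * 1e6, gk = p$gk * area_soma * 1e6,
         ena = p$ena, ek = p$ek, shift = p$shift, rest = p$rest)
  })
  ncomp_type <- vapply(per, function(z) z$ncomp, integer(1))
  ncomps <- ncomp_type[types]
  offsets <- cumsum(c(0L, ncomps[-length(ncomps)]))
  ntot <- sum(ncomps)
  C <- numeric(ntot); gpas <- numeric(ntot); EL <- numeric(ntot)
  tri_i <- vector("list", length(types)); tri_j <- tri_i; tri_x <- tri_i
  for (ci in seq_along(types)) {
    z <- per[[types[ci]]]
    sel <- offsets[ci] + seq_len(z$ncomp)
    C[sel] <- z$C; gpas[sel] <- z$gpas; EL[sel] <- z$EL
    child <- 2:z$ncomp
    tri_i[[ci]] <- offsets[ci] + child
    tri_j[[ci]] <- offsets[ci] + z$parent[child]
    tri_x[[ci]] <- z$gax[child]
  }
  ii <- unlist(tri_i); jj <- unlist(tri_j); xx <- unlist(tri_x)
  Gax <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(xx, xx),
                              dims = c(ntot, ntot))
  gax_diag <- as.numeric(Matrix::rowSums(Gax))
  list(
    ntot = ntot, offsets = offsets, ncomps = ncomps,
    C = C, gpas = gpas, EL = EL, Gax = Gax, gax_diag = gax_diag,
    soma_idx = offsets + 1L,
    gna = vapply(per, function(z) z$gna, numeric(1))[types],
    gk  = vapply(per, function(z) z$gk,  numeric(1))[types],
    ena = vapply(per, function(z) z$ena, numeric(1))[types],
    ek  = vapply(per, function(z) z$ek,  numeric(1))[types],
    shift = vapply(per, function(z) z$shift, numeric(1))[types],
    types = types
  )
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of `threshold`, with the crossing time linearly
#' interpolated between samples; crossings within `refractory` of the
#' previous accepted spike are merged into it.
#'
#' @param v Voltage trace (mV), sampled every `dt`.
#' @param dt Sampling step (ms).
#' @param threshold Detection threshold (mV), default 0.
#' @param refractory Merge window (ms), default 2.
#' @param t0 Time of the first sample (ms), default 0.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 2, t0 = 0) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  tc <- t0 + (up - 1) * dt + dt * (threshold - v[up]) / (v[up + 1] - v[up])
  keep <- numeric(0)
  last <- -Inf
  for (tt in tc) {
    if (tt - last >= refractory) {
      keep <- c(keep, tt)
      last <- tt
    }
  }
  keep
}

#' Run a network (or single-cell) simulation
#'
#' Integrates the full conductance-based network with the exponential-Euler
#' scheme at a fixed step: each compartment is advanced analytically under
#' its instantaneous total conductance, with neighbouring compartments,
#' gating variables and synaptic conductances held over the step.  Somatic
#' spikes (upward 0 mV crossings, 2 ms refractory) enqueue synaptic
#' deliveries at the next grid point at or after the interpolated spike
#' time plus the synapse's delay.  The run is fully deterministic given
#' the network, protocol and seed.
#'
#' @param network A `dg_network`.
#' @param protocol A [dg_protocol], or `NULL` for no stimulation.
#' @param config A [dg_sim_config].
#' @param cell_params Named list of per-type parameter sets, defaults to
#'   the calibrated [dg_cell_params()] set.
#' @param synapses Synapse table, defaults to [dg_synapse_table()]; every
#'   `synapse_ref` appearing in the network's edges must have a row.
#' @param inject Optional current-clamp table: data frame with `cell`,
#'   `comp` (label), `amp` (nA), `t_on`, `t_off` (ms).
#' @param seed Integer seed (mossy-cell stimulus choice).
#' @return An object of class `dg_sim`: list with `raster` (data frame
#'   `cell`, `type`, `time`), `traces` (data frame, `time` plus one column
#'   per recorded compartment named `"<cell>.<comp>"`), `spike_counts`
#'   (per-type totals), `stimulated` (cell ids), `config`, `seed`.
#' @export
run_simulation <- function(network, protocol = dg_protocol(),
                           config = dg_sim_config(),
                           cell_params = NULL,
                           synapses = dg_synapse_table(),
                           inject = NULL, seed = 1L) {
  stopifnot(inherits(network, "dg_network"), inherits(config, "dg_sim_config"))
  pops <- network$populations
  dt <- config$dt
  nsteps <- as.integer(round(config$duration / dt))

  if (is.null(cell_params)) {
    cell_params <- stats::setNames(lapply(DG_TYPES, dg_cell_params), DG_TYPES)
  }
  protos <- stats::setNames(
    lapply(DG_TYPES, function(tp) build_cell(tp, cell_params[[tp]])), DG_TYPES)
  flat <- flatten_cells(as.character(pops$type), protos)
  cell_of <- stats::setNames(seq_len(nrow(pops)), pops$cell)

  # ---- synapse bank -------------------------------------------------------
  missing_refs <- setdiff(unique(network$edges$synapse_ref), synapses$synapse_ref)
  if (length(missing_refs)) {
    stop("no synapse parameters for edge class(es): ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  }
  edges <- network$edges
  bank_comp <- integer(0); bank_ref <- character(0); bank_pre <- integer(0)
  if (nrow(edges)) {
    cls <- synapses[edges$synapse_ref, ]
    post_ci <- cell_of[edges$post]
    pre_ci <- cell_of[edges$pre]
    pre_index <- pops$index[pre_ci]
    nb <- vapply(as.character(pops$type[post_ci]),
                 function(tp) cell_geometry(tp)$n_branch, integer(1))
    branch <- (pre_index %% nb) + 1L
    locs <- mapply(target_comps, cls$target, as.character(pops$type[post_ci]),
                   branch, SIMPLIFY = FALSE)
    nrep <- lengths(locs)
    bank_comp <- flat$offsets[rep(post_ci, nrep)] + unlist(locs)
    bank_ref <- rep(edges$synapse_ref, nrep)
    bank_pre <- rep(pre_ci, nrep)
  }

  # stimulation sites
  stim <- NULL
  stim_times <- numeric(0)
  if (!is.null(protocol)) {
    if (is.null(protocol$spike_file) && protocol$onset >= config$duration) {
      stop("stimulus onset must fall within the simulation window", call. = FALSE)
    }
    stim <- build_stimulation(protocol, network, seed = seed)
    stim_times <- attr(stim, "times")
  }
  stim_comp <- integer(0); stim_ref <- character(0)
  if (!is.null(stim) && nrow(stim)) {
    for (k in seq_len(nrow(stim))) {
      ci <- cell_of[[stim$cell[k]]]
      tp <- stim$type[k]
      ref <- paste0("stim_", tp)
      if (!ref %in% synapses$synapse_ref) {
        stop("no synapse parameters for stimulation class ", ref, call. = FALSE)
      }
      geo <- cell_geometry(tp)
      locs <- unlist(lapply(seq_len(geo$n_branch), function(b) {
        target_comps(synapses[ref, "target"], tp, b)
      }))
      stim_comp <- c(stim_comp, flat$offsets[ci] + locs)
      stim_ref <- c(stim_ref, rep(ref, length(locs)))
    }
  }

  all_comp <- c(bank_comp, stim_comp)
  all_ref <- c(bank_ref, stim_ref)
  nbank <- length(all_comp)
  cls <- synapses[all_ref, ]
  sub <- config$substeps
  hstep <- dt / sub
  eA <- exp(-hstep / cls$tau_rise)
  eB <- exp(-hstep / cls$tau_decay)
  wadd <- cls$gmax * syn_norm_factor(cls$tau_rise, cls$tau_decay)
  Ebank <- cls$e_rev
  delay_b <- cls$delay
  if (any(delay_b < dt)) stop("synaptic delays must be at least dt", call. = FALSE)
  Msyn <- if (nbank) {
    Matrix::sparseMatrix(i = all_comp, j = seq_len(nbank), x = 1,
                         dims = c(flat$ntot, nbank))
  } else NULL

  # per presynaptic cell: bank entries and their delays
  out_idx <- split(seq_along(bank_pre), bank_pre)

  # delivery buckets, preloaded with the stimulus events
  buckets <- vector("list", nsteps + 1L)
  if (length(stim_comp)) {
    stim_bank <- length(bank_comp) + seq_along(stim_comp)
    for (ts in stim_times) {
      ks <- ceiling((ts + delay_b[stim_bank]) / dt - 1e-9)
      for (ku in unique(ks)) {
        if (ku <= nsteps) buckets[[ku]] <- c(buckets[[ku]], stim_bank[ks == ku])
      }
    }
  }

  # injected currents resolved to global compartments
  inj <- NULL
  if (!is.null(inject) && nrow(inject)) {
    ci <- cell_of[inject$cell]
    loc <- mapply(comp_label_to_index, inject$comp,
                  as.character(pops$type[ci]))
    inj <- data.frame(comp = flat$offsets[ci] + loc, amp = inject$amp,
                      t_on = inject$t_on, t_off = inject$t_off)
  }

  # ---- recording ----------------------------------------------------------
  record <- config$record
  if (is.null(record)) {
    rec_cells <- "GC0"
    if (!is.null(stim)) {
      sg <- stim$cell[stim$type == "GC"]
      if (length(sg)) rec_cells <- unique(c(rec_cells, sg[1]))
    }
    record <- do.call(rbind, lapply(rec_cells, function(cc) {
      data.frame(cell = cc, comp = c("soma", paste0("d1s", 1:4)),
                 stringsAsFactors = FALSE)
    }))
  }
  rec_ci <- cell_of[record$cell]
  if (anyNA(rec_ci)) stop("recording refers to unknown cell", call. = FALSE)
  rec_idx <- flat$offsets[rec_ci] +
    mapply(comp_label_to_index, record$comp, as.character(pops$type[rec_ci]))
  rec_names <- paste(record$cell, record$comp, sep = ".")

  # ---- state --------------------------------------------------------------
  ncell <- nrow(pops)
  V <- rep(config$v_init, flat$ntot)
  st <- hh_steady(rep(config$v_init, ncell), flat$shift)
  m <- st$m; h <- st$h; n <- st$n
  A <- numeric(nbank); B <- numeric(nbank)
  soma <- flat$soma_idx
  last_spike <- rep(-Inf, ncell)
  rast_cell <- integer(0); rast_time <- numeric(0)
  traces <- matrix(NA_real_, nrow = nsteps + 1L, ncol = length(rec_idx))
  traces[1L, ] <- V[rec_idx]

  gpasEL <- flat$gpas * flat$EL
  refractory <- 2

  # Per-step coefficients of the membrane equation given a state estimate:
  # total conductance and the conductance-weighted drive of every
  # compartment (leak + axial + synaptic + active Na/K + injection).
  step_coeffs <- function(V, m, h, n, g_syn, t_now) {
    Gtot <- flat$gpas + flat$gax_diag
    U <- gpasEL + as.numeric(flat$Gax %*% V)
    if (nbank) {
      Gtot <- Gtot + as.numeric(Msyn %*% g_syn)
      U <- U + as.numeric(Msyn %*% (g_syn * Ebank))
    }
    gna_t <- flat$gna * m^3 * h
    gk_t <- flat$gk * n^4
    Gtot[soma] <- Gtot[soma] + gna_t + gk_t
    U[soma] <- U[soma] + gna_t * flat$ena + gk_t * flat$ek
    if (!is.null(inj)) {
      on <- inj$t_on < t_now & t_now <= inj$t_off
      for (q in which(on)) U[inj$comp[q]] <- U[inj$comp[q]] + inj$amp[q]
    }
    list(G = Gtot, U = U)
  }

  for (kk in seq_len(nsteps * sub)) {
    t_now <- kk * hstep
    g_mid <- numeric(0)
    if (nbank) {
      # trapezoidal conductance over the substep; events snapped to the dt
      # grid become visible only after the substep that ends on it
      g_prev <- B - A
      A <- A * eA; B <- B * eB
      g_mid <- 0.5 * (g_prev + (B - A))
      if (kk %% sub == 0L) {
        bk <- buckets[[kk %/% sub]]
        if (!is.null(bk)) {
          add <- wadd[bk]
          for (u in seq_along(bk)) { # bk may repeat an entry across sources
            A[bk[u]] <- A[bk[u]] + add[u]
            B[bk[u]] <- B[bk[u]] + add[u]
          }
        }
      }
    }
    Vp_soma <- V[soma]

    # stage 1: exponential Euler with start-of-substep coefficients
    c1 <- step_coeffs(V, m, h, n, g_mid, t_now)
    V1 <- c1$U / c1$G + (V - c1$U / c1$G) * exp(-hstep * c1$G / flat$C)
    r1 <- hh_rates(0.5 * (Vp_soma + V1[soma]), flat$shift)
    m1 <- hh_gate_step(m, r1$am, r1$bm, hstep)
    h1 <- hh_gate_step(h, r1$ah, r1$bh, hstep)
    n1 <- hh_gate_step(n, r1$an, r1$bn, hstep)

    # stage 2: redo the substep with averaged coefficients (midpoint)
    c2 <- step_coeffs(V1, m1, h1, n1, g_mid, t_now)
    Gm <- 0.5 * (c1$G + c2$G)
    Um <- 0.5 * (c1$U + c2$U)
    V <- Um / Gm + (V - Um / Gm) * exp(-hstep * Gm / flat$C)
    r <- hh_rates(0.5 * (Vp_soma + V[soma]), flat$shift)
    m <- hh_gate_step(m, r$am, r$bm, hstep)
    h <- hh_gate_step(h, r$ah, r$bh, hstep)
    n <- hh_gate_step(n, r$an, r$bn, hstep)

    if (anyNA(V) || max(abs(V)) > 200) {
      bad <- which(!is.finite(V) | abs(V) > 200)[1]
      ci <- findInterval(bad, flat$offsets + 1L)
      stop(sprintf("numerical blow-up in cell %s at t = %.1f ms",
                   pops$cell[ci], t_now), call. = FALSE)
    }

    Vn_soma <- V[soma]
    crossed <- which(Vp_soma < 0 & Vn_soma >= 0 & (t_now - last_spike) >= refractory)
    for (ci in crossed) {
      tc <- (t_now - hstep) + hstep * (0 - Vp_soma[ci]) / (Vn_soma[ci] - Vp_soma[ci])
      last_spike[ci] <- tc
      rast_cell <- c(rast_cell, ci)
      rast_time <- c(rast_time, tc)
      oi <- out_idx[[as.character(ci)]]
      if (!is.null(oi)) {
        ks <- ceiling((tc + delay_b[oi]) / dt - 1e-9)
        for (ku in unique(ks)) {
          if (ku <= nsteps) buckets[[ku]] <- c(buckets[[ku]], oi[ks == ku])
        }
      }
    }
    if (kk %% sub == 0L) traces[kk %/% sub + 1L, ] <- V[rec_idx]
  }

  raster <- data.frame(cell = pops$cell[rast_cell],
                       type = as.character(pops$type[rast_cell]),
                       time = rast_time, stringsAsFactors = FALSE)
  raster <- raster[order(raster$time, raster$cell), , drop = FALSE]
  rownames(raster) <- NULL
  tr <- data.frame(time = seq(0, config$duration, by = dt))
  for (j in seq_along(rec_names)) tr[[rec_names[j]]] <- traces[, j]
  counts <- vapply(DG_TYPES, function(tp) sum(raster$type == tp), integer(1))
  structure(
    list(raster = raster, traces = tr, spike_counts = counts,
         stimulated = if (is.null(stim)) character(0) else stim$cell,
         config = config, seed = as.integer(seed), mode = network$mode),
    class = "dg_sim"
  )
}

hh_gate_step <- function(x, a, b, dt) {
  tot <- a + b
  xinf <- a / tot
  xinf + (x - xinf) * exp(-dt * tot)
}

#' @export
print.dg_sim <- function(x, ...) {
  cat(sprintf("<dg_sim> %s network, %g ms at dt %g ms, seed %d\n",
              x$mode, x$config$duration, x$config$dt, x$seed))
  cat(sprintf("  %d spikes (%s); %d stimulated cells; %d recorded traces\n",
              nrow(x$raster),
              paste(sprintf("%s %d", names(x$spike_counts), x$spike_counts),
                    collapse = ", "),
              length(x$stimulated), ncol(x$traces) - 1L))
  invisible(x)
}

#' Simulate a single isolated cell under current clamp
#'
#' Convenience wrapper used by calibration and the single-cell tests: one
#' cell of the given type, no synapses, optional somatic current step.
#'
#' @param type Cell type.
#' @param params Parameter set, defaults to [dg_cell_params()].
#' @param amp Step amplitude (nA) injected at the soma (0 for none).
#' @param t_on,t_off Step window (ms).
#' @param duration,dt Simulation length and step (ms).
#' @param v_init Initial potential (mV); defaults to the cell's rest.
#' @return A `dg_sim` whose traces hold the soma and dendrite-1 sections.
#' @export
simulate_cell <- function(type, params = dg_cell_params(type), amp = 0,
                          t_on = 20, t_off = 80, duration = 100, dt = 0.1,
                          v_init = params$rest) {
  type <- match.arg(type, DG_TYPES)
  counts <- stats::setNames(rep(1L, 4L), DG_TYPES)
  rules <- list()
  net <- generate_network(counts = counts, mode = "healthy", seed = 1L,
                          rules = rules)
  cp <- stats::setNames(lapply(DG_TYPES, dg_cell_params), DG_TYPES)
  cp[[type]] <- params
  cfg <- dg_sim_config(dt = dt, duration = duration, v_init = v_init,
                       record = data.frame(
                         cell = paste0(type, 0),
                         comp = c("soma", paste0("d1s", 1:4)),
                         stringsAsFactors = FALSE))
  inj <- if (amp != 0) {
    data.frame(cell = paste0(type, 0), comp = "soma", amp = amp,
               t_on = t_on, t_off = t_off, stringsAsFactors = FALSE)
  } else NULL
  run_simulation(net, protocol = NULL, config = cfg, cell_params = cp,
                 inject = inj, seed = 1L)
}
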