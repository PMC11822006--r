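#' Biophysical parameters for the subiculum compartmental model
#'
#' Channel and membrane densities: delayed-rectifier potassium uniform at
#' 0.04 S/cm2; voltage-gated sodium 0.09 S/cm2 at the soma and 0.027 S/cm2
#' elsewhere; T-type calcium uniform at 0.03125 mS/cm2; leak 0.003125
#' mS/cm2 within 100 um (path distance) of the soma and 0.00625 mS/cm2
#' elsewhere, with a leak reversal adjustable per cell within [-46, -35]
#' mV; A-type potassium 0.00495 S/cm2 within 50 um of the soma and
#' 0.00495 x (1 + 0.01 xdist) S/cm2 beyond, with radial obliques overridden
#' to 0.0198 S/cm2 everywhere. Specific capacitance and axial resistivity
#' default to the standard 1 uF/cm2 and 150 Ohm cm.
#'
#' @param cm_uf_cm2 specific membrane capacitance (uF/cm2).
#' @param ra_ohm_cm axial resistivity (Ohm cm).
#' @param e_leak_mv leak reversal potential (mV), normally in [-46, -35].
#' @param ... overrides for any density field (S/cm2 unless noted).
#' @return list of class `biophys_params`.
#' @export
biophys_params <- function(cm_uf_cm2 = 1, ra_ohm_cm = 150, e_leak_mv = -40,
                           ...) {
  p <- list(
    cm_uf_cm2 = cm_uf_cm2, ra_ohm_cm = ra_ohm_cm, e_leak_mv = e_leak_mv,
    g_leak_proximal = 0.003125e-3, g_leak_distal = 0.00625e-3,
    leak_boundary_um = 100,
    g_kdr = 0.04,
    g_nav_soma = 0.09, g_nav_other = 0.027,
    g_cat = 0.03125e-3,
    g_ka_prox = 0.00495, ka_slope_per_um = 0.01, ka_boundary_um = 50,
    g_ka_oblique = 0.0198
  )
  override <- list(...)
  bad <- setdiff(names(override), names(p))
  if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
  p[names(override)] <- override
  gfields <- grep("^g_", names(p), value = TRUE)
  if (any(unlist(p[gfields]) < 0)) stopf("conductance densities must be >= 0")
  structure(p, class = "biophys_params")
}

#' Discretize a morphology into compartments
#'
#' Splits every SWC edge into sub-compartments no longer than `max_len_um`.
#' Each compartment records its midpoint path distance from the soma
#' (`xdist_um`), structure type, membrane area (lateral cylinder surface;
#' a single-node soma is treated as a sphere of area 4 pi r^2), and the
#' axial resistance to its parent compartment (half-compartment resistances
#' in series, from `ra` and geometry).
#'
#' @param morph a [neuron_morphology].
#' @param params a [biophys_params] (for `ra_ohm_cm`).
#' @param max_len_um maximum compartment length (default 5).
#' @return data.frame of class `compartments`: one row per compartment with
#'   `parent` (0 for the root), `type`, `xdist_um`, `length_um`,
#'   `radius_um`, `area_cm2`, `r_axial_ohm`.
#' @export
build_compartments <- function(morph, params = biophys_params(),
                               max_len_um = 5) {
  stopifnot(inherits(morph, "neuron_morphology"))
  nodes <- morph$nodes
  ra <- params$ra_ohm_cm
  um <- 1e-4  # cm per um
  half_r <- function(len_um, rad_um) {
    ra * (len_um / 2 * um) / (pi * (rad_um * um)^2)
  }
  root_i <- which(nodes$parent == -1)
  root_area <- if (nodes$type[root_i] == "soma") {
    4 * pi * (nodes$radius[root_i] * um)^2
  } else {
    0  # point junction; membrane lives on the attached cables
  }
  comps <- list(data.frame(parent = 0L, type = nodes$type[root_i],
                           xdist_um = 0, length_um = 0,
                           radius_um = nodes$radius[root_i],
                           area_cm2 = root_area, r_axial_ohm = NA_real_,
                           half_ohm = 0))
  node_comp <- setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  node_comp[as.character(nodes$id[root_i])] <- 1L
  next_id <- 2L
  # process nodes in xdist order so parents are always built first
  for (i in order(nodes$xdist)) {
    if (nodes$parent[i] == -1) next
    pi_ <- match(nodes$parent[i], nodes$id)
    len <- nodes$xdist[i] - nodes$xdist[pi_]
    m <- max(1L, ceiling(len / max_len_um))
    sub_len <- len / m
    prev <- node_comp[as.character(nodes$parent[i])]
    for (s in seq_len(m)) {
      frac <- (s - 0.5) / m
      rad <- nodes$radius[pi_] + frac * (nodes$radius[i] - nodes$radius[pi_])
      r_half <- half_r(sub_len, rad)
      prev_half <- comps[[prev]]$half_ohm
      comps[[next_id]] <- data.frame(
        parent = prev, type = nodes$type[i],
        xdist_um = nodes$xdist[pi_] + frac * len,
        length_um = sub_len, radius_um = rad,
        area_cm2 = 2 * pi * (rad * um) * (sub_len * um),
        r_axial_ohm = prev_half + r_half, half_ohm = r_half)
      prev <- next_id
      next_id <- next_id + 1L
    }
    node_comp[as.character(nodes$id[i])] <- prev
  }
  out <- do.call(rbind, comps)
  out$half_ohm <- NULL
  rownames(out) <- NULL
  class(out) <- c("compartments", class(out))
  out
}

#' Assign channel densities to compartments
#'
#' Applies the density rules: leak by the 100-um path-distance boundary;
#' A-type potassium constant within 50 um and linearly increasing with
#' xdist beyond (with the oblique override applied at any distance);
#' sodium by soma vs. elsewhere; delayed-rectifier potassium and T-type
#' calcium uniform.
#'
#' @param comps a `compartments` data.frame ([build_compartments]).
#' @param params a [biophys_params].
#' @return `comps` with added columns `g_leak`, `g_kdr`, `g_nav`, `g_cat`,
#'   `g_ka` (S/cm2).
#' @export
assign_densities <- function(comps, params = biophys_params()) {
  known <- names(SWC_TYPES)
  if (!all(comps$type %in% known)) {
    stopf("unknown structure type(s): %s",
          paste(setdiff(unique(comps$type), known), collapse = ", "))
  }
  x <- comps$xdist_um
  comps$g_leak <- ifelse(x < params$leak_boundary_um,
                         params$g_leak_proximal, params$g_leak_distal)
  comps$g_kdr <- params$g_kdr
  comps$g_nav <- ifelse(comps$type == "soma", params$g_nav_soma,
                        params$g_nav_other)
  comps$g_cat <- params$g_cat
  g_ka <- ifelse(x < params$ka_boundary_um, params$g_ka_prox,
                 params$g_ka_prox * (1 + params$ka_slope_per_um * x))
  g_ka[comps$type == "oblique"] <- params$g_ka_oblique
  comps$g_ka <- g_ka
  comps
}

# Sparse conductance (Laplacian + membrane) matrix and membrane vectors.
passive_system <- function(comps) {
  n <- nrow(comps)
  g_m <- comps$g_leak * comps$area_cm2  # siemens
  i_idx <- which(comps$parent > 0)
  g_ax <- 1 / comps$r_axial_ohm[i_idx]
  ii <- c(seq_len(n), i_idx, comps$parent[i_idx], i_idx, comps$parent[i_idx])
  jj <- c(seq_len(n), comps$parent[i_idx], i_idx, i_idx, comps$parent[i_idx])
  vv <- c(g_m, -g_ax, -g_ax, g_ax, g_ax)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  list(G = G, g_m = g_m)
}

#' Passive input resistance by steady-state linear solve
#'
#' Assigns leak densities, builds the passive conductance matrix of the
#' compartment tree (axial conductances from `ra` and geometry, membrane
#' leak from densities and areas), injects `i_step_pa` at the soma, and
#' solves the sparse linear system for the steady-state voltage deflection.
#'
#' @param morph a [neuron_morphology].
#' @param params a [biophys_params].
#' @param i_step_pa injected current (default 5 pA; the magnitude cancels
#'   in the resistance).
#' @param max_len_um compartment length limit (default 5 um).
#' @return input resistance at the soma in megaohms; the full deflection
#'   vector is in `attr(, "deflection_mv")`.
#' @export
passive_input_resistance <- function(morph, params = biophys_params(),
                                     i_step_pa = 5, max_len_um = 5) {
  comps <- assign_densities(build_compartments(morph, params, max_len_um),
                            params)
  if (all(comps$area_cm2 * comps$g_leak == 0)) stopf("no membrane leak anywhere")
  sys <- passive_system(comps)
  i_vec <- numeric(nrow(comps))
  i_vec[1] <- i_step_pa * 1e-12
  v <- as.numeric(Matrix::solve(sys$G, i_vec))
  r_in <- v[1] / (i_step_pa * 1e-12) / 1e6
  structure(r_in, deflection_mv = v * 1e3, comps = comps)
}

#' Voltage trace container
#'
#' @param t_ms time vector (ms, uniform dt).
#' @param v_mv somatic voltage (mV).
#' @param i_pa injected step current (pA).
#' @param delay_ms,dur_ms step onset and duration (ms).
#' @return object of class `voltage_trace`.
#' @export
voltage_trace <- function(t_ms, v_mv, i_pa, delay_ms, dur_ms) {
  if (length(t_ms) != length(v_mv)) stopf("t_ms and v_mv lengths differ")
  if (any(!is.finite(v_mv))) stopf("non-finite voltages in trace")
  dts <- diff(t_ms)
  if (length(dts) && diff(range(dts)) > 1e-9 * max(dts)) {
    stopf("time base must be uniform")
  }
  structure(list(t_ms = t_ms, v_mv = v_mv, i_pa = i_pa, delay_ms = delay_ms,
                 dur_ms = dur_ms, dt_ms = if (length(dts)) dts[1] else NA),
            class = "voltage_trace")
}

#' Simulate a somatic current step on the compartment tree
#'
#' Backward-Euler integration of the cable equation with pluggable
#' Hodgkin-Huxley-style channels (see [hh_channel]). With an empty channel
#' list the model is passive and the steady-state somatic deflection
#' converges to the [passive_input_resistance] prediction.
#'
#' @param morph a [neuron_morphology].
#' @param params a [biophys_params].
#' @param channels list of channel objects from [hh_channel] (empty =
#'   passive).
#' @param i_pa step amplitude (default 150 pA).
#' @param dur_ms step duration (default 500 ms).
#' @param delay_ms onset delay (default 50 ms).
#' @param total_ms total simulated time (default `delay_ms + dur_ms + 100`).
#' @param dt_ms time step (default 0.05 ms with channels, 0.5 passive).
#' @param v_init_mv initial voltage (default the leak reversal).
#' @param max_len_um compartment length limit.
#' @return a [voltage_trace] of the somatic voltage.
#' @export
simulate_current_step <- function(morph, params = biophys_params(),
                                  channels = list(), i_pa = 150,
                                  dur_ms = 500, delay_ms = 50,
                                  total_ms = delay_ms + dur_ms + 100,
                                  dt_ms = if (length(channels)) 0.05 else 0.5,
                                  v_init_mv = params$e_leak_mv,
                                  max_len_um = 5) {
  comps <- assign_densities(build_compartments(morph, params, max_len_um),
                            params)
  sys <- passive_system(comps)
  n <- nrow(comps)
  cap <- params$cm_uf_cm2 * 1e-6 * comps$area_cm2  # farads
  if (cap[1] == 0) stopf("soma compartment has zero membrane; cannot inject there")
  n_steps <- ceiling(total_ms / dt_ms)
  t_ms <- (0:n_steps) * dt_ms
  v <- rep(v_init_mv * 1e-3, n)  # volts
  e_leak <- params$e_leak_mv * 1e-3
  # channel state
  ch_states <- lapply(channels, function(ch) ch$init(v * 1e3, comps))
  diag_cap <- cap / (dt_ms * 1e-3)
  M_passive <- sys$G + Matrix::Diagonal(n, diag_cap)
  factor <- if (!length(channels)) Matrix::Cholesky(Matrix::forceSymmetric(M_passive)) else NULL
  v_soma <- numeric(n_steps + 1)
  v_soma[1] <- v[1] * 1e3
  for (s in seq_len(n_steps)) {
    t_now <- s * dt_ms
    inj <- if (t_now > delay_ms && t_now <= delay_ms + dur_ms) i_pa * 1e-12 else 0
    i_vec <- numeric(n)
    i_vec[1] <- inj
    rhs <- diag_cap * v + sys$g_m * e_leak + i_vec
    if (length(channels)) {
      g_extra <- numeric(n)
      for (c_i in seq_along(channels)) {
        ch <- channels[[c_i]]
        ch_states[[c_i]] <- ch$update(ch_states[[c_i]], v * 1e3, dt_ms)
        g <- ch$conductance(ch_states[[c_i]], comps)  # siemens per comp
        g_extra <- g_extra + g
        rhs <- rhs + g * ch$e_rev_mv * 1e-3
      }
      M <- M_passive + Matrix::Diagonal(n, g_extra)
      v <- as.numeric(Matrix::solve(M, rhs))
    } else {
      v <- as.numeric(Matrix::solve(factor, rhs))
    }
    if (any(!is.finite(v))) {
      stopf("integration diverged at t = %.2f ms (dt = %g ms)", t_now, dt_ms)
    }
    v_soma[s + 1] <- v[1] * 1e3
  }
  voltage_trace(t_ms, v_soma, i_pa, delay_ms, dur_ms)
}

#' Tune the leak reversal to a target resting potential
#'
#' Adjusts the leak reversal within the allowed [-46, -35] mV interval
#' until the simulated resting membrane potential is within `tol_mv` of
#' the target (bisection; in a passive model the rest equals the leak
#' reversal exactly). Unattainable targets are clipped to the interval
#' boundary with a warning.
#'
#' @param morph a [neuron_morphology].
#' @param params a [biophys_params].
#' @param target_rmp_mv target resting potential (mV).
#' @param channels channel list (empty = passive).
#' @param tol_mv tolerance (default 0.5 mV).
#' @param settle_ms relaxation time used to measure rest (default 300 ms).
#' @return tuned `e_leak_mv` value.
#' @export
tune_leak_reversal <- function(morph, params = biophys_params(),
                               target_rmp_mv, channels = list(),
                               tol_mv = 0.5, settle_ms = 300) {
  lo <- -46; hi <- -35
  rest_at <- function(e) {
    if (!length(channels)) return(e)
    p <- params; p$e_leak_mv <- e
    tr <- simulate_current_step(morph, p, channels, i_pa = 0, dur_ms = 0,
                                delay_ms = 0, total_ms = settle_ms,
                                v_init_mv = e)
    tail(tr$v_mv, 1)
  }
  if (rest_at(lo) > target_rmp_mv + tol_mv) {
    warnf("target RMP %.1f mV unattainable; clipping e_leak to %.1f mV",
          target_rmp_mv, lo)
    return(lo)
  }
  if (rest_at(hi) < target_rmp_mv - tol_mv) {
    warnf("target RMP %.1f mV unattainable; clipping e_leak to %.1f mV",
          target_rmp_mv, hi)
    return(hi)
  }
  if (!length(channels)) return(target_rmp_mv)
  for (iter in 1:40) {
    mid <- (lo + hi) / 2
    r <- rest_at(mid)
    if (abs(r - target_rmp_mv) <= tol_mv) return(mid)
    if (r < target_rmp_mv) lo <- mid else hi <- mid
  }
  mid
}

# steady-state voltage over the last fraction of the step, with drift check
steady_state_v <- function(trace, frac = 0.1, drift_tol_mv = 0.5) {
  t0 <- trace$delay_ms; t1 <- trace$delay_ms + trace$dur_ms
  idx <- which(trace$t_ms > t1 - frac * trace$dur_ms & trace$t_ms <= t1)
  half <- length(idx) %/% 2
  a <- mean(trace$v_mv[idx[seq_len(half)]])
  b <- mean(trace$v_mv[idx[(half + 1):length(idx)]])
  if (abs(b - a) > drift_tol_mv) {
    stopf("no steady state: drift %.2f mV over the final window", abs(b - a))
  }
  mean(trace$v_mv[idx])
}

#' Spike times by threshold crossing
#'
#' Upward crossings of `threshold_mv` (default 0 mV) with a refractory
#' period.
#'
#' @param trace a [voltage_trace].
#' @param threshold_mv detection threshold (default 0).
#' @param refractory_ms minimum spacing between detected spikes (default 2).
#' @return numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold_mv = 0, refractory_ms = 2) {
  v <- trace$v_mv
  up <- which(v[-1] >= threshold_mv & v[-length(v)] < threshold_mv)
  times <- trace$t_ms[up + 1]
  if (!length(times)) return(numeric(0))
  keep <- times[1]
  for (t in times[-1]) if (t - tail(keep, 1) >= refractory_ms) keep <- c(keep, t)
  keep
}

#' Electrophysiological metrics from a family of current-step traces
#'
#' * Input resistance: steady-state deflection of the small negative step
#'   (current in [-50, -40] pA), as |dV_ss| / |I| in megaohms.
#' * Sag ratio: from the -100 pA trace, (V_ss - V_peak) / (V_peak -
#'   V_baseline), where V_peak is the peak hyperpolarization; larger values
#'   mean larger sag, and a monotone (sag-free) response gives 0.
#' * Rheobase: smallest step current evoking at least one spike.
#' * Input-output curve: spike count per step.
#'
#' @param traces list of [voltage_trace] objects with distinct `i_pa`.
#' @param threshold_mv,refractory_ms spike-detection parameters.
#' @return list with `r_in_mohm`, `sag_ratio`, `rheobase_pa`, `io_curve`
#'   (data.frame `i_pa`, `n_spikes`); metrics whose required step is absent
#'   are NA.
#' @export
trace_metrics <- function(traces, threshold_mv = 0, refractory_ms = 2) {
  stopifnot(length(traces) >= 1)
  i_pa <- vapply(traces, function(x) x$i_pa, numeric(1))
  baseline <- function(tr) mean(tr$v_mv[tr$t_ms < tr$delay_ms])
  r_in <- NA_real_
  i_small <- which(i_pa >= -50 & i_pa <= -40)
  if (length(i_small)) {
    tr <- traces[[i_small[1]]]
    dv <- steady_state_v(tr) - baseline(tr)
    r_in <- abs(dv) / abs(tr$i_pa) * 1000  # mV/pA -> MOhm
  }
  sag <- NA_real_
  i_sag <- which(i_pa == -100)
  if (length(i_sag)) {
    tr <- traces[[i_sag[1]]]
    during <- tr$t_ms > tr$delay_ms & tr$t_ms <= tr$delay_ms + tr$dur_ms
    v_peak <- min(tr$v_mv[during])
    v_ss <- steady_state_v(tr)
    v_base <- baseline(tr)
    sag <- (v_ss - v_peak) / (v_peak - v_base)
  }
  io <- data.frame(i_pa = i_pa,
                   n_spikes = vapply(traces, function(tr) {
                     length(detect_spikes(tr, threshold_mv, refractory_ms))
                   }, numeric(1)))
  io <- io[order(io$i_pa), ]
  rownames(io) <- NULL
  spiking <- io$i_pa[io$n_spikes >= 1 & io$i_pa > 0]
  list(r_in_mohm = r_in, sag_ratio = sag,
       rheobase_pa = if (length(spiking)) min(spiking) else NA_real_,
       io_curve = io)
}
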