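#' Hodgkin-Huxley-style channel plug-in
#'
#' Gating kinetics are pluggable: a channel is defined by the density
#' column it draws from (`density_col`, one of the columns produced by
#' [assign_densities]), a reversal potential, and a list of gates, each
#' with an integer `power`, a steady-state function `inf(v_mv)` and a time
#' constant function `tau_ms(v_mv)` (both vectorized over compartments).
#' Gates relax toward their steady state with exponential-Euler updates;
#' the conductance is `gbar * prod(gate^power) * area`.
#'
#' @param name channel name.
#' @param density_col column of the density table holding gbar (S/cm2),
#'   e.g. `"g_nav"`.
#' @param e_rev_mv reversal potential (mV).
#' @param gates list of gates, each `list(power =, inf =, tau_ms =)`.
#' @return object of class `hh_channel` with `init`, `update`,
#'   `conductance` closures, usable by [simulate_current_step].
#' @export
hh_channel <- function(name, density_col, e_rev_mv, gates) {
  force(name); force(density_col); force(e_rev_mv); force(gates)
  structure(list(
    name = name, density_col = density_col, e_rev_mv = e_rev_mv,
    gates = gates,
    init = function(v_mv, comps) {
      lapply(gates, function(g) g$inf(v_mv))
    },
    update = function(state, v_mv, dt_ms) {
      lapply(seq_along(gates), function(i) {
        inf <- gates[[i]]$inf(v_mv)
        tau <- pmax(gates[[i]]$tau_ms(v_mv), 1e-3)
        inf + (state[[i]] - inf) * exp(-dt_ms / tau)
      })
    },
    conductance = function(state, comps) {
      open <- rep(1, nrow(comps))
      for (i in seq_along(gates)) open <- open * state[[i]]^gates[[i]]$power
      comps[[density_col]] * comps$area_cm2 * open
    }
  ), class = "hh_channel")
}

sigmoid <- function(v, v_half, k) 1 / (1 + exp(-(v - v_half) / k))

#' Example channel set with generic hippocampal-style kinetics
#'
#' Builds transient sodium (m^3 h), delayed-rectifier potassium (n^4),
#' A-type potassium (a b) and T-type calcium (s^2 u) channels with simple
#' sigmoidal steady states and voltage-dependent time constants. The
#' kinetics are illustrative defaults for exploring firing behaviour; the
#' density rules come from [assign_densities] and any gate model can be
#' swapped in via [hh_channel].
#'
#' @return list of [hh_channel] objects.
#' @export
default_channels <- function() {
  list(
    hh_channel("nav", "g_nav", e_rev_mv = 55, gates = list(
      list(power = 3, inf = function(v) sigmoid(v, -35, 6),
           tau_ms = function(v) 0.1 + 0 * v),
      list(power = 1, inf = function(v) sigmoid(v, -60, -6),
           tau_ms = function(v) 1 + 7 * exp(-((v + 60) / 20)^2))
    )),
    hh_channel("kdr", "g_kdr", e_rev_mv = -90, gates = list(
      list(power = 4, inf = function(v) sigmoid(v, -30, 10),
           tau_ms = function(v) 1 + 4 * exp(-((v + 30) / 30)^2))
    )),
    hh_channel("ka", "g_ka", e_rev_mv = -90, gates = list(
      list(power = 1, inf = function(v) sigmoid(v, -30, 15),
           tau_ms = function(v) 0.5 + 0 * v),
      list(power = 1, inf = function(v) sigmoid(v, -70, -6),
           tau_ms = function(v) 5 + 20 * exp(-((v + 60) / 30)^2))
    )),
    hh_channel("cat", "g_cat", e_rev_mv = 120, gates = list(
      list(power = 2, inf = function(v) sigmoid(v, -50, 6),
           tau_ms = function(v) 2 + 0 * v),
      list(power = 1, inf = function(v) sigmoid(v, -75, -5),
           tau_ms = function(v) 20 + 0 * v)
    ))
  )
}
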