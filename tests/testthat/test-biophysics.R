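test_that("SWC round-trips and rejects malformed trees", {
  chain <- data.frame(id = 1:3, type = c("soma", "basal", "basal"),
                      x = c(0, 0, 0), y = c(0, 3, 7), z = 0,
                      radius = c(5, 1, 1), parent = c(-1, 1, 2))
  m <- neuron_morphology(chain)
  expect_equal(m$nodes$xdist, c(0, 3, 7))
  path <- tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(m2$nodes, m$nodes)

  bad <- chain; bad$parent[3] <- 99
  expect_error(neuron_morphology(bad), "missing node")
  bad2 <- chain; bad2$radius[2] <- 0
  expect_error(neuron_morphology(bad2), "radius")
  bad3 <- chain; bad3$parent[1] <- 3
  expect_error(neuron_morphology(bad3), "root|cycle")

  # oblique sidecar relabelling
  sidecar <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 3), sidecar, row.names = FALSE)
  m3 <- read_swc(path, oblique_ids = sidecar)
  expect_equal(m3$nodes$type[3], "oblique")
})

test_that("oblique pruning removes whole subtrees and membrane area", {
  pyr <- generate_morphology("pyramidal_like")
  pruned <- suppressWarnings(prune_obliques(pyr))
  expect_false(any(pruned$nodes$type == "oblique"))
  p <- biophys_params()
  a_full <- sum(build_compartments(pyr, p)$area_cm2)
  a_pruned <- sum(build_compartments(pruned, p)$area_cm2)
  expect_lt(a_pruned, a_full)
  expect_warning(same <- prune_obliques(pruned), "no oblique")
  expect_identical(same, pruned)
})

test_that("density rules follow xdist, structure type, and oblique override", {
  pyr <- generate_morphology("pyramidal_like")
  p <- biophys_params()
  comps <- assign_densities(build_compartments(pyr, p), p)
  soma <- comps[comps$type == "soma", ]
  expect_equal(soma$g_nav, 0.09)
  expect_true(all(comps$g_nav[comps$type != "soma"] == 0.027))
  expect_true(all(comps$g_kdr == 0.04))
  expect_true(all(comps$g_cat == 0.03125e-3))
  # A-type K: flat proximal, linear distal, oblique override
  prox <- comps$type != "oblique" & comps$xdist_um < 50
  expect_true(all(comps$g_ka[prox] == 0.00495))
  dist <- comps$type != "oblique" & comps$xdist_um >= 50
  expect_equal(comps$g_ka[dist],
               0.00495 * (1 + 0.01 * comps$xdist_um[dist]))
  expect_true(all(comps$g_ka[comps$type == "oblique"] == 0.0198))
  # printed-value arithmetic at xdist = 200 um
  i200 <- which.min(abs(comps$xdist_um - 200))
  expect_equal(0.00495 * (1 + 0.01 * 200), 0.01485)
  # leak split at 100 um
  expect_true(all(comps$g_leak[comps$xdist_um < 100] == 0.003125e-3))
  expect_true(all(comps$g_leak[comps$xdist_um >= 100] == 0.00625e-3))
})

test_that("passive input resistance matches closed-form cable theory", {
  p <- biophys_params()
  # isopotential sphere: R = 1 / (g A)
  sph <- generate_morphology("soma_only", soma_radius_um = 10)
  r_sph <- as.numeric(passive_input_resistance(sph, p))
  r_true <- 1 / (p$g_leak_proximal * 4 * pi * (10e-4)^2) / 1e6
  expect_lt(abs(r_sph - r_true) / r_true, 0.001)

  # sealed-end cylinder: R = R_inf coth(L / lambda), uniform leak
  pu <- biophys_params(g_leak_proximal = 0.00625e-3)
  L <- 1000; d <- 2
  cyl <- generate_morphology("cylinder", length_um = L, diameter_um = d)
  r_cyl <- as.numeric(passive_input_resistance(cyl, pu))
  R_m <- 1 / 0.00625e-3
  a_cm <- d / 2 * 1e-4
  lambda <- sqrt(R_m * a_cm / (2 * pu$ra_ohm_cm))
  r_inf <- sqrt((R_m / (pi * d * 1e-4)) * (pu$ra_ohm_cm / (pi * a_cm^2)))
  r_true <- r_inf / tanh(L * 1e-4 / lambda) / 1e6
  expect_lt(abs(r_cyl - r_true) / r_true, 0.01)

  # pruning obliques strictly increases input resistance
  pyr <- generate_morphology("pyramidal_like")
  r_full <- as.numeric(passive_input_resistance(pyr, p))
  r_pruned <- as.numeric(passive_input_resistance(
    suppressWarnings(prune_obliques(pyr)), p))
  expect_gt(r_pruned, r_full)

  # current conservation at steady state
  r_obj <- passive_input_resistance(pyr, p, i_step_pa = 5)
  comps <- assign_densities(build_compartments(pyr, p), p)
  v <- attr(r_obj, "deflection_mv") * 1e-3
  leak_sum <- sum(comps$g_leak * comps$area_cm2 * v)
  expect_lt(abs(leak_sum - 5e-12) / 5e-12, 0.001)
})

test_that("transient simulation converges to the steady-state solve", {
  p <- biophys_params()
  pyr <- generate_morphology("pyramidal_like")
  r_in <- as.numeric(passive_input_resistance(pyr, p))
  tr <- simulate_current_step(pyr, p, i_pa = 5, dur_ms = 2000, delay_ms = 10,
                              total_ms = 2050, dt_ms = 0.5)
  dv <- tr$v_mv[which.min(abs(tr$t_ms - 2010))] - p$e_leak_mv
  dv_pred <- r_in * 5 * 1e-3  # MOhm * pA -> mV
  expect_lt(abs(dv - dv_pred) / dv_pred, 0.01)

  # halving dt barely changes the endpoint (first-order convergence)
  sph <- generate_morphology("soma_only")
  t1 <- simulate_current_step(sph, p, i_pa = 5, dur_ms = 400, delay_ms = 10,
                              total_ms = 420, dt_ms = 0.4)
  t2 <- simulate_current_step(sph, p, i_pa = 5, dur_ms = 400, delay_ms = 10,
                              total_ms = 420, dt_ms = 0.2)
  v1 <- tail(t1$v_mv, 1); v2 <- tail(t2$v_mv, 1)
  expect_lt(abs(v1 - v2) / abs(v2 - p$e_leak_mv), 0.001)

  # zero current: flat at rest
  t0 <- simulate_current_step(sph, p, i_pa = 0, dur_ms = 100, delay_ms = 10,
                              total_ms = 150)
  expect_true(all(abs(t0$v_mv - p$e_leak_mv) < 1e-9))
})

test_that("active channels produce spikes under a strong step", {
  sph <- generate_morphology("soma_only", soma_radius_um = 10)
  p <- biophys_params()
  tr <- simulate_current_step(sph, p, channels = default_channels(),
                              i_pa = 150, dur_ms = 200, delay_ms = 20,
                              total_ms = 250, dt_ms = 0.025)
  expect_gt(length(detect_spikes(tr)), 0)
})

test_that("leak-reversal tuning respects the allowed interval", {
  sph <- generate_morphology("soma_only")
  p <- biophys_params()
  expect_equal(tune_leak_reversal(sph, p, target_rmp_mv = -40), -40)
  expect_warning(lo <- tune_leak_reversal(sph, p, target_rmp_mv = -65),
                 "clipping")
  expect_equal(lo, -46)
  expect_warning(hi <- tune_leak_reversal(sph, p, target_rmp_mv = -10),
                 "clipping")
  expect_equal(hi, -35)
})

test_that("trace metrics recover constructed electrophysiology", {
  fam <- list(
    make_rc_trace(-50), make_rc_trace(-100), make_rc_trace(20),
    make_rc_trace(60), make_rc_trace(100)
  )
  # add spikes (brief excursions above 0 mV) to the 60 and 100 pA traces
  spike_at <- function(tr, times_ms) {
    for (tm in times_ms) tr$v_mv[which.min(abs(tr$t_ms - tm))] <- 30
    tr
  }
  fam[[4]] <- spike_at(fam[[4]], c(200, 300))
  fam[[5]] <- spike_at(fam[[5]], c(150, 200, 250, 300))
  met <- trace_metrics(fam)
  expect_equal(met$r_in_mohm, 200, tolerance = 0.01)
  expect_equal(met$sag_ratio, 0, tolerance = 1e-6)  # monotone: no sag
  expect_equal(met$rheobase_pa, 60)
  expect_equal(met$io_curve$n_spikes[met$io_curve$i_pa == 100], 4)

  # refractory period merges crossings closer than 2 ms
  t <- seq(0, 10, by = 0.1)
  v <- rep(-70, length(t)); v[c(30, 32, 80)] <- 10
  tr <- voltage_trace(t, v, 100, 0, 10)
  expect_equal(length(detect_spikes(tr)), 2)
})
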