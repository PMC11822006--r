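test_that("behavior generator is deterministic and confined to the arena", {
  cfg <- synth_config(seed = 1, duration_s = 60,
                      cell_specs = list(cell_spec("untuned")))
  a <- generate_behavior_track(cfg)
  b <- generate_behavior_track(cfg)
  expect_identical(a, b)
  r2 <- a$track$x_cm^2 + a$track$y_cm^2
  expect_true(all(r2 <= 30^2 + 1e-9))
  expect_error(synth_config(seed = 1, duration_s = -5), "positive")
  expect_error(synth_config(seed = 1, fs_hz = 0), "positive")
})

test_that("forced dwell plants exact interaction times", {
  cfg <- synth_config(seed = 2, duration_s = 120,
                      cell_specs = list(cell_spec("untuned")),
                      forced_dwell_s = c(A = 45, B = 15))
  beh <- generate_behavior_track(cfg)
  dur <- tapply(beh$bouts$end_s - beh$bouts$start_s, beh$bouts$object_id, sum)
  expect_equal(unname(dur[["A"]]), 45)
  expect_equal(unname(dur[["B"]]), 15)
  expect_equal(discrimination_index(beh$bouts)$di, 0.5)
})

test_that("calcium generator is deterministic, NaN-free, and labelled", {
  cfg <- synth_config(seed = 4, duration_s = 60, cell_specs = list(
    cell_spec("object_responder"), cell_spec("place"), cell_spec("speed"),
    cell_spec("untuned")))
  beh <- generate_behavior_track(cfg)
  r1 <- generate_calcium_recording(beh$track, beh$bouts, cfg)
  r2 <- generate_calcium_recording(beh$track, beh$bouts, cfg)
  expect_identical(r1$recording$C, r2$recording$C)
  expect_false(anyNA(r1$recording$C))
  expect_true(all(r1$recording$S %in% c(0, 1)))
  expect_equal(r1$truth$label,
               c("object_responder", "place", "speed", "untuned"))
  # mismatched track length is an alignment error
  short <- behavior_track(beh$track$t_s[1:100], beh$track$x_cm[1:100],
                          beh$track$y_cm[1:100], fs = 20)
  expect_error(generate_calcium_recording(short, beh$bouts, cfg),
               "does not cover")
})

test_that("adding cells does not perturb earlier cells or the track", {
  base <- list(cell_spec("place"), cell_spec("untuned"))
  cfg1 <- synth_config(seed = 5, duration_s = 30, cell_specs = base)
  cfg2 <- synth_config(seed = 5, duration_s = 30,
                       cell_specs = c(base, list(cell_spec("speed"))))
  b1 <- generate_behavior_track(cfg1)
  b2 <- generate_behavior_track(cfg2)
  expect_identical(b1$track, b2$track)
  r1 <- generate_calcium_recording(b1$track, b1$bouts, cfg1)
  r2 <- generate_calcium_recording(b2$track, b2$bouts, cfg2)
  expect_identical(r1$recording$C[1:2, ], r2$recording$C[1:2, ])
})

test_that("synthetic image plants separated cells with known geometry", {
  img <- generate_cell_image(image_config(seed = 6, n_a = 6, n_b = 6,
                                          n_inhibitory = 2,
                                          image_size_px = 300))
  tr <- img$truth
  n <- nrow(tr)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((tr$center_x_um[i] - tr$center_x_um[j])^2 +
                (tr$center_y_um[i] - tr$center_y_um[j])^2)
      expect_gte(d, tr$semi_major_um[i] + tr$semi_major_um[j] + 2)
    }
  }
  # soma masks never overlap: every labelled pixel has exactly one id
  expect_true(all(img$cell_labels %in% 0:n))
  # planted ellipse geometry flows through shape_features
  sf <- shape_features(ellipse_polygon(c(0, 0), 6, 3, angle = 0),
                       alveus_angle = 0)
  expect_equal(sf$alveus_aspect_ratio, 0.5, tolerance = 1e-3)
  expect_equal(sf$width_um, 12, tolerance = 1e-3)
})

test_that("projection generator plants an ATN-dominant cluster", {
  p1 <- generate_projection_profiles(seed = 7)
  p2 <- generate_projection_profiles(seed = 7)
  expect_identical(p1, p2)
  expect_true(all(p1$lengths >= 0))
  dom <- p1$lengths[p1$truth == 1L, , drop = FALSE]
  expect_true(all(dom[, "ATN"] / rowSums(dom) >= 0.95))
  expect_error(generate_projection_profiles(seed = 1, regions = "ATN"),
               "2 regions")
})

test_that("morphology kinds are valid trees with analytic geometry", {
  cyl <- generate_morphology("cylinder", length_um = 1000, diameter_um = 2)
  expect_equal(sum(cyl$nodes$parent == -1), 1)
  comps <- build_compartments(cyl, biophys_params())
  area <- sum(comps$area_cm2)
  expect_equal(area, pi * 2e-4 * 1000e-4, tolerance = 1e-3)

  pyr <- generate_morphology("pyramidal_like")
  obl <- generate_morphology("obliqueless")
  pruned <- suppressWarnings(prune_obliques(pyr))
  expect_identical(obl, pruned)
  expect_false(any(obl$nodes$type == "oblique"))
  expect_error(generate_morphology("banana"))

  # acyclic and connected: xdist defined everywhere
  expect_false(anyNA(pyr$nodes$xdist))
})
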