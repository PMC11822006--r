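test_that("z-scoring normalizes per cell and rejects constant traces", {
  Z <- zscore_traces(matrix(c(0, 2, 0, 2), 1))
  expect_equal(as.numeric(Z), c(-1, 1, -1, 1))
  M <- matrix(rnorm(5 * 100, mean = 3, sd = 2), 5)
  Z <- zscore_traces(M)
  expect_true(all(abs(rowMeans(Z)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(Z^2)) - 1) < 1e-12))
  expect_error(zscore_traces(rbind(M[1, ], rep(7, 100))), "constant")
})

test_that("global dF/F follows (C - F) / F", {
  Fv <- c(2, 5)
  C <- rbind(rep(2, 10), rep(10, 10))
  rec <- calcium_recording(C, fs = 20)
  d <- global_dff(rec, baseline = Fv)
  expect_equal(d[1, ], rep(0, 10))
  expect_equal(d[2, ], rep(1, 10))
  expect_error(global_dff(rec, baseline = c(0, 5)), "positive")
})

test_that("local dF/F response uses the 10 s pre / 20 s post windows", {
  fs <- 10; n <- 600
  C <- matrix(1, 2, n)
  # cell 2 steps from 1.0 to 1.5 at t = 30 s
  C[2, (30 * fs + 1):n] <- 1.5
  rec <- calcium_recording(C, fs = fs)
  bouts <- data.frame(start_s = 30, end_s = 32, object_id = "A",
                      object_class = "novel")
  resp <- local_dff_response(rec, bouts)
  expect_equal(unname(resp[1, 1]), 0)
  expect_equal(unname(resp[2, 1]), 0.5)
  early <- data.frame(start_s = 2, end_s = 4, object_id = "A",
                      object_class = "novel")
  expect_error(suppressWarnings(local_dff_response(rec, early)), "no bouts")
  both <- rbind(early, bouts)
  expect_warning(local_dff_response(rec, both), "dropped")
})

test_that("peri-event delta-Z is baseline-anchored and averages correctly", {
  fs <- 10; n <- 2000
  Z <- matrix(0, 1, n)
  bouts <- data.frame(start_s = c(60, 120), end_s = c(62, 122),
                      object_id = "A", object_class = "novel")
  pe <- peri_event_deltaz(Z, bouts, fs = fs)
  expect_true(all(pe$delta_z == 0))

  # planted +1 step at each onset
  Zs <- Z
  for (t0 in bouts$start_s) {
    Zs[1, (t0 * fs + 1):((t0 + 30) * fs)] <- 1
  }
  pe <- peri_event_deltaz(Zs, bouts, fs = fs)
  post <- pe$bin_centers_s > 0
  expect_true(all(abs(pe$delta_z[1, , post] - 1) < 1e-12))
  # pre-window bins average to zero by construction
  pre <- pe$bin_centers_s < 0
  expect_true(all(abs(apply(pe$delta_z[1, , pre, drop = FALSE], 2, mean)) < 1e-12))
  # two identical events average to either event
  expect_equal(pe$class_average$novel[1, ], pe$delta_z[1, 1, ])
})

test_that("responder criterion honors amplitude and duration boundaries", {
  fs <- 20; n <- 4000
  onset_s <- 100
  bouts <- data.frame(start_s = onset_s, end_s = onset_s + 2,
                      object_id = "A", object_class = "novel")
  cases <- expand.grid(amp = c(0.2, 0.25, 0.5), dur = c(5, 10, 15))
  Z <- matrix(0, nrow(cases), n)
  for (r in seq_len(nrow(cases))) {
    k0 <- onset_s * fs + 1
    Z[r, k0:(k0 + cases$dur[r] * fs - 1)] <- cases$amp[r]
  }
  res <- classify_responders(Z, bouts, fs = fs)
  expected <- cases$amp >= 0.25 & cases$dur >= 10
  expect_equal(unname(res$flags[, "novel"]), expected)

  # monotone in threshold and duration
  stricter_thr <- classify_responders(Z, bouts, fs = fs, threshold = 0.3)
  stricter_dur <- classify_responders(Z, bouts, fs = fs, min_duration_s = 12)
  expect_true(all(stricter_thr$flags[, 1] <= res$flags[, 1]))
  expect_true(all(stricter_dur$flags[, 1] <= res$flags[, 1]))

  expect_error(classify_responders(Z, bouts, fs = fs, window_s = 5),
               "min_duration_s")
})

test_that("peak percentile is 100 for the session's dominant transient", {
  fs <- 20; n <- 300 * fs
  z <- rep(0, n)
  z[150 * fs + 5] <- 10  # single spike inside the trial window
  bouts <- data.frame(start_s = 150, end_s = 152, object_id = "A",
                      object_class = "novel")
  pp <- peak_percentile_statistic(matrix(z, 1), bouts, fs = fs)
  expect_equal(unname(pp$percentiles[1, 1]), 100)
  short <- matrix(rnorm(60), 1)
  expect_error(peak_percentile_statistic(short, bouts, fs = 1), "null windows")
})

test_that("peak percentile is invariant to per-cell affine trace rescaling", {
  set.seed(11)
  fs <- 20; n <- 200 * fs
  C <- matrix(rnorm(2 * n, 5, 2), 2)
  bouts <- data.frame(start_s = c(60, 120), end_s = c(62, 122),
                      object_id = "A", object_class = "novel")
  p1 <- peak_percentile_statistic(zscore_traces(C), bouts, fs = fs)
  p2 <- peak_percentile_statistic(zscore_traces(3 * C + 10), bouts, fs = fs)
  expect_equal(p1$percentiles, p2$percentiles, tolerance = 1e-12)
})

test_that("ensemble overlap uses the overlap coefficient", {
  ov <- ensemble_overlap(list(s1 = c(1, 2, 3), s2 = c(1, 2, 3)))
  expect_equal(ov["s1", "s2"], 1)
  expect_equal(ensemble_overlap(list(1:3, 4:6))[1, 2], 0)
  expect_equal(ensemble_overlap(list(1:2, 1:10))[1, 2], 1)  # subset
  expect_true(is.na(ensemble_overlap(list(integer(0), 1:3))[1, 2]))
  expect_error(ensemble_overlap(list(1:3)), "2 segments")
})

test_that("planted responders in generated sessions are recovered", {
  cfg <- synth_config(seed = 31, duration_s = 300, cell_specs = c(
    replicate(10, cell_spec("object_responder"), simplify = FALSE),
    replicate(10, cell_spec("untuned"), simplify = FALSE)))
  beh <- generate_behavior_track(cfg)
  nov <- c(30, 90, 150, 210)
  bouts <- parse_interactions(data.frame(
    start_s = c(nov, nov + 30), end_s = c(nov, nov + 30) + 3,
    object_id = rep(c("A", "B"), each = 4),
    object_class = rep(c("novel", "familiar"), each = 4)))
  rec <- generate_calcium_recording(beh$track, bouts, cfg)
  Z <- zscore_traces(rec$recording)
  res <- classify_responders(Z, bouts, fs = rec$recording$fs)
  expect_true(all(res$flags[1:10, "novel"]))
})
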