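test_that("mutual information matches hand-computed joint tables", {
  # independence: joint = outer product of marginals
  joint <- outer(c(0.2, 0.3, 0.5), c(0.6, 0.4))
  expect_equal(mutual_information_from_joint(joint), 0)
  # 2 equi-occupied bins, spikes only in bin 1: exactly 1 bit
  joint2 <- rbind(c(0, 0.5), c(0.5, 0))
  expect_equal(mutual_information_from_joint(joint2), 1)
  expect_error(mutual_information_from_joint(matrix(0, 2, 2)), "zero")
})

test_that("series-based spatial MI reproduces the joint-table value", {
  # alternate between two spatial bins; spike iff in bin 1
  n <- 400
  x <- rep(c(-15, 15), n / 2)
  y <- rep(0, n)
  tr <- behavior_track(t_s = seq_len(n) - 1, x_cm = x, y_cm = y, fs = 1)
  s <- rep(c(1, 0), n / 2)
  mi <- spatial_mutual_information(s, tr)
  expect_equal(mi$mi_bits, 1)
  # independent signal gives (near-)zero MI on the constructed table
  s_ind <- rep(c(1, 1, 0, 0), n / 4)  # spikes half the time in each bin
  expect_equal(spatial_mutual_information(s_ind, tr)$mi_bits, 0)
  expect_error(spatial_mutual_information(s[1:10], tr), "lengths")
})

test_that("plug-in MI agrees with the double-loop oracle on random tables", {
  set.seed(42)
  for (rep in 1:25) {
    nb <- sample(2:20, 1)
    nk <- sample(2:4, 1)
    joint <- matrix(rexp(nb * nk), nb, nk)
    joint[sample(length(joint), nb)] <- 0  # sprinkle structural zeros
    expect_lt(abs(mutual_information_from_joint(joint) - mi_oracle(joint)),
              1e-12)
  }
})

test_that("MI is non-negative, bounded by marginal entropies, relabel-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    joint <- matrix(rexp(12 * 2), 12, 2)
    mi <- mutual_information_from_joint(joint)
    p <- joint / sum(joint)
    hx <- -sum(rowSums(p) * log2(rowSums(p)))
    hk <- -sum(colSums(p) * log2(colSums(p)))
    expect_gte(mi, -1e-14)
    expect_lte(mi, min(hx, hk) + 1e-12)
    perm <- sample(nrow(joint))
    expect_equal(mutual_information_from_joint(joint[perm, ]), mi)
  }
})

test_that("circular-shift null rotates only the signal with bounded offsets", {
  set.seed(8)
  n <- 1000; fs <- 10
  sig <- rnorm(n)
  cov <- rnorm(n)
  sn <- circular_shift_null(function(s, c) cor(s, c), sig, cov, fs = fs,
                            n_shuffles = 500, min_offset_s = 10, seed = 1)
  expect_equal(sn$observed, cor(sig, cov))
  expect_length(sn$null, 500)
  expect_true(all(sn$offsets >= 10 * fs))
  expect_true(all(sn$offsets <= n - 10 * fs))
  # constant signal: every shuffle equals the observed statistic
  cn <- circular_shift_null(function(s, c) mean(s * c), rep(2, n), cov,
                            fs = fs, n_shuffles = 20, seed = 1)
  expect_true(all(cn$null == cn$observed))
  expect_error(circular_shift_null(function(s, c) 0, sig, cov, fs = fs,
                                   n_shuffles = 0), "at least 1")
})

test_that("place-cell flags apply the strict 95% rule", {
  obs_hi <- shuffle_null(observed = 2, null = runif(500), offsets = 1:500)
  obs_med <- shuffle_null(observed = 0.5, null = seq(0, 1, length.out = 500),
                          offsets = 1:500)
  flags <- classify_place_cells(list(obs_hi, obs_med))
  expect_equal(flags, c(TRUE, FALSE))
  expect_error(classify_place_cells(list(1)), "invalid")
})

test_that("speed tuning is two-sided and exact on constructed traces", {
  set.seed(9)
  n <- 3000; fs <- 10
  speed <- abs(rnorm(n)) + 0.1
  st <- speed_tuning(speed, speed, fs = fs, n_shuffles = 200, seed = 2)
  expect_equal(st$statistic, 1)
  expect_true(st$flag)
  neg <- speed_tuning(-speed, speed, fs = fs, n_shuffles = 200, seed = 2)
  expect_equal(neg$statistic, -1)
  expect_true(neg$flag)  # two-sided criterion catches negative tuning
  expect_error(speed_tuning(rep(1, n), speed, fs = fs), "zero-variance")
})

test_that("mobility tuning normalizes by immobile activity", {
  n <- 2000; fs <- 10
  mob <- rep(c(TRUE, FALSE), n / 2)
  trace <- ifelse(mob, 2, 1)
  mt <- mobility_tuning(trace + rnorm(n, 0, 1e-6), mob, fs = fs,
                        n_shuffles = 100, seed = 3)
  expect_equal(mt$statistic, 1, tolerance = 1e-4)
  same <- mobility_tuning(rep(1, n) + rnorm(n, 0, 1e-9), mob, fs = fs,
                          n_shuffles = 50, seed = 3)
  expect_equal(same$statistic, 0, tolerance = 1e-6)
  expect_error(mobility_tuning(trace, rep(TRUE, n), fs = fs), "both mobility")
})

test_that("planted speed cells are recovered across seeds", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- synth_config(seed = seed, duration_s = 120,
                        cell_specs = list(cell_spec("speed", gain = 0.5)))
    beh <- generate_behavior_track(cfg)
    rec <- generate_calcium_recording(beh$track, beh$bouts, cfg)
    sp <- compute_speed(beh$track)
    st <- speed_tuning(rec$recording$C[1, ], sp, fs = 20, n_shuffles = 200,
                       seed = seed)
    hits <- hits + st$flag
  }
  expect_gte(hits, 9)
})
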