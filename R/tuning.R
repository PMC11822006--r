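#' Plug-in mutual information from a joint table
#'
#' Computes I = sum_ik P_ik * log2(P_ik / (P_i * P_k)) from a joint
#' count or probability table, with the 0 * log 0 = 0 convention and
#' empty rows/columns excluded. This is the estimator underlying
#' [spatial_mutual_information]; it is exposed so it can be checked against
#' independent implementations.
#'
#' @param joint matrix of joint counts or probabilities (bins x states).
#' @return mutual information in bits.
#' @export
mutual_information_from_joint <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stopf("joint table must be non-negative")
  tot <- sum(joint)
  if (tot <= 0) stopf("joint table sums to zero")
  p <- joint / tot
  px <- rowSums(p)
  pk <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (px[nz[, 1]] * pk[nz[, 2]])))
}

#' Spatial bin specification
#'
#' A square grid over the arena bounding box. Bins never visited are
#' excluded from the occupancy histogram.
#'
#' @param nx,ny number of bins along x and y (default 10 x 10).
#' @param arena_diameter_cm arena diameter (grid spans the bounding square).
#' @return list of class `bin_spec`.
#' @export
spatial_bins <- function(nx = 10, ny = 10, arena_diameter_cm = 60) {
  assert_scalar_pos(nx, "nx"); assert_scalar_pos(ny, "ny")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 arena_diameter_cm = arena_diameter_cm),
            class = "bin_spec")
}

# Map positions to 1..(nx*ny) bin indices over the arena bounding square.
position_bin_index <- function(x_cm, y_cm, bin_spec) {
  half <- bin_spec$arena_diameter_cm / 2
  ix <- pmin(pmax(floor((x_cm + half) / (2 * half) * bin_spec$nx), 0),
             bin_spec$nx - 1L)
  iy <- pmin(pmax(floor((y_cm + half) / (2 * half) * bin_spec$ny), 0),
             bin_spec$ny - 1L)
  as.integer(iy * bin_spec$nx + ix + 1L)
}

#' Spatial mutual information of a binarized spiking signal
#'
#' Mutual information (bits) between binned spatial position X and the
#' discrete signal K (binarized deconvolved spikes; any discrete signal is
#' accepted), from the plug-in joint histogram:
#' I_pos = sum_i sum_k P(x_i, k) log2(P(x_i, k) / (P(x_i) P(k))).
#'
#' @param s_cell signal vector (0/1 spikes, or any small set of discrete
#'   values), aligned sample-by-sample with the positions.
#' @param track a [behavior_track], or a list/data.frame with `x_cm`,
#'   `y_cm`.
#' @param bin_spec a [spatial_bins] specification.
#' @return list with `mi_bits` and `occupancy` (P_x over occupied bins,
#'   P_k, and the joint P_xk).
#' @export
spatial_mutual_information <- function(s_cell, track, bin_spec = spatial_bins()) {
  x <- track$x_cm; y <- track$y_cm
  if (length(s_cell) != length(x)) {
    stopf("signal (%d) and positions (%d) have different lengths",
          length(s_cell), length(x))
  }
  pos_bin <- position_bin_index(x, y, bin_spec)
  occupied <- sort(unique(pos_bin))
  if (length(occupied) < 2) {
    warnf("all samples fall in a single spatial bin; MI = 0")
  }
  k_vals <- sort(unique(s_cell))
  joint <- table(factor(pos_bin, levels = occupied),
                 factor(s_cell, levels = k_vals))
  joint <- matrix(as.numeric(joint), length(occupied), length(k_vals))
  p <- joint / sum(joint)
  list(mi_bits = mutual_information_from_joint(joint),
       occupancy = list(p_x = rowSums(p), p_k = colSums(p), p_xk = p,
                        bins = occupied, k_values = k_vals))
}

# Fast path used by shuffle loops: MI in bits for a binary signal given
# precomputed position-bin indices and per-bin occupancy counts.
mi_binary_fast <- function(s01, pos_bin, occ_counts, n) {
  n1 <- tabulate(pos_bin[s01 != 0], nbins = length(occ_counts))
  n0 <- occ_counts - n1
  k1 <- sum(n1); k0 <- n - k1
  mi <- 0
  nz1 <- n1 > 0
  if (k1 > 0 && any(nz1)) {
    mi <- mi + sum(n1[nz1] / n * log2((n1[nz1] * n) / (occ_counts[nz1] * k1)))
  }
  nz0 <- n0 > 0
  if (k0 > 0 && any(nz0)) {
    mi <- mi + sum(n0[nz0] / n * log2((n0[nz0] * n) / (occ_counts[nz0] * k0)))
  }
  mi
}

#' Circular-shift null distribution for a tuning statistic
#'
#' Recomputes `stat_fn` after circularly rotating the signal relative to
#' its behavioral covariate by offsets drawn uniformly from
#' [min_offset_s, T - min_offset_s] (in samples). Only the signal is
#' rotated; the covariate stays fixed. The observed statistic is
#' `stat_fn(signal, covariate)` on unshifted data.
#'
#' @param stat_fn function(signal, covariate) -> scalar statistic.
#' @param signal numeric vector (trace or binarized spikes).
#' @param covariate behavioral covariate passed through to `stat_fn`
#'   (vector, list, or track).
#' @param fs sampling rate (samples/s).
#' @param n_shuffles number of shuffles (default 500).
#' @param min_offset_s minimum circular offset in seconds (default 10).
#' @param criterion significance rule stored on the result; see
#'   [shuffle_null].
#' @param seed seed for the offset draw.
#' @return a [shuffle_null].
#' @export
circular_shift_null <- function(stat_fn, signal, covariate, fs,
                                n_shuffles = 500, min_offset_s = 10,
                                criterion = "above_95", seed = NULL) {
  if (n_shuffles < 1) stopf("n_shuffles must be at least 1")
  n <- length(signal)
  min_off <- round(min_offset_s * fs)
  if (n < 2 * min_off) {
    stopf("session (%d samples) shorter than twice the minimum offset (%d)",
          n, min_off)
  }
  observed <- stat_fn(signal, covariate)
  offsets <- with_seed(seed, {
    sample.int(n - 2L * min_off + 1L, n_shuffles, replace = TRUE) + min_off - 1L
  })
  null <- vapply(offsets, function(off) {
    shifted <- signal[c((n - off + 1L):n, 1L:(n - off))]
    stat_fn(shifted, covariate)
  }, numeric(1))
  shuffle_null(observed, null, offsets, criterion = criterion, seed = seed)
}

#' Place-cell analysis over a population
#'
#' Computes spatial mutual information per cell from the binarized spike
#' matrix and a circular-shift null (default 500 offsets, minimum 10 s),
#' then flags place cells whose observed MI strictly exceeds 95% of their
#' shuffled MI values.
#'
#' @param rec a [calcium_recording] with `S`, or a cells x samples binary
#'   matrix.
#' @param track a [behavior_track] aligned with the recording.
#' @param bin_spec a [spatial_bins].
#' @param n_shuffles,min_offset_s shuffle-null parameters.
#' @param seed seed for offset draws (per-cell substreams derived from it).
#' @return data.frame of class `tuning_result` rows: `cell_id`, `mi_bits`,
#'   `null_p95`, `percentile`, `is_place_cell`; null distributions in
#'   `attr(, "nulls")`.
#' @export
place_cell_analysis <- function(rec, track, bin_spec = spatial_bins(),
                                n_shuffles = 500, min_offset_s = 10,
                                seed = 1) {
  S <- if (inherits(rec, "calcium_recording")) {
    if (is.null(rec$S)) stopf("recording has no binarized spike matrix S")
    rec$S
  } else as.matrix(rec)
  fs <- if (inherits(rec, "calcium_recording")) rec$fs else track$fs
  n <- ncol(S)
  if (n != length(track$x_cm)) stopf("recording and track lengths differ")
  pos_bin <- position_bin_index(track$x_cm, track$y_cm, bin_spec)
  occupied <- sort(unique(pos_bin))
  pos_idx <- match(pos_bin, occupied)
  occ_counts <- tabulate(pos_idx, nbins = length(occupied))
  min_off <- round(min_offset_s * fs)
  if (n < 2 * min_off) stopf("session shorter than twice the minimum offset")
  ids <- rownames(S)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_len(nrow(S)))
  res <- vector("list", nrow(S))
  nulls <- vector("list", nrow(S))
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    obs <- mi_binary_fast(s, pos_idx, occ_counts, n)
    cell_seed <- substream_seed(seed, paste0("mi_cell", i))
    offsets <- with_seed(cell_seed, {
      sample.int(n - 2L * min_off + 1L, n_shuffles, replace = TRUE) + min_off - 1L
    })
    null <- vapply(offsets, function(off) {
      shifted <- s[c((n - off + 1L):n, 1L:(n - off))]
      mi_binary_fast(shifted, pos_idx, occ_counts, n)
    }, numeric(1))
    sn <- shuffle_null(obs, null, offsets, criterion = "above_95",
                       seed = cell_seed)
    nulls[[i]] <- sn
    res[[i]] <- data.frame(cell_id = ids[i], mi_bits = obs,
                           null_p95 = quantile(null, 0.95, names = FALSE),
                           percentile = sn$percentile,
                           is_place_cell = is_significant(sn))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "nulls") <- nulls
  class(out) <- c("tuning_result", class(out))
  out
}

#' Flag place cells from MI results and their shuffle nulls
#'
#' A cell is a place cell if its observed spatial MI strictly exceeds the
#' 95th percentile of its shuffled MI values.
#'
#' @param nulls list of [shuffle_null] objects (one per cell), e.g. from
#'   [circular_shift_null] with the same bin specification.
#' @return logical vector of flags.
#' @export
classify_place_cells <- function(nulls) {
  if (!length(nulls)) stopf("no shuffle nulls supplied")
  vapply(nulls, function(x) {
    if (!inherits(x, "shuffle_null")) stopf("missing or invalid shuffle null")
    is_significant(x)
  }, logical(1))
}

#' Speed tuning of a calcium trace
#'
#' Pearson correlation between the trace and instantaneous running speed,
#' tested against a circular-shift null (two-sided: significant if the
#' observed correlation falls outside the central 95% of the shuffled
#' correlations).
#'
#' @param trace numeric trace vector.
#' @param speed numeric speed vector (cm/s), aligned with `trace`.
#' @param fs sampling rate (samples/s).
#' @param n_shuffles,min_offset_s shuffle parameters (500 and 10 s).
#' @param seed shuffle seed.
#' @return list of class `tuning_result_cell`: `statistic` (r), `flag`,
#'   `null` ([shuffle_null]).
#' @export
speed_tuning <- function(trace, speed, fs, n_shuffles = 500,
                         min_offset_s = 10, seed = 1) {
  if (length(trace) != length(speed)) stopf("trace and speed lengths differ")
  if (sd(trace) == 0 || sd(speed) == 0) {
    stopf("speed correlation undefined: zero-variance input")
  }
  null <- circular_shift_null(function(sig, cov) cor(sig, cov), trace, speed,
                              fs = fs, n_shuffles = n_shuffles,
                              min_offset_s = min_offset_s,
                              criterion = "outside_central_95", seed = seed)
  structure(list(statistic = null$observed, flag = is_significant(null),
                 null = null, type = "speed"),
            class = "tuning_result_cell")
}

#' Mobility tuning of a calcium trace
#'
#' Statistic: (mean activity while mobile - mean activity while immobile) /
#' mean activity while immobile, tested with the same two-sided
#' circular-shift null as speed tuning.
#'
#' @param trace numeric trace vector.
#' @param mobile logical vector of mobility flags ([classify_mobility]).
#' @param fs sampling rate (samples/s).
#' @param n_shuffles,min_offset_s shuffle parameters.
#' @param seed shuffle seed.
#' @return list of class `tuning_result_cell`.
#' @export
mobility_tuning <- function(trace, mobile, fs, n_shuffles = 500,
                            min_offset_s = 10, seed = 1) {
  if (length(trace) != length(mobile)) stopf("trace and mobility lengths differ")
  if (!any(mobile) || all(mobile)) {
    stopf("both mobility states must be occupied")
  }
  stat_fn <- function(sig, mob) {
    mu_i <- mean(sig[!mob])
    if (mu_i == 0) stopf("mean immobile activity is zero; statistic undefined")
    (mean(sig[mob]) - mu_i) / mu_i
  }
  null <- circular_shift_null(stat_fn, trace, mobile, fs = fs,
                              n_shuffles = n_shuffles,
                              min_offset_s = min_offset_s,
                              criterion = "outside_central_95", seed = seed)
  structure(list(statistic = null$observed, flag = is_significant(null),
                 null = null, type = "mobility"),
            class = "tuning_result_cell")
}
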