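#' Z-score calcium traces over the full session
#'
#' Each cell's trace is mean-subtracted and divided by its session-wide
#' standard deviation (population SD, denominator n, so e.g. the trace
#' 0, 2, 0, 2 maps exactly to -1, 1, -1, 1).
#'
#' @param rec a [calcium_recording] or a cells x samples matrix.
#' @return cells x samples matrix of z-scored traces.
#' @export
zscore_traces <- function(rec) {
  C <- if (inherits(rec, "calcium_recording")) rec$C else as.matrix(rec)
  sds <- sqrt(rowMeans((C - rowMeans(C))^2))
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    ids <- if (!is.null(rownames(C))) rownames(C)[bad] else as.character(bad)
    stopf("constant trace(s), z-score undefined for cell(s): %s",
          paste(ids, collapse = ", "))
  }
  (C - rowMeans(C)) / sds
}

#' Global delta-F-over-F
#'
#' Computes (C - F) / F per cell, where F is either a user-supplied per-cell
#' baseline (mirroring manual baseline identification) or, by default, a
#' low percentile of each cell's trace.
#'
#' @param rec a [calcium_recording] or matrix.
#' @param baseline optional numeric vector of per-cell baselines F (> 0).
#' @param probs percentile (0-1) used for the automatic baseline when
#'   `baseline` is NULL; default 0.1.
#' @return cells x samples dF/F matrix.
#' @export
global_dff <- function(rec, baseline = NULL, probs = 0.1) {
  C <- if (inherits(rec, "calcium_recording")) rec$C else as.matrix(rec)
  if (is.null(baseline)) {
    baseline <- apply(C, 1, quantile, probs = probs, names = FALSE)
  }
  if (length(baseline) != nrow(C)) stopf("baseline must have one value per cell")
  if (any(baseline <= 0)) {
    stopf("baseline F must be positive for all cells (offending: %s)",
          paste(which(baseline <= 0), collapse = ", "))
  }
  (C - baseline) / baseline
}

#' Local dF/F response to interaction bouts
#'
#' For each cell and bout, the baseline F is the mean trace value in the
#' 10 s before bout onset, and the response is the mean of (C - F) / F over
#' the 20 s after onset. Bouts without a full pre/post window inside the
#' session are dropped with a warning; cell-events with non-positive
#' baseline are returned as NA.
#'
#' @param rec a [calcium_recording].
#' @param bouts bout data.frame ([parse_interactions]).
#' @param pre_s baseline window (s), default 10.
#' @param post_s response window (s), default 20.
#' @return cells x events matrix of responses (NA where the baseline was
#'   non-positive); kept events recorded in `attr(, "events")`.
#' @export
local_dff_response <- function(rec, bouts, pre_s = 10, post_s = 20) {
  stopifnot(inherits(rec, "calcium_recording"))
  fs <- rec$fs
  n <- ncol(rec$C)
  k_pre <- round(pre_s * fs)
  k_post <- round(post_s * fs)
  onset <- floor(bouts$start_s * fs) + 1L
  ok <- onset - k_pre >= 1L & onset + k_post - 1L <= n
  if (!all(ok)) warnf("%d bout(s) dropped: pre/post window outside session",
                      sum(!ok))
  if (!any(ok)) stopf("no bouts with a full pre/post window")
  keep <- which(ok)
  out <- matrix(NA_real_, nrow(rec$C), length(keep))
  flagged <- 0L
  for (j in seq_along(keep)) {
    k0 <- onset[keep[j]]
    pre <- rec$C[, (k0 - k_pre):(k0 - 1L), drop = FALSE]
    post <- rec$C[, k0:(k0 + k_post - 1L), drop = FALSE]
    f <- rowMeans(pre)
    resp <- (rowMeans(post) - f) / f
    bad <- f <= 0
    resp[bad] <- NA_real_
    flagged <- flagged + sum(bad)
    out[, j] <- resp
  }
  if (flagged > 0) warnf("%d cell-event(s) excluded: non-positive baseline F",
                         flagged)
  rownames(out) <- rec$cell_ids
  attr(out, "events") <- bouts[keep, , drop = FALSE]
  out
}

# Sample-resolution peri-event windows: list with onset sample indices per
# class, after dropping events whose windows are clipped by session edges.
event_onsets <- function(bouts, fs, n, pre_s, post_s) {
  onset <- floor(bouts$start_s * fs) + 1L
  ok <- onset - round(pre_s * fs) >= 1L & onset + round(post_s * fs) - 1L <= n
  list(onset = onset[ok], class = bouts$object_class[ok], dropped = sum(!ok))
}

#' Peri-event binned delta-Z tensor
#'
#' Aligns z-scored traces to bout onsets, subtracts each cell-event's
#' pre-window mean (sampled at full resolution), and averages the result in
#' fixed-width bins. Also returns event-averaged traces per object class.
#'
#' @param Z cells x samples z-scored matrix ([zscore_traces]).
#' @param bouts bout data.frame.
#' @param fs sampling rate (samples/s).
#' @param pre_s,post_s window before/after onset (s); defaults 10 and 30.
#' @param bin_s bin width (s), default 2.
#' @return list of class `peri_event_tensor`: `delta_z` (cells x events x
#'   bins array), `bin_centers_s`, `event_class`, `class_average` (named
#'   list of cells x bins matrices), and the window parameters. Events with
#'   clipped windows are dropped (count in `n_dropped`).
#' @export
peri_event_deltaz <- function(Z, bouts, fs, pre_s = 10, post_s = 30,
                              bin_s = 2) {
  Z <- as.matrix(Z)
  n <- ncol(Z)
  ev <- event_onsets(bouts, fs, n, pre_s, post_s)
  if (!length(ev$onset)) stopf("no events retained: all windows clipped by session edges")
  k_pre <- round(pre_s * fs)
  k_post <- round(post_s * fs)
  k_bin <- round(bin_s * fs)
  n_bins <- (k_pre + k_post) %/% k_bin
  n_cells <- nrow(Z)
  dz <- array(NA_real_, c(n_cells, length(ev$onset), n_bins))
  for (j in seq_along(ev$onset)) {
    k0 <- ev$onset[j]
    win <- Z[, (k0 - k_pre):(k0 + k_post - 1L), drop = FALSE]
    base <- rowMeans(win[, seq_len(k_pre), drop = FALSE])
    win <- win - base
    for (b in seq_len(n_bins)) {
      cols <- ((b - 1L) * k_bin + 1L):(b * k_bin)
      dz[, j, b] <- rowMeans(win[, cols, drop = FALSE])
    }
  }
  bin_centers <- (seq_len(n_bins) - 0.5) * bin_s - pre_s
  class_avg <- lapply(split(seq_along(ev$onset), ev$class), function(idx) {
    m <- apply(dz[, idx, , drop = FALSE], c(1, 3), mean)
    dimnames(m) <- list(rownames(Z), NULL)
    m
  })
  structure(
    list(delta_z = dz, bin_centers_s = bin_centers, event_class = ev$class,
         class_average = class_avg, pre_s = pre_s, post_s = post_s,
         bin_s = bin_s, n_dropped = ev$dropped),
    class = "peri_event_tensor"
  )
}

#' Classify object-responder cells
#'
#' A cell is a responder for an object class if, following any interaction
#' of that class, its baseline-subtracted z-scored activity (delta-Z; the
#' baseline is the mean over `pre_s` seconds before onset) stays at or
#' above `threshold` contiguously for at least `min_duration_s` within the
#' `window_s`-second evaluation window. Both boundaries are inclusive: a
#' delta-Z of exactly 0.25 held for exactly 10 s qualifies. The duration
#' test runs at sample resolution, not on 2-s bins.
#'
#' @param Z cells x samples z-scored matrix.
#' @param bouts bout data.frame.
#' @param fs sampling rate (samples/s).
#' @param threshold minimum delta-Z (default 0.25).
#' @param min_duration_s minimum contiguous duration (default 10 s).
#' @param window_s evaluation window after onset (default 30 s); must be >=
#'   `min_duration_s`.
#' @param pre_s baseline window before onset (default 10 s).
#' @return list of class `responder_result`: `flags` (cells x classes
#'   logical matrix), `percent` (per-class responder percentage), and the
#'   parameters used.
#' @export
classify_responders <- function(Z, bouts, fs, threshold = 0.25,
                                min_duration_s = 10, window_s = 30,
                                pre_s = 10) {
  if (window_s < min_duration_s) {
    stopf("window_s (%g) must be at least min_duration_s (%g)",
          window_s, min_duration_s)
  }
  Z <- as.matrix(Z)
  n <- ncol(Z)
  ev <- event_onsets(bouts, fs, n, pre_s, window_s)
  if (!length(ev$onset)) stopf("no events retained for responder classification")
  k_pre <- round(pre_s * fs)
  k_win <- round(window_s * fs)
  min_k <- round(min_duration_s * fs)
  classes <- sort(unique(ev$class))
  flags <- matrix(FALSE, nrow(Z), length(classes),
                  dimnames = list(rownames(Z), classes))
  for (j in seq_along(ev$onset)) {
    k0 <- ev$onset[j]
    base <- rowMeans(Z[, (k0 - k_pre):(k0 - 1L), drop = FALSE])
    win <- Z[, k0:(k0 + k_win - 1L), drop = FALSE] - base
    hit <- apply(win >= threshold, 1, longest_run) >= min_k
    cl <- ev$class[j]
    flags[, cl] <- flags[, cl] | hit
  }
  structure(
    list(flags = flags, percent = 100 * colMeans(flags),
         threshold = threshold, min_duration_s = min_duration_s,
         window_s = window_s, pre_s = pre_s, n_events = length(ev$onset)),
    class = "responder_result"
  )
}

#' @exportS3Method base::print
print.responder_result <- function(x, ...) {
  cat("<responder_result>\n")
  for (cl in colnames(x$flags)) {
    cat(sprintf("  %s: %d/%d cells (%.1f%%)\n", cl, sum(x$flags[, cl]),
                nrow(x$flags), x$percent[cl]))
  }
  invisible(x)
}

# delta-Z peak for windows starting at the given sample indices: max over
# the window minus the mean over the pre_s seconds before it.
window_peaks <- function(z, starts, k_win, k_pre) {
  vapply(starts, function(k0) {
    max(z[k0:(k0 + k_win - 1L)]) - mean(z[(k0 - k_pre):(k0 - 1L)])
  }, numeric(1))
}

#' Duration-parameter-free peak-percentile statistic
#'
#' For each cell, the trial statistic is the peak delta-Z in the 20-s
#' window after each novel-class bout onset (baseline: mean z over the
#' 10 s before the window). Each trial peak is converted to a percentile
#' relative to a per-cell null distribution of peak delta-Z values computed
#' over sliding windows across the whole session (stride `stride_s`; trial
#' windows are not excluded, which is conservative).
#'
#' @param Z cells x samples z-scored matrix.
#' @param bouts bout data.frame; trials are bouts of class `"novel"` or
#'   `"moved_location"` unless `classes` says otherwise.
#' @param fs sampling rate (samples/s).
#' @param window_s trial/null window length (default 20 s).
#' @param stride_s stride between null windows (default 1 s).
#' @param pre_s baseline window (default 10 s).
#' @param classes object classes treated as trials.
#' @param min_null minimum number of null windows required (default 50).
#' @return list of class `peak_percentile_result`: `percentiles` (cells x
#'   trials matrix; percentile = 100 * fraction of null values <= observed),
#'   `trial_peaks`, `null_peaks` (list per cell), `pooled` (vector of all
#'   percentiles).
#' @export
peak_percentile_statistic <- function(Z, bouts, fs, window_s = 20,
                                      stride_s = 1, pre_s = 10,
                                      classes = c("novel", "moved_location"),
                                      min_null = 50) {
  Z <- as.matrix(Z)
  n <- ncol(Z)
  k_win <- round(window_s * fs)
  k_pre <- round(pre_s * fs)
  k_stride <- max(1L, round(stride_s * fs))
  null_starts <- seq.int(k_pre + 1L, n - k_win + 1L, by = k_stride)
  if (length(null_starts) < min_null) {
    stopf("only %d null windows available (< %d); session too short",
          length(null_starts), min_null)
  }
  tb <- bouts[bouts$object_class %in% classes, , drop = FALSE]
  ev <- event_onsets(tb, fs, n, pre_s, window_s)
  if (!length(ev$onset)) stopf("no trial windows retained")
  n_cells <- nrow(Z)
  pct <- matrix(NA_real_, n_cells, length(ev$onset),
                dimnames = list(rownames(Z), NULL))
  peaks <- pct
  nulls <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    z <- Z[i, ]
    null_i <- window_peaks(z, null_starts, k_win, k_pre)
    obs_i <- window_peaks(z, ev$onset, k_win, k_pre)
    pct[i, ] <- vapply(obs_i, function(o) 100 * mean(null_i <= o), numeric(1))
    peaks[i, ] <- obs_i
    nulls[[i]] <- null_i
  }
  structure(
    list(percentiles = pct, trial_peaks = peaks, null_peaks = nulls,
         pooled = as.numeric(pct), window_s = window_s, stride_s = stride_s,
         pre_s = pre_s, n_null = length(null_starts)),
    class = "peak_percentile_result"
  )
}

#' Compare pooled peak percentiles between two populations
#'
#' Mann-Whitney/Wilcoxon rank-sum test on the pooled trial percentiles of
#' two cell populations (e.g. two imaging cohorts).
#'
#' @param pct_a,pct_b numeric vectors (or `peak_percentile_result` objects)
#'   of pooled percentiles.
#' @return `htest` from [stats::wilcox.test].
#' @export
compare_peak_percentiles <- function(pct_a, pct_b) {
  if (inherits(pct_a, "peak_percentile_result")) pct_a <- pct_a$pooled
  if (inherits(pct_b, "peak_percentile_result")) pct_b <- pct_b$pooled
  wilcox.test(pct_a, pct_b)
}

#' Overlap of responder ensembles across session segments
#'
#' Overlap coefficient |A intersect B| / min(|A|, |B|) for every pair of
#' segments; pairs where either ensemble is empty are undefined (NA).
#'
#' @param ensembles list (length >= 2) of cell-id vectors or logical
#'   membership vectors, one per session segment.
#' @return symmetric matrix of overlap coefficients with NA diagonal
#'   companions for empty sets.
#' @export
ensemble_overlap <- function(ensembles) {
  if (length(ensembles) < 2) stopf("need at least 2 segments")
  sets <- lapply(ensembles, function(e) {
    if (is.logical(e)) which(e) else e
  })
  k <- length(sets)
  out <- matrix(NA_real_, k, k)
  nm <- names(ensembles)
  if (!is.null(nm)) dimnames(out) <- list(nm, nm)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- sets[[i]]; b <- sets[[j]]
      if (length(a) == 0 || length(b) == 0) next
      out[i, j] <- length(intersect(a, b)) / min(length(a), length(b))
    }
  }
  out
}
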