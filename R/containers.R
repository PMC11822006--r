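#' Behavior track container
#'
#' Bundles a timestamped arena trajectory with its sampling rate and arena
#' geometry. Times are in seconds and strictly increasing; positions are in
#' centimetres in an arena-centred frame (origin at the arena centre).
#'
#' @param t_s numeric vector of sample times (s), strictly increasing.
#' @param x_cm,y_cm numeric position vectors (cm), same length as `t_s`.
#' @param fs sampling rate (samples/s).
#' @param arena_diameter_cm arena diameter (cm); positions must lie within
#'   the arena radius plus `tol_cm`.
#' @param tol_cm tolerance on the confinement check (cm).
#' @return An object of class `behavior_track`: a list with elements
#'   `t_s`, `x_cm`, `y_cm`, `fs`, `arena_diameter_cm`.
#' @export
behavior_track <- function(t_s, x_cm, y_cm, fs, arena_diameter_cm = 60,
                           tol_cm = 1e-6) {
  if (length(t_s) != length(x_cm) || length(t_s) != length(y_cm)) {
    stopf("t_s, x_cm, y_cm must have equal length")
  }
  if (length(t_s) >= 2 && any(diff(t_s) <= 0)) {
    stopf("track times must be strictly increasing")
  }
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(arena_diameter_cm, "arena_diameter_cm")
  r <- sqrt(x_cm^2 + y_cm^2)
  if (any(r > arena_diameter_cm / 2 + tol_cm)) {
    stopf("positions fall outside the arena radius (%g cm)", arena_diameter_cm / 2)
  }
  structure(
    list(t_s = as.numeric(t_s), x_cm = as.numeric(x_cm),
         y_cm = as.numeric(y_cm), fs = fs,
         arena_diameter_cm = arena_diameter_cm),
    class = "behavior_track"
  )
}

#' @exportS3Method base::print
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d samples @ %g Hz, %.1f s, arena %g cm\n",
              length(x$t_s), x$fs, diff(range(x$t_s)), x$arena_diameter_cm))
  invisible(x)
}

#' @export
as.data.frame.behavior_track <- function(x, ...) {
  data.frame(t_s = x$t_s, x_cm = x$x_cm, y_cm = x$y_cm)
}

#' Calcium recording container
#'
#' Holds denoised per-cell calcium traces (the `C` output of a CNMF-style
#' source-extraction pipeline) and, optionally, the matched binarized
#' deconvolved spike matrix `S`.
#'
#' @param C cells x samples numeric matrix of denoised traces.
#' @param fs sampling rate (samples/s).
#' @param S optional cells x samples binary matrix (0/1), same shape as `C`.
#' @param cell_ids optional character vector of cell identifiers.
#' @return An object of class `calcium_recording`.
#' @export
calcium_recording <- function(C, fs, S = NULL, cell_ids = NULL) {
  C <- as.matrix(C)
  if (anyNA(C)) stopf("C contains NA values")
  assert_scalar_pos(fs, "fs")
  if (!is.null(S)) {
    S <- as.matrix(S)
    if (!identical(dim(S), dim(C))) stopf("S and C must have identical shape")
    if (anyNA(S) || !all(S %in% c(0, 1))) stopf("S must be binary (0/1), no NA")
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%03d", seq_len(nrow(C)))
  if (length(cell_ids) != nrow(C)) stopf("cell_ids length must match nrow(C)")
  rownames(C) <- cell_ids
  if (!is.null(S)) rownames(S) <- cell_ids
  structure(list(C = C, S = S, fs = fs, cell_ids = cell_ids),
            class = "calcium_recording")
}

#' @exportS3Method base::print
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d cells x %d samples @ %g Hz%s\n",
              nrow(x$C), ncol(x$C), x$fs,
              if (is.null(x$S)) "" else " (+S)"))
  invisible(x)
}

#' Shuffle-null container
#'
#' An observed statistic together with its circular-offset null
#' distribution, the offsets used, and the percentile of the observed value
#' in the null.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null statistics.
#' @param offsets integer vector of circular offsets (samples) used.
#' @param criterion `"above_95"` (one-sided, e.g. spatial information) or
#'   `"outside_central_95"` (two-sided, e.g. speed/mobility tuning).
#' @param seed seed used to draw the offsets (recorded for reproducibility).
#' @return Object of class `shuffle_null` with an additional `percentile`
#'   field: `100 * mean(null <= observed)`.
#' @export
shuffle_null <- function(observed, null, offsets, criterion = c("above_95",
                         "outside_central_95"), seed = NULL) {
  criterion <- match.arg(criterion)
  if (length(null) < 1) stopf("null distribution must have at least one value")
  structure(
    list(observed = observed, null = as.numeric(null),
         offsets = as.integer(offsets),
         percentile = 100 * mean(null <= observed),
         criterion = criterion, seed = seed),
    class = "shuffle_null"
  )
}

#' Significance flag from a shuffle null
#'
#' One-sided (`above_95`): significant iff the observed statistic strictly
#' exceeds the 95th percentile of the null (ties are non-significant).
#' Two-sided (`outside_central_95`): significant iff the observed value lies
#' strictly outside the central 95% band (2.5th-97.5th percentiles).
#'
#' @param x a [shuffle_null] object.
#' @return logical flag.
#' @export
is_significant <- function(x) {
  stopifnot(inherits(x, "shuffle_null"))
  if (x$criterion == "above_95") {
    x$observed > quantile(x$null, 0.95, names = FALSE)
  } else {
    lo <- quantile(x$null, 0.025, names = FALSE)
    hi <- quantile(x$null, 0.975, names = FALSE)
    x$observed < lo || x$observed > hi
  }
}

#' @exportS3Method base::print
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> observed %.4g, %d shuffles, percentile %.1f (%s)\n",
              x$observed, length(x$null), x$percentile, x$criterion))
  invisible(x)
}
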