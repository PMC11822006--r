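#' Parse and validate object-interaction annotations
#'
#' Interaction bouts are the intervals during which the animal investigates
#' an object; they are typically scored from video. Each row gives the bout
#' start and end (seconds), the object identifier, and the object class.
#'
#' @param table data.frame with columns `start_s`, `end_s`, `object_id`,
#'   `object_class` (one of `"novel"`, `"familiar"`, `"moved_location"`).
#' @return A validated data.frame of bouts sorted by start time, with a
#'   `duration_s` column added.
#' @details Bouts belonging to the same object must not overlap; violations
#'   are reported with the offending row number of the input table.
#' @export
parse_interactions <- function(table) {
  need <- c("start_s", "end_s", "object_id", "object_class")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stopf("interaction table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  classes <- c("novel", "familiar", "moved_location")
  for (i in seq_len(nrow(table))) {
    if (!is.finite(table$start_s[i]) || !is.finite(table$end_s[i])) {
      stopf("row %d: non-finite bout times", i)
    }
    if (table$end_s[i] <= table$start_s[i]) {
      stopf("row %d: end_s (%g) must exceed start_s (%g)", i,
            table$end_s[i], table$start_s[i])
    }
    if (!table$object_class[i] %in% classes) {
      stopf("row %d: unknown object_class '%s'", i, table$object_class[i])
    }
  }
  for (obj in unique(table$object_id)) {
    idx <- which(table$object_id == obj)
    o <- idx[order(table$start_s[idx])]
    if (length(o) > 1) {
      ov <- which(table$start_s[o][-1] < table$end_s[o][-length(o)])
      if (length(ov)) {
        stopf("row %d: bout overlaps previous bout for object '%s'",
              o[ov[1] + 1], obj)
      }
    }
  }
  out <- table[order(table$start_s), need, drop = FALSE]
  out$object_class <- as.character(out$object_class)
  out$object_id <- as.character(out$object_id)
  out$duration_s <- out$end_s - out$start_s
  rownames(out) <- NULL
  out
}

#' Instantaneous running speed from a behavior track
#'
#' Speed is the norm of the central-difference displacement divided by the
#' time step (one-sided differences at the endpoints), optionally smoothed
#' with a boxcar of `smooth_window_s` seconds. Central differences make the
#' speed of a time-reversed track equal the original sample-wise.
#'
#' @param track a [behavior_track].
#' @param smooth_window_s boxcar width in seconds (0 disables smoothing).
#'   Default 0.5 s.
#' @return numeric vector of speeds (cm/s), one per track sample.
#' @export
compute_speed <- function(track, smooth_window_s = 0.5) {
  stopifnot(inherits(track, "behavior_track"))
  n <- length(track$t_s)
  if (n < 2) stopf("need at least 2 samples to compute speed")
  if (any(diff(track$t_s) <= 0)) stopf("track times must be strictly increasing")
  x <- track$x_cm; y <- track$y_cm; t <- track$t_s
  v <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
    (t[i + 1] - t[i - 1])
  v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1])
  v[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) / (t[n] - t[n - 1])
  if (smooth_window_s > 0) {
    v <- boxcar_smooth(v, round(smooth_window_s * track$fs))
  }
  v
}

#' Classify mobility from running speed
#'
#' A sample is mobile when its speed strictly exceeds the threshold
#' (default 1 cm/s); samples exactly at the threshold count as immobile.
#'
#' @param speed numeric vector of speeds (cm/s).
#' @param threshold_cm_s mobility threshold (cm/s), default 1.
#' @return logical vector of mobile flags.
#' @export
classify_mobility <- function(speed, threshold_cm_s = 1) {
  if (!is.numeric(threshold_cm_s) || threshold_cm_s < 0) {
    stopf("threshold_cm_s must be non-negative")
  }
  if (any(!is.finite(speed))) stopf("speed contains non-finite values")
  speed > threshold_cm_s
}

#' Discrimination index from interaction bouts
#'
#' DI = (T_novel - T_familiar) / (T_novel + T_familiar), where T_novel and
#' T_familiar are total interaction times summed over bouts. In
#' novel-object-location sessions, `moved_location` bouts count toward the
#' novel side (novel location vs. familiar location).
#'
#' @param bouts data.frame as returned by [parse_interactions].
#' @return list with `di`, `t_novel_s`, `t_familiar_s`, `t_total_s`.
#' @export
discrimination_index <- function(bouts) {
  if (is.null(bouts) || nrow(bouts) == 0) stopf("no interaction bouts supplied")
  bouts <- parse_interactions(bouts)
  dur <- bouts$end_s - bouts$start_s
  t_nov <- sum(dur[bouts$object_class %in% c("novel", "moved_location")])
  t_fam <- sum(dur[bouts$object_class == "familiar"])
  t_tot <- sum(dur)
  if (t_nov + t_fam == 0) stopf("DI undefined: no novel or familiar interaction time")
  list(di = (t_nov - t_fam) / (t_nov + t_fam),
       t_novel_s = t_nov, t_familiar_s = t_fam, t_total_s = t_tot)
}
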