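#' Configuration for synthetic imaging sessions
#'
#' Describes a synthetic 5-minute open-field session recorded at
#' miniscope-like sampling: a circular arena with two objects, a population
#' of cells with planted tuning, and the calcium-trace noise model. All
#' generators are deterministic given `seed`; per-entity substreams mean
#' that adding cells never perturbs the behavior track.
#'
#' @param seed integer seed controlling every random draw.
#' @param duration_s session length in seconds (default 300).
#' @param fs_hz sampling rate in samples/s (default 20; one shared clock for
#'   behavior and traces).
#' @param arena_diameter_cm circular arena diameter in cm (default 60).
#' @param cell_specs list of cell specifications from [cell_spec()].
#' @param noise_sd additive Gaussian trace noise SD (trace units; default 1,
#'   so planted amplitudes are approximately in post-z-scoring units).
#' @param calcium_tau_s single-exponential calcium decay constant in
#'   seconds (default 1.5).
#' @param object_classes named character vector mapping object ids to
#'   classes (default `c(A = "novel", B = "familiar")`).
#' @param interaction_radius_cm distance from an object centre within which
#'   the animal counts as interacting (default 3 cm).
#' @param min_dwell_s minimum dwell to open a bout (default 0.5 s).
#' @param min_gap_s minimum out-of-radius gap that closes a bout; shorter
#'   gaps are merged (default 1 s).
#' @param forced_dwell_s optional named numeric vector (seconds per object
#'   id): when given, the track is scripted to dwell at each object for
#'   exactly the stated time, for controlled tests of bout scoring.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed, duration_s = 300, fs_hz = 20,
                         arena_diameter_cm = 60, cell_specs = list(),
                         noise_sd = 1, calcium_tau_s = 1.5,
                         object_classes = c(A = "novel", B = "familiar"),
                         interaction_radius_cm = 3, min_dwell_s = 0.5,
                         min_gap_s = 1, forced_dwell_s = NULL) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs_hz, "fs_hz")
  assert_scalar_pos(arena_diameter_cm, "arena_diameter_cm")
  if (!is.numeric(seed) || length(seed) != 1) stopf("seed must be a single integer")
  structure(
    list(seed = as.integer(seed), duration_s = duration_s, fs_hz = fs_hz,
         arena_diameter_cm = arena_diameter_cm, cell_specs = cell_specs,
         noise_sd = noise_sd, calcium_tau_s = calcium_tau_s,
         object_classes = object_classes,
         interaction_radius_cm = interaction_radius_cm,
         min_dwell_s = min_dwell_s, min_gap_s = min_gap_s,
         forced_dwell_s = forced_dwell_s),
    class = "synth_config"
  )
}

#' Specify one synthetic cell
#'
#' @param label one of `"object_responder"`, `"place"`, `"speed"`,
#'   `"untuned"`.
#' @param ... effect parameters overriding the per-label defaults:
#'   * object_responder: `amplitude_z` (plateau height in units of the
#'     baseline noise SD, default 3 -- a strong sustained response, well
#'     clear of the 0.25 delta-Z responder criterion), `response_duration_s`
#'     (default 15).
#'   * place: `center_cm` (length-2, default `c(0, 10)`), `width_cm`
#'     (Gaussian field SD, default 5), `peak_rate_hz` (default 8),
#'     `base_rate_hz` (default 0.05), `event_amp` (default 1).
#'   * speed: `gain` (trace units per cm/s, default 0.3).
#'   * untuned: `rate_hz` (default 0.5), `event_amp` (default 1).
#' @return list of class `cell_spec` with the label and resolved parameters.
#' @export
cell_spec <- function(label = c("object_responder", "place", "speed", "untuned"),
                      ...) {
  label <- match.arg(label)
  defaults <- switch(label,
    object_responder = list(amplitude_z = 3, response_duration_s = 15),
    place = list(center_cm = c(0, 10), width_cm = 5, peak_rate_hz = 8,
                 base_rate_hz = 0.05, event_amp = 1),
    speed = list(gain = 0.3),
    untuned = list(rate_hz = 0.5, event_amp = 1)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad)) stopf("unknown parameter(s) for '%s' cell: %s", label,
                         paste(bad, collapse = ", "))
  defaults[names(override)] <- override
  structure(c(list(label = label), defaults), class = "cell_spec")
}

# Default object positions: on the horizontal axis at +/- diameter/4.
object_positions <- function(config) {
  r <- config$arena_diameter_cm / 4
  ids <- names(config$object_classes)
  pos <- cbind(x = c(-r, r, rep(0, max(0, length(ids) - 2))),
               y = rep(0, length(ids)))
  rownames(pos) <- ids
  pos[seq_along(ids), , drop = FALSE]
}

# Emit interaction bouts from per-sample in-radius flags: gaps shorter than
# min_gap_s are merged; bouts shorter than min_dwell_s are dropped. A bout
# spans [first in-radius time, exit time), so an unbroken k-sample dwell has
# duration exactly k/fs.
emit_bouts <- function(track, obj_pos, object_classes, radius_cm,
                       min_dwell_s, min_gap_s) {
  dt <- 1 / track$fs
  res <- list()
  for (obj in rownames(obj_pos)) {
    d <- sqrt((track$x_cm - obj_pos[obj, "x"])^2 +
              (track$y_cm - obj_pos[obj, "y"])^2)
    inr <- d <= radius_cm
    if (!any(inr)) next
    r <- rle(inr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by out-gaps < min_gap_s
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1) * dt
        if (gap_s < min_gap_s) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
    }
    start_s <- track$t_s[merged$start]
    end_s <- track$t_s[merged$end] + dt
    keep <- (end_s - start_s) >= min_dwell_s
    if (any(keep)) {
      res[[obj]] <- data.frame(start_s = start_s[keep], end_s = end_s[keep],
                               object_id = obj,
                               object_class = unname(object_classes[obj]))
    }
  }
  if (!length(res)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      object_id = character(0), object_class = character(0)))
  }
  out <- do.call(rbind, res)
  parse_interactions(out)
}

#' Generate a synthetic behavior track with interaction bouts
#'
#' Produces a smoothed bounded random walk confined to the circular arena
#' (an Ornstein-Uhlenbeck velocity process with wall reflection), two fixed
#' object locations, and interaction bouts emitted whenever the agent
#' dwells within the interaction radius of an object. With
#' `forced_dwell_s`, the trajectory is instead scripted so the total
#' in-radius time per object equals the requested dwell exactly.
#'
#' @param config a [synth_config].
#' @return list with `track` ([behavior_track]), `bouts` (validated bout
#'   data.frame), and `truth` (object positions/classes and generator
#'   parameters).
#' @export
generate_behavior_track <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$duration_s * config$fs_hz)
  dt <- 1 / config$fs_hz
  rad <- config$arena_diameter_cm / 2
  obj_pos <- object_positions(config)
  xy <- with_seed(substream_seed(config$seed, "track"), {
    if (is.null(config$forced_dwell_s)) {
      random_walk_xy(n, dt, rad)
    } else {
      scripted_dwell_xy(n, dt, rad, obj_pos, config$forced_dwell_s,
                        config$interaction_radius_cm, config$min_gap_s)
    }
  })
  track <- behavior_track(t_s = (seq_len(n) - 1) * dt, x_cm = xy[, 1],
                          y_cm = xy[, 2], fs = config$fs_hz,
                          arena_diameter_cm = config$arena_diameter_cm)
  bouts <- emit_bouts(track, obj_pos, config$object_classes,
                      config$interaction_radius_cm, config$min_dwell_s,
                      config$min_gap_s)
  list(track = track, bouts = bouts,
       truth = list(object_positions = obj_pos,
                    object_classes = config$object_classes,
                    forced_dwell_s = config$forced_dwell_s,
                    seed = config$seed))
}

# OU-velocity random walk reflected at the arena wall, with a two-state
# move/rest process (exponential bout lengths) so sessions contain both
# mobility and immobility, as real open-field behavior does.
random_walk_xy <- function(n, dt, rad, tau_v = 1, speed_sd = 6,
                           mean_move_s = 20, mean_rest_s = 5) {
  v <- matrix(0, n, 2)
  p <- matrix(0, n, 2)
  a <- exp(-dt / tau_v)
  b <- speed_sd * sqrt(1 - a^2)
  noise <- matrix(rnorm(2 * n), n, 2)
  switch_u <- runif(n)
  moving <- TRUE
  margin <- 0.98 * rad
  for (i in 2:n) {
    p_switch <- dt / (if (moving) mean_move_s else mean_rest_s)
    if (switch_u[i] < p_switch) moving <- !moving
    gain <- if (moving) b else 0.02 * b
    v[i, ] <- a * v[i - 1, ] + gain * noise[i, ]
    if (!moving) v[i, ] <- v[i, ] * 0.8  # glide to a stop
    p[i, ] <- p[i - 1, ] + v[i, ] * dt
    r <- sqrt(sum(p[i, ]^2))
    if (r > margin) {
      # reflect position and velocity about the wall normal
      u <- p[i, ] / r
      p[i, ] <- u * (2 * margin - r)
      v[i, ] <- v[i, ] - 2 * sum(v[i, ] * u) * u
    }
  }
  p
}

# Scripted trajectory: visit each object in turn and sit at its centre for
# the exact number of in-radius samples requested, travelling via the arena
# centre between visits. Approach/departure samples that fall inside the
# interaction radius are counted toward the dwell so bout durations come
# out exact.
scripted_dwell_xy <- function(n, dt, rad, obj_pos, forced_dwell_s,
                              radius_cm, min_gap_s) {
  path <- matrix(NA_real_, 0, 2)
  home <- c(0, -rad * 0.6)  # rest point away from both objects
  travel_speed <- 10  # cm/s
  seg_to <- function(from, to) {
    d <- sqrt(sum((to - from)^2))
    k <- max(1L, ceiling(d / (travel_speed * dt)))
    cbind(seq(from[1], to[1], length.out = k + 1),
          seq(from[2], to[2], length.out = k + 1))[-1, , drop = FALSE]
  }
  cur <- home
  # lead-in rest so the first bout has peri-event history available
  lead_k <- min(round(15 / dt), n %/% 4)
  path <- rbind(path, matrix(rep(home, each = lead_k), lead_k, 2))
  for (obj in names(forced_dwell_s)) {
    target <- obj_pos[obj, ]
    approach <- seg_to(cur, target)
    d_obj <- sqrt((approach[, 1] - target[1])^2 + (approach[, 2] - target[2])^2)
    in_approach <- sum(d_obj <= radius_cm)
    # departure in-radius samples (same geometry back to home)
    departure <- seg_to(target, home)
    d_dep <- sqrt((departure[, 1] - target[1])^2 + (departure[, 2] - target[2])^2)
    in_departure <- sum(d_dep <= radius_cm)
    k_total <- round(forced_dwell_s[[obj]] / dt)
    k_sit <- k_total - in_approach - in_departure
    if (k_sit < 0) stopf("forced dwell %.2f s too short for travel geometry",
                         forced_dwell_s[[obj]])
    path <- rbind(path, approach,
                  matrix(rep(target, each = k_sit), k_sit, 2),
                  departure)
    cur <- home
    gap_k <- ceiling(min_gap_s / dt) + 2L
    path <- rbind(path, matrix(rep(home, each = gap_k), gap_k, 2))
  }
  if (nrow(path) > n) stopf("forced dwell script exceeds session length")
  rbind(path, matrix(rep(home, each = n - nrow(path)), n - nrow(path), 2))
}

#' Generate a synthetic calcium recording with planted tuning
#'
#' For each cell in `config$cell_specs`, builds a denoised-style trace and
#' a matched binarized event train:
#' * `object_responder`: a sustained plateau of height `amplitude_z`
#'   starting at each novel-class bout onset, decaying with the calcium
#'   time constant afterwards.
#' * `place`: a Gaussian spatial rate field drives Bernoulli point events
#'   that are convolved with a single-exponential calcium kernel.
#' * `speed`: trace proportional to instantaneous running speed.
#' * `untuned`: constant-rate events plus noise.
#' All cells receive iid Gaussian noise of SD `noise_sd`. Cells draw from
#' per-cell substreams of `config$seed`.
#'
#' @param track a [behavior_track] covering the configured duration.
#' @param bouts interaction bouts for the session (novel-class onsets drive
#'   object responders).
#' @param config a [synth_config] whose `cell_specs` is non-empty.
#' @return list with `recording` ([calcium_recording] including `S`) and
#'   `truth` (data.frame of per-cell labels plus the spec list).
#' @export
generate_calcium_recording <- function(track, bouts, config) {
  stopifnot(inherits(config, "synth_config"), inherits(track, "behavior_track"))
  n <- round(config$duration_s * config$fs_hz)
  if (length(track$t_s) != n) {
    stopf("track length (%d) does not cover the configured session (%d samples)",
          length(track$t_s), n)
  }
  specs <- config$cell_specs
  if (!length(specs)) stopf("config$cell_specs is empty")
  dt <- 1 / config$fs_hz
  decay <- exp(-dt / config$calcium_tau_s)
  speed <- compute_speed(track)
  novel_onsets <- bouts$start_s[bouts$object_class %in% c("novel", "moved_location")]
  C <- matrix(0, length(specs), n)
  S <- matrix(0, length(specs), n)
  labels <- character(length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    stopifnot(inherits(sp, "cell_spec"))
    labels[i] <- sp$label
    res <- with_seed(substream_seed(config$seed, paste0("cell", i)), {
      switch(sp$label,
        object_responder = synth_responder_cell(n, dt, decay, novel_onsets, sp,
                                                config$noise_sd),
        place = synth_place_cell(n, dt, decay, track, sp, config$noise_sd),
        speed = synth_speed_cell(n, dt, decay, speed, sp, config$noise_sd),
        untuned = synth_untuned_cell(n, dt, decay, sp, config$noise_sd)
      )
    })
    C[i, ] <- res$c
    S[i, ] <- res$s
  }
  rec <- calcium_recording(C, fs = config$fs_hz, S = S)
  truth <- data.frame(cell_id = rec$cell_ids, label = labels,
                      stringsAsFactors = FALSE)
  list(recording = rec, truth = truth, specs = specs)
}

exp_convolve <- function(events, decay) {
  as.numeric(filter(events, decay, method = "recursive"))
}

# Calcium-kernel-filtered Gaussian noise with unit stationary SD: denoised
# traces carry smooth, autocorrelated residuals, not white sample noise
# (a contiguous-duration criterion would be meaningless against the
# latter).
ou_noise <- function(n, decay, sd) {
  sd * sqrt(1 - decay^2) * exp_convolve(rnorm(n), decay)
}

synth_responder_cell <- function(n, dt, decay, onsets, sp, noise_sd) {
  sig <- numeric(n)
  s <- numeric(n)
  dur_k <- round(sp$response_duration_s / dt)
  for (t0 in onsets) {
    k0 <- floor(t0 / dt) + 1L
    if (k0 > n) next
    k1 <- min(n, k0 + dur_k - 1L)
    sig[k0:k1] <- pmax(sig[k0:k1], sp$amplitude_z)
    # exponential tail after the plateau
    if (k1 < n) {
      tail_idx <- (k1 + 1L):min(n, k1 + round(5 / dt))
      sig[tail_idx] <- pmax(sig[tail_idx],
                            sp$amplitude_z * decay^(seq_along(tail_idx)))
    }
    s[k0] <- 1
  }
  list(c = sig + ou_noise(n, decay, noise_sd), s = s)
}

synth_place_cell <- function(n, dt, decay, track, sp, noise_sd) {
  d2 <- (track$x_cm - sp$center_cm[1])^2 + (track$y_cm - sp$center_cm[2])^2
  rate <- sp$base_rate_hz + sp$peak_rate_hz * exp(-d2 / (2 * sp$width_cm^2))
  s <- as.numeric(runif(n) < pmin(rate * dt, 1))
  list(c = sp$event_amp * exp_convolve(s, decay) + ou_noise(n, decay, noise_sd), s = s)
}

synth_speed_cell <- function(n, dt, decay, speed, sp, noise_sd) {
  # events at a speed-proportional rate; trace tracks speed directly
  rate <- 0.05 * speed
  s <- as.numeric(runif(n) < pmin(rate * dt, 1))
  list(c = sp$gain * speed + ou_noise(n, decay, noise_sd), s = s)
}

synth_untuned_cell <- function(n, dt, decay, sp, noise_sd) {
  s <- as.numeric(runif(n) < pmin(sp$rate_hz * dt, 1))
  list(c = sp$event_amp * exp_convolve(s, decay) + ou_noise(n, decay, noise_sd), s = s)
}

#' Write a synthetic session to plain-text files
#'
#' Writes the track (`track.csv`: t_s, x_cm, y_cm), bouts (`bouts.csv`),
#' traces (`traces.csv`: one row per cell) and events (`events.csv`), plus
#' a `ground_truth.json` manifest, into `dir`.
#'
#' @param session list as returned by the generators (`track`, `bouts`,
#'   `recording`, `truth`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(session$track), file.path(dir, "track.csv"),
            row.names = FALSE)
  write.csv(session$bouts, file.path(dir, "bouts.csv"), row.names = FALSE)
  if (!is.null(session$recording)) {
    write.csv(data.frame(cell_id = session$recording$cell_ids,
                         session$recording$C, check.names = FALSE),
              file.path(dir, "traces.csv"), row.names = FALSE)
    if (!is.null(session$recording$S)) {
      write.csv(data.frame(cell_id = session$recording$cell_ids,
                           session$recording$S, check.names = FALSE),
                file.path(dir, "events.csv"), row.names = FALSE)
    }
  }
  truth <- session$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
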