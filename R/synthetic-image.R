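#' Ellipse polygon
#'
#' Vertices of an ellipse with semi-axes `a` (along the orientation axis)
#' and `b` (perpendicular), centred at `center`, rotated by `angle`
#' radians.
#'
#' @param center length-2 centre.
#' @param a,b semi-axes (same units as `center`).
#' @param angle orientation of the `a` axis (radians).
#' @param n number of vertices (default 64).
#' @return n x 2 matrix of vertices.
#' @export
ellipse_polygon <- function(center, a, b, angle = 0, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  ca <- cos(angle); sa <- sin(angle)
  cbind(center[1] + ca * x - sa * y, center[2] + sa * x + ca * y)
}

#' Configuration for synthetic two-population FISH images
#'
#' Emulates a field of two excitatory cell-body populations that differ in
#' soma size, orientation relative to the alveus, and marker expression:
#' population A (ovoid-like) has small somata elongated parallel to the
#' alveus axis and strong channel-1 (Ly6g6e-like) signal; population B
#' (pyramidal-like) has larger somata elongated perpendicular to the
#' alveus and strong channel-2 (Cck-like) signal. A small number of
#' Gad1-positive interneurons can be planted to exercise the excitatory
#' filter.
#'
#' @param seed integer seed.
#' @param n_a,n_b cells per population (defaults 20 and 20).
#' @param n_inhibitory planted Gad1-positive interneurons (default 8; the
#'   Gad1 probe needs enough true signal that the histogram-tail threshold
#'   stays above the background noise, mirroring real FISH channels).
#' @param image_size_px square image side (default 512).
#' @param pixel_size_um micrometres per pixel (default 0.5).
#' @param alveus_angle orientation of the alveus axis (radians, default 0).
#' @param axes_a,axes_b semi-axes (minor, major) in micrometres for each
#'   population (defaults `c(3, 6)` and `c(5, 10)`).
#' @param min_sep_um minimum boundary separation between cells (default 2).
#' @return list of class `image_config`.
#' @export
image_config <- function(seed, n_a = 20, n_b = 20, n_inhibitory = 8,
                         image_size_px = 512, pixel_size_um = 0.5,
                         alveus_angle = 0, axes_a = c(3, 6),
                         axes_b = c(5, 10), min_sep_um = 2) {
  structure(list(seed = as.integer(seed), n_a = n_a, n_b = n_b,
                 n_inhibitory = n_inhibitory, image_size_px = image_size_px,
                 pixel_size_um = pixel_size_um, alveus_angle = alveus_angle,
                 axes_a = axes_a, axes_b = axes_b, min_sep_um = min_sep_um),
            class = "image_config")
}

#' Generate a synthetic two-channel FISH image with ground truth
#'
#' Places non-overlapping elliptical cell bodies (with at least
#' `min_sep_um` separation), paints a bright DAPI nucleus inside each, and
#' fills probe channels: `ly6g6e` covers population-A somata, `cck`
#' population-B somata, `slc17a7` all excitatory somata, and `gad1` the
#' planted interneurons. Background is dim Gaussian noise so the
#' histogram-tail binarization keeps only probe signal.
#'
#' @param config an [image_config].
#' @return list with `channels` (named list of numeric matrices: dapi,
#'   slc17a7, gad1, ly6g6e, cck), `nuclear_labels` (ground-truth nuclear
#'   label matrix), `cell_labels` (full-soma label matrix),
#'   `pixel_size_um`, `alveus_angle`, and `truth` (per-cell data.frame with
#'   population, centre, semi-axes, orientation and a `polygons` list in
#'   micrometres).
#' @export
generate_cell_image <- function(config) {
  stopifnot(inherits(config, "image_config"))
  with_seed(substream_seed(config$seed, "image"), {
    px <- config$pixel_size_um
    sz <- config$image_size_px
    n_tot <- config$n_a + config$n_b + config$n_inhibitory
    pop <- c(rep("A", config$n_a), rep("B", config$n_b),
             rep("I", config$n_inhibitory))
    axes <- rbind(matrix(config$axes_a, config$n_a, 2, byrow = TRUE),
                  matrix(config$axes_b, config$n_b, 2, byrow = TRUE),
                  matrix(c(5, 5), config$n_inhibitory, 2, byrow = TRUE))
    # jitter sizes slightly; keep the two populations well separated
    axes <- axes * matrix(runif(n_tot * 2, 0.95, 1.05), n_tot, 2)
    # orientation of the MAJOR axis: parallel to the alveus for A,
    # perpendicular for B
    ang <- ifelse(pop == "A", config$alveus_angle,
                  config$alveus_angle + pi / 2) + rnorm(n_tot, 0, 0.05)
    r_major <- axes[, 2]
    centers <- matrix(NA_real_, n_tot, 2)
    margin <- max(r_major) + 2
    lim <- sz * px - margin
    for (i in seq_len(n_tot)) {
      placed <- FALSE
      for (try in seq_len(5000)) {
        cand <- runif(2, margin, lim)
        if (i == 1) { placed <- TRUE } else {
          prev <- seq_len(i - 1)
          dmin <- sqrt((centers[prev, 1] - cand[1])^2 +
                       (centers[prev, 2] - cand[2])^2)
          placed <- all(dmin >= r_major[i] + r_major[prev] + config$min_sep_um)
        }
        if (placed) { centers[i, ] <- cand; break }
      }
      if (!placed) stopf("could not place cell %d without overlap after bounded retries", i)
    }
    # rasterize
    blank <- function() matrix(0, sz, sz)
    cell_labels <- matrix(0L, sz, sz)
    nuc_labels <- matrix(0L, sz, sz)
    xg <- (row(blank()) - 0.5) * px
    yg <- (col(blank()) - 0.5) * px
    inside_ellipse <- function(cx, cy, a, b, th) {
      dx <- xg - cx; dy <- yg - cy
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      (u / b)^2 + (v / a)^2 <= 1  # b = major semi-axis along orientation
    }
    polys <- vector("list", n_tot)
    for (i in seq_len(n_tot)) {
      soma <- inside_ellipse(centers[i, 1], centers[i, 2], axes[i, 1],
                             axes[i, 2], ang[i])
      nuc <- inside_ellipse(centers[i, 1], centers[i, 2], 0.55 * axes[i, 1],
                            0.55 * axes[i, 2], ang[i])
      cell_labels[soma] <- i
      nuc_labels[nuc] <- i
      polys[[i]] <- ellipse_polygon(centers[i, ], axes[i, 2], axes[i, 1],
                                    ang[i])
    }
    bg <- function() matrix(pmax(rnorm(sz * sz, 100, 10), 0), sz, sz)
    paint <- function(img, sel) {
      img[sel] <- runif(sum(sel), 2000, 6000)
      img
    }
    ch <- list(dapi = bg(), slc17a7 = bg(), gad1 = bg(), ly6g6e = bg(),
               cck = bg())
    ch$dapi <- paint(ch$dapi, nuc_labels > 0)
    ch$slc17a7 <- paint(ch$slc17a7, cell_labels > 0 &
                          matrix(pop[pmax(cell_labels, 1)] != "I", sz, sz))
    if (any(pop == "I")) {
      ch$gad1 <- paint(ch$gad1, cell_labels > 0 &
                         matrix(pop[pmax(cell_labels, 1)] == "I", sz, sz))
    }
    ch$ly6g6e <- paint(ch$ly6g6e, cell_labels > 0 &
                         matrix(pop[pmax(cell_labels, 1)] == "A", sz, sz))
    ch$cck <- paint(ch$cck, cell_labels > 0 &
                      matrix(pop[pmax(cell_labels, 1)] == "B", sz, sz))
    truth <- data.frame(cell = seq_len(n_tot), population = pop,
                        center_x_um = centers[, 1], center_y_um = centers[, 2],
                        semi_minor_um = axes[, 1], semi_major_um = axes[, 2],
                        angle_rad = ang)
    list(channels = ch, nuclear_labels = nuc_labels,
         cell_labels = cell_labels, pixel_size_um = px,
         alveus_angle = config$alveus_angle, truth = truth,
         polygons = polys)
  })
}
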