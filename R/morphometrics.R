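#' Binarize a probe channel at the histogram tail
#'
#' The threshold is the smallest intensity such that the fraction of pixels
#' strictly above it is at most `tail_fraction`; pixels above the threshold
#' form the mask. The tail fraction is restricted to the 0.2-1% range used
#' for FISH probe signal.
#'
#' @param image numeric matrix of intensities.
#' @param tail_fraction fraction of pixels to keep, in [0.002, 0.01]
#'   (default 0.005).
#' @return logical mask matrix; the threshold is in `attr(, "threshold")`.
#' @export
binarize_channel <- function(image, tail_fraction = 0.005) {
  if (tail_fraction < 0.002 || tail_fraction > 0.01) {
    stopf("tail_fraction must be in [0.002, 0.01]")
  }
  v <- as.numeric(image)
  n <- length(v)
  vals <- sort(unique(v))
  if (length(vals) == 1) {
    warnf("constant image: empty mask")
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- vals
    return(mask)
  }
  counts <- tabulate(match(v, vals), nbins = length(vals))
  frac_above <- (n - cumsum(counts)) / n
  thr <- vals[which(frac_above <= tail_fraction)[1]]
  mask <- image > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Segment nuclei from a DAPI channel
#'
#' Gaussian blur, binarization (Otsu by default), and connected-component
#' labelling. Touching nuclei merged by a coarse blur stay merged; choose
#' `blur_sigma_px` to match nuclear separation.
#'
#' @param dapi_image numeric matrix.
#' @param blur_sigma_px Gaussian blur sigma in pixels (default 2).
#' @param threshold `"otsu"` or a numeric intensity threshold on the
#'   blurred image.
#' @return integer label matrix (0 = background, labels 1..n).
#' @export
segment_nuclei <- function(dapi_image, blur_sigma_px = 2, threshold = "otsu") {
  img <- EBImage::Image(dapi_image / max(1, max(dapi_image)))
  if (blur_sigma_px > 0) img <- EBImage::gblur(img, sigma = blur_sigma_px)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(img, range = range(img))
  } else {
    threshold / max(1, max(dapi_image))
  }
  bin <- img > thr
  if (!any(bin)) {
    warnf("empty foreground: zero nuclei")
    return(matrix(0L, nrow(dapi_image), ncol(dapi_image)))
  }
  lab <- EBImage::bwlabel(bin)
  matrix(as.integer(EBImage::imageData(lab)), nrow(dapi_image), ncol(dapi_image))
}

#' Dilate nuclear labels into cell ROIs
#'
#' Isotropic dilation of each labelled nucleus by `radius_um` (converted to
#' a pixel radius of `ceiling(radius_um / pixel_size_um)`), to include the
#' cytosol around the DAPI nucleus. Pixels contested by two dilated nuclei
#' are assigned to the nearest seed (Euclidean distance to nucleus pixels).
#'
#' @param labels integer label matrix ([segment_nuclei]).
#' @param pixel_size_um pixel size in micrometres.
#' @param radius_um dilation radius in micrometres (default 3).
#' @return integer ROI label matrix (same labels as the input nuclei).
#' @export
dilate_rois <- function(labels, pixel_size_um, radius_um = 3) {
  if (missing(pixel_size_um) || !is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stopf("pixel_size_um must be a positive number")
  }
  if (radius_um < 0) stopf("radius_um must be non-negative")
  if (radius_um == 0) return(labels)
  radius_px <- ceiling(radius_um / pixel_size_um)
  fg <- labels > 0
  # distance of each background pixel to the nearest nucleus pixel
  dm <- EBImage::distmap(EBImage::Image(1 * !fg))
  dm <- matrix(as.numeric(EBImage::imageData(dm)), nrow(labels), ncol(labels))
  cand <- which(!fg & dm > 0 & dm <= radius_px, arr.ind = TRUE)
  out <- labels
  if (nrow(cand)) {
    seeds <- which(fg, arr.ind = TRUE)
    seed_lab <- labels[fg]
    assigned <- class::knn1(seeds, cand, factor(seed_lab))
    out[cand] <- as.integer(as.character(assigned))
  }
  out
}

#' Percent area covered (PAC) of a probe within a cell ROI
#'
#' 100 times the fraction of ROI pixels covered by the binarized probe
#' mask.
#'
#' @param channel_mask logical mask ([binarize_channel]).
#' @param roi logical matrix selecting the cell ROI.
#' @return PAC in [0, 100].
#' @export
percent_area_covered <- function(channel_mask, roi) {
  if (!any(roi)) stopf("empty ROI")
  100 * sum(channel_mask & roi) / sum(roi)
}

#' Per-cell PAC table across probe channels
#'
#' @param channel_masks named list of logical masks, one per probe.
#' @param roi_labels integer ROI label matrix ([dilate_rois]).
#' @return data.frame with `cell` and one `pac_<probe>` column per channel.
#' @export
pac_table <- function(channel_masks, roi_labels) {
  ids <- sort(setdiff(unique(as.integer(roi_labels)), 0L))
  out <- data.frame(cell = ids)
  for (nm in names(channel_masks)) {
    out[[paste0("pac_", nm)]] <- vapply(ids, function(id) {
      percent_area_covered(channel_masks[[nm]], roi_labels == id)
    }, numeric(1))
  }
  out
}

#' Filter putative excitatory neurons by marker PAC
#'
#' Keeps cells with Slc17a7 PAC at or above `slc_min` (boundary inclusive)
#' and Gad1 PAC equal to `gad_max` (default exactly zero).
#'
#' @param cells data.frame with `pac_slc17a7` and `pac_gad1` columns.
#' @param slc_min minimum Slc17a7 PAC (default 0.3).
#' @param gad_max maximum Gad1 PAC (default 0; cells must have none).
#' @return the retained rows of `cells`.
#' @export
filter_excitatory <- function(cells, slc_min = 0.3, gad_max = 0) {
  for (col in c("pac_slc17a7", "pac_gad1")) {
    if (is.null(cells[[col]])) stopf("missing channel column '%s'", col)
  }
  cells[cells$pac_slc17a7 >= slc_min & cells$pac_gad1 <= gad_max, , drop = FALSE]
}

#' Phenotype index from marker PACs
#'
#' Index = (Ly6g6e - Cck) / (Ly6g6e + Cck), on PAC values. Positive values
#' label the cell Ly6g6e-type, negative values Cck-type; an index of
#' exactly 0 is left unassigned, and cells with both PACs zero are
#' undefined (NA index) and flagged with a warning.
#'
#' @param pac_ly6g6e,pac_cck non-negative PAC vectors.
#' @return data.frame with `index` in [-1, 1] (or NA) and `label` in
#'   `{"Ly6g6e", "Cck", "unassigned", NA}`.
#' @export
phenotype_index <- function(pac_ly6g6e, pac_cck) {
  if (any(pac_ly6g6e < 0) || any(pac_cck < 0)) stopf("PAC values must be >= 0")
  tot <- pac_ly6g6e + pac_cck
  idx <- ifelse(tot > 0, (pac_ly6g6e - pac_cck) / tot, NA_real_)
  if (anyNA(idx)) warnf("%d cell(s) with zero PAC in both channels excluded (NA index)",
                        sum(is.na(idx)))
  label <- rep(NA_character_, length(idx))
  label[!is.na(idx) & idx > 0] <- "Ly6g6e"
  label[!is.na(idx) & idx < 0] <- "Cck"
  label[!is.na(idx) & idx == 0] <- "unassigned"
  data.frame(index = idx, label = label, stringsAsFactors = FALSE)
}

# Closed-polygon helpers (vertices as an n x 2 matrix, not repeated).
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(p) {
  j <- c(2:nrow(p), 1)
  sum(sqrt((p[j, 1] - p[, 1])^2 + (p[j, 2] - p[, 2])^2))
}

# Rotating-calipers Feret diameters on the convex hull.
feret_diameters <- function(p) {
  h <- p[grDevices::chull(p), , drop = FALSE]
  nh <- nrow(h)
  d <- as.matrix(dist(h))
  fmax <- max(d)
  j <- c(2:nh, 1)
  widths <- vapply(seq_len(nh), function(i) {
    e <- h[j[i], ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nvec <- c(-e[2], e[1]) / len
    proj <- (h[, 1] - h[i, 1]) * nvec[1] + (h[, 2] - h[i, 2]) * nvec[2]
    max(abs(proj))
  }, numeric(1))
  c(feret_min = min(widths), feret_max = fmax)
}

#' Alveus-registered shape features of a cell-body polygon
#'
#' The polygon is rotated so the alveus axis is horizontal; width is then
#' the extent along the alveus and height the extent perpendicular to it.
#' Features: height, width, alveus aspect ratio (height/width), area,
#' perimeter, circularity (4 pi area / perimeter^2), minimum and maximum
#' Feret diameter (rotating calipers on the convex hull; perimeter uses the
#' original polygon), and Feret ratio (min/max).
#'
#' @param polygon n x 2 matrix of vertices (micrometres, or pixels with
#'   `pixel_size_um` set), in order, not closed.
#' @param alveus_angle orientation of the alveus axis in the image frame
#'   (radians, default 0 = horizontal).
#' @param pixel_size_um scale factor applied to vertices (default 1, i.e.
#'   vertices already in micrometres).
#' @return one-row data.frame of class `shape_features` with columns
#'   `height_um`, `width_um`, `alveus_aspect_ratio`, `area_um2`,
#'   `perimeter_um`, `circularity`, `feret_min_um`, `feret_max_um`,
#'   `feret_ratio`.
#' @export
shape_features <- function(polygon, alveus_angle = 0, pixel_size_um = 1) {
  p <- as.matrix(polygon) * pixel_size_um
  if (nrow(p) < 3) stopf("polygon needs at least 3 vertices")
  area <- polygon_area(p)
  if (area <= 0) stopf("degenerate polygon: zero area")
  # rotate by -alveus_angle so the alveus is horizontal
  ca <- cos(-alveus_angle); sa <- sin(-alveus_angle)
  q <- cbind(ca * p[, 1] - sa * p[, 2], sa * p[, 1] + ca * p[, 2])
  width <- diff(range(q[, 1]))
  height <- diff(range(q[, 2]))
  perim <- polygon_perimeter(p)
  fer <- feret_diameters(p)
  data.frame(
    height_um = height, width_um = width,
    alveus_aspect_ratio = height / width,
    area_um2 = area, perimeter_um = perim,
    circularity = 4 * pi * area / perim^2,
    feret_min_um = unname(fer["feret_min"]),
    feret_max_um = unname(fer["feret_max"]),
    feret_ratio = unname(fer["feret_min"] / fer["feret_max"])
  )
}

#' PCA of cell-body shape features
#'
#' Principal component analysis on centred, unit-variance-scaled features,
#' with a deterministic sign convention (the largest-magnitude loading of
#' each component is made positive).
#'
#' @param features numeric data.frame/matrix (cells x features).
#' @return list with `scores`, `loadings`, `explained_variance`
#'   (eigenvalues; they sum to the number of features), and
#'   `prop_variance`.
#' @export
pca_embedding <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2 || ncol(X) < 2) stopf("need at least 2 cells and 2 features")
  vars <- apply(X, 2, stats::var)
  if (any(vars == 0)) {
    stopf("zero-variance feature(s): %s",
          paste(colnames(X)[vars == 0], collapse = ", "))
  }
  fit <- prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2
  list(scores = fit$x, loadings = fit$rotation, explained_variance = ev,
       prop_variance = ev / sum(ev))
}
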