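PIPELINE_STAGES <- c("simulate", "analyze_session", "tuning", "morphometry",
                     "projections", "biophysics")

default_run_config <- function() {
  list(
    seed = 1,
    stages = c("simulate", "analyze_session", "tuning"),
    simulate = list(duration_s = 300, fs_hz = 20, arena_diameter_cm = 60,
                    n_responder = 10, n_place = 10, n_speed = 5,
                    n_untuned = 25, forced_dwell_s = NULL),
    analyze_session = list(threshold = 0.25, min_duration_s = 10,
                           window_s = 30, pre_s = 10),
    tuning = list(n_shuffles = 500, min_offset_s = 10, nx = 10, ny = 10),
    morphometry = list(n_a = 20, n_b = 20, n_inhibitory = 8,
                       tail_fraction = 0.005),
    projections = list(n_dominant = 10, n_multi = 50, n_neighbors = 20,
                       k = 2),
    biophysics = list(kind = "pyramidal_like", i_step_pa = 5)
  )
}

validate_run_config <- function(config) {
  defaults <- default_run_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  merged <- utils::modifyList(defaults, config)
  unknown_stage <- setdiff(merged$stages, PIPELINE_STAGES)
  if (length(unknown_stage)) {
    stopf("unknown stage(s): %s", paste(unknown_stage, collapse = ", "))
  }
  if ("analyze_session" %in% merged$stages && !"simulate" %in% merged$stages) {
    stopf("stage 'analyze_session' requires 'simulate'")
  }
  if ("tuning" %in% merged$stages && !"simulate" %in% merged$stages) {
    stopf("stage 'tuning' requires 'simulate'")
  }
  merged
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' data and writes tidy CSV outputs plus a JSON manifest (resolved
#' parameters, seed, package version, and SHA-1 hashes of every output
#' file) into `out_dir`. Runs are bit-identical under a fixed config and
#' seed.
#'
#' Stages: `simulate` (session generation), `analyze_session` (responder
#' classification and DI), `tuning` (place/speed/mobility), `morphometry`
#' (synthetic FISH image to phenotype/PCA), `projections` (profile
#' clustering), `biophysics` (passive input resistance, with and without
#' obliques).
#'
#' @param config named list, or path to a YAML file with the same
#'   structure; unknown fields or stages raise a config error before any
#'   computation.
#' @param out_dir output directory (created).
#' @param seed optional override of `config$seed`.
#' @return list of stage results, invisibly; side effect: files in
#'   `out_dir` and `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  if ("simulate" %in% cfg$stages) {
    sim <- cfg$simulate
    specs <- c(
      replicate(sim$n_responder, cell_spec("object_responder"), simplify = FALSE),
      lapply(seq_len(sim$n_place), function(i) {
        ang <- 2 * pi * i / max(1, sim$n_place)
        cell_spec("place", center_cm = 12 * c(cos(ang), sin(ang)))
      }),
      replicate(sim$n_speed, cell_spec("speed"), simplify = FALSE),
      replicate(sim$n_untuned, cell_spec("untuned"), simplify = FALSE)
    )
    sc <- synth_config(seed = cfg$seed, duration_s = sim$duration_s,
                       fs_hz = sim$fs_hz,
                       arena_diameter_cm = sim$arena_diameter_cm,
                       cell_specs = specs,
                       forced_dwell_s = sim$forced_dwell_s)
    beh <- generate_behavior_track(sc)
    rec <- generate_calcium_recording(beh$track, beh$bouts, sc)
    results$simulate <- list(config = sc, track = beh$track,
                             bouts = beh$bouts, recording = rec$recording,
                             truth = rec$truth)
    write_session(list(track = beh$track, bouts = beh$bouts,
                       recording = rec$recording, truth = rec$truth),
                  file.path(out_dir, "session"))
  }
  if ("analyze_session" %in% cfg$stages) {
    an <- cfg$analyze_session
    sim <- results$simulate
    Z <- zscore_traces(sim$recording)
    resp <- classify_responders(Z, sim$bouts, fs = sim$recording$fs,
                                threshold = an$threshold,
                                min_duration_s = an$min_duration_s,
                                window_s = an$window_s, pre_s = an$pre_s)
    di <- if (nrow(sim$bouts)) discrimination_index(sim$bouts) else NULL
    out <- data.frame(cell_id = rownames(resp$flags), resp$flags,
                      check.names = FALSE)
    write.csv(out, file.path(out_dir, "responders.csv"), row.names = FALSE)
    results$analyze_session <- list(responders = resp, di = di)
  }
  if ("tuning" %in% cfg$stages) {
    tu <- cfg$tuning
    sim <- results$simulate
    bins <- spatial_bins(tu$nx, tu$ny, sim$track$arena_diameter_cm)
    place <- place_cell_analysis(sim$recording, sim$track, bins,
                                 n_shuffles = tu$n_shuffles,
                                 min_offset_s = tu$min_offset_s,
                                 seed = substream_seed(cfg$seed, "place"))
    speed <- compute_speed(sim$track)
    mobile <- classify_mobility(speed)
    speed_res <- lapply(seq_len(nrow(sim$recording$C)), function(i) {
      speed_tuning(sim$recording$C[i, ], speed, fs = sim$recording$fs,
                   n_shuffles = tu$n_shuffles,
                   min_offset_s = tu$min_offset_s,
                   seed = substream_seed(cfg$seed, paste0("speed", i)))
    })
    tun <- data.frame(place[, c("cell_id", "mi_bits", "is_place_cell")],
                      speed_r = vapply(speed_res, `[[`, numeric(1), "statistic"),
                      speed_tuned = vapply(speed_res, `[[`, logical(1), "flag"))
    write.csv(tun, file.path(out_dir, "tuning.csv"), row.names = FALSE)
    results$tuning <- list(place = place, speed = speed_res, table = tun)
  }
  if ("morphometry" %in% cfg$stages) {
    mo <- cfg$morphometry
    img <- generate_cell_image(image_config(seed = substream_seed(cfg$seed, "img"),
                                            n_a = mo$n_a, n_b = mo$n_b,
                                            n_inhibitory = mo$n_inhibitory))
    pheno <- phenotype_pipeline(img, tail_fraction = mo$tail_fraction)
    write.csv(pheno$cells, file.path(out_dir, "morphometry.csv"),
              row.names = FALSE)
    results$morphometry <- pheno
  }
  if ("projections" %in% cfg$stages) {
    pr <- cfg$projections
    prof <- generate_projection_profiles(substream_seed(cfg$seed, "proj"),
                                         n_dominant = pr$n_dominant,
                                         n_multi = pr$n_multi)
    norm <- normalize_profiles(prof$lengths)
    cl <- embed_and_cluster(norm, n_neighbors = pr$n_neighbors, k = pr$k,
                            seed = substream_seed(cfg$seed, "umap"))
    out <- data.frame(neuron = seq_len(nrow(norm)), cluster = cl$labels,
                      truth = prof$truth)
    write.csv(out, file.path(out_dir, "projection_clusters.csv"),
              row.names = FALSE)
    results$projections <- list(profiles = prof, clusters = cl, table = out)
  }
  if ("biophysics" %in% cfg$stages) {
    bp <- cfg$biophysics
    morph <- generate_morphology(bp$kind)
    params <- biophys_params()
    r_full <- passive_input_resistance(morph, params, i_step_pa = bp$i_step_pa)
    r_pruned <- if (any(morph$nodes$type == "oblique")) {
      passive_input_resistance(prune_obliques(morph), params,
                               i_step_pa = bp$i_step_pa)
    } else NA_real_
    out <- data.frame(morphology = c(bp$kind, paste0(bp$kind, "_obliqueless")),
                      r_in_mohm = c(as.numeric(r_full), as.numeric(r_pruned)))
    write.csv(out, file.path(out_dir, "input_resistance.csv"),
              row.names = FALSE)
    results$biophysics <- list(table = out)
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "subitools",
    version = as.character(utils::packageVersion("subitools")),
    seed = cfg$seed,
    config = cfg,
    outputs = lapply(setNames(files, files), function(f) {
      digest::digest(file = file.path(out_dir, f), algo = "sha1")
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(results)
}

#' Read a pipeline manifest
#'
#' @param path manifest.json path or its run directory.
#' @return manifest list.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' FISH phenotyping pipeline on a two-channel image set
#'
#' Runs the full image route: histogram-tail binarization of each probe
#' channel, DAPI nuclear segmentation, 3-um ROI dilation, per-cell PAC,
#' excitatory filtering (Slc17a7/Gad1), phenotype index, alveus-registered
#' shape features of the soma outline, and PCA of the features.
#'
#' @param img image set from [generate_cell_image] (or the same structure
#'   built from real channels).
#' @param tail_fraction histogram-tail fraction for probe binarization.
#' @param dilation_um ROI dilation radius (default 3 um).
#' @return list with `cells` (per-cell table: PACs, phenotype index/label,
#'   shape features, PC1/PC2), `pca`, `roi_labels`.
#' @export
phenotype_pipeline <- function(img, tail_fraction = 0.005, dilation_um = 3) {
  masks <- lapply(img$channels[setdiff(names(img$channels), "dapi")],
                  binarize_channel, tail_fraction = tail_fraction)
  nuclei <- segment_nuclei(img$channels$dapi)
  rois <- dilate_rois(nuclei, pixel_size_um = img$pixel_size_um,
                      radius_um = dilation_um)
  pac <- pac_table(masks, rois)
  # segmentation labels carry no meaning; map each ROI to the generating
  # cell (majority overlap) when a ground-truth label image is available
  if (!is.null(img$cell_labels)) {
    pac$truth_cell <- vapply(pac$cell, function(id) {
      hit <- img$cell_labels[rois == id]
      hit <- hit[hit > 0]
      if (!length(hit)) return(NA_integer_)
      as.integer(names(which.max(table(hit))))
    }, integer(1))
  }
  kept <- filter_excitatory(pac)
  pheno <- phenotype_index(kept$pac_ly6g6e, kept$pac_cck)
  kept$index <- pheno$index
  kept$label <- pheno$label
  # soma outline: ground-truth polygon for the matched cell when known,
  # otherwise the ROI contour
  feats <- do.call(rbind, lapply(seq_len(nrow(kept)), function(r) {
    tc <- kept$truth_cell[r]
    poly <- if (!is.null(img$polygons) && !is.null(tc) && !is.na(tc)) {
      img$polygons[[tc]]
    } else {
      oc <- EBImage::ocontour(EBImage::Image(rois == kept$cell[r]))[[1]]
      oc * img$pixel_size_um
    }
    shape_features(poly, alveus_angle = img$alveus_angle)
  }))
  cells <- cbind(kept, feats)
  pca <- pca_embedding(feats)
  cells$pc1 <- pca$scores[, 1]
  cells$pc2 <- pca$scores[, 2]
  list(cells = cells, pca = pca, roi_labels = rois)
}
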