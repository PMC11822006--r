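# SWC structure-type codes; type 5 is used as a documented extension for
# radial oblique dendrites (standard SWC reserves 5+ for custom types).
SWC_TYPES <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L, oblique = 5L)

#' Neuron morphology container
#'
#' A validated SWC-style segment tree: one row per node with id, structure
#' type (`soma`, `axon`, `basal`, `apical`, `oblique`), 3-D position
#' (micrometres), radius (micrometres) and parent id (-1 for the root).
#' `xdist` is the path distance (micrometres) from the soma root to each
#' node, used by distance-dependent channel-density rules.
#'
#' @param nodes data.frame with columns `id`, `type` (character or SWC
#'   integer code), `x`, `y`, `z`, `radius`, `parent`.
#' @return object of class `neuron_morphology`: list with `nodes`
#'   (including `xdist`).
#' @export
neuron_morphology <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stopf("nodes must have columns: %s", paste(need, collapse = ", "))
  }
  nodes <- nodes[, need]
  if (is.numeric(nodes$type)) {
    nodes$type <- names(SWC_TYPES)[match(nodes$type, SWC_TYPES)]
  }
  if (anyNA(nodes$type) || !all(nodes$type %in% names(SWC_TYPES))) {
    stopf("unknown structure type(s)")
  }
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  if (any(nodes$radius <= 0)) {
    stopf("non-positive radius at node(s): %s",
          paste(nodes$id[nodes$radius <= 0], collapse = ", "))
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) stopf("tree must have exactly one root, found %d",
                                length(roots))
  nonroot <- nodes$parent != -1
  orphan <- nonroot & !(nodes$parent %in% nodes$id)
  if (any(orphan)) {
    stopf("parent id(s) reference missing node(s): %s",
          paste(nodes$parent[orphan], collapse = ", "))
  }
  # cycle/connectivity check + xdist by traversal from the root
  ord <- match(nodes$parent, nodes$id)
  xdist <- rep(NA_real_, nrow(nodes))
  xdist[roots] <- 0
  pending <- TRUE
  guard <- 0L
  while (pending) {
    pending <- FALSE
    guard <- guard + 1L
    if (guard > nrow(nodes) + 1L) stopf("cycle detected in morphology")
    todo <- which(is.na(xdist) & !is.na(ord) & !is.na(xdist[ord]))
    if (length(todo)) {
      p <- ord[todo]
      seg <- sqrt((nodes$x[todo] - nodes$x[p])^2 +
                  (nodes$y[todo] - nodes$y[p])^2 +
                  (nodes$z[todo] - nodes$z[p])^2)
      xdist[todo] <- xdist[p] + seg
      pending <- any(is.na(xdist))
    } else if (any(is.na(xdist))) {
      stopf("disconnected nodes or cycle detected in morphology")
    }
  }
  nodes$xdist <- xdist
  structure(list(nodes = nodes), class = "neuron_morphology")
}

#' @exportS3Method base::print
print.neuron_morphology <- function(x, ...) {
  cat(sprintf("<neuron_morphology> %d nodes (%s), max xdist %.0f um\n",
              nrow(x$nodes),
              paste(sprintf("%s:%d", names(table(x$nodes$type)),
                            as.integer(table(x$nodes$type))), collapse = ", "),
              max(x$nodes$xdist)))
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (`id type x y z radius parent`, `#` comments,
#' root parent -1). Structure type 5 is read as `oblique`; alternatively an
#' `oblique_ids` vector (or a sidecar CSV with an `id` column) relabels
#' dendritic nodes as obliques.
#'
#' @param path SWC file path.
#' @param oblique_ids optional integer node ids, or path to a sidecar CSV
#'   with an `id` column, marking oblique-branch nodes.
#' @return a [neuron_morphology].
#' @export
read_swc <- function(path, oblique_ids = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad)) stopf("SWC parse error at line %d: expected 7 columns", bad[1])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stopf("SWC parse error: non-numeric field")
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  if (!is.null(oblique_ids)) {
    if (is.character(oblique_ids)) oblique_ids <- read.csv(oblique_ids)$id
    nodes$type[nodes$id %in% oblique_ids] <- SWC_TYPES[["oblique"]]
  }
  neuron_morphology(nodes)
}

#' Write a morphology to SWC
#'
#' @param morph a [neuron_morphology].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  stopifnot(inherits(morph, "neuron_morphology"))
  n <- morph$nodes
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d", n$id,
                   SWC_TYPES[n$type], n$x, n$y, n$z, n$radius, n$parent)
  writeLines(c("# id type x y z radius parent", lines), path)
  invisible(path)
}

#' Remove radial-oblique branches from a morphology
#'
#' Deletes every subtree rooted at an oblique-labelled node, producing the
#' "obliqueless" variant of a pyramidal-like morphology. If no oblique
#' labels are present the morphology is returned unchanged with a warning.
#'
#' @param morph a [neuron_morphology].
#' @return a [neuron_morphology] without oblique-typed segments.
#' @export
prune_obliques <- function(morph) {
  stopifnot(inherits(morph, "neuron_morphology"))
  nodes <- morph$nodes
  if (!any(nodes$type == "oblique")) {
    warnf("no oblique labels present; morphology unchanged")
    return(morph)
  }
  drop <- nodes$type == "oblique"
  repeat {
    extra <- !drop & nodes$parent %in% nodes$id[drop]
    if (!any(extra)) break
    drop <- drop | extra
  }
  neuron_morphology(nodes[!drop, setdiff(names(nodes), "xdist")])
}

#' Generate a synthetic morphology
#'
#' Four kinds:
#' * `cylinder`: a single unbranched cable of the stated length and
#'   diameter (useful for closed-form cable checks).
#' * `soma_only`: a single spherical soma node.
#' * `pyramidal_like`: soma, apical trunk with labelled radial-oblique
#'   side branches, an apical tuft, and a basal tree.
#' * `obliqueless`: `pyramidal_like` with the oblique branches pruned
#'   (constructed exactly as `prune_obliques(pyramidal_like)`).
#'
#' @param kind morphology kind.
#' @param length_um,diameter_um cylinder geometry (defaults 1000 and 2).
#' @param step_um node spacing along cables (default 10).
#' @param soma_radius_um soma radius (default 10).
#' @param n_obliques number of oblique branches on the trunk (default 6).
#' @param oblique_length_um length of each oblique branch (default 150).
#' @return a [neuron_morphology].
#' @export
generate_morphology <- function(kind = c("cylinder", "soma_only",
                                         "pyramidal_like", "obliqueless"),
                                length_um = 1000, diameter_um = 2,
                                step_um = 10, soma_radius_um = 10,
                                n_obliques = 6, oblique_length_um = 150) {
  kind <- match.arg(kind)
  if (kind == "cylinder") {
    n <- ceiling(length_um / step_um)
    z <- seq(0, length_um, length.out = n + 1)
    nodes <- data.frame(id = seq_len(n + 1), type = "basal", x = 0, y = 0,
                        z = z, radius = diameter_um / 2,
                        parent = c(-1L, seq_len(n)))
    return(neuron_morphology(nodes))
  }
  if (kind == "soma_only") {
    return(neuron_morphology(data.frame(id = 1L, type = "soma", x = 0, y = 0,
                                        z = 0, radius = soma_radius_um,
                                        parent = -1L)))
  }
  if (kind == "obliqueless") {
    full <- generate_morphology("pyramidal_like", length_um = length_um,
                                diameter_um = diameter_um, step_um = step_um,
                                soma_radius_um = soma_radius_um,
                                n_obliques = n_obliques,
                                oblique_length_um = oblique_length_um)
    return(suppressWarnings(prune_obliques(full)))
  }
  # pyramidal_like
  nodes <- data.frame(id = 1L, type = "soma", x = 0, y = 0, z = 0,
                      radius = soma_radius_um, parent = -1L)
  next_id <- 2L
  add_cable <- function(nodes, from_id, dir, len, radius, type, next_id,
                        step = step_um) {
    k <- ceiling(len / step)
    from <- nodes[match(from_id, nodes$id), ]
    tvals <- seq_len(k) / k * len
    ids <- next_id - 1L + seq_len(k)
    new <- data.frame(id = ids, type = type,
                      x = from$x + dir[1] * tvals,
                      y = from$y + dir[2] * tvals,
                      z = from$z + dir[3] * tvals,
                      radius = radius,
                      parent = c(from_id, ids[-k]))
    list(nodes = rbind(nodes, new), next_id = next_id + k, tip = ids[k])
  }
  trunk_len <- 400
  res <- add_cable(nodes, 1L, c(0, 0, 1), trunk_len, 1.5, "apical", next_id)
  nodes <- res$nodes; next_id <- res$next_id; trunk_tip <- res$tip
  # oblique branches leave the trunk at evenly spaced points
  trunk_ids <- nodes$id[nodes$type == "apical"]
  attach_at <- trunk_ids[round(seq(0.2, 0.8, length.out = n_obliques) *
                               length(trunk_ids))]
  for (j in seq_len(n_obliques)) {
    dir <- c(cos(j * pi / 3), sin(j * pi / 3), 0)
    res <- add_cable(nodes, attach_at[j], dir, oblique_length_um, 0.5,
                     "oblique", next_id)
    nodes <- res$nodes; next_id <- res$next_id
  }
  # apical tuft: two branches from the trunk tip
  for (dir in list(c(0.5, 0, 1), c(-0.5, 0, 1))) {
    res <- add_cable(nodes, trunk_tip, dir / sqrt(sum(dir^2)), 200, 0.8,
                     "apical", next_id)
    nodes <- res$nodes; next_id <- res$next_id
  }
  # basal tree: three branches from the soma
  for (dir in list(c(1, 0, -0.5), c(-1, 0, -0.5), c(0, 1, -0.5))) {
    res <- add_cable(nodes, 1L, dir / sqrt(sum(dir^2)), 180, 0.8, "basal",
                     next_id)
    nodes <- res$nodes; next_id <- res$next_id
  }
  neuron_morphology(nodes)
}

#' Generate synthetic axon-projection profiles
#'
#' Two planted clusters of region-by-neuron axon lengths: an ATN-dominant
#' cluster concentrating at least `dominant_frac` of each neuron's length
#' in the designated region, and a multi-target cluster spreading length
#' across the remaining regions (Dirichlet weights).
#'
#' @param seed integer seed.
#' @param n_dominant,n_multi neurons per cluster (defaults 10 and 50).
#' @param regions region names; the first is the dominant target (default
#'   ATN plus five other gray-matter acronyms).
#' @param total_mm_range range of total axon length per neuron (mm).
#' @param dominant_frac minimum fraction of length in the dominant region
#'   for cluster-1 neurons (default 0.95).
#' @return list with `lengths` (neurons x regions matrix, mm) and `truth`
#'   (cluster labels).
#' @export
generate_projection_profiles <- function(seed, n_dominant = 10, n_multi = 50,
                                         regions = c("ATN", "RSP", "PRE",
                                                     "PAR", "POST", "MB"),
                                         total_mm_range = c(20, 60),
                                         dominant_frac = 0.95) {
  if (length(regions) < 2) stopf("need at least 2 regions")
  if (n_dominant + n_multi < 2) stopf("need at least 2 neurons")
  with_seed(substream_seed(seed, "projections"), {
    n <- n_dominant + n_multi
    k <- length(regions)
    rdirichlet <- function(alpha) {
      g <- stats::rgamma(length(alpha), shape = alpha)
      g / sum(g)
    }
    m <- matrix(0, n, k, dimnames = list(NULL, regions))
    totals <- runif(n, total_mm_range[1], total_mm_range[2])
    for (i in seq_len(n_dominant)) {
      f <- runif(1, dominant_frac, 0.99)
      rest <- rdirichlet(rep(1, k - 1)) * (1 - f)
      m[i, ] <- c(f, rest) * totals[i]
    }
    for (i in (n_dominant + 1):n) {
      w <- rdirichlet(rep(2, k - 1))
      f1 <- runif(1, 0, 0.02)
      m[i, ] <- c(f1, w * (1 - f1)) * totals[i]
    }
    truth <- rep(c(1L, 2L), c(n_dominant, n_multi))
    list(lengths = m, truth = truth)
  })
}
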