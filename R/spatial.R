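#' Labeled anatomical point set of one imaging session
#'
#' Bundles the ROI centroid positions, depths and type labels of one
#' field of view, together with the convex hull of all positions (the
#' region of interest for the edge-corrected spatial statistics).
#'
#' @param positions Two-column matrix of (x, y) positions in um.
#' @param labels Integer type labels per point.
#' @param depths Optional depths in um.
#' @param session_id Optional session identifier.
#' @param hull Optional known region of interest (counterclockwise convex
#'   polygon). By default the convex hull of the positions is used; note
#'   that a data-driven hull is slightly smaller than the true sampling
#'   window, which biases density references built from `hull_area`
#'   upward by a percent or two at typical session sizes.
#' @return `sc_points`: list with `positions`, `labels`, `depths`,
#'   `session_id`, `hull` (counterclockwise polygon) and `hull_area`.
#' @export
make_point_set <- function(positions, labels, depths = NULL,
                           session_id = NA, hull = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("at least one point is required")
  if (length(labels) != nrow(positions))
    stop("`labels` must match the number of points")
  if (is.null(hull))
    hull <- if (nrow(positions) >= 3) convex_hull(positions) else positions
  structure(list(positions = positions, labels = as.integer(labels),
                 depths = depths, session_id = session_id,
                 hull = hull,
                 hull_area = if (nrow(hull) >= 3) polygon_area(hull)
                             else 0),
            class = "sc_points")
}

#' Split a dataset into per-session labeled point sets
#'
#' Sessions with 5 or fewer neurons are excluded, matching the inclusion
#' rule for the anatomical analyses.
#'
#' @param dataset An `sc_dataset`.
#' @param labels Type labels per neuron (defaults to ground truth).
#' @param min_neurons Minimum neurons per included session (default 6).
#' @return List of `sc_points`.
#' @export
dataset_point_sets <- function(dataset, labels = NULL, min_neurons = 6) {
  labels <- labels %||% dataset$labels
  ses <- vapply(dataset$neurons, `[[`, 1, "session_id")
  out <- list()
  for (s in unique(ses)) {
    i <- which(ses == s)
    if (length(i) < min_neurons) next
    pos <- t(vapply(dataset$neurons[i], `[[`, numeric(2), "position"))
    dep <- vapply(dataset$neurons[i], `[[`, numeric(1), "depth")
    out[[length(out) + 1]] <- make_point_set(pos, labels[i], dep, s)
  }
  out
}

#' Density recovery profile of one type in one session
#'
#' The probability per unit area of finding a cell of a given type as a
#' function of distance from a cell of the same type: for each annulus
#' `[r, r + bin)` the mean count of same-type cells over reference cells,
#' divided by the mean area of the annulus clipped to the session's
#' convex hull (exact analytic edge correction).
#'
#' @param point_set `sc_points` for one session.
#' @param type_id Type whose profile is computed.
#' @param bin_width Annulus width in um (default 10).
#' @param r_max Maximum radius in um (default 300).
#' @return `sc_drp`: list with `bin_edges`, `density` (cells/um^2),
#'   `counts`, `areas`, `n_reference`; `NULL` density (undefined flag)
#'   when fewer than 2 cells of the type are present.
#' @export
drp <- function(point_set, type_id, bin_width = 10, r_max = 300) {
  idx <- which(point_set$labels == type_id)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  if (length(idx) < 2) {
    return(structure(list(bin_edges = edges, density = NULL, counts = NULL,
                          areas = NULL, n_reference = length(idx),
                          undefined = TRUE), class = "sc_drp"))
  }
  pts <- point_set$positions[idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(pts))
  counts <- numeric(nb)
  for (i in seq_along(idx)) {
    d <- dmat[i, -i]
    counts <- counts + tabulate(findInterval(d, edges,
                                             rightmost.closed = FALSE,
                                             left.open = TRUE) , nbins = nb)
  }
  disc_areas <- disc_polygon_areas(pts, edges, point_set$hull)
  ann <- disc_areas[, -1, drop = FALSE] - disc_areas[, -(nb + 1), drop = FALSE]
  counts <- counts / length(idx)
  areas <- colMeans(ann)
  dens <- ifelse(areas > 0, counts / areas, NA_real_)
  structure(list(bin_edges = edges, density = dens, counts = counts,
                 areas = areas, n_reference = length(idx),
                 undefined = FALSE), class = "sc_drp")
}

#' Average density recovery profiles across sessions
#'
#' @param profiles List of `sc_drp` with identical bins.
#' @return List with `bin_edges`, `density` (mean across defined
#'   profiles) and `sem`.
#' @export
average_drp <- function(profiles) {
  profiles <- Filter(function(p) !isTRUE(p$undefined), profiles)
  if (length(profiles) == 0) return(NULL)
  M <- do.call(rbind, lapply(profiles, `[[`, "density"))
  list(bin_edges = profiles[[1]]$bin_edges,
       density = colMeans(M, na.rm = TRUE),
       sem = apply(M, 2, function(x)
         stats::sd(x, na.rm = TRUE) / sqrt(sum(is.finite(x)))),
       n_sessions = length(profiles))
}

#' Density ratio: near versus far density on the receptive-field scale
#'
#' Compares the mean density of same-type cells within half a receptive
#' field diameter of a cell to the density in the annulus spanning
#' 0.5-1 RF diameters. Visual angle is converted to collicular distance
#' at 88 degrees per mm. A ratio above 1 indicates clustering (patches)
#' on the RF scale.
#'
#' @param profile `sc_drp` (or averaged profile) with `counts` and
#'   `areas`, or `density` only (bins are then weighted equally).
#' @param rf_diameter_deg Receptive-field diameter in degrees.
#' @param deg_per_mm Retinotopic magnification (default 88 deg/mm).
#' @return Scalar density ratio; `NaN` when the far-band density is zero.
#' @export
density_ratio <- function(profile, rf_diameter_deg, deg_per_mm = 88) {
  R <- rf_diameter_deg / deg_per_mm * 1000     # um
  edges <- profile$bin_edges
  if (max(edges) < R)
    stop("profile must extend to at least one RF diameter (", round(R),
         " um)")
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  near <- mid <= 0.5 * R
  far <- mid > 0.5 * R & mid <= R
  if (!is.null(profile$counts) && !is.null(profile$areas)) {
    num <- sum(profile$counts[near]) / sum(profile$areas[near])
    den <- sum(profile$counts[far]) / sum(profile$areas[far])
  } else {
    num <- mean(profile$density[near], na.rm = TRUE)
    den <- mean(profile$density[far], na.rm = TRUE)
  }
  if (!is.finite(den) || den == 0) return(NaN)
  num / den
}

#' Cross-type neighborhood density matrix
#'
#' `D(i, j)`: the number of type-`j` neurons within `radius` of type-`i`
#' neurons, relative to the count expected if type `j` were uniformly
#' distributed over the session hull (per-disc expectation clipped to the
#' hull, summed over reference cells, so that `D = 1` under uniformity).
#' The diagonal exceeding 1 with off-diagonal entries below 1 is the
#' signature of type-specific patches.
#'
#' @param point_set `sc_points`.
#' @param radius Neighborhood radius in um (default 50).
#' @param types Types to include (default: all present).
#' @return List with `D` (types x types), `n_obs`, `n_exp`; entries are
#'   `NA` where a type is absent or the expectation degenerates.
#' @export
cross_type_density <- function(point_set, radius = 50, types = NULL) {
  labs <- point_set$labels
  types <- types %||% sort(unique(labs))
  nt <- length(types)
  pos <- point_set$positions
  n <- nrow(pos)
  dmat <- as.matrix(stats::dist(pos))
  hull <- point_set$hull
  hull_area <- point_set$hull_area
  disc_areas <- disc_polygon_areas(pos, radius, hull)[, 1]
  D <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  n_obs <- n_exp <- D
  for (a in seq_len(nt)) {
    ia <- which(labs == types[a])
    if (length(ia) == 0) next
    for (b in seq_len(nt)) {
      ib <- which(labs == types[b])
      Nj <- length(ib)
      if (Nj == 0) next
      obs <- 0
      expc <- 0
      for (i in ia) {
        others <- setdiff(ib, i)
        obs <- obs + sum(dmat[i, others] <= radius)
        expc <- expc + length(others) * disc_areas[i] / hull_area
      }
      n_obs[a, b] <- obs; n_exp[a, b] <- expc
      if (expc > 0) D[a, b] <- obs / expc
    }
  }
  list(D = D, n_obs = n_obs, n_exp = n_exp, radius = radius)
}

#' Normalized distance between two type point clouds
#'
#' Euclidean distance between the centroids of the two types divided by
#' the mean of their mean pairwise (within-type) distances. Near 0 for
#' interleaved types, large for spatially separated ones.
#'
#' @param points_i,points_j Two-column matrices (>= 2 points each).
#' @return Scalar normalized distance; `NA` with fewer than 2 points in
#'   either type.
#' @export
normalized_distance <- function(points_i, points_j) {
  points_i <- as.matrix(points_i); points_j <- as.matrix(points_j)
  if (nrow(points_i) < 2 || nrow(points_j) < 2) return(NA_real_)
  ci <- colMeans(points_i); cj <- colMeans(points_j)
  dij <- sqrt(sum((ci - cj)^2))
  pdi <- mean(stats::dist(points_i))
  pdj <- mean(stats::dist(points_j))
  dij / (0.5 * (pdi + pdj))
}

#' Bootstrap test of the spatial separation of two types
#'
#' For every session with at least `min_per_type` neurons of both types,
#' shuffles the labels within the pooled pair and computes the fraction
#' of shuffles whose normalized distance reaches the observed one. The
#' pair is declared separated when every qualifying session has
#' p <= alpha.
#'
#' @param sessions List of `sc_points`.
#' @param type_i,type_j Types to compare.
#' @param n_boot Number of label shuffles per session (default 1000).
#' @param alpha Significance threshold (default 0.01).
#' @param min_per_type Qualification threshold per session (default 10).
#' @param seed Integer seed.
#' @return List with `significant` (TRUE/FALSE, or `NA` when no session
#'   qualifies), `p_values` (per qualifying session), `observed_nd`,
#'   `sessions` (ids).
#' @export
separation_test <- function(sessions, type_i, type_j, n_boot = 1000,
                            alpha = 0.01, min_per_type = 10, seed = 1) {
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  p_values <- numeric(0); nds <- numeric(0); ids <- c()
  for (ps in sessions) {
    ii <- which(ps$labels == type_i); jj <- which(ps$labels == type_j)
    if (length(ii) < min_per_type || length(jj) < min_per_type) next
    pool <- ps$positions[c(ii, jj), , drop = FALSE]
    ni <- length(ii)
    obs <- normalized_distance(pool[seq_len(ni), , drop = FALSE],
                               pool[-seq_len(ni), , drop = FALSE])
    cnt <- 0
    for (b in seq_len(n_boot)) {
      perm <- sample.int(nrow(pool))
      nd <- normalized_distance(pool[perm[seq_len(ni)], , drop = FALSE],
                                pool[perm[-seq_len(ni)], , drop = FALSE])
      if (nd >= obs) cnt <- cnt + 1
    }
    p_values <- c(p_values, cnt / n_boot)
    nds <- c(nds, obs)
    ids <- c(ids, ps$session_id)
  }
  if (length(p_values) == 0)
    return(list(significant = NA, p_values = numeric(0),
                observed_nd = numeric(0), sessions = ids))
  list(significant = max(p_values) <= alpha, p_values = p_values,
       observed_nd = nds, sessions = ids)
}

#' Composition of types (or groups) across depth bins
#'
#' Tabulates label composition within depth ranges (default 0-100,
#' 100-200, 200-350 um) and tests composition-by-depth independence with
#' a chi-square test on the count table (no continuity correction).
#'
#' @param depths Depths in um.
#' @param labels Type / group / genotype labels.
#' @param depth_bins Bin edges in um.
#' @return List with `fractions` (labels x bins, columns sum to 1),
#'   `counts`, `chisq` (statistic), `df`, `p_value`.
#' @export
depth_composition <- function(depths, labels,
                              depth_bins = c(0, 100, 200, 350)) {
  bin <- cut(depths, depth_bins, include.lowest = TRUE, right = FALSE)
  counts <- table(label = labels, depth = bin)
  keep <- colSums(counts) > 0
  if (!all(keep)) {
    warning("empty depth bin(s) excluded: ",
            paste(colnames(counts)[!keep], collapse = ", "))
    counts <- counts[, keep, drop = FALSE]
  }
  fractions <- sweep(counts, 2, colSums(counts), "/")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(fractions = fractions, counts = counts,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
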