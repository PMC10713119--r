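#' Tuning parameters for automatic radius selection
#'
#' @param phi minimum average degree for a candidate radius, as a fraction
#'   of the sample count (default 0.10): radii whose neighbor graph has
#'   average degree below `phi * n` are excluded, guarding against sparse,
#'   overfit graphs that exaggerate distances.
#' @param epsilon correlation margin (default 0.05) a smaller radius must
#'   beat the incumbent by before it is preferred; larger values bias the
#'   choice toward large radii that trust more original distances.
#' @param n_radii number of candidate radii evaluated (default 50).
#' @param smooth if `TRUE`, Gaussian-average the adjusted matrices of all
#'   degree-valid radii around the chosen one instead of trusting a single
#'   radius (default `FALSE`).
#' @param smooth_sigma Gaussian width in radius units; default (`NULL`) is
#'   one tenth of the candidate-grid span, so roughly the +/-2 neighboring
#'   grid radii carry visible weight.
#' @param variance_threshold cumulative variance the ordination axes used in
#'   the selection objective must exceed (default 0.80).
#' @param max_dims cap on the number of ordination axes in the objective
#'   (default 10).
#' @return an object of class `lmdist_params`.
#' @export
lmdist_params <- function(phi = 0.10, epsilon = 0.05, n_radii = 50,
                          smooth = FALSE, smooth_sigma = NULL,
                          variance_threshold = 0.80, max_dims = 10) {
  stopifnot(phi > 0, phi < 1,
            epsilon >= 0,
            n_radii >= 1,
            is.logical(smooth), length(smooth) == 1,
            is.null(smooth_sigma) || smooth_sigma > 0,
            variance_threshold > 0, variance_threshold < 1,
            max_dims >= 1)
  structure(list(phi = phi, epsilon = epsilon, n_radii = as.integer(n_radii),
                 smooth = smooth, smooth_sigma = smooth_sigma,
                 variance_threshold = variance_threshold,
                 max_dims = as.integer(max_dims)),
            class = "lmdist_params")
}

#' Candidate radius grid
#'
#' `n_radii` evenly spaced values from just above the minimum positive
#' off-diagonal distance up to and including the maximum distance. The grid
#' spans the full data range: the largest radius trusts (almost) every
#' original value and yields a near-identity adjustment, the smallest
#' trusts only the tightest neighborhoods.
#'
#' @param D distance matrix (or `dist`) with at least one positive
#'   off-diagonal entry.
#' @param n_radii grid size (default 50).
#' @return strictly increasing numeric vector of length `n_radii` (fewer if
#'   all positive distances are equal).
#' @export
candidate_radii <- function(D, n_radii = 50) {
  D <- as_distance_matrix(D)
  off <- D[upper.tri(D)]
  pos <- off[off > 0]
  if (length(pos) == 0)
    stop("all pairwise distances are zero; no radius grid possible")
  lo <- min(pos)
  hi <- max(off)
  if (hi == lo) return(hi)
  lo + seq_len(n_radii) * (hi - lo) / n_radii
}

#' Ordination-fidelity objective for one adjusted matrix
#'
#' How faithfully does a low-dimensional PCoA of the adjusted matrix
#' reproduce the adjusted distances themselves? The embedding is truncated
#' to the smallest axis count exceeding `variance_threshold` cumulative
#' variance (capped at `max_dims`), Euclidean distances among the embedded
#' points are computed, and the Pearson correlation between the two
#' upper-triangle distance vectors is returned. Saturated matrices embed
#' poorly (the arch spreads the gradient over several axes), so this score
#' rises as the adjustment restores an embeddable geometry.
#'
#' @param adjusted adjusted distance matrix.
#' @param params an [lmdist_params()] object (only `variance_threshold` and
#'   `max_dims` are used).
#' @return Pearson correlation in \[-1, 1\]; 0 with a warning when the
#'   embedding is degenerate.
#' @export
objective_correlation <- function(adjusted, params = lmdist_params()) {
  adjusted <- as_distance_matrix(adjusted)
  if (nrow(adjusted) < 3) stop("objective needs at least 3 samples")
  v <- adjusted[upper.tri(adjusted)]
  emb <- tryCatch(pcoa(adjusted), error = function(e) NULL)
  if (is.null(emb)) {
    warning("degenerate embedding: all points identical")
    return(0)
  }
  nd <- dims_for_variance(emb, params$variance_threshold, params$max_dims)
  ed <- as.matrix(dist(emb$coordinates[, seq_len(nd), drop = FALSE]))
  e <- ed[upper.tri(ed)]
  if (sd(v) == 0 || sd(e) == 0) {
    # constant distances: Pearson is undefined, but an equilateral simplex
    # embeds exactly -- score 1 when the embedding reproduces the input
    if (max(abs(v - e)) <= 1e-8 * max(v, 1e-12)) return(1)
    warning("degenerate embedding: constant coordinates")
    return(0)
  }
  cor(v, e)
}

# The selection rule, factored out so it can be verified exhaustively:
# walk the grid from the largest radius down, consider only degree-valid
# radii; the first valid radius is the incumbent, and a smaller radius
# displaces it only when its objective correlation exceeds the incumbent's
# by more than epsilon. Returns the index of the winner, or NA.
choose_radius_index <- function(radius, correlation, valid, epsilon) {
  stopifnot(length(radius) == length(correlation),
            length(radius) == length(valid))
  best <- NA_integer_
  best_cor <- -Inf
  for (k in order(radius, decreasing = TRUE)) {
    if (!valid[k]) next
    if (is.na(best) || correlation[k] > best_cor + epsilon) {
      best <- k
      best_cor <- correlation[k]
    }
  }
  best
}

new_lmdist_result <- function(adjusted, chosen_radius, diagnostics,
                              smoothed = FALSE, params = NULL) {
  structure(list(adjusted = adjusted, chosen_radius = chosen_radius,
                 diagnostics = diagnostics, smoothed = smoothed,
                 params = params),
            class = "lmdist_result")
}

#' @export
print.lmdist_result <- function(x, ...) {
  n <- nrow(x$adjusted)
  if (is.null(x$chosen_radius)) {
    cat(sprintf("lmdist result: %d samples, no adjustment performed\n", n))
  } else {
    cat(sprintf("lmdist result: %d samples, radius %.6g%s\n", n,
                x$chosen_radius, if (x$smoothed) " (Gaussian-smoothed)" else ""))
  }
  if (nrow(x$diagnostics) > 0)
    cat(sprintf("  %d candidate radii evaluated, %d degree-valid\n",
                nrow(x$diagnostics), sum(x$diagnostics$degree_valid)))
  invisible(x)
}

#' Evaluate the radius grid and pick the working radius
#'
#' Every candidate radius is turned into a neighbor graph; radii whose
#' average degree falls below `phi * n` are marked invalid and never chosen.
#' Valid radii get the full adjustment (connectivity repair + geodesics) and
#' the ordination-fidelity objective; the largest valid radius is preferred
#' unless a smaller one beats the incumbent correlation by more than
#' `epsilon`. With fewer than 4 samples, or when no radius is valid, no
#' adjustment is performed and the input is returned unchanged.
#'
#' @param D distance matrix (or `dist`).
#' @param params an [lmdist_params()] object.
#' @param keep_adjusted keep the adjusted matrix of every valid radius in
#'   the result (needed for [gaussian_smooth()]; default `FALSE`).
#' @return an `lmdist_result`: `adjusted` matrix, `chosen_radius` (or
#'   `NULL`), a `diagnostics` data frame (radius, average_degree,
#'   degree_valid, objective_correlation, n_mst_edges), and `smoothed`.
#' @export
select_radius <- function(D, params = lmdist_params(), keep_adjusted = FALSE) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  empty_diag <- data.frame(radius = numeric(0), average_degree = numeric(0),
                           degree_valid = logical(0),
                           objective_correlation = numeric(0),
                           n_mst_edges = integer(0))
  if (n < 4) {
    warning("fewer than 4 samples: radius selection skipped, no adjustment")
    return(new_lmdist_result(D, NULL, empty_diag, FALSE, params))
  }
  radii <- candidate_radii(D, params$n_radii)
  m <- length(radii)
  mst <- complete_mst(D)
  avg_deg <- numeric(m)
  valid <- logical(m)
  corr <- rep(NA_real_, m)
  nmst <- rep(NA_integer_, m)
  per_radius <- vector("list", m)
  for (k in rev(seq_len(m))) {   # largest radius first
    ng <- build_neighbor_graph(D, radii[k])
    avg_deg[k] <- average_degree(ng)
    valid[k] <- avg_deg[k] >= params$phi * n
    if (valid[k]) {
      ngc <- connect_graph(ng, D, mst = mst)
      nmst[k] <- ngc$n_mst_edges
      adj <- geodesic_distances(ngc)
      corr[k] <- objective_correlation(adj, params)
      per_radius[[k]] <- adj
    }
  }
  diagnostics <- data.frame(radius = radii, average_degree = avg_deg,
                            degree_valid = valid,
                            objective_correlation = corr,
                            n_mst_edges = nmst)
  win <- choose_radius_index(radii, corr, valid, params$epsilon)
  if (is.na(win)) {
    res <- new_lmdist_result(D, NULL, diagnostics, FALSE, params)
  } else {
    res <- new_lmdist_result(per_radius[[win]], radii[win], diagnostics,
                             FALSE, params)
  }
  if (keep_adjusted) {
    res$per_radius <- per_radius[valid]
    res$per_radius_values <- radii[valid]
  }
  res
}

#' Gaussian smoothing of adjusted matrices across radii
#'
#' Rather than committing to a single radius, average the adjusted matrices
#' of all degree-valid radii, elementwise, with Gaussian weights
#' \eqn{w_k \propto \exp(-(r_k - r^*)^2 / 2\sigma^2)} centered at the chosen
#' radius. The result is a convex combination, so every entry stays between
#' the elementwise min and max of the inputs.
#'
#' @param matrices list of adjusted distance matrices, one per radius.
#' @param radii numeric vector of the corresponding radii.
#' @param chosen the center radius (the selected one).
#' @param sigma Gaussian width in radius units.
#' @return the smoothed distance matrix.
#' @export
gaussian_smooth <- function(matrices, radii, chosen, sigma) {
  if (length(matrices) == 0) stop("no adjusted matrices to smooth")
  stopifnot(length(matrices) == length(radii), sigma > 0)
  w <- exp(-(radii - chosen)^2 / (2 * sigma^2))
  if (sum(w) == 0) {           # sigma so small all weights underflow
    w <- as.numeric(seq_along(radii) == which.min(abs(radii - chosen)))
  }
  w <- w / sum(w)
  out <- Reduce(`+`, Map(`*`, matrices, w))
  as_distance_matrix(out)
}

#' Fully automatic local manifold adjustment
#'
#' Runs [select_radius()] and, when `params$smooth` is on and a radius was
#' chosen, replaces the single-radius result with the Gaussian-weighted
#' average over all degree-valid radii.
#'
#' @inheritParams select_radius
#' @return an `lmdist_result`.
#' @examples
#' pts <- cbind(sort(runif(12)))
#' res <- lmdist_auto(dist(pts), lmdist_params(n_radii = 10))
#' res$chosen_radius
#' @export
lmdist_auto <- function(D, params = lmdist_params()) {
  res <- select_radius(D, params, keep_adjusted = params$smooth)
  if (params$smooth && !is.null(res$chosen_radius)) {
    sigma <- params$smooth_sigma
    if (is.null(sigma)) {
      span <- diff(range(res$diagnostics$radius))
      sigma <- if (span > 0) span / 10 else res$chosen_radius / 10
    }
    res$adjusted <- gaussian_smooth(res$per_radius, res$per_radius_values,
                                    res$chosen_radius, sigma)
    res$smoothed <- TRUE
  }
  res$per_radius <- NULL
  res$per_radius_values <- NULL
  res
}

#' Adjust a beta-diversity distance matrix (front door)
#'
#' With a fixed `radius`, applies the graph-geodesic transform at that
#' radius; with `radius = NULL` (default), delegates to [lmdist_auto()].
#'
#' @param D distance matrix (or `dist`).
#' @param radius fixed neighborhood radius, or `NULL` for automatic
#'   selection.
#' @param params an [lmdist_params()] object (used in automatic mode; in
#'   fixed mode only for diagnostics bookkeeping).
#' @return an `lmdist_result`.
#' @export
lmdist <- function(D, radius = NULL, params = lmdist_params()) {
  D <- as_distance_matrix(D)
  if (is.null(radius)) return(lmdist_auto(D, params))
  ng <- build_neighbor_graph(D, radius)
  ad <- average_degree(ng)
  ngc <- connect_graph(ng, D)
  adj <- geodesic_distances(ngc)
  diagnostics <- data.frame(radius = radius, average_degree = ad,
                            degree_valid = ad >= params$phi * nrow(D),
                            objective_correlation = NA_real_,
                            n_mst_edges = ngc$n_mst_edges)
  new_lmdist_result(adj, radius, diagnostics, FALSE, params)
}
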