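# AFQ-style bundle cleaning and 100-node tract profile quantification.

#' Resample a fiber to equidistant nodes
#'
#' Returns `n_nodes` points equally spaced in arc length from the first to
#' the last point of the polyline. Point coordinates are interpolated
#' linearly along the polyline; per-point scalar values, when supplied, are
#' interpolated with a cubic spline over arc length.
#'
#' @param fiber Numeric `m x 3` matrix with positive arc length.
#' @param n_nodes Number of nodes (default 100).
#' @param values Optional numeric vector of per-point scalars.
#' @return List with `points` (`n_nodes x 3`), `arc` (node arc positions)
#'   and, if requested, `values` (length `n_nodes`).
#' @export
resample_fiber <- function(fiber, n_nodes = 100L, values = NULL) {
  n_nodes <- assert_scalar_count(n_nodes, "n_nodes", 2L)
  arc <- cum_arc(fiber)
  L <- arc[length(arc)]
  if (L <= 0) stopf("cannot resample a zero-length fiber")
  s <- seq(0, L, length.out = n_nodes)
  pts <- sapply(1:3, function(k) stats::approx(arc, fiber[, k], xout = s)$y)
  out <- list(points = matrix(pts, n_nodes, 3L), arc = s)
  if (!is.null(values)) {
    if (length(values) != nrow(fiber))
      stopf("`values` must align with the fiber points")
    # spline over arc length; duplicate arc positions (coincident points)
    # are collapsed first
    keep <- !duplicated(arc)
    out$values <- splinefun(arc[keep], values[keep], method = "fmm")(s)
  }
  out
}

# Align fiber orientations: flip any fiber whose endpoints match the
# reference better when reversed. Reference is the first fiber.
align_fibers <- function(bundle) {
  ref <- bundle$fibers[[1]]
  a <- ref[1, ]; b <- ref[nrow(ref), ]
  for (i in seq_along(bundle$fibers)) {
    f <- bundle$fibers[[i]]
    d_fwd <- sum((f[1, ] - a)^2) + sum((f[nrow(f), ] - b)^2)
    d_rev <- sum((f[nrow(f), ] - a)^2) + sum((f[1, ] - b)^2)
    if (d_rev < d_fwd) {
      bundle$fibers[[i]] <- f[nrow(f):1, , drop = FALSE]
      bundle$values[[i]] <- rev(bundle$values[[i]])
    }
  }
  bundle
}

resampled_node_array <- function(bundle, n_nodes) {
  bundle <- align_fibers(bundle)
  nf <- n_fibers(bundle)
  pts <- array(NA_real_, c(nf, n_nodes, 3L))
  vals <- matrix(NA_real_, nf, n_nodes)
  for (i in seq_len(nf)) {
    r <- resample_fiber(bundle$fibers[[i]], n_nodes, bundle$values[[i]])
    pts[i, , ] <- r$points
    vals[i, ] <- r$values
  }
  list(points = pts, values = vals)
}

#' Core trajectory of a fiber bundle
#'
#' The core is the pointwise mean of the (orientation-aligned, resampled)
#' fibers; the spread is the pointwise 3 x 3 positional covariance.
#'
#' @param bundle A [streamline_bundle()] with at least 2 fibers.
#' @param n_nodes Number of nodes (default 100).
#' @return An object of class `core_trajectory`: list with `node_positions`
#'   (`n_nodes x 3`), `node_spread` (`3 x 3 x n_nodes`) and `n_fibers`.
#' @export
core_trajectory <- function(bundle, n_nodes = 100L) {
  if (n_fibers(bundle) < 2L) stopf("core trajectory needs >= 2 fibers")
  rs <- resampled_node_array(bundle, n_nodes)
  pos <- apply(rs$points, c(2, 3), mean)
  spread <- array(0, c(3L, 3L, n_nodes))
  for (j in seq_len(n_nodes)) spread[, , j] <- stats::cov(rs$points[, j, ])
  structure(list(node_positions = pos, node_spread = spread,
                 n_fibers = n_fibers(bundle)),
            class = "core_trajectory")
}

# Mahalanobis distance of each fiber's node points to the core;
# returns fibers x nodes matrix. Pseudo-inverse handles degenerate spread
# (zero spread with zero deviation gives distance 0).
node_mahalanobis <- function(points, core) {
  nf <- dim(points)[1]; nn <- dim(points)[2]
  d <- matrix(0, nf, nn)
  for (j in seq_len(nn)) {
    Sinv <- MASS::ginv(core$node_spread[, , j])
    dev <- sweep(points[, j, , drop = FALSE][, 1, ], 2, core$node_positions[j, ])
    d[, j] <- sqrt(pmax(0, rowSums((dev %*% Sinv) * dev)))
  }
  d
}

#' Clean a streamline bundle by outlier rules
#'
#' Removes fibers whose arc length exceeds the bundle mean by more than 4
#' standard deviations, then fibers whose core-deviation score (the mean
#' over nodes of the Mahalanobis distance of the fiber's node points under
#' the core's positional covariance) exceeds the score mean by more than 5
#' standard deviations. Statistics are recomputed and the two rules
#' reapplied until no fiber is removed, up to `max_pass` passes.
#'
#' @param bundle A [streamline_bundle()] with at least 3 fibers.
#' @param n_nodes Nodes used for the core computation (default 100).
#' @param max_pass Maximum cleaning passes (default 5).
#' @return The cleaned [streamline_bundle()]; indices of removed fibers
#'   (relative to the input) in `attr(, "removed")`.
#' @export
clean_bundle <- function(bundle, n_nodes = 100L, max_pass = 5L) {
  if (n_fibers(bundle) < 3L) stopf("cleaning needs >= 3 fibers")
  keep <- seq_len(n_fibers(bundle))
  cur <- bundle
  for (pass in seq_len(max_pass)) {
    removed_this_pass <- integer()
    # rule 1: fiber length
    lens <- vapply(cur$fibers, fiber_length, 1)
    thr_len <- mean(lens) + 4 * sd(lens)
    drop1 <- which(lens > thr_len)
    if (length(drop1) == n_fibers(cur))
      stopf("degenerate bundle: all fibers removed by the length rule")
    if (length(drop1)) {
      removed_this_pass <- c(removed_this_pass, keep[drop1])
      keep <- keep[-drop1]
      cur <- streamline_bundle(cur$fibers[-drop1], cur$values[-drop1],
                               cur$tract_id)
    }
    # rule 2: deviation from the core trajectory
    if (n_fibers(cur) >= 3L) {
      rs <- resampled_node_array(cur, n_nodes)
      core <- core_trajectory(cur, n_nodes)
      score <- rowMeans(node_mahalanobis(rs$points, core))
      thr_dev <- mean(score) + 5 * sd(score)
      drop2 <- which(score > thr_dev)
      if (length(drop2) == n_fibers(cur))
        stopf("degenerate bundle: all fibers removed by the deviation rule")
      if (length(drop2)) {
        removed_this_pass <- c(removed_this_pass, keep[drop2])
        keep <- keep[-drop2]
        cur <- streamline_bundle(cur$fibers[-drop2], cur$values[-drop2],
                                 cur$tract_id)
      }
    }
    if (length(removed_this_pass) == 0L) break
    if (n_fibers(cur) < 3L) break
  }
  if (n_fibers(cur) == 0L) stopf("degenerate bundle: all fibers removed")
  attr(cur, "removed") <- setdiff(seq_len(n_fibers(bundle)), keep)
  cur
}

#' Summarize a bundle into a tract profile
#'
#' At each of the `n_nodes` nodes the profile value is the weighted mean of
#' the contributing fibers' interpolated scalar values, with Gaussian
#' weights `exp(-d^2 / 2)` of each fiber point's Mahalanobis distance `d`
#' to the core at that node, normalized per node. Values are therefore
#' convex combinations of the fiber values.
#'
#' @param bundle A cleaned [streamline_bundle()] with >= 2 fibers.
#' @param subject_id Subject identifier recorded in the profile.
#' @param property Diffusion property the scalar values represent.
#' @param n_nodes Number of profile nodes (default 100).
#' @return An object of class `tract_profile`: list with `subject_id`,
#'   `tract_id`, `property`, `values` (length `n_nodes`) and `units`.
#' @export
profile_bundle <- function(bundle, subject_id, property = "FA",
                           n_nodes = 100L) {
  if (n_fibers(bundle) < 2L) stopf("profiling needs >= 2 fibers")
  if (!property %in% diffusion_properties())
    stopf("unknown property '%s'", property)
  rs <- resampled_node_array(bundle, n_nodes)
  core <- core_trajectory(bundle, n_nodes)
  d <- node_mahalanobis(rs$points, core)
  w <- exp(-d^2 / 2)
  wsum <- colSums(w)
  if (any(wsum <= 0)) stopf("zero total fiber weight at a node")
  vals <- colSums(w * rs$values) / wsum
  structure(list(subject_id = subject_id, tract_id = bundle$tract_id,
                 property = property, values = vals,
                 units = property_units(property)),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("<tract_profile> %s / %s / %s: %d nodes, range [%.4g, %.4g]\n",
              x$subject_id, x$tract_id, x$property, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
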