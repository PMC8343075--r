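# Streamline bundles: containers, synthesis, JSON-lines IO.

#' Streamline bundle container
#'
#' A set of 3-D polylines ("fibers") with one scalar value per point (one
#' diffusion property sampled along the fiber), belonging to one tract.
#'
#' @param fibers List of numeric matrices, each `m_i x 3` with `m_i >= 2`.
#' @param values List of numeric vectors aligned 1:1 with the fiber points.
#' @param tract_id Canonical tract name.
#' @return An object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(fibers, values, tract_id = "unspecified") {
  if (length(fibers) != length(values))
    stopf("`fibers` and `values` must have the same length")
  for (i in seq_along(fibers)) {
    f <- fibers[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) < 2L)
      stopf("fiber %d must be an m x 3 matrix with m >= 2", i)
    if (length(values[[i]]) != nrow(f))
      stopf("values of fiber %d do not align with its points", i)
  }
  structure(list(fibers = fibers, values = values, tract_id = tract_id),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  cat(sprintf("<streamline_bundle> '%s': %d fibers, %d-%d points\n",
              x$tract_id, length(x$fibers),
              min(vapply(x$fibers, nrow, 1L)),
              max(vapply(x$fibers, nrow, 1L))))
  invisible(x)
}

n_fibers <- function(bundle) length(bundle$fibers)

# cumulative arc length of a polyline (first entry 0)
cum_arc <- function(points) {
  seg <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(seg))
}

fiber_length <- function(points) {
  a <- cum_arc(points)
  a[length(a)]
}

# position on (linearly extrapolated) polyline at arc distance s
points_at_arc <- function(points, s) {
  arc <- cum_arc(points)
  L <- arc[length(arc)]
  out <- matrix(NA_real_, length(s), 3L)
  for (k in 1:3) {
    f <- stats::approxfun(arc, points[, k], rule = 2)
    out[, k] <- f(pmin(s, L))
  }
  over <- s > L
  if (any(over)) {
    dirv <- points[nrow(points), ] - points[nrow(points) - 1L, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    out[over, ] <- rep(points[nrow(points), ], each = sum(over)) +
      (s[over] - L) %o% dirv
  }
  out
}

#' Generate a synthetic streamline bundle
#'
#' Fibers are copies of a centerline displaced by a rigid Gaussian offset,
#' with mild fiber-length jitter; this is a fixture generator for the
#' bundle-cleaning and profiling rules. `outlier_spec` injects fibers that
#' violate those rules by construction: `n_long` fibers of roughly twice the
#' centerline length (far beyond the mean + 4 SD length rule) and `n_far`
#' fibers displaced by `30 * dispersion_sd` from the bundle core (far beyond
#' the 5 SD core-deviation rule). Per-point scalars are sampled from
#' `field(s)` where `s` in [0, 1] is the normalized arc position along the
#' fiber.
#'
#' @param n_fibers Number of regular fibers (>= 1).
#' @param centerline Numeric `m x 3` matrix with positive arc length.
#' @param dispersion_sd SD of the rigid fiber offset, in the centerline's
#'   length units.
#' @param length_jitter SD of the relative fiber-length perturbation.
#' @param outlier_spec List with counts `n_long` and `n_far`.
#' @param field Function of normalized arc position returning the scalar
#'   value (vectorized).
#' @param seed Integer seed.
#' @param tract_id Tract name attached to the bundle.
#' @return A [streamline_bundle()]; injected outlier indices are recorded in
#'   `attr(, "injected")`.
#' @export
#' @examples
#' cl <- cbind(seq(0, 99, length.out = 50), 0, 0)
#' b <- generate_bundle(20, cl, dispersion_sd = 1, seed = 7)
generate_bundle <- function(n_fibers, centerline, dispersion_sd,
                            length_jitter = 0.02,
                            outlier_spec = list(n_long = 0L, n_far = 0L),
                            field = function(s) rep(0.5, length(s)),
                            seed = 1L, tract_id = "unspecified") {
  assert_scalar_count(n_fibers, "n_fibers", 1L)
  if (!is.matrix(centerline) || ncol(centerline) != 3L || nrow(centerline) < 2L)
    stopf("`centerline` must be an m x 3 matrix with m >= 2")
  L <- fiber_length(centerline)
  if (L <= 0) stopf("degenerate centerline with zero arc length")
  n_long <- as.integer(outlier_spec$n_long %||% 0L)
  n_far <- as.integer(outlier_spec$n_far %||% 0L)
  npts <- max(nrow(centerline), 20L)

  with_seed(seed, {
    make_fiber <- function(scale, offset) {
      s <- seq(0, L * scale, length.out = npts)
      pts <- points_at_arc(centerline, s) +
        matrix(offset, npts, 3L, byrow = TRUE)
      vals <- field(s / (L * scale))
      list(points = pts, values = vals)
    }
    fibers <- vector("list", n_fibers + n_long + n_far)
    for (i in seq_len(n_fibers)) {
      scale <- max(0.1, 1 + rnorm(1, 0, length_jitter))
      offset <- rnorm(3, 0, dispersion_sd)
      fibers[[i]] <- make_fiber(scale, offset)
    }
    idx_long <- if (n_long > 0) n_fibers + seq_len(n_long) else integer()
    for (i in idx_long) {
      offset <- rnorm(3, 0, dispersion_sd)
      fibers[[i]] <- make_fiber(2.0, offset)
    }
    idx_far <- if (n_far > 0) n_fibers + n_long + seq_len(n_far) else integer()
    for (i in idx_far) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      scale <- max(0.1, 1 + rnorm(1, 0, length_jitter))
      fibers[[i]] <- make_fiber(scale, u * 30 * dispersion_sd)
    }
    b <- streamline_bundle(lapply(fibers, `[[`, "points"),
                           lapply(fibers, `[[`, "values"), tract_id)
    attr(b, "injected") <- list(long = idx_long, far = idx_far)
    b
  })
}

#' Read and write streamline bundles as JSON lines
#'
#' One fiber per line: a JSON object with fields `tract_id`, `points`
#' (array of `[x, y, z]`) and `values`.
#'
#' @param bundle A [streamline_bundle()].
#' @param path File path.
#' @return `read_bundle()` returns a [streamline_bundle()];
#'   `write_bundle()` returns `path` invisibly.
#' @export
write_bundle <- function(bundle, path) {
  lines <- vapply(seq_along(bundle$fibers), function(i) {
    jsonlite::toJSON(list(tract_id = bundle$tract_id,
                          points = unname(bundle$fibers[[i]]),
                          values = bundle$values[[i]]),
                     digits = NA, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  streamline_bundle(lapply(recs, function(r) matrix(r$points, ncol = 3L)),
                    lapply(recs, function(r) as.numeric(r$values)),
                    tract_id = recs[[1]]$tract_id)
}
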