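#' Vietoris-Rips persistence of a point cloud
#'
#' Computes persistent homology of the Vietoris-Rips filtration over the
#' Euclidean metric, in dimensions 0 and (optionally) 1. Every point is
#' born at filtration value 0 in dimension 0; components merge at the
#' single-linkage (minimum-spanning-tree) edge lengths, and each connected
#' component still alive at `max_radius` contributes one essential class
#' with `death = Inf`. Dimension-1 classes are born at the cycle-creating
#' edge and die at the triangle that fills them; zero-persistence pairs are
#' dropped; classes still open at `max_radius` are reported with
#' `death = Inf`.
#'
#' @param points a numeric matrix of point coordinates (one point per row),
#'   e.g. an [embed_cloud()] result.
#' @param max_dim top homological dimension, 0 or 1.
#' @param max_radius filtration cutoff; defaults to the cloud diameter, so
#'   that nothing is essential except the final component.
#' @return A `"persistence_diagram"`: a data frame with columns
#'   `dimension`, `birth`, `death` (Inf for essential classes), carrying
#'   the cutoff as attribute `"max_radius"` and the cloud size as
#'   `"n_points"`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' rips_persistence(sq, max_dim = 1)
#' @export
rips_persistence <- function(points, max_dim = 1L, max_radius = NULL) {
  points <- unclass(points)
  if (!is.matrix(points) || !is.numeric(points))
    stop("'points' must be a numeric matrix (one point per row)", call. = FALSE)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  if (!max_dim %in% c(0L, 1L)) stop("'max_dim' must be 0 or 1", call. = FALSE)
  if (is.null(max_radius)) {
    # diameter; cheap relative to the filtration itself
    max_radius <- sqrt(max(rowSums(points^2))) * 2
    rng <- apply(points, 2, range)
    max_radius <- min(max_radius, sqrt(sum((rng[2, ] - rng[1, ])^2)))
  }
  if (max_radius <= 0) stop("'max_radius' must be positive", call. = FALSE)
  res <- cpp_rips(points, max_radius, as.integer(max_dim))
  n <- nrow(points)
  h0 <- data.frame(dimension = 0L,
                   birth = 0,
                   death = c(res$h0_deaths, rep(Inf, res$n_components)))
  out <- h0
  if (max_dim >= 1L && nrow(res$h1) > 0) {
    h1 <- data.frame(dimension = 1L, birth = res$h1[, 1], death = res$h1[, 2])
    out <- rbind(h0, h1)
  }
  structure(out, max_radius = max_radius, n_points = n,
            class = c("persistence_diagram", "data.frame"))
}

#' @export
print.persistence_diagram <- function(x, ...) {
  for (dm in sort(unique(x$dimension))) {
    sub <- x[x$dimension == dm, ]
    cat(sprintf("dim %d: %d features (%d essential)\n", dm, nrow(sub),
                sum(is.infinite(sub$death))))
  }
  invisible(x)
}

as_persistence_diagram <- function(x) {
  if (inherits(x, "persistence_diagram")) return(x)
  if (is.data.frame(x) && all(c("dimension", "birth", "death") %in% names(x)))
    return(structure(x, class = c("persistence_diagram", "data.frame")))
  stop("'x' is not a persistence diagram", call. = FALSE)
}

#' Random sample on a torus surface
#'
#' Samples `count` points uniformly (with respect to surface area, via
#' rejection on the tube angle) from the torus of revolution
#' `(sqrt(x^2 + y^2) - a)^2 + z^2 = b^2` with central radius `a = 2b`.
#' A dense sample has one connected component and two independent loops,
#' which is the canonical fixture for checking that a persistence pipeline
#' recovers Betti numbers (1, 2).
#'
#' @param count number of points (>= 4).
#' @param tube_radius tube radius `b` (> 0); the central radius is `2 * b`.
#' @param seed optional integer for reproducibility.
#' @return A `count` x 3 matrix of coordinates with attributes
#'   `"tube_radius"` and `"central_radius"`.
#' @export
torus_fixture <- function(count = 1500L, tube_radius = 1, seed = NULL) {
  if (count < 4 || count != round(count)) stop("'count' must be an integer >= 4")
  if (tube_radius <= 0) stop("'tube_radius' must be positive")
  b <- tube_radius
  a <- 2 * b
  pts <- .with_seed(seed, {
    theta <- runif(count, 0, 2 * pi)
    # rejection sampling for area-uniform tube angle phi
    phi <- numeric(count)
    got <- 0L
    while (got < count) {
      need <- count - got
      cand <- runif(2 * need, 0, 2 * pi)
      keep <- runif(2 * need) < (a + b * cos(cand)) / (a + b)
      cand <- cand[keep]
      take <- min(length(cand), need)
      if (take > 0) phi[(got + 1):(got + take)] <- cand[seq_len(take)]
      got <- got + take
    }
    cbind(x = (a + b * cos(phi)) * cos(theta),
          y = (a + b * cos(phi)) * sin(theta),
          z = b * sin(phi))
  })
  structure(pts, tube_radius = b, central_radius = a)
}

#' Death-based binning of a persistence diagram
#'
#' Counts features per homological dimension by death value into the given
#' bins (right-closed). Essential classes (`death = Inf`) are capped at the
#' last edge and counted in the final bin, so the dimension-0 row always
#' sums to the number of points in the source cloud.
#'
#' @param diagram a [rips_persistence()] diagram.
#' @param edges strictly increasing bin boundaries covering every finite
#'   death.
#' @param cap_essential count essential classes in the final bin
#'   (default) or drop them.
#' @return A `"binning_table"`: data frame with one row per dimension and
#'   one column per bin.
#' @examples
#' d <- rips_persistence(rbind(c(0, 0), c(0.5, 0), c(2, 0)))
#' death_binning(d, edges = c(0, 1, 2.5))
#' @export
death_binning <- function(diagram, edges, cap_essential = TRUE) {
  diagram <- as_persistence_diagram(diagram)
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("'edges' must be strictly increasing with >= 2 values", call. = FALSE)
  finite <- diagram$death[is.finite(diagram$death)]
  if (length(finite) && max(finite) > edges[length(edges)])
    stop("last edge must cover the maximum finite death", call. = FALSE)
  dims <- sort(unique(diagram$dimension))
  counts <- matrix(0L, nrow = length(dims), ncol = length(edges) - 1)
  for (r in seq_along(dims)) {
    dd <- diagram$death[diagram$dimension == dims[r]]
    if (cap_essential) dd[is.infinite(dd)] <- edges[length(edges)]
    else dd <- dd[is.finite(dd)]
    if (length(dd))
      counts[r, ] <- tabulate(findInterval(dd, edges, left.open = TRUE,
                                           all.inside = TRUE),
                              nbins = length(edges) - 1)
  }
  colnames(counts) <- paste0(utils::head(edges, -1), "-", edges[-1])
  out <- data.frame(dimension = dims, counts, check.names = FALSE)
  structure(out, edges = edges, class = c("binning_table", "data.frame"))
}

#' Count prominent features by persistence gap
#'
#' Sorts the persistences (death minus birth; essential classes are capped
#' at the filtration cutoff) in decreasing order and returns how many
#' features precede the largest multiplicative gap exceeding `gap_factor`.
#' If no consecutive ratio exceeds the factor, 0 is returned: the diagram
#' has no feature standing out from the noise scale. A torus sample, for
#' example, has exactly 2 prominent dimension-1 features.
#'
#' @param diagram a [rips_persistence()] diagram.
#' @param dimension homological dimension to examine.
#' @param gap_factor multiplicative gap threshold (> 1).
#' @return Integer count of prominent features.
#' @export
prominent_feature_count <- function(diagram, dimension = 1L, gap_factor = 3) {
  diagram <- as_persistence_diagram(diagram)
  if (gap_factor <= 1) stop("'gap_factor' must be > 1", call. = FALSE)
  sub <- diagram[diagram$dimension == dimension, ]
  if (nrow(sub) == 0) return(0L)
  cap <- attr(diagram, "max_radius")
  death <- sub$death
  if (any(is.infinite(death))) {
    if (is.null(cap)) cap <- max(death[is.finite(death)], sub$birth)
    death[is.infinite(death)] <- cap
  }
  pers <- sort(death - sub$birth, decreasing = TRUE)
  pers <- pers[pers > 0]
  if (!length(pers)) return(0L)
  if (length(pers) == 1) return(1L)
  ratio <- pers[-length(pers)] / pmax(pers[-1], .Machine$double.xmin)
  if (max(ratio) <= gap_factor) return(0L)
  which.max(ratio)
}

#' Matching distances between persistence diagrams
#'
#' Bottleneck and Wasserstein distances between the features of one
#' homological dimension, allowing matches to the diagonal `death = birth`.
#' The ground metric on the persistence plane is L-infinity; the
#' Wasserstein distance of order `q` sums per-match L-infinity costs raised
#' to `q` and takes the `q`-th root. Essential classes are dropped
#' (finite-part convention) unless `essential = "cap"`, which caps their
#' death at the larger filtration cutoff of the two diagrams.
#'
#' @param d1,d2 [rips_persistence()] diagrams.
#' @param kind `"bottleneck"` or `"wasserstein"`.
#' @param q Wasserstein order, 1 or 2 (ignored for bottleneck).
#' @param dimension homological dimension compared.
#' @param essential `"drop"` (default) or `"cap"`.
#' @return A non-negative number; 0 exactly when the finite parts agree as
#'   multisets.
#' @examples
#' a <- data.frame(dimension = 1L, birth = 0, death = 2)
#' b <- data.frame(dimension = 1L, birth = 0, death = 1)
#' diagram_distance(a, b, "bottleneck", dimension = 1)  # 1
#' @export
diagram_distance <- function(d1, d2, kind = c("bottleneck", "wasserstein"),
                             q = 1, dimension = 0L,
                             essential = c("drop", "cap")) {
  kind <- match.arg(kind)
  essential <- match.arg(essential)
  if (!q %in% c(1, 2)) stop("'q' must be 1 or 2", call. = FALSE)
  pick <- function(d) {
    d <- as_persistence_diagram(d)
    cap <- attr(d, "max_radius")
    sub <- d[d$dimension == dimension, c("birth", "death"), drop = FALSE]
    list(m = as.matrix(sub), cap = cap)
  }
  a <- pick(d1); b <- pick(d2)
  A <- a$m; B <- b$m
  if (essential == "cap") {
    cap <- max(c(a$cap, b$cap, A[is.finite(A)], B[is.finite(B)], 0))
    A[is.infinite(A)] <- cap
    B[is.infinite(B)] <- cap
  } else {
    A <- A[is.finite(A[, 2]), , drop = FALSE]
    B <- B[is.finite(B[, 2]), , drop = FALSE]
  }
  if (nrow(A) == 0 && nrow(B) == 0) return(0)
  if (kind == "bottleneck") cpp_bottleneck(A, B) else cpp_wasserstein(A, B, q)
}
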