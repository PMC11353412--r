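new_matrix_cloud <- function(members, provenance = NULL, reports = NULL) {
  structure(members, provenance = provenance, reports = reports,
            class = "matrix_cloud")
}

#' Matrix clouds
#'
#' A `matrix_cloud` is an ordered list of numeric matrices of one common
#' shape, carrying a provenance attribute (generator name and parameters,
#' including the seed) sufficient to regenerate it bit-identically.
#'
#' @param members a list of numeric matrices of one common shape.
#' @param provenance optional named list describing how the members were
#'   produced.
#' @return An object of class `"matrix_cloud"`.
#' @export
matrix_cloud <- function(members, provenance = NULL) {
  if (!is.list(members) || length(members) == 0)
    stop("'members' must be a non-empty list of matrices", call. = FALSE)
  lapply(members, .check_matrix, arg = "members[[i]]")
  shapes <- vapply(members, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) > 1)
    stop("all members must share one shape", call. = FALSE)
  new_matrix_cloud(members, provenance)
}

as_matrix_cloud <- function(x) {
  if (inherits(x, "matrix_cloud")) return(x)
  if (is.list(x)) return(new_matrix_cloud(x))
  stop("cannot interpret input as a matrix cloud", call. = FALSE)
}

#' @export
print.matrix_cloud <- function(x, ...) {
  dims <- if (length(x)) paste(dim(x[[1]]), collapse = " x ") else "empty"
  cat(sprintf("matrix cloud: %d members (%s)\n", length(x), dims))
  prov <- attr(x, "provenance")
  if (!is.null(prov$generator))
    cat(sprintf("  generator: %s(mean = %g, sd = %g, seed = %s)\n",
                prov$generator, prov$mean, prov$sd,
                if (is.null(prov$seed)) "none" else prov$seed))
  if (!is.null(prov$surgery))
    cat("  surgery:", prov$surgery$variant, "\n")
  invisible(x)
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a Gaussian random-matrix cloud
#'
#' Draws `count` matrices of order `n` with i.i.d. normal entries. The
#' defaults (10^4 matrices, 3 x 3, mean 0, standard deviation 0.01) are the
#' standard conditions for studying the conditioning of freshly initialised
#' small convolution filters; `sd` is the standard deviation, not the
#' variance.
#'
#' @param count number of matrices (>= 1).
#' @param n matrix order (>= 2).
#' @param mean,sd parameters of the normal law on the entries (`sd > 0`).
#' @param seed optional integer; given the same seed the cloud is
#'   regenerated bit-identically, and the caller's RNG state is left
#'   untouched.
#' @return A [matrix_cloud()] with full provenance.
#' @examples
#' cl <- generate_gaussian_cloud(5, seed = 1)
#' sapply(cl, function(m) condition_report(m)$kappa)
#' @export
generate_gaussian_cloud <- function(count = 10000L, n = 3L, mean = 0,
                                    sd = 0.01, seed = NULL) {
  if (count < 1 || count != round(count)) stop("'count' must be a positive integer")
  if (n < 2 || n != round(n)) stop("'n' must be an integer >= 2")
  if (sd <= 0) stop("'sd' must be positive")
  members <- .with_seed(seed, {
    ent <- matrix(rnorm(count * n * n, mean = mean, sd = sd), nrow = count)
    lapply(seq_len(count), function(i) matrix(ent[i, ], n, n, byrow = TRUE))
  })
  new_matrix_cloud(members, provenance = list(
    generator = "gaussian", count = as.integer(count), n = as.integer(n),
    mean = mean, sd = sd, seed = seed))
}

#' Member-wise inverse of a cloud
#'
#' Inverts each member, preserving order. A member whose smallest singular
#' value falls below `tol` times its largest is treated as numerically
#' singular and rejected with its index, rather than silently dropped or
#' regenerated.
#'
#' @param cloud a [matrix_cloud()] of square matrices.
#' @param tol relative singularity threshold.
#' @return A `matrix_cloud` of the inverses.
#' @export
invert_cloud <- function(cloud, tol = 1e-12) {
  cloud <- as_matrix_cloud(cloud)
  out <- vector("list", length(cloud))
  for (i in seq_along(cloud)) {
    d <- svd(cloud[[i]], nu = 0, nv = 0)$d
    if (d[length(d)] < tol * d[1])
      stop(sprintf("member %d is numerically singular (sigma_n/sigma_1 = %.3g)",
                   i, d[length(d)] / d[1]), call. = FALSE)
    out[[i]] <- solve(cloud[[i]])
  }
  prov <- attr(cloud, "provenance")
  prov$transform <- c(prov$transform, "inverse")
  new_matrix_cloud(out, prov)
}

#' Normalise-and-flatten embedding onto the unit sphere
#'
#' Flattens each member row-major to a vector of length `n * m` and scales
#' it to unit Euclidean norm (whole-matrix Frobenius normalisation), so an
#' n x n cloud becomes a point cloud on the sphere S^(n^2 - 1). Positive
#' scalar multiples of a matrix map to the same point.
#'
#' @param cloud a [matrix_cloud()]; no member may be the zero matrix.
#' @param transform_tag label stored with the embedding (`"original"` or
#'   `"inverse"`), purely descriptive.
#' @return An `"embedded_cloud"`: a numeric matrix with one unit-norm row
#'   per member.
#' @export
embed_cloud <- function(cloud, transform_tag = "original") {
  cloud <- as_matrix_cloud(cloud)
  if (length(cloud) == 0) stop("cannot embed an empty cloud", call. = FALSE)
  pts <- t(vapply(seq_along(cloud), function(i) {
    v <- as.vector(t(cloud[[i]]))  # row-major flatten
    nrm <- sqrt(sum(v^2))
    if (nrm == 0)
      stop(sprintf("member %d is the zero matrix and has no direction", i),
           call. = FALSE)
    v / nrm
  }, numeric(length(cloud[[1]]))))
  structure(pts, transform_tag = transform_tag,
            provenance = attr(cloud, "provenance"),
            class = c("embedded_cloud", "matrix"))
}

#' Extreme-condition-number subclouds
#'
#' Sorts the members by condition number (ascending, ties broken stably by
#' original index) and returns the `k` best- and `k` worst-conditioned
#' members as two clouds, the conventional way of contrasting
#' well-conditioned against ill-conditioned ensembles.
#'
#' @param cloud a [matrix_cloud()] of square matrices.
#' @param k subcloud size (<= number of members).
#' @return A list with components `bottom` (lowest kappa), `top` (highest
#'   kappa), and `kappa` (all condition numbers in original order).
#' @export
select_extremes <- function(cloud, k = 64L) {
  cloud <- as_matrix_cloud(cloud)
  if (k < 1 || k > length(cloud))
    stop(sprintf("'k' must be in 1..%d", length(cloud)), call. = FALSE)
  kap <- vapply(cloud, function(m) condition_report(m)$kappa, 0)
  ord <- order(kap)  # stable
  prov <- attr(cloud, "provenance")
  bot <- new_matrix_cloud(cloud[ord[seq_len(k)]],
                          c(prov, list(selection = sprintf("bottom-%d kappa", k))))
  top_idx <- ord[seq(length(cloud) - k + 1, length(cloud))]
  top <- new_matrix_cloud(cloud[top_idx],
                          c(prov, list(selection = sprintf("top-%d kappa", k))))
  list(bottom = bot, top = top, kappa = kap)
}

#' Summarise the conditioning of a cloud
#'
#' Min/max/mean and histogram counts of the spectral norm, inverse norm and
#' condition number over the members; the kappa histogram can be binned on
#' a log10 scale since condition numbers of Gaussian ensembles are
#' heavy-tailed.
#'
#' @param cloud a [matrix_cloud()] of square matrices.
#' @param bins number of histogram bins.
#' @param log_kappa bin kappa on the log10 scale?
#' @return A list with a `stats` data frame (one row per quantity) and a
#'   `histograms` list of [hist()]-style objects.
#' @export
condition_summary <- function(cloud, bins = 30L, log_kappa = TRUE) {
  cloud <- as_matrix_cloud(cloud)
  if (length(cloud) == 0) stop("empty cloud", call. = FALSE)
  reps <- lapply(cloud, condition_report)
  vals <- list(norm = vapply(reps, `[[`, 0, "norm"),
               inverse_norm = vapply(reps, `[[`, 0, "inverse_norm"),
               kappa = vapply(reps, `[[`, 0, "kappa"))
  stats <- data.frame(
    quantity = names(vals),
    min = vapply(vals, min, 0),
    max = vapply(vals, max, 0),
    mean = vapply(vals, mean, 0),
    row.names = NULL)
  histograms <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    v <- v[is.finite(v)]
    if (nm == "kappa" && log_kappa) v <- log10(v)
    graphics::hist(v, breaks = bins, plot = FALSE)
  })
  names(histograms) <- names(vals)
  list(stats = stats, histograms = histograms)
}
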