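#' @useDynLib svdsurgery, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
NULL

.check_matrix <- function(x, square = FALSE, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  if (square && nrow(x) != ncol(x))
    stop(sprintf("'%s' must be square", arg), call. = FALSE)
  invisible(x)
}

#' Singular value decomposition as a factor object
#'
#' Thin wrapper around [base::svd()] that returns the factors in the
#' `A = U diag(d) Vt` orientation used by the surgery operators, with the
#' singular values guaranteed non-negative and non-increasing.
#'
#' @param x a numeric matrix with finite entries (rectangular allowed).
#' @return An object of class `"svd_factors"`: a list with components `u`
#'   (n x k orthonormal columns), `d` (non-increasing singular values) and
#'   `vt` (k x m, orthonormal rows).
#' @examples
#' f <- svd_decompose(diag(c(4, 2, 1)))
#' f$d
#' @seealso [svd_reconstruct()], [condition_report()]
#' @export
svd_decompose <- function(x) {
  .check_matrix(x)
  s <- svd(x)
  structure(list(u = s$u, d = s$d, vt = t(s$v)), class = "svd_factors")
}

#' Rebuild a matrix from (possibly modified) SVD factors
#'
#' Computes `U diag(d) Vt`. The singular values must be non-negative and
#' non-increasing: every surgery operator keeps this ordering, and a factor
#' object that violates it is refused rather than silently reordered.
#'
#' @param factors an `"svd_factors"` object, typically from
#'   [svd_decompose()] with the `d` component edited.
#' @param tol relative tolerance for the monotonicity check.
#' @return The reconstructed numeric matrix.
#' @export
svd_reconstruct <- function(factors, tol = 1e-9) {
  if (!inherits(factors, "svd_factors"))
    stop("'factors' must come from svd_decompose()", call. = FALSE)
  d <- factors$d
  if (any(d < 0))
    stop("singular values must be non-negative", call. = FALSE)
  if (length(d) > 1) {
    slack <- tol * max(d, 1)
    if (any(diff(d) > slack))
      stop("singular values must be non-increasing", call. = FALSE)
  }
  factors$u %*% (d * factors$vt)
}

#' Condition diagnostics of a square matrix
#'
#' Reports the spectral norm (largest singular value), the spectral norm of
#' the inverse (reciprocal of the smallest singular value) and the condition
#' number `kappa = norm * inverse_norm = sigma_1 / sigma_n`. An exactly
#' singular matrix is reported with `inverse_norm = kappa = Inf` and
#' `singular = TRUE` rather than raising an error, so that ensembles
#' containing near-singular members can still be summarised.
#'
#' @param x a square numeric matrix.
#' @return An object of class `"condition_report"`: list with `norm`,
#'   `inverse_norm`, `kappa`, `singular` and the singular values `d`.
#' @examples
#' condition_report(diag(c(10, 5, 0.1)))$kappa  # 100
#' @export
condition_report <- function(x) {
  .check_matrix(x, square = TRUE)
  d <- svd(x, nu = 0, nv = 0)$d
  s1 <- d[1]
  sn <- d[length(d)]
  singular <- sn == 0
  structure(list(norm = s1,
                 inverse_norm = if (singular) Inf else 1 / sn,
                 kappa = if (singular) Inf else s1 / sn,
                 singular = singular,
                 d = d),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("spectral norm  %.10g\ninverse norm   %.10g\nkappa          %.10g%s\n",
              x$norm, x$inverse_norm, x$kappa,
              if (x$singular) "  (singular)" else ""))
  invisible(x)
}

.surgery_factors <- function(x) {
  .check_matrix(x, square = TRUE)
  if (nrow(x) < 2)
    stop("surgery needs a square matrix of order >= 2", call. = FALSE)
  f <- svd_decompose(x)
  if (f$d[1] <= 0)
    stop("zero matrix: surgery undefined (sigma_1 = 0)", call. = FALSE)
  f
}

#' Tail replacement surgery
#'
#' Replaces every singular value below position `pivot_j` with
#' `sigma_{pivot_j}` and reconstructs, so the output spectrum is
#' `(sigma_1, ..., sigma_j, sigma_j, ..., sigma_j)`. The spectral norm is
#' untouched and the condition number drops to `sigma_1 / sigma_j`.
#'
#' @param x a square numeric matrix.
#' @param pivot_j index of the last singular value kept (1..n). With
#'   `pivot_j = n` the matrix is returned unchanged.
#' @return The reconditioned matrix.
#' @examples
#' condition_report(tail_replace(diag(c(4, 2, 1)), 2))$kappa  # 2
#' @export
tail_replace <- function(x, pivot_j) {
  f <- .surgery_factors(x)
  k <- length(f$d)
  if (!is.numeric(pivot_j) || length(pivot_j) != 1 ||
      pivot_j < 1 || pivot_j > k || pivot_j != round(pivot_j))
    stop(sprintf("'pivot_j' must be an integer in 1..%d", k), call. = FALSE)
  if (pivot_j == k) return(x)
  f$d[(pivot_j + 1):k] <- f$d[pivot_j]
  svd_reconstruct(f)
}

#' Linear-combination replacement surgery
#'
#' Replaces every singular value at positions `>= start_index` with the
#' single value `a * sigma_1 + b * sigma_2` (computed from the original
#' spectrum) and reconstructs. With non-negative weights the condition
#' number of the output is `sigma_1 / (a sigma_1 + b sigma_2)`, hence
#' bounded by `1/a`; e.g. weights `(1/3, 2/3)` bound kappa below 3 and
#' `(1/2, 1/2)` below 2, for every input.
#'
#' A replacement value exceeding `sigma_1` is refused (it would raise the
#' spectral norm); one exceeding `sigma_{start_index - 1}` only triggers a
#' warning, since monotonicity of the output spectrum is then broken.
#'
#' @param x a square numeric matrix.
#' @param weights numeric pair `(a, b)`, both non-negative.
#' @param start_index first position replaced (>= 2).
#' @return The reconditioned matrix.
#' @examples
#' out <- linear_combination_replace(diag(c(9, 3, 1)), c(1/3, 2/3))
#' condition_report(out)$kappa  # 1.8
#' @export
linear_combination_replace <- function(x, weights, start_index = 2) {
  f <- .surgery_factors(x)
  k <- length(f$d)
  if (!is.numeric(weights) || length(weights) != 2 || any(weights < 0))
    stop("'weights' must be two non-negative numbers (a, b)", call. = FALSE)
  if (start_index < 2 || start_index > k || start_index != round(start_index))
    stop(sprintf("'start_index' must be an integer in 2..%d", k), call. = FALSE)
  v <- weights[1] * f$d[1] + weights[2] * f$d[2]
  if (v > f$d[1] * (1 + 1e-12))
    stop("replacement value exceeds sigma_1; refusing to raise the spectral norm",
         call. = FALSE)
  if (v > f$d[start_index - 1] * (1 + 1e-12))
    warning("replacement value exceeds sigma_{start_index-1}; output spectrum reordered")
  f$d[start_index:k] <- v
  f$d <- sort(f$d, decreasing = TRUE)  # no-op unless the warning fired
  svd_reconstruct(f)
}

#' Full orthogonalisation surgery
#'
#' Replaces every singular value with `sigma_1`, i.e. returns
#' `sigma_1 * U Vt`: a scaled orthogonal matrix with condition number 1 and
#' the spectral norm of the input. Its inverse is its transpose divided by
#' `sigma_1^2`, so `out %*% t(out) = sigma_1^2 * I`.
#'
#' @param x a square numeric matrix with `sigma_1 > 0`.
#' @return The scaled orthogonal matrix.
#' @export
orthogonalize <- function(x) {
  f <- .surgery_factors(x)
  f$d[1] * (f$u %*% f$vt)
}

#' Threshold-and-smooth surgery with a condition number bound
#'
#' Guarantees `kappa(out) <= C` while changing well-conditioned matrices not
#' at all: if `kappa(x) <= C` the input is returned bit-identical, with no
#' decomposition round-trip applied. Otherwise every singular value below
#' `x = sigma_1 / C` is raised to that floor, and a forward smoothing pass
#' `sigma_{i+1} <- (sigma_{i+1} + sigma_i) / 2` runs from the last
#' un-clipped index, easing the step the floor introduces. The spectral
#' norm is preserved, the output spectrum is non-increasing and stays at or
#' above the floor, and the operator is idempotent.
#'
#' @param x a square numeric matrix with `sigma_1 > 0`.
#' @param bound_C target upper bound for the condition number (> 1).
#' @return The reconditioned matrix (or `x` itself when already in range).
#' @examples
#' f <- svd_decompose(threshold_smooth(diag(c(10, 5, 0.1)), 10))
#' f$d  # 10 5 3
#' @export
threshold_smooth <- function(x, bound_C) {
  if (!is.numeric(bound_C) || length(bound_C) != 1 || bound_C <= 1)
    stop("'bound_C' must be a single number > 1", call. = FALSE)
  f <- .surgery_factors(x)
  d <- f$d
  k <- length(d)
  floor_x <- d[1] / bound_C
  clipped <- d < floor_x
  if (!any(clipped)) return(x)
  d[clipped] <- floor_x
  j <- which(clipped)[1] - 1L  # last un-clipped index
  if (j >= 1 && j <= k - 1) {
    for (i in j:(k - 1)) d[i + 1] <- (d[i + 1] + d[i]) / 2
  }
  f$d <- d
  svd_reconstruct(f)
}

#' Surgery policy objects
#'
#' Bundles a surgery variant with exactly the parameters that variant
#' needs, for batch application and for serialisation alongside results.
#'
#' @param variant one of `"tail_replace"`, `"linear_combination"`,
#'   `"orthogonalize"`, `"threshold_smooth"`.
#' @param pivot_j pivot index (tail_replace only).
#' @param weights numeric pair `(a, b)` (linear_combination only).
#' @param start_index first replaced position (linear_combination only).
#' @param bound_C condition number bound (threshold_smooth only).
#' @return An object of class `"surgery_policy"`.
#' @examples
#' p <- surgery_policy("linear_combination", weights = c(1/2, 1/2))
#' @export
surgery_policy <- function(variant = c("tail_replace", "linear_combination",
                                       "orthogonalize", "threshold_smooth"),
                           pivot_j = NULL, weights = NULL,
                           start_index = 2L, bound_C = NULL) {
  variant <- match.arg(variant)
  p <- switch(variant,
    tail_replace = {
      if (is.null(pivot_j)) stop("tail_replace needs 'pivot_j'", call. = FALSE)
      list(variant = variant, pivot_j = as.integer(pivot_j))
    },
    linear_combination = {
      if (is.null(weights)) stop("linear_combination needs 'weights'", call. = FALSE)
      if (sum(weights) > 1 + 1e-12)
        warning("weights with a + b > 1 can break monotonicity on some inputs")
      list(variant = variant, weights = as.numeric(weights),
           start_index = as.integer(start_index))
    },
    orthogonalize = list(variant = variant),
    threshold_smooth = {
      if (is.null(bound_C)) stop("threshold_smooth needs 'bound_C'", call. = FALSE)
      list(variant = variant, bound_C = as.numeric(bound_C))
    })
  structure(p, class = "surgery_policy")
}

#' @export
print.surgery_policy <- function(x, ...) {
  pars <- x[setdiff(names(x), "variant")]
  cat("surgery policy:", x$variant,
      if (length(pars)) paste0("(", paste(names(pars), unlist(pars),
                                          sep = " = ", collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Apply a surgery policy to one matrix
#'
#' @param x a square numeric matrix.
#' @param policy a [surgery_policy()] object.
#' @return The reconditioned matrix.
#' @export
apply_policy <- function(x, policy) {
  if (!inherits(policy, "surgery_policy"))
    stop("'policy' must be a surgery_policy object", call. = FALSE)
  switch(policy$variant,
         tail_replace = tail_replace(x, policy$pivot_j),
         linear_combination = linear_combination_replace(x, policy$weights,
                                                         policy$start_index),
         orthogonalize = orthogonalize(x),
         threshold_smooth = threshold_smooth(x, policy$bound_C))
}

#' Apply a surgery policy to every member of a cloud
#'
#' Element-wise application preserving order and count. The result carries
#' a per-member before/after table of norm, inverse norm and condition
#' number as attribute `"reports"`.
#'
#' @param cloud a [matrix_cloud()] whose members are square and share one
#'   shape.
#' @param policy a [surgery_policy()] object.
#' @return A `matrix_cloud` of the reconditioned members.
#' @export
apply_policy_batch <- function(cloud, policy) {
  cloud <- as_matrix_cloud(cloud)
  if (length(cloud) > 0) {
    shapes <- vapply(cloud, function(m) paste(dim(m), collapse = "x"), "")
    if (length(unique(shapes)) > 1)
      stop("all cloud members must share one shape", call. = FALSE)
    if (nrow(cloud[[1]]) != ncol(cloud[[1]]))
      stop("cloud members must be square for surgery", call. = FALSE)
  }
  out <- lapply(cloud, apply_policy, policy = policy)
  reports <- NULL
  if (length(cloud) > 0) {
    before <- lapply(cloud, condition_report)
    after <- lapply(out, condition_report)
    reports <- data.frame(
      index = seq_along(cloud),
      norm_before = vapply(before, `[[`, 0, "norm"),
      inverse_norm_before = vapply(before, `[[`, 0, "inverse_norm"),
      kappa_before = vapply(before, `[[`, 0, "kappa"),
      norm_after = vapply(after, `[[`, 0, "norm"),
      inverse_norm_after = vapply(after, `[[`, 0, "inverse_norm"),
      kappa_after = vapply(after, `[[`, 0, "kappa"))
  }
  prov <- attr(cloud, "provenance")
  prov$surgery <- unclass(policy)
  new_matrix_cloud(out, prov, reports = reports)
}
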