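# Independent oracles used to cross-check the compiled persistence code.

# GF(2) rank by plain Gaussian elimination
gf2_rank <- function(M) {
  if (is.null(dim(M)) || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col] == 1L)
    piv <- piv[piv > r]
    if (!length(piv)) next
    r <- r + 1L
    if (piv[1] != r) M[c(piv[1], r), ] <- M[c(r, piv[1]), ]
    for (row in which(M[, col] == 1L)) {
      if (row != r) M[row, ] <- (M[row, ] + M[r, ]) %% 2
    }
  }
  r
}

# first Betti number of the Vietoris-Rips complex at threshold t, by
# enumerating all edges and triangles and computing
# beta_1 = E - V + C - rank(boundary_2) over GF(2)
brute_betti1 <- function(pts, t) {
  n <- nrow(pts)
  D <- as.matrix(dist(pts))
  edges <- which(upper.tri(D) & D <= t, arr.ind = TRUE)
  E <- nrow(edges)
  comp <- seq_len(n)
  for (k in seq_len(E)) {
    a <- comp[edges[k, 1]]; b <- comp[edges[k, 2]]
    if (a != b) comp[comp == b] <- a
  }
  C <- length(unique(comp))
  eid <- matrix(0L, n, n)
  for (k in seq_len(E)) eid[edges[k, 1], edges[k, 2]] <- k
  tri <- t(combn(n, 3))
  ok <- apply(tri, 1, function(v)
    D[v[1], v[2]] <= t && D[v[1], v[3]] <= t && D[v[2], v[3]] <= t)
  tri <- tri[ok, , drop = FALSE]
  B2 <- matrix(0L, max(E, 1), nrow(tri))
  if (nrow(tri) && E) {
    for (k in seq_len(nrow(tri))) {
      v <- sort(tri[k, ])
      B2[eid[v[1], v[2]], k] <- 1L
      B2[eid[v[1], v[3]], k] <- 1L
      B2[eid[v[2], v[3]], k] <- 1L
    }
  }
  E - n + C - gf2_rank(B2)
}

# number of dimension-dm features alive at threshold t according to a diagram
diagram_betti <- function(pd, dm, t) {
  sub <- pd[pd$dimension == dm, ]
  sum(sub$birth <= t & sub$death > t)
}

# single-linkage merge heights (equal to the MST edge weights, hence the
# finite dimension-0 deaths) via stats::hclust, an independent code path
single_linkage_deaths <- function(pts) {
  sort(stats::hclust(dist(pts), method = "single")$height)
}

random_points <- function(n, d, seed) {
  set.seed(seed)
  matrix(runif(n * d), n, d)
}

random_invertible <- function(n = 3, seed = NULL, sd = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rnorm(n * n, sd = sd), n, n)
    if (condition_report(m)$kappa < 1e8) return(m)
  }
}

expect_same_matrix <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol * max(1, max(abs(b))))
}
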