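test_that("rips recovers hand-enumerable diagrams on tiny configurations", {
  # two points at distance d: one component dies at d, one is essential
  two <- rbind(c(0, 0), c(0, 3))
  pd <- rips_persistence(two, max_dim = 0)
  expect_equal(nrow(pd), 2)
  expect_equal(sort(pd$death), c(3, Inf))
  expect_true(all(pd$birth == 0))

  # unit square: single 1-cycle born at side length, killed at the diagonal
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  h1 <- rips_persistence(sq, max_dim = 1)
  h1 <- h1[h1$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1, tolerance = 1e-12)
  expect_equal(h1$death, sqrt(2), tolerance = 1e-12)

  # regular hexagon, circumradius 1: cycle (1, sqrt(3))
  th <- 2 * pi * (0:5) / 6
  hx <- rips_persistence(cbind(cos(th), sin(th)), max_dim = 1)
  hx <- hx[hx$dimension == 1, ]
  expect_equal(nrow(hx), 1)
  expect_equal(hx$birth, 1, tolerance = 1e-12)
  expect_equal(hx$death, sqrt(3), tolerance = 1e-12)

  expect_error(rips_persistence(matrix(0, 1, 2)), "2 points")
})

test_that("dimension-0 deaths equal single-linkage merge heights", {
  for (seed in 1:6) {
    pts <- random_points(25, 3, seed)
    pd <- rips_persistence(pts, max_dim = 0)
    expect_equal(nrow(pd), 25)  # one feature per point
    deaths <- sort(pd$death[is.finite(pd$death)])
    expect_equal(deaths, single_linkage_deaths(pts), tolerance = 1e-12)
    expect_equal(sum(is.infinite(pd$death)), 1)
  }
})

test_that("diagrams agree with the brute-force GF(2) Betti oracle on <= 6 points", {
  for (seed in 1:8) {
    pts <- random_points(6, 2, seed)
    pd <- rips_persistence(pts, max_dim = 1)
    crit <- sort(unique(as.vector(dist(pts))))
    probes <- c((crit[-1] + crit[-length(crit)]) / 2, max(crit) * 1.01)
    for (t in probes) {
      expect_equal(diagram_betti(pd, 1L, t), brute_betti1(pts, t),
                   info = sprintf("seed %d, t %.4f", seed, t))
    }
  }
})

test_that("a filtration cutoff caps unfilled cycles as essential classes", {
  th <- 2 * pi * (0:5) / 6
  pts <- cbind(cos(th), sin(th))
  pd <- rips_persistence(pts, max_dim = 1, max_radius = 1.2)  # < sqrt(3)
  h1 <- pd[pd$dimension == 1, ]
  expect_equal(nrow(h1), 1)
  expect_identical(h1$death, Inf)
  expect_equal(h1$birth, 1, tolerance = 1e-12)
})

test_that("torus samples satisfy the surface equation and are reproducible", {
  tor <- torus_fixture(400, tube_radius = 0.5, seed = 8)
  b <- 0.5; a <- 1
  resid <- (sqrt(tor[, 1]^2 + tor[, 2]^2) - a)^2 + tor[, 3]^2 - b^2
  expect_lt(max(abs(resid)), 1e-12)
  expect_identical(torus_fixture(400, 0.5, seed = 8), tor)
  expect_error(torus_fixture(3), "count")
  expect_error(torus_fixture(10, 0), "tube_radius")
})

test_that("death binning counts per dimension with the essential-cap rule", {
  d <- structure(data.frame(dimension = c(0L, 0L), birth = c(0, 0),
                            death = c(0.5, Inf)),
                 class = c("persistence_diagram", "data.frame"))
  tab <- death_binning(d, edges = c(0, 1, 2))
  expect_equal(unlist(tab[1, -1], use.names = FALSE), c(1L, 1L))

  empty <- structure(data.frame(dimension = integer(), birth = numeric(),
                                death = numeric()),
                     class = c("persistence_diagram", "data.frame"))
  expect_equal(nrow(death_binning(empty, c(0, 1))), 0)

  cl <- generate_gaussian_cloud(64, seed = 17)
  pd <- rips_persistence(embed_cloud(cl), max_dim = 1, max_radius = 2.5)
  tab <- death_binning(pd, default_bin_edges("coarse"))
  expect_equal(sum(tab[tab$dimension == 0, -1]), 64)  # conservation

  expect_error(death_binning(pd, c(1, 0.5)), "increasing")
  expect_error(death_binning(pd, c(0, 0.1)), "cover")
})

test_that("prominence counting finds gaps in sorted persistence", {
  one <- structure(data.frame(dimension = 1L, birth = 0.2, death = 0.9),
                   class = c("persistence_diagram", "data.frame"))
  expect_equal(prominent_feature_count(one, 1, 3), 1L)

  none <- structure(data.frame(dimension = 1L, birth = c(0, 0, 0),
                               death = c(1, 0.9, 0.8)),
                    class = c("persistence_diagram", "data.frame"))
  expect_equal(prominent_feature_count(none, 1, 3), 0L)

  # a circle has exactly one prominent cycle
  set.seed(30)
  th <- runif(80, 0, 2 * pi)
  circ <- rips_persistence(cbind(cos(th), sin(th)), max_dim = 1)
  expect_equal(prominent_feature_count(circ, 1, 3), 1L)

  # uniform points in a disc: no prominent cycle at gap factor 3
  set.seed(31)
  r <- sqrt(runif(150)); ang <- runif(150, 0, 2 * pi)
  disc <- rips_persistence(cbind(r * cos(ang), r * sin(ang)), max_dim = 1)
  expect_equal(prominent_feature_count(disc, 1, 3), 0L)
})

test_that("diagram distances are metrics with the exact matching values", {
  a <- structure(data.frame(dimension = 1L, birth = 0, death = 2),
                 class = c("persistence_diagram", "data.frame"))
  b <- structure(data.frame(dimension = 1L, birth = 0, death = 1),
                 class = c("persistence_diagram", "data.frame"))
  # optimal matching pairs the two points at L-inf cost 1 (the all-diagonal
  # alternative costs max(1, 0.5) = 1 for bottleneck, 1.5 for W1)
  expect_equal(diagram_distance(a, b, "bottleneck", dimension = 1), 1)
  expect_equal(diagram_distance(a, b, "wasserstein", q = 1, dimension = 1), 1)
  expect_equal(diagram_distance(a, b, "wasserstein", q = 2, dimension = 1), 1)
  expect_equal(diagram_distance(a, a, "bottleneck", dimension = 1), 0)
  expect_equal(diagram_distance(b, b, "wasserstein", q = 2, dimension = 1), 0)

  # one diagram empty: everything projects to the diagonal
  empty <- structure(data.frame(dimension = integer(), birth = numeric(),
                                death = numeric()),
                     class = c("persistence_diagram", "data.frame"))
  expect_equal(diagram_distance(a, empty, "bottleneck", dimension = 1), 1)
  expect_equal(diagram_distance(a, empty, "wasserstein", q = 1, dimension = 1), 1)

  # symmetry and triangle inequality on random diagrams
  set.seed(41)
  mk <- function(n) {
    birth <- runif(n)
    structure(data.frame(dimension = 1L, birth = birth,
                         death = birth + runif(n)),
              class = c("persistence_diagram", "data.frame"))
  }
  x <- mk(7); y <- mk(5); z <- mk(6)
  for (kind in c("bottleneck", "wasserstein")) {
    dxy <- diagram_distance(x, y, kind, dimension = 1)
    dyx <- diagram_distance(y, x, kind, dimension = 1)
    dxz <- diagram_distance(x, z, kind, dimension = 1)
    dzy <- diagram_distance(z, y, kind, dimension = 1)
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(dxy, dxz + dzy + 1e-12)
  }
})

test_that("bottleneck distance is stable under small point perturbations", {
  pts <- random_points(30, 3, 52)
  eps <- 0.01
  set.seed(53)
  pert <- pts + matrix(runif(length(pts), -eps / sqrt(3), eps / sqrt(3)),
                       nrow(pts))
  d1 <- rips_persistence(pts, max_dim = 1)
  d2 <- rips_persistence(pert, max_dim = 1)
  # a pairwise distance can change by both endpoints' displacements, so the
  # Vietoris-Rips stability bound is 2 * eps
  for (dm in 0:1)
    expect_lte(diagram_distance(d1, d2, "bottleneck", dimension = dm), 2 * eps)
})

test_that("diagram CSV round trip preserves essentials", {
  cl <- generate_gaussian_cloud(10, seed = 19)
  pd <- rips_persistence(embed_cloud(cl), max_dim = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagram_csv(pd, path)
  back <- read_diagram_csv(path)
  expect_equal(back$dimension, pd$dimension)
  expect_equal(back$birth, pd$birth, tolerance = 1e-15)
  expect_equal(back$death, pd$death, tolerance = 1e-15)
})
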