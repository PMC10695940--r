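# icv: convex-hull volume

test_that("hull volumes of cube, tetrahedron and sphere match closed forms", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  r <- convex_hull_volume(cube)
  expect_equal(r$volume * 1000, 1, tolerance = 1e-12)
  expect_equal(r$n_hull_vertices, 8L)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    10 / (2 * sqrt(2))
  rt <- convex_hull_volume(tet)
  expect_equal(rt$volume * 1000, 1000 / (6 * sqrt(2)), tolerance = 1e-9)
  set.seed(1)
  p <- matrix(rnorm(30000), ncol = 3)
  p <- 50 * p / sqrt(rowSums(p^2))
  rs <- convex_hull_volume(p)
  ball <- 4 / 3 * pi * 50^3
  expect_lte(rs$volume * 1000, ball)                  # inscribed polytope
  expect_lt(abs(rs$volume * 1000 / ball - 1), 0.01)   # within 1%
})

test_that("hull volume is invariant under rigid motion", {
  set.seed(7)
  q <- matrix(rnorm(600), ncol = 3)
  v0 <- convex_hull_volume(q)$volume
  th <- 0.9
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  qt <- q %*% t(Rz) + matrix(c(10, -4, 2), nrow(q), 3, byrow = TRUE)
  expect_equal(convex_hull_volume(qt)$volume, v0, tolerance = 1e-10)
})

test_that("adding interior points never changes the hull volume", {
  set.seed(2)
  q <- matrix(rnorm(300), ncol = 3) * 5
  v0 <- convex_hull_volume(q)$volume
  inner <- matrix(runif(90, -0.5, 0.5), ncol = 3)
  expect_equal(convex_hull_volume(rbind(q, inner))$volume, v0,
               tolerance = 1e-12)
})

test_that("hull volume bounds the enclosed mesh volume from above", {
  s <- generate_skull(skull_spec(mesh_edge_target = 8))
  hull_ml <- convex_hull_volume(s$vertices)$volume
  # close the foramen with a fan to get a watertight mesh volume
  loop <- s$foramen_loop
  cen <- colMeans(s$vertices[loop, ])
  v2 <- rbind(s$vertices, cen)
  ci <- nrow(v2)
  fan <- cbind(loop, c(loop[-1], loop[1]), ci)
  closed <- rbind(s$faces, fan)
  mv <- mesh_volume(v2, closed)
  if (mv < 0) mv <- mesh_volume(v2, closed[, c(1, 3, 2)])
  expect_gt(hull_ml, abs(mv) * 0.999)
})

test_that("degenerate input errors clearly", {
  expect_error(convex_hull_volume(matrix(rnorm(6), ncol = 3)), "degenerate")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(convex_hull_volume(flat), "degenerate")
  expect_error(convex_hull_volume(matrix(1, 10, 2)))
})

test_that("icv_gain computes percent gain and validates input", {
  expect_equal(icv_gain(1000, 1200), 20)
  expect_equal(icv_gain(800, 760), -5)
  expect_error(icv_gain(0, 100))
  expect_error(icv_gain(-5, 100))
})
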