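# Shared helpers for the test suite.

# structured grid of a unit (or a x b) rectangle in the z = 0 plane
grid_mesh <- function(nx, ny, a = 1, b = 1) {
  xs <- seq(0, a, length.out = nx + 1)
  ys <- seq(0, b, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  nodes <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * (nx + 1) + i
  tris <- matrix(0L, 0, 3)
  for (j in 1:ny) for (i in 1:nx) {
    tris <- rbind(tris,
                  c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                  c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  list(nodes = nodes, tris = tris)
}

# total surface area of a region of a cut mesh
region_area <- function(cut, reg) {
  f <- cut$faces[cut$region == reg, , drop = FALSE]
  v1 <- cut$vertices[f[, 1], , drop = FALSE]
  v2 <- cut$vertices[f[, 2], , drop = FALSE]
  v3 <- cut$vertices[f[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# a small aligned skull reused across tests (coarse, deterministic)
cached_aligned_skull <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 6))
      cache <<- align_to_frame(s)$surface
    }
    cache
  }
})
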