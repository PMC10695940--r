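# synthetic_skull: parametric calvarium generator

test_that("skull_spec validates its arguments", {
  sp <- skull_spec()
  expect_s3_class(sp, "skull_spec")
  expect_equal(sp$length_ap, 170)
  expect_equal(sp$width_ml, 140)
  expect_equal(sp$height_cc, 100)
  expect_error(skull_spec(length_ap = -1))
  expect_error(skull_spec(thickness = 0))
  expect_error(skull_spec(mesh_edge_target = 0))
  expect_error(skull_spec(foramen_radius = -2))
})

test_that("generated skull is a valid open shell with landmarks", {
  s <- generate_skull(skull_spec(mesh_edge_target = 8))
  expect_s3_class(s, "skull_surface")
  expect_true(validate_skull_surface(s))
  expect_true(all(c("nasion", "meatus_left", "meatus_right") %in%
                    names(s$landmarks)))
  expect_gt(length(s$foramen_loop), 3)
  # foramen loop is a boundary loop of the mesh
  bnd <- unique(as.vector(vaultsim:::boundary_half_edges(s$faces)))
  expect_true(all(s$foramen_loop %in% bnd))
  # extents match the spec within a tolerance of one edge length
  ext <- apply(s$vertices, 2, function(v) diff(range(v)))
  expect_lt(abs(ext[1] - 170), 8)
  expect_lt(abs(ext[3] - 140), 8)
})

test_that("hemisphere special case reproduces the half-ball hull volume", {
  sp <- skull_spec(length_ap = 160, width_ml = 160, height_cc = 80,
                   foramen_radius = 0, mesh_edge_target = 4,
                   bump_amplitude = 0)
  s <- generate_skull(sp)
  hv_mm3 <- convex_hull_volume(s$vertices)$volume * 1000
  expect_lt(abs(hv_mm3 / (2 / 3 * pi * 80^3) - 1), 0.02)
})

test_that("generation is deterministic and seed-sensitive", {
  sp <- skull_spec(mesh_edge_target = 9, seed = 4)
  s1 <- generate_skull(sp)
  s2 <- generate_skull(sp)
  expect_identical(s1$vertices, s2$vertices)
  s3 <- generate_skull(skull_spec(mesh_edge_target = 9, seed = 5))
  expect_false(identical(s1$vertices, s3$vertices))
})

test_that("bump amplitude zero gives a mirror-symmetric surface", {
  s <- cached_aligned_skull()
  zm <- mean(range(s$vertices[, 3]))
  vm <- s$vertices
  vm[, 3] <- 2 * zm - vm[, 3]
  d <- vapply(seq_len(nrow(vm)), function(i) {
    min(sqrt(colSums((t(s$vertices) - vm[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 1e-6)
})

test_that("default skull volume is in the infant range and converges", {
  sd1 <- generate_skull(skull_spec())
  v_ml <- convex_hull_volume(sd1$vertices)$volume
  expect_gt(v_ml, 900)
  expect_lt(v_ml, 1800)
  s6 <- generate_skull(skull_spec(bump_amplitude = 0))
  s3 <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 3))
  v6 <- convex_hull_volume(s6$vertices)$volume
  v3 <- convex_hull_volume(s3$vertices)$volume
  expect_lt(abs(v3 - v6) / v6, 0.005)
})

test_that("growth scaling scales hull volume by factor^3", {
  s <- generate_skull(skull_spec(mesh_edge_target = 8))
  sg <- scale_for_growth(s, 1.1)
  r <- convex_hull_volume(sg$vertices)$volume /
    convex_hull_volume(s$vertices)$volume
  expect_lt(abs(r - 1.1^3), 1e-6)
  expect_error(scale_for_growth(s, 0))
})

test_that("a 20-seed sweep yields valid surfaces at coarse resolution", {
  for (sdd in 1:20) {
    ss <- generate_skull(skull_spec(mesh_edge_target = 9, seed = sdd))
    expect_true(validate_skull_surface(ss))
  }
})

test_that("generate_cohort assigns procedures and honours variability", {
  coh <- generate_cohort(2, 3, 1, skull_spec(mesh_edge_target = 10),
                         variability = 0.05, seed = 1)
  expect_length(coh, 6)
  tab <- table(vapply(coh, `[[`, "", "procedure"))
  expect_equal(as.integer(tab[c("L2", "T2", "TL4")]), c(3L, 2L, 1L))
  expect_false(identical(coh[[1]]$surface$vertices, coh[[2]]$surface$vertices))
  coh0 <- generate_cohort(2, 0, 0, skull_spec(mesh_edge_target = 10),
                          variability = 0, seed = 1)
  expect_identical(coh0[[1]]$surface$vertices, coh0[[2]]$surface$vertices)
  # reproducible across calls
  coh2 <- generate_cohort(2, 3, 1, skull_spec(mesh_edge_target = 10),
                          variability = 0.05, seed = 1)
  expect_identical(coh[[4]]$surface$vertices, coh2[[4]]$surface$vertices)
})

test_that("validate_skull_surface rejects broken meshes", {
  s <- generate_skull(skull_spec(mesh_edge_target = 9))
  bad <- s
  bad$faces <- rbind(bad$faces, bad$faces[1, ])      # duplicated face
  expect_error(validate_skull_surface(bad))
  bad2 <- s
  bad2$landmarks$nasion <- NULL
  expect_error(validate_skull_surface(bad2))
})
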