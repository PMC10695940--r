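# frame_osteotomy part 1: rigid transforms and landmark-based alignment

test_that("transforms compose, invert and apply correctly", {
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tf <- frame_transform(rotation = Rz, translation = c(1, -2, 3))
  p <- matrix(rnorm(30), ncol = 3)
  q <- apply_transform(tf, p)
  expect_equal(apply_transform(invert_transform(tf), q), p, tolerance = 1e-12)
  tf2 <- frame_transform(translation = c(5, 5, 5))
  expect_equal(apply_transform(compose_transforms(tf2, tf), p),
               apply_transform(tf2, q), tolerance = 1e-12)
  # non-orthonormal rotation is rejected
  expect_error(frame_transform(rotation = matrix(1, 3, 3)))
})

test_that("alignment is the identity for an already-aligned skull", {
  s <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 8))
  al <- align_to_frame(s)
  expect_lt(max(abs(al$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(al$transform$translation)), 1e-9)
})

test_that("alignment recovers an arbitrary rigid displacement", {
  s <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 8))
  th <- 40 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s
  s2$vertices <- s$vertices %*% t(Rz) + matrix(c(5, -7, 2), nrow(s$vertices),
                                               3, byrow = TRUE)
  s2$landmarks <- lapply(s$landmarks, function(p) as.numeric(Rz %*% p) + c(5, -7, 2))
  al2 <- align_to_frame(s2)
  expect_lt(max(abs(al2$surface$vertices - s$vertices)), 1e-8)
  # frame invariants: origin at the left meatus, right meatus on an axis
  lm <- al2$surface$landmarks
  expect_lt(max(abs(lm$meatus_left)), 1e-9)
})

test_that("swapped left/right landmarks are rejected", {
  s <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 8))
  s_bad <- s
  s_bad$landmarks$meatus_left <- s$landmarks$meatus_right
  s_bad$landmarks$meatus_right <- s$landmarks$meatus_left
  expect_error(align_to_frame(s_bad))
})
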