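# frame_osteotomy part 2: parametrized cut and spring placement

test_that("osteotomy_params validates inputs", {
  p <- osteotomy_params(L = 10, H = 20, alpha = 55)
  expect_s3_class(p, "osteotomy_params")
  expect_error(osteotomy_params(10, 20, 55, kerf = 0))
  expect_error(osteotomy_params(-1, 20, 55))
})

test_that("the cut removes a symmetric band and labels two regions", {
  s <- cached_aligned_skull()
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  expect_s3_class(cut, "cut_skull")
  # face conservation: kept + removed = original
  expect_equal(nrow(cut$faces) + length(cut$removed_faces), cut$n_faces_original)
  expect_setequal(unique(cut$region), c("anterior", "posterior"))
  # removed set is mirror-symmetric about the midsagittal plane
  V <- cut$vertices
  zm <- cut$z_mid
  rem <- s$faces[cut$removed_faces, , drop = FALSE]
  cen <- (V[rem[, 1], ] + V[rem[, 2], ] + V[rem[, 3], ]) / 3
  cenm <- cen
  cenm[, 3] <- 2 * zm - cenm[, 3]
  d <- vapply(seq_len(nrow(cenm)), function(i) {
    min(sqrt(rowSums(sweep(cen, 2, cenm[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 1e-6)
  # the foramen rim stays with the fixed segment in front of the cut: every
  # rim vertex is incident to anterior-region faces (the posterior region is
  # the distracted flap)
  ant_verts <- unique(as.vector(cut$faces[cut$region == "anterior", ]))
  expect_true(all(cut$foramen_loop %in% ant_verts))
})

test_that("a larger bottom-end offset L shrinks the distracted flap", {
  s <- cached_aligned_skull()
  cut1 <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  cut2 <- apply_osteotomy(s, osteotomy_params(L = 18.5, H = 15, alpha = 60))
  expect_lt(region_area(cut2, "posterior"), region_area(cut1, "posterior"))
})

test_that("hinged cut leaves the shell connected", {
  s <- cached_aligned_skull()
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  comp <- vaultsim:::face_components(cut$faces)
  expect_equal(max(comp), 1L)
  # hinge faces carry a reduced but positive thickness scale
  expect_true(any(cut$face_scale < 1))
  expect_true(all(cut$face_scale > 0))
})

test_that("spring placements follow the procedure definitions", {
  expect_length(procedure_placements("T2"), 2)
  expect_length(procedure_placements("L2"), 2)
  expect_length(procedure_placements("TL4"), 4)
  expect_error(procedure_placements("X9"))
  expect_error(spring_placement("lateral", -5))
})

test_that("place_springs yields paired anchors across the kerf", {
  s <- cached_aligned_skull()
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  V <- cut$vertices
  for (proc in c("T2", "L2", "TL4")) {
    cs <- place_springs(cut, procedure_placements(proc))
    np <- cs$notch_pairs
    expect_length(np, if (proc == "TL4") 4 else 2)
    for (p in np) {
      gap <- sqrt(sum((V[p$anterior, ] - V[p$posterior, ])^2))
      expect_gt(gap, cut$params$kerf / 2)   # anchors sit on opposite rims
      expect_lt(gap, 30)
    }
  }
  # T2 top anchors are mirror-symmetric
  cs <- place_springs(cut, procedure_placements("T2"))
  a1 <- V[cs$notch_pairs[[1]]$anterior, ]
  a2 <- V[cs$notch_pairs[[2]]$anterior, ]
  a2[3] <- 2 * cut$z_mid - a2[3]
  expect_lt(sqrt(sum((a1 - a2)^2)), 2 * 6)  # within ~2 edge lengths
})

test_that("unreachable notch positions are rejected", {
  s <- cached_aligned_skull()
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  expect_error(place_springs(cut, list(spring_placement("lateral", 500))))
})

test_that("parameter space covers the procedure's parameters with baselines", {
  s <- cached_aligned_skull()
  par0 <- osteotomy_params(L = 8.5, H = 15, alpha = 60)
  ps4 <- build_parameter_space(s, list(params = par0,
                                       placements = procedure_placements("TL4")),
                               "TL4")
  expect_s3_class(ps4, "parameter_space")
  expect_setequal(ps4$bounds$name, c("L", "H", "alpha", "S_T", "S_L"))
  ps2 <- build_parameter_space(s, list(params = par0,
                                       placements = procedure_placements("T2")),
                               "T2")
  expect_setequal(ps2$bounds$name, c("L", "H", "alpha", "S_T"))
  expect_true(all(ps2$bounds$lower < ps2$bounds$upper))
  expect_true(all(ps2$bounds$baseline >= ps2$bounds$lower &
                    ps2$bounds$baseline <= ps2$bounds$upper))
  # alpha interval is +/-20% of |alpha|; L and H +/-10% of skull extents
  a_row <- ps2$bounds[ps2$bounds$name == "alpha", ]
  expect_equal(a_row$upper - a_row$lower, 2 * 0.2 * 60, tolerance = 1e-9)
  # alpha = 0 falls back to a default interval with a warning
  par_zero <- osteotomy_params(L = 8.5, H = 15, alpha = 0)
  expect_warning(
    ps0 <- build_parameter_space(s, list(params = par_zero,
                                         placements = procedure_placements("T2")),
                                 "T2"),
    regexp = "alpha")
  a0 <- ps0$bounds[ps0$bounds$name == "alpha", ]
  expect_lt(a0$lower, a0$upper)
})
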