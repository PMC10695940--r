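# shell_fem: verification oracles and solver behaviour

test_that("1-D spring-bar truss matches the closed-form equilibrium", {
  elastic <- material_model(prony = list())
  K <- 2.0; Lb <- 50; d0 <- 10
  sm <- spring_model("S12")
  nodes <- rbind(c(0, 0, 0), c(Lb, 0, 0), c(Lb + d0, 0, 0))
  mod <- fe_model(nodes, matrix(integer(0), 0, 3), elastic, thickness = 1,
                  fixed_nodes = c(1, 3),
                  springs = list(list(a = 2, b = 3, model = sm)),
                  bars = list(list(a = 1, b = 2, k = K)),
                  extra_fixed_dofs = c(8, 9, 10, 11, 12))
  res <- solve_expansion(mod, duration = 1, n_steps = 1, track_icv = "none")
  open_fin <- res$openings[nrow(res$openings), 1]
  expected <- sm$L0 * sm$k / (sm$k + K) + d0 * K / (sm$k + K)
  expect_lt(abs(open_fin - expected), 1e-8)
  # spring force balances the bar force
  f_spring <- spring_force(sm, open_fin)
  expect_lt(abs(f_spring - K * (open_fin - d0)), 1e-8)
})

test_that("simply supported plate deflection matches the Kirchhoff closed form", {
  m <- grid_mesh(32, 32)
  matp <- material_model(E = 1000, nu = 0.3, prony = list())
  n <- nrow(m$nodes)
  bnd <- which(m$nodes[, 1] %in% c(0, 1) | m$nodes[, 2] %in% c(0, 1))
  extraf <- c(as.vector(outer(c(1, 2, 6), 6 * (seq_len(n) - 1), `+`)),
              6 * (bnd - 1) + 3)
  pm <- fe_model(m$nodes, m$tris, matp, thickness = 0.01,
                 fixed_nodes = integer(0), extra_fixed_dofs = extraf)
  q <- 1e-3
  fz <- pressure_loads(m$nodes, m$tris, q, direction = c(0, 0, 1))
  resp <- solve_expansion(pm, duration = 1, n_steps = 1,
                          external_forces = fz, track_icv = "none")
  cen <- which(m$nodes[, 1] == 0.5 & m$nodes[, 2] == 0.5)
  wc <- resp$displacements[[1]][cen, 3]
  D0 <- 1000 * 0.01^3 / 12 / (1 - 0.3^2)
  w_theory <- 0.00406235 * q / D0
  expect_lt(abs(wc / w_theory - 1), 0.03)
})

test_that("membrane patch test recovers constant stress to 1e-8", {
  mp_nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                    c(0.3, 0.4, 0))
  mp_tris <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  matp <- material_model(E = 1000, nu = 0.3, prony = list())
  pmod <- fe_model(mp_nodes, mp_tris, matp, thickness = 0.01,
                   extra_fixed_dofs = c(1:24, 27, 28, 29, 30))
  exx <- 1e-3; eyy <- -2e-3; gxy <- 5e-4
  up <- numeric(30)
  for (i in 1:4) {
    x <- mp_nodes[i, 1]; y <- mp_nodes[i, 2]
    up[6 * (i - 1) + 1] <- exx * x + gxy / 2 * y
    up[6 * (i - 1) + 2] <- eyy * y + gxy / 2 * x
  }
  K5 <- pmod$K
  fixed <- c(1:24, 27:30)
  free <- setdiff(1:30, fixed)
  up[free] <- as.numeric(solve(K5[free, free], -K5[free, fixed] %*% up[fixed]))
  S <- membrane_stresses(pmod, up)
  f <- 1000 / (1 - 0.3^2)
  expected <- c(f * (exx + 0.3 * eyy), f * (eyy + 0.3 * exx), 0,
                1000 / 2.6 * gxy, 0, 0)
  expect_lt(max(abs(sweep(S, 2, expected))), 1e-8)
})

test_that("quasi-elastic relaxation curve matches the Prony form to 1e-6", {
  m <- grid_mesh(8, 8)
  n <- nrow(m$nodes)
  bnd <- which(m$nodes[, 1] %in% c(0, 1) | m$nodes[, 2] %in% c(0, 1))
  extraf <- c(as.vector(outer(c(1, 2, 6), 6 * (seq_len(n) - 1), `+`)),
              6 * (bnd - 1) + 3)
  mat1 <- material_model(E = 1000, nu = 0.3,
                         prony = list(list(g = 0.6, tau = 5)))
  pm2 <- fe_model(m$nodes, m$tris, mat1, thickness = 0.01,
                  extra_fixed_dofs = extraf)
  fz <- pressure_loads(m$nodes, m$tris, 1e-3, direction = c(0, 0, 1))
  r2 <- solve_expansion(pm2, duration = 20, n_steps = 5,
                        external_forces = fz, track_icv = "none")
  cen <- which(m$nodes[, 1] == 0.5 & m$nodes[, 2] == 0.5)
  w0 <- solve_expansion(pm2, duration = 1e-9, n_steps = 1,
                        external_forces = fz,
                        track_icv = "none")$displacements[[1]][cen, 3]
  for (j in 1:5) {
    tj <- 20 * j / 5
    ratio <- r2$displacements[[j]][cen, 3] / w0
    expected <- 1 / (0.4 + 0.6 * exp(-tj / 5))
    expect_lt(abs(ratio / expected - 1), 1e-6)
  }
})

test_that("relax_factor reproduces the Prony series and its limits", {
  mat <- material_model(E = 1000, nu = 0.3,
                        prony = list(list(g = 0.6, tau = 5)))
  expect_equal(vaultsim:::relax_factor(mat, 0), 1)
  expect_equal(vaultsim:::relax_factor(mat, 5), 0.4 + 0.6 * exp(-1), tolerance = 1e-12)
  expect_equal(vaultsim:::relax_factor(mat, 1e9), 0.4, tolerance = 1e-9)
  expect_error(material_model(prony = list(list(g = 1.2, tau = 5))))
  expect_error(material_model(E = -5))
})

test_that("spring registry and force law match the hardware", {
  s10 <- spring_model("S10"); s12 <- spring_model("S12"); s14 <- spring_model("S14")
  expect_equal(s10$k, 0.17)
  expect_equal(s12$k, 0.39)
  expect_equal(s14$k, 0.68)
  expect_equal(c(s10$L0, s12$L0, s14$L0), c(60, 60, 60))
  expect_equal(c(s10$wire_diameter, s12$wire_diameter, s14$wire_diameter),
               c(1.0, 1.2, 1.4))
  # linear toward the natural opening, zero past it
  expect_equal(spring_force(s12, 30), 0.39 * 30)
  expect_equal(spring_force(s12, 60), 0)
  expect_equal(spring_force(s12, 75), 0)
  expect_error(spring_force(s12, -1))
  expect_error(spring_model("S99"))
})

test_that("assembled stiffness is symmetric and SPD on the constrained set", {
  s <- cached_aligned_skull()
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 60))
  cs <- place_springs(cut, procedure_placements("T2"))
  mod <- build_fe_model(cs, material_model())
  K <- mod$K
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-10)
  # Cholesky of the free-free block succeeded at model build time
  expect_s3_class(mod, "fe_model")
  expect_lt(length(mod$free), 6 * nrow(mod$nodes))
})

test_that("expansion of a cut skull is monotone and converged", {
  s <- generate_skull(skull_spec(bump_amplitude = 0, mesh_edge_target = 9))
  s <- align_to_frame(s)$surface
  cut <- apply_osteotomy(s, osteotomy_params(L = 8.5, H = 15, alpha = 55))
  cs <- place_springs(cut, procedure_placements("TL4"))
  mod <- build_fe_model(cs, material_model())
  res <- solve_expansion(mod, duration = 150, n_steps = 5, track_icv = "all")
  expect_true(res$newton_converged)
  expect_true(all(diff(res$icv_ml) >= -1e-6))
  # openings grow from the compressed state and stay below the free length
  expect_true(all(res$openings[nrow(res$openings), ] >
                    res$openings[1, ] - 1e-9))
  expect_true(all(res$openings <= 60 + 1e-6))
})
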