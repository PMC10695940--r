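# doe_sensitivity: space-filling design, response surface, sensitivities

make_space <- function() {
  s <- cached_aligned_skull()
  par0 <- osteotomy_params(L = 8.5, H = 15, alpha = 60)
  build_parameter_space(s, list(params = par0,
                                placements = procedure_placements("TL4")),
                        "TL4")
}

test_that("designs satisfy the Latin-hypercube stratification property", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 11)
  n <- nrow(d$unit)
  expect_equal(n, 27)                # 5-parameter rule
  for (j in seq_len(ncol(d$unit))) {
    # exactly one point per 1/n stratum in every dimension
    expect_equal(sort(findInterval(d$unit[, j], seq(0, 1, length.out = n + 1),
                                   rightmost.closed = TRUE)),
                 1:n)
  }
})

test_that("the exchange optimization does not worsen the maximin criterion", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 3)
  expect_gte(vaultsim:::min_pair_dist(d$unit),
             vaultsim:::min_pair_dist(d$unit_initial))
})

test_that("designs are reproducible given a seed and sized by the rule", {
  sp <- make_space()
  d1 <- optimal_space_filling(sp, seed = 5)
  d2 <- optimal_space_filling(sp, seed = 5)
  expect_identical(d1$samples, d2$samples)
  d3 <- optimal_space_filling(sp, seed = 6)
  expect_false(identical(d1$samples, d3$samples))
  s <- cached_aligned_skull()
  par0 <- osteotomy_params(L = 8.5, H = 15, alpha = 60)
  sp2 <- build_parameter_space(s, list(params = par0,
                                       placements = procedure_placements("T2")),
                               "T2")
  expect_equal(nrow(optimal_space_filling(sp2, seed = 1)$samples), 25)
  expect_error(optimal_space_filling(sp, n_samples = 3, seed = 1))
  # all sampled points respect the bounds
  for (j in seq_len(nrow(sp$bounds))) {
    expect_true(all(d1$samples[, j] >= sp$bounds$lower[j] - 1e-12))
    expect_true(all(d1$samples[, j] <= sp$bounds$upper[j] + 1e-12))
  }
})

test_that("a known quadratic response is recovered exactly", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 2)
  U <- vaultsim:::unit_scale(d$samples, sp)
  y <- 3 + 2 * U[, 1] - 5 * U[, 2] + 4 * U[, 1]^2 + 1.5 * U[, 1] * U[, 3]
  fit <- fit_response_surface(d, y)
  expect_gt(fit$loo_r2, 1 - 1e-8)
  pred <- predict(fit, d$samples)
  expect_lt(max(abs(pred - y)), 1e-8)
  # coefficient values (names follow the quadratic basis)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["L"]), 2, tolerance = 1e-8)
})

test_that("analytic sensitivity of a linear surface is exact", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 4)
  U <- vaultsim:::unit_scale(d$samples, sp)
  # U is scaled to [-1, 1]; y = 1000 + 100 u1 changes by 200 over the L
  # interval, so the sensitivity at the midpoint reference is +20%
  y <- 1000 + 100 * U[, 1]
  fit <- fit_response_surface(d, y)
  b <- sp$bounds
  ref <- setNames((b$lower + b$upper) / 2, b$name)
  ch <- local_sensitivity(fit, sp, reference = ref)
  s_l <- ch$sensitivities$sensitivity_pct[ch$sensitivities$parameter == "L"]
  expect_equal(s_l, 20, tolerance = 1e-8)
  others <- ch$sensitivities$sensitivity_pct[ch$sensitivities$parameter != "L"]
  expect_lt(max(abs(others)), 1e-8)
})

test_that("sensitivity guards against bad references and responses", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 4)
  U <- vaultsim:::unit_scale(d$samples, sp)
  fit <- fit_response_surface(d, 1000 + 10 * U[, 2])
  b <- sp$bounds
  out_ref <- setNames(b$upper + 1, b$name)
  expect_error(local_sensitivity(fit, sp, reference = out_ref), "bounds")
  neg_fit <- fit_response_surface(d, -1000 + 0 * U[, 1] + 10 * U[, 2])
  expect_error(local_sensitivity(neg_fit, sp), "positive")
  # NA responses are dropped; too few finite responses error
  y <- 1000 + 10 * U[, 1]
  y[1:3] <- NA
  fit2 <- fit_response_surface(d, y)
  expect_equal(fit2$n_used, nrow(d$samples) - 3)
  y_few <- y; y_few[4:27] <- NA
  expect_error(fit_response_surface(d, y_few))
  expect_error(fit_response_surface(d, y[-1]), "one response per design row")
})

test_that("extreme configurations pick the min and max response rows", {
  sp <- make_space()
  d <- optimal_space_filling(sp, seed = 9)
  y <- seq_len(nrow(d$samples)) * 1.0
  y[5] <- -50; y[9] <- 1e4
  ex <- extreme_configurations(d, y)
  expect_equal(ex$min$index, 5L)
  expect_equal(ex$max$index, 9L)
  expect_equal(ex$max$icv_ml, 1e4)
  expect_equal(unname(ex$min$parameters), unname(d$samples[5, ]))
})
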