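# cohort_stats: Wilcoxon tests, group aggregation, agreement analysis

# brute-force exact two-sided rank-sum p-value (no ties)
wilcox_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- combn(n + m, n)
  ws <- apply(combs, 2, function(ix) sum(seq_len(n + m)[ix])) - n * (n + 1) / 2
  # two-sided: double the smaller tail as in the exact Wilcoxon test
  mu <- n * m / 2
  p <- if (w_obs > mu) {
    2 * mean(ws >= w_obs)
  } else if (w_obs < mu) {
    2 * mean(ws <= w_obs)
  } else 1
  min(p, 1)
}

test_that("exact path equals brute-force enumeration for all small splits", {
  set.seed(42)
  for (n in 2:6) {
    for (m in 2:6) {
      a <- rnorm(n)
      b <- rnorm(m, mean = 0.5)
      expect_equal(wilcoxon_rank(a, b), wilcox_enum(a, b), tolerance = 1e-12,
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
})

test_that("ties fall back to the normal approximation and degenerate data error", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 4, 5)
  expect_no_error(p <- wilcoxon_rank(a, b))
  expect_true(p > 0 && p <= 1)
  expect_error(wilcoxon_rank(c(1, 1), c(1, 1)), "identical")
  expect_error(wilcoxon_rank(numeric(0), 1:3))
})

test_that("group_average aggregates per group and runs all pairwise tests", {
  mk_chart <- function(proc, id, sens) {
    structure(list(sensitivities = data.frame(parameter = names(sens),
                                              sensitivity_pct = unname(sens),
                                              stringsAsFactors = FALSE),
                   case_id = id, procedure = proc),
              class = "sensitivity_chart")
  }
  charts <- list(
    mk_chart("T2", "c1", c(L = 10, H = -5, alpha = -2, S_T = -15)),
    mk_chart("T2", "c2", c(L = 14, H = -7, alpha = -4, S_T = -17)),
    mk_chart("L2", "c3", c(L = 3, H = -2, alpha = -1, S_L = 4)),
    mk_chart("L2", "c4", c(L = 5, H = -4, alpha = -3, S_L = 2)))
  g <- group_average(charts)
  expect_s3_class(g, "group_summary")
  t2l <- g$summary[g$summary$group == "T2" & g$summary$parameter == "L", ]
  expect_equal(t2l$mean, 12)
  expect_equal(t2l$sd, sd(c(10, 14)))
  expect_equal(t2l$n, 2L)
  # S_L is reported only for the group that uses it
  expect_false(any(g$summary$group == "T2" & g$summary$parameter == "S_L"))
  # comparisons exist for shared parameters between the two groups
  expect_true(all(c("L", "H", "alpha") %in% g$comparisons$parameter))
  expect_true(all(g$comparisons$p_value > 0 & g$comparisons$p_value <= 1,
                  na.rm = TRUE))
  expect_error(group_average(list(structure(list(sensitivities = NULL,
                                                 procedure = NA_character_),
                                            class = "sensitivity_chart"))))
})

test_that("agreement reproduces Bland-Altman statistics and correlation", {
  set.seed(3)
  obs <- rnorm(12, 1200, 100)
  pred <- obs + rnorm(12, -50, 30)
  ag <- agreement(pred, obs)
  d <- pred - obs
  expect_equal(ag$mean_difference, mean(d))
  expect_equal(ag$sd_difference, sd(d))
  expect_equal(unname(ag$limits["lower"]), mean(d) - 1.96 * sd(d))
  expect_equal(unname(ag$limits["upper"]), mean(d) + 1.96 * sd(d))
  expect_equal(ag$r, unname(cor(pred, obs)))
  expect_equal(ag$p_value, cor.test(pred, obs)$p.value)
  expect_equal(ag$mean_abs_rel_error_pct, mean(abs(d) / obs) * 100)
  # most differences fall inside the limits of agreement
  inside <- mean(d >= ag$limits["lower"] & d <= ag$limits["upper"])
  expect_gte(inside, 0.9)
  expect_error(agreement(1:2, 1:2))
  expect_error(agreement(rep(1, 5), rnorm(5)))
})
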