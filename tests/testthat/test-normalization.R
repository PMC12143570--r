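# Independent Monte-Carlo oracle: mean emission fraction over
# rejection-filtered start/length sequences, written without reusing any of
# the package's closed forms or its sampler.
mc_emission_fraction <- function(n, l_max, pmf, p_g, reps) {
  D <- n + l_max - 1
  g <- matrix(runif(D * reps) < p_g, D, reps)
  L <- matrix(sample.int(l_max, D * reps, replace = TRUE, prob = pmf), D, reps)
  e <- matrix(FALSE, n, reps)
  for (d in 0:(l_max - 1)) {
    rows <- (1:n) + (l_max - 1) - d
    e <- e | (g[rows, , drop = FALSE] & L[rows, , drop = FALSE] > d)
  }
  frac <- colMeans(e)[colSums(e) > 0]
  c(mean = mean(frac), se = sd(frac) / sqrt(length(frac)))
}

test_that("fixed-k emission fraction matches its closed form and limits", {
  # k = 1, n = 1: numerator and denominator coincide
  expect_equal(pe_from_pg_fixed(0.3, 1, 1), 1)
  # p_g -> 0 limit is the feasibility bound k / (n + k - 1)
  expect_equal(pe_from_pg_fixed(0, 3, 10), 3 / 12)
  expect_equal(pe_from_pg_fixed(1e-12, 3, 10), 3 / 12, tolerance = 1e-6)
  # frozen from an independent MC run (2e5 filtered sequences): 0.27720(30)
  expect_equal(pe_from_pg_fixed(0.1, 2, 10), 0.2769, tolerance = 5e-4)
  set.seed(101)
  mc <- mc_emission_fraction(10, 2, c(0, 1), 0.1, 1e5)
  expect_lt(abs(pe_from_pg_fixed(0.1, 2, 10) - mc["mean"]), 3 * mc["se"])
})

test_that("general emission fraction reduces to the fixed form and matches MC", {
  # point mass at k reduces algebraically to the fixed-k expression
  for (k in c(1L, 2L, 5L, 8L)) {
    for (p_g in c(1e-5, 0.01, 0.2, 0.9)) {
      for (n in c(5L, 50L, 400L)) {
        expect_equal(
          pe_from_pg(p_g, burst_length_pmf("fixed", k = k), n),
          pe_from_pg_fixed(p_g, k, n),
          tolerance = 1e-12
        )
      }
    }
  }
  # frozen from an independent MC run (2e5 filtered sequences): 0.17932(21)
  levy2 <- burst_length_pmf("levy", l_max = 2)
  expect_equal(pe_from_pg(0.1, levy2, 10), 0.17932, tolerance = 7e-4)
  set.seed(202)
  mc <- mc_emission_fraction(10, 2, levy2$pmf, 0.1, 1e5)
  expect_lt(abs(pe_from_pg(0.1, levy2, 10) - mc["mean"]), 3 * mc["se"])
  # uniform law against MC too
  unif <- burst_length_pmf("uniform", l_max = 4)
  set.seed(303)
  mc <- mc_emission_fraction(12, 4, unif$pmf, 0.05, 1e5)
  expect_lt(abs(pe_from_pg(0.05, unif, 12) - mc["mean"]), 3 * mc["se"])
  expect_error(
    pe_from_pg(0.1, structure(list(kind = "levy", k = NA, l_max = 2,
                                   pmf = c(1.2, -0.2)),
                              class = "burst_model"), 10),
    "negative"
  )
})

test_that("emission fraction is strictly increasing in p_g", {
  grid <- seq(0.001, 0.999, length.out = 200)
  for (model in list(burst_length_pmf("fixed", k = 4),
                     burst_length_pmf("levy", l_max = 8),
                     burst_length_pmf("uniform", l_max = 8))) {
    vals <- vapply(grid, pe_from_pg, numeric(1), burst_model = model, n = 30)
    expect_true(all(diff(vals) > 0))
  }
})

test_that("solve_pg round-trips through the forward map", {
  models <- list(
    burst_length_pmf("fixed", k = 1), burst_length_pmf("fixed", k = 8),
    burst_length_pmf("levy", l_max = 8), burst_length_pmf("uniform", l_max = 8)
  )
  for (model in models) {
    for (target in c(0.06, 0.2, 0.7)) {
      res <- solve_pg(target, model, 200)
      expect_lt(abs(res$p_e_achieved - target), 1e-10)
      expect_lt(abs(pe_from_pg(res$p_g, model, 200) - target), 1e-10)
      expect_gt(res$p_e_target, res$p_e_min)
    }
  }
  # k = 1 at very large n: filtering is negligible, so p_g ~ p_e
  res <- solve_pg(0.04, burst_length_pmf("fixed", k = 1), 1e6)
  expect_equal(res$p_g, 0.04, tolerance = 1e-6)
})

test_that("infeasible sparsity targets are rejected with the bound", {
  expect_equal(pe_min(burst_length_pmf("fixed", k = 3), 10), 3 / 12)
  err <- expect_error(
    solve_pg(0.2, burst_length_pmf("fixed", k = 3), 10),
    class = "burstfusion_infeasible_sparsity"
  )
  expect_match(conditionMessage(err), "0.25")
  # general bound E[L] / (n - 1 + E[L])
  lv <- burst_length_pmf("levy", l_max = 2)
  el <- sum((1:2) * lv$pmf)
  expect_equal(pe_min(lv, 10), el / (9 + el))
  expect_error(solve_pg(pe_min(lv, 10), lv, 10),
               class = "burstfusion_infeasible_sparsity")
})

test_that("solved p_g decreases with burst length at fixed sparsity", {
  pg <- vapply(1:8, function(k) {
    solve_pg(0.04, burst_length_pmf("fixed", k = k), 200)$p_g
  }, numeric(1))
  expect_true(all(diff(pg) < 0))
})
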