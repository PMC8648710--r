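test_that("the stationary operator matches the single-patch logistic quadrature oracle", {
  m <- sp_logistic()
  expect_identical(apply_Kbar(m, 0), 0)
  om2 <- omega_constants(m)$omega2
  for (rho in c(0.5, 3, 50, 2000)) {
    kb <- apply_Kbar(m, rho)
    oracle <- stats::integrate(function(a)
      rho * 30 * exp(-0.5 * a) / (1 + rho * (1 - exp(-0.5 * a))),
      1, 2, rel.tol = 1e-13)$value
    expect_lt(abs(kb - oracle), 1e-7 * max(1, oracle))
    expect_lte(kb, om2 + 1e-9)
  }
  expect_error(apply_Kbar(two_patch_sym(), c(-1, 1)), "nonnegative")
})

test_that("the maximal solution equals the scalar bisection root (single patch)", {
  m <- sp_logistic()
  ms <- maximal_solution(m)
  root <- scalar_theta_root(30, 0.5, 1, 2)
  expect_lt(abs(ms$theta - root), 1e-6)
  # no births -> the only solution is zero
  m0 <- patch_model(1, 3, mortality_law("logistic", mu = 0.5, L = 1),
                    birth_rate(1e-12, c(1, 2)))
  expect_lt(maximal_solution(m0)$theta, 1e-10)
})

test_that("subcritical models have a vanishing maximal solution", {
  m <- sp_logistic(m0 = amp_for(0.7, 0.5))
  om2 <- omega_constants(m)$omega2
  expect_lt(maximal_solution(m)$theta, 1e-8 * om2)
})

test_that("the net reproductive matrix decouples without dispersal and obeys Remark-1 exactness", {
  md <- make_scenario("decoupled_patches", R0_targets = c(1.4, 0.7))
  R <- next_generation_matrix(md)
  expect_lt(abs(R[1, 2]) + abs(R[2, 1]), 1e-12)
  expect_lt(abs(R[1, 1] - 1.4), 1e-8)
  expect_lt(abs(R[2, 2] - 0.7), 1e-8)
  expect_equal(basic_reproduction_number(R)$R0, 1.4, tolerance = 1e-10)
  # no births -> zero matrix
  m0 <- patch_model(2, 3, mortality_law("logistic", mu = c(1, 1), L = c(1, 1)),
                    birth_rate(c(0, 0), c(1, 2)))
  expect_true(all(abs(next_generation_matrix(m0)) < 1e-14))
})

test_that("with mass-conserving symmetric dispersal the column sums equal the single-patch integral", {
  mc <- two_patch_sym(eps = 0.2, mu = 0.5, m0 = 12)
  R <- next_generation_matrix(mc)
  single <- 12 * (exp(-0.5) - exp(-1)) / 0.5
  expect_lt(max(abs(colSums(R) - single)), 1e-7)
  # cross-check one column against a dense hand-rolled linear-ODE integration
  A <- 0.2 * matrix(c(-1, 1, 1, -1), 2, 2) - diag(c(0.5, 0.5))
  sol <- rk4_linear_Y(function(x) A, c(1, 0), 3, nsteps = 6000)
  keep <- sol$ages >= 1 & sol$ages <= 2
  mY <- 12 * sol$Y[, keep]
  h <- sol$ages[2] - sol$ages[1]
  col1 <- rowSums(mY) * h - (mY[, 1] + mY[, ncol(mY)]) * h / 2
  expect_lt(max(abs(R[, 1] - col1)), 1e-5)
})

test_that("spectral radius, Perron vector and Collatz-Wielandt bracket are consistent", {
  bp <- basic_reproduction_number(diag(c(1.4, 0.7)))
  expect_equal(bp$R0, 1.4, tolerance = 1e-14)
  m <- di_single(m0 = 10, mu0 = 1)
  R0 <- basic_reproduction_number(m)$R0
  expect_lt(abs(R0 - 10 * (exp(-1) - exp(-2))), 1e-8)
  r <- make_scenario("random_connected", seed = 21)
  bp2 <- basic_reproduction_number(r)
  expect_true(all(bp2$perron_vector > 0))
  expect_lte(bp2$cw[1], bp2$R0 + 1e-10)
  expect_gte(bp2$cw[2], bp2$R0 - 1e-10)
  expect_lt(bp2$cw[2] - bp2$cw[1], 1e-6 * bp2$R0)
  expect_error(basic_reproduction_number(matrix(c(1, -0.1, 0, 1), 2, 2)),
               "nonnegative")
})

test_that("stationary analysis bundles a consistent dichotomy", {
  fit <- stationary_analysis(sp_logistic())
  expect_equal(fit$classification, "permanence")
  expect_true(all(fit$theta > 0))
  expect_lt(fit$fixed_point_residual, 1e-7)
  expect_true(all(fit$P_limit > 0))
  expect_equal(coef(fit), fit$theta)
  # no births: extinction with zero limiting population
  m0 <- patch_model(1, 3, mortality_law("logistic", mu = 0.5, L = 1),
                    birth_rate(1e-12, c(1, 2)))
  fit0 <- stationary_analysis(m0)
  expect_equal(fit0$classification, "extinction")
  expect_true(all(fit0$P_limit == 0))
})

test_that("decoupled source and sink: permanence only on the source patch", {
  md <- make_scenario("decoupled_patches", R0_targets = c(2.5, 0.7))
  th <- maximal_solution(md)$theta
  om2 <- omega_constants(md)$omega2
  expect_lt(abs(th[1] - scalar_theta_root(amp_for(2.5, 0.5), 0.5, 1, 2)), 1e-6)
  expect_lt(th[2], 1e-8 * om2)
})

test_that("the scaled operators decrease in lambda and are dominated by the linearisation", {
  set.seed(31)
  for (m in random_pool(c(2, 8))) {
    Rm <- next_generation_matrix(m)
    for (trial in 1:5) {
      x <- stats::runif(m$N, 0.2, 3)
      l1 <- stats::runif(1, 0.05, 1)
      l2 <- l1 + stats::runif(1, 0.1, 2)
      R1 <- apply_Kbar(m, l1 * x) / l1
      R2 <- apply_Kbar(m, l2 * x) / l2
      expect_true(all(R1 >= R2 - 1e-9))
      expect_true(all(R2 <= Rm %*% x + 1e-9))
    }
  }
})

test_that("classification flips from extinction to permanence across R0 = 1", {
  base_amp <- amp_for(1, 0.5)          # R0(s) = s exactly
  cls <- function(s) stationary_analysis(sp_logistic(m0 = s * base_amp))$classification
  expect_equal(cls(0.90), "extinction")
  expect_equal(cls(1.10), "permanence")
  # theta decreases continuously to 0 as the family approaches criticality
  th <- vapply(c(1.3, 1.15, 1.05),
               function(s) maximal_solution(sp_logistic(m0 = s * base_amp))$theta, 0)
  expect_true(all(diff(th) < 0) && th[3] > 0)
  expect_lt(th[3], 0.35)
})
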