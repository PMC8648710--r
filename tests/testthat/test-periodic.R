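# a sinusoidally modulated single-patch logistic model with period T
sinus_model <- function(T = 2, depth = 0.3, m0 = 30, mu0 = 0.5) {
  patch_model(1, 3,
              mortality_law("logistic",
                            mu = function(a, t) mu0 * (1 + 0 * a),
                            L = function(a, t) 1 + 0 * a),
              birth_rate(function(a, t)
                m0 * (a >= 1 & a <= 2) * (1 + depth * sin(2 * pi * t / T)),
                support = c(1, 2)),
              f = tent_f(), f_support = c(0, 0.5),
              time_dependence = "periodic", period = T)
}

as_periodic <- function(m, T = 2) { m$time_dependence <- "periodic"; m$period <- T; m }

test_that("periodic machinery reduces to the stationary one for constant coefficients", {
  m <- sp_logistic()
  pm <- as_periodic(m)
  # operator equivalence at every node
  rho <- periodic_function(matrix(3, 1, 64), 2)
  Kt <- apply_Ktilde(pm, rho)$values
  Kb <- apply_Kbar(m, 3)
  expect_lt(max(abs(Kt - Kb)) / Kb, 1e-4)
  # R0 equivalence
  st <- stationary_analysis(m)
  pr <- periodic_R0(pm, M_points = 64)
  expect_lt(abs(pr$R0 - st$R0) / st$R0, 1e-4)
  # maximal-solution equivalence; the periodic solution is flat
  th <- periodic_maximal_solution(pm, M_points = 64)
  expect_lt(max(abs(th$values - st$theta)) / st$theta, 1e-4)
  expect_lt(diff(range(th$values)), 1e-8 * st$theta)
})

test_that("the periodic operator maps the order interval into itself and is monotone", {
  pm <- sinus_model()
  om2 <- omega_constants(pm)$omega2
  set.seed(6)
  v1 <- matrix(stats::runif(32, 0, 50), 1)
  v2 <- v1 + matrix(stats::runif(32, 0, 30), 1)
  K1 <- apply_Ktilde(pm, periodic_function(v1, 2))$values
  K2 <- apply_Ktilde(pm, periodic_function(v2, 2))$values
  expect_true(max(K1) <= om2 + 1e-8 && max(K2) <= om2 + 1e-8)
  expect_true(all(K2 >= K1 - 1e-9))
  z <- apply_Ktilde(pm, periodic_function(matrix(0, 1, 32), 2))$values
  expect_true(all(z == 0))
  # period mismatch is a domain error
  expect_error(apply_Ktilde(pm, periodic_function(v1, 3)), "period mismatch")
})

test_that("no births means a vanishing periodic maximal solution and zero periodic R0", {
  pm <- sinus_model(m0 = 1e-10)
  th <- periodic_maximal_solution(pm, M_points = 32)
  expect_lt(max(th$values), 1e-6)
  expect_lt(periodic_R0(pm, M_points = 32)$R0, 1e-8)
})

test_that("the periodic linearised operator is homogeneous in the birth rate", {
  pr1 <- periodic_R0(sinus_model(m0 = 30), M_points = 32)$R0
  for (s in c(0.5, 2)) {
    prs <- periodic_R0(sinus_model(m0 = 30 * s), M_points = 32)$R0
    expect_lt(abs(prs - s * pr1) / (s * pr1), 1e-8)
  }
})

test_that("a supercritical periodic model has a strictly positive periodic fixed point", {
  pm <- sinus_model()
  th <- periodic_maximal_solution(pm, M_points = 32)
  expect_true(all(th$values > 0))
  expect_lt(attr(th, "residual"), 1e-8)
  expect_gt(diff(range(th$values)), 0.01 * max(th$values))  # genuinely periodic
  # evaluation is periodic: t and t + T agree
  tt <- c(0.3, 0.9, 1.7)
  expect_equal(pf_eval(th, tt), pf_eval(th, tt + 2), tolerance = 1e-12)
  # dynamics approach the periodic maximal solution
  tr <- solve_newborns(pm, horizon = 50)
  late <- tr$times >= 45
  ref <- pf_eval(th, tr$times[late])
  expect_lt(max(abs(tr$rho[, late] - ref)) / max(ref), 0.02)
})

test_that("envelopes of a periodic model reproduce it and widen with noise", {
  pm <- sinus_model()
  env <- build_envelopes(pm, period = 2, n_periods = 3)
  ages <- seq(1.05, 1.95, length.out = 7)
  tt <- seq(10, 12, length.out = 9)
  for (t in tt) {
    mv <- patchpop:::.ev_m(pm, ages, rep(t, 7))
    up <- patchpop:::.ev_m(env$upper, ages, rep(t, 7))
    lo <- patchpop:::.ev_m(env$lower, ages, rep(t, 7))
    # agreement up to the phase-interpolation error of the tabulated envelope
    expect_true(all(up >= mv - 2e-3 * max(mv)))
    expect_true(all(lo <= mv + 2e-3 * max(mv)))
    mu <- patchpop:::.ev_mu(pm, ages, rep(t, 7))
    expect_true(all(patchpop:::.ev_mu(env$upper, ages, rep(t, 7)) <= mu + 1e-6))
    expect_true(all(patchpop:::.ev_mu(env$lower, ages, rep(t, 7)) >= mu - 1e-6))
  }
  # bounded noise eta: envelopes stay within eta plus safety of the clean rates
  eta <- 0.1
  noisy <- patch_model(1, 3,
    mortality_law("logistic", mu = function(a, t) 0.5 + 0 * a,
                  L = function(a, t) 1 + 0 * a),
    birth_rate(function(a, t)
      30 * (a >= 1 & a <= 2) * (1 + 0.3 * sin(pi * t) + eta * sin(sqrt(2) * t)),
      support = c(1, 2)),
    f = tent_f(), f_support = c(0, 0.5), time_dependence = "general")
  envn <- build_envelopes(noisy, period = 2, n_periods = 6)
  clean_max <- 30 * 1.3
  expect_lt(max(patchpop:::.ev_m(envn$upper, 1.5, 0.7)), clean_max * (1 + eta) + 1e-3)
  # enlarging the scan never shrinks the upper envelope
  env2 <- build_envelopes(noisy, period = 2, n_periods = 12)
  aa <- seq(1.1, 1.9, length.out = 5)
  for (t in seq(0, 2, length.out = 5))
    expect_true(all(patchpop:::.ev_m(env2$upper, aa, rep(t, 5)) >=
                    patchpop:::.ev_m(envn$upper, aa, rep(t, 5)) - 1e-9))
})

test_that("sandwich bounds trap an irregular trajectory between its periodic envelopes", {
  eta <- 0.08
  noisy <- patch_model(1, 3,
    mortality_law("logistic", mu = function(a, t) 0.5 + 0 * a,
                  L = function(a, t) 1 + 0 * a),
    birth_rate(function(a, t)
      30 * (a >= 1 & a <= 2) *
        (1 + 0.2 * sin(pi * t) + eta * sin(sqrt(2) * t)),
      support = c(1, 2)),
    f = tent_f(), f_support = c(0, 0.5), time_dependence = "general")
  env <- build_envelopes(noisy, period = 2, n_periods = 6)
  sb <- sandwich_bounds(noisy, env, horizon = 40, epsilon = 0.5)
  expect_equal(sb$verdict, "tube")
  expect_lte(sb$T2, 40)
  # a subcritical upper envelope forces extinction of the irregular model
  weak <- patch_model(1, 3,
    mortality_law("logistic", mu = function(a, t) 0.5 + 0 * a,
                  L = function(a, t) 1 + 0 * a),
    birth_rate(function(a, t)
      amp_for(0.8, 0.5) * (a >= 1 & a <= 2) * (1 + 0.05 * sin(sqrt(2) * t)),
      support = c(1, 2)),
    f = tent_f(), f_support = c(0, 0.5), time_dependence = "general")
  envw <- build_envelopes(weak, period = 2, n_periods = 6)
  sbw <- sandwich_bounds(weak, envw, horizon = 40, epsilon = 0.5)
  expect_equal(sbw$verdict, "extinction")
  om2 <- omega_constants(weak)$omega2
  expect_lt(max(sbw$terminal), 1e-3 * om2)
})
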