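test_that("psi is evaluated stably through its removable singularity", {
  expect_identical(psi_exp(0), 0.5)                    # series branch
  expect_equal(psi_exp(1), exp(1) - 2, tolerance = 1e-14)
  expect_equal(psi_exp(-1), exp(-1), tolerance = 1e-14)
  # continuity across the series/direct switch at |z| = 1e-4
  z <- c(-2e-4, -1e-4, -5e-5, 0, 5e-5, 1e-4, 2e-4)
  expect_lt(max(abs(diff(psi_exp(z)))), 1e-4)
  expect_lt(abs(psi_exp(1e-3) - (exp(1e-3) - 1 - 1e-3) / 1e-6), 1e-12)
  # increasing and positive on a wide grid; z*psi(z) increasing through 0
  zz <- seq(-8, 8, length.out = 401)
  expect_true(all(psi_exp(zz) > 0))
  expect_true(all(diff(psi_exp(zz)) > 0))
  expect_true(all(diff(zz * psi_exp(zz)) > 0))
})

test_that("scenario generation is deterministic and hypothesis-clean", {
  for (fam in c("single_patch_logistic", "decoupled_patches", "source_sink",
                "random_connected")) {
    m1 <- make_scenario(fam, seed = 3)
    m2 <- make_scenario(fam, seed = 3)
    aa <- seq(0.1, 2.9, length.out = 13)
    expect_identical(patchpop:::.ev_m(m1, aa, aa * 0),
                     patchpop:::.ev_m(m2, aa, aa * 0))
    expect_identical(patchpop:::.ev_mu(m1, aa, aa * 0),
                     patchpop:::.ev_mu(m2, aa, aa * 0))
    if (!is.null(m1$dispersal))
      expect_identical(m1$dispersal$constant, m2$dispersal$constant)
    rep <- validate_hypotheses(m1)
    if (fam == "decoupled_patches") {
      # isolated patches cannot satisfy the accessibility condition
      expect_true(all(rep$pass[c("H1", "H2", "H3", "H4", "H5")]))
    } else expect_true(all(rep$pass))
  }
  # different seeds give different random models
  r1 <- make_scenario("random_connected", seed = 1)
  r2 <- make_scenario("random_connected", seed = 2)
  expect_false(identical(patchpop:::.ev_mu(r1, 1, 0), patchpop:::.ev_mu(r2, 1, 0)))
})

test_that("calibrated amplitudes hit their reproduction-number targets", {
  m <- make_scenario("single_patch_logistic", mu0 = 0.5, m0 = 30)
  expect_lt(abs(basic_reproduction_number(m)$R0 - 60 * (exp(-0.5) - exp(-1))) /
            (60 * (exp(-0.5) - exp(-1))), 1e-8)
  md <- make_scenario("decoupled_patches", R0_targets = c(1.4, 0.7))
  R <- next_generation_matrix(md)
  expect_lt(max(abs(diag(R) - c(1.4, 0.7))), 1e-8)
})

test_that("the two-sink design calibrates both isolated sinks exactly and gains from dispersal", {
  d <- design_two_sink(1, 0.4, 0.3)
  expect_lt(max(abs(d$R0_isolated - 1)), 1e-8)
  expect_true(all(d$P_direction > 0))
  expect_true(d$c1 > d$c_star)           # source-side support above c*
  expect_true(d$c2 > 0 && d$c2 < d$d2 && d$c1 < d$d1)
  # the exact first-order kernels are positive on the respective supports
  dmu <- 0.6
  h1 <- function(a) (0.3 - 1) * a + a^2 * dmu * psi_exp(dmu * a) * 0.3
  h2 <- function(a) (1 - 0.3) * a + a^2 * (-dmu) * psi_exp(-dmu * a) * 1
  a1 <- seq(d$c1 + 1e-6, d$d1, length.out = 33)
  a2 <- seq(d$c2, d$d2 - 1e-6, length.out = 33)
  expect_true(all(h1(a1) > 0))
  expect_true(all(h2(a2) > 0))
  # full two-patch model: permanence from two sinks at eps = 1e-3
  R0e <- basic_reproduction_number(two_sink_model(d, 1e-3))$R0
  expect_gt(R0e, 1)
  expect_error(design_two_sink(0.4, 1, 0.3))    # needs mu1 > mu2
  expect_error(design_two_sink(1, 0.4, 0.6))    # needs rho2 < 1/2
})

test_that("first-order dispersal perturbation has the predicted sign and quadratic error", {
  m0 <- make_scenario("decoupled_patches", R0_targets = c(1.5, 0.7),
                      mu = c(0.5, 0.8))
  B <- matrix(c(-1, 1, 0.5, -0.6), 2, 2)
  rep <- source_sink_perturbation(m0, B, eps = c(0.04, 0.02, 0.01))
  expect_lt(rep$coefficient, 0)               # emigration from the source costs
  expect_true(all(diff(rep$table$R0_numeric) > 0))  # R0 decreasing in eps
  expect_true(all(rep$order > 1.7 & rep$order < 2.3))
  # B11 = 0: zero first-order coefficient, purely quadratic error
  B0 <- matrix(c(0, 1, 0.5, -0.6), 2, 2)
  rep0 <- source_sink_perturbation(m0, B0, eps = c(0.04, 0.02))
  expect_identical(rep0$coefficient, 0)
  expect_true(all(rep0$order > 1.7 & rep0$order < 2.3))
  # a sink-first model is rejected
  msink <- make_scenario("decoupled_patches", R0_targets = c(0.9, 0.7))
  expect_error(source_sink_perturbation(msink, B), "unique source")
})

test_that("scenario configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_scenario_config(path, "single_patch_logistic", seed = 4)
  m <- read_model_config(path)
  expect_s3_class(m, "patch_model")
  expect_equal(basic_reproduction_number(m)$R0, 60 * (exp(-0.5) - exp(-1)),
               tolerance = 1e-8)
  # explicit model description
  path2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(N = 2, b = 3, b1 = 2.5,
                        mortality = list(kind = "logistic", mu = c(0.5, 0.8),
                                         L = c(1, 1)),
                        birth = list(amplitude = c(12, 5), support = c(1, 2)),
                        dispersal = list(matrix = list(c(-0.01, 0.01), c(0.01, -0.01))),
                        f = list(amplitude = c(1, 1), support = c(0, 0.5))),
                   path2)
  m2 <- read_model_config(path2)
  expect_equal(m2$N, 2)
  expect_true(all(validate_hypotheses(m2)$pass))
})
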