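test_that("logistic laws pass the structure hypotheses with gamma = 1 and p = mu/L", {
  m <- sp_logistic()
  rep <- validate_hypotheses(m)
  expect_true(all(rep$pass))
  expect_equal(rep$gamma, 1)
  # p(a) = inf over t, k of mu/L = 0.5 here, so mu_inf = 0.5
  expect_equal(rep$mu_inf, 0.5, tolerance = 1e-12)
  expect_true(all(abs(rep$p_of_a$p - 0.5) < 1e-12))
  expect_true(all(is.finite(rep$beta)) && all(rep$beta < rep$max_fertility_age))
})

test_that("support and sign violations are detected and named", {
  # fecundity leaking outside the declared fertile window fails H4
  leaky <- patch_model(1, 4, mortality_law("logistic", mu = 0.5, L = 1),
                       birth_rate(function(a, t) 5 * (a >= 1 & a <= 2.6),
                                  support = c(1, 2)),
                       b1 = 3)
  rep <- validate_hypotheses(leaky)
  expect_false(rep$pass[["H4"]])
  expect_true(any(grepl("H4", rep$messages)))
  # declaring the support beyond b1 is rejected at construction
  expect_error(patch_model(1, 3, mortality_law("logistic", mu = 0.5, L = 1),
                           birth_rate(5, c(1, 2.8)), b1 = 2.5),
               "A_m < b1")
  # a negative off-diagonal dispersal entry fails H3 with the entry named
  bad <- patch_model(2, 3, mortality_law("logistic", mu = c(1, 1), L = c(1, 1)),
                     birth_rate(c(5, 5), c(1, 2)),
                     dispersal = matrix(c(-0.1, 0.2, -0.05, -0.1), 2, 2))
  rep2 <- validate_hypotheses(bad)
  expect_false(rep2$pass[["H3"]])
  expect_true(any(grepl("D\\[1,2\\]", rep2$messages)))
})

test_that("hypothesis reports are deterministic and serialise to JSON", {
  m <- make_scenario("random_connected", seed = 5)
  r1 <- validate_hypotheses(m)
  r2 <- validate_hypotheses(m)
  expect_identical(r1$pass, r2$pass)
  expect_identical(r1$beta, r2$beta)
  js <- hypothesis_report_json(r1)
  parsed <- jsonlite::fromJSON(js)
  expect_true(all(unlist(parsed$pass)))
})

test_that("accessibility follows the dispersal digraph", {
  mk <- function(D) patch_model(nrow(D), 3,
                                mortality_law("logistic", mu = rep(1, nrow(D)),
                                              L = rep(1, nrow(D))),
                                birth_rate(rep(5, nrow(D)), c(1, 2)),
                                dispersal = D)
  # symmetric positive coupling: both patches accessible everywhere
  sym <- mk(0.3 * matrix(c(-1, 1, 1, -1), 2, 2))
  expect_true(accessibility(sym, 1) && accessibility(sym, 2))
  # one-way arrow: D[1,2] > 0 only, so the digraph has the arc 1 -> 2
  oneway <- mk(matrix(c(0, 0, 0.5, 0), 2, 2))
  expect_true(accessibility(oneway, 1))
  expect_false(accessibility(oneway, 2))
  # 3-cycle: verified against a brute-force transitive closure
  D3 <- matrix(0, 3, 3); D3[1, 2] <- D3[2, 3] <- D3[3, 1] <- 0.4
  cyc <- mk(D3)
  adj <- D3 > 0
  for (k in 1:3) expect_identical(accessibility(cyc, k), reach_all_from(adj, k))
})

test_that("adding a positive dispersal entry never destroys accessibility", {
  set.seed(42)
  for (trial in 1:25) {
    N <- sample(2:4, 1)
    D <- matrix(stats::runif(N * N) * (stats::runif(N * N) < 0.4), N, N)
    diag(D) <- 0
    mk <- function(D) patch_model(N, 3,
                                  mortality_law("logistic", mu = rep(1, N), L = rep(1, N)),
                                  birth_rate(rep(5, N), c(1, 2)), dispersal = D)
    base <- vapply(1:N, function(k) accessibility(mk(D), k), TRUE)
    ij <- sample(which(diag(N) == 0), 1)
    D2 <- D; D2[ij] <- D2[ij] + 0.5
    more <- vapply(1:N, function(k) accessibility(mk(D2), k), TRUE)
    expect_true(all(more >= base))
  }
})

test_that("majorant constants match their closed forms", {
  # gamma = 1, mu_inf = 1, D = 0 -> omega1 = 1; [a_m, A_m] = [1, e], m sup 2 -> omega2 = 2
  m1 <- patch_model(1, 3, mortality_law("logistic", mu = 1, L = 1),
                    birth_rate(2, c(1, exp(1))))
  om <- omega_constants(m1)
  expect_equal(om$omega1, 1, tolerance = 1e-12)
  expect_equal(om$omega2, 2, tolerance = 1e-12)
  # gamma = 1, mu_inf = 2, N = 2, ||D|| = 1, b = 3 -> omega1 = 7/2
  m2 <- patch_model(2, 3, mortality_law("logistic", mu = c(2, 2), L = c(1, 1)),
                    birth_rate(c(2, 2), c(1, 2)),
                    dispersal = matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(omega_constants(m2)$omega1, 7 / 2, tolerance = 1e-12)
  # gamma != 1: the age integral in omega2 cross-checks against quadrature
  m3 <- patch_model(1, 3, mortality_law("power_law", mu = 1, p = 2, gamma = 2),
                    birth_rate(3, c(1, 2)))
  om3 <- omega_constants(m3)
  J <- stats::integrate(function(a) a^(-1 / 2), 1, 2, rel.tol = 1e-12)$value
  expect_equal(om3$omega2, om3$omega1 * 3 * J, tolerance = 1e-10)
  # density-independent mortality has no majorant
  expect_error(omega_constants(di_single()), "gamma > 0")
})

test_that("sampled mortality is nonnegative and nondecreasing on a density ladder", {
  for (m in random_pool(c(3, 9))) {
    ages <- seq(0, m$b, length.out = 17)
    prev <- NULL
    for (v in c(0, 0.5, 1, 2, 5)) {
      M <- patchpop:::.ev_M(m, matrix(v, m$N, 17), ages, rep(0, 17))
      expect_true(all(M >= 0))
      if (!is.null(prev)) expect_true(all(M >= prev - 1e-12))
      prev <- M
    }
  }
})
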