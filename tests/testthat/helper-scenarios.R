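# shared fixtures: all models are built in code at test time

# continuous tent-shaped initial distribution on [0, hi]
tent_f <- function(amp = 1, hi = 0.5) {
  function(a) amp * pmax(0, pmin(1, 2 * (hi - a) / hi)) * (a >= 0)
}

# single patch, logistic regulation; closed-form linear R0 = m0 (e^{-mu a1} - e^{-mu a2})/mu
sp_logistic <- function(m0 = 30, mu0 = 0.5, support = c(1, 2), L = 1, b = 3) {
  make_scenario("single_patch_logistic", m0 = m0, mu0 = mu0,
                support = support, L = L, b = b)
}

# amplitude for a target single-patch R0 with a box on [a1, a2]
amp_for <- function(target, mu, a1 = 1, a2 = 2) {
  target * mu / (exp(-mu * a1) - exp(-mu * a2))
}

# single patch, density-independent mortality (gamma = 0)
di_single <- function(mu0 = 0.5, m0 = 10, support = c(1, 2), b = 3,
                      f = tent_f()) {
  patch_model(1, b, mortality_law("density_independent", mu = mu0),
              birth_rate(m0, support), f = f, f_support = c(0, 0.5))
}

# two identical logistic patches coupled by mass-conserving symmetric dispersal
two_patch_sym <- function(eps = 0.2, mu = 0.5, m0 = 12, b = 3) {
  B <- matrix(c(-1, 1, 1, -1), 2, 2)
  patch_model(2, b, mortality_law("logistic", mu = c(mu, mu), L = c(1, 1)),
              birth_rate(c(m0, m0), c(1, 2)), dispersal = eps * B,
              f = tent_f(), f_support = c(0, 0.5))
}

# pool of seeded random connected scenarios
random_pool <- function(seeds) lapply(seeds, function(s)
  make_scenario("random_connected", seed = s))
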