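# independent oracles: deliberately naive implementations that do not share
# code paths with the package internals

# explicit upwind finite-difference discretisation of the transport equations
# for a single patch (CFL = 1: exact transport + Euler mortality), with the
# birth boundary condition closed by a rectangle-rule integral
upwind_solve <- function(mu, m0, sup, f_fun, b, h, horizon,
                         logistic_L = NULL) {
  na <- round(b / h)
  ages <- (0:na) * h
  n <- f_fun(ages)
  n[1] <- 0
  mvec <- m0 * (ages >= sup[1] & ages <= sup[2])
  nt <- round(horizon / h)
  rho <- numeric(nt + 1)
  Ptot <- numeric(nt + 1)
  rho[1] <- sum(mvec * n) * h
  Ptot[1] <- sum(n) * h
  for (i in 1:nt) {
    M <- if (is.null(logistic_L)) mu else mu * (1 + n / logistic_L)
    n_new <- c(0, (n * pmax(1 - h * M, 0))[-(na + 1)])
    n_new[1] <- sum(mvec * n_new) * h
    n <- n_new
    rho[i + 1] <- n[1]
    Ptot[i + 1] <- sum(n) * h
  }
  list(times = (0:nt) * h, rho = rho, P = Ptot)
}

# Bernoulli closed form for the logistic cohort with constant mu, L = 1:
# h(a) = rho0 Pi(a) / (1 + rho0 (1 - Pi(a))), Pi(a) = e^{-mu a}
logistic_phi_exact <- function(rho0, mu, a) {
  Pi <- exp(-mu * a)
  rho0 * Pi / (1 + rho0 * (1 - Pi))
}

# positive root of the single-patch logistic characteristic equation
# int m(a) Pi(a) / (1 + theta (1 - Pi(a))) da = 1, by bisection over a bracket
scalar_theta_root <- function(m0, mu, a1, a2, L = 1) {
  I <- function(th) stats::integrate(function(a)
    m0 * exp(-mu * a) / (1 + (th / L) * (1 - exp(-mu * a))),
    a1, a2, rel.tol = 1e-13)$value
  lo <- 0; hi <- 1
  while (I(hi) > 1) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (I(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force transitive closure (Warshall) on a sign pattern
reach_all_from <- function(adj, k) {
  N <- nrow(adj)
  R <- adj | diag(TRUE, N)
  for (m in 1:N) for (i in 1:N) if (R[i, m]) R[i, ] <- R[i, ] | R[m, ]
  all(R[k, ])
}

# dense hand-rolled RK4 for the linearised cohort system (constant coefficients)
rk4_linear_Y <- function(A_fun, y0, b, nsteps = 4000) {
  h <- b / nsteps
  out <- matrix(0, length(y0), nsteps + 1)
  out[, 1] <- y0
  y <- y0
  for (i in 1:nsteps) {
    x <- (i - 1) * h
    k1 <- A_fun(x) %*% y
    k2 <- A_fun(x + h / 2) %*% (y + h / 2 * k1)
    k3 <- A_fun(x + h / 2) %*% (y + h / 2 * k2)
    k4 <- A_fun(x + h) %*% (y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[, i + 1] <- y
  }
  list(ages = (0:nsteps) * h, Y = out)
}
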