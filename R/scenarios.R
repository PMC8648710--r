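#' The exponential remainder function psi
#'
#' \eqn{\psi(z) = z^{-2}(e^z - 1 - z) = 1/2 + z/3! + z^2/4! + \cdots}:
#' continuous, positive and increasing on the real line. It packages the
#' removable singularities of the first-order dispersal integrals in the
#' two-sink construction; for \eqn{|z| \le 10^{-4}} the 5-term Taylor series
#' is used to avoid cancellation.
#'
#' @param z numeric vector.
#' @return \eqn{\psi(z)}, vectorised.
#' @export
psi_exp <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) <= 1e-4
  zs <- z[small]
  out[small] <- 1 / 2 + zs / 6 + zs^2 / 24 + zs^3 / 120 + zs^4 / 720
  zb <- z[!small]
  out[!small] <- (exp(zb) - 1 - zb) / zb^2
  out
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# amplitude making a box [a1, a2] with constant mortality mu reach the
# target single-patch reproduction number
.box_amp_for_R0 <- function(target, mu, a1, a2) {
  target * mu / (exp(-mu * a1) - exp(-mu * a2))
}

# continuous initial age distribution: amp on [0, hi/2], ramping to 0 at hi
# (H5 assumes a continuous f; a jump would degrade the renewal quadrature)
.tent_f <- function(amp, hi) {
  force(amp); force(hi)
  function(a) amp * pmax(0, pmin(1, 2 * (hi - a) / hi)) * (a >= 0)
}

#' Generate a benchmark scenario
#'
#' Deterministic (seeded) scenario families used as fixtures throughout the
#' package. All generated models satisfy the structure hypotheses by
#' construction.
#'
#' \describe{
#'  \item{`single_patch_logistic`}{one patch, constant mortality `mu0`,
#'    logistic regulation with carrying scale `L`, box fecundity `m0` on
#'    `support`. Its linear reproduction number has the closed form
#'    \eqn{R_0 = m_0 (e^{-\mu_0 a_1} - e^{-\mu_0 a_2})/\mu_0}.}
#'  \item{`decoupled_patches`}{isolated patches whose box amplitudes are
#'    calibrated so that patch `k` has single-patch reproduction number
#'    `R0_targets[k]`.}
#'  \item{`source_sink`}{patch 1 a source (`R0_source > 1`), remaining
#'    patches sinks, coupled by `D = eps * B` with a Metzler `B` whose
#'    columns sum to at most 0.}
#'  \item{`two_sink_migratory`}{the two-patch all-sink construction of
#'    [design_two_sink()].}
#'  \item{`random_connected`}{`N` logistic patches with random constant
#'    mortalities and amplitudes and a random strongly connected Metzler
#'    dispersal matrix with nonpositive column sums (so the no-birth-in-
#'    transit bounds apply).}
#' }
#'
#' @param family scenario family.
#' @param ... family parameters (see Details above; all have defaults).
#' @param seed integer seed controlling any randomised choice; the same
#'   `family`, parameters and `seed` reproduce the model exactly.
#' @return a [patch_model()] (with attribute `"scenario"`).
#' @export
make_scenario <- function(family = c("single_patch_logistic", "decoupled_patches",
                                     "source_sink", "two_sink_migratory",
                                     "random_connected"),
                          ..., seed = 1L) {
  family <- match.arg(family)
  args <- list(...)
  gp <- function(name, default) if (!is.null(args[[name]])) args[[name]] else default
  model <- switch(family,
    single_patch_logistic = {
      mu0 <- gp("mu0", 0.5); m0 <- gp("m0", 30); sup <- gp("support", c(1, 2))
      L <- gp("L", 1); b <- gp("b", 3); b1 <- gp("b1", (max(sup) + b) / 2)
      patch_model(1, b,
                  mortality_law("logistic", mu = mu0, L = L),
                  birth_rate(m0, sup, ramp = gp("ramp", 0)),
                  f = .tent_f(gp("f_amp", 1), min(sup) / 2),
                  f_support = c(0, min(sup) / 2), b1 = b1)
    },
    decoupled_patches = {
      targets <- gp("R0_targets", c(1.4, 0.7))
      N <- length(targets)
      mu <- rep_len(gp("mu", 0.5), N)
      sup <- gp("support", c(1, 2)); b <- gp("b", 3)
      amp <- .box_amp_for_R0(targets, mu, sup[1], sup[2])
      patch_model(N, b,
                  mortality_law("logistic", mu = mu, L = rep_len(gp("L", 1), N)),
                  birth_rate(amp, sup),
                  f = .tent_f(1, sup[1] / 2), f_support = c(0, sup[1] / 2),
                  b1 = gp("b1", (max(sup) + b) / 2))
    },
    source_sink = {
      R0s <- c(gp("R0_source", 1.5), gp("R0_sinks", 0.7))
      N <- length(R0s)
      mu <- rep_len(gp("mu", c(0.5, 0.8)), N)
      sup <- gp("support", c(1, 2)); b <- gp("b", 3)
      eps <- gp("eps", 0.01)
      B <- gp("B", NULL)
      if (is.null(B)) {
        B <- matrix(0, N, N)
        B[1, 1] <- -1
        for (k in 2:N) { B[k, 1] <- 1 / (N - 1); B[1, k] <- 0.5; B[k, k] <- -0.6 }
      }
      amp <- .box_amp_for_R0(R0s, mu, sup[1], sup[2])
      patch_model(N, b,
                  mortality_law("logistic", mu = mu, L = rep(1, N)),
                  birth_rate(amp, sup),
                  dispersal = eps * B,
                  f = .tent_f(1, sup[1] / 2), f_support = c(0, sup[1] / 2),
                  b1 = gp("b1", (max(sup) + b) / 2))
    },
    two_sink_migratory = {
      des <- design_two_sink(gp("mu1", 1), gp("mu2", 0.4), gp("rho2", 0.3),
                             scan_eps = FALSE)
      two_sink_model(des, eps = gp("eps", 1e-3))
    },
    random_connected = .with_seed(seed, {
      N <- gp("N", 3)
      b <- gp("b", 3); sup <- gp("support", c(1, 2))
      mu <- stats::runif(N, 0.3, 1)
      amp <- .box_amp_for_R0(stats::runif(N, gp("R0_min", 0.6), gp("R0_max", 4)),
                             mu, sup[1], sup[2])
      repeat {   # rejection-sample a strongly connected sign pattern
        Doff <- matrix(stats::runif(N * N, 0, gp("D_scale", 0.3)) *
                         (stats::runif(N * N) < 0.6), N, N)
        diag(Doff) <- 0
        D <- Doff
        diag(D) <- -(1 + stats::runif(N, 0, 0.5)) * colSums(Doff)
        m0 <- patch_model(N, b, mortality_law("logistic", mu = mu, L = rep(1, N)),
                          birth_rate(amp, sup), dispersal = D,
                          f = .tent_f(1, sup[1] / 2), f_support = c(0, sup[1] / 2))
        if (all(vapply(seq_len(N), function(k) accessibility(m0, k), TRUE))) break
      }
      m0
    }))
  attr(model, "scenario") <- list(family = family, args = args, seed = seed)
  model
}

#' Design a permanent two-patch population out of two sinks
#'
#' Calibrates a two-patch model of a migratory population in which *both*
#' patches are sinks in isolation (each isolated reproduction number exactly
#' one) yet weak symmetric dispersal \eqn{D = \varepsilon B},
#' \eqn{B = \begin{pmatrix} -1 & 1 \\ 1 & -1 \end{pmatrix}}, makes the
#' coupled reproduction number exceed one. With constant mortalities
#' \eqn{\mu_1 > \mu_2 > 0}, the fertile supports are placed by solving (with
#' \eqn{\rho_1 = 1}, \eqn{0 < \rho_2 < 1/2})
#' \deqn{1/\rho_2 - 1 = c_1 (\mu_1 - \mu_2)\, \psi((\mu_1 - \mu_2) c_1), \quad
#'       1 - \rho_2 = d_2 (\mu_1 - \mu_2)\, \psi((\mu_2 - \mu_1) d_2),}
#' both monotone in the unknown, so that the first-order correction kernels
#' \eqn{h_1} and \eqn{h_2} are positive on the respective supports and hence
#' the first-order matrix \eqn{\mathcal{P}} satisfies
#' \eqn{\mathcal{P}(1, \rho_2)^t > 0}. Amplitudes are set to
#' \eqn{\mu_k / (e^{-\mu_k c_k} - e^{-\mu_k d_k})} so each isolated
#' \eqn{R_0^{(k)} = 1} exactly.
#'
#' @param mu1,mu2 constant mortalities, `mu1 > mu2 > 0`.
#' @param rho2 direction parameter in `(0, 1/2)`.
#' @param d1_margin length of patch 1's support, `[c1, c1 + d1_margin]`.
#' @param c2_margin patch 2's support is `[max(d2 - c2_margin, d2/2), d2]`.
#' @param scan_eps if `TRUE`, scan a logarithmic grid of dispersal strengths
#'   and record the largest with coupled `R0 > 1`.
#' @param eps_grid dispersal strengths scanned.
#' @return an object of class `"two_sink_design"`: calibrated geometry
#'   (`c_star`, `c1`, `d1`, `c2`, `d2`), amplitudes, the printed first-order
#'   matrix `P_matrix` (diagonal -1), `P_direction` \eqn{= \mathcal{P}(1,
#'   \rho_2)^t}, the quadrature-checked isolated `R0_isolated`, and (when
#'   scanned) `epsilon_max`.
#' @export
design_two_sink <- function(mu1, mu2, rho2, d1_margin = 0.5, c2_margin = 0.5,
                            scan_eps = TRUE,
                            eps_grid = 10^seq(-4, -1, length.out = 13)) {
  stopifnot(mu1 > mu2, mu2 > 0, rho2 > 0, rho2 < 1 / 2)
  dmu <- mu1 - mu2
  # z * psi(z) increases from 0 to Inf; z * psi(-z) increases from 0 to 1
  gpos <- function(c) c * dmu * psi_exp(dmu * c)
  gneg <- function(d) d * dmu * psi_exp(-dmu * d)
  root_inc <- function(g, target) {   # expand the bracket, then bisect
    hi <- 1 / dmu
    while (g(hi) < target) {
      hi <- 2 * hi
      if (hi > 1e9 / dmu) stop("two-sink design error: calibration target unreachable")
    }
    stats::uniroot(function(x) g(x) - target, c(1e-10, hi), tol = 1e-13)$root
  }
  c_star <- root_inc(gpos, 1)
  c1 <- root_inc(gpos, 1 / rho2 - 1)
  d2 <- root_inc(gneg, 1 - rho2)
  d1 <- c1 + d1_margin
  c2 <- max(d2 - c2_margin, d2 / 2)
  if (!(c2 > 0 && c2 < d2 && c1 < d1))
    stop("two-sink design error: margins produce an empty support")
  h <- c(.box_amp_for_R0(1, mu1, c1, d1), .box_amp_for_R0(1, mu2, c2, d2))
  # quadrature check of the isolated reproduction numbers
  R0_iso <- vapply(1:2, function(k) {
    cc <- if (k == 1) c(c1, d1) else c(c2, d2)
    mu <- if (k == 1) mu1 else mu2
    stats::integrate(function(a) h[k] * exp(-mu * a), cc[1], cc[2],
                     rel.tol = 1e-12)$value
  }, 0)
  # printed first-order matrix: diagonal -1, off-diagonal dispersal integrals,
  # evaluated through psi to avoid cancellation as mu1 -> mu2
  P12 <- stats::integrate(function(a)
    h[1] * exp(-mu1 * a) * a * (1 + dmu * a * psi_exp(dmu * a)),
    c1, d1, rel.tol = 1e-12)$value
  P21 <- stats::integrate(function(a)
    h[2] * exp(-mu2 * a) * a * (1 - dmu * a * psi_exp(-dmu * a)),
    c2, d2, rel.tol = 1e-12)$value
  P <- matrix(c(-1, P21, P12, -1), 2, 2)
  Pdir <- as.numeric(P %*% c(1, rho2))
  des <- structure(list(mu = c(mu1, mu2), rho2 = rho2, c_star = c_star,
                        c1 = c1, d1 = d1, c2 = c2, d2 = d2,
                        amplitudes = h, R0_isolated = R0_iso,
                        P_matrix = P, P_direction = Pdir,
                        epsilon_max = NA_real_),
                   class = "two_sink_design")
  if (any(Pdir <= 0))
    warning("P (1, rho2)^t is not positive; the first-order argument fails")
  if (scan_eps) {
    emax <- NA_real_
    for (eps in eps_grid) {
      R0e <- basic_reproduction_number(two_sink_model(des, eps))$R0
      if (R0e > 1) emax <- eps else break
    }
    des$epsilon_max <- emax
  }
  des
}

#' Instantiate the two-sink design as a patch model
#'
#' @param design a `"two_sink_design"`.
#' @param eps dispersal strength \eqn{\varepsilon}.
#' @param L logistic carrying scale (density regulation does not enter the
#'   linear reproduction numbers).
#' @export
two_sink_model <- function(design, eps = 1e-3, L = 1) {
  B <- matrix(c(-1, 1, 1, -1), 2, 2)
  Am <- max(design$d1, design$d2)
  patch_model(2, b = Am + 1,
              mortality_law("logistic", mu = design$mu, L = rep(L, 2)),
              birth_rate(design$amplitudes,
                         rbind(c(design$c1, design$d1), c(design$c2, design$d2))),
              dispersal = eps * B,
              f = .tent_f(1, min(design$c1, design$c2) / 2),
              f_support = c(0, min(design$c1, design$c2) / 2),
              b1 = Am + 0.5)
}

#' @export
print.two_sink_design <- function(x, ...) {
  cat("Two-sink construction (both patches subcritical in isolation)\n")
  cat(sprintf("  mu = (%g, %g), rho2 = %g, c* = %.6g\n",
              x$mu[1], x$mu[2], x$rho2, x$c_star))
  cat(sprintf("  supports: patch 1 [%.6g, %.6g], patch 2 [%.6g, %.6g]\n",
              x$c1, x$d1, x$c2, x$d2))
  cat(sprintf("  isolated R0: %.10g, %.10g (target 1)\n",
              x$R0_isolated[1], x$R0_isolated[2]))
  cat("  P (1, rho2)^t =", paste(signif(x$P_direction, 6), collapse = ", "), "\n")
  if (!is.na(x$epsilon_max))
    cat(sprintf("  largest scanned eps with coupled R0 > 1: %g\n", x$epsilon_max))
  invisible(x)
}

#' First-order R0 perturbation for a single source with sinks
#'
#' For isolated patches (`D == 0`) with patch 1 the unique source, switching
#' on weak dispersal \eqn{D = \varepsilon B} perturbs the basic reproduction
#' number as
#' \deqn{R_0(\varepsilon) = R_0^{(1)} + \varepsilon \int_0^\infty m_1(a)\,
#'   \Pi_1(a) \int_0^a B_{11}(s)\, ds\, da + O(\varepsilon^2),}
#' where \eqn{\Pi_1} is patch 1's survival (the inner integral is the
#' accumulated emigration/migration mortality along the characteristic; for
#' constant \eqn{B_{11}} it is \eqn{B_{11} a}). The function evaluates the
#' first-order prediction, the numerically exact \eqn{R_0(\varepsilon)} for
#' each requested \eqn{\varepsilon} (via the net reproductive matrix of the
#' perturbed model), and the observed convergence order of the prediction
#' error under \eqn{\varepsilon}-halving (close to 2 when the second-order
#' term is nonzero).
#'
#' @param model0 a [patch_model()] with no dispersal whose patch 1 is the
#'   unique source.
#' @param B Metzler matrix (constant, or function of age).
#' @param eps dispersal strengths; successive halvings give order estimates.
#' @param n_nodes quadrature nodes.
#' @return object of class `"perturbation_report"` with `R0_patch`,
#'   `coefficient`, a table of `eps`, `R0_numeric`, `prediction`, `error`,
#'   and `order` (Richardson estimates between consecutive entries).
#' @export
source_sink_perturbation <- function(model0, B, eps = c(0.02, 0.01),
                                     n_nodes = 48) {
  .check_constant(model0, "the perturbation analysis")
  if (!is.null(model0$dispersal) && .D_norm(model0) > 0)
    stop("base model must have D == 0")
  Rm0 <- next_generation_matrix(model0, n_nodes)
  R0k <- diag(Rm0)
  if (!(R0k[1] > 1 && all(R0k[-1] <= 1)))
    stop("patch 1 must be the unique source (R0^(1) > 1 >= R0^(k))")
  Bfun <- if (is.matrix(B)) function(a) B else B
  Boff <- Bfun(model0$birth$a_m); Boff <- Boff - diag(diag(Boff))
  if (any(Boff < -1e-12)) stop("B must be Metzler")
  gl <- .gl(n_nodes, model0$birth$a_m, model0$birth$A_m)
  mu1 <- function(s) .ev_mu(model0, s, rep(0, length(s)))[1, ]
  Pi1 <- exp(-.cumint_at(mu1, gl$x))
  m1 <- .ev_m(model0, gl$x, rep(0, n_nodes))[1, ]
  B11cum <- .cumint_at(function(s) vapply(s, function(si) Bfun(si)[1, 1], 0), gl$x)
  coefficient <- sum(gl$w * m1 * Pi1 * B11cum)
  eps <- sort(eps, decreasing = TRUE)
  R0n <- vapply(eps, function(e) {
    m <- model0
    m$dispersal <- if (is.matrix(B)) dispersal_field(e * B) else
      dispersal_field(function(a, t) e * Bfun(a), N = model0$N)
    basic_reproduction_number(m, n_nodes)$R0
  }, 0)
  pred <- R0k[1] + eps * coefficient
  err <- abs(R0n - pred)
  ord <- if (length(eps) >= 2)
    log(err[-length(err)] / err[-1]) / log(eps[-length(eps)] / eps[-1])
  else numeric(0)
  structure(list(R0_patch = R0k, coefficient = coefficient,
                 table = data.frame(eps = eps, R0_numeric = R0n,
                                    prediction = pred, error = err),
                 order = ord),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat("Source-sink dispersal perturbation of R0\n")
  cat(sprintf("  isolated R0 per patch: %s\n",
              paste(signif(x$R0_patch, 6), collapse = ", ")))
  cat(sprintf("  first-order coefficient: %.8g\n", x$coefficient))
  print(x$table, row.names = FALSE)
  if (length(x$order))
    cat("  observed order(s):", paste(signif(x$order, 4), collapse = ", "), "\n")
  invisible(x)
}
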