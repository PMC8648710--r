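#' Stationary theory: characteristic operator, maximal solution, R0
#'
#' In a constant environment the large-time behaviour is governed by the
#' finite-dimensional characteristic equation \eqn{\bar{\mathcal{K}}\rho = \rho},
#' where
#' \deqn{\bar{\mathcal{K}}\rho = \int_{a_m}^{A_m} m(a)\, \varphi(a; \rho)\, da}
#' and \eqn{\varphi(a;\rho)} is the stationary cohort profile with newborn
#' vector \eqn{\rho}. The operator is nondecreasing with image inside
#' \eqn{[0, \omega_2]^N}; iterating it downward from any point above
#' \eqn{\omega_2 \mathbf{1}} yields the *maximal solution* \eqn{\theta}.
#' Its linearisation at zero is the net reproductive matrix
#' \eqn{\mathcal{R}_0} whose spectral radius is the basic reproduction
#' number \eqn{R_0}; the dichotomy holds: \eqn{R_0 \le 1} forces
#' \eqn{\theta = 0} and extinction, \eqn{R_0 > 1} gives \eqn{\theta \gg 0},
#' permanence, and convergence of every solution with nonvanishing
#' initial-data term to \eqn{\theta}.
#'
#' @name stationary
NULL

.gl <- function(n, lo, hi) pracma::gaussLegendre(n, lo, hi)

# composite Gauss-Legendre over the fertile interval, split at every
# support breakpoint (per-patch boxes make the integrand only piecewise
# smooth; panel-wise quadrature restores spectral accuracy)
.birth_gl <- function(model, n_nodes = 48) {
  am <- model$birth$a_m; Am <- model$birth$A_m
  br <- c(am, Am)
  S <- model$birth$support
  if (!is.null(S)) {
    br <- c(br, as.numeric(S))
    if (model$birth$ramp > 0)
      br <- c(br, as.numeric(S) - model$birth$ramp, as.numeric(S) + model$birth$ramp)
  }
  br <- sort(unique(pmin(pmax(br, am), Am)))
  xs <- numeric(0); ws <- numeric(0)
  for (i in seq_len(length(br) - 1)) {
    if (br[i + 1] - br[i] < 1e-12) next
    gl <- .gl(n_nodes, br[i], br[i + 1])
    xs <- c(xs, gl$x); ws <- c(ws, gl$w)
  }
  list(x = xs, w = ws)
}

# phi(a; rho) (or linearised Y) at prescribed increasing positive ages
.phi_at <- function(model, rho, at, linearized = FALSE,
                    atol = 1e-13, rtol = 1e-11) {
  ord <- order(at)
  tms <- c(0, at[ord])
  vals <- .lsoda_cohort(model, rho, tms, "phi", 0, linearized, atol, rtol)
  out <- matrix(0, model$N, length(at))
  out[, ord] <- vals[, -1, drop = FALSE]
  out[out < 0 & out > -1e-10] <- 0
  out
}

#' Apply the stationary characteristic operator
#'
#' @param model a constant-environment [patch_model()].
#' @param rho nonnegative newborn vector (length `N`).
#' @param n_nodes Gauss-Legendre nodes on the fertile interval.
#' @return the vector \eqn{\bar{\mathcal{K}}\rho}.
#' @export
apply_Kbar <- function(model, rho, n_nodes = 48) {
  .check_constant(model, "the characteristic operator")
  if (any(rho < 0)) stop("rho must be nonnegative")
  if (all(rho == 0)) return(rho * 0)
  gl <- .birth_gl(model, n_nodes)
  phi <- .phi_at(model, rho, gl$x, atol = 1e-12, rtol = 1e-10)
  mv <- .ev_m(model, gl$x, rep(0, length(gl$x)))
  as.numeric((mv * phi) %*% gl$w)
}

#' Maximal solution of the stationary characteristic equation
#'
#' Iterates \eqn{\bar{\mathcal{K}}} downward from
#' \eqn{\rho^+ = (\omega_2 + 1)\mathbf{1}}; the iterates are component-wise
#' non-increasing and converge to the maximal solution \eqn{\theta}. The
#' limit is independent of the starting point above \eqn{\omega_2}; a second
#' run from \eqn{2\rho^+} verifies this numerically.
#'
#' @inheritParams apply_Kbar
#' @param tol sup-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @param verify_start run a second iteration from a doubled start and check
#'   agreement within `10 * tol`.
#' @param lower optional known lower solution; `theta >= lower` is checked.
#' @return list with `theta`, `iterations`, `history` (sup-norm changes).
#' @export
maximal_solution <- function(model, tol = 1e-9, max_iter = 500L,
                             verify_start = TRUE, lower = NULL, n_nodes = 48) {
  .check_constant(model, "the maximal solution")
  om <- omega_constants(model)
  run <- function(start) {
    rho <- start
    hist <- numeric(0)
    for (it in seq_len(max_iter)) {
      rho_new <- apply_Kbar(model, rho, n_nodes)
      if (max(rho_new - rho) > 1e-9 * max(1, om$omega2))
        stop("monotone iteration increased beyond round-off; ",
             "quadrature/ODE tolerances are inconsistent")
      d <- max(abs(rho_new - rho))
      hist <- c(hist, d)
      rho <- rho_new
      if (d < tol) break
    }
    if (d >= tol) stop("maximal-solution iteration did not converge in ",
                       max_iter, " steps (last change ", signif(d, 3), ")")
    list(theta = rho, hist = hist)
  }
  r1 <- run(rep(om$omega2 + 1, model$N))
  if (verify_start) {
    r2 <- run(rep(2 * (om$omega2 + 1), model$N))
    if (max(abs(r1$theta - r2$theta)) > 10 * tol)
      warning("maximal solution depends on the starting point beyond 10*tol; ",
              "reduce tol")
  }
  if (!is.null(lower) && any(r1$theta < lower - 10 * tol))
    warning("computed theta lies below the supplied lower solution")
  list(theta = r1$theta, iterations = length(r1$hist), history = r1$hist,
       omega2 = om$omega2)
}

#' Net reproductive matrix
#'
#' Column `j` is \eqn{\int m(a)\, Y(a; e_j)\, da} with `Y` the cohort
#' linearisation at zero density; the \eqn{\lambda \to 0} limit of the scaled
#' operators is realised directly by the linear system. Under the
#' accessibility condition the matrix is strongly positive (hence
#' irreducible).
#'
#' @inheritParams apply_Kbar
#' @return a nonnegative `N x N` matrix.
#' @export
next_generation_matrix <- function(model, n_nodes = 48) {
  .check_constant(model, "the net reproductive matrix")
  N <- model$N
  gl <- .birth_gl(model, n_nodes)
  mv <- .ev_m(model, gl$x, rep(0, length(gl$x)))
  R <- matrix(0, N, N)
  for (j in seq_len(N)) {
    Y <- .phi_at(model, as.numeric(seq_len(N) == j), gl$x, linearized = TRUE)
    R[, j] <- (mv * Y) %*% gl$w
  }
  R
}

.power_radius <- function(A, tol = 1e-12, max_iter = 5000L) {
  x <- rep(1, nrow(A)) / sqrt(nrow(A))
  lam <- 0; converged <- FALSE
  for (i in seq_len(max_iter)) {
    y <- A %*% x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(list(value = 0, vector = x, iters = i, converged = TRUE))
    y <- as.numeric(y / ny)
    if (max(abs(y - x)) < tol) { lam <- ny; x <- y; converged <- TRUE; break }
    x <- y; lam <- ny
  }
  list(value = lam, vector = x, iters = i, converged = converged)
}

#' Basic reproduction number
#'
#' Spectral radius of a net reproductive matrix (dense eigendecomposition,
#' cross-checked by power iteration), together with the Perron vector and the
#' Collatz-Wielandt bracket
#' \eqn{\min_i (\mathcal{R}_0 x)_i / x_i \le R_0 \le \max_i (\mathcal{R}_0 x)_i / x_i}.
#'
#' @param x a nonnegative matrix, or a constant-environment [patch_model()]
#'   (in which case the matrix is built first).
#' @param ... passed on to methods.
#' @return list with `R0`, `perron_vector` (unit 1-norm), `cw` (the
#'   Collatz-Wielandt bracket at the returned vector), and `R0_matrix`.
#' @export
basic_reproduction_number <- function(x, ...) UseMethod("basic_reproduction_number")

#' @export
basic_reproduction_number.matrix <- function(x, ...) {
  if (any(x < 0)) stop("net reproductive matrix must be nonnegative")
  ev <- eigen(x)
  i <- which.max(Re(ev$values))
  R0 <- Re(ev$values[i])
  v <- abs(Re(ev$vectors[, i]))
  if (sum(v) > 0) v <- v / sum(v)
  pw <- .power_radius(x)
  if (pw$converged && R0 > 1e-12 && abs(pw$value - R0) > 1e-6 * R0)
    warning("power iteration and eigendecomposition disagree on R0: ",
            signif(pw$value, 8), " vs ", signif(R0, 8))
  cw <- if (all(v > 0)) range((x %*% v) / v) else c(NA_real_, NA_real_)
  list(R0 = R0, perron_vector = v, cw = cw, R0_matrix = x)
}

#' @export
basic_reproduction_number.patch_model <- function(x, n_nodes = 48, ...) {
  basic_reproduction_number(next_generation_matrix(x, n_nodes))
}

#' Full stationary analysis: R0, maximal solution, dichotomy
#'
#' Bundles the net reproductive matrix, \eqn{R_0} with its Perron vector, the
#' maximal solution \eqn{\theta}, the equilibrium age profile
#' \eqn{\varphi(a;\theta)}, the limiting total population
#' \eqn{\int_0^b \varphi(a;\theta) da}, and the extinction/permanence
#' classification. Models with \eqn{|R_0 - 1| < } `near_margin` are flagged
#' `"indeterminate"`: the monotone iteration slows critically at
#' \eqn{R_0 = 1} and a numerical classification there is not trustworthy.
#'
#' @inheritParams apply_Kbar
#' @param tol tolerance for the maximal-solution iteration.
#' @param near_margin half-width of the numerically indeterminate band
#'   around \eqn{R_0 = 1}.
#' @param check_hypotheses validate (H2)-(H6) first.
#' @return an object of class `"stationary_fit"`.
#' @export
stationary_analysis <- function(model, tol = 1e-9, n_nodes = 48,
                                near_margin = 0.02, check_hypotheses = FALSE) {
  .check_constant(model, "stationary analysis")
  if (check_hypotheses) {
    rep <- validate_hypotheses(model)
    if (!all(rep$pass)) stop("structure hypotheses fail; see validate_hypotheses()")
  }
  om <- omega_constants(model)
  Rm <- next_generation_matrix(model, n_nodes)
  bp <- basic_reproduction_number(Rm)
  ms <- maximal_solution(model, tol = tol, n_nodes = n_nodes)
  theta <- ms$theta
  zthr <- 1e-8 * om$omega2
  near <- abs(bp$R0 - 1) < near_margin
  cls <- if (near) "indeterminate" else if (bp$R0 <= 1) "extinction" else "permanence"
  if (!near) {
    if (bp$R0 > 1 + near_margin && max(theta) <= zthr)
      stop("inconsistent dichotomy: R0 = ", signif(bp$R0, 6),
           " > 1 but theta ~ 0 (", signif(max(theta), 3), ")")
    if (bp$R0 < 1 - near_margin && max(theta) > zthr)
      stop("inconsistent dichotomy: R0 = ", signif(bp$R0, 6),
           " <= 1 but theta = ", signif(max(theta), 6), " > threshold")
  }
  if (cls == "extinction") theta <- theta * 0
  kres <- max(abs(apply_Kbar(model, theta, n_nodes) - theta))
  ages <- .default_ages(model)
  prof <- equilibrium_profile(model, theta, ages)
  glb <- .gl(64, 0, model$b)
  P_limit <- if (max(theta) == 0) rep(0, model$N)
             else as.numeric(.phi_at(model, theta, glb$x, atol = 1e-12, rtol = 1e-10) %*% glb$w)
  structure(list(R0_matrix = Rm, R0 = bp$R0, perron_vector = bp$perron_vector,
                 cw = bp$cw, theta = theta, equilibrium_profile = prof,
                 P_limit = P_limit, classification = cls,
                 near_critical = near, zero_threshold = zthr,
                 fixed_point_residual = kres, iterations = ms$iterations,
                 omega = om),
            class = "stationary_fit")
}

#' @export
print.stationary_fit <- function(x, ...) {
  cat("Stationary analysis of a multi-patch age-structured model\n")
  cat(sprintf("  R0 = %.6g  ->  %s%s\n", x$R0, x$classification,
              if (x$near_critical) " (|R0 - 1| below the numerical margin)" else ""))
  cat("  theta (maximal newborn vector):",
      paste(signif(x$theta, 6), collapse = ", "), "\n")
  cat("  limiting total population:",
      paste(signif(x$P_limit, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stationary_fit <- function(object, ...) {
  print(object)
  cat("  Perron vector:", paste(signif(object$perron_vector, 5), collapse = ", "), "\n")
  cat(sprintf("  Collatz-Wielandt bracket: [%.8g, %.8g]\n",
              object$cw[1], object$cw[2]))
  cat(sprintf("  fixed-point residual ||Kbar(theta) - theta|| = %.3g after %d iterations\n",
              object$fixed_point_residual, object$iterations))
  cat(sprintf("  omega1 = %.5g, omega2 = %.5g\n",
              object$omega$omega1, object$omega$omega2))
  invisible(object)
}

#' @export
coef.stationary_fit <- function(object, ...) object$theta

#' @export
plot.stationary_fit <- function(x, ...) {
  plot(x$equilibrium_profile,
       main = sprintf("equilibrium age profile (R0 = %.3g)", x$R0), ...)
  invisible(x)
}
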