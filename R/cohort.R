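#' Cohort solutions along characteristics
#'
#' The balance equations reduce, along characteristics `t - a = const`, to
#' cooperative ODE systems in age. Three systems are used throughout:
#' \describe{
#'  \item{forward (`cohort_phi`)}{\eqn{\Phi(x; \rho, y)}: the cohort born at
#'    time `y` with newborn vector \eqn{\rho(y)}; solves
#'    \eqn{h' = -M(h, x, x+y) h + D(x, x+y) h}, \eqn{h(0) = \rho(y)}.}
#'  \item{initial-data (`cohort_psi`)}{\eqn{\Psi(x; f, y)}: the cohort that
#'    had age `y` at time 0; solves \eqn{h' = -M(h, x+y, x) h + D(x+y, x) h},
#'    \eqn{h(0) = f(y)}; identically zero for `y >= b`.}
#'  \item{linearised (`cohort_linearized`)}{\eqn{Y(a; x_0)}: the
#'    linearisation at zero density, \eqn{Y' = (D(a) - M(0, a)) Y}; its
#'    fecundity-weighted integral builds the net reproductive matrix.}
#' }
#' Solutions are computed with an adaptive solver (`deSolve::lsoda`,
#' atol 1e-10 / rtol 1e-8 by default) and returned on a fixed uniform age grid
#' (512 points on `[0, b]` by default) so that downstream quadrature shares
#' one grid. Round-off negativity is clamped at `-1e-12`; anything below
#' `-1e-8` raises an error.
#'
#' @param model a [patch_model()].
#' @param rho0 nonnegative initial newborn vector (length `N`).
#' @param y time offset (birth time for `cohort_phi`, initial age for
#'   `cohort_psi`).
#' @param ages output age grid (defaults to 512 uniform points on `[0, b]`).
#' @param atol,rtol solver tolerances.
#' @return an object of class `"cohort_profile"`: list with `ages` (grid) and
#'   `values` (`N x length(ages)` matrix), plus metadata.
#' @name cohort
NULL

.default_ages <- function(model, n = 512) seq(0, model$b, length.out = n)

.clamp <- function(H, scale = 1) {
  if (any(H < -1e-8 * max(1, scale)))
    stop("solver produced significantly negative densities (min ",
         format(min(H)), "); tighten tolerances")
  H[H < 0] <- 0
  H
}

.lsoda_cohort <- function(model, h0, ages, mode = c("phi", "psi"), y = 0,
                          linearized = FALSE, atol = 1e-10, rtol = 1e-8) {
  mode <- match.arg(mode)
  N <- model$N
  rhs <- function(x, h, parms) {
    H <- matrix(h, N, 1)
    if (mode == "phi") { a <- x; tt <- x + y } else { a <- x + y; tt <- x }
    V <- if (linearized) matrix(0, N, 1) else H
    dH <- -.ev_M(model, V, a, tt) * H + .apply_D(model, H, a, tt)
    list(as.numeric(dH))
  }
  if (ages[1] != 0) stop("age grid must start at 0")
  sol <- deSolve::ode(y = as.numeric(h0), times = ages, func = rhs, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  t(unname(sol[, -1, drop = FALSE]))
}

#' @rdname cohort
#' @export
cohort_phi <- function(model, rho0, y = 0, ages = NULL, atol = 1e-10, rtol = 1e-8) {
  if (any(rho0 < 0)) stop("rho0 must be nonnegative")
  if (y < 0) stop("y must be nonnegative")
  if (is.null(ages)) ages <- .default_ages(model)
  vals <- .clamp(.lsoda_cohort(model, rho0, ages, "phi", y, FALSE, atol, rtol),
                 max(rho0, 1))
  structure(list(ages = ages, values = vals, system = "phi", offset = y,
                 init = rho0), class = "cohort_profile")
}

#' @rdname cohort
#' @export
cohort_psi <- function(model, y, ages = NULL, atol = 1e-10, rtol = 1e-8) {
  if (y < 0) stop("y must be nonnegative")
  if (is.null(ages)) ages <- .default_ages(model)
  f0 <- as.numeric(.ev_f(model, y))
  if (y >= model$b || all(f0 == 0)) {
    vals <- matrix(0, model$N, length(ages))
  } else {
    vals <- .clamp(.lsoda_cohort(model, f0, ages, "psi", y, FALSE, atol, rtol),
                   max(f0, 1))
  }
  structure(list(ages = ages, values = vals, system = "psi", offset = y,
                 init = f0), class = "cohort_profile")
}

#' @rdname cohort
#' @param x0 initial vector for the linearised system.
#' @export
cohort_linearized <- function(model, x0, y = 0, ages = NULL,
                              atol = 1e-12, rtol = 1e-10) {
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  if (is.null(ages)) ages <- .default_ages(model)
  vals <- .lsoda_cohort(model, x0, ages, "phi", y, TRUE, atol, rtol)
  vals[vals < 0 & vals > -1e-12] <- 0
  structure(list(ages = ages, values = vals, system = "linearized", offset = y,
                 init = x0), class = "cohort_profile")
}

#' Stationary cohort profile
#'
#' For a constant environment, \eqn{\varphi(a; \rho)} is the cohort profile
#' with newborn vector \eqn{\rho}; it does not depend on the birth time.
#'
#' @inheritParams cohort
#' @param rho nonnegative newborn vector.
#' @export
equilibrium_profile <- function(model, rho, ages = NULL, atol = 1e-10, rtol = 1e-8) {
  .check_constant(model, "the stationary cohort profile")
  cohort_phi(model, rho, y = 0, ages = ages, atol = atol, rtol = rtol)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("Cohort profile (%s system), %d patches on %d ages in [0, %g]\n",
              x$system, nrow(x$values), length(x$ages), max(x$ages)))
  cat("  initial vector:", paste(signif(x$init, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_profile <- function(x, ...) {
  d <- data.frame(age = x$ages)
  for (k in seq_len(nrow(x$values))) d[[paste0("n_", k)]] <- x$values[k, ]
  d
}

#' @export
plot.cohort_profile <- function(x, ...) {
  graphics::matplot(x$ages, t(x$values), type = "l", lty = 1,
                    xlab = "age", ylab = "density", ...)
  invisible(x)
}

# ---- batched fixed-step RK4 along characteristics ----------------------
#
# Marches an N x K matrix of cohorts simultaneously. Offsets y (length K)
# give, per column, the birth time ("phi" side: a = x, t = x + y) or the
# initial age ("psi" side: a = x + y, t = x). Used by the renewal and
# periodic operators where thousands of characteristics share one grid.

.rk4_batch <- function(model, H0, x_grid, y, side = c("phi", "psi"),
                       linearized = FALSE) {
  side <- match.arg(side)
  N <- nrow(H0); K <- ncol(H0)
  nx <- length(x_grid)
  out <- array(0, dim = c(N, K, nx))
  out[, , 1] <- H0
  H <- H0
  rhs <- function(H, x) {
    if (side == "phi") { a <- rep(x, K); tt <- x + y } else { a <- x + y; tt <- rep(x, K) }
    V <- if (linearized) 0 * H else H
    -.ev_M(model, V, a, tt) * H + .apply_D(model, H, a, tt)
  }
  for (i in seq_len(nx - 1)) {
    h <- x_grid[i + 1] - x_grid[i]
    x <- x_grid[i]
    k1 <- rhs(H, x)
    # sub-step when the local decay rate is under-resolved (the universal
    # majorant makes very dense cohorts collapse much faster than the grid)
    scale <- max(abs(H), 1e-12)
    nsub <- min(128L, max(1L, ceiling(h * max(abs(k1)) / (0.25 * scale))))
    hh <- h / nsub
    for (s in seq_len(nsub)) {
      xs <- x + (s - 1) * hh
      k1s <- if (s == 1L) k1 else rhs(H, xs)
      k2 <- rhs(H + hh / 2 * k1s, xs + hh / 2)
      k3 <- rhs(H + hh / 2 * k2, xs + hh / 2)
      k4 <- rhs(H + hh * k3, xs + hh)
      H <- H + hh / 6 * (k1s + 2 * k2 + 2 * k3 + k4)
      if (!linearized) H[H < 0] <- 0
    }
    out[, , i + 1] <- H
  }
  out
}
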