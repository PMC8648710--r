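#' The renewal (newborn) integral equation
#'
#' Writing \eqn{\rho(t) = n(0, t)} for the vector of per-patch birth rates,
#' the balance equations are equivalent to the integral equation
#' \deqn{\rho = \mathcal{K}\rho + \mathcal{F} f,}
#' where
#' \deqn{(\mathcal{K}\rho)(t) = \int_0^t m(a,t)\, \Phi(a; \rho, t-a)\, da,
#'       \qquad
#'       (\mathcal{F} f)(t) = \int_t^\infty m(a,t)\, \Psi(t; f, a-t)\, da.}
#' Both operators are positive and nondecreasing with bounded ranges:
#' every component of \eqn{\mathcal{K}\rho} is at most \eqn{\omega_2}
#' (see [omega_constants()]) and \eqn{\mathcal{F} f} vanishes for
#' \eqn{t \ge A_m}. [solve_newborns()] iterates
#' \eqn{\rho^{(i+1)} = \mathcal{K}\rho^{(i)} + \mathcal{F}f} from
#' \eqn{\rho^{(0)} = 0}; the iterates increase monotonically to the unique
#' solution, with the a-priori tail envelope
#' \eqn{2\omega_2 e^{Ct} (Ct)^i / i!}, \eqn{C = e^{Nb\|D\|} \|m\|_\infty}.
#'
#' Discretisation: uniform time grid with step `dt` (default
#' `(A_m - a_m)/32`), composite trapezoid in age on the same grid, the
#' convolution reading \eqn{\rho(t - a)} at grid points (ages and times share
#' the step, so no interpolation error enters the convolution).
#'
#' @param model a [patch_model()].
#' @param rho an `N x length(times)` matrix of newborn rates (or a
#'   `newborn_trajectory`).
#' @param times uniform time grid starting at 0.
#' @name renewal
NULL

# integral over [lo, hi] of the linear interpolant of node values on grid x:
# returns quadrature weights for the node values
.trapz_weights <- function(x, lo, hi) {
  n <- length(x); w <- numeric(n)
  for (i in seq_len(n - 1)) {
    l <- max(x[i], lo); r <- min(x[i + 1], hi)
    if (r > l) {
      h <- x[i + 1] - x[i]
      w[i]     <- w[i]     + ((x[i + 1] - l)^2 - (x[i + 1] - r)^2) / (2 * h)
      w[i + 1] <- w[i + 1] + ((r - x[i])^2 - (l - x[i])^2) / (2 * h)
    }
  }
  w
}

.traj_times <- function(rho, times) {
  if (inherits(rho, "newborn_trajectory")) return(list(rho = rho$rho, times = rho$times))
  list(rho = rho, times = times)
}

.check_dt <- function(model, dt) {
  if (dt > (model$birth$A_m - model$birth$a_m) / 4)
    stop("time step ", format(dt), " is coarser than a quarter of the fertile window; ",
         "the age quadrature would be meaningless")
}

#' @rdname renewal
#' @export
apply_K <- function(model, rho, times = NULL) {
  tr <- .traj_times(rho, times)
  rho <- tr$rho; times <- tr$times
  if (any(rho < 0)) stop("rho must be nonnegative")
  nt <- length(times)
  dt <- times[2] - times[1]
  .check_dt(model, dt)
  am <- model$birth$a_m; Am <- model$birth$A_m
  na <- ceiling(Am / dt - 1e-9)
  ages <- seq(0, by = dt, length.out = na + 1)
  # Phi(a_j; rho, y_q) for all birth times y_q = times[q]
  Phi <- .rk4_batch(model, rho, ages, times, side = "phi")
  w <- .trapz_weights(ages, am, Am)
  const_m <- model$time_dependence == "constant"
  if (const_m) m_at <- .ev_m(model, ages, rep(0, na + 1))
  out <- matrix(0, model$N, nt)
  for (j in which(w > 0)) {
    idx <- seq.int(j, nt)                # times t with t >= a_j
    if (!length(idx)) next
    mj <- if (const_m) m_at[, j] else .ev_m(model, rep(ages[j], length(idx)), times[idx])
    contrib <- Phi[, idx - j + 1, j, drop = FALSE]   # offset y = t - a_j
    dim(contrib) <- c(model$N, length(idx))
    out[, idx] <- out[, idx] + w[j] * mj * contrib
  }
  # early times t < A_m: integral runs only to t, redo with clipped weights
  for (i in seq_len(min(na, nt - 1))) {
    ti <- times[i + 1]
    wi <- .trapz_weights(ages, am, min(ti, Am))
    acc <- matrix(0, model$N, 1)
    for (j in which(wi > 0)) {
      if (i - j + 2 < 1) next
      mj <- if (const_m) m_at[, j] else .ev_m(model, ages[j], ti)
      acc <- acc + wi[j] * as.numeric(mj) * Phi[, i - j + 2, j]   # y = t_i - a_j
    }
    out[, i + 1] <- acc
  }
  out[, 1] <- 0
  structure(list(times = times, rho = out, iterations = NA_integer_,
                 residual = NA_real_, history = NULL),
            class = "newborn_trajectory")
}

#' @rdname renewal
#' @export
apply_F <- function(model, times) {
  nt <- length(times)
  dt <- times[2] - times[1]
  .check_dt(model, dt)
  am <- model$birth$a_m; Am <- model$birth$A_m
  ny <- ceiling(Am / dt - 1e-9)
  ys <- seq(0, by = dt, length.out = ny + 1)
  F0 <- .ev_f(model, ys)
  out <- matrix(0, model$N, nt)
  if (all(F0 == 0)) {
    return(structure(list(times = times, rho = out, iterations = NA_integer_,
                          residual = NA_real_, history = NULL),
                     class = "newborn_trajectory"))
  }
  nx <- min(ny, nt - 1)
  Psi <- .rk4_batch(model, F0, ys[seq_len(nx + 1)], ys, side = "psi")
  for (i in 0:nx) {                       # t_i = i dt <= A_m
    ti <- times[i + 1]
    if (ti >= Am) break
    aa <- ys + ti                          # ages a = y + t
    wi <- .trapz_weights(aa, max(ti, am), Am)
    jj <- which(wi > 0)
    if (!length(jj)) next
    mvals <- .ev_m(model, aa[jj], rep(ti, length(jj)))
    contrib <- Psi[, jj, i + 1, drop = FALSE]
    dim(contrib) <- c(model$N, length(jj))
    out[, i + 1] <- (mvals * contrib) %*% wi[jj]
  }
  structure(list(times = times, rho = out, iterations = NA_integer_,
                 residual = NA_real_, history = NULL),
            class = "newborn_trajectory")
}

#' Solve the renewal equation by monotone Picard iteration
#'
#' @inheritParams renewal
#' @param horizon time horizon (at least `A_m`).
#' @param dt time step; default `(A_m - a_m)/32`.
#' @param tol stopping tolerance on the sup-norm change between iterates.
#' @param max_iter maximal number of Picard sweeps.
#' @param start optional starting trajectory (`N x nt` matrix); default 0, for
#'   which the iterates are provably nondecreasing.
#' @return a `"newborn_trajectory"`: `times`, `rho` (`N x nt`), `iterations`,
#'   final fixed-point `residual`, per-iteration `history`, and the a-priori
#'   `envelope` diagnostics.
#' @export
solve_newborns <- function(model, horizon, dt = NULL, tol = 1e-8,
                           max_iter = 400L, start = NULL) {
  am <- model$birth$a_m; Am <- model$birth$A_m
  if (horizon < Am) stop("horizon must be at least A_m")
  if (tol <= 0) stop("tol must be positive")
  if (is.null(dt)) dt <- (Am - am) / 32
  .check_dt(model, dt)
  nt <- ceiling(horizon / dt - 1e-9) + 1
  times <- seq(0, by = dt, length.out = nt)
  Ff <- apply_F(model, times)$rho
  om2 <- tryCatch(omega_constants(model)$omega2, error = function(e) NA_real_)
  rho <- if (is.null(start)) matrix(0, model$N, nt) else {
    stopifnot(is.matrix(start), nrow(start) == model$N, ncol(start) == nt)
    start
  }
  monotone <- is.null(start)
  history <- numeric(0)
  scale <- max(Ff, om2, 1, na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    rho_new <- apply_K(model, rho, times)$rho + Ff
    delta <- max(abs(rho_new - rho))
    history <- c(history, delta)
    if (monotone && min(rho_new - rho) < -1e-6 * scale)
      stop("Picard iterates failed to be nondecreasing beyond round-off; ",
           "quadrature/ODE tolerances are inconsistent")
    rho <- rho_new
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("renewal iteration did not reach tol = ", tol, " in ", max_iter,
         " sweeps; last changes: ",
         paste(signif(utils::tail(history, 5), 3), collapse = ", "))
  resid <- max(abs(rho - apply_K(model, rho, times)$rho - Ff))
  env <- NA_real_
  if (is.finite(om2)) {
    C <- exp(model$N * model$b * .D_norm(model)) * .m_sup(model)
    i <- length(history)
    env <- 2 * om2 * exp(min(C * horizon, 700)) *
      exp(i * log(C * horizon) - lgamma(i + 1))
  }
  structure(list(times = times, rho = rho, iterations = length(history),
                 residual = resid, history = history, envelope = env,
                 omega2 = om2),
            class = "newborn_trajectory")
}

#' @export
print.newborn_trajectory <- function(x, ...) {
  cat(sprintf("Newborn trajectory: %d patches on t in [0, %g] (%d nodes)\n",
              nrow(x$rho), max(x$times), length(x$times)))
  if (!is.na(x$iterations))
    cat(sprintf("  Picard sweeps: %d, fixed-point residual: %.3g\n",
                x$iterations, x$residual))
  cat("  terminal rho:", paste(signif(x$rho[, ncol(x$rho)], 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.newborn_trajectory <- function(x, ...) {
  d <- data.frame(t = x$times)
  for (k in seq_len(nrow(x$rho))) d[[paste0("rho_", k)]] <- x$rho[k, ]
  d
}

#' @export
plot.newborn_trajectory <- function(x, ...) {
  graphics::matplot(x$times, t(x$rho), type = "l", lty = 1,
                    xlab = "time", ylab = "newborns / time", ...)
  invisible(x)
}

#' Reconstruct the age density and total population
#'
#' Given a solved newborn trajectory, rebuilds
#' \eqn{n(a, t) = \Phi(a; \rho, t - a)} for \eqn{t > a} and
#' \eqn{n(a, t) = \Psi(t; f, a - t)} for \eqn{a \ge t} (the initial-data
#' branch is used on the diagonal `a = t`, a convention: the weak solution
#' does not fix the diagonal value, and the two branches agree there whenever
#' `f(0) = rho(0)`), and the total population
#' \eqn{P(t) = \int_0^b n(a, t)\, da}.
#'
#' @param model a [patch_model()].
#' @param traj a `"newborn_trajectory"` solving the renewal equation.
#' @return an object of class `"population_field"`: `ages`, `times`, density
#'   array `n` (`N x n_ages x n_times`), and `P` (`N x n_times`).
#' @export
reconstruct_density <- function(model, traj) {
  times <- traj$times; rho <- traj$rho
  dt <- times[2] - times[1]
  nt <- length(times)
  na <- floor(model$b / dt + 1e-9)
  ages <- seq(0, by = dt, length.out = na + 1)
  Phi <- .rk4_batch(model, rho, ages, times, side = "phi")
  nxp <- min(na, nt - 1)
  F0 <- .ev_f(model, ages)
  Psi <- .rk4_batch(model, F0, times[seq_len(nxp + 1)], ages, side = "psi")
  n <- array(0, dim = c(model$N, na + 1, nt))
  for (i in seq_len(nt)) {                # time index i -> t = (i-1) dt
    n[, 1, i] <- rho[, i]                 # the newborn edge is rho by definition
    for (j in seq.int(2, na + 1)) {       # age index j -> a = (j-1) dt
      if (i > j) {                        # t > a: forward branch
        n[, j, i] <- Phi[, i - j + 1, j]
      } else if (j - i + 1 <= na + 1 && i <= nxp + 1) {  # a >= t: initial branch
        n[, j, i] <- Psi[, j - i + 1, i]
      }
    }
  }
  # diagonal mismatch diagnostic (f(0) != rho(0) is legitimate data)
  mism <- max(abs(.ev_f(model, 0) - rho[, 1]))
  if (mism > 1e-6 * max(1, max(rho)))
    message("note: f(0) differs from rho(0) by ", signif(mism, 3),
            "; the density is discontinuous across a = t")
  w <- .trapz_weights(ages, 0, model$b)
  P <- matrix(0, model$N, nt)
  for (i in seq_len(nt)) {
    sl <- n[, , i, drop = FALSE]; dim(sl) <- c(model$N, na + 1)
    P[, i] <- sl %*% w
  }
  structure(list(ages = ages, times = times, n = n, P = P),
            class = "population_field")
}

#' @export
print.population_field <- function(x, ...) {
  cat(sprintf("Population field: %d patches, %d ages x %d times\n",
              dim(x$n)[1], dim(x$n)[2], dim(x$n)[3]))
  cat("  terminal total population:",
      paste(signif(x$P[, ncol(x$P)], 6), collapse = ", "), "\n")
  invisible(x)
}

#' Total population time series of a population field
#'
#' @param field a `"population_field"`.
#' @return data frame with `t` and one column `P_k` per patch.
#' @export
total_population <- function(field) {
  d <- data.frame(t = field$times)
  for (k in seq_len(nrow(field$P))) d[[paste0("P_", k)]] <- field$P[k, ]
  d
}

#' @export
as.data.frame.population_field <- function(x, ...) {
  # long format: (a, t, patch, n)
  N <- dim(x$n)[1]
  g <- expand.grid(age = x$ages, t = x$times, patch = seq_len(N))
  g$n <- as.numeric(aperm(x$n, c(2, 3, 1)))
  g
}
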