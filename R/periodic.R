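#' Periodic environments
#'
#' For vital rates with period `T` the relevant characteristic equation lives
#' on the cone of nonnegative `T`-periodic functions:
#' \eqn{\tilde{\mathcal{K}}\rho(t) = \int_0^\infty m(a,t) \Phi(a;\rho,t-a) da}.
#' Periodic functions are represented by their values at `M` uniform
#' collocation nodes per period with periodic *linear* interpolation, which
#' preserves positivity and the monotone structure of the iteration (a
#' spectral representation would not). The periodic maximal solution is the
#' downward monotone limit of \eqn{\tilde{\mathcal{K}}} iterates; the
#' periodic basic reproduction number is the spectral radius of the
#' linearised operator materialised as an `(M N) x (M N)` nonnegative matrix
#' on node values.
#'
#' @param values `N x M` matrix of nonnegative node values.
#' @param period period `T`.
#' @param times optional node times (default `seq(0, T, length.out = M + 1)`
#'   without the right endpoint).
#' @return `periodic_function()`: object of class `"periodic_function"`.
#' @name periodic
NULL

#' @rdname periodic
#' @export
periodic_function <- function(values, period, times = NULL) {
  if (!is.matrix(values)) values <- matrix(values, 1)
  M <- ncol(values)
  if (is.null(times)) times <- seq(0, period, length.out = M + 1)[seq_len(M)]
  stopifnot(period > 0, all(values >= 0), length(times) == M)
  structure(list(values = values, period = period, times = times),
            class = "periodic_function")
}

#' Evaluate a periodic function (periodic linear interpolation)
#'
#' @param pf a `"periodic_function"`.
#' @param t vector of times.
#' @return `N x length(t)` matrix.
#' @export
pf_eval <- function(pf, t) {
  M <- ncol(pf$values)
  dph <- pf$period / M
  ph <- (t %% pf$period) / dph
  i0 <- pmin(floor(ph), M - 1)
  lam <- ph - i0
  i1 <- (i0 + 1) %% M
  pf$values[, i0 + 1, drop = FALSE] * rep(1 - lam, each = nrow(pf$values)) +
    pf$values[, i1 + 1, drop = FALSE] * rep(lam, each = nrow(pf$values))
}

#' @export
print.periodic_function <- function(x, ...) {
  cat(sprintf("Periodic function: period %g, %d patches x %d nodes\n",
              x$period, nrow(x$values), ncol(x$values)))
  cat("  range:", paste(signif(range(x$values), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
plot.periodic_function <- function(x, ...) {
  graphics::matplot(x$times, t(x$values), type = "l", lty = 1,
                    xlab = "time (one period)", ylab = "value", ...)
  invisible(x)
}

.periodic_age_grid <- function(model, n_age = NULL) {
  Am <- model$birth$A_m; am <- model$birth$a_m
  if (is.null(n_age)) n_age <- ceiling(Am / ((Am - am) / 64))
  seq(0, Am, length.out = n_age + 1)
}

.check_periodic <- function(model, pf = NULL) {
  if (model$time_dependence == "general")
    stop("model is not periodic")
  Tm <- if (model$time_dependence == "constant") NULL else model$period
  if (!is.null(pf) && !is.null(Tm) && abs(pf$period - Tm) > 1e-12 * Tm)
    stop("period mismatch between model (", Tm, ") and function (", pf$period, ")")
}

# Phi(a_j; rho, y_q) batched over the M collocation offsets; array N x M x n_ages
.periodic_phi_batch <- function(model, pf, ages, linearized = FALSE) {
  H0 <- pf$values
  .rk4_batch(model, H0, ages, pf$times, side = "phi", linearized = linearized)
}

# interpolation in the offset y at fixed age index; Phi is N x M x nages
.interp_offset <- function(Phi, j, y, period) {
  M <- dim(Phi)[2]
  dph <- period / M
  ph <- (y %% period) / dph
  i0 <- min(floor(ph), M - 1)
  lam <- ph - i0
  i1 <- (i0 + 1) %% M
  (1 - lam) * Phi[, i0 + 1, j] + lam * Phi[, i1 + 1, j]
}

#' Apply the periodic characteristic operator
#'
#' @param model a periodic [patch_model()] (a constant-environment model is
#'   accepted and treated as periodic with the function's period).
#' @param pf a `"periodic_function"` with the model's period.
#' @param n_age number of age steps on `[0, A_m]` for the quadrature.
#' @return a `"periodic_function"` holding \eqn{\tilde{\mathcal{K}}\rho}.
#' @export
apply_Ktilde <- function(model, pf, n_age = NULL) {
  .check_periodic(model, pf)
  ages <- .periodic_age_grid(model, n_age)
  Phi <- .periodic_phi_batch(model, pf, ages)
  w <- .trapz_weights(ages, model$birth$a_m, model$birth$A_m)
  M <- ncol(pf$values)
  out <- matrix(0, model$N, M)
  for (i in seq_len(M)) {
    ti <- pf$times[i]
    jj <- which(w > 0)
    mv <- .ev_m(model, ages[jj], rep(ti, length(jj)))
    acc <- 0
    for (s in seq_along(jj)) {
      j <- jj[s]
      acc <- acc + w[j] * mv[, s] * .interp_offset(Phi, j, ti - ages[j], pf$period)
    }
    out[, i] <- acc
  }
  periodic_function(out, pf$period, pf$times)
}

#' Periodic maximal solution
#'
#' Monotone non-increasing iteration of \eqn{\tilde{\mathcal{K}}} from
#' \eqn{\rho^+ \equiv (\omega_2 + 1)\mathbf{1}}.
#'
#' @inheritParams apply_Ktilde
#' @param period the period (required for a constant-coefficient model run
#'   through the periodic machinery; otherwise taken from the model).
#' @param M_points collocation nodes per period.
#' @param tol sup-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @param verify_start second run from a doubled start, checked within
#'   `10 * tol`.
#' @return a `"periodic_function"` \eqn{\theta(t)} with attributes
#'   `iterations` and `residual` (fixed-point defect).
#' @export
periodic_maximal_solution <- function(model, period = NULL, M_points = 64,
                                      tol = 1e-8, max_iter = 300L,
                                      n_age = NULL, verify_start = FALSE) {
  .check_periodic(model)
  if (is.null(period)) period <- model$period
  if (is.null(period)) stop("period required")
  om2 <- omega_constants(model)$omega2
  run <- function(level) {
    pf <- periodic_function(matrix(level, model$N, M_points), period)
    for (it in seq_len(max_iter)) {
      pf_new <- apply_Ktilde(model, pf, n_age)
      if (max(pf_new$values - pf$values) > 1e-8 * max(1, om2))
        stop("periodic monotone iteration increased beyond round-off")
      d <- max(abs(pf_new$values - pf$values))
      pf <- pf_new
      if (d < tol) break
    }
    if (d >= tol) stop("periodic maximal-solution iteration did not converge")
    attr(pf, "iterations") <- it
    pf
  }
  th <- run(om2 + 1)
  if (verify_start) {
    th2 <- run(2 * (om2 + 1))
    if (max(abs(th2$values - th$values)) > 10 * tol)
      warning("periodic maximal solution depends on the start beyond 10*tol")
  }
  attr(th, "residual") <- max(abs(apply_Ktilde(model, th, n_age)$values - th$values))
  th
}

#' Periodic basic reproduction number
#'
#' The linearised periodic operator (cohorts propagated with the zero-density
#' mortality along characteristics, weighted by fecundity) is materialised as
#' an `(M N) x (M N)` nonnegative matrix acting on collocation values; its
#' spectral radius is returned. Dense eigendecomposition is used for
#' `M * N <= 2048` and cross-checked by power iteration.
#'
#' @inheritParams periodic_maximal_solution
#' @return list with `R0`, the discretised operator `matrix`, and the
#'   dominant periodic eigenfunction as a `"periodic_function"`.
#' @export
periodic_R0 <- function(model, period = NULL, M_points = 64, n_age = NULL) {
  .check_periodic(model)
  if (is.null(period)) period <- model$period
  if (is.null(period)) stop("period required")
  N <- model$N
  ages <- .periodic_age_grid(model, n_age)
  nodes <- seq(0, period, length.out = M_points + 1)[seq_len(M_points)]
  # matrix cohort solutions: for each offset q, Y(x; y_q) in R^{N x N}
  H0 <- matrix(0, N, N * M_points)
  for (q in seq_len(M_points)) H0[, (q - 1) * N + seq_len(N)] <- diag(N)
  yrep <- rep(nodes, each = N)
  Y <- .rk4_batch(model, H0, ages, yrep, side = "phi", linearized = TRUE)
  w <- .trapz_weights(ages, model$birth$a_m, model$birth$A_m)
  A <- matrix(0, M_points * N, M_points * N)
  dph <- period / M_points
  for (i in seq_len(M_points)) {
    ti <- nodes[i]
    rows <- (i - 1) * N + seq_len(N)
    for (j in which(w > 0)) {
      mv <- as.numeric(.ev_m(model, ages[j], ti))
      y <- (ti - ages[j]) %% period
      ph <- y / dph
      q0 <- min(floor(ph), M_points - 1)
      lam <- ph - q0
      q1 <- (q0 + 1) %% M_points
      Y0 <- Y[, q0 * N + seq_len(N), j, drop = FALSE]; dim(Y0) <- c(N, N)
      Y1 <- Y[, q1 * N + seq_len(N), j, drop = FALSE]; dim(Y1) <- c(N, N)
      Yi <- (1 - lam) * Y0 + lam * Y1      # Y at offset y
      blk <- w[j] * mv * Yi                # rows scaled by m_k(a_j, t_i)
      cols0 <- q0 * N + seq_len(N); cols1 <- q1 * N + seq_len(N)
      A[rows, cols0] <- A[rows, cols0] + (1 - lam) * blk
      A[rows, cols1] <- A[rows, cols1] + lam * blk
    }
  }
  A[A < 0] <- 0
  if (M_points * N <= 2048) {
    bp <- basic_reproduction_number(A)
    R0 <- bp$R0
    vec <- bp$perron_vector
  } else {
    pw <- .power_radius(A)
    R0 <- pw$value
    vec <- abs(pw$vector)
  }
  ef <- periodic_function(matrix(vec, N, M_points), period, nodes)
  list(R0 = R0, matrix = A, eigenfunction = ef)
}

#' Periodic envelopes of an irregularly varying model
#'
#' For a model whose rates vary irregularly but are bounded by equiperiodic
#' functions for `t >= T1`, builds the best-case (upper) and worst-case
#' (lower) periodic models by taking per-phase running extrema over `K`
#' observed periods of the sampled rates (mortality ordering is reversed:
#' the *upper* model has the *smaller* mortality), then inflating/deflating
#' by a safety factor to absorb interpolation error.
#'
#' @param model a [patch_model()] (general time dependence).
#' @param period the envelope period `T`.
#' @param T1 onset time (default `b`, so that initial-data terms of the
#'   envelope problems vanish beyond it).
#' @param n_periods number `K` of periods scanned.
#' @param M_phase phase-grid resolution per period.
#' @param n_age age-grid resolution.
#' @param safety multiplicative safety factor (default `1 + 1e-6`).
#' @return object of class `"envelope_models"` with components `upper` and
#'   `lower` (periodic [patch_model()]s), plus the sampling diagnostics.
#' @export
build_envelopes <- function(model, period, T1 = NULL, n_periods = 8,
                            M_phase = 64, n_age = 65, safety = 1 + 1e-6) {
  if (is.null(T1)) T1 <- model$b
  N <- model$N
  law <- model$mortality
  ages <- seq(0, model$b, length.out = n_age)
  phases <- seq(0, period, length.out = M_phase + 1)[seq_len(M_phase)]
  # start sampling at the first period boundary at or after T1, so the
  # tabulated phase axis coincides with absolute time modulo the period
  T1p <- ceiling(T1 / period - 1e-12) * period
  samp <- function(f) {
    lo <- array(Inf, c(N, n_age, M_phase)); hi <- array(-Inf, c(N, n_age, M_phase))
    for (p in seq_len(n_periods)) {
      tt <- T1p + (p - 1) * period + phases
      for (q in seq_len(M_phase)) {
        v <- f(ages, rep(tt[q], n_age))
        if (any(!is.finite(v))) stop("rate unbounded on the sampling grid")
        lo[, , q] <- pmin(lo[, , q], v); hi[, , q] <- pmax(hi[, , q], v)
      }
    }
    list(lo = lo, hi = hi)
  }
  mu_s <- samp(function(a, t) .ev_mu(model, a, t))
  m_s <- samp(function(a, t) .ev_m(model, a, t))
  if (law$kind == "logistic") {
    r_s <- samp(function(a, t) .ev_mu(model, a, t) /
                  .ev_prate(law$L, N, a, t))   # mu / L
  }
  mk_rates <- function(arr, fac) {
    lapply(seq_len(N), function(k) {
      vals <- pmax(arr[k, , ] * fac, 0)
      rate_table(ages, phases, period, vals)
    })
  }
  build <- function(which) {
    if (which == "upper") {       # best case: most births, least mortality
      m_r <- mk_rates(m_s$hi, safety)
      mu_r <- mk_rates(mu_s$lo, 1 / safety)
      if (law$kind == "logistic") r_r <- mk_rates(r_s$lo, 1 / safety)
    } else {
      m_r <- mk_rates(m_s$lo, 1 / safety)
      mu_r <- mk_rates(mu_s$hi, safety)
      if (law$kind == "logistic") r_r <- mk_rates(r_s$hi, safety)
    }
    mort <- switch(law$kind,
      density_independent = mortality_law("density_independent", mu = mu_r),
      logistic = {
        Lr <- lapply(seq_len(N), function(k) {
          muf <- mu_r[[k]]; rf <- r_r[[k]]
          function(a, t) pmax(muf(a, t), 1e-300) / pmax(rf(a, t), 1e-300)
        })
        mortality_law("logistic", mu = mu_r, L = Lr)
      },
      power_law = mortality_law("power_law", mu = mu_r, p = law$p_raw,
                                gamma = law$gamma, mu_inf = law$mu_inf))
    # dispersal envelopes: entrywise extrema over sampled times
    disp <- model$dispersal
    if (!is.null(disp) && is.null(disp$constant)) {
      Dlo <- matrix(Inf, N, N); Dhi <- matrix(-Inf, N, N)
      for (a in ages) for (p in seq_len(n_periods)) for (q in seq(1, M_phase, by = 4)) {
        D <- .D_at(model, a, T1p + (p - 1) * period + phases[q])
        Dlo <- pmin(Dlo, D); Dhi <- pmax(Dhi, D)
      }
      disp <- dispersal_field(if (which == "upper") Dhi else Dlo)
    }
    patch_model(N, model$b, mort,
                birth_rate(m_r, support = c(model$birth$a_m, model$birth$A_m)),
                dispersal = disp, f = model$f_raw, f_support = model$f_support,
                b1 = model$b1, time_dependence = "periodic", period = period)
  }
  structure(list(upper = build("upper"), lower = build("lower"),
                 period = period, T1 = T1, n_periods = n_periods,
                 safety = safety),
            class = "envelope_models")
}

#' @export
print.envelope_models <- function(x, ...) {
  cat(sprintf("Periodic envelope models: period %g, onset T1 = %g, %d periods scanned\n",
              x$period, x$T1, x$n_periods))
  invisible(x)
}

#' Sandwich bounds for an irregularly varying environment
#'
#' Solves the renewal problem for the general model and the two periodic
#' characteristic equations of its envelopes; reports the first time `T2`
#' after which
#' \eqn{\rho^-(t) - \varepsilon \le \chi(t) \le \rho^+(t) + \varepsilon}
#' holds on the grid. If the upper envelope's periodic \eqn{R_0^+ \le 1} the
#' verdict is extinction and the terminal newborn level is reported instead.
#'
#' @param model the general time-dependent [patch_model()].
#' @param envelopes an `"envelope_models"` object.
#' @param horizon simulation horizon.
#' @param epsilon tube half-width \eqn{\varepsilon}.
#' @param M_points collocation nodes for the envelope problems.
#' @param ... passed to [solve_newborns()].
#' @return list with `verdict` (`"tube"`, `"extinction"`, or
#'   `"not attained"`), `T2`, the trajectory `chi`, and the envelope
#'   solutions `rho_minus`, `rho_plus`.
#' @export
sandwich_bounds <- function(model, envelopes, horizon, epsilon,
                            M_points = 32, ...) {
  chi <- solve_newborns(model, horizon = horizon, ...)
  up <- periodic_R0(envelopes$upper, M_points = M_points)
  if (up$R0 <= 1) {
    return(list(verdict = "extinction", R0_plus = up$R0, T2 = NA_real_,
                chi = chi, terminal = chi$rho[, ncol(chi$rho)],
                rho_minus = NULL, rho_plus = NULL))
  }
  th_p <- periodic_maximal_solution(envelopes$upper, M_points = M_points)
  lo <- periodic_R0(envelopes$lower, M_points = M_points)
  th_m <- if (lo$R0 > 1) periodic_maximal_solution(envelopes$lower, M_points = M_points)
          else periodic_function(matrix(0, model$N, M_points), envelopes$period)
  up_t <- pf_eval(th_p, chi$times)
  lo_t <- pf_eval(th_m, chi$times)
  ok <- apply(chi$rho <= up_t + epsilon & chi$rho >= lo_t - epsilon, 2, all)
  T2 <- NA_real_
  if (ok[length(ok)]) {
    last_bad <- max(c(0, which(!ok)))
    T2 <- chi$times[min(last_bad + 1, length(ok))]
  }
  list(verdict = if (is.na(T2)) "not attained" else "tube",
       T2 = T2, epsilon = epsilon, R0_plus = up$R0, R0_minus = lo$R0,
       chi = chi, rho_minus = th_m, rho_plus = th_p)
}
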