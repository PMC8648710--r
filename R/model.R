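#' Mortality laws
#'
#' The per-patch mortality \eqn{M_k(v, a, t)} gives the death rate of age-`a`
#' individuals at time `t` when the local age-class density is `v` (pure
#' intra-cohort competition: only same-aged individuals on the same patch
#' compete). Three families are supported:
#' \describe{
#'   \item{`density_independent`}{\eqn{M_k = \mu_k(a,t)}; no regulation
#'     (\eqn{\gamma = 0}).}
#'   \item{`logistic`}{\eqn{M_k = \mu_k(a,t)(1 + v/L_k(a,t))} with regulatory
#'     function (carrying-capacity scale) \eqn{L_k}; satisfies the
#'     superlinearity condition with \eqn{\gamma = 1} and
#'     \eqn{p(a) = \inf_{t,k} \mu_k/L_k}.}
#'   \item{`power_law`}{\eqn{M_k = \mu_k(a,t) + p(a) v^\gamma} with
#'     \eqn{p(a) \ge \mu_\infty > 0}.}
#' }
#'
#' @param kind one of `"density_independent"`, `"logistic"`, `"power_law"`.
#' @param mu baseline mortality (units 1/time): numeric vector (constant per
#'   patch), a vectorised function of `(a, t)`, or a list of per-patch
#'   functions.
#' @param L regulatory function for the logistic law (same units as density).
#' @param p age function \eqn{p(a)} for the power law.
#' @param gamma competition exponent \eqn{\gamma \ge 0}.
#' @param mu_inf lower bound \eqn{\mu_\infty > 0} for `p` (power law).
#' @export
mortality_law <- function(kind = c("logistic", "density_independent", "power_law"),
                          mu, L = NULL, p = NULL, gamma = NULL, mu_inf = NULL) {
  kind <- match.arg(kind)
  if (is.null(gamma)) gamma <- switch(kind, density_independent = 0, logistic = 1, power_law = NULL)
  if (kind == "power_law") {
    if (is.null(p) || is.null(gamma)) stop("power_law needs p and gamma")
    if (is.null(mu_inf)) {
      mu_inf <- if (is.numeric(p)) min(p) else {
        aa <- seq(1e-6, 50, length.out = 257); min(vapply(aa, function(a) min(p(a, 0)), 0))
      }
    }
    if (mu_inf <= 0) stop("power_law requires p(a) >= mu_inf > 0")
  }
  if (kind == "logistic" && is.null(L)) stop("logistic law needs L")
  structure(list(kind = kind, mu = NULL, L = NULL, p = NULL,
                 gamma = gamma, mu_inf = mu_inf,
                 mu_raw = mu, L_raw = L, p_raw = p),
            class = "mortality_law")
}

#' Birth rates
#'
#' Per-patch fecundity \eqn{m_k(a, t)} (offspring per individual per unit
#' time), compactly supported in age: `m_k` vanishes outside
#' \eqn{[a_m, A_m] \subset (0, b_1)}.
#'
#' @param m numeric vector of box amplitudes (one per patch), a vectorised
#'   function of `(a, t)`, or a list of per-patch functions (e.g. built with
#'   [rate_box()] / [rate_bump()]).
#' @param support for numeric `m`: either `c(lo, hi)` shared by all patches or
#'   an `N x 2` matrix of per-patch supports. For functional `m` the overall
#'   support `c(a_m, A_m)` must be given here.
#' @param ramp edge mollification width for box rates (default 0: exact box).
#' @export
birth_rate <- function(m, support, ramp = 0) {
  if (is.numeric(m)) {
    N <- length(m)
    S <- if (is.matrix(support)) support else matrix(rep(support, each = N), N, 2)
    stopifnot(nrow(S) == N, all(S[, 1] < S[, 2]), all(S[, 1] > 0))
    fns <- lapply(seq_len(N), function(k) rate_box(m[k], S[k, 1], S[k, 2], ramp))
    out <- list(m_raw = fns, support = S,
                a_m = min(S[, 1]) - ramp * (ramp > 0),
                A_m = max(S[, 2]) + ramp * (ramp > 0),
                amp = m, ramp = ramp)
  } else {
    stopifnot(length(support) == 2, support[1] > 0, support[1] < support[2])
    out <- list(m_raw = m, support = NULL, a_m = support[1], A_m = support[2],
                amp = NULL, ramp = 0)
  }
  structure(out, class = "birth_rate")
}

#' Dispersal fields
#'
#' The dispersal matrix \eqn{D(a, t)}: entry \eqn{D_{kj}} (\eqn{k \ne j}) is
#' the rate at which age-`a` individuals move from patch `j` *into* patch `k`;
#' the diagonal \eqn{D_{kk} \le 0} collects emigration and migration-related
#' mortality. `D` must be Metzler (nonnegative off-diagonal).
#'
#' @param D constant `N x N` matrix, or a function `(a, t)` returning an
#'   `N x N` matrix (set `vectorized = TRUE` if it accepts vectors and returns
#'   an `N x N x K` array).
#' @param N patch count (required for functional `D`).
#' @param vectorized whether a functional `D` is vectorised over `(a, t)`.
#' @export
dispersal_field <- function(D, N = NULL, vectorized = FALSE) {
  if (is.matrix(D) && is.numeric(D)) {
    stopifnot(nrow(D) == ncol(D))
    structure(list(constant = D, fn = NULL, N = nrow(D), vectorized = TRUE),
              class = "dispersal_field")
  } else if (is.function(D)) {
    if (is.null(N)) stop("N required for a functional dispersal field")
    structure(list(constant = NULL, fn = D, N = N, vectorized = vectorized),
              class = "dispersal_field")
  } else stop("D must be a numeric matrix or a function")
}

#' Multi-patch age-structured population model
#'
#' Bundles the full specification of one model instance: patch count `N`,
#' maximal life span `b` (constant in time), mortality law, birth rates,
#' dispersal field, and initial age distribution `f`. The population density
#' \eqn{n_k(a,t)} obeys the balance (transport) equations
#' \deqn{\partial_t n + \partial_a n = -M(n,a,t)\,n + D(a,t)\,n}
#' with birth law \eqn{n(0,t) = \int m(a,t)\, n(a,t)\, da} and initial age
#' distribution \eqn{n(a,0) = f(a)}.
#'
#' @param N number of patches (\eqn{\ge 1}).
#' @param b maximal life span (time units).
#' @param mortality a [mortality_law()].
#' @param birth a [birth_rate()]; its support must satisfy
#'   \eqn{0 < a_m < A_m < b_1 \le b}.
#' @param dispersal a [dispersal_field()], a numeric matrix, or `NULL` for
#'   isolated patches.
#' @param f initial age distribution: numeric amplitudes with `f_support`, a
#'   vectorised function of age, or `NULL` (empty habitat). Must be continuous
#'   with support inside `[0, b)`.
#' @param f_support support interval for numeric `f`.
#' @param b1 constant with `A_m < b1 <= b` (defaults to midway between `A_m`
#'   and `b`).
#' @param time_dependence `"constant"`, `"periodic"` or `"general"`.
#' @param period period `T` when `time_dependence = "periodic"`.
#' @return an object of class `"patch_model"`.
#' @seealso [validate_hypotheses()], [stationary_analysis()],
#'   [solve_newborns()], [make_scenario()]
#' @export
patch_model <- function(N, b, mortality, birth, dispersal = NULL,
                        f = NULL, f_support = NULL, b1 = NULL,
                        time_dependence = c("constant", "periodic", "general"),
                        period = NULL) {
  time_dependence <- match.arg(time_dependence)
  stopifnot(N >= 1, b > 0)
  if (!inherits(mortality, "mortality_law")) stop("mortality must be a mortality_law")
  if (!inherits(birth, "birth_rate")) stop("birth must be a birth_rate")
  if (is.matrix(dispersal)) dispersal <- dispersal_field(dispersal)
  if (!is.null(dispersal) && dispersal$N != N) stop("dispersal dimension != N")
  if (is.null(b1)) b1 <- (birth$A_m + b) / 2
  if (!(birth$A_m < b1 && b1 <= b)) stop("need A_m < b1 <= b")
  if (time_dependence == "periodic" && is.null(period)) stop("periodic model needs a period")

  law <- mortality
  law$mu <- .as_prate(law$mu_raw, N, "mu")
  law$L <- .as_prate(law$L_raw, N, "L")
  law$p <- .as_prate(law$p_raw, N, "p")

  bb <- birth
  bb$m <- .as_prate(bb$m_raw, N, "m")

  if (is.numeric(f)) {
    if (is.null(f_support)) stop("numeric f needs f_support")
    amp <- rep_len(f, N)
    f_fn <- .as_prate(lapply(seq_len(N), function(k)
      rate_box(amp[k], max(f_support[1], 1e-9), f_support[2])), N, "f")
  } else if (is.function(f)) {
    f_fn <- .as_prate(function(a, t) f(a), N, "f")
  } else f_fn <- NULL

  structure(list(N = N, b = b, b1 = b1, mortality = law, birth = bb,
                 dispersal = dispersal, f = f_fn, f_raw = f,
                 f_support = f_support,
                 time_dependence = time_dependence, period = period),
            class = "patch_model")
}

# ---- evaluation helpers -------------------------------------------------

.ev_mu <- function(model, a, t) .ev_prate(model$mortality$mu, model$N, a, t)
.ev_m  <- function(model, a, t) .ev_prate(model$birth$m, model$N, a, t)
.ev_f  <- function(model, a) {
  K <- length(a)
  if (is.null(model$f)) return(matrix(0, model$N, K))
  out <- .ev_prate(model$f, model$N, a, a * 0)
  out[, a >= model$b | a < 0] <- 0  # supp f in [0, b)
  out
}

# M(V, a, t): V is N x K
.ev_M <- function(model, V, a, t) {
  law <- model$mortality
  mu <- .ev_mu(model, a, t)
  switch(law$kind,
    density_independent = mu,
    logistic = mu * (1 + pmax(V, 0) / .ev_prate(law$L, model$N, a, t)),
    power_law = mu + .ev_prate(law$p, model$N, a, t) * pmax(V, 0)^law$gamma)
}

# dispersal applied to state H (N x K) at ages a, times t
.apply_D <- function(model, H, a, t) {
  dsp <- model$dispersal
  if (is.null(dsp)) return(0 * H)
  if (!is.null(dsp$constant)) return(dsp$constant %*% H)
  K <- max(length(a), length(t))
  a <- rep_len(a, K); t <- rep_len(t, K)
  out <- 0 * H
  if (dsp$vectorized) {
    Darr <- dsp$fn(a, t)
    for (k in seq_len(model$N)) for (l in seq_len(model$N))
      out[k, ] <- out[k, ] + Darr[k, l, ] * H[l, ]
  } else {
    for (j in seq_len(K)) out[, j] <- dsp$fn(a[j], t[j]) %*% H[, j]
  }
  out
}

# D as matrix at a single (a, t)
.D_at <- function(model, a, t) {
  dsp <- model$dispersal
  if (is.null(dsp)) return(matrix(0, model$N, model$N))
  if (!is.null(dsp$constant)) return(dsp$constant)
  if (dsp$vectorized) {
    arr <- dsp$fn(a, t)
    if (length(dim(arr)) == 3) arr[, , 1] else arr
  } else dsp$fn(a, t)
}

# sup-norm ||D|| = sup max |entry|
.D_norm <- function(model, n_a = 33, n_t = 9) {
  dsp <- model$dispersal
  if (is.null(dsp)) return(0)
  if (!is.null(dsp$constant)) return(max(abs(dsp$constant)))
  tmax <- if (!is.null(model$period)) model$period else model$b
  mx <- 0
  for (a in seq(0, model$b, length.out = n_a))
    for (t in seq(0, tmax, length.out = n_t))
      mx <- max(mx, max(abs(.D_at(model, a, t))))
  mx
}

.m_sup <- function(model) {
  if (!is.null(model$birth$amp)) return(max(model$birth$amp))
  tmax <- if (!is.null(model$period)) model$period else model$b
  ages <- seq(model$birth$a_m, model$birth$A_m, length.out = 129)
  .prate_sup(model$birth$m, model$N, ages, seq(0, tmax, length.out = 17))
}

.check_constant <- function(model, what = "this analysis") {
  if (model$time_dependence != "constant")
    stop("time-dependent model: ", what, " requires a constant environment", call. = FALSE)
}

#' @export
print.patch_model <- function(x, ...) {
  cat("Multi-patch age-structured population model\n")
  cat(sprintf("  patches N = %d, life span b = %g (b1 = %g)\n", x$N, x$b, x$b1))
  cat(sprintf("  mortality: %s (gamma = %s)\n", x$mortality$kind,
              format(x$mortality$gamma)))
  cat(sprintf("  fertile ages: [%g, %g]\n", x$birth$a_m, x$birth$A_m))
  cat(sprintf("  dispersal: %s\n",
              if (is.null(x$dispersal)) "none (isolated patches)"
              else if (!is.null(x$dispersal$constant)) "constant matrix" else "age/time dependent"))
  cat(sprintf("  environment: %s%s\n", x$time_dependence,
              if (!is.null(x$period)) sprintf(" (T = %g)", x$period) else ""))
  invisible(x)
}

#' @export
summary.patch_model <- function(object, ...) {
  print(object)
  rep <- try(validate_hypotheses(object), silent = TRUE)
  if (!inherits(rep, "try-error")) print(rep)
  invisible(object)
}

#' Simulate the population dynamics of a patch model
#'
#' Runs the renewal solver ([solve_newborns()]) and reconstructs the full age
#' density and total population ([reconstruct_density()]). The model is
#' deterministic; `nsim` and `seed` are accepted for compatibility with the
#' generic and ignored beyond seeding.
#'
#' @param object a [patch_model()].
#' @param nsim ignored (deterministic dynamics).
#' @param seed optional RNG seed (unused by the deterministic solver).
#' @param horizon time horizon.
#' @param ... passed to [solve_newborns()].
#' @return a `population_field` (invisibly also carries the newborn
#'   trajectory as attribute `"newborns"`).
#' @export
simulate.patch_model <- function(object, nsim = 1, seed = NULL, horizon, ...) {
  if (!is.null(seed)) set.seed(seed)
  traj <- solve_newborns(object, horizon = horizon, ...)
  out <- reconstruct_density(object, traj)
  attr(out, "newborns") <- traj
  out
}
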