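#' A-priori two-sided estimates for R0 and the maximal solution
#'
#' Under the no-birth-in-transit condition (nonpositive column sums of the
#' dispersal matrix: migrants may die but do not reproduce en route), the
#' basic reproduction number is sandwiched:
#' \deqn{\max_k \int_0^\infty m_k(a) e^{-\int_0^a (\mu_k + |D_{kk}|)}\, da
#'   \;\le\; R_0 \;\le\; \int_0^\infty m(a) e^{-\int_0^a \mu}\, da,}
#' with \eqn{m(a) = \max_k m_k(a)} and \eqn{\mu(a) = \min_k \mu_k(a)}. Both
#' bounds are attained in the decoupled case. Companion scalar bounds
#' \eqn{\theta_+} ([theta_plus()]) and \eqn{\theta^-_k} ([theta_minus()])
#' bracket the maximal newborn vector.
#'
#' @name bounds
NULL

# exponent integral int_0^a g(s) ds at each of the (increasing) ages `at`,
# by per-interval Gauss-Legendre; g is a vectorised scalar function
.cumint_at <- function(g, at, n_inner = 24) {
  prev_a <- 0; prev_v <- 0
  out <- numeric(length(at))
  for (i in seq_along(at)) {
    gl <- .gl(n_inner, prev_a, at[i])
    prev_v <- prev_v + sum(gl$w * g(gl$x))
    out[i] <- prev_v
    prev_a <- at[i]
  }
  out
}

.Dkk_abs <- function(model, k) {
  function(s) vapply(s, function(si) abs(.D_at(model, si, 0)[k, k]), 0)
}

# per-patch fertile interval (falls back to the overall one)
.patch_support <- function(model, k) {
  S <- model$birth$support
  if (is.null(S)) c(model$birth$a_m, model$birth$A_m) else S[k, ]
}

#' @rdname bounds
#' @param model a constant-environment [patch_model()].
#' @param n_nodes Gauss-Legendre nodes per integral.
#' @return `r0_bounds()`: object with `lower`, `upper`, `lower_per_patch`,
#'   and `applicable` (whether the column-sum condition holds).
#' @export
r0_bounds <- function(model, n_nodes = 48) {
  .check_constant(model, "R0 bounds")
  N <- model$N
  applicable <- TRUE
  for (a in seq(0, model$b, length.out = 17)) {
    D <- .D_at(model, a, 0)
    if (any(colSums(D) > 1e-10)) { applicable <- FALSE; break }
  }
  lower_k <- numeric(N)
  for (k in seq_len(N)) {
    sp <- .patch_support(model, k)
    gl <- .gl(n_nodes, sp[1], sp[2])
    gk <- function(s) .ev_mu(model, s, rep(0, length(s)))[k, ] + .Dkk_abs(model, k)(s)
    S <- exp(-.cumint_at(gk, gl$x))
    mk <- .ev_m(model, gl$x, rep(0, n_nodes))[k, ]
    lower_k[k] <- sum(gl$w * mk * S)
  }
  gl <- .birth_gl(model, n_nodes)
  mmax <- apply(.ev_m(model, gl$x, rep(0, length(gl$x))), 2, max)
  gmin <- function(s) apply(.ev_mu(model, s, rep(0, length(s))), 2, min)
  Smax <- exp(-.cumint_at(gmin, gl$x))
  upper <- sum(gl$w * mmax * Smax)
  structure(list(lower = max(lower_k), lower_per_patch = lower_k,
                 upper = upper, applicable = applicable),
            class = "r0_bounds")
}

#' @export
print.r0_bounds <- function(x, ...) {
  cat(sprintf("R0 bounds: %.6g <= R0 <= %.6g%s\n", x$lower, x$upper,
              if (!x$applicable) "  [NOT applicable: column-sum condition fails]" else ""))
  invisible(x)
}

# monotone-decreasing root: I(t) = 1 on a log bracket
.bisect_decreasing <- function(I, lo = 1e-12, hi = 1e12, rel = 1e-10) {
  if (I(lo) <= 1) return(NA_real_)
  if (I(hi) >= 1) stop("upper bracket too small for the bound equation")
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (I(mid) > 1) lo <- mid else hi <- mid
    if (hi / lo - 1 < rel) break
  }
  sqrt(lo * hi)
}

#' @rdname bounds
#' @param R0 optionally, a precomputed basic reproduction number.
#' @param exponent which exponent convention to use inside `P(a)`:
#'   `"displayed"` uses \eqn{e^{-\int \mu}}, `"derivation"` uses
#'   \eqn{e^{-\gamma\int\mu}} (they coincide for \eqn{\gamma = 1}).
#' @return `theta_plus()`: the scalar upper bound \eqn{\theta_+} satisfying
#'   \eqn{\sum_k \theta_k \le \theta_+}, or `NA` when \eqn{R_0 \le 1}.
#' @export
theta_plus <- function(model, R0 = NULL, n_nodes = 48,
                       exponent = c("displayed", "derivation")) {
  .check_constant(model, "the theta_+ bound")
  exponent <- match.arg(exponent)
  if (is.null(R0)) R0 <- basic_reproduction_number(model, n_nodes)$R0
  if (R0 <= 1) return(NA_real_)
  g <- model$mortality$gamma
  if (g <= 0) stop("theta_+ requires gamma > 0")
  N <- model$N
  gl <- .birth_gl(model, n_nodes)
  gmin <- function(s) apply(.ev_mu(model, s, rep(0, length(s))), 2, min)
  cum_mu <- .cumint_at(gmin, gl$x)
  S <- exp(-cum_mu)
  mmax <- apply(.ev_m(model, gl$x, rep(0, length(gl$x))), 2, max)
  gam_in <- if (exponent == "displayed") 1 else g
  P_int <- function(a) {
    gli <- .gl(n_nodes, 0, a)
    p <- .p_of_a(model, gli$x)
    cm <- .cumint_at(gmin, gli$x)
    (g / N^g) * sum(gli$w * p * exp(-gam_in * cm))
  }
  P <- vapply(gl$x, P_int, 0)
  I <- function(t) sum(gl$w * mmax * S / (1 + t^g * P)^(1 / g))
  if (I(0) <= 1)
    warning("I(0) <= 1 while R0 > 1: theta_+ consistency check failed")
  .bisect_decreasing(I)
}

#' @rdname bounds
#' @param q age function bounding the density response from above:
#'   \eqn{M_k(v,a) - M_k(0,a) \le q(a) v^\gamma} for all patches. Defaults to
#'   \eqn{\sup_k \mu_k(a)/L_k(a)} for logistic laws (exact there).
#' @return `theta_minus()`: per-patch lower bounds \eqn{\theta^-_k \le
#'   \theta_k}; `NA` for patches whose isolated-growth condition fails.
#' @export
theta_minus <- function(model, q = NULL, n_nodes = 48) {
  .check_constant(model, "the theta_- bound")
  g <- model$mortality$gamma
  if (is.null(g) || g <= 0) stop("theta_- requires gamma > 0")
  N <- model$N
  law <- model$mortality
  if (is.null(q)) {
    if (law$kind == "logistic") {
      q <- function(s) {
        mu <- .ev_mu(model, s, rep(0, length(s)))
        L <- .ev_prate(law$L, N, s, rep(0, length(s)))
        apply(mu / L, 2, max)
      }
    } else if (law$kind == "power_law") {
      q <- function(s) apply(.ev_prate(law$p, N, s, rep(0, length(s))), 2, max)
    } else stop("supply q for this mortality law")
  } else if (is.numeric(q)) {
    qv <- q; q <- function(s) rep(qv[1], length(s))
  }
  # sampled validity check of the upper density-response bound
  vss <- c(0.5, 1, 2, 5)
  ss <- seq(1e-3, model$b, length.out = 33)
  for (v in vss) {
    lhs <- .ev_M(model, matrix(v, N, length(ss)), ss, rep(0, length(ss))) -
           .ev_M(model, matrix(0, N, length(ss)), ss, rep(0, length(ss)))
    rhs <- matrix(q(ss) * v^g, N, length(ss), byrow = TRUE)
    if (any(lhs > rhs * (1 + 1e-8) + 1e-12))
      stop("q(a) violates the upper density-response bound at a sampled point")
  }
  out <- rep(NA_real_, N)
  for (k in seq_len(N)) {
    sp <- .patch_support(model, k)
    gl <- .gl(n_nodes, sp[1], sp[2])
    gk <- function(s) .ev_mu(model, s, rep(0, length(s)))[k, ] + .Dkk_abs(model, k)(s)
    S <- exp(-.cumint_at(gk, gl$x))
    mk <- .ev_m(model, gl$x, rep(0, n_nodes))[k, ]
    if (sum(gl$w * mk * S) <= 1) next      # isolated-growth condition fails
    Q_int <- function(a) {
      gli <- .gl(n_nodes, 0, a)
      cm <- .cumint_at(gk, gli$x)
      g * sum(gli$w * q(gli$x) * exp(-g * cm))
    }
    Q <- vapply(gl$x, Q_int, 0)
    I <- function(t) sum(gl$w * mk * S / (1 + t^g * Q)^(1 / g))
    out[k] <- .bisect_decreasing(I)
  }
  out
}
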