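#' Parametric rate-function families
#'
#' Vital rates in a [patch_model()] are nonnegative functions of age `a` and
#' time `t`, one per patch. Internally every rate is normalised to a *prate*:
#' a closure `f(a, t)` taking equal-length vectors and returning an
#' `N x length(a)` matrix. The constructors below build the standard families
#' used by the scenario generator: constants, boxes on an interval (optionally
#' mollified at the edges), smooth bumps, and tabulated periodic rates.
#'
#' @param amp nonnegative amplitude (scalar).
#' @param lo,hi support interval, `0 < lo < hi`.
#' @param ramp mollification width at each edge of a box (same units as age);
#'   `0` gives an exact indicator, a positive value a trapezoidal ramp.
#' @return a vectorised function of `(a, t)`.
#' @name rate_families
NULL

#' @rdname rate_families
#' @export
rate_box <- function(amp, lo, hi, ramp = 0) {
  stopifnot(amp >= 0, lo < hi, ramp >= 0, ramp <= (hi - lo) / 2)
  f <- function(a, t = 0) {
    if (ramp <= 0) return(amp * as.numeric(a >= lo & a <= hi))
    up <- pmin(pmax((a - lo) / ramp + 1, 0), 1)  # ramp on [lo - ramp, lo]
    dn <- pmin(pmax((hi - a) / ramp + 1, 0), 1)  # ramp on [hi, hi + ramp]
    amp * up * dn * as.numeric(a >= lo - ramp & a <= hi + ramp)
  }
  attr(f, "support") <- c(lo - ramp * (ramp > 0), hi + ramp * (ramp > 0))
  attr(f, "sup_norm") <- amp
  f
}

#' @rdname rate_families
#' @export
rate_bump <- function(amp, lo, hi) {
  stopifnot(amp >= 0, lo < hi)
  f <- function(a, t = 0) {
    u <- (2 * a - lo - hi) / (hi - lo)
    v <- numeric(length(a))
    inside <- abs(u) < 1
    v[inside] <- amp * exp(1 - 1 / (1 - u[inside]^2))
    v
  }
  attr(f, "support") <- c(lo, hi)
  attr(f, "sup_norm") <- amp
  f
}

#' @rdname rate_families
#' @param ages,phases grids on which `values` is tabulated; `phases` spans one
#'   period `[0, period)`.
#' @param period period of the tabulated rate.
#' @param values matrix `length(ages) x length(phases)` of rate values.
#' @export
rate_table <- function(ages, phases, period, values) {
  stopifnot(is.matrix(values), nrow(values) == length(ages),
            ncol(values) == length(phases), period > 0)
  na <- length(ages); np <- length(phases)
  f <- function(a, t = 0) {
    K <- max(length(a), length(t))
    a <- rep_len(a, K); t <- rep_len(t, K)
    ia <- findInterval(a, ages, all.inside = TRUE)
    wa <- (a - ages[ia]) / (ages[ia + 1] - ages[ia])
    wa <- pmin(pmax(wa, 0), 1)
    ph <- (t %% period)
    dph <- period / np
    ip <- pmin(floor(ph / dph) + 1, np)
    wp <- ph / dph - (ip - 1)
    ip2 <- ifelse(ip == np, 1L, ip + 1L)
    v00 <- values[cbind(ia, ip)];     v10 <- values[cbind(ia + 1, ip)]
    v01 <- values[cbind(ia, ip2)];    v11 <- values[cbind(ia + 1, ip2)]
    (1 - wa) * ((1 - wp) * v00 + wp * v01) + wa * ((1 - wp) * v10 + wp * v11)
  }
  attr(f, "sup_norm") <- max(values)
  attr(f, "period") <- period
  f
}

# ---- internal normalisation to per-patch rates --------------------------

# A prate is list(fn = function(a,t)->NxK, const = numeric N or NULL, sup = ...)
.as_prate <- function(x, N, what = "rate") {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) {
    v <- rep_len(as.numeric(x), N)
    return(list(fn = NULL, const = v, sup = max(abs(v))))
  }
  if (is.function(x)) {
    fn <- function(a, t) {
      K <- max(length(a), length(t))
      a <- rep_len(a, K); t <- rep_len(t, K)
      res <- x(a, t)
      if (is.matrix(res)) {
        if (nrow(res) != N) stop("rate function returned wrong number of rows for ", what)
        res
      } else if (length(res) == K) {
        matrix(rep(res, each = N), N, K)
      } else stop("rate function for ", what, " must return a length-K vector or N x K matrix")
    }
    return(list(fn = fn, const = NULL, sup = attr(x, "sup_norm")))
  }
  if (is.list(x)) {
    if (length(x) != N) stop(what, ": need one function per patch")
    fns <- lapply(x, function(g) if (is.function(g)) g else function(a, t) rep_len(g, length(a)))
    fn <- function(a, t) {
      K <- max(length(a), length(t))
      a <- rep_len(a, K); t <- rep_len(t, K)
      do.call(rbind, lapply(fns, function(g) {
        r <- g(a, t)
        rep_len(r, K)
      }))
    }
    sups <- vapply(x, function(g) {
      s <- if (is.function(g)) attr(g, "sup_norm") else abs(g)
      if (is.null(s)) NA_real_ else s
    }, 0)
    return(list(fn = fn, const = NULL, sup = if (anyNA(sups)) NULL else max(sups)))
  }
  stop("cannot interpret ", what)
}

.ev_prate <- function(p, N, a, t) {
  K <- max(length(a), length(t))
  if (!is.null(p$const)) return(matrix(p$const, N, K))
  p$fn(a, t)
}

# sup-norm of a prate, sampled if no closed form is available
.prate_sup <- function(p, N, ages, times) {
  if (is.null(p)) return(0)
  if (!is.null(p$const)) return(max(abs(p$const)))
  if (!is.null(p$sup)) return(p$sup)
  g <- expand.grid(a = ages, t = times)
  max(abs(.ev_prate(p, N, g$a, g$t)))
}
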