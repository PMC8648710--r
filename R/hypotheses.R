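#' Graph accessibility of a patch through the dispersal network
#'
#' Patch `k` is *accessible* at age `a` (and time `t`) if, in the digraph
#' associated with the dispersal matrix `D(a, t)` (an arc leads from `i` to
#' `j`, `i != j`, iff `D[i, j] > 0`), every other patch is reachable from `k`.
#' Reachability is computed by breadth-first search on the sign pattern.
#'
#' @param model a [patch_model()].
#' @param k patch index.
#' @param a age at which to evaluate the dispersal matrix.
#' @param t time at which to evaluate the dispersal matrix.
#' @return `TRUE` iff every patch `j != k` is reachable from `k`.
#' @export
accessibility <- function(model, k, a = 0, t = 0) {
  N <- model$N
  if (N == 1) return(TRUE)
  D <- .D_at(model, a, t)
  if (any(!is.finite(D))) stop("non-finite dispersal matrix at (a, t) = (", a, ", ", t, ")")
  adj <- D > 0
  diag(adj) <- FALSE
  seen <- rep(FALSE, N); seen[k] <- TRUE
  frontier <- k
  while (length(frontier)) {
    nxt <- integer(0)
    for (i in frontier) {
      new <- which(adj[i, ] & !seen)
      seen[new] <- TRUE
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  all(seen)
}

#' Universal-majorant constants
#'
#' For a superlinear mortality response (\eqn{\gamma > 0}) every cohort
#' solution is bounded by \eqn{\omega_1 a^{-1/\gamma}} regardless of its
#' initial size, with
#' \deqn{\omega_1 = \left(\frac{1 + N\|D\| b}{\gamma \mu_\infty}\right)^{1/\gamma},
#'       \qquad \omega_2 = \omega_1 \|m\|_\infty \int_{a_m}^{A_m} a^{-1/\gamma}\, da.}
#' \eqn{\omega_2} bounds the image of every birth operator in the package.
#'
#' @param model a [patch_model()] with \eqn{\gamma > 0}.
#' @return list with `omega1`, `omega2` and the ingredients
#'   (`gamma`, `mu_inf`, `D_norm`, `m_sup`).
#' @export
omega_constants <- function(model) {
  g <- model$mortality$gamma
  if (is.null(g) || g <= 0)
    stop("omega constants are only defined for gamma > 0 (density-dependent mortality)")
  mu_inf <- .mu_inf(model)
  Dn <- .D_norm(model)
  msup <- .m_sup(model)
  omega1 <- ((1 + model$N * Dn * model$b) / (g * mu_inf))^(1 / g)
  am <- model$birth$a_m; Am <- model$birth$A_m
  J <- if (abs(g - 1) < 1e-12) log(Am / am)
       else (Am^(1 - 1 / g) - am^(1 - 1 / g)) / (1 - 1 / g)
  list(omega1 = omega1, omega2 = omega1 * msup * J,
       gamma = g, mu_inf = mu_inf, D_norm = Dn, m_sup = msup)
}

# effective (p(a), mu_inf) for the superlinearity condition
.p_of_a <- function(model, a, n_t = 9) {
  law <- model$mortality
  tmax <- if (!is.null(model$period)) model$period else model$b
  tt <- seq(0, tmax, length.out = n_t)
  switch(law$kind,
    power_law = apply(.ev_prate(law$p, model$N, a, a * 0), 2, min),
    logistic = {
      # p(a) = inf over t and k of mu_k(a,t) / L_k(a,t)
      vapply(a, function(ai) {
        min(vapply(tt, function(ti) {
          min(.ev_mu(model, ai, ti) / .ev_prate(law$L, model$N, ai, ti))
        }, 0))
      }, 0)
    },
    density_independent = rep(0, length(a)))
}

.mu_inf <- function(model, n_a = 65) {
  law <- model$mortality
  if (law$kind == "power_law") return(law$mu_inf)
  if (law$kind == "density_independent") return(0)
  aa <- seq(1e-6, model$b, length.out = n_a)
  min(.p_of_a(model, aa))
}

#' Numerically validate the structure hypotheses of a patch model
#'
#' Checks, by sampling on age/time/density grids, the structural hypotheses
#' under which the theory of this package applies:
#' \describe{
#'  \item{H1}{constant maximal life span `b` (holds by construction here).}
#'  \item{H2}{mortality nonnegative, nondecreasing in density, and
#'    superlinear: \eqn{M_k(v,a,t) - M_k(0,a,t) \ge p(a) v^\gamma} with
#'    \eqn{p(a) \ge \mu_\infty > 0} (for \eqn{\gamma > 0}).}
#'  \item{H3}{dispersal Metzler (nonnegative off-diagonal) with finite
#'    sup-norm.}
#'  \item{H4}{fecundity compactly supported: \eqn{supp\, m \subset [a_m, A_m]}
#'    with \eqn{0 < a_m < A_m < b_1}.}
#'  \item{H5}{initial distribution continuous with support in `[0, b)`.}
#'  \item{H6}{every patch `k` is accessible at some age \eqn{\beta_k}
#'    strictly before its maximal fertility age.}
#' }
#' A sampled check is evidence, not a proof; failures name the violating
#' sample point.
#'
#' @param model a [patch_model()].
#' @param v_samples density ladder on which monotonicity/superlinearity of the
#'   mortality is probed.
#' @param n_ages,n_times grid sizes.
#' @return an object of class `"hypothesis_report"`.
#' @export
validate_hypotheses <- function(model, v_samples = NULL,
                                n_ages = 64, n_times = 16) {
  N <- model$N
  law <- model$mortality
  g <- law$gamma
  if (is.null(v_samples)) {
    vtop <- 5
    om <- try(suppressWarnings(omega_constants(model)), silent = TRUE)
    if (!inherits(om, "try-error")) vtop <- max(5, om$omega2)
    v_samples <- c(0, 0.5, 1, 2, 5, vtop)
  }
  v_samples <- sort(unique(v_samples))
  ages <- seq(0, model$b, length.out = n_ages)
  tmax <- if (!is.null(model$period)) model$period else model$b
  times <- seq(0, tmax, length.out = n_times)
  msg <- character(0)
  pass <- c(H1 = TRUE, H2 = TRUE, H3 = TRUE, H4 = TRUE, H5 = TRUE, H6 = TRUE)

  # H2: nonnegativity, monotonicity in v, superlinearity
  p_grid <- .p_of_a(model, ages)
  mu_inf <- if (g > 0) max(min(p_grid), 0) else 0
  for (ti in times) {
    prev <- NULL
    for (v in v_samples) {
      V <- matrix(v, N, length(ages))
      M <- .ev_M(model, V, ages, rep(ti, length(ages)))
      if (any(!is.finite(M))) {
        pass["H2"] <- FALSE
        bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
        stop(sprintf("non-finite mortality at patch %d, a = %.4g, t = %.4g, v = %.4g",
                     bad[1], ages[bad[2]], ti, v))
      }
      if (any(M < -1e-12)) {
        pass["H2"] <- FALSE
        msg <- c(msg, sprintf("H2: negative mortality at t = %.4g, v = %.4g", ti, v))
      }
      if (!is.null(prev) && any(M < prev - 1e-10)) {
        pass["H2"] <- FALSE
        bad <- which(M < prev - 1e-10, arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("H2: mortality decreasing in v at patch %d, a = %.4g, t = %.4g",
                              bad[1], ages[bad[2]], ti))
      }
      if (g > 0 && v > 0) {
        M0 <- .ev_M(model, matrix(0, N, length(ages)), ages, rep(ti, length(ages)))
        lhs <- M - M0
        rhs <- matrix(p_grid * v^g, N, length(ages), byrow = TRUE)
        if (any(lhs < rhs - 1e-8 * (1 + rhs))) {
          pass["H2"] <- FALSE
          bad <- which(lhs < rhs - 1e-8 * (1 + rhs), arr.ind = TRUE)[1, ]
          msg <- c(msg, sprintf("H2: superlinearity fails at patch %d, a = %.4g, t = %.4g, v = %.4g",
                                bad[1], ages[bad[2]], ti, v))
        }
      }
      prev <- M
    }
  }
  if (g > 0 && mu_inf <= 0) {
    pass["H2"] <- FALSE
    msg <- c(msg, "H2: inf_a p(a) is not positive")
  }

  # H3: Metzler + finite
  if (!is.null(model$dispersal)) {
    for (ti in times) for (ai in ages[seq(1, n_ages, by = 4)]) {
      D <- .D_at(model, ai, ti)
      if (any(!is.finite(D))) stop(sprintf("non-finite dispersal at a = %.4g, t = %.4g", ai, ti))
      off <- D; diag(off) <- 0
      if (any(off < -1e-12)) {
        pass["H3"] <- FALSE
        bad <- which(off < -1e-12, arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("H3: negative off-diagonal D[%d,%d] = %.4g at a = %.4g, t = %.4g",
                              bad[1], bad[2], D[bad[1], bad[2]], ai, ti))
      }
    }
  }

  # H4: support of m inside [a_m, A_m] with 0 < a_m < A_m < b1
  am <- model$birth$a_m; Am <- model$birth$A_m
  if (!(am > 0 && am < Am && Am < model$b1)) {
    pass["H4"] <- FALSE
    msg <- c(msg, sprintf("H4: need 0 < a_m (%.4g) < A_m (%.4g) < b1 (%.4g)", am, Am, model$b1))
  }
  out_ages <- c(seq(0, am * (1 - 1e-9), length.out = 9),
                seq(min(Am * (1 + 1e-9), model$b), model$b, length.out = 9))
  for (ti in times) {
    mo <- .ev_m(model, out_ages, rep(ti, length(out_ages)))
    if (any(abs(mo) > 1e-12)) {
      pass["H4"] <- FALSE
      bad <- which(abs(mo) > 1e-12, arr.ind = TRUE)[1, ]
      msg <- c(msg, sprintf("H4: m_%d(a = %.4g, t = %.4g) = %.4g outside [a_m, A_m]",
                            bad[1], out_ages[bad[2]], ti, mo[bad[1], bad[2]]))
    }
  }

  # H5: f finite, nonnegative, supported in [0, b)
  fv <- .ev_f(model, ages)
  if (any(!is.finite(fv)) || any(fv < -1e-12)) {
    pass["H5"] <- FALSE
    msg <- c(msg, "H5: initial distribution not finite/nonnegative on the grid")
  }
  if (any(.ev_f(model, model$b * (1 - 1e-12)) > 1e-8) && !is.null(model$f_support) &&
      model$f_support[2] >= model$b) {
    pass["H5"] <- FALSE
    msg <- c(msg, "H5: supp f reaches b")
  }

  # H6: accessibility before the maximal fertility age
  abar <- .max_fertility_age(model, ages, times)
  beta <- rep(NA_real_, N)
  for (k in seq_len(N)) {
    cand <- ages[ages < abar[k] & ages > 0]
    for (ai in cand) {
      ok <- all(vapply(times, function(ti) accessibility(model, k, ai, ti), TRUE))
      if (ok) { beta[k] <- ai; break }
    }
    if (is.na(beta[k])) {
      pass["H6"] <- FALSE
      msg <- c(msg, sprintf("H6: patch %d not accessible before its maximal fertility age %.4g",
                            k, abar[k]))
    }
  }

  structure(list(pass = pass, beta = beta, max_fertility_age = abar,
                 p_of_a = data.frame(a = ages, p = p_grid),
                 mu_inf = if (g > 0) mu_inf else NA_real_,
                 gamma = g, messages = msg, sampled = TRUE),
            class = "hypothesis_report")
}

# per-patch maximal fertility age (sup of supp m_k, inf over t)
.max_fertility_age <- function(model, ages, times) {
  N <- model$N
  if (!is.null(model$birth$support)) return(model$birth$support[, 2])
  sup_a <- rep(0, N)
  for (k in seq_len(N)) {
    mins <- rep(Inf, 1)
    per_t <- vapply(times, function(ti) {
      mv <- .ev_m(model, ages, rep(ti, length(ages)))[k, ]
      if (all(mv <= 1e-14)) 0 else max(ages[mv > 1e-14])
    }, 0)
    sup_a[k] <- min(per_t)
  }
  sup_a
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("Structure-hypothesis report (sampled checks)\n")
  for (h in names(x$pass))
    cat(sprintf("  %s: %s\n", h, if (x$pass[[h]]) "pass (sampled)" else "FAIL"))
  if (all(is.finite(x$beta)))
    cat("  accessible ages beta_k:", paste(signif(x$beta, 4), collapse = ", "), "\n")
  if (length(x$messages)) {
    cat("  diagnostics:\n")
    for (m in unique(x$messages)) cat("   -", m, "\n")
  }
  invisible(x)
}

#' Serialise a hypothesis report to JSON
#'
#' @param x a `"hypothesis_report"`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
hypothesis_report_json <- function(x, path = NULL) {
  obj <- list(pass = as.list(x$pass), beta = x$beta,
              max_fertility_age = x$max_fertility_age,
              mu_inf = x$mu_inf, gamma = x$gamma,
              messages = x$messages, sampled = x$sampled)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
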