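#' Structured model configuration files
#'
#' A model can be described in a small YAML file, either through a scenario
#' stanza,
#' \preformatted{
#' scenario:
#'   family: single_patch_logistic
#'   seed: 1
#'   params: {mu0: 0.5, m0: 30}
#' }
#' or explicitly:
#' \preformatted{
#' N: 2
#' b: 3
#' b1: 2.5
#' mortality: {kind: logistic, mu: [0.5, 0.8], L: [1, 1]}
#' birth: {amplitude: [12, 5], support: [1, 2]}   # or support per patch (list of pairs)
#' dispersal: {matrix: [[-0.01, 0.01], [0.01, -0.01]]}
#' f: {amplitude: [1, 1], support: [0, 0.5]}
#' }
#' Rate functions beyond constants and boxes (smooth bumps, tables) are
#' available programmatically.
#'
#' @param path YAML file path.
#' @return `read_model_config()`: a [patch_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    return(do.call(make_scenario,
                   c(list(family = sc$family, seed = if (is.null(sc$seed)) 1L else sc$seed),
                     sc$params)))
  }
  mo <- cfg$mortality
  law <- mortality_law(mo$kind,
                       mu = unlist(mo$mu),
                       L = if (!is.null(mo$L)) unlist(mo$L) else NULL,
                       p = if (!is.null(mo$p)) unlist(mo$p) else NULL,
                       gamma = mo$gamma, mu_inf = mo$mu_inf)
  bi <- cfg$birth
  sup <- bi$support
  sup <- if (is.list(sup)) do.call(rbind, lapply(sup, unlist)) else unlist(sup)
  br <- birth_rate(unlist(bi$amplitude), sup,
                   ramp = if (is.null(bi$ramp)) 0 else bi$ramp)
  disp <- if (!is.null(cfg$dispersal))
    dispersal_field(do.call(rbind, lapply(cfg$dispersal$matrix, unlist))) else NULL
  f_amp <- if (!is.null(cfg$f)) unlist(cfg$f$amplitude) else NULL
  f_sup <- if (!is.null(cfg$f)) unlist(cfg$f$support) else NULL
  patch_model(cfg$N, cfg$b, law, br, dispersal = disp,
              f = f_amp, f_support = f_sup, b1 = cfg$b1,
              time_dependence = if (is.null(cfg$time_dependence)) "constant"
                                else cfg$time_dependence,
              period = cfg$period)
}

#' @rdname read_model_config
#' @param family,params,seed scenario description to store.
#' @export
write_scenario_config <- function(path, family, params = list(), seed = 1L) {
  yaml::write_yaml(list(scenario = list(family = family, seed = seed,
                                        params = params)), path)
  invisible(path)
}
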