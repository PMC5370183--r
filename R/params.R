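#' Degradation-model rate constants
#'
#' Container for the first-order rate constants of the photocycle-coupled
#' degradation model of ZTL targets.  `k1` and `k2` are the degradation rates
#' of the target protein when ZTL is fully in its light state (cysteinyl-FMN
#' adduct formed) and fully in its dark state, respectively.  `k3` is the LOV
#' adduct-decay (dark-reversion) rate of ZTL itself, which governs how fast the
#' instantaneous degradation coefficient relaxes from `k1` to `k2` after dusk.
#' `m8` is a ZTL-independent first-order degradation channel that applies to
#' TOC1 only (presumed nuclear turnover); it defaults to 0.
#'
#' All rates are in reciprocal hours.  `k3 = 0` (a photocycle that never
#' reverts) and `k3 = Inf` (instantaneous reversion) are accepted and handled
#' as explicit limit cases by the model functions.
#'
#' @param k1 light-state degradation rate (hr^-1), >= 0.
#' @param k2 dark-state degradation rate (hr^-1), >= 0.
#' @param k3 adduct-decay (dark-reversion) rate (hr^-1), >= 0, may be `Inf`.
#' @param m8 ZTL-independent degradation rate (hr^-1), >= 0; used for TOC1.
#' @return An object of class `"degradation_params"`.
#' @examples
#' degradation_params(k1 = 0.14, k2 = 0.8, k3 = 0.7)
#' @export
degradation_params <- function(k1, k2, k3, m8 = 0) {
  for (nm in c("k1", "k2", "k3", "m8")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be a single non-missing number", nm))
    if (v < 0)
      stop(sprintf("'%s' must be non-negative (got %g)", nm, v))
  }
  if (is.infinite(k1) || is.infinite(k2) || is.infinite(m8))
    stop("'k1', 'k2' and 'm8' must be finite")
  structure(list(k1 = k1, k2 = k2, k3 = k3, m8 = m8),
            class = "degradation_params")
}

#' @export
print.degradation_params <- function(x, ...) {
  cat("Degradation parameters (hr^-1):\n")
  cat(sprintf("  k1 (light-state) = %g\n", x$k1))
  cat(sprintf("  k2 (dark-state)  = %g\n", x$k2))
  cat(sprintf("  k3 (adduct decay) = %g\n", x$k3))
  if (x$m8 > 0) cat(sprintf("  m8 (ZTL-independent) = %g\n", x$m8))
  invisible(x)
}

as_degradation_params <- function(x) {
  if (inherits(x, "degradation_params")) return(x)
  if (is.list(x) && all(c("k1", "k2", "k3") %in% names(x)))
    return(degradation_params(x$k1, x$k2, x$k3,
                              if (is.null(x$m8)) 0 else x$m8))
  stop("cannot interpret 'params' as degradation parameters; ",
       "use degradation_params()")
}

#' Published-model degradation rates
#'
#' The degradation rate constants of the published Arabidopsis clock models
#' from which `k1` and `k2` are derived: `m17`/`m24` for PRR5 and `m6`/`m7`
#' for TOC1, plus the ZTL-independent TOC1 term `m8`.  In those models the
#' dark indicator simply adds the second term at night, so the light-state
#' rate is `m17` (or `m6`) and the dark-state rate their sum.
#'
#' @param m17,m24 PRR5 rates (hr^-1), >= 0.
#' @param m6,m7,m8 TOC1 rates (hr^-1), >= 0.
#' @return An object of class `"pokhilko_rates"`.
#' @export
pokhilko_rates <- function(m17 = NA_real_, m24 = NA_real_,
                           m6 = NA_real_, m7 = NA_real_, m8 = 0) {
  vals <- list(m17 = m17, m24 = m24, m6 = m6, m7 = m7, m8 = m8)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L)
      stop(sprintf("'%s' must be a single number", nm))
    if (!is.na(v) && v < 0)
      stop(sprintf("'%s' must be non-negative", nm))
  }
  structure(vals, class = "pokhilko_rates")
}

#' Convert published-model rates to photocycle-model parameters
#'
#' Maps the degradation constants of the published clock models onto the
#' light/dark-state parameters of the photocycle-coupled model: for PRR5,
#' `k1 = m17` and `k2 = m17 + m24`; for TOC1, `k1 = m6`, `k2 = m6 + m7`,
#' with `m8` passed through unchanged.
#'
#' @param rates a [pokhilko_rates()] object (or a named list with the
#'   required components for the chosen species).
#' @param species `"PRR5"` or `"TOC1"`.
#' @return A [degradation_params()] object.  `k3` is not part of the
#'   published models, which switch between rates instantaneously at dusk;
#'   the returned object therefore carries `k3 = Inf`, their implicit limit.
#'   Replace it with a measured adduct-decay rate before simulating the
#'   photocycle-coupled model.
#' @export
convert_pokhilko_params <- function(rates, species = c("PRR5", "TOC1")) {
  species <- match.arg(species)
  if (!inherits(rates, "pokhilko_rates")) rates <- do.call(pokhilko_rates, as.list(rates))
  if (species == "PRR5") {
    if (is.na(rates$m17) || is.na(rates$m24))
      stop("PRR5 conversion requires 'm17' and 'm24'")
    degradation_params(k1 = rates$m17, k2 = rates$m17 + rates$m24, k3 = Inf)
  } else {
    if (is.na(rates$m6) || is.na(rates$m7))
      stop("TOC1 conversion requires 'm6' and 'm7'")
    degradation_params(k1 = rates$m6, k2 = rates$m6 + rates$m7, k3 = Inf,
                       m8 = rates$m8)
  }
}

# evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs expr untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
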