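#' ZTL light-state fraction during the dark phase
#'
#' After lights-off the cysteinyl-FMN adduct of ZTL decays thermally, so the
#' fraction of ZTL still in its light state falls as `exp(-k3 * t)`, where `t`
#' is the dusk clock (hours since the last light-to-dark transition) and `k3`
#' the adduct-decay rate.  Total ZTL is normalised to 1, so the dark-state
#' fraction is `1 - light_state_fraction(t, k3)`.
#'
#' @param t_since_dusk hours since dusk, >= 0 (vectorised).
#' @param k3 adduct-decay rate (hr^-1), >= 0; `Inf` allowed (instant reversion).
#' @return Light-state fraction in \[0, 1\].
#' @export
light_state_fraction <- function(t_since_dusk, k3) {
  if (!is.numeric(t_since_dusk) || any(is.na(t_since_dusk)) ||
      any(t_since_dusk < 0))
    stop("'t_since_dusk' must be non-negative")
  if (!is.numeric(k3) || length(k3) != 1L || is.na(k3) || k3 < 0)
    stop("'k3' must be a single non-negative rate")
  if (is.infinite(k3)) return(as.numeric(t_since_dusk == 0))
  exp(-k3 * t_since_dusk)
}

#' Instantaneous degradation coefficient after dusk
#'
#' The effective first-order coefficient acting on a ZTL target during the
#' dark phase: `(k1 - k2) * exp(-k3 * t) + k2`.  It equals the light-state
#' rate `k1` at dusk and relaxes to the dark-state rate `k2` as the ZTL
#' photocycle reverts.  The TOC1-specific `m8` channel is not included here;
#' it is added by the species-level functions.
#'
#' @param t_since_dusk hours since dusk, >= 0 (vectorised).
#' @param params a [degradation_params()] object.
#' @return Coefficient in hr^-1.
#' @export
effective_degradation_coefficient <- function(t_since_dusk, params) {
  params <- as_degradation_params(params)
  frac <- light_state_fraction(t_since_dusk, params$k3)
  (params$k1 - params$k2) * frac + params$k2
}

# Closed-form solution of dc/dt = -[(k1-k2) e^{-k3 t} + k2 + extra] c from
# dusk, with c(0) = c0.  `extra` is the constant ZTL-independent channel
# (m8 for TOC1, 0 for PRR5).  k3 = 0 and k3 = Inf use explicit limit branches.
decay_closed_form <- function(t, c0, k1, k2, k3, extra = 0) {
  if (any(t < 0)) stop("'t_since_dusk' must be non-negative")
  if (k3 == 0) {
    # photocycle never reverts: ZTL stays light-state, coefficient stays k1
    return(c0 * exp(-(k1 + extra) * t))
  }
  if (is.infinite(k3)) {
    # instant reversion: coefficient is k2 for all t > 0
    return(c0 * exp(-(k2 + extra) * t))
  }
  c0 * exp(((k1 - k2) / k3) * (exp(-k3 * t) - 1) - (k2 + extra) * t)
}

#' Closed-form PRR5 level during the dark phase
#'
#' Exact solution of the photocycle-coupled degradation model for PRR5,
#' `c(t) = c0 * exp(((k1 - k2)/k3) * (exp(-k3 t) - 1) - k2 t)`, with `t`
#' measured from dusk.  `k3 = 0` collapses to `c0 * exp(-k1 t)` (with a
#' warning, since the generic form divides by `k3`); `k3 = Inf` collapses to
#' `c0 * exp(-k2 t)`.
#'
#' @param t_since_dusk hours since dusk, >= 0 (vectorised).
#' @param c0 level at dusk, > 0.
#' @param params a [degradation_params()] object.
#' @return Relative PRR5 level (same units as `c0`).
#' @export
prr5_analytic <- function(t_since_dusk, c0, params) {
  params <- as_degradation_params(params)
  if (!is.numeric(c0) || length(c0) != 1L || is.na(c0) || c0 <= 0)
    stop("'c0' must be a single positive level")
  if (params$k3 == 0)
    warning("k3 = 0: photocycle never reverts; using the limit form c0*exp(-k1*t)")
  decay_closed_form(t_since_dusk, c0, params$k1, params$k2, params$k3)
}

#' Closed-form TOC1 level during the dark phase
#'
#' As [prr5_analytic()] but with the additional constant ZTL-independent
#' degradation channel `m8`:
#' `c(t) = c0 * exp(((k1 - k2)/k3) * (exp(-k3 t) - 1) - (k2 + m8) t)`.
#'
#' @inheritParams prr5_analytic
#' @return Relative TOC1 level.
#' @export
toc1_analytic <- function(t_since_dusk, c0, params) {
  params <- as_degradation_params(params)
  if (!is.numeric(c0) || length(c0) != 1L || is.na(c0) || c0 <= 0)
    stop("'c0' must be a single positive level")
  if (params$k3 == 0)
    warning("k3 = 0: photocycle never reverts; using the limit form c0*exp(-(k1+m8)*t)")
  decay_closed_form(t_since_dusk, c0, params$k1, params$k2, params$k3,
                    extra = params$m8)
}

species_analytic <- function(species, t, c0, params) {
  extra <- if (species == "TOC1") params$m8 else 0
  decay_closed_form(t, c0, params$k1, params$k2, params$k3, extra = extra)
}

#' Numerical integration of the dark-phase degradation model
#'
#' Integrates `dc/dt = -[(k1 - k2) exp(-k3 t) + k2 (+ m8 for TOC1)] c` from
#' dusk with an adaptive solver (deSolve::lsoda, rtol 1e-8 / atol 1e-12 by
#' default).  Serves as the independent numerical oracle for the closed-form
#' solutions, which it matches to a relative tolerance of about 1e-6.
#'
#' @param species `"PRR5"` or `"TOC1"`.
#' @param c0 level at dusk, > 0.
#' @param params a [degradation_params()] object.
#' @param times monotone increasing time grid (hr since dusk) starting at 0.
#' @param rtol,atol solver tolerances.
#' @return A data frame of class `"ztl_simulation"` with columns `time_hr`,
#'   `species`, `level`, `ztl_light_fraction`, `phase` (all `"dark"`).
#' @export
integrate_numeric <- function(species = c("PRR5", "TOC1"), c0, params, times,
                              rtol = 1e-8, atol = 1e-12) {
  species <- match.arg(species)
  params <- as_degradation_params(params)
  if (!is.numeric(times) || length(times) < 1L || times[1] != 0 ||
      is.unsorted(times, strictly = TRUE))
    stop("'times' must be a strictly increasing grid starting at 0 (dusk)")
  if (c0 <= 0) stop("'c0' must be positive")
  extra <- if (species == "TOC1") params$m8 else 0
  if (length(times) == 1L) {
    lev <- c0
  } else {
    rhs <- function(t, y, p) {
      coef <- (p$k1 - p$k2) * exp(-p$k3 * t) + p$k2 + p$extra
      list(-coef * y)
    }
    p <- list(k1 = params$k1, k2 = params$k2,
              k3 = if (is.infinite(params$k3)) NA_real_ else params$k3,
              extra = extra)
    if (is.infinite(params$k3)) {
      # limit branch: coefficient is constant k2 (+extra) for t > 0
      lev <- c0 * exp(-(params$k2 + extra) * times)
    } else {
      sol <- deSolve::lsoda(y = c(level = c0), times = times, func = rhs,
                            parms = p, rtol = rtol, atol = atol)
      diag <- attr(sol, "istate")
      if (!is.null(diag) && diag[1] < 0)
        stop("ODE solver failed to converge (istate = ", diag[1], "); ",
             "see deSolve::diagnostics for details")
      if (nrow(sol) != length(times))
        stop("ODE solver returned an incomplete trajectory")
      lev <- sol[, "level"]
    }
  }
  structure(data.frame(time_hr = times,
                       species = species,
                       level = as.numeric(lev),
                       ztl_light_fraction = light_state_fraction(times, params$k3),
                       phase = "dark",
                       stringsAsFactors = FALSE),
            class = c("ztl_simulation", "data.frame"))
}

#' Simulate a ZTL target under a light/dark schedule
#'
#' Piecewise trajectory of the photocycle-coupled degradation model under a
#' [light_schedule()].  During light phases the adduct is photostationary
#' (near-saturated light state), so the level decays at the constant rate
#' `k1` (`k1 + m8` for TOC1) and the light-state fraction is 1.  At each
#' light-to-dark transition the dusk clock restarts and the dark-phase closed
#' form applies; at each dark-to-light transition the light-state fraction is
#' reset to 1 instantaneously (photo-activation is fast on the hours
#' timescale).  The level itself is continuous throughout.
#'
#' @param species `"PRR5"` or `"TOC1"`.
#' @param c0 level at ZT0 (lights-on), > 0.
#' @param params a [degradation_params()] object.
#' @param schedule a [light_schedule()].
#' @param step sampling step (hr); phase boundaries are always included.
#' @return A data frame of class `"ztl_simulation"` with columns `time_hr`
#'   (hr since ZT0), `species`, `level`, `ztl_light_fraction`, `phase`.
#' @examples
#' wt <- preset_params("WT")$params
#' sim <- simulate_schedule("PRR5", c0 = 1, wt, gen_ld_schedule(), step = 0.5)
#' head(sim)
#' @export
simulate_schedule <- function(species = c("PRR5", "TOC1"), c0, params,
                              schedule, step = 0.1) {
  species <- match.arg(species)
  params <- as_degradation_params(params)
  if (!inherits(schedule, "light_schedule"))
    stop("'schedule' must be a light_schedule")
  if (nrow(schedule) == 0L) stop("schedule is empty")
  if (c0 <= 0) stop("'c0' must be positive")
  if (step <= 0) stop("'step' must be positive")
  total <- schedule_total(schedule)
  times <- sort(unique(c(seq(0, total, by = step), schedule$end, total)))
  out <- schedule_level(times, c0, params, schedule, species)
  structure(data.frame(time_hr = times,
                       species = species,
                       level = out$level,
                       ztl_light_fraction = out$ztl_light_fraction,
                       phase = out$phase,
                       stringsAsFactors = FALSE),
            class = c("ztl_simulation", "data.frame"))
}

# Exact piecewise level at arbitrary times within a schedule.
# Levels at phase starts are propagated analytically, so the trajectory is
# continuous and independent of the sampling grid.
schedule_level <- function(times, c0, params, schedule, species) {
  extra <- if (species == "TOC1") params$m8 else 0
  # level at the start of each phase
  starts <- numeric(nrow(schedule))
  starts[1] <- c0
  if (nrow(schedule) > 1) {
    for (i in seq_len(nrow(schedule) - 1L)) {
      d <- schedule$duration[i]
      starts[i + 1L] <- if (schedule$kind[i] == "light") {
        starts[i] * exp(-(params$k1 + extra) * d)
      } else {
        decay_closed_form(d, starts[i], params$k1, params$k2, params$k3, extra)
      }
    }
  }
  loc <- schedule_lookup(schedule, times)
  level <- numeric(length(times))
  frac <- numeric(length(times))
  for (j in seq_along(times)) {
    i <- loc$phase[j]; s <- loc$t_in_phase[j]
    if (loc$kind[j] == "light") {
      level[j] <- starts[i] * exp(-(params$k1 + extra) * s)
      frac[j] <- 1
    } else {
      level[j] <- decay_closed_form(s, starts[i], params$k1, params$k2,
                                    params$k3, extra)
      frac[j] <- light_state_fraction(s, params$k3)
    }
  }
  list(level = level, ztl_light_fraction = frac, phase = loc$kind)
}

#' @export
print.ztl_simulation <- function(x, ...) {
  cat(sprintf("ZTL-target simulation: %s, %d time points over %g hr\n",
              x$species[1], nrow(x), max(x$time_hr)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
plot.ztl_simulation <- function(x, log = "", ...) {
  graphics::plot(x$time_hr, x$level, type = "l", xlab = "time (hr)",
                 ylab = sprintf("relative %s level", x$species[1]),
                 log = log, ...)
  dark <- x$phase == "dark"
  if (any(dark) && any(!dark)) {
    runs <- rle(dark)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (r in which(runs$values)) {
      graphics::rect(x$time_hr[starts[r]], graphics::par("usr")[3],
                     x$time_hr[ends[r]], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.3), border = NA)
    }
  }
  invisible(x)
}

#' Apparent single-exponential degradation rate of a time course
#'
#' Fits a single exponential `c(t) = c0 * exp(-k t)` to a protein time course
#' by least squares on the log scale, pooling replicates.  This treats the
#' system as if it contained only dark-state protein, so when the underlying
#' kinetics follow the photocycle-coupled model the result is a time-averaged
#' apparent rate lying between `k1` and `k2`; such rates are accurate as
#' comparative terms between variants only, not as mechanistic constants.
#'
#' @param tc a [protein_timecourse()] (or any data frame with `time_hr` and
#'   `level` columns).
#' @return A list of class `"rate_estimate"`: `k` (hr^-1), `se`, `c0`,
#'   `n`, and `decaying` (FALSE, with a warning, if the fitted rate is not
#'   positive).
#' @export
effective_rate_constant <- function(tc) {
  if (!is.data.frame(tc) || !all(c("time_hr", "level") %in% names(tc)))
    stop("'tc' must contain columns 'time_hr' and 'level'")
  if (length(unique(tc$time_hr)) < 2L)
    stop("at least two distinct time points are required")
  if (any(tc$level <= 0)) stop("levels must be positive")
  fit <- stats::lm(log(level) ~ time_hr, data = tc)
  k <- -unname(stats::coef(fit)["time_hr"])
  se <- if (nrow(tc) > 2L)
          suppressWarnings(summary(fit)$coefficients["time_hr", "Std. Error"])
        else NA_real_
  decaying <- k > 0
  if (!decaying)
    warning("time course does not decay; estimate is unconstrained")
  structure(list(k = k, se = se,
                 c0 = exp(unname(stats::coef(fit)[1])),
                 n = nrow(tc), decaying = decaying),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Apparent degradation rate: k = %.4g hr^-1 (SE %.3g, n = %d)\n",
              x$k, x$se, x$n))
  cat("  (comparative, single-exponential approximation)\n")
  invisible(x)
}
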