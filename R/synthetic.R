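#' Noise specification for synthetic data
#'
#' Declares the statistical structure the synthetic-data generators emulate:
#' additive Gaussian instrument noise on absorbance readings and
#' multiplicative mean-one lognormal biological noise on densitometry-style
#' protein levels, over a fixed number of biological replicates.
#'
#' @param absorbance_sd additive Gaussian sd on absorbance (AU), default 0.005.
#' @param protein_cv fractional coefficient of variation of the multiplicative
#'   lognormal protein noise, default 0.10.
#' @param n_replicates number of replicates generated, default 3.
#' @param seed integer seed; the seed fully determines the generated data.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(absorbance_sd = 0.005, protein_cv = 0.10,
                       n_replicates = 3L, seed = NULL) {
  if (absorbance_sd < 0 || protein_cv < 0)
    stop("noise magnitudes must be non-negative")
  if (n_replicates < 1) stop("'n_replicates' must be at least 1")
  structure(list(absorbance_sd = absorbance_sd, protein_cv = protein_cv,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "noise_spec")
}

# presets for the characterised ZTL photocycle variants: measured adduct-decay
# time constants tau (hr) and the derived k3 = 1/tau as printed; V48I-class
# variants are allosteric dark-mimics, encoded as k1 = k2 (the light state
# behaves like the dark state), independent of their slowed photocycle.
# The V48I:G80R tau is a lower bound (recovery exceeds the observation window).
ztl_preset_table <- data.frame(
  name = c("WT", "G80R", "V48I", "G46S:G80R", "V48I:G80R"),
  k1 = c(0.14, 0.14, 0.8, 0.14, 0.8),
  k2 = c(0.8, 0.8, 0.8, 0.8, 0.8),
  k3 = c(0.7, 0.15, 0.09, 0.05, 0.02),
  tau = c(1.4, 6.6, 10.7, 21, 65),
  tau_is_lower_bound = c(FALSE, FALSE, FALSE, FALSE, TRUE),
  allosteric = c(FALSE, FALSE, TRUE, FALSE, TRUE),
  stringsAsFactors = FALSE)

#' Parameter presets for the characterised ZTL variants
#'
#' Returns the published kinetic parameter set for a named ZTL photocycle
#' variant: the adduct-decay rate `k3` (reciprocal of the measured recovery
#' time constant `tau`), and the light/dark degradation rates `k1 = 0.14`,
#' `k2 = 0.8` hr^-1.  V48I-containing variants are allosteric dark-mimics
#' whose light state behaves like the dark state; they are encoded with
#' `k1 = k2 = 0.8` hr^-1 (the `allosteric` flag is set), separately from
#' their slowed photocycle.
#'
#' @param name one of `"WT"`, `"G80R"`, `"V48I"`, `"G46S:G80R"`,
#'   `"V48I:G80R"`.
#' @return A list with components `params` (a [degradation_params()]) and
#'   `preset` (name, `k3`, `tau`, `tau_is_lower_bound`, `allosteric`).
#' @examples
#' preset_params("WT")$params    # k1 = 0.14, k2 = 0.8, k3 = 0.7
#' @export
preset_params <- function(name) {
  i <- match(name, ztl_preset_table$name)
  if (is.na(i))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(ztl_preset_table$name, collapse = ", ")))
  row <- ztl_preset_table[i, ]
  list(params = degradation_params(k1 = row$k1, k2 = row$k2, k3 = row$k3),
       preset = list(name = row$name, k3 = row$k3, tau = row$tau,
                     tau_is_lower_bound = row$tau_is_lower_bound,
                     allosteric = row$allosteric))
}

#' Names of the available variant presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() ztl_preset_table$name

#' Generate synthetic absorbance dark-recovery traces
#'
#' Simulates replicate dual-wavelength recovery traces
#' `y(t) = y0 + A * exp(-k t)` with independent additive Gaussian noise per
#' point and channel.  Defaults mimic a ~30 uM LOV-domain sample (dark-state
#' 450 nm extinction ~12500: plateau around 0.35-0.4 AU) that was fully
#' photo-bleached at t = 0, recovering toward the dark-state spectrum (hence
#' negative amplitude).
#'
#' @param k adduct-decay rate (hr^-1), > 0.
#' @param y0 plateau absorbance (AU).
#' @param A amplitude (AU); negative for recovery.
#' @param t_grid increasing sampling times (hr), non-empty.
#' @param noise a [noise_spec()]; `noise$seed` (if non-NULL) makes the output
#'   reproducible without touching the caller's RNG state.
#' @param channels which channels to generate (`"a450"`, `"a478"`).
#' @return A list of [absorbance_trace()] objects, one per replicate.
#' @export
gen_absorbance_trace <- function(k, y0 = 0.35, A = -0.30, t_grid,
                                 noise = noise_spec(),
                                 channels = c("a450", "a478")) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive rate")
  if (length(t_grid) == 0L) stop("'t_grid' is empty")
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] < 0)
    stop("'t_grid' must be strictly increasing and non-negative")
  channels <- match.arg(channels, several.ok = TRUE)
  clean <- y0 + A * exp(-k * t_grid)
  with_seed(noise$seed, {
    lapply(seq_len(noise$n_replicates), function(r) {
      vals <- lapply(channels, function(ch) {
        clean + stats::rnorm(length(t_grid), 0, noise$absorbance_sd)
      })
      names(vals) <- channels
      absorbance_trace(time_hr = t_grid,
                       a450 = vals[["a450"]],
                       a478 = vals[["a478"]],
                       replicate = r)
    })
  })
}

#' Generate a synthetic protein time course
#'
#' Simulates replicated, loading-control-normalised protein levels under a
#' light schedule: the noiseless trajectory follows the photocycle-coupled
#' degradation model (piecewise over the schedule, see
#' [simulate_schedule()]), and each observation is multiplied by an
#' independent mean-one lognormal factor with coefficient of variation
#' `noise$protein_cv` — the multiplicative error structure typical of western
#' blot densitometry.
#'
#' @param truth generating [degradation_params()].
#' @param schedule a [light_schedule()].
#' @param c0 level at ZT0, > 0.
#' @param times sampling times (hr since ZT0), within the schedule span.
#' @param noise a [noise_spec()].
#' @param species `"PRR5"` or `"TOC1"`.
#' @return A [protein_timecourse()] with `noise$n_replicates` replicates and
#'   condition derived from the schedule (LL if all-light, else LD).
#' @export
gen_protein_timecourse <- function(truth, schedule, c0 = 1, times,
                                   noise = noise_spec(),
                                   species = c("PRR5", "TOC1")) {
  species <- match.arg(species)
  truth <- as_degradation_params(truth)
  if (!inherits(schedule, "light_schedule"))
    stop("'schedule' must be a light_schedule")
  if (length(times) < 1L) stop("'times' is empty")
  total <- schedule_total(schedule)
  if (any(times < 0 | times > total + 1e-9))
    stop(sprintf("sampling times must lie within the schedule span [0, %g] hr",
                 total))
  times <- sort(times)
  clean <- schedule_level(times, c0, truth, schedule, species)$level
  cv <- noise$protein_cv
  sigma <- sqrt(log(1 + cv^2))
  mu <- -sigma^2 / 2          # mean-one lognormal
  nt <- length(times)
  with_seed(noise$seed, {
    levels <- unlist(lapply(seq_len(noise$n_replicates), function(r) {
      if (cv == 0) clean else clean * stats::rlnorm(nt, mu, sigma)
    }))
    protein_timecourse(
      time_hr = rep(times, noise$n_replicates),
      level = levels,
      replicate = rep(seq_len(noise$n_replicates), each = nt),
      condition = schedule_condition(schedule),
      species = species,
      schedule = schedule)
  })
}
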