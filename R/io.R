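#' Read a protein time course from CSV
#'
#' Expects a comma-separated file with header columns `time_hr`, `level`,
#' `replicate`, `condition`, `species` (UTF-8, decimal point).  `condition`
#' and `species` must be constant within a file.  Times must be sorted
#' (non-decreasing) within each replicate and levels strictly positive;
#' violations are reported with the offending data row.
#'
#' @param path file path.
#' @param time_unit `"hours"` (default) or `"seconds"`; seconds are converted
#'   to hours at ingestion.
#' @return A [protein_timecourse()].
#' @export
read_timecourse <- function(path, time_unit = c("hours", "seconds")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hr", "level", "replicate", "condition", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) stop(path, ": no data rows")
  if (time_unit == "seconds") df$time_hr <- df$time_hr / 3600
  bad <- which(!is.finite(df$level) | df$level <= 0)
  if (length(bad))
    stop(sprintf("%s: non-positive level at data row %d (time %g)",
                 path, bad[1], df$time_hr[bad[1]]))
  for (r in unique(df$replicate)) {
    tt <- df$time_hr[df$replicate == r]
    if (is.unsorted(tt))
      stop(sprintf("%s: times are not sorted within replicate '%s'", path, r))
  }
  cond <- unique(df$condition)
  spec <- unique(df$species)
  if (length(cond) != 1L || length(spec) != 1L)
    stop(path, ": 'condition' and 'species' must each be constant in a file")
  protein_timecourse(df$time_hr, df$level, df$replicate,
                     condition = cond, species = spec)
}

#' Write a protein time course to CSV
#'
#' @param tc a [protein_timecourse()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  if (!inherits(tc, "protein_timecourse"))
    stop("'tc' must be a protein_timecourse")
  df <- as.data.frame(tc)
  df$condition <- attr(tc, "condition")
  df$species <- attr(tc, "species")
  utils::write.csv(df[, c("time_hr", "level", "replicate",
                          "condition", "species")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read absorbance recovery traces from CSV
#'
#' Expects header columns `time_hr`, `replicate`, and at least one of `a450`,
#' `a478`.  Each replicate becomes one [absorbance_trace()].
#'
#' @param path file path.
#' @param time_unit `"hours"` or `"seconds"` (converted at ingestion).
#' @return A list of [absorbance_trace()] objects, one per replicate.
#' @export
read_trace <- function(path, time_unit = c("hours", "seconds")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_hr", "replicate") %in% names(df)))
    stop(path, ": required columns 'time_hr' and 'replicate' not found")
  chans <- intersect(c("a450", "a478"), names(df))
  if (length(chans) == 0L)
    stop(path, ": neither absorbance channel (a450, a478) is present")
  if (time_unit == "seconds") df$time_hr <- df$time_hr / 3600
  lapply(unique(df$replicate), function(r) {
    sub <- df[df$replicate == r, , drop = FALSE]
    absorbance_trace(time_hr = sub$time_hr,
                     a450 = if ("a450" %in% chans) sub$a450 else NULL,
                     a478 = if ("a478" %in% chans) sub$a478 else NULL,
                     replicate = r)
  })
}

#' Write absorbance traces to CSV
#'
#' @param traces an [absorbance_trace()] or list thereof.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "absorbance_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    df <- data.frame(time_hr = tr$time_hr, replicate = tr$replicate)
    if (!is.null(tr$a450)) df$a450 <- tr$a450
    if (!is.null(tr$a478)) df$a478 <- tr$a478
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a simulation to CSV
#'
#' Columns: `time_hr`, `species`, `level`, `ztl_light_fraction`, `phase`.
#'
#' @param sim a `"ztl_simulation"` from [simulate_schedule()] or
#'   [integrate_numeric()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  if (!inherits(sim, "ztl_simulation")) stop("'sim' must be a ztl_simulation")
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report as structured key-value text
#'
#' Serialises the estimates, fixed parameters, objective, convergence status,
#' seed and package version of a fit to a YAML file.
#'
#' @param fit a `"degradation_fit"` or `"photocycle_fit"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  rep <- if (inherits(fit, "degradation_fit")) {
    list(kind = "degradation_fit",
         species = fit$species, condition = fit$condition,
         estimates = as.list(fit$estimates),
         fixed = fit$fixed,
         objective = fit$objective,
         objective_space = fit$objective_space,
         converged = fit$converged,
         nonidentifiable = fit$nonidentifiable,
         ci = if (is.null(fit$ci)) NULL else
           apply(fit$ci, 1, as.list, simplify = FALSE),
         seed = fit$seed)
  } else if (inherits(fit, "photocycle_fit")) {
    list(kind = "photocycle_fit", channel = fit$channel,
         y0 = fit$y0, A = fit$A, k = fit$k, tau = fit$tau,
         tau_se = fit$tau_se, rss = fit$rss,
         converged = fit$converged,
         tau_is_lower_bound = fit$tau_is_lower_bound)
  } else stop("unsupported fit object")
  rep$package_version <- as.character(utils::packageVersion("ztlkin"))
  yaml::write_yaml(rep, path)
  invisible(path)
}

# known config keys per CLI command; unknown keys are rejected
run_config_schema <- list(
  simulate = c("preset", "k1", "k2", "k3", "m8", "schedule", "c0", "step",
               "species", "out", "seed"),
  `fit-photocycle` = c("in", "channel", "out", "time_unit"),
  `fit-degradation` = c("in", "preset", "k1", "k2", "k3", "m8", "free",
                        "objective", "c0", "out", "seed"),
  generate = c("kind", "preset", "k1", "k2", "k3", "m8", "schedule", "c0",
               "times", "t_max", "step", "species", "sd", "cv", "replicates",
               "out", "seed"),
  recover = c("preset", "schedule", "times", "t_max", "step", "species",
              "free", "cv", "replicates", "seeds", "out", "seed"))

#' Read and validate a run configuration
#'
#' Reads a YAML configuration for one CLI command and validates it against
#' the command's known keys; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param command one of `simulate`, `fit-photocycle`, `fit-degradation`,
#'   `generate`, `recover`.
#' @return A named list.
#' @export
read_run_config <- function(path, command) {
  if (!command %in% names(run_config_schema))
    stop("unknown command '", command, "'")
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop(path, ": config must be a key-value mapping")
  unknown <- setdiff(names(cfg), run_config_schema[[command]])
  if (length(unknown))
    stop(sprintf("%s: unknown config key(s) for '%s': %s", path, command,
                 paste(unknown, collapse = ", ")))
  cfg
}
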