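#' Light/dark forcing schedules
#'
#' A light schedule is an ordered sequence of light and dark phases, each with
#' a duration in hours.  Time zero is lights-on (Zeitgeber time ZT0).  The
#' "dusk clock" that drives the ZTL light-state fraction restarts at every
#' light-to-dark transition.
#'
#' @param kind character vector of `"light"` / `"dark"` phase labels.
#' @param duration numeric vector of phase durations (hr), all > 0.
#' @return An object of class `"light_schedule"`: a data frame with columns
#'   `kind`, `duration`, `start`, `end`.
#' @seealso [gen_ld_schedule()], [ll_schedule()]
#' @export
light_schedule <- function(kind, duration) {
  kind <- tolower(as.character(kind))
  if (length(kind) == 0L) stop("schedule must contain at least one phase")
  if (!all(kind %in% c("light", "dark")))
    stop("phase kinds must be 'light' or 'dark'")
  if (length(duration) != length(kind))
    stop("'kind' and 'duration' must have the same length")
  if (!is.numeric(duration) || any(!is.finite(duration)) || any(duration <= 0))
    stop("all phase durations must be positive finite hours")
  end <- cumsum(duration)
  start <- c(0, end[-length(end)])
  structure(data.frame(kind = kind, duration = duration,
                       start = start, end = end),
            class = c("light_schedule", "data.frame"))
}

#' Alternating light/dark (LD) schedule
#'
#' Builds the standard diel forcing: `n_cycles` repetitions of
#' `light_hours` light followed by `dark_hours` dark, starting with light at
#' ZT0.  The default is the 12 hr light / 12 hr dark photoperiod.
#'
#' @param light_hours,dark_hours phase durations (hr), > 0.
#' @param n_cycles number of light+dark cycles, >= 1.
#' @return A [light_schedule()].
#' @examples
#' gen_ld_schedule()            # 12L/12D, one cycle
#' gen_ld_schedule(16, 8, 2)    # long-day, two cycles
#' @export
gen_ld_schedule <- function(light_hours = 12, dark_hours = 12, n_cycles = 1) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1)
    stop("'n_cycles' must be at least 1")
  n_cycles <- as.integer(n_cycles)
  light_schedule(kind = rep(c("light", "dark"), n_cycles),
                 duration = rep(c(light_hours, dark_hours), n_cycles))
}

#' Continuous-light (LL) schedule
#'
#' @param duration total duration of the light phase (hr), > 0.
#' @return A [light_schedule()] with a single light phase.
#' @export
ll_schedule <- function(duration = 24) {
  light_schedule("light", duration)
}

#' @export
print.light_schedule <- function(x, ...) {
  cond <- if (all(x$kind == "light")) "LL" else "LD"
  cat(sprintf("Light schedule (%s), total %g hr:\n", cond, sum(x$duration)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  ZT %5.1f - %5.1f : %s\n", x$start[i], x$end[i], x$kind[i]))
  invisible(x)
}

schedule_total <- function(schedule) sum(schedule$duration)

schedule_condition <- function(schedule) {
  if (all(schedule$kind == "light")) "LL" else "LD"
}

# For each time (hr since ZT0), locate the enclosing phase.
# Right-continuous convention: a time exactly at a transition belongs to the
# phase that starts there (so at dusk the dusk clock reads 0 and the
# light-state fraction is 1); the final endpoint belongs to the last phase.
# Returns a data.frame: phase index, kind, time since phase start.
schedule_lookup <- function(schedule, times) {
  total <- schedule_total(schedule)
  if (any(times < 0 | times > total + 1e-9))
    stop(sprintf("times must lie within the schedule span [0, %g] hr", total))
  idx <- findInterval(times, schedule$start, rightmost.closed = FALSE)
  idx[idx > nrow(schedule)] <- nrow(schedule)
  data.frame(phase = idx,
             kind = schedule$kind[idx],
             t_in_phase = times - schedule$start[idx])
}

# Parse compact schedule strings: "12L12D" (optionally "x2" cycles) or "LL".
parse_schedule_string <- function(s, ll_hours = 24) {
  s <- trimws(toupper(s))
  if (s == "LL") return(ll_schedule(ll_hours))
  m <- regmatches(s, regexec("^([0-9.]+)L([0-9.]+)D(X([0-9]+))?$", s))[[1]]
  if (length(m) == 0L)
    stop(sprintf("cannot parse schedule '%s'; use e.g. '12L12D', '12L12Dx2' or 'LL'", s))
  n <- if (m[5] == "") 1L else as.integer(m[5])
  gen_ld_schedule(as.numeric(m[2]), as.numeric(m[3]), n)
}
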