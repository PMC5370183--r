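#' Absorbance dark-recovery trace
#'
#' Timed absorbance readings at 450 and/or 478 nm from a LOV-domain
#' dark-recovery experiment: the sample is driven to the light state
#' (cysteinyl-FMN adduct, bleached at both wavelengths) and the flavin
#' absorbance recovers monoexponentially as the adduct decays in darkness.
#'
#' @param time_hr times (hr), strictly increasing from 0.
#' @param a450,a478 absorbance readings (AU); either channel may be `NULL`,
#'   but not both.  Each supplied channel needs at least 5 points.
#' @param temperature sample temperature (K), metadata only.
#' @param base_catalyzed logical flag for imidazole-catalysed recovery runs
#'   (metadata only; the same monoexponential model is fitted).
#' @param replicate replicate identifier.
#' @return An object of class `"absorbance_trace"`.
#' @export
absorbance_trace <- function(time_hr, a450 = NULL, a478 = NULL,
                             temperature = 296, base_catalyzed = FALSE,
                             replicate = 1L) {
  if (!is.numeric(time_hr) || length(time_hr) < 2L)
    stop("'time_hr' must be a numeric vector of at least 2 times")
  if (any(!is.finite(time_hr)) || time_hr[1] < 0 ||
      is.unsorted(time_hr, strictly = TRUE))
    stop("'time_hr' must be finite, non-negative and strictly increasing")
  if (is.null(a450) && is.null(a478))
    stop("at least one absorbance channel (a450, a478) is required")
  for (ch in c("a450", "a478")) {
    v <- get(ch)
    if (is.null(v)) next
    if (length(v) != length(time_hr))
      stop(sprintf("'%s' must have the same length as 'time_hr'", ch))
    if (any(!is.finite(v)))
      stop(sprintf("'%s' contains non-finite values", ch))
    if (length(v) < 5L)
      stop(sprintf("'%s' needs at least 5 points to be fittable", ch))
  }
  structure(list(time_hr = time_hr, a450 = a450, a478 = a478,
                 temperature = temperature,
                 base_catalyzed = isTRUE(base_catalyzed),
                 replicate = replicate),
            class = "absorbance_trace")
}

#' @export
print.absorbance_trace <- function(x, ...) {
  ch <- c("450 nm"[!is.null(x$a450)], "478 nm"[!is.null(x$a478)])
  cat(sprintf("Absorbance recovery trace: %d points over %g hr (%s)%s\n",
              length(x$time_hr), max(x$time_hr), paste(ch, collapse = " + "),
              if (x$base_catalyzed) ", base-catalysed" else ""))
  cat(sprintf("  replicate %s, %g K\n", x$replicate, x$temperature))
  invisible(x)
}

trace_channels <- function(trace) {
  c("a450"[!is.null(trace$a450)], "a478"[!is.null(trace$a478)])
}

# derivative-free starting values for y = y0 + A exp(-k t):
# y0 from the tail (last 10% of points), A from first-minus-plateau,
# k from the slope of log|y - y0| over points clearly away from the plateau.
monoexp_start <- function(t, y) {
  n <- length(y)
  ntail <- max(2L, ceiling(0.1 * n))
  y0g <- mean(y[(n - ntail + 1L):n])
  Ag <- y[1] - y0g
  if (Ag == 0) Ag <- (min(y) - max(y)) / 2
  resid <- y - y0g
  usable <- which(abs(resid) > max(abs(Ag) * 0.05, 1e-12) &
                  sign(resid) == sign(Ag))
  kg <- NA_real_
  if (length(usable) >= 2L) {
    sl <- stats::coef(stats::lm(log(abs(resid[usable])) ~ t[usable]))[2]
    if (is.finite(sl) && sl < 0) kg <- -unname(sl)
  }
  if (!is.finite(kg) || kg <= 0) kg <- log(2) / (diff(range(t)) / 2)
  list(y0 = y0g, A = Ag, k = kg)
}

#' Fit a monoexponential recovery to an absorbance trace
#'
#' Fits `y = y0 + A * exp(-k * t)` to one absorbance channel of a
#' dark-recovery trace by unweighted nonlinear least squares in linear
#' absorbance space (Levenberg-Marquardt).  Starting values come from a
#' log-linear pre-fit (see Details).  The rate constant `k` and the time
#' constant `tau = 1/k` are the quantities of interest; for recovery toward
#' higher absorbance the amplitude `A` is negative.
#'
#' If the fitted time constant exceeds three times the observation window the
#' result is flagged as a lower bound (`tau_is_lower_bound`), since the
#' plateau is then essentially unconstrained by the data.
#'
#' @param trace an [absorbance_trace()].
#' @param channel `"a450"` or `"a478"`; defaults to the first available.
#' @param start optional named list of starting values (`y0`, `A`, `k`).
#' @return An object of class `"photocycle_fit"` with components `y0`, `A`,
#'   `k`, `tau`, `se` (named vector for y0/A/k), `tau_se`, `rss`,
#'   `converged`, `channel`, `n`, `tau_is_lower_bound`, and the data used.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`.
#' @examples
#' tr <- gen_absorbance_trace(k = 1 / 1.4, t_grid = seq(0, 7, 0.15),
#'                            noise = noise_spec(seed = 1))[[1]]
#' fit <- fit_monoexponential(tr, "a450")
#' coef(fit)
#' @export
fit_monoexponential <- function(trace, channel = NULL, start = NULL) {
  if (!inherits(trace, "absorbance_trace"))
    stop("'trace' must be an absorbance_trace")
  avail <- trace_channels(trace)
  if (is.null(channel)) channel <- avail[1]
  channel <- match.arg(channel, c("a450", "a478"))
  if (!channel %in% avail)
    stop(sprintf("channel '%s' is not present in this trace", channel))
  t <- trace$time_hr
  y <- trace[[channel]]
  if (length(y) < 5L) stop("at least 5 points are required per channel")
  if (is.null(start)) start <- monoexp_start(t, y)
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + A * exp(-k * t), data = dat,
                      start = start, lower = c(-Inf, -Inf, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(y0 = NA_real_, A = NA_real_, k = NA_real_, tau = NA_real_,
                se = c(y0 = NA_real_, A = NA_real_, k = NA_real_),
                tau_se = NA_real_, rss = NA_real_, converged = FALSE,
                channel = channel, n = length(y),
                tau_is_lower_bound = FALSE, single_channel = FALSE,
                replicate = trace$replicate, message = conditionMessage(fit),
                data = dat, model = NULL)
    class(res) <- "photocycle_fit"
    return(res)
  }
  cf <- stats::coef(fit)
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  k <- unname(cf["k"])
  converged <- isTRUE(fit$convInfo$isConv) && k > 0
  span <- diff(range(t))
  if (converged && k > 0 && span < log(2) / k)
    warning(sprintf(paste0("observation window (%.3g hr) is shorter than one ",
                           "fitted half-life (%.3g hr); the rate is poorly ",
                           "constrained"), span, log(2) / k))
  tau <- 1 / k
  res <- list(y0 = unname(cf["y0"]), A = unname(cf["A"]), k = k, tau = tau,
              se = c(y0 = unname(se["y0"]), A = unname(se["A"]),
                     k = unname(se["k"])),
              tau_se = unname(se["k"]) / k^2,    # delta method on 1/k
              rss = sum(stats::residuals(fit)^2),
              converged = converged, channel = channel, n = length(y),
              tau_is_lower_bound = is.finite(tau) && tau > 3 * span,
              single_channel = FALSE, replicate = trace$replicate,
              message = NULL, data = dat, model = fit)
  class(res) <- "photocycle_fit"
  res
}

#' @export
print.photocycle_fit <- function(x, ...) {
  cat(sprintf("Monoexponential recovery fit (%s, n = %d)\n", x$channel, x$n))
  if (!x$converged) {
    cat("  DID NOT CONVERGE", if (!is.null(x$message)) paste0(": ", x$message),
        "\n")
    return(invisible(x))
  }
  cat(sprintf("  k   = %.4g +/- %.2g hr^-1\n", x$k, x$se["k"]))
  bound <- if (x$tau_is_lower_bound) " (lower bound: tau > 3x window)" else ""
  cat(sprintf("  tau = %.4g +/- %.2g hr%s\n", x$tau, x$tau_se, bound))
  cat(sprintf("  y0  = %.4g AU, A = %.4g AU, RSS = %.3g\n", x$y0, x$A, x$rss))
  if (x$single_channel)
    cat("  (single surviving channel of a two-channel combination)\n")
  invisible(x)
}

#' @export
summary.photocycle_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$model)) print(summary(object$model))
  invisible(object)
}

#' @export
coef.photocycle_fit <- function(object, ...) {
  c(y0 = object$y0, A = object$A, k = object$k)
}

#' @export
predict.photocycle_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  object$y0 + object$A * exp(-object$k * t)
}

#' @export
fitted.photocycle_fit <- function(object, ...) predict(object)

#' @export
residuals.photocycle_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
plot.photocycle_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, xlab = "time (hr)",
                 ylab = sprintf("absorbance (%s, AU)", x$channel), ...)
  if (x$converged) {
    tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
    graphics::lines(tt, x$y0 + x$A * exp(-x$k * tt), col = 2)
  }
  invisible(x)
}

#' Combine per-channel recovery fits into one rate estimate
#'
#' The 450 and 478 nm channels report the same adduct-decay process, so their
#' independently fitted rate constants are combined into a single per-sample
#' estimate: `k` is the arithmetic mean of the channel rates and its
#' uncertainty the larger of the half-range and the pooled standard error.
#' If one channel failed to converge the surviving channel's result is
#' returned, flagged `single_channel`.
#'
#' @param fit450,fit478 `"photocycle_fit"` objects for the two channels.
#' @return A `"photocycle_fit"` object (channel `"combined"`).
#' @export
combine_channel_fits <- function(fit450, fit478) {
  stopifnot(inherits(fit450, "photocycle_fit"),
            inherits(fit478, "photocycle_fit"))
  ok <- c(fit450$converged, fit478$converged)
  if (!any(ok)) stop("neither channel fit converged; nothing to combine")
  if (sum(ok) == 1L) {
    out <- if (ok[1]) fit450 else fit478
    out$single_channel <- TRUE
    return(out)
  }
  k <- mean(c(fit450$k, fit478$k))
  half_range <- abs(fit450$k - fit478$k) / 2
  pooled <- sqrt(mean(c(fit450$se["k"], fit478$se["k"])^2))
  se_k <- max(half_range, pooled, na.rm = TRUE)
  res <- list(y0 = mean(c(fit450$y0, fit478$y0)),
              A = mean(c(fit450$A, fit478$A)),
              k = k, tau = 1 / k,
              se = c(y0 = NA_real_, A = NA_real_, k = se_k),
              tau_se = se_k / k^2,
              rss = fit450$rss + fit478$rss,
              converged = TRUE, channel = "combined",
              n = fit450$n + fit478$n,
              tau_is_lower_bound = fit450$tau_is_lower_bound &&
                fit478$tau_is_lower_bound,
              single_channel = FALSE, replicate = fit450$replicate,
              message = NULL,
              data = rbind(fit450$data, fit478$data), model = NULL)
  class(res) <- "photocycle_fit"
  res
}

#' Summarise recovery time constants across replicates
#'
#' @param fits a list of `"photocycle_fit"` objects (one per replicate).
#' @return A one-row data frame: `tau_mean` (hr), `tau_sd` (sample sd across
#'   replicates, `NA` with fewer than 2 replicates), `k_mean` (hr^-1), `n`.
#' @examples
#' # tau = {1.3, 1.4, 1.5} -> mean 1.4, sd 0.1
#' @export
summarize_replicates <- function(fits) {
  if (inherits(fits, "photocycle_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fits to summarise")
  if (!all(ok))
    warning(sum(!ok), " non-converged fit(s) excluded from the summary")
  taus <- vapply(fits[ok], `[[`, numeric(1), "tau")
  ks <- vapply(fits[ok], `[[`, numeric(1), "k")
  n <- sum(ok)
  data.frame(tau_mean = mean(taus),
             tau_sd = if (n >= 2L) stats::sd(taus) else NA_real_,
             k_mean = mean(ks),
             n = n)
}
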