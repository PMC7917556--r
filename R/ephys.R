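## Patch-clamp derived quantities: calcium charge, capacitance change, pool
## dynamics, and synaptic-vesicle unit conversions.

#' Calcium charge of a depolarization step
#'
#' Trapezoidal time integral of the leak-subtracted current over the stimulus
#' window; the sign of the current is preserved (inward current negative).
#'
#' @param time_s sample times, s.
#' @param current_pA current trace, pA.
#' @param stim_window_s length-2 numeric `(start, end)` in seconds.
#' @param leak_pA constant leak or leak trace (default 0: already
#'   leak-corrected upstream, e.g. by a p/10 protocol).
#' @param magnitude return `abs(Q)` when TRUE.
#' @return charge in pC.
#' @export
qca <- function(time_s, current_pA, stim_window_s, leak_pA = 0,
                magnitude = FALSE) {
  if (stim_window_s[1] < min(time_s) || stim_window_s[2] > max(time_s))
    stop("window error: stimulus window outside trace")
  sel <- time_s >= stim_window_s[1] & time_s <= stim_window_s[2]
  q <- pracma::trapz(time_s[sel],
                     (current_pA - leak_pA)[sel]) # pA * s = pC
  if (magnitude) abs(q) else q
}

#' Capacitance change evoked by a depolarization
#'
#' Difference between the average membrane capacitance over 400 ms after and
#' 400 ms before the depolarization, skipping the first 100 ms after it
#' (capacitance estimates immediately after a depolarization are contaminated
#' by conductance transients).
#'
#' @param time_s sample times, s.
#' @param cm_fF capacitance trace, fF (may contain NA during the stimulus).
#' @param stim_window_s length-2 numeric `(start, end)` in seconds.
#' @param pre_s,post_s,skip_s averaging windows (defaults 0.4, 0.4, 0.1 s).
#' @return capacitance jump in fF.
#' @export
delta_cm <- function(time_s, cm_fF, stim_window_s,
                     pre_s = 0.4, post_s = 0.4, skip_s = 0.1) {
  if (stim_window_s[1] - pre_s < min(time_s) ||
      stim_window_s[2] + skip_s + post_s > max(time_s))
    stop("margin error: need ", pre_s, " s before and ", skip_s + post_s,
         " s after the depolarization")
  pre <- time_s >= stim_window_s[1] - pre_s & time_s < stim_window_s[1]
  post <- time_s >= stim_window_s[2] + skip_s &
    time_s < stim_window_s[2] + skip_s + post_s
  mean(cm_fF[post], na.rm = TRUE) - mean(cm_fF[pre], na.rm = TRUE)
}

#' Fit pool-depletion dynamics to responses over stimulus durations
#'
#' Least-squares fit of `RRP * (1 - exp(-t/tau)) + slope * t` to cumulative
#' responses (capacitance jumps or glutamate-signal areas) measured for
#' different depolarization durations. The exponential component is the
#' depletion of the readily releasable pool; the linear component the
#' sustained (replenishment-limited) release.
#'
#' @param durations_ms stimulus durations, ms (>= 4 distinct values).
#' @param responses responses in fF or a.u., same length.
#' @return object of class `pool_fit`: list with `rrp_size`, `tau_ms`,
#'   `slope_per_ms`, `r_squared`, `converged`.
#' @export
fit_pool <- function(durations_ms, responses) {
  if (length(unique(durations_ms)) < 4)
    stop("need >= 4 distinct stimulus durations")
  df <- data.frame(t = durations_ms, y = responses)
  # variable projection: the model is linear in (RRP, slope) given tau, so a
  # tau grid with non-negative linear least squares gives a robust start (and
  # a fallback when the degenerate linear limit defeats the full fit)
  varpro <- function() {
    taus <- exp(seq(log(0.5), log(4 * max(durations_ms)), length.out = 60))
    best <- NULL
    for (tau in taus) {
      X <- cbind(rrp = 1 - exp(-df$t / tau), slope = df$t)
      cf <- tryCatch(stats::coef(stats::lm.fit(X, df$y)),
                     error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      cf <- pmax(cf, 0)
      ssr <- sum((df$y - X %*% cf)^2)
      if (is.null(best) || ssr < best$ssr)
        best <- list(rrp = cf[["rrp"]], tau = tau, slope = cf[["slope"]],
                     ssr = ssr)
    }
    best
  }
  vp <- varpro()
  fit <- tryCatch({
    nf <- minpack.lm::nlsLM(
      y ~ rrp * (1 - exp(-t / tau)) + slope * t, data = df,
      start = list(rrp = if (!is.null(vp)) vp$rrp else max(df$y) / 2,
                   tau = if (!is.null(vp)) vp$tau
                         else max(min(durations_ms), 5),
                   slope = if (!is.null(vp)) vp$slope
                           else max(df$y) / max(df$t) / 2),
      lower = c(0, 1e-3, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(nf)
    pred <- stats::predict(nf)
    list(rrp_size = unname(cf["rrp"]), tau_ms = unname(cf["tau"]),
         slope_per_ms = unname(cf["slope"]), ssr = sum((df$y - pred)^2))
  }, error = function(e) NULL)
  if (is.null(fit) || (!is.null(vp) && vp$ssr < fit$ssr))
    fit <- if (is.null(vp)) NULL else
      list(rrp_size = vp$rrp, tau_ms = vp$tau, slope_per_ms = vp$slope,
           ssr = vp$ssr)
  out <- if (is.null(fit)) {
    list(rrp_size = NA_real_, tau_ms = NA_real_, slope_per_ms = NA_real_,
         r_squared = NA_real_, converged = FALSE)
  } else {
    sst <- sum((df$y - mean(df$y))^2)
    list(rrp_size = fit$rrp_size, tau_ms = fit$tau_ms,
         slope_per_ms = fit$slope_per_ms,
         r_squared = if (sst > 0) 1 - fit$ssr / sst else NA_real_,
         converged = TRUE)
  }
  class(out) <- "pool_fit"
  out
}

#' Convert responses and rates to synaptic-vesicle units
#'
#' Conversions between capacitance, glutamate-signal area and vesicle counts
#' using the standard constants: ~40 aF of membrane per vesicle, ~12 active
#' zones per cell, and 0.23 a.u. of glutamate-signal area per vesicle.
#'
#' @param value numeric value to convert.
#' @param units `"fF_per_s"` (whole-cell capacitance rate -> SV/s per AZ),
#'   `"au_per_s"` (single-synapse area rate -> SV/s per AZ), or `"au"`
#'   (area -> SV count).
#' @param aF_per_sv,n_az,au_per_sv conversion constants.
#' @param round_result round to the nearest integer for reporting.
#' @return converted value (SV/s per AZ or SV).
#' @examples
#' sv_convert(242, "fF_per_s", round_result = TRUE)   # 504 SV/s per AZ
#' sv_convert(42.7, "au_per_s")                       # ~185.7 SV/s per AZ
#' @export
sv_convert <- function(value, units = c("fF_per_s", "au_per_s", "au"),
                       aF_per_sv = 40, n_az = 12, au_per_sv = 0.23,
                       round_result = FALSE) {
  units <- match.arg(units)
  if (aF_per_sv <= 0 || n_az <= 0 || au_per_sv <= 0)
    stop("conversion constants must be positive")
  out <- switch(units,
    fF_per_s = value * 1000 / aF_per_sv / n_az,
    au_per_s = value / au_per_sv,
    au = value / au_per_sv)
  if (round_result) round(out) else out
}
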