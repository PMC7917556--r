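## Fluorescence-voltage fitting: Boltzmann voltage dependence of release,
## driving-force-modified Boltzmann of synaptic calcium influx, fractional
## activation, descriptors (threshold, dynamic range) and the power-law
## calcium cooperativity of release.

r2_gate_default <- 0.7

# modified Boltzmann averaged over the voltage span of one frame exposure
ca_fv_model_avg <- function(V, F0, gmax, vh, k, v_r, exposure_mV) {
  if (exposure_mV <= 0)
    return(ca_fv_curve(V, F0, gmax, vh, k, v_r))
  off <- (c(1, 3, 5, 7, 9) / 10 - 0.5) * exposure_mV
  out <- 0
  for (o in off) out <- out + ca_fv_curve(V + o, F0, gmax, vh, k, v_r)
  out / length(off)
}

r_squared <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((y - pred)^2) / sst
}

#' Fit a Boltzmann activation curve to release responses
#'
#' Fits `1 / (1 + exp((V1/2 - V)/k))` to responses normalized to their
#' maximum, estimating the half-activation voltage and slope factor; the
#' threshold `V10 = V1/2 - k ln 9` and the 10-90% dynamic range `k ln 81`
#' follow in closed form. Fits with R^2 at or below the acceptance gate are
#' flagged excluded.
#'
#' @param V step potentials, mV (>= 5 values spanning the rise).
#' @param auc responses (normalized internally when `normalize = TRUE`).
#' @param normalize divide by the maximum before fitting (default TRUE).
#' @param r2_gate acceptance gate on R^2 (default 0.7).
#' @return object of class `boltzmann_fit`: `v_half_mV`, `k_mV`, `amplitude`,
#'   `v10_mV`, `v90_mV`, `dynamic_range_mV`, `r_squared`, `n_points`,
#'   `excluded`, `converged`.
#' @export
fit_release_boltzmann <- function(V, auc, normalize = TRUE,
                                  r2_gate = r2_gate_default) {
  if (length(V) < 5) stop("need >= 5 voltage points")
  y <- if (normalize) auc / max(auc) else auc
  # initialize V1/2 at the half-maximum crossing
  v_init <- tryCatch(stats::approx(y, V, xout = max(y) / 2,
                                   ties = "ordered")$y,
                     error = function(e) NA_real_)
  if (!is.finite(v_init)) v_init <- stats::median(V)
  fit <- tryCatch({
    nf <- minpack.lm::nlsLM(
      y ~ 1 / (1 + exp((vh - V) / k)),
      data = data.frame(y = y, V = V),
      start = list(vh = v_init, k = 5),
      lower = c(min(V) - 50, 0.1), upper = c(max(V) + 50, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(nf)
    r2 <- r_squared(y, stats::predict(nf))
    d <- boltzmann_descriptors(cf[["vh"]], cf[["k"]])
    list(v_half_mV = cf[["vh"]], k_mV = cf[["k"]], amplitude = 1,
         v10_mV = d[["v10"]], v90_mV = d[["v90"]],
         dynamic_range_mV = d[["dynamic_range"]],
         r_squared = r2, n_points = length(V),
         excluded = !is.na(r2) && r2 <= r2_gate, converged = TRUE)
  }, error = function(e) {
    list(v_half_mV = NA_real_, k_mV = NA_real_, amplitude = NA_real_,
         v10_mV = NA_real_, v90_mV = NA_real_, dynamic_range_mV = NA_real_,
         r_squared = NA_real_, n_points = length(V),
         excluded = TRUE, converged = FALSE)
  })
  class(fit) <- "boltzmann_fit"
  fit
}

#' Fit the driving-force-modified Boltzmann to a calcium FV relation
#'
#' Fits `F(V) = F0 + g_max (V - V_r) / (1 + exp((V1/2 - V)/k))` to a ramp
#' fluorescence-voltage relation with the reversal potential fixed (+47.6 mV
#' after liquid-junction correction; never fitted). The fractional activation
#' curve is obtained by dividing the fitted curve's deviation from baseline by
#' the extrapolated driving-force line `g_max (V - V_r)`, and a plain
#' Boltzmann is refitted to it to report `v_half_pact` and `k_pact`.
#'
#' With the sign convention used throughout, `g_max < 0` gives a
#' positive-going fluorescence change below `V_r`; a fitted `g_max > 0` is
#' sign-normalized with a warning.
#'
#' @param V ramp command voltages per frame, mV (mid-exposure values).
#' @param F fluorescence (raw or dF/F0) per frame.
#' @param v_r_mV fixed reversal potential (default 47.6).
#' @param r2_gate acceptance gate on R^2.
#' @param exposure_mV voltage span swept during one frame exposure (ramp
#'   rate x exposure time). When > 0 the fitted model is averaged over this
#'   span, removing the slope-factor broadening that frame integration
#'   otherwise causes (10 mV per frame at 100 Hz and 1 mV/ms).
#' @return object of class `mod_boltzmann_fit`: `F0`, `g_max`, `v_half_mV`,
#'   `k_mV`, `v_r_mV`, `r_squared`, `excluded`, `converged`, `no_signal`, and
#'   `fractional` (nested `boltzmann_fit` with `v_half_pact`/`k_pact`).
#' @export
fit_ca_fv <- function(V, F, v_r_mV = 47.6, r2_gate = r2_gate_default,
                      exposure_mV = 0) {
  ok <- is.finite(V) & is.finite(F)
  V <- V[ok]; F <- F[ok]
  if (length(V) < 8) stop("need >= 8 ramp samples")
  f0_init <- mean(F[V <= stats::quantile(V, 0.15)])
  # crude gain from the depolarized limb where activation ~ 1
  hi <- V >= stats::quantile(V, 0.8)
  g_init <- sum((F[hi] - f0_init) * (V[hi] - v_r_mV)) /
    sum((V[hi] - v_r_mV)^2)
  if (!is.finite(g_init) || g_init == 0) g_init <- -0.01
  # V1/2 init from the half-rise of the rising limb
  dev <- F - f0_init
  pk <- which.max(abs(dev))
  vh_rise <- tryCatch({
    rise <- seq_len(pk)
    stats::approx(dev[rise] / dev[pk], V[rise], xout = 0.5,
                  ties = "ordered")$y
  }, error = function(e) NA_real_)
  starts <- expand.grid(
    vh = unique(c(if (is.finite(vh_rise)) vh_rise, -50, -40, -30, -20)),
    k = c(4, 8))
  fit <- tryCatch({
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      nf_try <- tryCatch(minpack.lm::nlsLM(
        F ~ ca_fv_model_avg(V, F0, gmax, vh, k, v_r_mV, exposure_mV),
        data = data.frame(F = F, V = V),
        start = list(F0 = f0_init, gmax = g_init,
                     vh = starts$vh[s], k = starts$k[s]),
        lower = c(-Inf, -Inf, min(V) - 20, 0.1),
        upper = c(Inf, Inf, max(V), 60),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
        error = function(e) NULL)
      if (!is.null(nf_try) &&
          (is.null(best) || stats::deviance(nf_try) < stats::deviance(best)))
        best <- nf_try
    }
    if (is.null(best)) stop("no start converged")
    nf <- best
    cf <- stats::coef(nf)
    r2 <- r_squared(F, stats::predict(nf))
    pred <- stats::predict(nf)
    resid_sd <- stats::sd(F - pred)
    no_signal <- diff(range(pred)) <=
      max(2 * resid_sd, 1e-8 * max(abs(F), 1))
    gmax <- cf[["gmax"]]
    if (gmax > 0) {
      if (!no_signal)
        warning("fitted g_max > 0 is inconsistent with positive dF below ",
                "V_r; sign normalized")
      gmax <- -gmax
    }
    list(F0 = cf[["F0"]], g_max = gmax, v_half_mV = cf[["vh"]],
         k_mV = cf[["k"]], v_r_mV = v_r_mV, r_squared = r2,
         excluded = !is.na(r2) && r2 <= r2_gate,
         converged = TRUE, no_signal = no_signal)
  }, error = function(e) {
    list(F0 = NA_real_, g_max = NA_real_, v_half_mV = NA_real_,
         k_mV = NA_real_, v_r_mV = v_r_mV, r_squared = NA_real_,
         excluded = TRUE, converged = FALSE, no_signal = TRUE)
  })
  if (fit$converged && !fit$no_signal) {
    vg <- seq(min(V), min(max(V), v_r_mV - 5), by = 1)
    pact <- fractional_activation(fit, vg)
    bf <- fit_release_boltzmann(vg, pact, normalize = FALSE,
                                r2_gate = r2_gate)
    fit$fractional <- list(v_half_pact = bf$v_half_mV, k_pact = bf$k_mV,
                           r_squared = bf$r_squared)
  } else {
    fit$fractional <- list(v_half_pact = NA_real_, k_pact = NA_real_,
                           r_squared = NA_real_)
  }
  class(fit) <- "mod_boltzmann_fit"
  fit
}

#' Fractional activation from a modified Boltzmann fit
#'
#' The fitted curve minus baseline, divided by the extrapolated driving-force
#' line `g_max (V - V_r)`; equals the sigmoidal activation factor and lies in
#' `[0, 1]` over the fitted range.
#'
#' @param fit a `mod_boltzmann_fit`.
#' @param V voltages, mV (should stay below `v_r_mV`).
#' @return fractional activation values.
#' @export
fractional_activation <- function(fit, V) {
  line <- fit$g_max * (V - fit$v_r_mV)
  curve <- fit$g_max * (V - fit$v_r_mV) *
    boltzmann_activation(V, fit$v_half_mV, fit$k_mV)
  curve / line
}

#' Peak calcium signal from a ramp-aligned trace
#'
#' Mean of the frames whose command voltage falls in the given window
#' (default -17 to +3 mV, the top of the calcium influx-voltage relation).
#'
#' @param F fluorescence per frame (typically dF/F0).
#' @param V command voltage per frame, mV (NA outside the ramp).
#' @param window_mV length-2 voltage window.
#' @return mean fluorescence over the in-window frames.
#' @export
rhodff_peak <- function(F, V, window_mV = c(-17, 3)) {
  sel <- is.finite(V) & V >= window_mV[1] & V <= window_mV[2]
  if (!any(sel)) stop("window error: no frames in the voltage window")
  mean(F[sel])
}

#' Apparent calcium cooperativity of release
#'
#' Evaluates the fitted calcium and release curves on a common voltage grid
#' (default -57 to -17 mV in 1 mV steps), normalizes both to their grid
#' maximum, restricts to grid points where release does not exceed the given
#' fraction of its maximum (default 25%, avoiding pool-depletion saturation),
#' and fits the power function `A x^m` by least squares in linear space. The
#' log-log regression slope provides the initial value.
#'
#' @param ca_fit a `mod_boltzmann_fit` (synaptic calcium) OR a function of V
#'   returning the calcium-signal curve (e.g. a whole-cell charge fit).
#' @param rel_fit a `boltzmann_fit` for release.
#' @param grid_mV voltage grid.
#' @param cutoff release cutoff as a fraction of the grid maximum.
#' @param r2_gate acceptance gate on R^2.
#' @return object of class `cooperativity_fit`: `m`, `A`, `r_squared`,
#'   `n_points`, `excluded`, `converged`, `source`.
#' @export
cooperativity <- function(ca_fit, rel_fit, grid_mV = seq(-57, -17, by = 1),
                          cutoff = 0.25, r2_gate = r2_gate_default) {
  ca <- if (is.function(ca_fit)) {
    ca_fit(grid_mV)
  } else {
    stopifnot(inherits(ca_fit, "mod_boltzmann_fit"))
    ca_signal(grid_mV, ca_fit$g_max, ca_fit$v_half_mV, ca_fit$k_mV,
              ca_fit$v_r_mV)
  }
  rel <- boltzmann_activation(grid_mV, rel_fit$v_half_mV, rel_fit$k_mV)
  ca <- ca / max(ca)
  rel <- rel / max(rel)
  sel <- rel <= cutoff
  if (sum(sel) < 3)
    stop("insufficient-range error: < 3 grid points below the release cutoff")
  x <- ca[sel]; y <- rel[sel]
  pos <- x > 0 & y > 0
  ll <- stats::lm(log(y[pos]) ~ log(x[pos]))
  m_init <- unname(stats::coef(ll)[2])
  a_init <- exp(unname(stats::coef(ll)[1]))
  fit <- tryCatch({
    nf <- minpack.lm::nlsLM(y ~ A * x^m, data = data.frame(x = x, y = y),
                            start = list(A = a_init, m = max(m_init, 0.1)),
                            lower = c(1e-12, 0.01),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(nf)
    r2 <- r_squared(y, stats::predict(nf))
    list(m = cf[["m"]], A = cf[["A"]], r_squared = r2,
         n_points = sum(sel),
         excluded = !is.na(r2) && r2 <= r2_gate, converged = TRUE,
         source = if (is.function(ca_fit)) "whole_cell_QCa" else "synaptic_Ca")
  }, error = function(e) {
    list(m = NA_real_, A = NA_real_, r_squared = NA_real_,
         n_points = sum(sel), excluded = TRUE, converged = FALSE,
         source = if (is.function(ca_fit)) "whole_cell_QCa" else "synaptic_Ca")
  })
  class(fit) <- "cooperativity_fit"
  fit
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann fit: V1/2 = %.2f mV, k = %.2f mV (V10 = %.2f, DR = %.2f), R2 = %.3f%s\n",
    x$v_half_mV, x$k_mV, x$v10_mV, x$dynamic_range_mV, x$r_squared,
    if (isTRUE(x$excluded)) " [excluded]" else ""))
  invisible(x)
}

#' @export
print.mod_boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Modified Boltzmann fit: V1/2 = %.2f mV, k = %.2f mV, g_max = %.3g, F0 = %.3g (V_r fixed %.1f), R2 = %.3f\n",
    x$v_half_mV, x$k_mV, x$g_max, x$F0, x$v_r_mV, x$r_squared))
  invisible(x)
}

#' @export
print.cooperativity_fit <- function(x, ...) {
  cat(sprintf("Cooperativity fit: m = %.2f (A = %.3g), R2 = %.3f, %d points%s\n",
              x$m, x$A, x$r_squared, x$n_points,
              if (isTRUE(x$excluded)) " [excluded]" else ""))
  invisible(x)
}
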