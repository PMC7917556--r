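## Closed-form building blocks of the forward model. These are shared by the
## synthetic-data generator, the fitting oracles in the test suite, and the
## acceptance script; keeping them exported makes every downstream fit
## verifiable against the exact curves it is supposed to recover.

#' Boltzmann activation curve
#'
#' Sigmoidal open probability \eqn{P(V) = 1 / (1 + exp((V_{1/2} - V)/k))}.
#'
#' @param V membrane potential(s), mV.
#' @param v_half half-activation voltage, mV.
#' @param k slope factor, mV (> 0).
#' @return activation in (0, 1).
#' @export
boltzmann_activation <- function(V, v_half, k) {
  1 / (1 + exp((v_half - V) / k))
}

#' Driving-force-modified Boltzmann fluorescence-voltage curve
#'
#' The calcium-indicator fluorescence at an active zone during a voltage ramp:
#' \eqn{F(V) = F_0 + g_{max} (V - V_r) P(V)}. With the sign convention
#' `g_max < 0`, the fluorescence change is positive for potentials below the
#' reversal potential `v_r`.
#'
#' @param V membrane potential(s), mV.
#' @param F0 baseline fluorescence, a.u.
#' @param g_max signed gain, a.u./mV (negative by convention).
#' @param v_half,k Boltzmann parameters, mV.
#' @param v_r reversal potential, mV (fixed at +47.6 in the analysis).
#' @return fluorescence, a.u.
#' @export
ca_fv_curve <- function(V, F0, g_max, v_half, k, v_r = 47.6) {
  F0 + g_max * (V - v_r) * boltzmann_activation(V, v_half, k)
}

#' Synaptic calcium signal (fluorescence change above baseline)
#'
#' The hot-spot signal \eqn{\Delta Ca(V) = g_{max}(V - V_r) P(V)}, i.e.
#' [ca_fv_curve()] minus its baseline. With the convention `g_max < 0` the
#' signal is positive below `v_r` (both factors negative).
#'
#' @inheritParams ca_fv_curve
#' @return calcium signal, a.u. (>= 0 for V <= v_r when g_max < 0).
#' @export
ca_signal <- function(V, g_max, v_half, k, v_r = 47.6) {
  g_max * (V - v_r) * boltzmann_activation(V, v_half, k)
}

#' Instantaneous release rate under the power-law coupling model
#'
#' \eqn{\lambda(V) = r_0 (\Delta Ca(V)/\Delta Ca_{ref})^m}: the rate of
#' readily-releasable-pool consumption scales as the m-th power of the local
#' calcium signal, referenced to the signal at `v_ref`.
#'
#' @param V membrane potential(s), mV.
#' @param syn one ground-truth synapse record (a one-row data.frame or list
#'   with fields `g_max`, `v_half_ca`, `k_ca`, `m`, `rate_scale_per_ms`).
#' @param v_r reversal potential, mV.
#' @param v_ref reference potential for the calcium signal, mV.
#' @return rate in 1/ms.
#' @export
release_rate <- function(V, syn, v_r = 47.6, v_ref = -17) {
  ca <- ca_signal(V, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  ca_ref <- ca_signal(v_ref, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  syn$rate_scale_per_ms * (pmax(ca, 0) / ca_ref)^syn$m
}

#' Cumulative glutamate release for a step depolarization
#'
#' Closed form of the pool model driving the glutamate channel:
#' \deqn{Q(V, T) = RRP (1 - e^{-\lambda(V) T}) + s(V) T}
#' with \eqn{\lambda(V)} from [release_rate()] and the sustained rate
#' \eqn{s(V) = s_0 (\Delta Ca/\Delta Ca_{ref})^m} carrying the same power-law
#' calcium dependence (sustained release is calcium-driven replenishment; a
#' calcium-independent floor would mask the power relation at the foot of the
#' activation curve).
#'
#' @param V step potential(s), mV.
#' @param T_ms step duration, ms.
#' @param syn ground-truth synapse record (needs additionally `rrp_size_au`,
#'   `sustained_rate_au_per_s`).
#' @inheritParams release_rate
#' @return released amount, a.u.
#' @export
cumulative_release <- function(V, T_ms, syn, v_r = 47.6, v_ref = -17) {
  lam <- release_rate(V, syn, v_r, v_ref)          # 1/ms
  ca <- ca_signal(V, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  ca_ref <- ca_signal(v_ref, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  s <- syn$sustained_rate_au_per_s / 1000 * (pmax(ca, 0) / ca_ref)^syn$m
  syn$rrp_size_au * (1 - exp(-lam * T_ms)) + s * T_ms
}

#' Double-exponential indicator impulse response
#'
#' \eqn{g(t) = A (1 - e^{-t/\tau_{on}}) e^{-t/\tau_{off}}} for t >= 0.
#' With `normalize = "area"` the curve is scaled to unit time integral so that
#' the rendered trace integrates to the released amount; with
#' `normalize = "none"` A = 1.
#'
#' @param t_ms times from release onset, ms.
#' @param tau_on_ms,tau_off_ms rise and decay time constants, ms.
#' @param normalize `"none"` or `"area"`.
#' @return kernel values.
#' @export
indicator_kernel <- function(t_ms, tau_on_ms, tau_off_ms,
                             normalize = c("none", "area")) {
  normalize <- match.arg(normalize)
  g <- ifelse(t_ms < 0, 0,
              (1 - exp(-t_ms / tau_on_ms)) * exp(-t_ms / tau_off_ms))
  if (normalize == "area") {
    # integral of (1 - e^(-t/a)) e^(-t/b) over [0, Inf) = b - ab/(a+b)
    area <- tau_off_ms -
      tau_on_ms * tau_off_ms / (tau_on_ms + tau_off_ms)
    g <- g / area
  }
  g
}

#' Closed-form time to peak of the indicator response
#'
#' \eqn{t_{peak} = \tau_{on} \ln(\tau_{off}/\tau_{on} + 1)}.
#'
#' @param tau_on_ms,tau_off_ms time constants, ms.
#' @return time to peak, ms.
#' @export
time_to_peak <- function(tau_on_ms, tau_off_ms) {
  tau_on_ms * log(tau_off_ms / tau_on_ms + 1)
}

#' Closed-form Boltzmann descriptors
#'
#' Threshold voltage (10% activation) `v10 = v_half - k ln 9` and 10-90%
#' dynamic range `k ln 81` of a Boltzmann activation curve.
#'
#' @param v_half,k Boltzmann parameters, mV.
#' @return named numeric vector with `v10`, `v90`, `dynamic_range`.
#' @export
boltzmann_descriptors <- function(v_half, k) {
  c(v10 = v_half - k * log(9),
    v90 = v_half + k * log(9),
    dynamic_range = k * log(81))
}
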