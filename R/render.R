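## Rendering of ground-truth experiments: two-channel movie stacks and
## synthetic patch-clamp traces with the statistical structure the analysis
## assumes (Boltzmann-gated calcium influx with driving force, power-law
## release with pool depletion, indicator on/off kinetics, photobleaching,
## a 33.3 Hz spinning-disk artifact, shot and read noise).

# unit-peak 2-D Gaussian spot as a ny x nx matrix
gaussian_spot <- function(nx, ny, x0, y0, sigma) {
  gx <- exp(-((seq_len(nx) - x0)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(ny) - y0)^2) / (2 * sigma^2))
  outer(gy, gx)
}

# smoothed elliptical cell-body mask (baseline fluorescence of the cell)
cell_body_image <- function(ellipse, nx, ny, blur_sigma = 2) {
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  ca <- cos(ellipse$angle_rad); sa <- sin(ellipse$angle_rad)
  u <- (xs - ellipse$center[["x"]]) * ca + (ys - ellipse$center[["y"]]) * sa
  v <- -(xs - ellipse$center[["x"]]) * sa + (ys - ellipse$center[["y"]]) * ca
  mask <- (u / ellipse$semi_major)^2 + (v / ellipse$semi_minor)^2 <= 1
  img <- matrix(0, ny, nx)
  img[mask] <- 1
  as.matrix(EBImage::gblur(img, sigma = blur_sigma))
}

# axial attenuation of an out-of-focus spot (Gaussian profile in z)
axial_attenuation <- function(dz_um, fwhm_um) {
  sigma <- fwhm_um / (2 * sqrt(2 * log(2)))
  exp(-dz_um^2 / (2 * sigma^2))
}

# add multiplicative 33.3 Hz artifact, shot noise and read noise to a movie.
# `fluor` is the bleach/artifact-prone fluorescent part; `offset` the camera
# offset added afterwards.
finish_movie <- function(fluor, offset, t_s, acq, phase, noise = TRUE) {
  nf <- dim(fluor)[3]
  mov <- if (noise && acq$artifact_amp > 0) {
    art <- 1 + acq$artifact_amp * sin(2 * pi * acq$artifact_Hz * t_s + phase)
    sweep(fluor, 3, art, "*")
  } else fluor
  mov <- mov + offset
  mov[mov < 0] <- 0
  if (noise) {
    if (acq$shot_gain > 0)
      mov <- mov + stats::rnorm(length(mov), 0,
                                sqrt(acq$shot_gain * mov))
    if (acq$read_sd > 0)
      mov <- mov + stats::rnorm(length(mov), 0, acq$read_sd)
    mov[mov < 0] <- 0
  }
  mov
}

#' Render a ground-truth experiment into a movie bundle
#'
#' Renders one channel of the experiment according to the protocol kind:
#' a ramp protocol produces the calcium channel (Rhod-FF, 100 Hz, all planes;
#' hot-spot amplitude follows the driving-force-modified Boltzmann curve along
#' the ramp), a step protocol produces the glutamate channel (iGluSnFR, 50 Hz,
#' central plane; one movie per step level, with the cumulative-release signal
#' convolved with the indicator kernel and single-exponential photobleaching).
#' Both channels carry the 33.3 Hz illumination artifact plus shot and read
#' noise; out-of-focus planes attenuate spots by a Gaussian axial profile.
#'
#' @param gt a [sample_ground_truth()] object.
#' @param protocol a [make_protocol()] object.
#' @param seed integer seed for the noise draw.
#' @param noise logical; `FALSE` renders the noiseless expectation
#'   (no artifact, shot or read noise, used by oracles).
#' @param n_post_frames frames rendered after stimulus onset for step movies.
#' @return object of class `recording_bundle`. For ramps: `movies` is a list
#'   of per-plane arrays `[row, col, frame]`, `frame_voltage_mV` maps frames to
#'   mid-exposure command voltage. For steps: `movies` is a list per level (in
#'   protocol presentation order), each with the same geometry. Both carry
#'   `rate_Hz`, `stim_onset_frame`, `timestamps_s`, `protocol`, `acq`.
#' @export
render_movie <- function(gt, protocol, seed = 1L, noise = TRUE,
                         n_post_frames = 55) {
  stopifnot(inherits(gt, "ground_truth"),
            inherits(protocol, "voltage_protocol"))
  acq <- gt$cell
  if (acq$read_sd < 0 || acq$shot_gain < 0)
    stop("parameter error: negative noise parameters")
  nx <- ny <- acq$frame_px
  syn <- gt$synapses
  if (nrow(syn) > 0 &&
      (any(syn$hotspot_x < 1 | syn$hotspot_x > nx) ||
       any(syn$hotspot_y < 1 | syn$hotspot_y > ny)))
    stop("generation error: hot spot outside frame")
  spots <- lapply(seq_len(nrow(syn)), function(i)
    gaussian_spot(nx, ny, syn$hotspot_x[i], syn$hotspot_y[i],
                  acq$spot_sigma_px))
  cellimg <- cell_body_image(gt$ellipse, nx, ny)

  withr::with_seed(seed, {
    if (protocol$kind == "ramp") {
      render_ramp_bundle(gt, protocol, acq, spots, cellimg, noise)
    } else {
      render_step_bundle(gt, protocol, acq, spots, cellimg, noise,
                         n_post_frames)
    }
  })
}

render_ramp_bundle <- function(gt, protocol, acq, spots, cellimg, noise) {
  nx <- ny <- acq$frame_px
  syn <- gt$synapses
  rate <- acq$rate_rhod_Hz
  nb <- acq$baseline_frames
  n_ramp <- ceiling(protocol$ramp_duration_ms / 1000 * rate)
  nf <- nb + n_ramp + 10L
  t_s <- (seq_len(nf) - 0.5) / rate                   # mid-exposure times
  t_stim_ms <- (t_s - nb / rate) * 1000               # from ramp onset
  # mid-exposure command voltage (NA outside the ramp)
  v_mid <- ramp_voltage_at(protocol, t_stim_ms)
  v_mid[t_stim_ms < 0 | t_stim_ms > protocol$ramp_duration_ms] <- NA_real_

  # per-frame hot-spot amplitude: exposure-averaged calcium signal
  sub <- 5L
  amp <- matrix(0, nf, max(nrow(syn), 1))
  for (i in seq_len(nrow(syn))) {
    for (k in seq_len(nf)) {
      tt <- ((k - 1) + (seq_len(sub) - 0.5) / sub) / rate
      vv <- ramp_voltage_at(protocol, (tt - nb / rate) * 1000)
      amp[k, i] <- mean(ca_signal(vv, syn$g_max[i], syn$v_half_ca[i],
                                  syn$k_ca[i], acq$v_r_mV))
    }
  }

  movies <- vector("list", acq$n_planes)
  phase <- stats::runif(1, 0, 2 * pi)
  for (p in seq_len(acq$n_planes)) {
    fluor <- array(rep(acq$cell_f0 * cellimg, nf), c(ny, nx, nf))
    for (i in seq_len(nrow(syn))) {
      dz <- (p - syn$plane_index[i]) * acq$plane_spacing_um
      att <- axial_attenuation(dz, acq$axial_fwhm_um)
      if (att < 1e-4) next
      fluor <- fluor + outer(spots[[i]], att * amp[, i])
    }
    movies[[p]] <- finish_movie(fluor, acq$bg_level, t_s, acq, phase,
                                noise = noise)
  }
  structure(list(channel = "rhod", movies = movies, rate_Hz = rate,
                 stim_onset_frame = nb + 1L, timestamps_s = t_s,
                 frame_voltage_mV = v_mid, protocol = protocol, acq = acq,
                 ground_truth = gt),
            class = "recording_bundle")
}

render_step_bundle <- function(gt, protocol, acq, spots, cellimg, noise,
                               n_post_frames) {
  nx <- ny <- acq$frame_px
  syn <- gt$synapses
  rate <- acq$rate_iglu_Hz
  nb <- acq$baseline_frames
  nf <- nb + n_post_frames
  t_s <- (seq_len(nf) - 0.5) / rate
  t_stim_ms <- (t_s - nb / rate) * 1000
  central <- ceiling(acq$n_planes / 2)

  # baseline scene: boutons visible at rest (membrane-anchored sensor)
  base <- matrix(0, ny, nx)
  for (i in seq_len(nrow(syn))) base <- base + acq$bouton_f0 * spots[[i]]
  base <- base + 0.1 * acq$cell_f0 * cellimg   # faint cell outline crosstalk

  levels_run <- protocol$levels_mV[protocol$order]
  phase <- stats::runif(length(levels_run), 0, 2 * pi)
  bleach <- exp(-t_s / acq$bleach_tau_s)
  movies <- vector("list", length(levels_run))
  names(movies) <- sprintf("V%+d", round(levels_run))
  for (j in seq_along(levels_run)) {
    V <- levels_run[j]
    fluor <- array(rep(base, nf), c(ny, nx, nf))
    for (i in seq_len(nrow(syn))) {
      dz <- (central - syn$plane_index[i]) * acq$plane_spacing_um
      att <- axial_attenuation(dz, acq$axial_fwhm_um)
      resp <- release_response_trace(V, protocol$duration_ms, syn[i, ],
                                     t_stim_ms, acq$v_r_mV)
      fluor <- fluor + outer(spots[[i]], att * acq$iglu_gain * resp)
    }
    fluor <- sweep(fluor, 3, bleach, "*")
    movies[[j]] <- finish_movie(fluor, acq$bg_level, t_s, acq, phase[j],
                                noise = noise)
  }
  structure(list(channel = "iglu", movies = movies,
                 levels_mV = levels_run, rate_Hz = rate,
                 stim_onset_frame = nb + 1L, timestamps_s = t_s,
                 stim_duration_ms = protocol$duration_ms,
                 protocol = protocol, acq = acq, ground_truth = gt),
            class = "recording_bundle")
}

#' Noiseless glutamate-indicator response trace for one step
#'
#' Convolves the instantaneous release rate (pool depletion plus sustained
#' component) with the area-normalized indicator kernel, so that the time
#' integral of the returned trace equals the cumulative release
#' [cumulative_release()] as the sampling window grows.
#'
#' @param V step potential, mV.
#' @param T_ms step duration, ms.
#' @param syn one ground-truth synapse record.
#' @param t_ms sample times relative to stimulus onset, ms.
#' @param v_r reversal potential, mV.
#' @return response amplitude at `t_ms`, a.u. (zero before onset).
#' @export
release_response_trace <- function(V, T_ms, syn, t_ms, v_r = 47.6) {
  sub_dt <- 1                                      # ms
  tau <- seq(sub_dt / 2, T_ms, by = sub_dt)        # release times within step
  lam <- release_rate(V, syn, v_r)                 # 1/ms
  ca <- ca_signal(V, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  ca_ref <- ca_signal(-17, syn$g_max, syn$v_half_ca, syn$k_ca, v_r)
  s <- syn$sustained_rate_au_per_s / 1000 * (max(ca, 0) / ca_ref)^syn$m
  q_inc <- (syn$rrp_size_au * lam * exp(-lam * tau) + s) * sub_dt
  out <- numeric(length(t_ms))
  for (w in seq_along(tau)) {
    out <- out + q_inc[w] *
      indicator_kernel(t_ms - tau[w], syn$tau_on_ms, syn$tau_off_ms,
                       normalize = "area")
  }
  out
}

#' Synthesize patch-clamp traces for a ground-truth experiment
#'
#' Whole-cell current as the sum of per-synapse Boltzmann-gated conductances
#' times driving force, `I(t) = leak + sum_i g_i P_i(V) (V - V_r)` (pA, inward
#' negative), sampled at 10 kHz; membrane capacitance as baseline plus
#' cumulative release converted to fF, with white noise, sampled at 1 kHz.
#' The ground-truth calcium charge per step is returned in closed form.
#'
#' @param gt a [sample_ground_truth()] object.
#' @param protocol a step [make_protocol()] object.
#' @param seed integer seed.
#' @param leak_pA constant leak current, pA.
#' @param cm_baseline_fF resting membrane capacitance, fF.
#' @param cm_noise_fF white-noise SD on the capacitance trace, fF.
#' @param current_noise_pA white-noise SD on the current trace, pA.
#' @param aF_per_sv,au_per_sv,n_az vesicle-unit conversion constants.
#' @return object of class `ephys_traces`: per-level sweeps with `time_s`,
#'   `voltage_mV`, `current_pA` (10 kHz), `cm_time_s`, `cm_fF` (1 kHz),
#'   `stim_window_s`, plus `qca_true_pC` per level.
#' @export
synth_ephys <- function(gt, protocol, seed = 1L, leak_pA = -10,
                        cm_baseline_fF = 10000, cm_noise_fF = 2,
                        current_noise_pA = 3,
                        aF_per_sv = 40, au_per_sv = 0.23, n_az = 12) {
  stopifnot(inherits(gt, "ground_truth"), protocol$kind == "step")
  syn <- gt$synapses
  v_r <- gt$cell$v_r_mV
  rate <- 10000
  cm_rate <- 1000
  pre_s <- 0.5; post_s <- 0.7
  T_s <- protocol$duration_ms / 1000
  levels_run <- protocol$levels_mV[protocol$order]

  withr::with_seed(seed, {
    sweeps <- lapply(levels_run, function(V) {
      n <- round((pre_s + T_s + post_s) * rate)
      t_s <- (seq_len(n) - 0.5) / rate
      volt <- rep(protocol$holding_mV, n)
      stim <- t_s >= pre_s & t_s < pre_s + T_s
      volt[stim] <- V
      cur <- rep(leak_pA, n)
      for (i in seq_len(nrow(syn))) {
        p <- boltzmann_activation(volt, syn$v_half_ca[i], syn$k_ca[i])
        cur <- cur + syn$g_nS[i] * p * (volt - v_r)
      }
      if (current_noise_pA > 0)
        cur <- cur + stats::rnorm(n, 0, current_noise_pA)
      # capacitance trace: step up by the released membrane at stimulus end
      ncm <- round((pre_s + T_s + post_s) * cm_rate)
      cm_t <- (seq_len(ncm) - 0.5) / cm_rate
      dq_au <- sum(vapply(seq_len(nrow(syn)), function(i)
        cumulative_release(V, protocol$duration_ms, syn[i, ], v_r),
        numeric(1)))
      dcm_fF <- dq_au / au_per_sv * aF_per_sv / 1000
      cm <- cm_baseline_fF + ifelse(cm_t >= pre_s + T_s, dcm_fF, 0)
      # capacitance is not defined during the depolarization
      cm[cm_t >= pre_s & cm_t < pre_s + T_s] <- NA_real_
      if (cm_noise_fF > 0)
        cm <- cm + stats::rnorm(ncm, 0, cm_noise_fF)
      list(level_mV = V, time_s = t_s, voltage_mV = volt, current_pA = cur,
           cm_time_s = cm_t, cm_fF = cm,
           stim_window_s = c(pre_s, pre_s + T_s),
           dcm_true_fF = dcm_fF)
    })
    names(sweeps) <- sprintf("V%+d", round(levels_run))
    qca_true <- vapply(levels_run, function(V) {
      i_syn <- sum(syn$g_nS * boltzmann_activation(V, syn$v_half_ca,
                                                   syn$k_ca) * (V - v_r))
      i_syn * protocol$duration_ms / 1000   # pA * ms / 1000 = pC
    }, numeric(1))
    structure(list(sweeps = sweeps, levels_mV = levels_run,
                   rate_Hz = rate, cm_rate_Hz = cm_rate,
                   leak_pA = leak_pA, qca_true_pC = qca_true,
                   protocol = protocol),
              class = "ephys_traces")
  })
}
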