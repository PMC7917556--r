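#' Default per-cell acquisition and noise parameters
#'
#' The optical and noise constants of a rendered experiment: frame geometry,
#' indicator/camera noise, photobleaching, the 33.3 Hz spinning-disk
#' illumination artifact, cell-ellipse geometry, and the axial attenuation
#' profile. Defaults emulate spinning-disk imaging of an inner hair cell at
#' 103 nm pixel size with five planes spaced 0.5 um.
#'
#' @param frame_px frame side length in pixels (square frames).
#' @param pixel_size_nm pixel pitch, nm.
#' @param n_planes number of imaging planes for the calcium channel.
#' @param plane_spacing_um axial spacing between planes, um.
#' @param axial_fwhm_um FWHM of the Gaussian axial attenuation of an
#'   out-of-focus hot spot. The default 1.55 um reproduces a ~25% amplitude
#'   loss 0.5 um away from the optimal plane.
#' @param spot_sigma_px lateral Gaussian radius of a synaptic spot, px.
#' @param rate_iglu_Hz,rate_rhod_Hz frame rates of the two channels.
#' @param baseline_frames number of pre-stimulus frames rendered (and assumed
#'   by the analysis defaults).
#' @param cell_f0 baseline fluorescence of the cell body (calcium channel), a.u.
#' @param bouton_f0 baseline fluorescence of a sensor-expressing bouton, a.u.
#' @param iglu_gain pixel fluorescence change per unit instantaneous
#'   glutamate-indicator response (a.u. per a.u./ms); the default makes the
#'   peak dF/F0 at the strongest step approximately 1, as observed for this
#'   sensor.
#' @param bg_level camera offset / tissue background, a.u.
#' @param read_sd Gaussian read-noise SD, a.u.
#' @param shot_gain variance of shot noise per unit intensity
#'   (`var = shot_gain * intensity`); 0 disables shot noise.
#' @param bleach_tau_s photobleaching time constant of the glutamate channel, s.
#' @param artifact_amp relative amplitude of the 33.3 Hz illumination artifact.
#' @param artifact_Hz artifact frequency, Hz.
#' @param v_r_mV reversal potential of the calcium driving force, mV.
#' @return named list of acquisition parameters.
#' @export
default_acquisition <- function(frame_px = 96,
                                pixel_size_nm = 103,
                                n_planes = 5,
                                plane_spacing_um = 0.5,
                                axial_fwhm_um = 1.55,
                                spot_sigma_px = 4,
                                rate_iglu_Hz = 50,
                                rate_rhod_Hz = 100,
                                baseline_frames = 15,
                                cell_f0 = 80,
                                bouton_f0 = 60,
                                iglu_gain = 1500,
                                bg_level = 15,
                                read_sd = 1.5,
                                shot_gain = 0.02,
                                bleach_tau_s = 3,
                                artifact_amp = 0.01,
                                artifact_Hz = 100 / 3,
                                v_r_mV = 47.6) {
  as.list(environment())
}

#' Default pillar-modiolar gradient of calcium-channel voltage dependence
#'
#' The half-activation voltage of synaptic calcium influx is drawn as
#' `v_half_ca = intercept + slope * position + N(0, scatter)`, with position 0
#' at the pillar vertex and 1 at the modiolar vertex. The defaults place the
#' population mean at -41.15 mV with SD 5.7 mV (slope 8 mV per unit position
#' over uniform positions plus 5.2 mV residual scatter).
#'
#' @param slope_mV gradient slope, mV per unit position.
#' @param scatter_sd_mV residual SD around the gradient, mV.
#' @param intercept_mV value at position 0 (pillar), mV.
#' @return named list of gradient parameters.
#' @export
default_gradient <- function(slope_mV = 8,
                             scatter_sd_mV = 5.2,
                             intercept_mV = -45.15) {
  list(slope_mV = slope_mV, scatter_sd_mV = scatter_sd_mV,
       intercept_mV = intercept_mV)
}

#' Sample a ground-truth synapse population
#'
#' Draws per-synapse transfer-function parameters from the configured
#' distributions and lays the synapses out inside an elliptical cell at their
#' pillar-modiolar positions. The result is the reference against which the
#' pipeline's parameter recovery is measured.
#'
#' Per-synapse fields: `v_half_ca`, `k_ca` (mV), `g_max` (a.u./mV, negative),
#' `g_nS` (conductance for the synthetic whole-cell current), `m`
#' (cooperativity, >= 1), `rrp_size_au`, `tau_depletion_ms`,
#' `sustained_rate_au_per_s`, `rate_scale_per_ms`, `tau_on_ms`, `tau_off_ms`,
#' `position_01`, `hotspot_x`, `hotspot_y` (px), `plane_index` (1-based).
#'
#' @param n_synapses number of synapses (>= 1).
#' @param gradient list from [default_gradient()].
#' @param acq list from [default_acquisition()] (fixes frame geometry).
#' @param seed integer seed; the draw is bit-reproducible.
#' @return object of class `ground_truth`: list with `synapses` (data.frame),
#'   `ellipse` (center, semi-axes, angle, pillar side), and `cell`
#'   (per-cell optics/noise constants copied from `acq`).
#' @export
sample_ground_truth <- function(n_synapses,
                                gradient = default_gradient(),
                                acq = default_acquisition(),
                                seed = 1L) {
  if (n_synapses < 1) stop("n_synapses must be >= 1")
  if (gradient$scatter_sd_mV < 0) stop("parameter error: negative scatter SD")
  withr::with_seed(seed, {
    pos <- stats::runif(n_synapses)
    v_half_ca <- gradient$intercept_mV + gradient$slope_mV * pos +
      stats::rnorm(n_synapses, 0, gradient$scatter_sd_mV)
    k_ca <- pmin(pmax(stats::rnorm(n_synapses, 5, 1), 2.5), 9)
    m <- 1 + stats::rlnorm(n_synapses, log(1.3), 0.55)
    g_max <- -stats::rlnorm(n_synapses, log(0.9), 0.3)
    g_nS <- stats::rlnorm(n_synapses, log(0.35), 0.3)
    rrp <- stats::rlnorm(n_synapses, log(2.3), 0.3)
    tau_dep <- stats::rlnorm(n_synapses, log(11.4), 0.25)
    sus <- stats::rlnorm(n_synapses, log(42.7), 0.3)
    tau_on <- stats::rlnorm(n_synapses, log(10), 0.2)
    tau_off <- stats::rlnorm(n_synapses, log(80), 0.2)

    # cell ellipse: major axis = pillar-modiolar axis, pillar at low-x vertex
    cx <- acq$frame_px / 2
    a <- 0.36 * acq$frame_px
    b <- 0.18 * acq$frame_px
    ang <- stats::runif(1, -0.25, 0.25)
    ellipse <- list(center = c(x = cx, y = cx),
                    semi_major = a, semi_minor = b,
                    angle_rad = ang, pillar = "left")

    # hot spots sit near the membrane at the synapse's axial position;
    # active zones keep a large nearest-neighbor distance (~2 um), so
    # positions are resampled until hot spots are >= 18 px apart
    place <- function(p, side) {
      u <- (p * 2 - 1) * 0.85 * a
      vmax <- 0.75 * b * sqrt(pmax(1 - (u / (0.9 * a))^2, 0))
      v <- side * vmax
      c(cx + u * cos(ang) - v * sin(ang),
        cx + u * sin(ang) + v * cos(ang))
    }
    side <- sample(c(-1, 1), n_synapses, replace = TRUE)
    hxy <- t(vapply(seq_len(n_synapses),
                    function(i) place(pos[i], side[i]), numeric(2)))
    if (n_synapses > 1) {
      for (tries in seq_len(100)) {
        dmin <- min(stats::dist(hxy))
        if (dmin >= 18) break
        i <- which(as.matrix(stats::dist(hxy)) == dmin,
                   arr.ind = TRUE)[1, 1]
        pos[i] <- stats::runif(1)
        side[i] <- sample(c(-1, 1), 1)
        v_half_ca[i] <- gradient$intercept_mV +
          gradient$slope_mV * pos[i] +
          stats::rnorm(1, 0, gradient$scatter_sd_mV)
        hxy[i, ] <- place(pos[i], side[i])
      }
    }
    hx <- hxy[, 1]; hy <- hxy[, 2]
    plane <- sample.int(acq$n_planes, n_synapses, replace = TRUE)

    syn <- data.frame(
      synapse_id = seq_len(n_synapses),
      v_half_ca = v_half_ca, k_ca = k_ca, m = m,
      g_max = g_max, g_nS = g_nS,
      rrp_size_au = rrp, tau_depletion_ms = tau_dep,
      sustained_rate_au_per_s = sus,
      # pool depletion at the reference potential (-17 mV) proceeds with
      # the synapse's own depletion time constant
      rate_scale_per_ms = 1 / tau_dep,
      tau_on_ms = tau_on, tau_off_ms = tau_off,
      position_01 = pos,
      hotspot_x = hx, hotspot_y = hy,
      plane_index = plane)

    out <- list(synapses = syn, ellipse = ellipse,
                cell = acq, seed = as.integer(seed))
    class(out) <- "ground_truth"
    out
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d synapses, frame %dx%d px, %d planes\n",
              nrow(x$synapses), x$cell$frame_px, x$cell$frame_px,
              x$cell$n_planes))
  cat(sprintf("  v_half_ca: mean %.2f mV (SD %.2f)\n",
              mean(x$synapses$v_half_ca), stats::sd(x$synapses$v_half_ca)))
  cat(sprintf("  m: median %.2f (range %.2f-%.2f)\n",
              stats::median(x$synapses$m), min(x$synapses$m),
              max(x$synapses$m)))
  invisible(x)
}
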