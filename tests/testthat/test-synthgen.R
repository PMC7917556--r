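test_that("ground-truth sampling is reproducible and respects invariants", {
  gt1 <- sample_ground_truth(55, seed = 7)
  gt2 <- sample_ground_truth(55, seed = 7)
  expect_identical(gt1, gt2)
  syn <- gt1$synapses
  expect_true(all(syn$k_ca > 0))
  expect_true(all(syn$m >= 1))
  expect_true(all(syn$rrp_size_au >= 0))
  expect_true(all(syn$position_01 >= 0 & syn$position_01 <= 1))
  # hot spots lie inside the cell ellipse
  e <- gt1$ellipse
  ca <- cos(e$angle_rad); sa <- sin(e$angle_rad)
  u <- (syn$hotspot_x - e$center[["x"]]) * ca +
    (syn$hotspot_y - e$center[["y"]]) * sa
  v <- -(syn$hotspot_x - e$center[["x"]]) * sa +
    (syn$hotspot_y - e$center[["y"]]) * ca
  expect_true(all((u / e$semi_major)^2 + (v / e$semi_minor)^2 <= 1))
  expect_error(sample_ground_truth(0), ">= 1")
  expect_error(sample_ground_truth(5, gradient = list(slope_mV = 0,
                                                      scatter_sd_mV = -1,
                                                      intercept_mV = -41)),
               "negative scatter")
})

test_that("the planted voltage-dependence gradient is recoverable by OLS", {
  # null gradient: no position correlation
  gt0 <- sample_ground_truth(200, gradient = default_gradient(slope_mV = 0,
                                                scatter_sd_mV = 5.2),
                             seed = 3)
  r0 <- cor(gt0$synapses$position_01, gt0$synapses$v_half_ca)
  expect_lt(abs(r0), 0.2)
  # slope 8 mV/unit with 2 mV scatter: OLS recovers it within its CI
  gt8 <- sample_ground_truth(200, gradient = default_gradient(slope_mV = 8,
                                                scatter_sd_mV = 2),
                             seed = 3)
  fit <- lm(v_half_ca ~ position_01, data = gt8$synapses)
  ci <- confint(fit)["position_01", ]
  expect_gt(8, ci[1]); expect_lt(8, ci[2])
  expect_lt(abs(coef(fit)[["position_01"]] - 8), 1.5)
})

test_that("rendered movies are seed-deterministic and an empty scene is flat", {
  acq <- default_acquisition(frame_px = 48, n_planes = 2,
                             bleach_tau_s = Inf)
  gt <- sample_ground_truth(1, acq = acq, seed = 5)
  ramp <- make_protocol("ramp")
  b1 <- render_movie(gt, ramp, seed = 9)
  b2 <- render_movie(gt, ramp, seed = 9)
  expect_identical(b1$movies, b2$movies)
  # zero synapses, zero noise: every frame identical to the first
  gt0 <- gt; gt0$synapses <- gt$synapses[0, ]
  for (proto in list(ramp, make_protocol("step", levels_mV = c(-37, -17),
                                         duration_ms = 50, seed = 1))) {
    b0 <- render_movie(gt0, proto, seed = 1, noise = FALSE)
    movs <- if (proto$kind == "ramp") b0$movies else b0$movies
    for (mov in movs) {
      dev <- sweep(mov, c(1, 2), mov[, , 1])
      expect_lt(max(abs(dev)), 1e-10)
    }
  }
})

test_that("with zero noise the step response is monotone in voltage and bounded by the pool", {
  acq <- default_acquisition(frame_px = 48, n_planes = 1)
  for (seed in 21:25) {
    gt <- sample_ground_truth(1, acq = acq, seed = seed)
    s <- gt$synapses
    V <- seq(-62, -17, by = 5)
    q <- vapply(V, cumulative_release, numeric(1), T_ms = 50, syn = s)
    ca <- ca_signal(V, s$g_max, s$v_half_ca, s$k_ca)
    # release is a non-decreasing function of the calcium signal; in V it
    # is monotone only below the driving-force peak of the calcium curve
    expect_true(all(diff(q[order(ca)]) >= -1e-9 * max(q)))
    below_peak <- V <= V[which.max(ca)]
    expect_true(all(diff(q[below_peak]) >= -1e-9 * max(q)))
    # conservation: never more than the pool plus replenishment at the
    # voltage-dependent sustained rate
    ca_ref <- ca_signal(-17, s$g_max, s$v_half_ca, s$k_ca)
    s_v <- s$sustained_rate_au_per_s / 1000 * (ca / ca_ref)^s$m
    expect_true(all(q <= s$rrp_size_au + s_v * 50 + 1e-12))
  }
})

test_that("best-plane selection finds the ground-truth plane", {
  cfg <- pipeline_config()
  hits <- 0; total <- 0
  for (seed in 1:10) {
    gt <- sample_ground_truth(2, acq = cfg$acq, seed = 400L + seed)
    rhod <- render_movie(gt, make_protocol("ramp"), seed = seed)
    dfr <- lapply(rhod$movies, delta_f_image, baseline_frames = 1:15,
                  response_frames = 26:30)
    mean_df <- Reduce(`+`, lapply(dfr, unclass)) / length(dfr)
    rois <- detect_rois(mean_df, filter = cfg$roi_filter)
    for (r in seq_len(nrow(rois$rois))) {
      px <- rois$label_image == rois$rois$id[r]
      pl <- best_plane(rhod$movies, px, 1:15, 26:30)
      d2 <- (gt$synapses$hotspot_x - rois$rois$centroid_x[r])^2 +
        (gt$synapses$hotspot_y - rois$rois$centroid_y[r])^2
      truth <- gt$synapses$plane_index[which.min(d2)]
      total <- total + 1
      if (pl == truth) hits <- hits + 1
    }
  }
  expect_gte(total, 10)
  expect_gte(hits / total, 0.95)
})

test_that("synthetic ephys matches its closed forms", {
  proto <- make_protocol("step", levels_mV = c(-47, -27), duration_ms = 20,
                         seed = 1)
  gt <- sample_ground_truth(1, seed = 31)
  # zero conductance: zero calcium charge in every sweep
  gt0 <- gt; gt0$synapses$g_nS <- 0
  e0 <- synth_ephys(gt0, proto, seed = 1, current_noise_pA = 0, leak_pA = 0)
  expect_equal(unname(e0$qca_true_pC), c(0, 0))
  for (sw in e0$sweeps)
    expect_equal(qca(sw$time_s, sw$current_pA, sw$stim_window_s), 0,
                 tolerance = 1e-12)
  # single synapse: integrated charge equals g * P(V) * (V - V_r) * T;
  # integrate over a sample-aligned window inside the step so the
  # trapezoid is exact
  e1 <- synth_ephys(gt, proto, seed = 1, current_noise_pA = 0, leak_pA = 0)
  for (j in seq_along(e1$levels_mV)) {
    V <- e1$levels_mV[j]
    s <- gt$synapses
    sw <- e1$sweeps[[j]]
    tin <- sw$time_s[sw$time_s > sw$stim_window_s[1] &
                       sw$time_s < sw$stim_window_s[2]]
    win <- range(tin)
    analytic <- s$g_nS * boltzmann_activation(V, s$v_half_ca, s$k_ca) *
      (V - 47.6) * diff(win)
    expect_equal(qca(sw$time_s, sw$current_pA, win), analytic,
                 tolerance = 1e-6)
    full <- s$g_nS * boltzmann_activation(V, s$v_half_ca, s$k_ca) *
      (V - 47.6) * 20 / 1000
    expect_equal(e1$qca_true_pC[j], full, tolerance = 1e-12)
  }
  # saturation limit: RRP tau 10 ms, no sustained, 100-ms step releases
  # essentially the full pool
  gt2 <- gt
  gt2$synapses$rrp_size_au <- 10 * 0.23       # 10 vesicles in a.u.
  gt2$synapses$tau_depletion_ms <- 10
  gt2$synapses$rate_scale_per_ms <- 1 / 10
  gt2$synapses$sustained_rate_au_per_s <- 0
  long <- make_protocol("step", levels_mV = -17, duration_ms = 100, seed = 1)
  e2 <- synth_ephys(gt2, long, seed = 1, cm_noise_fF = 0)
  dcm_expect <- 10 * (1 - exp(-10)) * 40 / 1000   # SV * aF/SV in fF
  expect_equal(e2$sweeps[[1]]$dcm_true_fF, dcm_expect, tolerance = 1e-6)
  dcm_meas <- delta_cm(e2$sweeps[[1]]$cm_time_s, e2$sweeps[[1]]$cm_fF,
                       e2$sweeps[[1]]$stim_window_s)
  expect_equal(dcm_meas, dcm_expect, tolerance = 1e-6)
})

test_that("the indicator response trace integrates to the cumulative release", {
  gt <- sample_ground_truth(1, seed = 8)
  s <- gt$synapses
  t_ms <- seq(10, 4000, by = 10)   # long window captures the full kernel
  resp <- release_response_trace(-27, 50, s, t_ms)
  q <- cumulative_release(-27, 50, s)
  expect_equal(sum(resp) * 10, q, tolerance = 0.01)
})
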