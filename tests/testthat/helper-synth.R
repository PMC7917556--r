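# shared fixtures, all generated in code

# image with Gaussian spots at given (x, y) centers
spot_image <- function(centers, nx = 96, ny = 96, amp = 10, sigma = 4,
                       noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- if (noise_sd > 0) matrix(rnorm(nx * ny, 0, noise_sd), ny, nx)
         else matrix(0, ny, nx)
  for (cc in centers) {
    gx <- exp(-((seq_len(nx) - cc[1])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(ny) - cc[2])^2) / (2 * sigma^2))
    img <- img + amp * outer(gy, gx)
  }
  img
}

# movie with a constant baseline and a block step in given frames
block_movie <- function(nf = 25, ny = 32, nx = 32, level = 100,
                        block = NULL, rise = 0, rise_frames = integer()) {
  mov <- array(level, c(ny, nx, nf))
  if (!is.null(block) && length(rise_frames) > 0)
    mov[block$rows, block$cols, rise_frames] <-
      mov[block$rows, block$cols, rise_frames] + rise
  mov
}

# brute-force Kapur objective: independently coded loop over histogram splits
kapur_bruteforce <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  rng <- range(x)
  bin <- pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  best_t <- NA_integer_; best_obj <- -Inf
  for (t in 1:(n_bins - 1)) {
    pb <- sum(p[1:t]); pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    hb <- 0
    for (i in 1:t) if (p[i] > 0) hb <- hb - p[i] / pb * log(p[i] / pb)
    hf <- 0
    for (i in (t + 1):n_bins) if (p[i] > 0) hf <- hf - p[i] / pf * log(p[i] / pf)
    if (hb + hf > best_obj) { best_obj <- hb + hf; best_t <- t }
  }
  rng[1] + best_t / n_bins * diff(rng)
}

# synthetic profile table with planted property clusters; m increases with
# the planted group index so the label-ordering rule has something to find
make_profile_table <- function(n_per = c(10, 10, 10), sep = 10, seed = 1) {
  set.seed(seed)
  centers <- seq(0, by = sep, length.out = length(n_per))
  rows <- list()
  id <- 0
  for (g in seq_along(n_per)) {
    for (i in seq_len(n_per[g])) {
      id <- id + 1
      vals <- rnorm(length(clustering_properties), centers[g], 1)
      names(vals) <- clustering_properties
      vals["m"] <- centers[g] + rnorm(1, 0, 0.5)
      rows[[id]] <- data.frame(cell_id = "c1", synapse_id = id,
                               t(vals), position_01 = runif(1),
                               true_group = g)
    }
  }
  build_table(do.call(rbind, rows))
}

# one-cell synthetic bundle used by several test files (small, noiseless-ish)
small_cell <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config()
      cache <<- list(cfg = cfg, cell = generate_cell(2, cfg, 301L))
    }
    cache
  }
})

# expensive shared runs for the acceptance suite, computed once
acceptance_runs <- local({
  cache <- new.env()
  function(which) {
    if (is.null(cache[[which]])) {
      cache[[which]] <- switch(which,
        population_scale = {
          t0 <- Sys.time()
          res <- run_pipeline(pipeline_config(n_cells = 34,
                                              n_synapses_total = 55,
                                              seed = 1))
          attr(res, "elapsed_s") <- as.numeric(Sys.time() - t0,
                                               units = "secs")
          res
        },
        recovery = {
          cfg <- pipeline_config()
          allp <- NULL; allt <- NULL
          for (ci in 1:60) {
            cell <- generate_cell(2, cfg, 5000L + ci * 13L)
            res <- analyze_cell(cell, cfg, sprintf("r%02d", ci))
            if (!is.null(res$profiles)) {
              allp <- rbind(allp, res$profiles)
              allt <- rbind(allt, match_ground_truth(res$profiles, cell$gt))
            }
          }
          list(profiles = allp, truth = allt)
        })
    }
    cache[[which]]
  }
})
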