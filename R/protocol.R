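#' Build a voltage-command protocol
#'
#' Constructs either a family of step depolarizations from a holding potential
#' (presented in a pseudo-randomized, seed-deterministic order) or a linear
#' voltage ramp. The defaults mirror the standard single-synapse stimulation
#' set: 50-ms steps to -57 ... -17 mV from -87 mV, and a 150-ms ramp from
#' -87 to +63 mV at 1 mV/ms.
#'
#' @param kind `"step"` or `"ramp"`.
#' @param levels_mV step potentials (mV), required for `kind = "step"`.
#' @param duration_ms step duration in ms (default 50).
#' @param holding_mV holding potential (default -87).
#' @param ramp_range_mV length-2 numeric `(start, stop)` for `kind = "ramp"`
#'   (default `c(-87, 63)`).
#' @param ramp_rate_mV_per_ms ramp speed (default 1).
#' @param seed integer seed fixing the pseudo-random presentation order.
#' @return An object of class `voltage_protocol`: a list with the fields above
#'   plus `order` (permutation of level indices) and, for ramps,
#'   `ramp_duration_ms`.
#' @examples
#' p <- make_protocol("step", levels_mV = seq(-57, -17, by = 5), seed = 1)
#' r <- make_protocol("ramp")
#' r$ramp_duration_ms  # 150
#' @export
make_protocol <- function(kind = c("step", "ramp"),
                          levels_mV = NULL,
                          duration_ms = 50,
                          holding_mV = -87,
                          ramp_range_mV = c(-87, 63),
                          ramp_rate_mV_per_ms = 1,
                          seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "step") {
    if (is.null(levels_mV) || length(levels_mV) == 0)
      stop("invalid protocol: empty level list")
    if (any(levels_mV < -90 | levels_mV > 70))
      stop("invalid protocol: step levels outside [-90, +70] mV")
    if (duration_ms <= 0)
      stop("invalid protocol: non-positive step duration")
    n <- length(levels_mV)
    order <- if (n == 1L) 1L else
      withr::with_seed(seed, sample.int(n))
    out <- list(kind = "step", holding_mV = holding_mV,
                levels_mV = levels_mV, duration_ms = duration_ms,
                order = order, seed = as.integer(seed))
  } else {
    if (ramp_rate_mV_per_ms <= 0)
      stop("invalid protocol: non-positive ramp rate")
    if (length(ramp_range_mV) != 2 || ramp_range_mV[2] <= ramp_range_mV[1])
      stop("invalid protocol: ramp range must be increasing (start, stop)")
    out <- list(kind = "ramp", holding_mV = holding_mV,
                ramp_range_mV = ramp_range_mV,
                ramp_rate_mV_per_ms = ramp_rate_mV_per_ms,
                ramp_duration_ms =
                  diff(ramp_range_mV) / ramp_rate_mV_per_ms,
                seed = as.integer(seed))
  }
  class(out) <- "voltage_protocol"
  out
}

#' Command voltage of a ramp protocol at given times
#'
#' @param protocol a ramp `voltage_protocol`.
#' @param t_ms times in ms from ramp onset; times outside the ramp return the
#'   holding potential (before) or the final potential (after).
#' @return command voltage in mV, same length as `t_ms`.
#' @export
ramp_voltage_at <- function(protocol, t_ms) {
  stopifnot(inherits(protocol, "voltage_protocol"), protocol$kind == "ramp")
  v <- protocol$ramp_range_mV[1] + protocol$ramp_rate_mV_per_ms * t_ms
  v[t_ms < 0] <- protocol$holding_mV
  v[t_ms > protocol$ramp_duration_ms] <- protocol$ramp_range_mV[2]
  v
}

#' @export
print.voltage_protocol <- function(x, ...) {
  if (x$kind == "step") {
    cat(sprintf("Step protocol: %d levels (%s mV), %g ms each, holding %g mV\n",
                length(x$levels_mV),
                paste(x$levels_mV, collapse = ", "),
                x$duration_ms, x$holding_mV))
    cat("Presentation order:", paste(x$order, collapse = " "), "\n")
  } else {
    cat(sprintf("Ramp protocol: %g to %g mV at %g mV/ms (%g ms), holding %g mV\n",
                x$ramp_range_mV[1], x$ramp_range_mV[2],
                x$ramp_rate_mV_per_ms, x$ramp_duration_ms, x$holding_mV))
  }
  invisible(x)
}
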