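# Band-pass conditioning. The standard extracellular spike band is a
# third-order Butterworth band-pass with half-power edges at 200 and 3000 Hz.
# Application is zero-phase by default (forward-backward) so spike timestamps
# are not systematically shifted; the filter runs as a cascade of biquad
# second-order sections because an order-3 band-pass at 30 kHz with a 200 Hz
# edge is ill-conditioned in direct transfer-function form.

#' Design a Butterworth band-pass specification
#'
#' The specification is rate-independent; coefficients are realised when the
#' filter is applied (or when the response is evaluated) at a concrete
#' sampling rate. `low_hz` and `high_hz` are half-power (-3 dB) edges of the
#' single-pass response.
#'
#' @param low_hz,high_hz half-power band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Butterworth order of each (low/high) prototype stage (>= 1).
#' @param zero_phase apply forward-backward by default?
#' @return a list of class `filter_spec`.
#' @export
design_bandpass <- function(low_hz = 200, high_hz = 3000, order = 3,
                            zero_phase = TRUE) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 design = "butterworth", zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth band-pass order %d, %g-%g Hz (%s)\n",
              x$order, x$low_hz, x$high_hz,
              if (x$zero_phase) "zero-phase" else "causal"))
  invisible(x)
}

check_band <- function(spec, rate) {
  if (spec$high_hz >= rate / 2) {
    stop(sprintf("upper band edge %g Hz is not below the Nyquist frequency %g Hz",
                 spec$high_hz, rate / 2), call. = FALSE)
  }
}

# Direct-form design via signal::butter (order-n band-pass -> order-2n
# polynomial pair).
bandpass_ba <- function(spec, rate) {
  check_band(spec, rate)
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (rate / 2),
                 type = "pass")
}

# Factor a band-pass (b, a) into biquad sections. A Butterworth band-pass of
# order n has n zeros at z = 1, n at z = -1 and 2n poles in conjugate pairs;
# each section takes one conjugate pole pair and one (+1, -1) zero pair, so
# every section is well-conditioned.
bandpass_sos <- function(spec, rate) {
  ba <- bandpass_ba(spec, rate)
  n <- spec$order
  p <- polyroot(rev(ba$a))                    # poles
  stopifnot(length(p) == 2 * n)
  p <- p[order(Im(p))]
  pairs <- lapply(seq_len(n), function(i) c(p[i], p[2 * n + 1 - i]))
  gain <- ba$b[1]                             # a is monic, so b[1] is the gain
  sos <- matrix(0, nrow = n, ncol = 6)
  g <- rep(abs(gain)^(1 / n), n)
  if (gain < 0) g[1] <- -g[1]
  for (i in seq_len(n)) {
    pp <- pairs[[i]]
    a1 <- -Re(pp[1] + pp[2])
    a2 <- Re(pp[1] * pp[2])
    # zeros (z-1)(z+1) = z^2 - 1  ->  b = g * (1, 0, -1)
    sos[i, ] <- c(g[i], 0, -g[i], 1, a1, a2)
  }
  sos
}

sos_filter_1 <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- signal::filter(signal::Arma(b = sos[i, 1:3], a = sos[i, 4:6]), x)
  }
  as.numeric(x)
}

# Odd (point-reflected) padding avoids an artificial step at the ends.
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad < 1) return(list(x = x, pad = 0L))
  head_pad <- 2 * x[1] - x[seq(n_pad + 1L, 2L)]
  tail_pad <- 2 * x[n] - x[seq(n - 1L, n - n_pad)]
  list(x = c(head_pad, x, tail_pad), pad = n_pad)
}

filter_channel <- function(x, sos, zero_phase, n_pad) {
  if (length(x) == 0) return(x)
  padded <- reflect_pad(x, n_pad)
  y <- sos_filter_1(sos, padded$x)
  if (zero_phase) {
    y <- rev(sos_filter_1(sos, rev(y)))
  }
  if (padded$pad > 0) y <- y[(padded$pad + 1L):(padded$pad + length(x))]
  y
}

#' Apply a band-pass filter to a recording
#'
#' Each channel is filtered through the biquad cascade; zero-phase mode runs
#' the cascade forward and backward (squared magnitude response, no group
#' delay). Edges are handled with odd-reflection padding of three times the
#' filter length.
#'
#' @param recording an `mea_recording` with `rate > 2 * spec$high_hz`.
#' @param spec a [design_bandpass()] specification.
#' @param zero_phase override the spec's application mode.
#' @return a filtered `mea_recording` of identical shape and rate.
#' @export
apply_filter <- function(recording, spec = design_bandpass(),
                         zero_phase = spec$zero_phase) {
  stopifnot(inherits(recording, "mea_recording"), inherits(spec, "filter_spec"))
  check_band(spec, recording$rate)
  sos <- bandpass_sos(spec, recording$rate)
  n_pad <- 3L * (2L * spec$order + 1L)
  out <- recording
  out$signal <- t(apply(recording$signal, 1, filter_channel,
                        sos = sos, zero_phase = zero_phase, n_pad = n_pad))
  if (ncol(recording$signal) == 1L) out$signal <- t(out$signal)
  out
}

#' Magnitude response of a band-pass specification
#'
#' Evaluates the single-pass magnitude response at the given frequencies for
#' a concrete sampling rate (zero-phase application squares this response).
#'
#' @param spec a [design_bandpass()] specification.
#' @param freqs_hz frequencies to evaluate (Hz).
#' @param rate sampling rate (Hz).
#' @return tibble with `freq_hz` and `gain`.
#' @export
filter_response <- function(spec, freqs_hz, rate = 30000) {
  ba <- bandpass_ba(spec, rate)
  z <- exp(-1i * 2 * pi * freqs_hz / rate)
  h <- sapply(seq_along(z), function(i) {
    sum(ba$b * z[i]^(seq_along(ba$b) - 1)) /
      sum(ba$a * z[i]^(seq_along(ba$a) - 1))
  })
  tibble::tibble(freq_hz = freqs_hz, gain = Mod(h))
}

#' Locate the half-power (-3 dB) edges of a designed band-pass
#'
#' Numerical root search on the single-pass magnitude response for the
#' frequencies, below and above the pass band, where the gain crosses
#' `1/sqrt(2)`.
#'
#' @param spec a [design_bandpass()] specification.
#' @param rate sampling rate at which the filter is realised (Hz).
#' @return tibble with `edge` ("low"/"high") and `freq_hz`.
#' @export
half_power_points <- function(spec, rate = 30000) {
  target <- 1 / sqrt(2)
  gain_at <- function(f) filter_response(spec, f, rate)$gain - target
  mid <- sqrt(spec$low_hz * spec$high_hz)
  lo <- stats::uniroot(gain_at, lower = 1e-3, upper = mid, tol = 1e-10)$root
  hi <- stats::uniroot(gain_at, lower = mid, upper = rate / 2 - 1e-6,
                       tol = 1e-10)$root
  tibble::tibble(edge = c("low", "high"), freq_hz = c(lo, hi))
}
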