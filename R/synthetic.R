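# Ground-truth simulator. Generates per-channel Poisson spike trains with
# population bursts, renders them into extracellular voltage traces
# (biphasic difference-of-Gaussians templates, exponential spatial
# attenuation across the layout, additive Gaussian noise) and into a matched
# calcium fluorescence trace (rise/decay kernel on the population rate).
# Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Defaults emulate a quiet dissociated culture on a 30 kHz acquisition
#' system: 2 Hz background firing, population bursts every ~5 s of 10 spikes
#' at 100 Hz, -50 uV spike peaks over 5 uV r.m.s. noise, and a calcium
#' kernel with a fast (< 150 ms) rise and ~3 s decay.
#'
#' @param layout an `mea_layout` giving the channels to simulate.
#' @param duration_s recording length (s).
#' @param rate_hz sampling rate for rendered recordings (Hz).
#' @param baseline_rate_hz per-channel background Poisson rate (Hz); scalar
#'   or one value per channel.
#' @param burst_rate_hz population-burst rate (Hz).
#' @param burst_size spikes per burst per channel.
#' @param intra_burst_isi_s in-burst inter-spike interval (s).
#' @param template_peak_uv main (negative) spike phase amplitude (uV, < 0);
#'   scalar or per channel.
#' @param template_width_s trough-to-peak width of the spike waveform (s).
#' @param noise_sigma_uv additive Gaussian noise SD (uV).
#' @param attenuation_um exponential length-scale of cross-channel amplitude
#'   decay (um); the default 60 um keeps a 200 um neighbour below 4%.
#' @param refractory_s ground-truth trains are thinned to this minimum ISI.
#' @param well_sync share burst times only within a well (`TRUE`) or across
#'   the whole array (`FALSE`).
#' @param frame_rate_hz fluorescence frame rate (Hz).
#' @param ca_rise_s,ca_decay_s calcium kernel time constants (s), rise <
#'   decay; defaults 0.05 and 3.
#' @param ca_f0 baseline fluorescence (a.u.).
#' @param ca_gain dF/F0 contribution of one spike per channel.
#' @param ca_noise_sd fluorescence noise SD (a.u.).
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(layout = make_multiwell(1, 8), duration_s = 10,
                       rate_hz = 30000, baseline_rate_hz = 2,
                       burst_rate_hz = 0.2, burst_size = 10,
                       intra_burst_isi_s = 0.01, template_peak_uv = -50,
                       template_width_s = 0.0005, noise_sigma_uv = 5,
                       attenuation_um = 60, refractory_s = 0.002,
                       well_sync = FALSE, frame_rate_hz = 100,
                       ca_rise_s = 0.05, ca_decay_s = 3, ca_f0 = 100,
                       ca_gain = 0.02, ca_noise_sd = 0, seed = 1) {
  stopifnot(all(baseline_rate_hz >= 0), burst_rate_hz >= 0,
            noise_sigma_uv >= 0, ca_rise_s < ca_decay_s, duration_s > 0)
  structure(as.list(environment()), class = "sim_config")
}

# Population burst start times: homogeneous Poisson process of rate
# burst_rate over [0, duration], one realisation per sync group.
burst_times <- function(rate, duration) {
  n <- stats::rpois(1, rate * duration)
  sort(stats::runif(n, 0, duration))
}

#' Simulate ground-truth spike trains
#'
#' Per channel: homogeneous Poisson background plus population bursts
#' (shared burst start times, per-channel in-burst spikes at
#' `intra_burst_isi_s` with small timing jitter), thinned to the refractory
#' minimum ISI. With `well_sync` the burst times are shared within each well
#' and independent across wells.
#'
#' @param config a [sim_config()].
#' @return an `mea_spikes` object; attribute `burst_times` holds the
#'   ground-truth burst start times (a list per sync group).
#' @export
simulate_trains <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- config$layout
  ids <- lay$channel
  base <- rep_len(config$baseline_rate_hz, length(ids))
  withr::with_seed(as.integer(config$seed), {
    groups <- if (config$well_sync) lay$well_id else rep(0L, length(ids))
    bt <- lapply(unique(groups), function(g) {
      burst_times(config$burst_rate_hz, config$duration_s)
    })
    names(bt) <- as.character(unique(groups))
    per_ch <- lapply(seq_along(ids), function(i) {
      n_bg <- stats::rpois(1, base[i] * config$duration_s)
      ts <- stats::runif(n_bg, 0, config$duration_s)
      for (b in bt[[as.character(groups[i])]]) {
        jitter <- stats::rnorm(config$burst_size, 0, config$intra_burst_isi_s / 10)
        ts <- c(ts, b + (seq_len(config$burst_size) - 1) * config$intra_burst_isi_s +
                  jitter)
      }
      ts <- sort(ts[ts >= 0 & ts <= config$duration_s])
      # refractory thinning: drop spikes following the previous kept one
      # too closely
      if (length(ts) > 1) {
        keep <- ts[1]
        last <- ts[1]
        for (t in ts[-1]) {
          if (t - last >= config$refractory_s) {
            keep <- c(keep, t)
            last <- t
          }
        }
        ts <- keep
      }
      ts
    })
    ev <- tibble::tibble(channel = rep(ids, lengths(per_ch)),
                         time_s = unlist(per_ch) %||% numeric(0))
    out <- new_spike_trains(ev, duration = config$duration_s, channel_ids = ids)
    attr(out, "burst_times") <- bt
    out
  })
}

# Biphasic difference-of-Gaussians template sampled at `rate`: a sharp
# negative main phase at lag 0 and a slower positive rebound one width
# later, scaled so the minimum equals `peak_uv`.
spike_template <- function(peak_uv, width_s, rate) {
  s1 <- width_s / 3
  s2 <- width_s / 2
  # sample on an integer grid through t = 0 so the trough lands on a sample
  i0 <- -ceiling(4 * s1 * rate)
  i1 <- ceiling((width_s + 4 * s2) * rate)
  t <- (i0:i1) / rate
  k <- exp(-t^2 / (2 * s1^2)) - 0.5 * exp(-(t - width_s)^2 / (2 * s2^2))
  w <- -k / max(k) * abs(peak_uv)         # main lobe negative, depth |peak|
  if (peak_uv > 0) w <- -w
  list(w = w, center = -i0)               # samples before the trough
}

#' Render spike trains into an extracellular recording
#'
#' Each spike inserts its channel's template waveform at its timestamp; the
#' waveform also appears on other channels scaled by
#' `exp(-distance / attenuation_um)` (contributions below 2% are skipped).
#' Additive white Gaussian noise of `noise_sigma_uv` completes the trace;
#' superposition is linear.
#'
#' @param trains an `mea_spikes` ground-truth set (e.g. from
#'   [simulate_trains()]).
#' @param config the [sim_config()] describing templates, noise and layout.
#' @return an `mea_recording` at `config$rate_hz`.
#' @export
render_recording <- function(trains, config) {
  stopifnot(inherits(trains, "mea_spikes"), inherits(config, "sim_config"))
  lay <- config$layout
  ids <- lay$channel
  rate <- config$rate_hz
  n <- round(config$duration_s * rate)
  peaks <- rep_len(config$template_peak_uv, length(ids))
  d <- as.matrix(stats::dist(cbind(lay$x_um, lay$y_um)))
  atten <- exp(-d / config$attenuation_um)
  by_ch <- spikes_by_channel(trains)
  withr::with_seed(as.integer(config$seed) + 1L, {
    sig <- if (config$noise_sigma_uv > 0) {
      matrix(stats::rnorm(length(ids) * n, 0, config$noise_sigma_uv),
             nrow = length(ids))
    } else {
      matrix(0, nrow = length(ids), ncol = n)
    }
    for (i in seq_along(ids)) {
      ts <- by_ch[[i]]
      if (!length(ts)) next
      tmpl <- spike_template(peaks[i], config$template_width_s, rate)
      centers <- round(ts * rate) + 1L
      targets <- which(atten[i, ] >= 0.02)
      for (j in targets) {
        w <- tmpl$w * atten[i, j]
        for (c0 in centers) {
          i0 <- c0 - tmpl$center
          i1 <- i0 + length(w) - 1L
          w0 <- max(1L, i0)
          w1 <- min(n, i1)
          if (w0 > w1) next
          sig[j, w0:w1] <- sig[j, w0:w1] + w[(w0 - i0 + 1L):(w1 - i0 + 1L)]
        }
      }
    }
    new_recording(sig, rate = rate, channel_ids = ids)
  })
}

#' Render spike trains into a matched fluorescence trace
#'
#' The per-frame population spike count is convolved with a
#' rise-times-decay kernel `(1 - exp(-t/rise)) * exp(-t/decay)` and scaled
#' by `ca_gain`, so `F = F0 * (1 + gain * activity) + noise`.
#'
#' @param trains an `mea_spikes` set.
#' @param config the [sim_config()].
#' @return an `mea_fluor` trace at `config$frame_rate_hz`.
#' @export
render_fluorescence <- function(trains, config) {
  stopifnot(inherits(trains, "mea_spikes"), inherits(config, "sim_config"))
  fr <- config$frame_rate_hz
  n_frames <- max(1L, round(config$duration_s * fr))
  counts <- rep(0, n_frames)
  if (nrow(trains)) {
    f <- pmin(floor(trains$time_s * fr), n_frames - 1L) + 1L
    tab <- table(f)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  tk <- seq(0, min(6 * config$ca_decay_s, config$duration_s), by = 1 / fr)
  kernel <- (1 - exp(-tk / config$ca_rise_s)) * exp(-tk / config$ca_decay_s)
  act <- stats::convolve(counts, rev(kernel), type = "open")[seq_len(n_frames)]
  per_ch_act <- act / max(1L, length(attr(trains, "channel_ids")))
  f <- config$ca_f0 * (1 + config$ca_gain * per_ch_act)
  if (config$ca_noise_sd > 0) {
    f <- withr::with_seed(as.integer(config$seed) + 2L,
                          f + stats::rnorm(n_frames, 0, config$ca_noise_sd))
  }
  fluorescence_trace(f, frame_rate_hz = fr)
}
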