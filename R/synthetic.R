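#' Configuration for the synthetic EEG generator
#'
#' Defaults emulate a single-subject recording protocol: a 3,000-s record at
#' 256 Hz with 16 channels in which seizure activity covers roughly half of
#' the record (expected ~25 seizures of 40--80 s, i.e. ~1,500 s), so that
#' seizure and normal signal durations are approximately 1:1. Background
#' channels share a band-limited latent source so that the expected pairwise
#' Pearson correlation equals `base_coupling`; during seizures the channels
#' gain a coherent 3--5 Hz rhythm that raises both amplitude (by
#' `seizure_amp_gain`) and inter-channel coupling (to `seizure_coupling`).
#'
#' @param n_channels number of channels.
#' @param duration_s record length in seconds.
#' @param fs sampling rate, Hz. Must exceed `2 * osc_freq_hz`.
#' @param base_coupling background inter-channel Pearson correlation in
#'   `[0, 1)`.
#' @param seizure_rate expected number of seizures per record (Poisson).
#' @param seizure_len_s length-2 vector, (min, max) seizure duration in
#'   seconds.
#' @param seizure_amp_gain multiplicative amplitude factor (>= 1) of seizure
#'   segments relative to background.
#' @param seizure_coupling inter-channel correlation during seizures; must
#'   exceed `base_coupling`.
#' @param osc_freq_hz frequency of the rhythmic seizure component (Hz).
#' @param seed integer seed; the generator is deterministic given the
#'   configuration and seed and does not disturb the global RNG.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16, duration_s = 3000, fs = 256,
                       base_coupling = 0.2, seizure_rate = 25,
                       seizure_len_s = c(40, 80), seizure_amp_gain = 3,
                       seizure_coupling = 0.7, osc_freq_hz = 4, seed = 1L) {
  cfg <- list(n_channels = n_channels, duration_s = duration_s, fs = fs,
              base_coupling = base_coupling, seizure_rate = seizure_rate,
              seizure_len_s = seizure_len_s,
              seizure_amp_gain = seizure_amp_gain,
              seizure_coupling = seizure_coupling,
              osc_freq_hz = osc_freq_hz, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) gf_stop("gatformer_config_error", msg)
  ok(is_count(cfg$n_channels) && cfg$n_channels >= 2,
     "n_channels must be an integer >= 2")
  ok(is_scalar(cfg$duration_s) && cfg$duration_s > 0, "duration_s must be > 0")
  ok(is_scalar(cfg$fs) && cfg$fs > 0, "fs must be > 0")
  ok(is_scalar(cfg$base_coupling) && cfg$base_coupling >= 0 &&
       cfg$base_coupling < 1, "base_coupling must be in [0, 1)")
  ok(is_scalar(cfg$seizure_coupling) &&
       cfg$seizure_coupling > cfg$base_coupling && cfg$seizure_coupling <= 1,
     "seizure_coupling must be in (base_coupling, 1]")
  ok(is_scalar(cfg$seizure_rate) && cfg$seizure_rate >= 0,
     "seizure_rate must be >= 0")
  ok(is.numeric(cfg$seizure_len_s) && length(cfg$seizure_len_s) == 2 &&
       all(cfg$seizure_len_s > 0) &&
       cfg$seizure_len_s[1] <= cfg$seizure_len_s[2],
     "seizure_len_s must be (min, max) with 0 < min <= max")
  ok(is_scalar(cfg$seizure_amp_gain) && cfg$seizure_amp_gain >= 1,
     "seizure_amp_gain must be >= 1")
  ok(is_scalar(cfg$osc_freq_hz) && cfg$osc_freq_hz > 0 &&
       cfg$fs > 2 * cfg$osc_freq_hz,
     "fs must exceed 2 * osc_freq_hz")
  invisible(cfg)
}

# white noise band-limited to [lo, hi] Hz and normalised to unit sd
band_noise <- function(n, fs, lo = 0.5, hi = 30) {
  hi <- min(hi, 0.45 * fs)
  x <- rnorm(n)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- sd(y)
  if (s < 1e-12) return(rep(0, n))
  y / s
}

#' Generate background (non-seizure) EEG
#'
#' Channels are mixtures of one shared band-limited (0.5--30 Hz) latent noise
#' source and independent band-limited noise,
#' `sqrt(c) * latent + sqrt(1 - c) * own`, with `c = base_coupling`, so the
#' expected pairwise Pearson correlation between channels equals
#' `base_coupling`. Amplitudes are scaled to ~30 microvolt standard deviation.
#'
#' @param cfg a [sim_config].
#' @return an [eeg_record] with no seizure annotations.
#' @export
gen_background <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, unclass(cfg))
  n <- round(cfg$duration_s * cfg$fs)
  local_seed(cfg$seed, {
    latent <- band_noise(n, cfg$fs)
    c_mix <- cfg$base_coupling
    data <- matrix(0, cfg$n_channels, n)
    for (i in seq_len(cfg$n_channels)) {
      own <- band_noise(n, cfg$fs)
      data[i, ] <- 30 * (sqrt(c_mix) * latent + sqrt(1 - c_mix) * own)
    }
    eeg_record(data, cfg$fs,
               channel_labels = sprintf("CH%02d-REF", seq_len(cfg$n_channels)),
               subject_id = sprintf("sim%03d", cfg$seed))
  })
}

# Draw non-overlapping seizure intervals. Count is Poisson(seizure_rate);
# trailing intervals are dropped if total length would exceed 95% of the
# record. Gaps are proportional to uniform draws so placement is exchangeable.
draw_intervals <- function(cfg) {
  n <- rpois(1, cfg$seizure_rate)
  if (n == 0) return(empty_intervals())
  len <- runif(n, cfg$seizure_len_s[1], cfg$seizure_len_s[2])
  while (n > 0 && sum(len) > 0.95 * cfg$duration_s) {
    len <- len[-n]
    n <- n - 1L
  }
  if (n == 0)
    gf_stop("gatformer_simulation_error",
            "seizure intervals cannot fit in a %g s record", cfg$duration_s)
  free <- cfg$duration_s - sum(len)
  g <- runif(n + 1)
  gaps <- g / sum(g) * free
  starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(len)[-n])
  cbind(start_s = starts, end_s = starts + len)
}

#' Inject annotated seizures into a background record
#'
#' Draws non-overlapping seizure intervals and, within each, adds (i) a
#' coherent rhythmic oscillation at `osc_freq_hz` (with 10% frequency jitter
#' per seizure and a harmonic at twice the frequency) shared by all channels
#' and (ii) independent per-channel band-limited noise, with amplitudes chosen
#' so that within-seizure signal standard deviation is `seizure_amp_gain`
#' times background and the inter-channel correlation reaches
#' `seizure_coupling`. The added activity is amplitude-ramped over 1 s at
#' onset and offset. Annotated intervals are stored in the returned record.
#'
#' @param rec background [eeg_record] without annotations.
#' @param cfg the [sim_config] used to build `rec`.
#' @return an [eeg_record] with populated `seizure_intervals`.
#' @export
inject_seizures <- function(rec, cfg) {
  if (nrow(rec$seizure_intervals) > 0)
    gf_stop("gatformer_simulation_error", "record already has seizure annotations")
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, unclass(cfg))
  if (cfg$seizure_rate == 0) return(rec)
  fs <- rec$fs
  M <- nrow(rec$data)
  g2 <- cfg$seizure_amp_gain^2
  # decompose the variance gain into a coherent part (drives coupling) and an
  # incoherent part (drives amplitude only)
  beta2 <- max(cfg$seizure_coupling * g2 - cfg$base_coupling, 0)
  delta2 <- max(g2 - 1 - beta2, 0)
  sigma_bg <- 30
  local_seed(cfg$seed + 1L, {
    iv <- draw_intervals(cfg)
    data <- rec$data
    for (k in seq_len(nrow(iv))) {
      i0 <- floor(iv[k, 1] * fs) + 1L
      i1 <- min(floor(iv[k, 2] * fs), ncol(data))
      idx <- i0:i1
      t <- (idx - i0) / fs
      f <- cfg$osc_freq_hz * (1 + runif(1, -0.1, 0.1))
      ph <- runif(2, 0, 2 * pi)
      s <- sin(2 * pi * f * t + ph[1]) + 0.3 * sin(4 * pi * f * t + ph[2])
      s <- s / sd(s)
      ramp <- pmin(1, pmin(t, rev(t))) # 1 s linear on/off ramps
      coher <- sqrt(beta2) * s * ramp
      for (i in seq_len(M)) {
        extra <- if (delta2 > 0) sqrt(delta2) * band_noise(length(idx), fs) else 0
        data[i, idx] <- data[i, idx] + sigma_bg * (coher + extra * ramp)
      }
    }
    eeg_record(data, fs, rec$channel_labels, iv, rec$subject_id)
  })
}

#' Generate one complete annotated synthetic subject
#'
#' `gen_background()` followed by [inject_seizures()]; with default settings
#' this produces a 3,000-s, 16-channel, 256-Hz record with roughly half of
#' its duration covered by annotated seizures.
#'
#' @param cfg a [sim_config].
#' @return an annotated [eeg_record].
#' @export
#' @examples
#' rec <- make_subject(sim_config(duration_s = 60, seizure_rate = 2,
#'                                seizure_len_s = c(5, 10), seed = 7))
#' rec
make_subject <- function(cfg = sim_config()) {
  inject_seizures(gen_background(cfg), cfg)
}
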