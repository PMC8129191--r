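#' Specify a class-dependent band-limited effect
#'
#' Describes one discriminative response to simulate: at `contact_id`, the
#' band-limited component in `band` is amplitude-gated on during
#' `[onset_ms, onset_ms + duration_ms]` of every trial of `class_label`, with
#' a multiplicative RMS gain of `effect_size` relative to the background's
#' own content in that band. `effect_size = 1` is an exact null (nothing is
#' added).
#'
#' @param contact_id contact carrying the effect.
#' @param band numeric length-2, band edges in Hz.
#' @param class_label `"own"` or `"other"`.
#' @param onset_ms response latency after stimulus onset, ms.
#' @param duration_ms response duration, ms.
#' @param effect_size multiplicative band-RMS gain, >= 1.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(contact_id, band = c(60, 145), class_label = "own",
                        onset_ms = 300, duration_ms = 400, effect_size = 3) {
  stopifnot(effect_size >= 1, length(band) == 2, band[1] < band[2],
            onset_ms >= 0, duration_ms > 0)
  structure(list(contact_id = contact_id, band = band,
                 class_label = class_label, onset_ms = onset_ms,
                 duration_ms = duration_ms, effect_size = effect_size),
            class = "effect_spec")
}

#' Simulation configuration
#'
#' Defaults mirror a typical recording protocol for this paradigm: 1,000 ms
#' stimuli, 1,000 ms inter-trial intervals, 120 trials split evenly over the
#' two classes, shafts of 8 contacts, and pink-noise background. The montage
#' (2 shafts x 8 contacts) is a desk-scale montage; clinical implants carry
#' of the order of 100-150 contacts, which changes compute cost but not the
#' statistical structure any stage relies on.
#'
#' @param n_shafts number of electrode shafts.
#' @param contacts_per_shaft contacts per shaft (8-16 is realistic).
#' @param fs sampling frequency, Hz (1000 or 2000 are typical).
#' @param n_trials_per_class trials per class (>= 2).
#' @param stimulus_ms stimulus duration, ms.
#' @param iti_ms inter-trial interval, ms.
#' @param jitter_ms length-2 range of extra uniform jitter, ms (e.g.
#'   `c(100, 300)`), or `c(0, 0)` for none.
#' @param background list with `exponent` (1/f^a power-spectrum slope) and
#'   `amplitude` (signal SD in microvolts).
#' @param line_noise_amp 50 Hz line-contamination amplitude in microvolts;
#'   scalar or one value per contact.
#' @param effects list of [effect_spec()] objects.
#' @param regions optional character vector of region labels, one per
#'   contact; by default each shaft half is its own region.
#' @param modality `"auditory"` or `"visual"` (metadata only).
#' @param seed RNG seed for [generate_session()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_shafts = 2, contacts_per_shaft = 8, fs = 1000,
                       n_trials_per_class = 60, stimulus_ms = 1000,
                       iti_ms = 1000, jitter_ms = c(0, 0),
                       background = list(exponent = 1, amplitude = 20),
                       line_noise_amp = 0, effects = list(),
                       regions = NULL, modality = "auditory", seed = 1) {
  stopifnot(n_trials_per_class >= 2, stimulus_ms > 0, iti_ms > 0, fs > 0,
            contacts_per_shaft >= 1, n_shafts >= 1,
            length(jitter_ms) == 2, all(jitter_ms >= 0),
            jitter_ms[1] <= jitter_ms[2])
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  structure(list(n_shafts = n_shafts, contacts_per_shaft = contacts_per_shaft,
                 fs = fs, n_trials_per_class = n_trials_per_class,
                 stimulus_ms = stimulus_ms, iti_ms = iti_ms,
                 jitter_ms = jitter_ms, background = background,
                 line_noise_amp = line_noise_amp, effects = effects,
                 regions = regions, modality = modality, seed = seed),
            class = "sim_config")
}

# 1/f^a noise by spectral shaping of white Gaussian noise, rescaled to sd.
pink_noise <- function(n, exponent, sd_target) {
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)                 # two-sided frequency magnitude
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# raised-cosine gate: 20 ms cosine ramps lie inside [on, off] so that no
# effect energy precedes the nominal onset (the ground-truth latency)
cosine_gate <- function(n_total, on, off, fs, ramp_ms = 20) {
  g <- numeric(n_total)
  nr <- min(max(1L, round(ramp_ms / 1000 * fs)),
            floor((off - on + 1) / 2))
  g[on:off] <- 1
  ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
  g[on + seq_len(nr) - 1L] <- ramp
  g[off - seq_len(nr) + 1L] <- ramp
  g
}

#' Generate a synthetic SEEG session with known ground truth
#'
#' Continuous signals are 1/f background noise plus optional 50 Hz line
#' contamination plus, for each [effect_spec()], a band-limited noise
#' component whose envelope is gated on (20 ms cosine ramps) during the
#' specified window of matching-class trials. The added component's RMS is
#' `sqrt(effect_size^2 - 1)` times the background's RMS inside the band, so
#' that total band RMS during the response is `effect_size` times baseline.
#' Events are scheduled with the configured stimulus duration, inter-trial
#' interval and uniform jitter, in a balanced pseudo-random class sequence.
#' The same seed always yields a bit-identical session.
#'
#' @param config a [sim_config()].
#' @return a validated `seeg_session`; the discriminative
#'   (contact, window, class) ground truth is attached as the
#'   `"ground_truth"` attribute (a tibble).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::local_seed(cfg$seed)

  n_contacts <- cfg$n_shafts * cfg$contacts_per_shaft
  shaft_ids <- LETTERS[seq_len(cfg$n_shafts)]
  contacts <- contact_table(
    contact_id = paste0(rep(shaft_ids, each = cfg$contacts_per_shaft),
                        rep(seq_len(cfg$contacts_per_shaft), cfg$n_shafts)),
    shaft_id = rep(shaft_ids, each = cfg$contacts_per_shaft),
    index_on_shaft = rep(seq_len(cfg$contacts_per_shaft), cfg$n_shafts))
  if (is.null(cfg$regions)) {
    half <- ceiling(cfg$contacts_per_shaft / 2)
    contacts$region_label <- paste0(
      "region ", rep(shaft_ids, each = cfg$contacts_per_shaft),
      ifelse(rep(seq_len(cfg$contacts_per_shaft), cfg$n_shafts) <= half,
             "1", "2"))
  } else {
    stopifnot(length(cfg$regions) == n_contacts)
    contacts$region_label <- cfg$regions
  }

  bad <- setdiff(vapply(cfg$effects, `[[`, "", "contact_id"),
                 contacts$contact_id)
  if (length(bad))
    stop("effect_spec references unknown contact: ",
         paste(bad, collapse = ", "))

  fs <- cfg$fs
  n_trials <- 2L * cfg$n_trials_per_class
  stim_smp <- round(cfg$stimulus_ms / 1000 * fs)
  labels <- sample(rep(c("own", "other"), cfg$n_trials_per_class))
  jit <- if (cfg$jitter_ms[2] > 0)
    stats::runif(n_trials, cfg$jitter_ms[1], cfg$jitter_ms[2]) else
      numeric(n_trials)
  gaps <- round((cfg$iti_ms + jit) / 1000 * fs)
  # 2 s pre-roll so baselines and pre-onset rest windows always fit
  onsets <- integer(n_trials)
  cursor <- 2L * fs
  for (i in seq_len(n_trials)) {
    onsets[i] <- cursor
    cursor <- cursor + stim_smp + gaps[i]
  }
  # pad the tail so the total length is 5-smooth: every spectral step
  # (screen, notch, band power) then uses fast FFT lengths
  n_samples <- stats::nextn(cursor + round(1.5 * fs), c(2, 3, 5))

  for (e in cfg$effects) {
    if (e$onset_ms + e$duration_ms > cfg$stimulus_ms)
      stop(sprintf("effect on %s overruns the %d ms stimulus window",
                   e$contact_id, cfg$stimulus_ms))
  }

  sig <- matrix(0, n_contacts, n_samples)
  amp <- cfg$background$amplitude
  expo <- cfg$background$exponent
  for (c in seq_len(n_contacts))
    sig[c, ] <- pink_noise(n_samples, expo, amp)

  line_amp <- rep(cfg$line_noise_amp, length.out = n_contacts)
  if (any(line_amp > 0)) {
    tt <- seq_len(n_samples) / fs
    for (c in which(line_amp > 0))
      sig[c, ] <- sig[c, ] + line_amp[c] *
        sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
  }

  gt <- list()
  for (e in cfg$effects) {
    if (e$effect_size == 1) next
    c <- match(e$contact_id, contacts$contact_id)
    bp <- signal::butter(3, e$band / (fs / 2), "pass")
    # background RMS inside the band sets the component's reference scale
    band_bg <- signal::filtfilt(bp, sig[c, ])
    sigma_band <- stats::sd(band_bg)
    comp <- signal::filtfilt(bp, stats::rnorm(n_samples))
    comp <- comp / stats::sd(comp) * sigma_band *
      sqrt(e$effect_size^2 - 1)
    gate <- numeric(n_samples)
    hit <- which(labels == e$class_label)
    for (i in hit) {
      on <- onsets[i] + round(e$onset_ms / 1000 * fs) + 1L
      off <- onsets[i] + round((e$onset_ms + e$duration_ms) / 1000 * fs)
      gate <- pmax(gate, cosine_gate(n_samples, on, off, fs))
    }
    sig[c, ] <- sig[c, ] + comp * gate
    gt[[length(gt) + 1]] <- tibble::tibble(
      contact_id = e$contact_id, class_label = e$class_label,
      onset_ms = e$onset_ms, duration_ms = e$duration_ms,
      effect_size = e$effect_size,
      band_low = e$band[1], band_high = e$band[2])
  }
  gt <- if (length(gt)) dplyr::bind_rows(gt) else
    tibble::tibble(contact_id = character(), class_label = character(),
                   onset_ms = numeric(), duration_ms = numeric(),
                   effect_size = numeric(), band_low = numeric(),
                   band_high = numeric())

  session <- seeg_session(
    sig, fs, contacts,
    event_table(onsets, labels, modality = cfg$modality),
    meta = list(subject_id = "SIM", modality = cfg$modality,
                stimulus_ms = cfg$stimulus_ms, iti_ms = cfg$iti_ms,
                jitter_ms = cfg$jitter_ms))
  attr(session, "ground_truth") <- gt
  session
}
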