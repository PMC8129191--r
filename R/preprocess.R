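#' Frequency band definitions
#'
#' The three analysis bands: high-gamma (60-145 Hz), beta (13-30 Hz) and
#' alpha (8-12 Hz).
#'
#' @param name optional band name to look up.
#' @return a tibble of band definitions, or a single length-2 numeric range
#'   when `name` is given.
#' @export
band_definitions <- function(name = NULL) {
  bands <- tibble::tibble(
    name = c("high_gamma", "beta", "alpha"),
    low = c(60, 13, 8),
    high = c(145, 30, 12))
  if (is.null(name)) return(bands)
  row <- bands[bands$name == name, ]
  if (!nrow(row)) stop("unknown band: ", name)
  c(row$low, row$high)
}

# squared-magnitude frequency response |H|^2 of an IIR filter on the
# n-point DFT grid: multiplying a spectrum by it is the exact zero-phase
# (forward-backward) application of the filter, without edge transients
freq_gain_sq <- function(filt, n, e = NULL) {
  if (is.null(e)) e <- exp(-2i * pi * (seq_len(n) - 1) / n)
  horner <- function(cf) {
    acc <- rep(cf[length(cf)] + 0i, length(e))
    for (j in rev(seq_len(length(cf) - 1))) acc <- acc * e + cf[j]
    acc
  }
  Mod(horner(filt$b) / horner(filt$a))^2
}

# apply a real spectral gain to each row of a signal matrix (zero-phase)
apply_gain_rows <- function(signals, gain, rows = seq_len(nrow(signals))) {
  for (r in rows) {
    xf <- stats::fft(signals[r, ])
    signals[r, ] <- Re(stats::fft(xf * gain, inverse = TRUE)) /
      ncol(signals)
  }
  signals
}

# analytic signal via the frequency-domain construction (positive
# frequencies doubled, negative zeroed); no installed package exposes this.
analytic_signal <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(xf * h, inverse = TRUE) / n
}

#' Screen contacts for line-noise contamination
#'
#' Estimates each contact's power at the line frequency (mean periodogram
#' power within ±1 Hz of `line_freq`) and excludes every contact whose line
#' power strictly exceeds the median across contacts plus `mad_mult` times
#' their median absolute deviation (unscaled MAD). With identical line power
#' everywhere the MAD is zero and, because the comparison is strict, nothing
#' is removed.
#'
#' @param session a `seeg_session`.
#' @param line_freq line frequency, Hz.
#' @param mad_mult MAD multiplier for the exclusion threshold.
#' @param half_bw half-bandwidth of the line-power band, Hz.
#' @return the session with `excluded`/`exclusion_reason` updated; the
#'   per-contact line powers are attached as attribute `"line_power"`.
#' @export
screen_line_noise_contacts <- function(session, line_freq = 50,
                                       mad_mult = 10, half_bw = 1) {
  if (nrow(session$contacts) < 3)
    stop("need at least 3 contacts for a meaningful MAD-based screen")
  fs <- session$fs
  pw <- apply(session$signals, 1, function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                            detrend = TRUE, plot = FALSE)
    sel <- abs(sp$freq - line_freq) <= half_bw
    mean(sp$spec[sel])
  })
  thr <- stats::median(pw) + mad_mult * stats::mad(pw, constant = 1)
  bad <- pw > thr
  ct <- session$contacts
  ct$excluded <- ct$excluded | bad
  ct$exclusion_reason <- ifelse(bad & ct$exclusion_reason == "none",
                                "line_noise", ct$exclusion_reason)
  session$contacts <- ct
  attr(session, "line_power") <- pw
  session <- log_stage(session, "screen_line_noise")
  session
}

#' Comb notch filter at the line frequency and its harmonics
#'
#' Cascaded 4th-order Butterworth band-stop sections (±2 Hz) at `base`,
#' `2*base`, ... up to Nyquist. The cascade is applied zero-phase through
#' its squared-magnitude frequency response (the transient-free equivalent
#' of forward-backward filtering).
#'
#' @param session a `seeg_session`.
#' @param base line frequency, Hz.
#' @return the session with filtered signals.
#' @export
comb_notch <- function(session, base = 50) {
  fs <- session$fs
  n <- ncol(session$signals)
  harmonics <- seq(base, fs / 2 - base / 2, by = base)
  harmonics <- harmonics[harmonics + 2 < fs / 2]
  e <- exp(-2i * pi * (seq_len(n) - 1) / n)
  gain <- rep(1, n)
  for (h in harmonics)
    gain <- gain * freq_gain_sq(
      signal::butter(2, c(h - 2, h + 2) / (fs / 2), "stop"), n, e)
  session$signals <- apply_gain_rows(session$signals, gain)
  log_stage(session, "comb_notch")
}

#' Shaft-Laplacian re-referencing
#'
#' Each non-excluded contact is re-referenced against the mean of its
#' nearest non-excluded neighbours along the same shaft (one on each side;
#' end contacts use their single inner neighbour). All referenced traces are
#' computed from the original signals simultaneously. A contact with no
#' available neighbour (single-contact shaft after exclusions) is excluded
#' with reason `"no_neighbor"` and a warning.
#'
#' @param session a `seeg_session`.
#' @return the re-referenced session.
#' @export
laplacian_reference <- function(session) {
  ct <- session$contacts
  orig <- session$signals
  out <- orig
  orphan <- character()
  for (sh in unique(ct$shaft_id)) {
    rows <- which(ct$shaft_id == sh & !ct$excluded)
    rows <- rows[order(ct$index_on_shaft[rows])]
    if (length(rows) == 1) {
      orphan <- c(orphan, ct$contact_id[rows])
      next
    }
    for (j in seq_along(rows)) {
      nb <- rows[c(j - 1, j + 1)[c(j - 1, j + 1) >= 1 &
                                  c(j - 1, j + 1) <= length(rows)]]
      out[rows[j], ] <- orig[rows[j], ] -
        colMeans(orig[nb, , drop = FALSE])
    }
  }
  if (length(orphan)) {
    warning("contacts with no same-shaft neighbour excluded: ",
            paste(orphan, collapse = ", "))
    i <- match(orphan, ct$contact_id)
    ct$excluded[i] <- TRUE
    ct$exclusion_reason[i] <- "no_neighbor"
  }
  session$signals <- out
  session$contacts <- ct
  log_stage(session, "laplacian_reference")
}

#' Instantaneous band power
#'
#' Band-passes each kept contact with a 6th-order Butterworth filter
#' (applied zero-phase through its squared-magnitude response) and squares
#' the analytic-signal magnitude:
#' `power(t) = |analytic(bandpassed)(t)|^2`. The band-pass and the
#' analytic-signal construction share one FFT per contact.
#'
#' @param session a `seeg_session`.
#' @param band band name (see [band_definitions()]) or numeric length-2
#'   range in Hz.
#' @return object of class `seeg_power`: list with `power`
#'   (contacts x samples; `NA` rows for excluded contacts), `fs`,
#'   `contacts`, `events`, `band`, `meta`, `log`.
#' @export
band_power <- function(session, band = "high_gamma") {
  band_range <- if (is.character(band)) band_definitions(band) else band
  band_name <- if (is.character(band)) band else
    paste0(band[1], "-", band[2], "Hz")
  fs <- session$fs
  if (band_range[1] <= 0 || band_range[2] >= fs / 2)
    stop("band edges must lie strictly inside (0, fs/2)")
  bf <- signal::butter(3, band_range / (fs / 2), "pass")
  n <- ncol(session$signals)
  gain <- freq_gain_sq(bf, n)
  h <- numeric(n)                      # analytic-signal weights
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  pw <- matrix(NA_real_, nrow(session$signals), n)
  for (c in which(!session$contacts$excluded)) {
    xf <- stats::fft(session$signals[c, ])
    pw[c, ] <- Mod(stats::fft(xf * gain * h, inverse = TRUE) / n)^2
  }
  structure(list(power = pw, fs = fs, contacts = session$contacts,
                 events = session$events, band = band_name,
                 band_range = band_range, meta = session$meta,
                 log = c(attr(session, "stage_log"), "band_power")),
            class = "seeg_power")
}

#' Epoch band power and z-score against the pre-stimulus baseline
#'
#' Cuts the continuous power trace into per-trial windows (0 to
#' `window_ms` after each onset) and z-scores each trial/contact against
#' the mean and SD of that trial's own `baseline_ms` pre-onset interval.
#' The raw post-onset power and raw baseline power are retained for the
#' latency tests.
#'
#' @param power a `seeg_power`.
#' @param events optional event table overriding the one carried by `power`.
#' @param baseline_ms baseline length, ms (immediately pre-onset).
#' @param window_ms post-onset window length, ms.
#' @return object of class `seeg_epochs`: `z_power`, `raw_power`
#'   (trials x kept contacts x window samples), `baseline_power`
#'   (trials x kept contacts x baseline samples), `labels`, `fs`,
#'   `contacts` (full table with exclusion flags; array rows follow the
#'   non-excluded subset), `band`, `log`.
#' @export
epoch_and_zscore <- function(power, events = NULL, baseline_ms = 200,
                             window_ms = 1000) {
  stopifnot(inherits(power, "seeg_power"))
  ev <- events %||% power$events
  fs <- power$fs
  nb <- round(baseline_ms / 1000 * fs)
  nw <- round(window_ms / 1000 * fs)
  keep <- which(!power$contacts$excluded)
  n_tr <- nrow(ev)
  if (any(ev$onset_sample - nb < 0))
    stop("event at sample ", ev$onset_sample[which(ev$onset_sample < nb)[1]],
         ": fewer than ", baseline_ms, " ms of pre-onset signal")
  if (any(ev$onset_sample + nw > ncol(power$power)))
    stop("post-onset window extends beyond recording end")

  zp <- rp <- array(NA_real_, c(n_tr, length(keep), nw))
  bp <- array(NA_real_, c(n_tr, length(keep), nb))
  for (t in seq_len(n_tr)) {
    on <- ev$onset_sample[t]            # 0-based: sample on+1 is onset
    for (j in seq_along(keep)) {
      base <- power$power[keep[j], (on - nb + 1):on]
      post <- power$power[keep[j], (on + 1):(on + nw)]
      mu <- mean(base); s <- stats::sd(base)
      if (s == 0)
        stop(sprintf("trial %d, contact %s: constant baseline (sd = 0)",
                     t, power$contacts$contact_id[keep[j]]))
      bp[t, j, ] <- base
      rp[t, j, ] <- post
      zp[t, j, ] <- (post - mu) / s
    }
  }
  structure(list(z_power = zp, raw_power = rp, baseline_power = bp,
                 labels = ev$class_label, fs = fs,
                 contacts = power$contacts, band = power$band,
                 window_ms = window_ms, baseline_ms = baseline_ms,
                 log = c(power$log, "epoch_and_zscore")),
            class = "seeg_epochs")
}

#' @export
print.seeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<seeg_epochs> %s band: %d trials x %d contacts x %d samples (%d ms), %d ms baseline\n",
    x$band, dim(x$z_power)[1], dim(x$z_power)[2], dim(x$z_power)[3],
    x$window_ms, x$baseline_ms))
  invisible(x)
}

gaussian_kernel <- function(window_ms, fs) {
  half <- round(window_ms / 2 / 1000 * fs)
  sigma <- window_ms / 6 / 1000 * fs     # total support = ±3 sigma
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k / sum(k)
}

smooth_reflect <- function(x, k) {
  h <- (length(k) - 1) / 2
  n <- length(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  as.numeric(stats::filter(xp, k, sides = 2))[(h + 1):(h + n)]
}

#' Gaussian smoothing of epoched power
#'
#' Convolves every trial/contact z-power trace with a unit-area Gaussian
#' kernel of total support `window_ms` (sigma = `window_ms`/6, truncated at
#' ±3 sigma), with reflective boundary handling. Constant traces pass
#' through unchanged.
#'
#' @param epochs a `seeg_epochs`.
#' @param window_ms kernel support, ms.
#' @return the smoothed `seeg_epochs`.
#' @export
smooth_gaussian <- function(epochs, window_ms = 80) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  if (window_ms >= epochs$window_ms)
    stop("smoothing window must be shorter than the epoch")
  k <- gaussian_kernel(window_ms, epochs$fs)
  d <- dim(epochs$z_power)
  for (t in seq_len(d[1]))
    for (j in seq_len(d[2]))
      epochs$z_power[t, j, ] <- smooth_reflect(epochs$z_power[t, j, ], k)
  epochs$log <- c(epochs$log, "smooth_gaussian")
  epochs
}

#' Reject artifact-contaminated contacts
#'
#' For each contact the across-trial mean `M(t)` and standard error `SE(t)`
#' of the smoothed z-power are computed. Under the default rule a contact is
#' removed when `SE(t) > |M(t)|` at any post-onset time point where
#' `|M(t)|` exceeds `floor`. The floor keeps the rule away from time points
#' where the mean response merely crosses zero: there `SE > |M|` holds by
#' chance alone, since under the null `|M(t)|` is itself of order `SE(t)`.
#' The default 0.25 z sits a factor of ~2 above the across-trial SE at
#' typical trial counts (~0.09-0.15 z for 60-120 trials), so clean contacts
#' are essentially never removed while an artifact that shifts the mean by
#' more than `floor * n_trials` z-units on one trial still is. The alternative rule
#' `"se_vs_time_avg_se"` removes a contact when `SE(t)` exceeds twice its
#' own time average at any point.
#'
#' @param epochs a `seeg_epochs` (>= 2 trials).
#' @param floor minimal `|M(t)|` (z-units) at which the default rule
#'   applies.
#' @param rule which reading of the rejection rule to apply.
#' @return the `seeg_epochs` with offending contacts dropped from the
#'   arrays and flagged in the contacts table (reason `"artifact"`).
#' @export
reject_artifact_contacts <- function(epochs, floor = 0.25,
                                     rule = c("se_vs_mean_power",
                                              "se_vs_time_avg_se")) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  rule <- match.arg(rule)
  d <- dim(epochs$z_power)
  if (d[1] < 2) stop("artifact rejection needs at least 2 trials")
  kept_rows <- which(!epochs$contacts$excluded)
  bad <- logical(d[2])
  for (j in seq_len(d[2])) {
    tr <- epochs$z_power[, j, ]
    m <- colMeans(tr)
    se <- apply(tr, 2, stats::sd) / sqrt(d[1])
    bad[j] <- if (rule == "se_vs_mean_power")
      any(se > abs(m) & abs(m) >= floor)
    else any(se > 2 * mean(se))
  }
  if (any(bad)) {
    rows <- kept_rows[bad]
    epochs$contacts$excluded[rows] <- TRUE
    epochs$contacts$exclusion_reason[rows] <- "artifact"
    epochs$z_power <- epochs$z_power[, !bad, , drop = FALSE]
    epochs$raw_power <- epochs$raw_power[, !bad, , drop = FALSE]
    epochs$baseline_power <- epochs$baseline_power[, !bad, , drop = FALSE]
  }
  epochs$log <- c(epochs$log, "reject_artifact_contacts")
  epochs
}

#' Full pre-processing chain
#'
#' Runs the fixed stage order: line-noise contact screen, comb notch,
#' shaft-Laplacian reference, Butterworth band-pass + Hilbert power,
#' epoching with per-trial baseline z-scoring, Gaussian smoothing, and
#' artifact-contact rejection. The stage order is recorded in the result's
#' `log` element.
#'
#' @param session a `seeg_session`.
#' @param band band name or numeric range, see [band_power()].
#' @param config an [analysis_config()].
#' @return a `seeg_epochs` ready for [bin_features()].
#' @export
preprocess <- function(session, band = "high_gamma",
                       config = analysis_config()) {
  session <- screen_line_noise_contacts(session,
                                        line_freq = config$line_freq,
                                        mad_mult = config$mad_mult)
  session <- comb_notch(session, base = config$line_freq)
  session <- laplacian_reference(session)
  pw <- band_power(session, band)
  ep <- epoch_and_zscore(pw, baseline_ms = config$baseline_ms,
                         window_ms = config$window_ms)
  ep <- smooth_gaussian(ep, window_ms = config$smooth_ms)
  reject_artifact_contacts(ep, floor = config$artifact_floor,
                           rule = config$artifact_rule)
}

log_stage <- function(session, stage) {
  attr(session, "stage_log") <- c(attr(session, "stage_log"), stage)
  session
}

#' Stage provenance of a pipeline object
#' @param x a `seeg_session`, `seeg_power` or `seeg_epochs`.
#' @return character vector of stages applied, in order.
#' @export
stage_log <- function(x) {
  if (inherits(x, "seeg_session")) attr(x, "stage_log") else x$log
}
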