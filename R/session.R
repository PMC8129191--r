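#' SEEG recording sessions
#'
#' A `seeg_session` bundles one subject/modality worth of data: the continuous
#' multichannel recording, its sampling rate, the per-contact metadata
#' (shaft membership, position along the shaft, anatomical region label) and
#' the event table marking stimulus onsets. It is the input to the whole
#' pipeline.
#'
#' @param signals numeric matrix, contacts x samples, in microvolts.
#' @param fs sampling frequency in Hz.
#' @param contacts tibble of contact metadata, see [contact_table()].
#' @param events tibble of events, see [event_table()].
#' @param meta named list with at least `subject_id`, `modality`,
#'   `stimulus_ms`, `iti_ms`, `jitter_ms`.
#' @param validate run [validate_session()] on the result (default `TRUE`).
#'
#' @return an object of class `seeg_session`: a list with elements
#'   `signals`, `fs`, `contacts`, `events`, `meta`.
#' @export
seeg_session <- function(signals, fs, contacts, events, meta = list(),
                         validate = TRUE) {
  meta_defaults <- list(subject_id = "S0", modality = "auditory",
                        stimulus_ms = 1000, iti_ms = 1000, jitter_ms = c(0, 0))
  meta <- utils::modifyList(meta_defaults, meta)
  x <- structure(
    list(signals = signals, fs = fs,
         contacts = tibble::as_tibble(contacts),
         events = tibble::as_tibble(events),
         meta = meta),
    class = "seeg_session")
  if (validate) validate_session(x)
  x
}

#' Build a contact metadata table
#'
#' @param contact_id character vector of unique contact names.
#' @param shaft_id character vector, shaft (electrode) each contact sits on.
#' @param index_on_shaft integer, 1-based position along the shaft.
#' @param region_label anatomical parcel name (free string, matched
#'   case-insensitively after whitespace normalization).
#' @param hemisphere `"left"` or `"right"`.
#' @param mni_x,mni_y,mni_z optional MNI coordinates in millimetres.
#' @param excluded logical inclusion flag.
#' @param exclusion_reason one of `"none"`, `"line_noise"`, `"artifact"`,
#'   `"no_neighbor"`.
#' @return a tibble with one row per contact.
#' @export
contact_table <- function(contact_id, shaft_id, index_on_shaft,
                          region_label = "unknown",
                          hemisphere = "left",
                          mni_x = NA_real_, mni_y = NA_real_, mni_z = NA_real_,
                          excluded = FALSE, exclusion_reason = "none") {
  tibble::tibble(
    contact_id = as.character(contact_id),
    shaft_id = as.character(shaft_id),
    index_on_shaft = as.integer(index_on_shaft),
    region_label = region_label,
    hemisphere = hemisphere,
    mni_x = mni_x, mni_y = mni_y, mni_z = mni_z,
    excluded = excluded,
    exclusion_reason = exclusion_reason)
}

#' Build an event table
#'
#' Onsets are stored as 0-based integer sample indices; conversion to
#' milliseconds uses the session sampling rate, avoiding rounding drift.
#'
#' @param onset_sample integer vector, 0-based sample index of each stimulus
#'   onset, strictly increasing.
#' @param class_label `"own"`, `"other"` or `"rest"` per event.
#' @param modality `"auditory"` or `"visual"`.
#' @return a tibble with one row per event.
#' @export
event_table <- function(onset_sample, class_label, modality = "auditory") {
  tibble::tibble(
    onset_sample = as.integer(onset_sample),
    class_label = as.character(class_label),
    modality = modality)
}

#' Normalize a region label for matching
#'
#' Lower-cases and collapses whitespace so that `"Left  Insula "` and
#' `"left insula"` compare equal.
#' @param x character vector of region labels.
#' @return normalized character vector.
#' @export
normalize_region <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Validate a recording session
#'
#' Checks the structural invariants the pipeline relies on: signal/contact
#' agreement, unique contact identities, contiguous 1-based indices along
#' each shaft, strictly increasing and fairly balanced events, and that every
#' post-onset analysis window lies inside the recording. Violations raise an
#' error naming the offending contact or event row.
#'
#' @param session a `seeg_session`.
#' @return the session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "seeg_session"))
  sig <- session$signals
  ct <- session$contacts
  ev <- session$events
  if (!is.matrix(sig) || !is.numeric(sig))
    stop("signals must be a numeric matrix (contacts x samples)")
  if (nrow(sig) != nrow(ct))
    stop(sprintf("signals has %d rows but contacts table has %d entries",
                 nrow(sig), nrow(ct)))
  if (!(is.numeric(session$fs) && length(session$fs) == 1 && session$fs > 0))
    stop("fs must be a positive scalar")
  dup <- ct$contact_id[duplicated(ct$contact_id)]
  if (length(dup))
    stop("duplicate contact ids: ", paste(unique(dup), collapse = ", "))
  key <- paste(ct$shaft_id, ct$index_on_shaft)
  if (anyDuplicated(key))
    stop("duplicate (shaft_id, index_on_shaft) pair: ",
         key[duplicated(key)][1])
  for (sh in unique(ct$shaft_id)) {
    idx <- sort(ct$index_on_shaft[ct$shaft_id == sh])
    if (!identical(idx, seq_along(idx)))
      stop(sprintf("shaft %s: index_on_shaft must run 1..k contiguously", sh))
  }
  if (nrow(ev)) {
    if (any(diff(ev$onset_sample) <= 0)) {
      i <- which(diff(ev$onset_sample) <= 0)[1] + 1L
      stop(sprintf("event row %d: onsets must be strictly increasing", i))
    }
    bad <- which(ev$onset_sample < 0 |
                   ev$onset_sample + session$meta$stimulus_ms / 1000 * session$fs >
                   ncol(sig))
    if (length(bad))
      stop(sprintf(
        "event row %d: onset + stimulus window extends beyond recording end",
        bad[1]))
    n_own <- sum(ev$class_label == "own")
    n_other <- sum(ev$class_label == "other")
    if (n_own != n_other)
      stop(sprintf("unbalanced design: %d own vs %d other events",
                   n_own, n_other))
    if (!all(ev$class_label %in% c("own", "other", "rest")))
      stop("class_label must be one of own/other/rest")
  }
  invisible(session)
}

#' @export
print.seeg_session <- function(x, ...) {
  cat(sprintf(
    "<seeg_session> subject %s, %s modality\n  %d contacts on %d shafts, %.1f s at %g Hz, %d events (%d own / %d other)\n",
    x$meta$subject_id, x$meta$modality, nrow(x$contacts),
    length(unique(x$contacts$shaft_id)), ncol(x$signals) / x$fs, x$fs,
    nrow(x$events), sum(x$events$class_label == "own"),
    sum(x$events$class_label == "other")))
  invisible(x)
}

#' Number of kept (non-excluded) contacts
#' @param session a `seeg_session`.
#' @return integer count.
#' @export
n_kept_contacts <- function(session) sum(!session$contacts$excluded)

# ---- serialization ----------------------------------------------------------

#' Write a session to disk
#'
#' Emits the native on-disk layout: `signals.h5` (HDF5, float64 so the
#' round trip is bit-exact), `events.tsv` and `channels.tsv` following
#' BIDS-iEEG column conventions (`onset`, `trial_type`; `name`, `group`),
#' and `meta.json`. A ground-truth sidecar (`ground_truth.tsv`) is written
#' when the session carries one (synthetic sessions do).
#'
#' @param session a valid `seeg_session`.
#' @param out_dir output directory, created if missing.
#' @return named character vector of the files written, invisibly.
#' @export
write_session <- function(session, out_dir) {
  validate_session(session)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(out_dir, "signals.h5")
  ev_path <- file.path(out_dir, "events.tsv")
  ch_path <- file.path(out_dir, "channels.tsv")
  meta_path <- file.path(out_dir, "meta.json")

  if (file.exists(sig_path)) unlink(sig_path)
  rhdf5::h5createFile(sig_path)
  rhdf5::h5write(session$signals, sig_path, "signals")
  rhdf5::h5write(as.numeric(session$fs), sig_path, "fs")
  rhdf5::H5close()

  ev <- session$events
  ev_out <- tibble::tibble(
    onset = ev$onset_sample / session$fs,
    duration = session$meta$stimulus_ms / 1000,
    trial_type = ev$class_label,
    onset_sample = ev$onset_sample,
    modality = ev$modality)
  readr::write_tsv(ev_out, ev_path)

  ct <- session$contacts
  ch_out <- tibble::tibble(
    name = ct$contact_id, group = ct$shaft_id,
    index_on_shaft = ct$index_on_shaft,
    region = ct$region_label, hemisphere = ct$hemisphere,
    x = ct$mni_x, y = ct$mni_y, z = ct$mni_z,
    status = ifelse(ct$excluded, "bad", "good"),
    status_description = ct$exclusion_reason)
  readr::write_tsv(ch_path, x = ch_out)

  jsonlite::write_json(session$meta, meta_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(signals = sig_path, events = ev_path, channels = ch_path,
             meta = meta_path)

  gt <- attr(session, "ground_truth")
  if (!is.null(gt)) {
    gt_path <- file.path(out_dir, "ground_truth.tsv")
    readr::write_tsv(gt, gt_path)
    paths <- c(paths, ground_truth = gt_path)
  }
  invisible(paths)
}

#' Read a session from disk
#'
#' Reads signals from the native HDF5 container or from an EDF file
#' (`.edf`; 16-bit quantization, accepted as lossy), plus tab-separated
#' events and channels tables. If `signal_path` is a directory, the standard
#' file names written by [write_session()] are assumed.
#'
#' @param signal_path path to `signals.h5`, an `.edf` file, or a session
#'   directory.
#' @param events_path,channels_path,meta_path paths to the TSV/JSON tables;
#'   derived from the directory when `signal_path` is a directory.
#' @return a validated `seeg_session`.
#' @export
read_session <- function(signal_path, events_path = NULL,
                         channels_path = NULL, meta_path = NULL) {
  if (dir.exists(signal_path)) {
    d <- signal_path
    signal_path <- if (file.exists(file.path(d, "signals.h5")))
      file.path(d, "signals.h5") else file.path(d, "signals.edf")
    events_path <- events_path %||% file.path(d, "events.tsv")
    channels_path <- channels_path %||% file.path(d, "channels.tsv")
    mp <- file.path(d, "meta.json")
    if (is.null(meta_path) && file.exists(mp)) meta_path <- mp
  }
  if (grepl("\\.edf$", signal_path, ignore.case = TRUE)) {
    edf <- read_edf(signal_path)
    signals <- edf$signals
    fs <- edf$fs
  } else {
    signals <- rhdf5::h5read(signal_path, "signals")
    fs <- as.numeric(rhdf5::h5read(signal_path, "fs"))
    rhdf5::H5close()
  }

  ch <- readr::read_tsv(channels_path, show_col_types = FALSE,
                        progress = FALSE)
  need <- c("name", "group")
  miss <- setdiff(need, names(ch))
  if (length(miss))
    stop("channels table missing columns: ", paste(miss, collapse = ", "))
  contacts <- contact_table(
    contact_id = ch$name, shaft_id = ch$group,
    index_on_shaft = ch$index_on_shaft %||% stats::ave(
      seq_len(nrow(ch)), ch$group, FUN = seq_along),
    region_label = as.character(ch$region %||% "unknown"),
    hemisphere = as.character(ch$hemisphere %||% "left"),
    mni_x = as.numeric(ch$x %||% NA_real_),
    mni_y = as.numeric(ch$y %||% NA_real_),
    mni_z = as.numeric(ch$z %||% NA_real_),
    excluded = (ch$status %||% "good") == "bad",
    exclusion_reason = as.character(ch$status_description %||% "none"))

  ev <- readr::read_tsv(events_path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("onset", "trial_type"), names(ev))
  if (length(miss) && !("onset_sample" %in% names(ev)))
    stop("events table missing columns: ", paste(miss, collapse = ", "))
  onset_sample <- if ("onset_sample" %in% names(ev)) ev$onset_sample
    else as.integer(round(ev$onset * fs))
  events <- event_table(onset_sample, ev$trial_type,
                        modality = as.character(ev$modality %||% "auditory"))

  meta <- if (!is.null(meta_path)) jsonlite::read_json(meta_path,
                                                       simplifyVector = TRUE)
          else list()
  seeg_session(signals, fs, contacts, events, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
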