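#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its conventional default:
#' high-gamma band, LDA classifier, 20 selected features (10 per pair in
#' the three-class control), 1,000 permutations for selection, accuracy
#' significance and latency tests, 200 ms baseline, 1,000 ms analysis
#' window, 80 ms smoothing, 10 ms bins, MAD multiplier 10 for the
#' line-noise screen, and per-fold feature selection.
#'
#' @param band frequency band name or numeric range.
#' @param classifier `"lda"` or `"random_forest"`.
#' @param k selected features (two-class).
#' @param k_per_pair selected features per pairwise test (three-class).
#' @param alpha significance level (selection and accuracy).
#' @param n_perm_select,n_perm_acc,n_perm_latency permutation counts.
#' @param baseline_ms,window_ms,smooth_ms,bin_ms timing parameters, ms.
#' @param mad_mult,line_freq line-noise screen parameters.
#' @param artifact_floor,artifact_rule artifact-rejection parameters, see
#'   [reject_artifact_contacts()].
#' @param selection_mode `"per_fold"` (selection inside each training
#'   fold) or `"one_shot"` (whole-session selection, reporting only).
#' @param latency_persistence consecutive significant bins required for a
#'   latency call. The per-bin tests are uncorrected, so a single-bin
#'   first crossing is almost surely a false onset somewhere among 100
#'   bins; requiring 3 consecutive significant bins keeps the family-wise
#'   false-onset rate near 1% while leaving a sustained response's first
#'   bin untouched.
#' @param seed RNG seed for every stochastic step.
#' @return a list of class `seeg_config`.
#' @export
analysis_config <- function(band = "high_gamma", classifier = "lda",
                            k = 20, k_per_pair = 10, alpha = 0.05,
                            n_perm_select = 1000, n_perm_acc = 1000,
                            n_perm_latency = 1000, baseline_ms = 200,
                            window_ms = 1000, smooth_ms = 80, bin_ms = 10,
                            mad_mult = 10, line_freq = 50,
                            artifact_floor = 0.25,
                            artifact_rule = "se_vs_mean_power",
                            selection_mode = c("per_fold", "one_shot"),
                            latency_persistence = 3, seed = 1) {
  selection_mode <- match.arg(selection_mode)
  structure(list(band = band, classifier = classifier, k = k,
                 k_per_pair = k_per_pair, alpha = alpha,
                 n_perm_select = n_perm_select, n_perm_acc = n_perm_acc,
                 n_perm_latency = n_perm_latency,
                 baseline_ms = baseline_ms, window_ms = window_ms,
                 smooth_ms = smooth_ms, bin_ms = bin_ms,
                 mad_mult = mad_mult, line_freq = line_freq,
                 artifact_floor = artifact_floor,
                 artifact_rule = artifact_rule,
                 selection_mode = selection_mode,
                 latency_persistence = latency_persistence, seed = seed),
            class = "seeg_config")
}

band_power_chain <- function(session, config) {
  session <- screen_line_noise_contacts(session,
                                        line_freq = config$line_freq,
                                        mad_mult = config$mad_mult)
  session <- comb_notch(session, base = config$line_freq)
  session <- laplacian_reference(session)
  band_power(session, config$band)
}

#' Run the full two-class analysis
#'
#' Pre-processes the session, runs per-fold feature selection and
#' leave-one-out decoding with permutation significance, produces the
#' one-shot reporting selection and its per-region contribution table,
#' decodes the top-contributing region alone, and estimates response
#' latencies for the contacts contributing to the selected feature set.
#'
#' @param session a `seeg_session` (or a [sim_config()], which is
#'   generated first).
#' @param config an [analysis_config()].
#' @param latencies compute the per-contact latency table (slowest stage;
#'   set `FALSE` to skip).
#' @return a list of class `seeg_report`; see the elements `decoding`,
#'   `regions`, `top_region`, `latencies`, `report_features`,
#'   `removed_contacts`, `provenance`.
#' @export
run_two_class <- function(session, config = analysis_config(),
                          latencies = TRUE) {
  if (inherits(session, "sim_config")) session <- generate_session(session)
  validate_session(session)
  ep <- preprocess(session, band = config$band, config = config)
  feats <- bin_features(ep, bin_ms = config$bin_ms)
  # one-shot whole-session selection: used for reporting which regions and
  # contacts contribute; it also drives decoding when selection_mode is
  # "one_shot", but the default per-fold mode re-selects inside each fold
  rep_sel <- select_top_features(feats, k = min(config$k, ncol(feats$x)),
                                 alpha = config$alpha,
                                 n_perm = config$n_perm_select,
                                 seed = config$seed)
  dec_in <- if (config$selection_mode == "per_fold") feats else rep_sel
  res <- loo_decode(dec_in, classifier = config$classifier, k = config$k,
                    per_fold = config$selection_mode == "per_fold",
                    n_perm_select = config$n_perm_select,
                    alpha = config$alpha, seed = config$seed)
  res <- accuracy_significance(res, n_perm = config$n_perm_acc,
                               seed = config$seed)
  regions <- region_contribution(rep_sel)
  top_region <- regions$region_label[regions$is_max][1]
  top_res <- single_region_accuracy(ep, top_region, config)

  lat <- NULL
  if (latencies) {
    ids <- unique(selected_features(rep_sel)$provenance$contact_id)
    lat <- latency_table(ep, ids, alpha = config$alpha,
                         n_perm = config$n_perm_latency,
                         seed = config$seed,
                         persistence = config$latency_persistence,
                         bin_ms = config$bin_ms)
  }
  removed <- ep$contacts[ep$contacts$excluded, c("contact_id",
                                                 "exclusion_reason")]
  structure(list(meta = session$meta, config = config,
                 decoding = res, report_features = rep_sel,
                 regions = regions, top_region = top_region,
                 top_region_decoding = top_res, latencies = lat,
                 removed_contacts = removed,
                 n_kept_contacts = sum(!ep$contacts$excluded),
                 provenance = ep$log),
            class = "seeg_report")
}

#' @export
print.seeg_report <- function(x, ...) {
  cat(sprintf("<seeg_report> subject %s (%s), %s band\n",
              x$meta$subject_id, x$meta$modality, x$config$band))
  cat(sprintf("  kept %d contacts (removed: %d)\n", x$n_kept_contacts,
              nrow(x$removed_contacts)))
  cat(sprintf("  accuracy %.1f%% (threshold %.1f%%, p = %.3g)\n",
              x$decoding$accuracy, x$decoding$significance_threshold,
              x$decoding$permutation_p))
  cat(sprintf("  top region: %s (%d features, single-region accuracy %.1f%%)\n",
              x$top_region,
              x$regions$n_features[x$regions$is_max][1],
              x$top_region_decoding$accuracy))
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param report a `seeg_report` or `seeg_report3`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(meta = report$meta,
              config = unclass(report$config),
              provenance = report$provenance,
              removed_contacts = report$removed_contacts,
              decoding = glance(report$decoding),
              trials = tidy(report$decoding))
  if (!is.null(report$regions)) out$regions <- report$regions
  if (!is.null(report$latencies)) out$latencies <- report$latencies
  if (!is.null(report$multiclass)) {
    out$confusion <- report$multiclass$confusion
    out$class_metrics <- report$multiclass$metrics
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# rest epochs: the 1,000 ms window preceding each selected onset, z-scored
# against its own first 200 ms, binned like stimulus epochs
rest_epochs <- function(power, events, config, every = 2L) {
  fs <- power$fs
  nw <- round(config$window_ms / 1000 * fs)
  nb <- round(config$baseline_ms / 1000 * fs)
  stim_smp <- round(power$meta$stimulus_ms / 1000 * fs)
  sel_ev <- events[seq(1, nrow(events), by = every), ]
  prev_end <- c(-Inf, events$onset_sample + stim_smp)[
    match(sel_ev$onset_sample, events$onset_sample)]
  if (any(sel_ev$onset_sample - nw < prev_end))
    stop("rest window overlaps the preceding stimulus: increase the ",
         "inter-trial interval")
  if (any(sel_ev$onset_sample - nw < 0))
    stop("rest window precedes the recording start")
  rest_ev <- event_table(sel_ev$onset_sample - nw,
                         rep("rest", nrow(sel_ev)),
                         modality = sel_ev$modality)
  keep <- which(!power$contacts$excluded)
  n_tr <- nrow(rest_ev)
  zp <- rp <- array(NA_real_, c(n_tr, length(keep), nw))
  bp <- array(NA_real_, c(n_tr, length(keep), nb))
  for (t in seq_len(n_tr)) {
    on <- rest_ev$onset_sample[t]
    for (j in seq_along(keep)) {
      win <- power$power[keep[j], (on + 1):(on + nw)]
      base <- win[seq_len(nb)]
      mu <- mean(base); s <- stats::sd(base)
      if (s == 0)
        stop(sprintf("rest trial %d, contact %s: constant baseline", t,
                     power$contacts$contact_id[keep[j]]))
      zp[t, j, ] <- (win - mu) / s
      rp[t, j, ] <- win
      bp[t, j, ] <- base
    }
  }
  structure(list(z_power = zp, raw_power = rp, baseline_power = bp,
                 labels = rest_ev$class_label, fs = fs,
                 contacts = power$contacts, band = power$band,
                 window_ms = config$window_ms,
                 baseline_ms = config$baseline_ms,
                 log = c(power$log, "rest_epochs")),
            class = "seeg_epochs")
}

bind_epochs <- function(a, b) {
  stopifnot(dim(a$z_power)[2] == dim(b$z_power)[2],
            dim(a$z_power)[3] == dim(b$z_power)[3])
  bind3 <- function(x, y) {
    out <- array(NA_real_, c(dim(x)[1] + dim(y)[1], dim(x)[2], dim(x)[3]))
    out[seq_len(dim(x)[1]), , ] <- x
    out[dim(x)[1] + seq_len(dim(y)[1]), , ] <- y
    out
  }
  a$z_power <- bind3(a$z_power, b$z_power)
  a$raw_power <- bind3(a$raw_power, b$raw_power)
  a$baseline_power <- bind3(a$baseline_power, b$baseline_power)
  a$labels <- c(a$labels, b$labels)
  a$log <- unique(c(a$log, b$log))
  a
}

#' Run the three-class (rest / own / other) control analysis
#'
#' Adds a rest class built from the 1,000 ms pre-onset interval (z-scored
#' against its own first 200 ms, symmetric with stimulus epochs) of every
#' second event, so that the three classes are equal sized. Feature
#' selection is run pairwise (10 features per pair, 30 in total) inside
#' each leave-one-out fold; the result is summarised by confusion matrix,
#' per-class sensitivity and precision, and one-vs-rest ROC/AUC.
#'
#' @inheritParams run_two_class
#' @return a list of class `seeg_report3` with `decoding` and
#'   `multiclass` elements.
#' @export
run_three_class <- function(session, config = analysis_config()) {
  if (inherits(session, "sim_config")) session <- generate_session(session)
  validate_session(session)
  pw <- band_power_chain(session, config)
  stim <- epoch_and_zscore(pw, baseline_ms = config$baseline_ms,
                           window_ms = config$window_ms)
  rest <- rest_epochs(pw, session$events, config)
  ep <- bind_epochs(stim, rest)
  ep <- smooth_gaussian(ep, window_ms = config$smooth_ms)
  ep <- reject_artifact_contacts(ep, floor = config$artifact_floor,
                                 rule = config$artifact_rule)
  feats <- bin_features(ep, bin_ms = config$bin_ms)
  res <- loo_decode(feats, classifier = config$classifier,
                    k_per_pair = config$k_per_pair,
                    per_fold = config$selection_mode == "per_fold",
                    n_perm_select = config$n_perm_select,
                    alpha = config$alpha, seed = config$seed)
  res <- accuracy_significance(res, n_perm = config$n_perm_acc,
                               seed = config$seed)
  mc <- evaluate_threeclass(res)
  removed <- ep$contacts[ep$contacts$excluded, c("contact_id",
                                                 "exclusion_reason")]
  structure(list(meta = session$meta, config = config, decoding = res,
                 multiclass = mc, removed_contacts = removed,
                 n_kept_contacts = sum(!ep$contacts$excluded),
                 provenance = ep$log),
            class = "seeg_report3")
}

#' @export
print.seeg_report3 <- function(x, ...) {
  cat(sprintf("<seeg_report3> subject %s (%s): accuracy %.1f%% (threshold %.1f%%)\n",
              x$meta$subject_id, x$meta$modality, x$decoding$accuracy,
              x$decoding$significance_threshold))
  print(x$multiclass$metrics)
  invisible(x)
}
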