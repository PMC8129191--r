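#' Per-region contribution to the selected feature set
#'
#' Counts how many selected features trace to each anatomical region
#' (labels matched case-insensitively after whitespace normalization) and
#' flags the maximal contributor(s); ties are all flagged, mirroring joint
#' reporting of co-maximal regions.
#'
#' @param features a selected `seeg_features` (one-shot reporting
#'   selection; in per-fold decoding the contribution report comes from
#'   this whole-session selection).
#' @param contacts optional contact table used to count contacts per
#'   region.
#' @return tibble: `region_label`, `n_features`, `n_contacts`
#'   (contributing contacts), `is_max`.
#' @export
region_contribution <- function(features, contacts = NULL) {
  sel <- selected_features(features)$provenance
  if (any(is.na(sel$region_label) | sel$region_label == ""))
    stop("unlabeled contact among selected features")
  sel$region_norm <- normalize_region(sel$region_label)
  out <- sel |>
    dplyr::group_by(.data$region_norm) |>
    dplyr::summarise(region_label = dplyr::first(.data$region_label),
                     n_features = dplyr::n(),
                     n_contacts = dplyr::n_distinct(.data$contact_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_features))
  out$is_max <- out$n_features == max(out$n_features)
  dplyr::select(out, "region_label", "n_features", "n_contacts", "is_max")
}

#' Decode using contacts of a single region
#'
#' Re-runs the full feature extraction + selection + leave-one-out decoding
#' restricted to the region's kept contacts, with the same settings as the
#' multi-region analysis, and attaches the permutation significance
#' threshold.
#'
#' @param epochs a `seeg_epochs`.
#' @param region region label (matched case-insensitively).
#' @param config an [analysis_config()].
#' @return a `seeg_decoding` with significance filled in.
#' @export
single_region_accuracy <- function(epochs, region,
                                   config = analysis_config()) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  kept <- epochs$contacts[!epochs$contacts$excluded, ]
  sel <- which(normalize_region(kept$region_label) ==
                 normalize_region(region))
  if (!length(sel)) stop("region has no kept contacts: ", region)
  sub <- epochs
  sub$z_power <- epochs$z_power[, sel, , drop = FALSE]
  sub$raw_power <- epochs$raw_power[, sel, , drop = FALSE]
  sub$baseline_power <- epochs$baseline_power[, sel, , drop = FALSE]
  keep_ids <- kept$contact_id[sel]
  ct <- epochs$contacts
  ct$excluded <- ct$excluded | !(ct$contact_id %in% keep_ids)
  sub$contacts <- ct
  feats <- bin_features(sub, bin_ms = config$bin_ms)
  k <- min(config$k, ncol(feats$x))
  per_fold <- config$selection_mode == "per_fold"
  if (!per_fold)
    feats <- select_top_features(feats, k = k, alpha = config$alpha,
                                 n_perm = config$n_perm_select,
                                 seed = config$seed)
  res <- loo_decode(feats, classifier = config$classifier, k = k,
                    per_fold = per_fold,
                    n_perm_select = config$n_perm_select,
                    alpha = config$alpha, seed = config$seed)
  accuracy_significance(res, n_perm = config$n_perm_acc, seed = config$seed)
}

#' Identify cross-modal regions
#'
#' A region is cross-modal when its decoding accuracy strictly exceeds the
#' significance threshold in both modalities. By convention the threshold
#' applied to every single region is the multi-region significance level of
#' its modality (pass per-region thresholds to override). Regions present
#' in only one modality's table are skipped with a warning.
#'
#' @param auditory,visual tibbles with columns `region_label` and
#'   `accuracy` (and optionally `threshold`).
#' @param auditory_threshold,visual_threshold significance levels (%);
#'   ignored for rows carrying their own `threshold` column.
#' @return tibble of cross-modal regions with both accuracies and
#'   thresholds, plus `is_cross_modal` for all shared regions.
#' @export
find_cross_modal_regions <- function(auditory, visual,
                                     auditory_threshold = NULL,
                                     visual_threshold = NULL) {
  a <- tibble::as_tibble(auditory)
  v <- tibble::as_tibble(visual)
  a$region_norm <- normalize_region(a$region_label)
  v$region_norm <- normalize_region(v$region_label)
  only <- c(setdiff(a$region_norm, v$region_norm),
            setdiff(v$region_norm, a$region_norm))
  if (length(only))
    warning("regions present in only one modality skipped: ",
            paste(only, collapse = ", "))
  if (!"threshold" %in% names(a)) a$threshold <- auditory_threshold
  if (!"threshold" %in% names(v)) v$threshold <- visual_threshold
  m <- dplyr::inner_join(
    dplyr::select(a, "region_norm", "region_label",
                  auditory_accuracy = "accuracy",
                  auditory_threshold = "threshold"),
    dplyr::select(v, "region_norm", visual_accuracy = "accuracy",
                  visual_threshold = "threshold"),
    by = "region_norm")
  m$is_cross_modal <- m$auditory_accuracy > m$auditory_threshold &
    m$visual_accuracy > m$visual_threshold
  dplyr::select(m, -"region_norm")
}

#' Contacts contributing to both modalities within regions
#'
#' A cross-modal contact contributes selected features to the region's
#' feature set in both the auditory and the visual analysis. Proportions
#' are each region's pooled cross-modal contact count over the pooled
#' total across regions.
#'
#' @param auditory_features,visual_features selected `seeg_features` (or
#'   provenance tibbles with `contact_id` and `region_label`) from the two
#'   modalities.
#' @param regions optional character vector restricting the report.
#' @return tibble: `region_label`, `contacts` (list-column),
#'   `n_contacts`, `proportion` (%).
#' @export
cross_modal_contacts <- function(auditory_features, visual_features,
                                 regions = NULL) {
  prov <- function(f) {
    if (inherits(f, "seeg_features")) selected_features(f)$provenance
    else tibble::as_tibble(f)
  }
  a <- prov(auditory_features)
  v <- prov(visual_features)
  a$region_norm <- normalize_region(a$region_label)
  v$region_norm <- normalize_region(v$region_label)
  regs <- intersect(unique(a$region_norm), unique(v$region_norm))
  if (!is.null(regions))
    regs <- intersect(regs, normalize_region(regions))
  rows <- lapply(regs, function(rg) {
    ca <- unique(a$contact_id[a$region_norm == rg])
    cv <- unique(v$contact_id[v$region_norm == rg])
    both <- intersect(ca, cv)
    tibble::tibble(region_label = a$region_label[a$region_norm == rg][1],
                   contacts = list(both), n_contacts = length(both))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out))
    return(tibble::tibble(region_label = character(),
                          contacts = list(), n_contacts = integer(),
                          proportion = numeric()))
  out$proportion <- 100 * out$n_contacts / sum(out$n_contacts)
  dplyr::arrange(out, dplyr::desc(.data$n_contacts))
}

#' Regression of decoding accuracy on stimulus similarity
#'
#' Ordinary least squares of classification accuracy on the normalized
#' stimulus cross-correlation, used to ask whether accuracy in cross-modal
#' regions is explained by the physical difference between the stimuli.
#' Duplicated similarity values (regions of one subject sharing the same
#' stimulus pair) are permitted.
#'
#' @param records tibble with columns `cross_correlation` and `accuracy`.
#' @return tibble with `slope`, `intercept`, `r.squared`, `p.value` (slope
#'   test), `n`.
#' @export
regress_similarity_vs_accuracy <- function(records) {
  df <- as.data.frame(records)
  if (nrow(df) < 3) stop("need at least 3 points")
  if (stats::sd(df$cross_correlation) == 0)
    stop("zero variance in similarity values")
  fit <- stats::lm(accuracy ~ cross_correlation, data = df)
  s <- suppressWarnings(summary(fit))
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r.squared = s$r.squared,
                 p.value = s$coefficients[2, 4],
                 n = nrow(df))
}
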