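# Response-latency estimation: the first 10 ms bin whose amplitude differs
# significantly from the pre-stimulus baseline (activation latency) or
# between the two name classes (difference latency), by two-sample
# permutation tests per bin.

# two-sample permutation test of the mean difference for each column pair
# (A[, b] vs B[, b]); shared permutation indices across bins (seeded by the
# caller). Returns p-value per bin.
perm_test_bins <- function(A, B, n_perm) {
  na <- nrow(A); nb <- nrow(B); n <- na + nb
  P <- replicate(n_perm, sample.int(n))
  p <- numeric(ncol(A))
  for (b in seq_len(ncol(A))) {
    pool <- c(A[, b], B[, b])
    d_obs <- mean(A[, b]) - mean(B[, b])
    perm_vals <- matrix(pool[P], n, n_perm)
    d_perm <- colMeans(perm_vals[seq_len(na), , drop = FALSE]) -
      colMeans(perm_vals[(na + 1):n, , drop = FALSE])
    p[b] <- mean(abs(d_perm) >= abs(d_obs))
  }
  p
}

first_sig_bin <- function(p, alpha, persistence, bin_ms) {
  sig <- p < alpha
  if (persistence > 1) {
    runs <- stats::filter(as.numeric(sig), rep(1, persistence),
                          sides = 1)
    hit <- which(runs == persistence)
    if (!length(hit)) return(NA_real_)
    (hit[1] - persistence) * bin_ms
  } else {
    hit <- which(sig)
    if (!length(hit)) return(NA_real_)
    (hit[1] - 1) * bin_ms
  }
}

bin_means <- function(mat, fs, bin_ms) {
  len <- as.integer(round(bin_ms / 1000 * fs))
  nb <- ncol(mat) %/% len
  a <- array(mat[, seq_len(nb * len)], c(nrow(mat), len, nb))
  out <- colMeans(aperm(a, c(2, 1, 3)))
  matrix(out, nrow(mat), nb)
}

contact_row <- function(epochs, contact_id) {
  kept <- epochs$contacts$contact_id[!epochs$contacts$excluded]
  j <- match(contact_id, kept)
  if (is.na(j)) stop("contact not among kept contacts: ", contact_id)
  j
}

#' Activation latency of one contact for one class
#'
#' `x` holds the per-trial mean raw band power over the 200 ms baseline of
#' every trial of the class; for each 10 ms post-onset bin, `y` holds the
#' per-trial mean raw power in that bin. Each bin is tested against the
#' baseline by a two-sample permutation test of the mean difference; the
#' latency is the start time of the first significant bin (optionally the
#' first run of `persistence` consecutive significant bins), or `NA` when
#' no bin is significant. Tests are per-bin and uncorrected.
#'
#' @param epochs a `seeg_epochs`.
#' @param class_label `"own"` or `"other"`.
#' @param contact_id which contact to test.
#' @param alpha per-bin significance level.
#' @param n_perm permutations per bin.
#' @param seed RNG seed.
#' @param persistence number of consecutive significant bins required.
#' @param bin_ms bin length, ms.
#' @return latency in ms (bin start) or `NA_real_`.
#' @export
activation_latency <- function(epochs, class_label, contact_id,
                               alpha = 0.05, n_perm = 1000, seed = 1,
                               persistence = 1, bin_ms = 10) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  j <- contact_row(epochs, contact_id)
  tr <- which(epochs$labels == class_label)
  if (!length(tr)) stop("no trials of class ", class_label)
  if (length(tr) < 5) stop("need at least 5 trials of class ", class_label)
  x <- rowMeans(epochs$baseline_power[tr, j, , drop = TRUE])
  Y <- bin_means(epochs$raw_power[tr, j, , drop = TRUE], epochs$fs, bin_ms)
  withr::local_seed(seed)
  p <- perm_test_bins(Y, matrix(x, length(x), ncol(Y)), n_perm)
  first_sig_bin(p, alpha, persistence, bin_ms)
}

# z-scored bin means computed from the unsmoothed power: temporal
# smoothing spreads response energy backwards in time by up to half the
# kernel support, which would bias any first-crossing latency early, so
# latency tests normalize the raw power per trial against its own baseline
unsmoothed_z_bins <- function(epochs, trials, j, bin_ms) {
  Y <- bin_means(epochs$raw_power[trials, j, , drop = TRUE], epochs$fs,
                 bin_ms)
  base <- epochs$baseline_power[trials, j, , drop = TRUE]
  mu <- rowMeans(base)
  s <- apply(base, 1, stats::sd)
  (Y - mu) / s
}

#' Own-vs-other difference latency of one contact
#'
#' Per-bin two-sample permutation tests of the z-scored bin means between
#' own-name and other-name trials (bin means are taken on the unsmoothed
#' power and normalized against each trial's own baseline, so the temporal
#' smoothing used for feature extraction cannot bias the first crossing
#' early); returns the start of the first significant bin.
#'
#' @inheritParams activation_latency
#' @return latency in ms (bin start) or `NA_real_`.
#' @export
difference_latency <- function(epochs, contact_id, alpha = 0.05,
                               n_perm = 1000, seed = 1, persistence = 1,
                               bin_ms = 10) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  j <- contact_row(epochs, contact_id)
  own <- which(epochs$labels == "own")
  oth <- which(epochs$labels == "other")
  if (!length(own) || !length(oth)) stop("both classes must be present")
  A <- unsmoothed_z_bins(epochs, own, j, bin_ms)
  B <- unsmoothed_z_bins(epochs, oth, j, bin_ms)
  withr::local_seed(seed)
  p <- perm_test_bins(A, B, n_perm)
  first_sig_bin(p, alpha, persistence, bin_ms)
}

#' Latency table for a set of contacts
#'
#' Convenience wrapper computing own-vs-rest, other-vs-rest and
#' own-vs-other latencies for each contact.
#'
#' @param epochs a `seeg_epochs`.
#' @param contact_ids contacts to test (default: all kept).
#' @inheritParams activation_latency
#' @return tibble: `contact_id`, `region_label`, `own_vs_rest_ms`,
#'   `other_vs_rest_ms`, `own_vs_other_ms` (NA where never significant).
#' @export
latency_table <- function(epochs, contact_ids = NULL, alpha = 0.05,
                          n_perm = 1000, seed = 1, persistence = 1,
                          bin_ms = 10) {
  kept <- epochs$contacts[!epochs$contacts$excluded, ]
  contact_ids <- contact_ids %||% kept$contact_id
  rows <- lapply(seq_along(contact_ids), function(i) {
    cid <- contact_ids[i]
    tibble::tibble(
      contact_id = cid,
      region_label = kept$region_label[match(cid, kept$contact_id)],
      own_vs_rest_ms = activation_latency(epochs, "own", cid, alpha,
                                          n_perm, seed + i, persistence,
                                          bin_ms),
      other_vs_rest_ms = activation_latency(epochs, "other", cid, alpha,
                                            n_perm, seed + i, persistence,
                                            bin_ms),
      own_vs_other_ms = difference_latency(epochs, cid, alpha, n_perm,
                                           seed + i, persistence, bin_ms))
  })
  dplyr::bind_rows(rows)
}

#' Per-region latency summary and latency-type comparison
#'
#' Averages each latency type across a region's contacts (mean ± standard
#' error; a single-contact region is flagged with an undefined SE) and
#' compares latency types pairwise across contacts with two-sample
#' permutation tests.
#'
#' @param latencies a tibble as returned by [latency_table()].
#' @param n_perm permutations for the pairwise type comparisons.
#' @param seed RNG seed.
#' @return list with `summary` (region x type: mean, se, n) and
#'   `comparisons` (pairwise type tests pooled across regions).
#' @export
region_latency_summary <- function(latencies, n_perm = 1000, seed = 1) {
  lt <- tidyr::pivot_longer(latencies,
                            cols = dplyr::ends_with("_ms"),
                            names_to = "type", values_to = "latency_ms")
  lt$type <- sub("_ms$", "", lt$type)
  lt <- lt[!is.na(lt$latency_ms), ]
  if (!nrow(lt)) stop("no defined latencies to summarise")
  summ <- lt |>
    dplyr::group_by(.data$region_label, .data$type) |>
    dplyr::summarise(mean_ms = mean(.data$latency_ms),
                     se_ms = ifelse(dplyr::n() > 1,
                                    stats::sd(.data$latency_ms) /
                                      sqrt(dplyr::n()), NA_real_),
                     n = dplyr::n(), .groups = "drop")
  types <- unique(lt$type)
  comps <- list()
  withr::local_seed(seed)
  if (length(types) > 1) {
    prs <- utils::combn(types, 2, simplify = FALSE)
    for (pr in prs) {
      a <- lt$latency_ms[lt$type == pr[1]]
      b <- lt$latency_ms[lt$type == pr[2]]
      if (length(a) < 2 || length(b) < 2) next
      d_obs <- mean(a) - mean(b)
      pool <- c(a, b); na <- length(a); n <- length(pool)
      d_perm <- vapply(seq_len(n_perm), function(i) {
        s <- sample.int(n)
        mean(pool[s[seq_len(na)]]) - mean(pool[s[(na + 1):n]])
      }, 0)
      comps[[length(comps) + 1]] <- tibble::tibble(
        type_a = pr[1], type_b = pr[2], mean_diff_ms = d_obs,
        p.value = mean(abs(d_perm) >= abs(d_obs)))
    }
  }
  list(summary = summ,
       comparisons = if (length(comps)) dplyr::bind_rows(comps) else
         tibble::tibble(type_a = character(), type_b = character(),
                        mean_diff_ms = numeric(), p.value = numeric()))
}

#' Distribution of feature generation times
#'
#' Gaussian kernel density (Silverman bandwidth) of the selected features'
#' bin start times, truncated to the stimulus window and renormalized to
#' integrate to 1; with fewer than 5 times a histogram fallback is used and
#' flagged.
#'
#' @param features a selected `seeg_features`, or a numeric vector of
#'   feature times in ms.
#' @param region optional region label filter.
#' @param window_ms stimulus window, ms.
#' @return object of class `seeg_feature_density`: list with `grid_ms`,
#'   `density`, `mode_ms`, `type` (`"kde"` or `"histogram"`), `n`.
#' @export
feature_time_distribution <- function(features, region = NULL,
                                      window_ms = 1000) {
  if (inherits(features, "seeg_features")) {
    prov <- selected_features(features)$provenance
    if (!is.null(region))
      prov <- prov[normalize_region(prov$region_label) ==
                     normalize_region(region), ]
    times <- prov$bin_start_ms
  } else times <- as.numeric(features)
  n <- length(times)
  if (n < 5) {
    if (!n) stop("no feature times")
    br <- seq(0, window_ms, by = 100)
    h <- graphics::hist(times, breaks = br, plot = FALSE)
    return(structure(list(grid_ms = h$mids, density = h$density,
                          mode_ms = h$mids[which.max(h$density)],
                          type = "histogram", n = n),
                     class = "seeg_feature_density"))
  }
  bw <- if (stats::sd(times) == 0) 10 else stats::bw.nrd0(times)
  d <- stats::density(times, bw = bw, from = 0, to = window_ms, n = 512)
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  y <- d$y / area
  structure(list(grid_ms = d$x, density = y,
                 mode_ms = d$x[which.max(y)], type = "kde", n = n,
                 bw = bw),
            class = "seeg_feature_density")
}

#' @export
print.seeg_feature_density <- function(x, ...) {
  cat(sprintf("<seeg_feature_density> %s of %d feature times, mode %.0f ms\n",
              x$type, x$n, x$mode_ms))
  invisible(x)
}
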