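#' Bin epoched power into the spatiotemporal feature matrix
#'
#' Splits each trial/contact trace into 100 non-overlapping 10 ms bins and
#' takes the mean z-power per bin. Features are concatenated contact-major,
#' bin-minor (each contact contributes its 100-bin vector `v`; the
#' concatenation over contacts is the trial's feature vector `V`).
#'
#' @param epochs a `seeg_epochs` whose window is a multiple of `bin_ms`.
#' @param bin_ms bin length, ms.
#' @return object of class `seeg_features`: list with `x`
#'   (trials x features), `provenance` (tibble: `feature`, `contact_id`,
#'   `region_label`, `bin_index` 0-based, `bin_start_ms`), `labels`,
#'   and empty selection slots.
#' @export
bin_features <- function(epochs, bin_ms = 10) {
  stopifnot(inherits(epochs, "seeg_epochs"))
  d <- dim(epochs$z_power)
  len <- bin_ms / 1000 * epochs$fs
  if (abs(len - round(len)) > 1e-9)
    stop("bin length must be an integer number of samples at this fs")
  len <- as.integer(round(len))
  n_bins <- d[3] / len
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("epoch length must be a multiple of the bin length")
  n_bins <- as.integer(round(n_bins))
  n_tr <- d[1]; n_ct <- d[2]

  # mean over each bin: reinterpret time as (len x n_bins), average over len
  a <- array(epochs$z_power, c(n_tr, n_ct, len, n_bins))
  bm <- colMeans(aperm(a, c(3, 1, 2, 4)))        # -> n_tr x n_ct x n_bins
  x <- matrix(aperm(bm, c(1, 3, 2)), n_tr, n_bins * n_ct)

  kept <- epochs$contacts[!epochs$contacts$excluded, ]
  prov <- tibble::tibble(
    feature = seq_len(n_bins * n_ct),
    contact_id = rep(kept$contact_id, each = n_bins),
    region_label = rep(kept$region_label, each = n_bins),
    bin_index = rep(seq_len(n_bins) - 1L, n_ct),
    bin_start_ms = rep((seq_len(n_bins) - 1L) * bin_ms, n_ct))
  structure(list(x = x, provenance = prov, labels = epochs$labels,
                 bin_ms = bin_ms, band = epochs$band,
                 p_values = NULL, r_values = NULL, selected = NULL,
                 n_significant = NULL, bonferroni = NULL,
                 log = c(epochs$log, "bin_features")),
            class = "seeg_features")
}

#' @export
print.seeg_features <- function(x, ...) {
  cat(sprintf("<seeg_features> %d trials x %d features (%s band)%s\n",
              nrow(x$x), ncol(x$x), x$band,
              if (!is.null(x$selected))
                sprintf(", %d selected (%d Bonferroni-significant)",
                        sum(x$selected), x$n_significant) else ""))
  invisible(x)
}

# standardize columns to zero mean / unit variance; constant columns -> NA
zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colSums(sweep(m, 2, mu)^2) / (nrow(m) - 1))
  s[s == 0] <- NA_real_
  sweep(sweep(m, 2, mu), 2, s, "/")
}

# Spearman r of every column of X against binary labels, plus surrogate
# r-values from label permutations. With tie-free columns the surrogate
# distribution is identical across features (column ranks are permutations
# of 1..n), which `shared_null` exploits: one surrogate set serves all
# features. Returns list(r, mu, sigma, surrogates).
spearman_perm <- function(X, y01, n_perm, shared_null = FALSE) {
  n <- nrow(X)
  R <- apply(X, 2, rank)
  if (!is.matrix(R)) R <- matrix(R, nrow = n)
  Rz <- zscore_cols(R)
  yz <- as.numeric(scale(rank(y01)))
  r_obs <- as.numeric(crossprod(Rz, yz)) / (n - 1)

  P <- replicate(n_perm, sample.int(n))
  L <- matrix(yz[P], n, n_perm)
  if (shared_null) {
    ref <- as.numeric(scale(seq_len(n)))
    surr <- as.numeric(crossprod(ref, L)) / (n - 1)
    mu <- rep(mean(surr), ncol(X))
    sigma <- rep(stats::sd(surr), ncol(X))
    surrogates <- matrix(surr, nrow = 1)
  } else {
    S <- crossprod(Rz, L) / (n - 1)             # features x n_perm
    mu <- rowMeans(S)
    sigma <- sqrt(pmax(rowMeans(S^2) - mu^2, 0) * n_perm / (n_perm - 1))
    surrogates <- S
  }
  list(r = r_obs, mu = mu, sigma = sigma, surrogates = surrogates)
}

perm_p_from_fit <- function(r, mu, sigma, surrogates = NULL,
                            method = "gaussian") {
  p <- rep(1, length(r))
  ok <- !is.na(r) & !is.na(sigma) & sigma > 0
  if (method == "gaussian") {
    p[ok] <- pmin(1, 2 * stats::pnorm(-abs(r[ok] - mu[ok]) / sigma[ok]))
  } else {
    for (i in which(ok)) {
      s <- if (nrow(surrogates) == 1) surrogates[1, ] else surrogates[i, ]
      p[i] <- mean(abs(s - mu[i]) >= abs(r[i] - mu[i]))
    }
  }
  p
}

#' Permutation p-value of the Spearman correlation with class labels
#'
#' The feature's per-trial values are correlated with the binary class
#' labels (Spearman r). The labels are then shuffled `n_perm` times, a
#' Gaussian is fitted to the surrogate r-values, and the p-value is the
#' two-sided tail probability of the observed r under that Gaussian (the
#' fit is what resolves p-values below `1/n_perm`, which the Bonferroni
#' threshold requires). An empirical-percentile alternative is available.
#' A constant feature has no defined rank correlation and is assigned
#' `p = 1` by convention.
#'
#' @param feature_values numeric vector, one value per trial.
#' @param labels two-class label vector.
#' @param n_perm number of label shuffles (>= 100).
#' @param seed RNG seed.
#' @param method `"gaussian"` (default) or `"empirical"`.
#' @return list with `r` and `p`.
#' @export
spearman_perm_pvalue <- function(feature_values, labels, n_perm = 1000,
                                 seed = 1,
                                 method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be at least 100")
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two classes required")
  y01 <- as.integer(labels == cls[2])
  withr::local_seed(seed)
  fit <- spearman_perm(matrix(feature_values, ncol = 1), y01, n_perm)
  p <- perm_p_from_fit(fit$r, fit$mu, fit$sigma, fit$surrogates, method)
  list(r = if (is.na(fit$sigma[1])) NA_real_ else fit$r[1], p = p[1])
}

#' Select the most informative features by permutation test
#'
#' Computes a permutation p-value per feature (see
#' [spearman_perm_pvalue()]), applies the Bonferroni significance threshold
#' `alpha / dim(V)`, and keeps the `k` features with the smallest p-values.
#' Ties are broken by larger `|r|`, then by provenance order. All `k`
#' features are always returned; `n_significant` reports how many clear
#' Bonferroni.
#'
#' @param features a `seeg_features` from [bin_features()].
#' @param k number of features to keep.
#' @param alpha family-wise significance level before Bonferroni division.
#' @param n_perm label shuffles per test.
#' @param seed RNG seed.
#' @param method p-value method, see [spearman_perm_pvalue()].
#' @param shared_null reuse one surrogate-r distribution for all tie-free
#'   features (statistically identical for continuous features, much
#'   faster); set `FALSE` to force per-feature surrogates.
#' @return the `seeg_features` with `p_values`, `r_values`, `selected`
#'   (logical mask), `selected_idx` (in selection order), `n_significant`
#'   and `bonferroni` filled in.
#' @export
select_top_features <- function(features, k = 20, alpha = 0.05,
                                n_perm = 1000, seed = 1,
                                method = c("gaussian", "empirical"),
                                shared_null = NULL) {
  stopifnot(inherits(features, "seeg_features"))
  method <- match.arg(method)
  m <- ncol(features$x)
  if (k > m) stop("k exceeds the number of features")
  cls <- sort(unique(features$labels))
  if (length(cls) != 2) stop("exactly two classes required")
  y01 <- as.integer(features$labels == cls[2])
  if (is.null(shared_null))
    shared_null <- method == "gaussian" &&
      !any(apply(features$x, 2, anyDuplicated) > 0)
  withr::local_seed(seed)
  fit <- spearman_perm(features$x, y01, n_perm, shared_null = shared_null)
  p <- perm_p_from_fit(fit$r, fit$mu, fit$sigma, fit$surrogates, method)
  ord <- order(p, -abs(ifelse(is.na(fit$r), 0, fit$r)),
               seq_along(p))
  idx <- ord[seq_len(k)]
  features$p_values <- p
  features$r_values <- fit$r
  features$selected <- seq_len(m) %in% idx
  features$selected_idx <- idx
  features$bonferroni <- alpha / m
  features$n_significant <- sum(p[idx] < alpha / m)
  features$log <- c(features$log, "select_top_features")
  features
}

#' Extract the selected feature submatrix
#' @param features a selected `seeg_features`.
#' @return list with `x` (trials x k, in selection order) and `provenance`.
#' @export
selected_features <- function(features) {
  if (is.null(features$selected_idx)) stop("run select_top_features() first")
  list(x = features$x[, features$selected_idx, drop = FALSE],
       provenance = features$provenance[features$selected_idx, ])
}

#' Three-class feature selection by pairwise permutation tests
#'
#' Runs the two-class selection on each class pair — (rest, own),
#' (rest, other), (own, other) — keeping `k_per_pair` features per pair,
#' with Bonferroni correction applied within each execution. The union
#' (duplicates retained as distinct slots) is the three-class feature set
#' of dimension `3 * k_per_pair`.
#'
#' @param features a `seeg_features` whose labels contain three classes.
#' @param k_per_pair features kept per pairwise test.
#' @inheritParams select_top_features
#' @return a new `seeg_features` whose `x` has `3 * k_per_pair` columns and
#'   whose provenance carries a `pair` column; all trials are retained.
#' @export
select_threeclass_features <- function(features, k_per_pair = 10,
                                       alpha = 0.05, n_perm = 1000,
                                       seed = 1) {
  stopifnot(inherits(features, "seeg_features"))
  cls <- sort(unique(features$labels))
  if (length(cls) != 3)
    stop("three classes required, got: ", paste(cls, collapse = ", "))
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  cols <- integer(0)
  prov <- list()
  ns <- 0L
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    sub <- features
    tr <- features$labels %in% pr
    sub$x <- features$x[tr, , drop = FALSE]
    sub$labels <- features$labels[tr]
    sel <- select_top_features(sub, k = k_per_pair, alpha = alpha,
                               n_perm = n_perm, seed = seed + i)
    cols <- c(cols, sel$selected_idx)
    pi <- features$provenance[sel$selected_idx, ]
    pi$pair <- paste(pr, collapse = "_vs_")
    pi$p_value <- sel$p_values[sel$selected_idx]
    prov[[i]] <- pi
    ns <- ns + sel$n_significant
  }
  prov <- dplyr::bind_rows(prov)
  prov$slot <- seq_len(nrow(prov))
  structure(list(x = features$x[, cols, drop = FALSE],
                 provenance = prov, labels = features$labels,
                 bin_ms = features$bin_ms, band = features$band,
                 p_values = prov$p_value, r_values = NULL,
                 selected = rep(TRUE, length(cols)),
                 selected_idx = seq_along(cols),
                 n_significant = ns, bonferroni = alpha / ncol(features$x),
                 log = c(features$log, "select_threeclass_features")),
            class = "seeg_features")
}

#' @rdname tidy.seeg_features
#' @exportS3Method generics::tidy
tidy.seeg_features <- function(x, ...) {
  out <- x$provenance
  if (!is.null(x$p_values) && !("p_value" %in% names(out)) &&
      length(x$p_values) == nrow(out))
    out$p_value <- x$p_values
  if (!is.null(x$r_values) && length(x$r_values) == nrow(out))
    out$r <- x$r_values
  if (!is.null(x$selected) && length(x$selected) == nrow(out))
    out$selected <- x$selected
  out
}

#' Tidy a feature set
#'
#' Returns the per-feature provenance tibble with p-values, r-values and
#' selection flags when available.
#' @param x a `seeg_features`.
#' @param ... unused.
#' @return a tibble.
#' @name tidy.seeg_features
NULL
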