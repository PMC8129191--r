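#' Leave-one-out decoding
#'
#' For each trial in turn, the remaining trials form the training fold:
#' feature selection is re-run on the fold (default `per_fold = TRUE`, so
#' the held-out trial never influences selection), then either PCA + LDA
#' (the minimal number of principal components explaining > `var_explained`
#' of training variance, typically 2-6, feeds a linear discriminant) or a
#' 200-tree random forest is fitted and the held-out trial predicted. With
#' three classes the pairwise three-class selection is used
#' (`k_per_pair` features per pair).
#'
#' @param features a `seeg_features`. In `per_fold` mode pass the full
#'   (unselected) feature set; otherwise a selected one.
#' @param classifier `"lda"` or `"random_forest"`.
#' @param k features selected per training fold (two-class).
#' @param k_per_pair features per pairwise test (three-class).
#' @param per_fold re-run selection inside each training fold (anti-leakage
#'   default); `FALSE` uses `features$selected_idx` as-is.
#' @param n_perm_select label shuffles per selection test.
#' @param alpha selection significance level before Bonferroni division.
#' @param var_explained cumulative explained-variance cutoff for the PCA
#'   step of the LDA path.
#' @param n_trees random-forest size.
#' @param seed RNG seed (selection permutations and forest).
#' @return object of class `seeg_decoding`: list with `trials` (tibble:
#'   `trial`, `actual`, `predicted`, one score column per class),
#'   `accuracy` (%), `classifier`, `n_components_used` (per-fold vector,
#'   LDA path), `significance_threshold` and `permutation_p` (filled by
#'   [accuracy_significance()]).
#' @export
loo_decode <- function(features, classifier = c("lda", "random_forest"),
                       k = 20, k_per_pair = 10, per_fold = TRUE,
                       n_perm_select = 1000, alpha = 0.05,
                       var_explained = 0.9, n_trees = 200, seed = 1) {
  stopifnot(inherits(features, "seeg_features"))
  classifier <- match.arg(classifier)
  labels <- factor(features$labels)
  n <- nrow(features$x)
  cls <- levels(labels)
  if (any(table(labels) < 2)) stop("need at least 2 trials per class")
  withr::local_seed(seed)

  pred <- character(n)
  scores <- matrix(NA_real_, n, length(cls), dimnames = list(NULL, cls))
  ncomp_used <- rep(NA_integer_, n)

  # fast per-fold selection for tie-free two-class data: fold ranks follow
  # from the full-data ranks by a one-element update (dropping trial i
  # shifts every larger rank down by one), and the fold's surrogate-r
  # distribution is feature-independent, so one crossprod per fold gives
  # every observed r and one shared surrogate set gives the Gaussian fit.
  # Identical selections to select_top_features(), fold by fold.
  fast_sel <- per_fold && length(cls) == 2 &&
    !any(apply(features$x, 2, function(col) anyDuplicated(col) > 0))
  if (fast_sel) {
    Rfull <- apply(features$x, 2, rank)
    nf <- n - 1L
    sd_ref <- stats::sd(seq_len(nf))
    ref_z <- as.numeric(scale(seq_len(nf)))
    P <- replicate(n_perm_select, sample.int(nf))
  }

  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (per_fold && fast_sel) {
      Rf <- Rfull[tr_idx, , drop = FALSE]
      Rf <- Rf - sweep(Rf, 2, Rfull[i, ], ">")
      Rz <- (Rf - (nf + 1) / 2) / sd_ref
      yz <- as.numeric(scale(as.integer(features$labels[tr_idx] ==
                                          cls[2])))
      r <- as.numeric(crossprod(Rz, yz)) / (nf - 1)
      surr <- as.numeric(crossprod(ref_z, matrix(yz[P], nf))) / (nf - 1)
      p <- pmin(1, 2 * stats::pnorm(-abs(r - mean(surr)) /
                                      stats::sd(surr)))
      cols <- order(p, -abs(r), seq_along(p))[seq_len(k)]
      xtr <- features$x[tr_idx, cols, drop = FALSE]
      xte <- features$x[i, cols, drop = FALSE]
    } else if (per_fold) {
      fold <- features
      fold$x <- features$x[tr_idx, , drop = FALSE]
      fold$labels <- features$labels[tr_idx]
      sel <- if (length(cls) == 3)
        select_threeclass_features(fold, k_per_pair = k_per_pair,
                                   alpha = alpha, n_perm = n_perm_select,
                                   seed = seed)
      else select_top_features(fold, k = k, alpha = alpha,
                               n_perm = n_perm_select, seed = seed)
      cols <- if (length(cls) == 3)
        sel$provenance$feature else sel$selected_idx
      xtr <- features$x[tr_idx, cols, drop = FALSE]
      xte <- features$x[i, cols, drop = FALSE]
    } else {
      if (is.null(features$selected_idx))
        stop("per_fold = FALSE requires a pre-selected feature set")
      cols <- features$selected_idx
      xtr <- features$x[tr_idx, cols, drop = FALSE]
      xte <- features$x[i, cols, drop = FALSE]
    }
    ytr <- labels[tr_idx]
    if (length(unique(ytr)) < length(cls))
      stop("a class is absent from a training fold")

    if (classifier == "lda") {
      pc <- stats::prcomp(xtr, center = TRUE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      ncomp <- max(1L, which(cum > var_explained)[1])
      ncomp <- min(ncomp, ncol(pc$x))
      str <- pc$x[, seq_len(ncomp), drop = FALSE]
      ste <- predict(pc, xte)[, seq_len(ncomp), drop = FALSE]
      fit <- suppressWarnings(MASS::lda(str, grouping = ytr))
      pr <- predict(fit, ste)
      pred[i] <- as.character(pr$class)
      scores[i, colnames(pr$posterior)] <- pr$posterior[1, ]
      ncomp_used[i] <- ncomp
    } else {
      fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = n_trees)
      pr <- predict(fit, xte, type = "prob")
      pred[i] <- as.character(predict(fit, xte))
      scores[i, colnames(pr)] <- pr[1, ]
    }
  }

  trials <- tibble::tibble(trial = seq_len(n),
                           actual = as.character(labels),
                           predicted = pred)
  for (cl in cls) trials[[paste0("score_", cl)]] <- scores[, cl]
  structure(list(trials = trials,
                 accuracy = 100 * mean(pred == as.character(labels)),
                 classifier = classifier,
                 n_components_used = ncomp_used[!is.na(ncomp_used)],
                 classes = cls,
                 significance_threshold = NA_real_,
                 permutation_p = NA_real_,
                 perm_accuracies = NULL),
            class = "seeg_decoding")
}

#' @export
print.seeg_decoding <- function(x, ...) {
  cat(sprintf("<seeg_decoding> %s, %d trials: accuracy %.1f%%",
              x$classifier, nrow(x$trials), x$accuracy))
  if (!is.na(x$significance_threshold))
    cat(sprintf(" (threshold %.1f%%, p = %.3g)",
                x$significance_threshold, x$permutation_p))
  cat("\n")
  invisible(x)
}

#' Permutation significance of a decoding accuracy
#'
#' Keeps the classifier's output labels fixed and re-scores them against
#' `n_perm` random shuffles of the actual labels (permutation, so class
#' counts are preserved). The significance threshold is the 95th percentile
#' of the resulting empirical accuracy distribution (inverse-ECDF
#' percentile, so it sits on the discrete accuracy grid); the p-value is
#' the fraction of permuted accuracies at least as large as the observed
#' one.
#'
#' @param predicted,actual label vectors of equal length, or pass a
#'   `seeg_decoding` as `predicted` to have both extracted (and the result
#'   object updated).
#' @param n_perm number of shuffles (>= 100).
#' @param seed RNG seed.
#' @param quantile_level percentile defining the threshold.
#' @return for label-vector input, a list with `threshold` (%), `p` and
#'   `perm_accuracies`; for a `seeg_decoding`, the updated object.
#' @export
accuracy_significance <- function(predicted, actual = NULL, n_perm = 1000,
                                  seed = 1, quantile_level = 0.95) {
  if (inherits(predicted, "seeg_decoding")) {
    res <- predicted
    out <- accuracy_significance(res$trials$predicted, res$trials$actual,
                                 n_perm = n_perm, seed = seed,
                                 quantile_level = quantile_level)
    res$significance_threshold <- out$threshold
    res$permutation_p <- out$p
    res$perm_accuracies <- out$perm_accuracies
    return(res)
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length")
  withr::local_seed(seed)
  obs <- mean(predicted == actual)
  perm <- vapply(seq_len(n_perm),
                 function(i) mean(predicted == sample(actual)), 0)
  list(threshold = 100 * unname(stats::quantile(perm, quantile_level,
                                                type = 1)),
       p = mean(perm >= obs),
       perm_accuracies = 100 * perm)
}

#' Evaluate a three-class decoding
#'
#' Builds the confusion matrix from the leave-one-out predictions and
#' derives per-class sensitivity (`TP/(TP+FN)`, identical to the per-class
#' accuracy) and precision (`TP/(TP+FP)`), both in percent, plus one-vs-rest
#' ROC curves and trapezoidal AUC from the per-class scores.
#'
#' @param result a `seeg_decoding` with three classes and score columns.
#' @return object of class `seeg_multiclass`: list with `confusion`
#'   (3 x 3 counts, rows = actual), `metrics` (tibble: class, sensitivity,
#'   precision, auc), `roc` (tibble of per-class ROC points).
#' @export
evaluate_threeclass <- function(result) {
  stopifnot(inherits(result, "seeg_decoding"))
  tr <- result$trials
  cls <- result$classes
  if (length(cls) != 3) stop("three classes required")
  for (cl in cls)
    if (!paste0("score_", cl) %in% names(tr) ||
        all(is.na(tr[[paste0("score_", cl)]])))
      stop("per-class scores missing for ", cl)
  conf <- table(factor(tr$actual, cls), factor(tr$predicted, cls))
  conf <- matrix(as.integer(conf), 3, 3, dimnames = dimnames(conf))
  sens <- 100 * diag(conf) / rowSums(conf)
  prec <- 100 * diag(conf) / pmax(colSums(conf), 1)
  roc_pts <- list(); auc <- numeric(3)
  for (j in seq_along(cls)) {
    resp <- as.integer(tr$actual == cls[j])
    sc <- tr[[paste0("score_", cls[j])]]
    r <- pROC::roc(resp, sc, quiet = TRUE, direction = "<")
    auc[j] <- as.numeric(pROC::auc(r))
    roc_pts[[j]] <- tibble::tibble(class = cls[j],
                                   fpr = rev(1 - r$specificities),
                                   tpr = rev(r$sensitivities))
  }
  structure(list(confusion = conf,
                 metrics = tibble::tibble(class = cls,
                                          sensitivity = unname(sens),
                                          precision = unname(prec),
                                          auc = auc),
                 roc = dplyr::bind_rows(roc_pts)),
            class = "seeg_multiclass")
}

#' @export
print.seeg_multiclass <- function(x, ...) {
  cat("<seeg_multiclass>\n")
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' Two-factor summary of decoding accuracies
#'
#' Convenience fixed-effects two-way ANOVA of accuracies over frequency
#' band and classifier (balanced designs only). A factor whose sum of
#' squares is exactly zero is reported with `F = 0`, `p = 1`; a design
#' with zero residual variance but non-zero effects is refused with a
#' message about residual degrees of freedom.
#'
#' @param accuracies tibble/data.frame with columns `accuracy`, `band`,
#'   `classifier` (one row per dataset/cell replicate).
#' @return tibble with one row per term: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`.
#' @export
compare_bands <- function(accuracies) {
  df <- as.data.frame(accuracies)
  need <- c("accuracy", "band", "classifier")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  tab <- table(df$band, df$classifier)
  if (length(unique(as.vector(tab))) != 1)
    stop("unbalanced design: every band x classifier cell needs the same ",
         "number of accuracies")
  fit <- stats::aov(accuracy ~ band + classifier, data = df)
  s <- summary(fit)[[1]]
  out <- tibble::tibble(term = trimws(rownames(s)), df = s$Df,
                        sumsq = s$`Sum Sq`, meansq = s$`Mean Sq`,
                        statistic = s$`F value`, p.value = s$`Pr(>F)`)
  resid_ms <- out$meansq[out$term == "Residuals"]
  eff <- out$term != "Residuals"
  zero_eff <- eff & out$sumsq < 1e-12
  out$statistic[zero_eff] <- 0
  out$p.value[zero_eff] <- 1
  if (resid_ms < 1e-12 && any(eff & !zero_eff))
    stop("zero residual variance with non-zero effects: no residual ",
         "degrees of freedom to test against")
  out
}

#' @exportS3Method generics::tidy
tidy.seeg_decoding <- function(x, ...) x$trials

#' @exportS3Method generics::glance
glance.seeg_decoding <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    significance_threshold = x$significance_threshold,
    permutation_p = x$permutation_p,
    n_trials = nrow(x$trials),
    classifier = x$classifier,
    n_components_min = if (length(x$n_components_used))
      min(x$n_components_used) else NA_integer_,
    n_components_max = if (length(x$n_components_used))
      max(x$n_components_used) else NA_integer_)
}

#' @exportS3Method generics::tidy
tidy.seeg_multiclass <- function(x, ...) x$metrics
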