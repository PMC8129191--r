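test_that("binning yields 100 bins per contact in contact-major order", {
  # 2,000 Hz: 20 samples per 10 ms bin
  withr::local_seed(1)
  z <- array(rnorm(4 * 2 * 2000), c(4, 2, 2000))
  ep <- toy_epochs(z, labels = rep(c("own", "other"), 2), fs = 2000)
  f <- bin_features(ep)
  expect_equal(ncol(f$x), 200)
  expect_equal(sum(f$provenance$contact_id == "C1"), 100)
  expect_equal(f$provenance$bin_start_ms[1:3], c(0, 10, 20))
  # bin means agree with a direct computation
  expect_equal(f$x[3, 5], mean(z[3, 1, 81:100]))
  expect_equal(f$x[2, 101 + 7], mean(z[2, 2, 141:160]))

  # five contacts at 1,000 Hz: V has 500 features
  ep5 <- toy_epochs(array(rnorm(2 * 5 * 1000), c(2, 5, 1000)),
                    labels = c("own", "other"))
  expect_equal(ncol(bin_features(ep5)$x), 500)

  # constant trace: every bin equals the constant
  epc <- toy_epochs(array(3.5, c(2, 1, 1000)), labels = c("own", "other"))
  expect_true(all(bin_features(epc)$x == 3.5))

  # epoch length must be a multiple of the bin
  ep_bad <- toy_epochs(array(0, c(2, 1, 995)), labels = c("own", "other"))
  expect_error(bin_features(ep_bad), "multiple of the bin")
})

test_that("spearman permutation p-values behave at the extremes", {
  # constant feature: rank correlation undefined, p = 1 by convention
  out <- spearman_perm_pvalue(rep(2, 20), rep(c("own", "other"), 10),
                              seed = 1)
  expect_true(is.na(out$r))
  expect_equal(out$p, 1)

  # perfect separation at n = 20/20: |r| is the binary-label maximum and
  # the Gaussian-tail p is far below the 1/n_perm resolution
  y <- rep(c("own", "other"), each = 20)
  x <- c(rnorm(20, 10, 0.1), rnorm(20, -10, 0.1))
  out <- spearman_perm_pvalue(x, y, n_perm = 1000, seed = 2)
  expect_equal(abs(out$r), max(abs(cor(rank(x), as.integer(y == "own")))),
               tolerance = 1e-9)
  expect_lt(out$p, 1e-6)

  # the empirical method agrees with the Gaussian fit for moderate effects
  withr::local_seed(3)
  x <- rnorm(40) + 0.8 * rep(c(1, 0), 20)
  y <- rep(c("own", "other"), 20)
  pg <- spearman_perm_pvalue(x, y, seed = 4)$p
  pe <- spearman_perm_pvalue(x, y, seed = 4, method = "empirical")$p
  expect_lt(abs(pg - pe), 0.05)
})

test_that("selection keeps the k smallest p-values with |r| tie-breaking", {
  f <- toy_features(n_trials = 40, n_features = 100, seed = 5,
                    shift = 3, shifted_cols = 1:30)
  sel <- select_top_features(f, k = 20, seed = 6)
  expect_equal(sum(sel$selected), 20)
  expect_true(all(sel$selected_idx %in% 1:30))
  expect_equal(sel$bonferroni, 0.05 / 100)
  expect_equal(sel$n_significant, 20)
  expect_error(select_top_features(f, k = 200), "k exceeds")
})

test_that("selection traces all features to the informative contact", {
  f <- toy_features(n_trials = 40, n_features = 300, seed = 7,
                    shift = 3, shifted_cols = 1:100, contacts = 3)
  sel <- select_top_features(f, k = 20, seed = 8)
  expect_equal(unique(selected_features(sel)$provenance$contact_id),
               "C01")
})

test_that("selection is invariant to trial order", {
  f <- toy_features(n_trials = 30, n_features = 120, seed = 9,
                    shift = 2, shifted_cols = 1:10)
  sel1 <- sort(select_top_features(f, k = 10, seed = 10)$selected_idx)
  perm <- sample(30)
  f2 <- f; f2$x <- f$x[perm, ]; f2$labels <- f$labels[perm]
  sel2 <- sort(select_top_features(f2, k = 10, seed = 10)$selected_idx)
  expect_identical(sel1, sel2)
})

test_that("per-feature and shared-null surrogate paths agree", {
  f <- toy_features(n_trials = 30, n_features = 60, seed = 11,
                    shift = 1.5, shifted_cols = 1:6)
  a <- select_top_features(f, k = 6, seed = 12, shared_null = TRUE)
  b <- select_top_features(f, k = 6, seed = 12, shared_null = FALSE)
  expect_gte(length(intersect(a$selected_idx, b$selected_idx)), 5)
  expect_lt(max(abs(a$p_values - b$p_values)[a$p_values > 1e-6]), 0.1)
})

test_that("three-class selection returns 3 x k_per_pair feature slots", {
  f <- toy_features(n_trials = 60, n_features = 200, seed = 13,
                    labels = rep(c("rest", "own", "other"), 20))
  f$x[f$labels == "own", 1:20] <- f$x[f$labels == "own", 1:20] + 2
  f$x[f$labels != "rest", 21:40] <- f$x[f$labels != "rest", 21:40] + 2
  sel <- select_threeclass_features(f, k_per_pair = 10, seed = 14)
  expect_equal(ncol(sel$x), 30)
  expect_equal(nrow(sel$provenance), 30)
  expect_setequal(unique(sel$provenance$pair),
                  c("other_vs_rest", "own_vs_rest", "other_vs_own"))
  # rest-vs-stimulus pairs latch onto the features active in both names
  rvso <- sel$provenance[sel$provenance$pair %in%
                           c("other_vs_rest", "own_vs_rest"), ]
  expect_gt(mean(rvso$feature %in% 21:40), 0.5)
  expect_error(select_threeclass_features(
    toy_features(20, 50, seed = 1), k_per_pair = 10), "three classes")
})

test_that("indistinguishable classes yield no significant features", {
  f <- toy_features(n_trials = 60, n_features = 100, seed = 15,
                    labels = rep(c("rest", "own", "other"), 20))
  sel <- select_threeclass_features(f, k_per_pair = 10, seed = 16)
  expect_equal(sel$n_significant, 0)
})

test_that("tidy() exposes provenance with selection annotations", {
  f <- toy_features(n_trials = 20, n_features = 50, seed = 17)
  sel <- select_top_features(f, k = 5, seed = 18)
  td <- generics::tidy(sel)
  expect_equal(nrow(td), 50)
  expect_equal(sum(td$selected), 5)
  expect_true(all(c("p_value", "r", "contact_id", "bin_start_ms") %in%
                    names(td)))
})
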