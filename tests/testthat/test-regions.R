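selected_fixture <- function(region_counts, contacts_per_region = 2) {
  # build a selected feature set whose provenance spreads over regions
  total <- sum(region_counts)
  f <- toy_features(n_trials = 10, n_features = total, seed = 1,
                    contacts = 1)
  f$provenance$region_label <- rep(names(region_counts), region_counts)
  f$provenance$contact_id <- paste0(
    rep(names(region_counts), region_counts), "_c",
    unlist(lapply(region_counts, function(k)
      rep_len(seq_len(contacts_per_region), k))))
  f$selected <- rep(TRUE, total)
  f$selected_idx <- seq_len(total)
  f
}

test_that("region contribution counts selected features and flags the max", {
  f <- selected_fixture(c(`Left insula` = 9,
                          `Left transverse temporal` = 11))
  out <- region_contribution(f)
  expect_equal(out$n_features[out$region_label == "Left insula"], 9)
  expect_equal(out$n_features[out$region_label ==
                                "Left transverse temporal"], 11)
  expect_equal(out$region_label[out$is_max], "Left transverse temporal")
  expect_equal(sum(out$n_features), 20)

  # ties are flagged jointly
  f <- selected_fixture(c(A = 10, B = 10))
  out <- region_contribution(f)
  expect_equal(sum(out$is_max), 2)

  # all features from one region
  f <- selected_fixture(c(Insula = 20))
  out <- region_contribution(f)
  expect_equal(out$n_features, 20)
  expect_true(out$is_max)
})

test_that("region labels match case-insensitively after whitespace cleanup", {
  expect_equal(normalize_region("  Left   Insula "), "left insula")
  f <- selected_fixture(c(`left INSULA` = 5, `Left insula ` = 5))
  out <- region_contribution(f)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_features, 10)
})

test_that("single-region decoding recovers the effect region's accuracy", {
  s <- effect_session(seed = 30, effect_size = 3, n_trials_per_class = 20)
  ep <- preprocess(s)
  cfg <- analysis_config(n_perm_acc = 500)
  eff_region <- s$contacts$region_label[s$contacts$contact_id == "A2"]
  res <- single_region_accuracy(ep, eff_region, cfg)
  expect_gt(res$accuracy, res$significance_threshold)

  null_region <- setdiff(unique(s$contacts$region_label), eff_region)[1]
  res0 <- single_region_accuracy(ep, null_region, cfg)
  expect_lt(res0$accuracy, 75)
  expect_error(single_region_accuracy(ep, "nonexistent", cfg),
               "no kept contacts")
})

test_that("a one-contact region still supports the full pipeline", {
  s <- effect_session(seed = 31, effect_size = 3, n_trials_per_class = 10)
  ep <- preprocess(s)
  kept <- ep$contacts$contact_id[!ep$contacts$excluded]
  solo <- kept[length(kept)]
  ep$contacts$region_label[ep$contacts$contact_id == solo] <- "solo"
  res <- single_region_accuracy(ep, "solo",
                                analysis_config(k = 20, n_perm_acc = 200))
  expect_equal(nrow(res$trials), 20)
})

test_that("cross-modal regions need both accuracies above threshold", {
  aud <- tibble::tibble(region_label = c("SMG", "STG", "Insula"),
                        accuracy = c(70, 70, 55))
  vis <- tibble::tibble(region_label = c("SMG", "STG", "Fusiform"),
                        accuracy = c(70, 55, 80))
  expect_warning(
    out <- find_cross_modal_regions(aud, vis, 58, 58),
    "only one modality")
  expect_true(out$is_cross_modal[out$region_label == "SMG"])
  expect_false(out$is_cross_modal[out$region_label == "STG"])

  # monotone: raising either threshold never adds a region
  out_hi <- suppressWarnings(find_cross_modal_regions(aud, vis, 72, 58))
  expect_true(all(out_hi$is_cross_modal <= out$is_cross_modal))
})

test_that("cross-modal contacts are the per-region intersection", {
  aud <- tibble::tibble(contact_id = c("a1", "a2", "b1", "b2"),
                        region_label = c("SMG", "SMG", "MTG", "MTG"))
  vis <- tibble::tibble(contact_id = c("a1", "b1", "b2", "b3"),
                        region_label = c("SMG", "MTG", "MTG", "MTG"))
  out <- cross_modal_contacts(aud, vis)
  expect_equal(out$contacts[[which(out$region_label == "SMG")]], "a1")
  expect_setequal(out$contacts[[which(out$region_label == "MTG")]],
                  c("b1", "b2"))
  expect_equal(sum(out$n_contacts), 3)
  # 27-of-130 pooled convention: 20.8% per region
  big <- tibble::tibble(
    contact_id = paste0("c", 1:130),
    region_label = rep(c("SMG", "MTG", sprintf("R%d", 1:4)),
                       c(27, 27, 19, 19, 19, 19)))
  out <- cross_modal_contacts(big, big)
  expect_equal(round(out$proportion[out$region_label == "SMG"], 1), 20.8)
})

test_that("stimulus similarity is exact on identity and negation", {
  withr::local_seed(40)
  img <- matrix(runif(64 * 64) < 0.5, 64, 64) * 1
  expect_equal(stimulus_similarity(img, img, "visual"), 1)
  cimg <- img - mean(img)
  expect_equal(stimulus_similarity(cimg, -cimg, "visual"), -1)

  wav <- sin(2 * pi * 440 * seq_len(8000) / 8000) *
    (1 + 0.5 * sin(2 * pi * 3 * seq_len(8000) / 8000))
  expect_equal(stimulus_similarity(wav, wav, "auditory"), 1)

  # symmetry and bounds
  a <- make_stimulus_pair("visual", 0.3, seed = 41)
  s_ab <- stimulus_similarity(a$a, a$b, "visual")
  expect_equal(s_ab, stimulus_similarity(a$b, a$a, "visual"))
  expect_lte(abs(s_ab), 1)
  expect_error(stimulus_similarity(img * 0, img, "visual"), "zero-energy")
})

test_that("similarity-accuracy regression returns OLS slope, r2, p", {
  rec <- tibble::tibble(cross_correlation = c(0.1, 0.3, 0.5, 0.8),
                        accuracy = 2 * c(0.1, 0.3, 0.5, 0.8) + 1)
  out <- regress_similarity_vs_accuracy(rec)
  expect_equal(out$slope, 2, tolerance = 1e-9)
  expect_equal(out$r.squared, 1, tolerance = 1e-9)
  expect_error(regress_similarity_vs_accuracy(rec[1:2, ]), "3 points")
  rec$cross_correlation <- 0.4
  expect_error(regress_similarity_vs_accuracy(rec), "zero variance")
})
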