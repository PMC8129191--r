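make_session <- function(signals, fs = 1000, shafts = NULL, events = NULL) {
  n <- nrow(signals)
  shafts <- shafts %||% rep("S", n)
  idx <- stats::ave(seq_len(n), shafts, FUN = seq_along)
  ev <- events %||% event_table(integer(0), character(0))[0, ]
  seegdecode::seeg_session(
    signals, fs,
    contact_table(paste0("C", seq_len(n)), shafts, idx),
    ev, validate = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("line-noise screen removes exactly the contaminated contact", {
  fs <- 1000; t <- seq_len(20 * fs) / fs
  withr::local_seed(1)
  sig <- matrix(rnorm(10 * length(t)), 10)
  amp <- c(rep(1, 9), 100)                 # contact 10 carries 100x line
  for (i in 1:10) sig[i, ] <- sig[i, ] + amp[i] * sin(2 * pi * 50 * t)
  s <- screen_line_noise_contacts(make_session(sig))
  expect_equal(which(s$contacts$excluded), 10L)
  expect_equal(s$contacts$exclusion_reason[10], "line_noise")
  # the decision reproduces median + 10 * MAD on the measured line powers
  pw <- attr(s, "line_power")
  expect_identical(pw > median(pw) + 10 * mad(pw, constant = 1),
                   s$contacts$excluded)
})

test_that("degenerate MAD and line-free signals remove nothing", {
  fs <- 1000; t <- seq_len(10 * fs) / fs
  sig <- matrix(rep(sin(2 * pi * 50 * t), 5), 5, byrow = TRUE)
  s <- screen_line_noise_contacts(make_session(sig))
  expect_false(any(s$contacts$excluded))   # identical power: strict > median

  withr::local_seed(2)
  s <- screen_line_noise_contacts(make_session(matrix(rnorm(5 * 10 * fs), 5)))
  expect_false(any(s$contacts$excluded))
  expect_error(screen_line_noise_contacts(
    make_session(matrix(rnorm(2 * fs), 2))), "3 contacts")
})

test_that("comb notch attenuates harmonics and passes the band through", {
  fs <- 1000; t <- seq_len(10 * fs) / fs
  tone <- function(f) sin(2 * pi * f * t)
  s <- comb_notch(make_session(rbind(tone(50), tone(100), tone(80),
                                     tone(150), 0 * t)))
  rms <- apply(s$signals, 1, function(x) sqrt(mean(x^2)))
  in_rms <- sqrt(0.5)
  expect_lt(rms[1], 0.03 * in_rms)         # 50 Hz: >= 30 dB down
  expect_lt(rms[2], 0.03 * in_rms)         # 100 Hz harmonic
  expect_lt(rms[4], 0.03 * in_rms)         # 150 Hz harmonic
  expect_gt(rms[3], 0.9 * in_rms)          # 80 Hz passes
  expect_lt(abs(rms[3] - in_rms), 0.1 * in_rms)
  expect_equal(max(abs(s$signals[5, ])), 0)  # zero in, zero out
})

test_that("Laplacian referencing matches the hand-computed cases", {
  # identical signal on every contact: interior contacts exactly zero
  x <- matrix(rep(sin(seq_len(500) / 10), 4), 4, byrow = TRUE)
  s <- laplacian_reference(make_session(x))
  expect_equal(max(abs(s$signals[2, ])), 0)
  expect_equal(max(abs(s$signals[3, ])), 0)

  # 3-contact shaft holding constants 1, 2, 3
  s <- laplacian_reference(make_session(matrix(c(1, 2, 3), 3, 100)))
  expect_equal(unique(s$signals[2, ]), 0)      # 2 - (1+3)/2
  expect_equal(unique(s$signals[1, ]), -1)     # end contact: 1 - 2
  expect_equal(unique(s$signals[3, ]), 1)

  # single-contact shaft is orphaned
  expect_warning(
    s <- laplacian_reference(make_session(matrix(1:3, 3, 50),
                                          shafts = c("A", "A", "B"))),
    "no same-shaft neighbour")
  expect_true(s$contacts$excluded[3])
  expect_equal(s$contacts$exclusion_reason[3], "no_neighbor")
})

test_that("Hilbert band power matches the analytic-signal closed form", {
  fs <- 1000; t <- seq_len(5 * fs) / fs
  s <- make_session(rbind(sin(2 * pi * 100 * t),
                          sin(2 * pi * 5 * t),
                          0 * t))
  interior <- (fs + 1):(4 * fs)
  hg <- band_power(s, "high_gamma")
  expect_lt(max(abs(hg$power[1, interior] - 1)), 0.02)
  al <- band_power(s, "alpha")
  expect_lt(max(al$power[2, interior]), 0.02)  # 5 Hz is out of band
  expect_equal(max(hg$power[3, ]), 0)
  expect_error(band_power(s, c(100, 600)), "Nyquist|inside")
})

test_that("z-scoring uses each trial's own baseline", {
  fs <- 1000
  pw <- matrix(1, 1, 3000)
  pw[1, 1301:1400] <- 5                       # 100 ms plateau after onset
  pw[1, 1101:1300] <- rep(c(1, 3), 100)       # baseline mean 2, sd ~1
  power <- structure(list(
    power = pw, fs = fs,
    contacts = contact_table("C1", "S", 1),
    events = event_table(1300L, "own"),
    band = "high_gamma", band_range = c(60, 145),
    meta = list(stimulus_ms = 1000), log = character()),
    class = "seeg_power")
  ep <- epoch_and_zscore(power, baseline_ms = 200, window_ms = 1000)
  sd_b <- sd(rep(c(1, 3), 100))
  expect_equal(ep$z_power[1, 1, 50], (5 - 2) / sd_b, tolerance = 1e-12)
  expect_equal(ep$baseline_power[1, 1, ], rep(c(1, 3), 100))

  # post-onset power equal to the baseline mean gives z identically 0
  pw2 <- pw; pw2[1, 1301:2300] <- 2
  power$power <- pw2
  ep2 <- epoch_and_zscore(power)
  expect_equal(max(abs(ep2$z_power[1, 1, 101:1000])), 0)

  # constant baseline is an error naming trial and contact
  power$power <- matrix(1, 1, 3000)
  expect_error(epoch_and_zscore(power), "trial 1, contact C1")
})

test_that("Gaussian smoothing is unit-area, symmetric and exact on ramps", {
  ep <- toy_epochs(array(2, c(2, 1, 1000)), labels = c("own", "other"))
  sm <- smooth_gaussian(ep, 80)
  expect_lt(max(abs(sm$z_power - 2)), 1e-9)        # constants preserved

  z <- array(0, c(1, 1, 1000)); z[1, 1, 500] <- 1
  sm <- smooth_gaussian(toy_epochs(z, labels = "own"), 80)
  k <- sm$z_power[1, 1, ]
  expect_equal(sum(k), 1, tolerance = 1e-9)        # mass conserved
  expect_equal(k[460:499], rev(k[501:540]), tolerance = 1e-12)

  ramp <- array(seq(0, 1, length.out = 1000), c(1, 1, 1000))
  sm <- smooth_gaussian(toy_epochs(ramp, labels = "own"), 80)
  interior <- 100:900
  expect_lt(max(abs(sm$z_power[1, 1, interior] - ramp[1, 1, interior])),
            1e-6)
})

test_that("artifact rejection removes the deviant-trial contact only", {
  withr::local_seed(5)
  z <- array(rnorm(20 * 2 * 1000, 0, 0.3), c(20, 2, 1000))
  z[1, 2, 301:500] <- z[1, 2, 301:500] + 30       # one wild trial, contact 2
  ep <- toy_epochs(z, labels = rep(c("own", "other"), 10))
  out <- reject_artifact_contacts(ep)
  expect_equal(out$contacts$excluded, c(FALSE, TRUE))
  expect_equal(out$contacts$exclusion_reason[2], "artifact")
  expect_equal(dim(out$z_power)[2], 1)

  # identical trials: SE is zero everywhere, everything kept
  ep <- toy_epochs(array(rep(1:1000 / 500, each = 6), c(3, 2, 1000)),
                   labels = c("own", "other", "own"))
  out <- reject_artifact_contacts(ep)
  expect_false(any(out$contacts$excluded))
  expect_error(reject_artifact_contacts(
    toy_epochs(array(0, c(1, 2, 100)), labels = "own")), "2 trials")
})

test_that("the pipeline applies stages in the documented order", {
  s <- effect_session(seed = 9, effect_size = 1, n_trials_per_class = 3)
  ep <- preprocess(s)
  expect_equal(stage_log(ep),
               c("screen_line_noise", "comb_notch", "laplacian_reference",
                 "band_power", "epoch_and_zscore", "smooth_gaussian",
                 "reject_artifact_contacts"))
})

test_that("band definitions carry the conventional edges", {
  expect_equal(band_definitions("high_gamma"), c(60, 145))
  expect_equal(band_definitions("beta"), c(13, 30))
  expect_equal(band_definitions("alpha"), c(8, 12))
  expect_error(band_definitions("delta"), "unknown band")
})
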