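# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# toy feature set with iid Gaussian features (null unless shift is given)
toy_features <- function(n_trials = 40, n_features = 200, seed = 1,
                         labels = rep(c("own", "other"), n_trials / 2),
                         shift = 0, shifted_cols = integer(0),
                         contacts = max(1, n_features %/% 100)) {
  withr::local_seed(seed)
  x <- matrix(stats::rnorm(n_trials * n_features), n_trials, n_features)
  if (length(shifted_cols))
    x[labels == "own", shifted_cols] <-
      x[labels == "own", shifted_cols] + shift
  per <- n_features / contacts
  prov <- tibble::tibble(
    feature = seq_len(n_features),
    contact_id = rep(sprintf("C%02d", seq_len(contacts)), each = per),
    region_label = rep(sprintf("region %d", seq_len(contacts)), each = per),
    bin_index = rep(seq_len(per) - 1L, contacts),
    bin_start_ms = rep((seq_len(per) - 1L) * 10, contacts))
  structure(list(x = x, provenance = prov, labels = labels, bin_ms = 10,
                 band = "high_gamma", p_values = NULL, r_values = NULL,
                 selected = NULL, n_significant = NULL, bonferroni = NULL,
                 log = character()),
            class = "seeg_features")
}

# hand-built epochs object with full control over the arrays
toy_epochs <- function(z_power, raw_power = z_power,
                       baseline_power = NULL, labels, fs = 1000,
                       contacts = NULL) {
  d <- dim(z_power)
  if (is.null(baseline_power))
    baseline_power <- array(stats::rnorm(d[1] * d[2] * 200, 1, 0.1),
                            c(d[1], d[2], 200))
  if (is.null(contacts))
    contacts <- contact_table(paste0("C", seq_len(d[2])), "S",
                              seq_len(d[2]))
  structure(list(z_power = z_power, raw_power = raw_power,
                 baseline_power = baseline_power, labels = labels,
                 fs = fs, contacts = contacts, band = "high_gamma",
                 window_ms = d[3] / fs * 1000, baseline_ms = 200,
                 log = character()),
            class = "seeg_epochs")
}

# small synthetic session with one discriminative contact
effect_session <- function(seed = 1, effect_size = 3, onset_ms = 300,
                           n_trials_per_class = 30, contacts_per_shaft = 8,
                           n_shafts = 1, contact = "A2", class_label = "own",
                           modality = "auditory", extra_effects = list()) {
  effs <- c(list(effect_spec(contact, effect_size = effect_size,
                             onset_ms = onset_ms,
                             class_label = class_label)),
            extra_effects)
  if (effect_size == 1 && !length(extra_effects)) effs <- list()
  generate_session(sim_config(
    n_shafts = n_shafts, contacts_per_shaft = contacts_per_shaft,
    n_trials_per_class = n_trials_per_class, effects = effs,
    modality = modality, seed = seed))
}
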