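# Shared fixtures: small synthetic sessions and hand-built containers.

tiny_config <- function(trials = 12, seed = 1, ...) {
  generator_config(trials_per_session = trials, seed = seed, ...)
}

tiny_sessions <- function(seed = 1, trials = 12, profile = "broca_moderate",
                          ...) {
  sig <- generate_signature(seed = seed, profile = profile, ...)
  generate_participant(sig, tiny_config(trials = trials, seed = seed))
}

# Hand-built session: white-noise signal, explicit trial script.
# categories/latencies vectors define the trials; latency NA = no response.
scripted_session <- function(categories, latency_s = NULL, fs = 256,
                             session_index = 1, seed = 99) {
  set.seed(seed)
  n_tr <- length(categories)
  if (is.null(latency_s)) latency_s <- rep(2, n_tr)
  disp <- 10 * fs
  gap <- fs  # 1-s inter-trial gap
  stim <- as.integer(fs + (0:(n_tr - 1)) * (disp + gap))
  resp <- as.integer(stim + round(latency_s * fs))
  resp[is.na(latency_s) | categories == "NoResponse"] <- NA_integer_
  nsamp <- max(stim) + disp + fs
  layout <- channel_layout_1020()
  sig <- matrix(rnorm(16 * nsamp), 16, nsamp,
                dimnames = list(layout$names, NULL))
  ev <- trial_events(stim, resp, categories,
                     sprintf("item%03d", seq_len(n_tr)),
                     rep(1L, n_tr))
  eeg_session(sig, fs, layout, ev, "fix01", session_index)
}
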