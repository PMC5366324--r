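# Synthetic EEG session generator. Background activity per channel is a
# stationary AR(2) rhythm (resonant peak, default 10 Hz) over a white noise
# floor; outcome-linked activity is additive band-limited Gaussian noise in
# the signature's (channel, band) cells during the stimulus epoch, with RMS
# scaled by (1 + g * s_t) for the trial's latent state s_t. The same s_t
# drives response accuracy through the signature's logistic link, which is
# what makes the planted cells predictive of naming outcome.

#' Generator configuration
#'
#' Defaults reproduce the study design: three sessions of 300 naming trials
#' (900 trials per participant), 16-channel 10-20 montage at 256 Hz, 10-s
#' stimulus display and at most 5 s between trials.
#'
#' @param n_sessions,trials_per_session,fs,stimulus_duration,max_iti Study
#'   design parameters (durations in seconds).
#' @param background Per-channel background process: AR(2) resonance
#'   frequency \code{peak_hz}, its bandwidth \code{bandwidth_hz}, innovation
#'   scale \code{rhythm_sd} and white-noise floor \code{noise_sd}
#'   (microvolts).
#' @param trial_state_sd SD of the latent per-trial state.
#' @param seed Integer seed; each session derives its own stream from it.
#' @return A list of class \code{generator_config}.
#' @export
generator_config <- function(n_sessions = 3, trials_per_session = 300,
                             fs = 256, stimulus_duration = 10, max_iti = 5,
                             background = list(peak_hz = 10,
                                               bandwidth_hz = 2,
                                               rhythm_sd = 4,
                                               noise_sd = 4),
                             trial_state_sd = 1, seed = 1) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1, fs > 0,
            stimulus_duration > 0, max_iti > 1)
  structure(list(n_sessions = n_sessions,
                 trials_per_session = trials_per_session, fs = fs,
                 stimulus_duration = stimulus_duration, max_iti = max_iti,
                 background = background, trial_state_sd = trial_state_sd,
                 seed = as.integer(seed)), class = "generator_config")
}

# AR(2) coefficients for a resonance at peak_hz with the given bandwidth
.ar2_background <- function(peak_hz, bandwidth_hz, fs) {
  r <- exp(-pi * bandwidth_hz / fs)
  theta <- 2 * pi * peak_hz / fs
  c(2 * r * cos(theta), -r^2)
}

# Band-limited unit-RMS Gaussian noise via Fourier masking
.band_noise <- function(n, lo, hi, fs) {
  z <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  z[f < lo | f > hi] <- 0
  e <- Re(stats::fft(z, inverse = TRUE)) / n
  rms <- sqrt(mean(e^2))
  if (rms > 0) e / rms else e
}

# latency in seconds from a lognormal truncated to (0.25, 10]
.draw_latency <- function(n, meanlog, sdlog) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    x <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- x > 0.25 & x <= 10
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate one synthetic EEG session
#'
#' Simulates the full trial sequence (stimulus onsets, latent states,
#' outcomes, response latencies, inter-trial gaps uniform in (1 s, max_iti])
#' and the continuous 16-channel signal, then packages both as a validated
#' [eeg_session()]. Reproducible: the RNG stream is derived from
#' \code{config$seed} and \code{session_index} only.
#'
#' @param signature A [generate_signature()] object.
#' @param config A [generator_config()].
#' @param session_index Session number (1-3).
#' @param participant_id Participant label for the session container.
#' @param items Optional stimulus table with \code{name} and
#'   \code{set_index} columns (as from [partition_stimulus_sets()]); item
#'   names default to placeholders for the session's three sets.
#' @return An \code{eeg_session}; the latent trial states are attached as
#'   the \code{latent_state} element, and the derived seed as \code{seed}.
#' @export
generate_session <- function(signature, config, session_index,
                             participant_id = "sim01", items = NULL) {
  stopifnot(inherits(signature, "participant_signature"),
            inherits(config, "generator_config"))
  fs <- config$fs
  ntr <- config$trials_per_session
  seed <- config$seed + 7919L * as.integer(session_index)
  set.seed(seed)

  # --- trial schedule -----------------------------------------------------
  disp <- as.integer(round(config$stimulus_duration * fs))
  iti <- stats::runif(ntr, 1, config$max_iti)
  stim_onset <- as.integer(round(2 * fs) +
    cumsum(c(0, (disp + round(iti[-ntr] * fs)))))

  # --- latent states and outcomes -----------------------------------------
  s <- stats::rnorm(ntr, 0, config$trial_state_sd)
  eta <- signature$link_intercept +
    signature$link_slope * sum(signature$effect_weights$weight) * s
  correct <- stats::runif(ntr) < stats::plogis(eta)
  category <- character(ntr)
  category[correct] <- "Correct"
  n_err <- sum(!correct)
  if (n_err > 0) {
    base <- sample(names(signature$error_mix), n_err, replace = TRUE,
                   prob = signature$error_mix)
    promote <- c(FragmentIncorrect = "SelfCorrectedFragment",
                 SemanticError = "SelfCorrectedSemantic",
                 PhonologicalNeologistic = "SelfCorrectedPhonological")
    fam <- c(FragmentIncorrect = "fragment", SemanticError = "semantic",
             PhonologicalNeologistic = "phonological")
    u <- stats::runif(n_err)
    sc <- base %in% names(promote) &
      u < signature$self_correction_prob[fam[base]]
    sc[is.na(sc)] <- FALSE
    base[sc] <- promote[base[sc]]
    category[!correct] <- base
  }
  latency <- .draw_latency(ntr, signature$latency_params["meanlog"],
                           signature$latency_params["sdlog"])
  response_onset <- stim_onset + pmin(as.integer(round(latency * fs)), disp)
  response_onset[response_onset <= stim_onset] <- stim_onset + 1L
  response_onset[category == "NoResponse"] <- NA_integer_

  # --- item labels --------------------------------------------------------
  sets <- 3L * (as.integer(session_index) - 1L) + 1L + (seq_len(ntr) - 1L) %/%
    ceiling(ntr / 3)
  if (is.null(items)) {
    item <- sprintf("set%d_item%03d", sets, seq_len(ntr))
  } else {
    avail <- items[items$set_index %in% unique(sets), , drop = FALSE]
    if (nrow(avail) < ntr) stop("not enough items for this session's sets")
    item <- avail$name[seq_len(ntr)]
    sets <- avail$set_index[seq_len(ntr)]
  }

  # --- continuous signal ---------------------------------------------------
  layout <- channel_layout_1020()
  nch <- length(layout$names)
  nsamp <- max(stim_onset) + disp + as.integer(round(2 * fs))
  bg <- config$background
  ar2 <- .ar2_background(bg$peak_hz, bg$bandwidth_hz, fs)
  signal <- .ar2_noise_background_cpp(nch, nsamp, ar2[1], ar2[2],
                                      bg$rhythm_sd, bg$noise_sd)
  dimnames(signal) <- list(layout$names, NULL)

  # --- planted outcome-linked band activity --------------------------------
  ew <- signature$effect_weights
  if (nrow(ew) > 0 && any(ew$weight != 0)) {
    scale_t <- pmax(0, 1 + signature$effect_gain * s)
    for (e in seq_len(nrow(ew))) {
      ch <- match(ew$channel[e], layout$names)
      for (t in seq_len(ntr)) {
        idx <- stim_onset[t] + seq_len(disp)   # 0-based onset -> 1-based R
        signal[ch, idx] <- signal[ch, idx] +
          signature$effect_rms * scale_t[t] *
            .band_noise(disp, ew$band_lo[e], ew$band_hi[e], fs)
      }
    }
  }

  trials <- trial_events(stim_onset, response_onset, category, item, sets)
  session <- eeg_session(signal, fs, layout, trials, participant_id,
                         session_index)
  session$latent_state <- s
  session$seed <- seed
  session
}

#' Generate a full participant (all sessions)
#'
#' @inheritParams generate_session
#' @return List of \code{eeg_session} objects, one per session.
#' @export
generate_participant <- function(signature, config,
                                 participant_id = "sim01", items = NULL) {
  lapply(seq_len(config$n_sessions), function(i)
    generate_session(signature, config, i, participant_id, items))
}
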