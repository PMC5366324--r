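# Spectral feature extraction: order-40 Burg autoregressive spectra on 1000-ms
# sliding windows stepped every 62.5 ms, reduced to mean amplitudes in six
# 4-Hz bands (6-9 ... 26-29 Hz) and averaged across each trial's
# stimulus-to-response epoch.

#' Spectral analysis configuration
#'
#' @param ar_order Autoregressive model order (default 40).
#' @param bands Two-column matrix of band edges in Hz, inclusive; default the
#'   six 4-Hz bands 6-9, 10-13, 14-17, 18-21, 22-25, 26-29.
#' @param window_length Sliding-window length in seconds (default 1.0).
#' @param window_step Window step in seconds (default 0.0625, i.e. 62.5 ms).
#' @param eval_resolution Spectrum evaluation grid spacing in Hz within each
#'   band (default 0.25; band endpoints inclusive).
#' @return A list of class \code{spectral_config}.
#' @export
spectral_config <- function(ar_order = 40,
                            bands = cbind(c(6, 10, 14, 18, 22, 26),
                                          c(9, 13, 17, 21, 25, 29)),
                            window_length = 1.0, window_step = 0.0625,
                            eval_resolution = 0.25) {
  bands <- as.matrix(bands)
  stopifnot(ncol(bands) == 2, all(bands[, 2] > bands[, 1]), ar_order >= 1,
            window_length > 0, window_step > 0, eval_resolution > 0)
  if (nrow(bands) > 1 && any(bands[-1, 1] <= bands[-nrow(bands), 2]))
    stop("bands must be non-overlapping and ascending")
  structure(list(ar_order = as.integer(ar_order), bands = bands,
                 window_length = window_length, window_step = window_step,
                 eval_resolution = eval_resolution),
            class = "spectral_config")
}

.window_samples <- function(config, fs) {
  win <- config$window_length * fs
  step <- config$window_step * fs
  if (abs(win - round(win)) > 1e-9 || abs(step - round(step)) > 1e-9)
    stop("window length and step must be whole numbers of samples at fs = ", fs)
  c(win = as.integer(round(win)), step = as.integer(round(step)))
}

#' @rdname spectral_config
#' @param config A \code{spectral_config}.
#' @return \code{band_labels}: character vector like \code{"6-9"}.
#' @export
band_labels <- function(config = spectral_config()) {
  paste0(config$bands[, 1], "-", config$bands[, 2])
}

# evaluation grid: per band, inclusive [lo, hi] at eval_resolution; returns
# freqs, band index per frequency, and cos/sin matrices for the AR polynomial
.spectral_grids <- function(config, fs) {
  grids <- lapply(seq_len(nrow(config$bands)), function(b)
    seq(config$bands[b, 1], config$bands[b, 2], by = config$eval_resolution))
  freqs <- unlist(grids)
  band_idx <- rep(seq_along(grids), lengths(grids))
  # order x nfreq (order-major) for contiguous access in the C++ kernel
  theta <- outer(seq_len(config$ar_order), 2 * pi * freqs / fs)
  list(freqs = freqs, band_idx = as.integer(band_idx),
       cosmat = cos(theta), sinmat = sin(theta))
}

#' Fit an autoregressive model by Burg's method
#'
#' Burg's lattice recursion on the demeaned segment; all reflection
#' coefficients of the fitted model lie strictly inside (-1, 1), so the model
#' is stable. A constant (zero-variance) segment yields a degenerate model
#' with zero coefficients and zero innovation variance, whose spectrum is
#' identically zero.
#'
#' @param x Numeric sample vector (single channel); must be longer than
#'   \code{order}.
#' @param order AR order.
#' @param fs Sampling rate in Hz.
#' @return An object of class \code{ar_model}: \code{order}, \code{ar}
#'   (coefficients \eqn{a_1..a_p} in the convention
#'   \eqn{x_t = \sum_k a_k x_{t-k} + e_t}), \code{reflection},
#'   \code{sigma2} (innovation variance), \code{fs}, \code{degenerate}.
#' @export
fit_ar_burg <- function(x, order, fs = 256) {
  if (length(x) <= order)
    stop("segment too short for AR order ", order)
  fit <- .burg_fit_cpp(as.numeric(x), as.integer(order))
  structure(list(order = as.integer(order), ar = fit$ar,
                 reflection = fit$reflection, sigma2 = fit$sigma2,
                 mean = fit$mean, fs = fs,
                 degenerate = fit$sigma2 <= 0), class = "ar_model")
}

#' Amplitude spectrum of an AR model
#'
#' Power at frequency \eqn{f} is
#' \eqn{\sigma^2 \Delta t / |1 - \sum_k a_k e^{-i 2\pi f k / f_s}|^2} with
#' \eqn{\Delta t = 1/f_s}; the amplitude is its square root. A white-noise
#' (order-0 or all-zero) model has a flat spectrum.
#'
#' @param model An \code{ar_model}.
#' @param freqs Frequencies in Hz, inside (0, fs/2).
#' @return Nonnegative amplitude vector, one per frequency.
#' @export
ar_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "ar_model"))
  if (any(freqs <= 0 | freqs >= model$fs / 2))
    stop("frequencies must lie strictly inside (0, fs/2)")
  if (model$degenerate) return(rep(0, length(freqs)))
  if (model$order == 0 || all(model$ar == 0))
    return(rep(sqrt(model$sigma2 / model$fs), length(freqs)))
  theta <- outer(2 * pi * freqs / model$fs, seq_len(model$order))
  re <- 1 - cos(theta) %*% model$ar
  im <- sin(theta) %*% model$ar
  as.numeric(sqrt(model$sigma2 / model$fs) / sqrt(re^2 + im^2))
}

#' Mean spectral amplitude per analysis band
#'
#' Averages [ar_spectrum()] over each band's inclusive evaluation grid.
#'
#' @param model An \code{ar_model}.
#' @param config A [spectral_config()].
#' @return Named numeric vector, one amplitude per band.
#' @export
band_amplitudes <- function(model, config = spectral_config()) {
  g <- .spectral_grids(config, model$fs)
  amp <- ar_spectrum(model, g$freqs)
  out <- as.numeric(tapply(amp, g$band_idx, mean))
  names(out) <- band_labels(config)
  out
}

#' Per-window band amplitudes across a sliding epoch
#'
#' Windows are anchored at the epoch start and advance by the window step;
#' only windows fully inside the epoch are used, so an epoch of \eqn{L}
#' samples yields \eqn{\lfloor (L - w)/s \rfloor + 1} windows (window length
#' \eqn{w}, step \eqn{s}); a 10-s epoch at 256 Hz gives 145. Each window is
#' demeaned, Burg-fitted and reduced to band amplitudes.
#'
#' @param session An \code{eeg_session}.
#' @param channel Channel label.
#' @param epoch Half-open sample interval \code{c(start, end)}, 0-based.
#' @param config A [spectral_config()].
#' @return windows x bands matrix (0 rows, with a warning, if the epoch is
#'   shorter than one window).
#' @export
sliding_window_features <- function(session, channel, epoch,
                                    config = spectral_config()) {
  stopifnot(inherits(session, "eeg_session"), length(epoch) == 2)
  ws <- .window_samples(config, session$fs)
  start <- epoch[1]; end <- epoch[2]
  if (start < 0 || end > ncol(session$signal) || end <= start)
    stop("epoch out of bounds")
  x <- session$signal[channel, (start + 1):end]
  if (length(x) < ws["win"]) {
    warning("epoch shorter than one analysis window; no features")
    out <- matrix(numeric(0), 0, nrow(config$bands))
    colnames(out) <- band_labels(config)
    return(out)
  }
  g <- .spectral_grids(config, session$fs)
  out <- .burg_band_sliding_cpp(x, ws[["win"]], ws[["step"]],
                                config$ar_order, session$fs,
                                g$cosmat, g$sinmat, g$band_idx,
                                nrow(config$bands))
  colnames(out) <- band_labels(config)
  out
}

#' Trial-averaged spectral features for one trial
#'
#' The feature epoch runs from stimulus onset to immediately before the
#' response (response onset), or over the full 10-s display window for
#' no-response trials. Per (channel, band), the mean amplitude across the
#' epoch's complete sliding windows is returned.
#'
#' @param session An \code{eeg_session}.
#' @param trial One row of the session's trial table.
#' @param channels Channel labels to extract.
#' @param config A [spectral_config()].
#' @return Named numeric vector (\code{"<channel>_<lo>-<hi>"} order:
#'   channels outer, bands inner), with attribute \code{n_windows}; all-NA
#'   with \code{n_windows = 0} when the epoch is shorter than one window.
#' @export
trial_features <- function(session, trial, channels,
                           config = spectral_config()) {
  ep <- trial_epoch(trial, session$fs, ncol(session$signal))
  labels <- as.vector(t(outer(channels, band_labels(config), paste, sep = "_")))
  ws <- .window_samples(config, session$fs)
  if (ep[2] - ep[1] < ws["win"]) {
    out <- rep(NA_real_, length(labels))
    names(out) <- labels
    attr(out, "n_windows") <- 0L
    return(out)
  }
  vals <- lapply(channels, function(ch) {
    w <- sliding_window_features(session, ch, ep, config)
    colMeans(w)
  })
  out <- unlist(vals)
  names(out) <- labels
  attr(out, "n_windows") <-
    as.integer((ep[2] - ep[1] - ws[["win"]]) %/% ws[["step"]] + 1)
  out
}

#' Assemble the trial x (channel, band) feature table
#'
#' Runs the sliding-window spectral analysis over every trial of the given
#' sessions and stacks the trial-averaged amplitudes into the design matrix,
#' rows ordered by (session, trial). Trials whose epoch is shorter than one
#' analysis window are retained as rows but flagged \code{excluded} with NA
#' features and logged.
#'
#' @param sessions List of \code{eeg_session} objects (consistent montage).
#' @param channel_set \code{"3"}, \code{"9"} or \code{"16"}.
#' @param config A [spectral_config()].
#' @return Data frame of class \code{feature_table}: metadata columns
#'   (\code{participant}, \code{session}, \code{trial_id}, \code{category},
#'   \code{set_index}, \code{n_windows}, \code{excluded}) followed by the
#'   feature columns; attributes \code{channels}, \code{feature_cols} and
#'   \code{exclusion_log}.
#' @export
build_feature_table <- function(sessions, channel_set = "3",
                                config = spectral_config()) {
  if (inherits(sessions, "eeg_session")) sessions <- list(sessions)
  layouts <- unique(vapply(sessions, function(s)
    paste(s$layout$names, collapse = ","), ""))
  if (length(layouts) != 1) stop("sessions have inconsistent montages")
  channels <- channel_subset(channel_set, sessions[[1]]$layout)

  rows <- lapply(sessions, function(sess) {
    feats <- t(vapply(seq_len(nrow(sess$trials)), function(i) {
      f <- trial_features(sess, sess$trials[i, ], channels, config)
      c(f, n_windows = attr(f, "n_windows"))
    }, numeric(length(channels) * nrow(config$bands) + 1)))
    meta <- data.frame(
      participant = sess$participant_id,
      session = sess$session_index,
      trial_id = sess$trials$trial_id,
      category = sess$trials$category,
      set_index = sess$trials$set_index,
      n_windows = as.integer(feats[, ncol(feats)]),
      stringsAsFactors = FALSE)
    cbind(meta, as.data.frame(feats[, -ncol(feats), drop = FALSE]))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$session, tab$trial_id), ]
  rownames(tab) <- NULL
  tab$excluded <- tab$n_windows == 0
  feature_cols <- setdiff(names(tab), c("participant", "session", "trial_id",
                                        "category", "set_index", "n_windows",
                                        "excluded"))
  tab <- tab[, c("participant", "session", "trial_id", "category",
                 "set_index", "n_windows", "excluded", feature_cols)]
  log <- if (any(tab$excluded))
    sprintf("session %d trial %d: epoch shorter than one window",
            tab$session[tab$excluded], tab$trial_id[tab$excluded])
  else character()
  structure(tab, channels = channels, feature_cols = feature_cols,
            exclusion_log = log,
            class = c("feature_table", "data.frame"))
}

#' @rdname build_feature_table
#' @param table A \code{feature_table}.
#' @return \code{feature_matrix}: the numeric trials x features matrix.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, attr(table, "feature_cols"), drop = FALSE])
}

#' @rdname build_feature_table
#' @param path TSV output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
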