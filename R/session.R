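#' Standard 16-channel 10-20 scalp montage
#'
#' The canonical recording montage: 16 scalp electrodes placed by the 10-20
#' system, referenced to the right ear. The montage contains the midline
#' triplet Fz/Cz/Pz used for the compact 3-channel analysis and the 3 x 3
#' fronto-centro-parietal grid (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4) used for
#' the 9-channel analysis. 2-D positions are schematic head coordinates
#' (nose up, unit head radius) for topographic display.
#'
#' @param names Optional character vector of 16 unique 10-20 labels. The
#'   default montage is used when omitted. Must contain the 9-channel subset.
#' @return An object of class \code{channel_layout}: a list with \code{names},
#'   \code{reference} and a 16 x 2 \code{positions} matrix.
#' @examples
#' layout <- channel_layout_1020()
#' layout$names
#' @export
channel_layout_1020 <- function(names = NULL) {
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.40, 0.52), Fz = c(0, 0.50),
    F4  = c(0.40, 0.52),  F8  = c(0.81, 0.59),
    T3  = c(-1.00, 0.00), C3  = c(-0.50, 0.00), Cz = c(0, 0.00),
    C4  = c(0.50, 0.00),  T4  = c(1.00, 0.00),
    P3  = c(-0.40, -0.52), Pz = c(0, -0.50), P4 = c(0.40, -0.52),
    Oz  = c(0.00, -0.95))
  colnames(pos) <- c("x", "y")
  if (is.null(names)) names <- rownames(pos)
  # unknown labels get NA positions (they only matter for topography plots)
  positions <- pos[match(names, rownames(pos)), , drop = FALSE]
  rownames(positions) <- names
  layout <- structure(
    list(names = names, reference = "A2", positions = positions),
    class = "channel_layout")
  validate_channel_layout(layout)
  layout
}

#' @rdname channel_layout_1020
#' @param layout A \code{channel_layout}.
#' @export
validate_channel_layout <- function(layout) {
  stopifnot(inherits(layout, "channel_layout"))
  if (length(layout$names) != 16 || anyDuplicated(layout$names))
    stop("montage must have 16 unique channel labels")
  missing <- setdiff(channel_subset("9"), layout$names)
  if (length(missing) > 0)
    stop("montage is missing required channels: ", paste(missing, collapse = ", "))
  if (!is.matrix(layout$positions) || nrow(layout$positions) != 16)
    stop("positions must be a 16 x 2 matrix")
  invisible(layout)
}

#' Channel subsets used by the analyses
#'
#' @param which \code{"3"} (midline Fz, Cz, Pz), \code{"9"} (the
#'   fronto-centro-parietal 3 x 3 grid) or \code{"16"} (full montage).
#' @param layout Channel layout; only needed for \code{which = "16"}.
#' @return Character vector of channel labels in canonical order.
#' @export
channel_subset <- function(which = c("3", "9", "16"), layout = NULL) {
  which <- match.arg(as.character(which), c("3", "9", "16"))
  switch(which,
    "3" = c("Fz", "Cz", "Pz"),
    "9" = c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4"),
    "16" = if (is.null(layout)) channel_layout_1020()$names else layout$names)
}

#' Build a trial-event table
#'
#' One row per naming trial: stimulus onset (sample index, 0-based),
#' response onset (sample index or NA when the participant gave no response),
#' the scored response category, the target item name and the stimulus-set
#' index (1-9). Epochs are half-open \code{[start, end)} in samples.
#'
#' @param stimulus_onset Integer vector of 0-based sample indices.
#' @param response_onset Integer vector, NA allowed (must be NA exactly for
#'   \code{NoResponse} trials).
#' @param category Character vector of category codes.
#' @param item Character vector of item names.
#' @param set_index Integer vector in 1..9.
#' @return A data frame of class \code{trial_events}.
#' @export
trial_events <- function(stimulus_onset, response_onset, category, item,
                         set_index) {
  ev <- data.frame(
    trial_id = seq_along(stimulus_onset),
    stimulus_onset = as.integer(stimulus_onset),
    response_onset = as.integer(response_onset),
    category = as.character(category),
    item = as.character(item),
    set_index = as.integer(set_index),
    stringsAsFactors = FALSE)
  class(ev) <- c("trial_events", "data.frame")
  ev
}

#' Construct an EEG recording session
#'
#' Bundles a continuous multi-channel recording with its montage, sampling
#' rate and scored trial events into the canonical container used throughout
#' the pipeline.
#'
#' @param signal channels x samples numeric matrix, microvolts. Row names
#'   must match \code{layout$names}.
#' @param fs Sampling rate in Hz (canonical recordings use 256).
#' @param layout A \code{channel_layout}.
#' @param trials A \code{trial_events} table.
#' @param participant_id Character scalar.
#' @param session_index Integer in 1..3.
#' @return An object of class \code{eeg_session}.
#' @export
eeg_session <- function(signal, fs, layout, trials, participant_id,
                        session_index) {
  session <- structure(
    list(signal = signal, fs = fs, layout = layout, trials = trials,
         participant_id = as.character(participant_id),
         session_index = as.integer(session_index)),
    class = "eeg_session")
  validate_eeg_session(session)
  session
}

#' @rdname eeg_session
#' @param session An \code{eeg_session}.
#' @export
validate_eeg_session <- function(session) {
  stopifnot(inherits(session, "eeg_session"))
  validate_channel_layout(session$layout)
  sig <- session$signal
  if (!is.matrix(sig) || !is.numeric(sig))
    stop("signal must be a numeric channels x samples matrix")
  if (!identical(rownames(sig), session$layout$names))
    stop("signal row names must match the montage channel labels")
  if (session$fs <= 0) stop("sampling rate must be positive")
  tr <- session$trials
  .check_category(tr$category)
  nsamp <- ncol(sig)
  if (any(tr$stimulus_onset < 0) || any(tr$stimulus_onset >= nsamp))
    stop("stimulus onset outside the recorded signal")
  has_resp <- !is.na(tr$response_onset)
  if (any(tr$response_onset[has_resp] > nsamp))
    stop("response onset outside the recorded signal")
  if (any(has_resp & tr$response_onset <= tr$stimulus_onset))
    stop("response onset must follow stimulus onset")
  if (any(has_resp &
          (tr$response_onset - tr$stimulus_onset) > 10 * session$fs))
    stop("response onset more than 10 s after stimulus onset")
  if (any(has_resp != (tr$category != "NoResponse")))
    stop("response_onset must be absent exactly for NoResponse trials")
  if (nrow(tr) > 1) {
    if (is.unsorted(tr$stimulus_onset, strictly = TRUE))
      stop("trials must be time-ordered")
    ends <- pmin(tr$stimulus_onset + 10 * session$fs, nsamp)
    if (any(tr$stimulus_onset[-1] < ends[-nrow(tr)]))
      stop("trial display epochs overlap")
  }
  if (!(session$session_index %in% 1:3))
    stop("session_index must be 1, 2 or 3")
  invisible(session)
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf(
    "<eeg_session> participant %s, session %d: %d channels x %d samples @ %g Hz, %d trials\n",
    x$participant_id, x$session_index, nrow(x$signal), ncol(x$signal),
    x$fs, nrow(x$trials)))
  invisible(x)
}

# Half-open feature epoch [start, end) for one trial: stimulus onset up to the
# response onset, or the full 10-s display window when there is no response.
trial_epoch <- function(trial, fs, nsamp) {
  start <- trial$stimulus_onset
  end <- if (is.na(trial$response_onset)) start + as.integer(round(10 * fs))
         else trial$response_onset
  c(start, min(end, nsamp))
}
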