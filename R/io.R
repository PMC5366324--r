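# Session-level I/O: EDF for the continuous signal, TSV for the trial events.

#' Read and write trial-event tables
#'
#' Tab-separated, UTF-8, header row, one row per trial with columns
#' \code{trial_id}, \code{stimulus_onset_sample}, \code{response_onset_sample}
#' (empty for no-response trials), \code{category_code}, \code{item},
#' \code{set_index}. Leading \code{#} comment lines (used to record the
#' generator seed) are preserved on write and skipped on read.
#'
#' @param events A \code{trial_events} table.
#' @param path TSV file path.
#' @param comments Character vector written as \code{# }-prefixed header
#'   comment lines.
#' @return \code{write_events_tsv}: \code{path} invisibly;
#'   \code{read_events_tsv}: a \code{trial_events} table.
#' @export
write_events_tsv <- function(events, path, comments = character()) {
  out <- data.frame(
    trial_id = events$trial_id,
    stimulus_onset_sample = events$stimulus_onset,
    response_onset_sample = ifelse(is.na(events$response_onset), "",
                                   as.character(events$response_onset)),
    category_code = events$category,
    item = events$item,
    set_index = events$set_index,
    stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments) > 0)
    writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(category_code = "character",
                                          item = "character"),
                           fileEncoding = "UTF-8")
  required <- c("trial_id", "stimulus_onset_sample", "response_onset_sample",
                "category_code", "item", "set_index")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("events file is missing columns: ", paste(missing, collapse = ", "))
  resp <- tab$response_onset_sample
  if (is.character(resp)) resp[resp == ""] <- NA
  ev <- trial_events(
    stimulus_onset = tab$stimulus_onset_sample,
    response_onset = as.integer(resp),
    category = tab$category_code,
    item = tab$item,
    set_index = tab$set_index)
  ev$trial_id <- tab$trial_id
  no_resp_mismatch <- is.na(ev$response_onset) != (ev$category == "NoResponse")
  if (any(no_resp_mismatch))
    stop("inconsistent events: response_onset must be empty exactly for ",
         "NoResponse trials (rows ",
         paste(which(no_resp_mismatch), collapse = ", "), ")")
  ev
}

#' Write a session to disk (EDF signal + TSV events)
#'
#' @param session A valid \code{eeg_session}.
#' @param eeg_path Output EDF path.
#' @param events_path Output TSV path.
#' @param comments Optional comment lines for the events file.
#' @return Invisibly, a list of the two paths.
#' @export
write_eeg_session <- function(session, eeg_path, events_path,
                              comments = character()) {
  validate_eeg_session(session)
  write_edf(session$signal, session$fs, eeg_path,
            patient = session$participant_id,
            recording = sprintf("session %d", session$session_index))
  write_events_tsv(session$trials, events_path, comments = comments)
  invisible(list(eeg_path = eeg_path, events_path = events_path))
}

#' Read a session from disk
#'
#' Reconstructs a validated \code{eeg_session} from an EDF signal file and a
#' TSV event table. The EDF channel labels must cover the required montage;
#' participant id and session index are recovered from the EDF header.
#'
#' @param eeg_path EDF file path.
#' @param events_path Events TSV path.
#' @param layout Expected montage; defaults to [channel_layout_1020()] with
#'   the EDF's channel order.
#' @return A validated \code{eeg_session}.
#' @export
read_eeg_session <- function(eeg_path, events_path, layout = NULL) {
  edf <- read_edf(eeg_path)
  missing <- setdiff(channel_subset("9"), rownames(edf$signal))
  if (length(missing) > 0)
    stop("EDF is missing required montage channels: ",
         paste(missing, collapse = ", "))
  if (is.null(layout)) layout <- channel_layout_1020(rownames(edf$signal))
  sig <- edf$signal[layout$names, , drop = FALSE]
  trials <- read_events_tsv(events_path)
  sess_idx <- suppressWarnings(as.integer(sub("^session ", "", edf$recording)))
  if (is.na(sess_idx)) sess_idx <- 1L
  eeg_session(sig, edf$fs, layout, trials,
              participant_id = edf$patient, session_index = sess_idx)
}
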