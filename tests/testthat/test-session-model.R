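test_that("scoring schema has 10 categories in bijection with keypad values", {
  schema <- response_categories()
  expect_equal(nrow(schema), 10)
  expect_false(anyDuplicated(schema$code) > 0)
  expect_setequal(schema$keypad, 0:9)
  # keypad <-> code is a bijection
  expect_equal(schema$code[match(0:9, schema$keypad)], schema$code)
})

test_that("self-correction flag is true for exactly the three corrected error types", {
  expect_true(category_is_self_corrected("SelfCorrectedSemantic"))
  expect_false(category_is_self_corrected("Correct"))
  flags <- category_is_self_corrected(category_codes())
  expect_equal(sum(flags), 3)
  expect_setequal(category_codes()[flags],
                  c("SelfCorrectedFragment", "SelfCorrectedSemantic",
                    "SelfCorrectedPhonological"))
  expect_error(category_is_self_corrected("Hesitation"), "unknown")
})

test_that("category schema survives a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  write_category_schema(path)
  schema <- read_category_schema(path)
  expect_equal(schema$keypad, response_categories()$keypad)
  expect_equal(schema$self_corrected, response_categories()$self_corrected)
})

test_that("session validation enforces trial invariants", {
  s <- scripted_session(c("Correct", "SemanticError"), c(2, 3))
  expect_s3_class(validate_eeg_session(s), "eeg_session")

  bad <- s
  bad$trials$response_onset[1] <- bad$trials$stimulus_onset[1]  # not after
  expect_error(validate_eeg_session(bad), "follow stimulus onset")

  bad <- s
  bad$trials$response_onset[1] <- NA_integer_  # Correct without response
  expect_error(validate_eeg_session(bad), "NoResponse")

  bad <- s
  bad$trials$stimulus_onset[2] <- ncol(bad$signal) + 5L
  expect_error(validate_eeg_session(bad), "outside the recorded signal")

  bad <- s
  bad$trials$response_onset[2] <-
    bad$trials$stimulus_onset[2] + as.integer(11 * s$fs)
  expect_error(validate_eeg_session(bad), "10 s")
})

test_that("montage validation requires the 9-channel analysis subset", {
  expect_error(channel_layout_1020(c(channel_subset("9"), "Fp1", "Fp2",
                                     "F7", "F8", "T3", "T4")),
               "16 unique")
  bad_names <- c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T3", "C3", "C4",
                 "T4", "P3", "P4", "Oz", "Fz", "Cz", "T5")  # no Pz
  expect_error(channel_layout_1020(bad_names), "Pz")
})

test_that("EDF round trip is lossless up to 16-bit quantization", {
  fs <- 256
  layout <- channel_layout_1020()
  # all-zero signal comes back exactly zero
  zero <- matrix(0, 16, 2560, dimnames = list(layout$names, NULL))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(zero, fs, path)
  back <- read_edf(path)
  expect_equal(back$signal, zero)
  expect_equal(back$fs, fs)

  set.seed(7)
  sig <- matrix(rnorm(16 * 1000, sd = 30), 16, 1000,
                dimnames = list(layout$names, NULL))
  write_edf(sig, fs, path, patient = "p1")
  back <- read_edf(path)
  expect_equal(dim(back$signal), dim(sig))   # length-exact despite padding
  quant <- 2 * ceiling(apply(abs(sig), 1, max)) / (2 * 32767)
  expect_true(all(abs(back$signal - sig) <= quant + 1e-12))
  expect_equal(back$patient, "p1")
})

test_that("session write/read round trip preserves events exactly", {
  cats <- category_codes()  # all 10 categories, one trial each
  lat <- rep(2.5, 10)
  s <- scripted_session(cats, lat)
  eeg <- withr::local_tempfile(fileext = ".edf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_session(s, eeg, tsv, comments = "seed=99")
  back <- read_eeg_session(eeg, tsv)
  expect_equal(back$trials$category, s$trials$category)
  expect_equal(back$trials$stimulus_onset, s$trials$stimulus_onset)
  expect_equal(back$trials$response_onset, s$trials$response_onset)
  expect_equal(back$trials$item, s$trials$item)
  expect_equal(back$participant_id, s$participant_id)
  expect_equal(back$session_index, s$session_index)
  # the no-response trial serializes with an empty response field
  lines <- readLines(tsv)
  norow <- grep("NoResponse", lines, value = TRUE)
  expect_equal(strsplit(norow, "\t")[[1]][3], "")
})

test_that("inconsistent events files are rejected on read", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("trial_id\tstimulus_onset_sample\tresponse_onset_sample\tcategory_code\titem\tset_index",
               "1\t256\t\tCorrect\tapple\t1"), tsv)
  expect_error(read_events_tsv(tsv), "NoResponse")
})

test_that("generated sessions survive serialization with all trials intact", {
  sess <- tiny_sessions(seed = 5, trials = 10)[[1]]
  eeg <- withr::local_tempfile(fileext = ".edf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_eeg_session(sess, eeg, tsv)
  back <- read_eeg_session(eeg, tsv)
  expect_equal(nrow(back$trials), 10)
  expect_equal(back$trials$category, sess$trials$category)
  expect_lt(max(abs(back$signal - sess$signal)),
            2 * max(abs(sess$signal)) / 32767)
})

test_that("written EDF is readable by an independent EDF implementation", {
  sess <- scripted_session(c("Correct", "SemanticError"), c(2, 2))
  eeg <- withr::local_tempfile(fileext = ".edf")
  write_edf(sess$signal, sess$fs, eeg, patient = "xcheck")
  py <- sprintf(paste0(
    "import mne, numpy as np, sys\n",
    "raw = mne.io.read_raw_edf('%s', preload=True, verbose='error')\n",
    "d = raw.get_data()\n",
    "print(raw.info['sfreq']); print(len(raw.ch_names))\n",
    "np.savetxt(sys.stdout, d[:3, :5] * 1e6)\n"), eeg)
  out <- suppressWarnings(
    system2("python", "-", input = py, stdout = TRUE, stderr = FALSE))
  expect_equal(as.numeric(out[1]), 256)
  expect_equal(as.integer(out[2]), 16)
  vals <- do.call(rbind, lapply(out[3:5], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  quant <- 2 * max(abs(sess$signal)) / 32767
  expect_lt(max(abs(vals - sess$signal[1:3, 1:5])), quant)
})
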