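test_that("Burg fits agree with the reference implementation", {
  set.seed(11)
  for (ord in c(2, 10, 40)) {
    x <- as.numeric(stats::filter(rnorm(2000), c(1.2, -0.6),
                                  method = "recursive"))
    mine <- fit_ar_burg(x, ord)
    ref <- stats::ar.burg(x, aic = FALSE, order.max = ord, demean = TRUE)
    expect_equal(unname(mine$ar), unname(ref$ar), tolerance = 1e-10)
  }
})

test_that("fitted models are stable: reflection coefficients inside (-1, 1)", {
  set.seed(12)
  for (i in 1:10) {
    x <- as.numeric(stats::filter(rnorm(256), c(1.9, -0.95),
                                  method = "recursive")) + rnorm(256, sd = 0.1)
    m <- fit_ar_burg(x, 40)
    expect_true(all(abs(m$reflection) < 1))
  }
})

test_that("degenerate and too-short segments are handled", {
  m <- fit_ar_burg(rep(3.2, 300), 40)
  expect_true(m$degenerate)
  expect_equal(m$sigma2, 0)
  expect_equal(ar_spectrum(m, c(10, 20)), c(0, 0))
  expect_error(fit_ar_burg(rnorm(40), 40), "too short")
})

test_that("white-noise models give flat spectra; resonances peak at the pole angle", {
  flat <- structure(list(order = 0L, ar = numeric(0), reflection = numeric(0),
                         sigma2 = 1, fs = 256, degenerate = FALSE),
                    class = "ar_model")
  amp <- ar_spectrum(flat, seq(1, 127, by = 1))
  expect_equal(amp, rep(amp[1], length(amp)))
  expect_error(ar_spectrum(flat, 128), "fs/2")

  # AR(2) poles at r exp(+-i 2 pi f0/fs): spectrum peaks near f0
  fs <- 256; f0 <- 10; r <- 0.98
  a <- c(2 * r * cos(2 * pi * f0 / fs), -r^2)
  m2 <- structure(list(order = 2L, ar = a, reflection = numeric(2),
                       sigma2 = 1, fs = fs, degenerate = FALSE),
                  class = "ar_model")
  grid <- seq(2, 40, by = 0.05)
  expect_lt(abs(grid[which.max(ar_spectrum(m2, grid))] - f0), 1)
})

test_that("order-40 white-noise fits stay flat within 3 dB over 6-29 Hz", {
  set.seed(13)
  m <- fit_ar_burg(rnorm(2560), 40)
  expect_true(all(abs(m$ar) < 0.2))
  amp <- ar_spectrum(m, seq(6, 29, by = 0.25))
  expect_lt(20 * log10(max(amp) / min(amp)), 3)
})

test_that("band amplitudes: flat spectra equal across bands, rhythms localize, gain scales", {
  flat <- structure(list(order = 0L, ar = numeric(0), reflection = numeric(0),
                         sigma2 = 4, fs = 256, degenerate = FALSE),
                    class = "ar_model")
  ba <- band_amplitudes(flat)
  expect_equal(unname(ba), rep(ba[[1]], 6))

  set.seed(14)
  x <- sin(2 * pi * 10 * (0:2559) / 256) + rnorm(2560, sd = 0.05)
  ba <- band_amplitudes(fit_ar_burg(x, 40))
  expect_equal(names(which.max(ba)), "10-13")

  m1 <- fit_ar_burg(x, 40)
  m5 <- fit_ar_burg(5 * x, 40)
  expect_equal(band_amplitudes(m5), 5 * band_amplitudes(m1),
               tolerance = 1e-10)
})

test_that("sliding-window bookkeeping matches the closed-form count", {
  s <- scripted_session(c("NoResponse", "Correct"), c(NA, 1))
  # full 10-s epoch: 145 windows
  w <- sliding_window_features(s, "Cz", c(0, 2560))
  expect_equal(nrow(w), 145)
  expect_equal(colnames(w), band_labels())
  # exactly 1000 ms: one window
  expect_equal(nrow(sliding_window_features(s, "Cz", c(0, 256))), 1)
  # 999 ms: none
  expect_warning(w0 <- sliding_window_features(s, "Cz", c(0, 255)),
                 "shorter than one")
  expect_equal(nrow(w0), 0)

  # property: count equals brute-force enumeration for random epoch lengths
  set.seed(15)
  for (len in sample(256:3000, 25)) {
    w <- sliding_window_features(s, "Fz", c(0, len))
    n_brute <- 0; start <- 0
    while (start + 256 <= len) { n_brute <- n_brute + 1; start <- start + 16 }
    expect_equal(nrow(w), n_brute)
  }
})

test_that("trial features average the epoch's windows", {
  s <- scripted_session(c("Correct", "NoResponse"), c(1, NA))
  # response at exactly stimulus + 1000 ms: one window, feature == its row
  f <- trial_features(s, s$trials[1, ], "Cz")
  expect_equal(attr(f, "n_windows"), 1L)
  ep <- c(s$trials$stimulus_onset[1], s$trials$response_onset[1])
  w <- sliding_window_features(s, "Cz", ep)
  expect_equal(unname(f[paste0("Cz_", band_labels())]), unname(w[1, ]))
  # no-response trial: the full 145-window display epoch
  f2 <- trial_features(s, s$trials[2, ], "Cz")
  expect_equal(attr(f2, "n_windows"), 145L)
  expect_false(anyNA(f2))
})

test_that("trial features on stationary signal match whole-epoch band amplitudes", {
  set.seed(16)
  s <- scripted_session("NoResponse", NA)
  ep <- c(s$trials$stimulus_onset[1], s$trials$stimulus_onset[1] + 2560L)
  x <- s$signal["Pz", (ep[1] + 1):ep[2]]
  whole <- band_amplitudes(fit_ar_burg(x, 40))
  f <- trial_features(s, s$trials[1, ], "Pz")
  expect_equal(unname(f), unname(whole), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("feature tables have the documented shape and are deterministic", {
  sessions <- tiny_sessions(seed = 2, trials = 8)
  tab3 <- build_feature_table(sessions, "3")
  expect_equal(length(attr(tab3, "feature_cols")), 18)
  expect_equal(nrow(tab3), 24)
  expect_equal(tab3$session, rep(1:3, each = 8))
  expect_true(all(diff(tab3$trial_id[tab3$session == 2]) > 0))
  expect_equal(attr(tab3, "feature_cols")[1:2], c("Fz_6-9", "Fz_10-13"))

  tab9 <- build_feature_table(sessions[[1]], "9")
  expect_equal(length(attr(tab9, "feature_cols")), 54)

  tab3b <- build_feature_table(sessions, "3")
  expect_identical(as.data.frame(tab3), as.data.frame(tab3b))
})

test_that("too-short epochs are flagged excluded, not dropped silently", {
  s <- scripted_session(c("Correct", "Correct"), c(0.6, 3))
  tab <- build_feature_table(s, "3")
  expect_equal(tab$excluded, c(TRUE, FALSE))
  expect_true(anyNA(feature_matrix(tab)[1, ]))
  expect_false(anyNA(feature_matrix(tab)[2, ]))
  expect_length(attr(tab, "exclusion_log"), 1)
})
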