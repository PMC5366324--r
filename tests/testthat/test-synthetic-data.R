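test_that("signatures are reproducible and restricted to the 9-channel grid", {
  s1 <- generate_signature(seed = 42)
  s2 <- generate_signature(seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1$effect_weights$channel %in% channel_subset("9")))
  expect_true(all(s1$effect_weights$weight != 0))
  expect_equal(sum(s1$error_mix), 1, tolerance = 1e-12)

  null_sig <- generate_signature(seed = 42, null_effect = TRUE)
  expect_true(all(null_sig$effect_weights$weight == 0))
})

test_that("profile-derived error mixtures preserve the behavioral profile", {
  prof <- participant_profiles()
  expect_equal(rowSums(prof[, -1]), rep(1, nrow(prof)), tolerance = 1e-12)
  sig <- generate_signature(seed = 1, profile = "broca_severe")
  # severe profile: phonological errors common, many self-corrected
  expect_gt(sig$error_mix[["PhonologicalNeologistic"]], 0.3)
  expect_gt(sig$self_correction_prob[["phonological"]], 0.3)
  expect_error(generate_signature(profile = "wernicke"), "unknown profile")
})

test_that("generated sessions are reproducible and respect the trial design", {
  cfg <- tiny_config(trials = 15, seed = 9)
  sig <- generate_signature(seed = 9)
  a <- generate_session(sig, cfg, 1)
  b <- generate_session(sig, cfg, 1)
  expect_identical(a$trials, b$trials)
  expect_identical(a$signal, b$signal)
  c2 <- generate_session(sig, cfg, 2)
  expect_false(identical(a$trials$category, c2$trials$category))

  expect_equal(nrow(a$trials), 15)
  fs <- cfg$fs
  disp <- 10 * fs
  # responses inside the 10-s display; gaps in (1 s, max_iti]
  resp <- a$trials$response_onset
  stim <- a$trials$stimulus_onset
  expect_true(all(is.na(resp) | (resp - stim) <= disp))
  expect_true(all(is.na(resp) | (resp - stim) > 0.25 * fs / 2))
  gaps <- (stim[-1] - (stim[-15] + disp)) / fs
  expect_true(all(gaps > 1 - 1/fs & gaps <= cfg$max_iti + 1/fs))
  # no-response trials carry no onset, and only those
  expect_identical(is.na(resp), a$trials$category == "NoResponse")
})

test_that("null signatures hit the logistic base accuracy within binomial error", {
  sig <- generate_signature(seed = 3, null_effect = TRUE,
                            profile = "transcortical_motor")
  cfg <- generator_config(trials_per_session = 300, seed = 21)
  sess <- generate_session(sig, cfg, 1)
  p <- stats::plogis(sig$link_intercept)
  phat <- mean(sess$trials$category == "Correct")
  expect_lt(abs(phat - p), 3.5 * sqrt(p * (1 - p) / 300))
})

test_that("a strong positive link orders accuracy by latent-state tercile", {
  sig <- generate_signature(seed = 4, profile = "broca_moderate",
                            link_slope = 4)
  cfg <- generator_config(trials_per_session = 300, seed = 22)
  sess <- generate_session(sig, cfg, 1)
  s <- sess$latent_state
  correct <- sess$trials$category == "Correct"
  terc <- cut(s, stats::quantile(s, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
              labels = c("lo", "mid", "hi"))
  expect_gt(mean(correct[terc == "hi"]), mean(correct[terc == "lo"]))
})

test_that("stimulus filtering applies both thresholds inclusively", {
  items <- data.frame(
    name = paste0("it", 1:5),
    naming_agreement = c(0.19, 0.20, 0.90, 0.50, 0.80),
    familiarity      = c(4.00, 3.75, 3.74, 5.00, 1.00))
  kept <- filter_stimulus_items(items)
  expect_equal(kept$name, c("it2", "it4"))
  expect_error(filter_stimulus_items(transform(items, familiarity = 7)),
               "familiarity")
})

test_that("simulated pools filter down to enough usable items", {
  pool <- simulate_stimulus_pool(n = 1469, seed = 2)
  kept <- filter_stimulus_items(pool)
  expect_gte(nrow(kept), 900)
  expect_identical(simulate_stimulus_pool(n = 100, seed = 5),
                   simulate_stimulus_pool(n = 100, seed = 5))
})

test_that("the 900-item partition yields nine disjoint sets of 100", {
  items <- data.frame(name = sprintf("uniq%03d", 1:900))
  part <- partition_stimulus_sets(items, seed = 3)
  expect_equal(as.vector(table(part$set_index)), rep(100L, 9))
  expect_equal(sort(part$name), sort(items$name))  # nothing lost or duplicated
  expect_error(partition_stimulus_sets(items[1:899, , drop = FALSE], seed = 1),
               "900")
})

test_that("repeat names are traded out of each session's three sets", {
  # 860 unique names + 20 names duplicated twice
  items <- data.frame(name = c(sprintf("uniq%03d", 1:860),
                               rep(sprintf("dup%02d", 1:20), each = 2)))
  part <- partition_stimulus_sets(items, seed = 7)
  for (s in 1:3) {
    nm <- part$name[(part$set_index - 1) %/% 3 + 1 == s]
    expect_equal(anyDuplicated(nm), 0)
  }
  # an all-duplicate pool is unsatisfiable
  bad <- data.frame(name = rep("clock", 900))
  expect_error(partition_stimulus_sets(bad, seed = 1), "duplicated names")
})

test_that("sessions draw items from the partitioned sets when provided", {
  items <- data.frame(name = sprintf("uniq%03d", 1:900))
  part <- partition_stimulus_sets(items, seed = 3)
  sig <- generate_signature(seed = 1)
  cfg <- generator_config(trials_per_session = 300, seed = 30)
  sess <- generate_session(sig, cfg, 2, items = part)
  expect_setequal(unique(sess$trials$set_index), 4:6)
  expect_true(all(sess$trials$item %in% part$name[part$set_index %in% 4:6]))
})
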