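# Participant signatures: the per-participant generative link between
# trial-to-trial brain state, band-limited EEG amplitude and naming outcome,
# plus behavioral profiles (first-attempt accuracy and error-type mixtures)
# spanning the heterogeneity seen in aphasic naming.

#' Built-in behavioral profiles
#'
#' Eight response-frequency profiles covering a realistic range of aphasia
#' presentations, from very mild anomic (94% correct) to severe nonfluent
#' (26% correct, frequent no-responses) and a circumlocution-heavy conduction
#' profile. Each row gives the expected proportion of trials per response
#' category; rows sum to 1.
#'
#' @return Data frame, one row per profile, with a \code{profile} name column
#'   and one column per response category code.
#' @export
participant_profiles <- function() {
  p <- rbind(
    anomic_mild          = c( 3, 84, 1, 0,  5, 0,  0,  6, 1, 0),
    broca_severe         = c(14, 26, 1, 6, 20, 0,  2, 20, 11, 0),
    conduction_circumloc = c(26, 26, 0, 1, 19, 1, 23,  2, 1, 0),
    transcortical_motor  = c( 2, 75, 0, 0, 15, 5,  1,  0, 1, 0),
    broca_moderate       = c(24, 34, 0, 1, 26, 0,  1, 11, 1, 1),
    anomic_mild_b        = c( 3, 78, 0, 0,  8, 2,  0,  3, 5, 0),
    anomic_very_mild     = c( 0, 94, 0, 0,  3, 2,  1,  0, 0, 0),
    anomic_moderate      = c( 7, 74, 0, 0, 11, 3,  2,  1, 2, 0))
  p <- p / rowSums(p)
  out <- data.frame(profile = rownames(p), p, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- category_codes()
  out
}

#' Draw a participant signature
#'
#' A signature specifies everything participant-specific in the generative
#' model: which (channel, band) cells carry outcome-linked amplitude
#' modulation and with what link weight, the logistic accuracy link
#' \eqn{P(\mathrm{correct}) = \mathrm{logit}^{-1}(a + b \sum_{cb} w_{cb} s_t)}
#' on the latent per-trial state \eqn{s_t}, the amplitude modulation gain and
#' in-band effect RMS, the response-latency distribution (truncated
#' lognormal; invented, no latencies are reported for this task) and the
#' error-type mixture with per-family self-correction probabilities.
#'
#' Effect cells are restricted to the 9-channel fronto-centro-parietal grid.
#' The link intercept \eqn{a} and the error mixture come from the chosen
#' behavioral profile; with \code{null_effect = TRUE} all effect weights are
#' zero, so outcomes are independent of the EEG.
#'
#' @param seed Integer seed.
#' @param null_effect Zero out all effect weights.
#' @param profile Name of a row of [participant_profiles()].
#' @param n_effects Number of (channel, band) effect cells to draw.
#' @param effect_channels Channels the effect cells are sampled from; must be
#'   a subset of the 9-channel grid (default: all of it). Restricting this to
#'   the montage under analysis separates detection power from scalp
#'   coverage.
#' @param link_slope Slope \eqn{b} of the accuracy link.
#' @param effect_gain Gain \eqn{g} of the amplitude modulation
#'   \eqn{(1 + g s_t)}.
#' @param effect_rms Baseline RMS (microvolts) of the added band-limited
#'   effect noise.
#' @param latency_meanlog,latency_sdlog Lognormal response-latency
#'   parameters (seconds scale); samples are truncated to (0.25, 10].
#' @return An object of class \code{participant_signature}.
#' @export
generate_signature <- function(seed = 1, null_effect = FALSE,
                               profile = "broca_moderate", n_effects = 2,
                               effect_channels = channel_subset("9"),
                               link_slope = 1.5, effect_gain = 0.35,
                               effect_rms = 14,
                               latency_meanlog = log(2.5),
                               latency_sdlog = 0.4) {
  profiles <- participant_profiles()
  if (!profile %in% profiles$profile)
    stop("unknown profile: ", profile)
  if (!all(effect_channels %in% channel_subset("9")))
    stop("effect channels must lie within the 9-channel grid")
  prof <- profiles[profiles$profile == profile, -1]
  codes <- category_codes()
  schema <- response_categories()

  set.seed(seed)
  channels <- effect_channels
  bands <- spectral_config()$bands
  cells <- expand.grid(channel = channels, band = seq_len(nrow(bands)),
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(cells), n_effects)
  effect_weights <- data.frame(
    channel = cells$channel[pick],
    band_lo = bands[cells$band[pick], 1],
    band_hi = bands[cells$band[pick], 2],
    weight = if (null_effect) rep(0, n_effects)
             else stats::runif(n_effects, 0.8, 1.2),
    stringsAsFactors = FALSE)

  p_correct <- as.numeric(prof[["Correct"]])
  # error mixture over the six non-correct, non-self-corrected outcomes;
  # self-corrected variants arise by promotion within their error family
  base_err <- c(NoResponse = prof[["NoResponse"]],
                FragmentIncorrect = prof[["FragmentIncorrect"]] +
                  prof[["SelfCorrectedFragment"]],
                SemanticError = prof[["SemanticError"]] +
                  prof[["SelfCorrectedSemantic"]],
                Circumlocution = prof[["Circumlocution"]],
                PhonologicalNeologistic = prof[["PhonologicalNeologistic"]] +
                  prof[["SelfCorrectedPhonological"]],
                Perseveration = prof[["Perseveration"]])
  error_mix <- unlist(base_err) / sum(unlist(base_err))
  sc_prob <- c(
    fragment = .ratio(prof[["SelfCorrectedFragment"]],
                      prof[["SelfCorrectedFragment"]] + prof[["FragmentIncorrect"]]),
    semantic = .ratio(prof[["SelfCorrectedSemantic"]],
                      prof[["SelfCorrectedSemantic"]] + prof[["SemanticError"]]),
    phonological = .ratio(prof[["SelfCorrectedPhonological"]],
                          prof[["SelfCorrectedPhonological"]] +
                            prof[["PhonologicalNeologistic"]]))

  structure(list(
    profile = profile,
    effect_weights = effect_weights,
    link_intercept = stats::qlogis(p_correct),
    link_slope = if (null_effect) 0 else link_slope,
    effect_gain = effect_gain,
    effect_rms = effect_rms,
    latency_params = c(meanlog = latency_meanlog, sdlog = latency_sdlog),
    error_mix = error_mix,
    self_correction_prob = sc_prob,
    seed = seed), class = "participant_signature")
}

.ratio <- function(num, den) if (den > 0) as.numeric(num / den) else 0

#' @export
print.participant_signature <- function(x, ...) {
  cat(sprintf("<participant_signature> profile %s, %d effect cell(s), a=%.3f b=%.2f\n",
              x$profile, nrow(x$effect_weights), x$link_intercept, x$link_slope))
  invisible(x)
}
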