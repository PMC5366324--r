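# Behavioral analyses: response-type tabulation and one-way within-subject
# (repeated measures) ANOVA with Mauchly's sphericity test and the
# Greenhouse-Geisser correction.

#' Tabulate scored responses
#'
#' Counts and percentages per response category, per participant (optionally
#' split by session), plus headline accuracy. Only first-attempt correct
#' responses count as correct: no-response and self-corrected responses are
#' incorrect for the accuracy figure.
#'
#' @param trials A \code{trial_events} table, an \code{eeg_session}, or a
#'   list of sessions from one participant.
#' @param by_session Tabulate each session separately.
#' @return Object of class \code{response_tabulation}: data frame with
#'   \code{session} (\code{"all"} or the session index), one row per
#'   category with \code{count} and \code{percent}, plus attribute
#'   \code{accuracy} (proportion Correct, overall).
#' @export
tabulate_responses <- function(trials, by_session = FALSE) {
  if (inherits(trials, "eeg_session")) trials <- list(trials)
  if (is.list(trials) && !is.data.frame(trials)) {
    tabs <- lapply(trials, function(s)
      data.frame(session = rep(s$session_index, nrow(s$trials)),
                 category = s$trials$category, stringsAsFactors = FALSE))
    dat <- do.call(rbind, tabs)
  } else {
    dat <- data.frame(session = rep(1L, nrow(trials)),
                      category = trials$category, stringsAsFactors = FALSE)
  }
  if (nrow(dat) == 0) stop("no scored trials to tabulate")
  .check_category(dat$category)
  codes <- category_codes()
  one <- function(d, label) {
    counts <- table(factor(d$category, levels = codes))
    data.frame(session = label, category = codes,
               count = as.integer(counts),
               percent = 100 * as.numeric(counts) / nrow(d),
               stringsAsFactors = FALSE)
  }
  out <- if (by_session)
    do.call(rbind, lapply(split(dat, dat$session), function(d)
      one(d, as.character(d$session[1]))))
  else one(dat, "all")
  rownames(out) <- NULL
  structure(out, accuracy = mean(dat$category == "Correct"),
            n_trials = nrow(dat),
            class = c("response_tabulation", "data.frame"))
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Standard within-subject decomposition of a subjects x conditions score
#' matrix: \eqn{SS_{total} = SS_{subjects} + SS_{conditions} + SS_{error}},
#' \eqn{F = MS_{cond}/MS_{error}} on \eqn{(c-1, (c-1)(s-1))} degrees of
#' freedom. Sphericity is assessed by Mauchly's W (chi-square approximation
#' on \eqn{c(c-1)/2 - 1} df) computed from the covariance of orthonormal
#' condition contrasts; the Greenhouse-Geisser
#' \eqn{\epsilon = \mathrm{tr}(T)^2 / ((c-1)\,\mathrm{tr}(T^2))} deflates
#' both df when sphericity is rejected at \code{sphericity_alpha}.
#'
#' @param scores Numeric subjects x conditions matrix (>= 2 subjects, no
#'   missing cells), e.g. correct-response counts per session.
#' @param sphericity_alpha Threshold below which the corrected test is
#'   reported (default 0.05).
#' @return Object of class \code{rm_anova}: \code{F}, \code{df_num},
#'   \code{df_den}, \code{p}, \code{mauchly_W}, \code{mauchly_chisq},
#'   \code{mauchly_df}, \code{p_sphericity}, \code{gg_epsilon},
#'   \code{df_num_corrected}, \code{df_den_corrected}, \code{p_corrected},
#'   \code{sphericity_violated}, \code{ss} (the decomposition).
#' @export
rm_anova_one_way <- function(scores, sphericity_alpha = 0.05) {
  scores <- as.matrix(scores)
  s <- nrow(scores); c <- ncol(scores)
  if (s < 2) stop("need at least 2 subjects")
  if (c < 2) stop("need at least 2 within-subject conditions")
  if (anyNA(scores)) stop("missing cells are not supported")
  gm <- mean(scores)
  ss_total <- sum((scores - gm)^2)
  if (ss_total == 0) stop("scores are constant; nothing to decompose")
  ss_subj <- c * sum((rowMeans(scores) - gm)^2)
  ss_cond <- s * sum((colMeans(scores) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df_num <- c - 1
  df_den <- (c - 1) * (s - 1)
  ms_cond <- ss_cond / df_num
  ms_err <- ss_err / df_den
  if (ms_err <= 0) stop("zero error variance; F undefined")
  Fval <- ms_cond / ms_err
  p <- stats::pf(Fval, df_num, df_den, lower.tail = FALSE)

  # orthonormal contrasts of the condition covariance
  C <- t(stats::contr.helmert(c)) / sqrt(colSums(stats::contr.helmert(c)^2))
  S <- stats::cov(scores)
  T_ <- C %*% S %*% t(C)
  W <- det(T_) / (sum(diag(T_)) / df_num)^df_num
  d <- 1 - (2 * df_num^2 + df_num + 2) / (6 * df_num * (s - 1))
  chisq <- -(s - 1) * d * log(W)
  mdf <- c * (c - 1) / 2 - 1
  p_sph <- stats::pchisq(chisq, mdf, lower.tail = FALSE)
  eps <- sum(diag(T_))^2 / (df_num * sum(T_^2))

  violated <- is.finite(p_sph) && p_sph < sphericity_alpha
  dfn_c <- eps * df_num
  dfd_c <- eps * df_den
  p_corr <- stats::pf(Fval, dfn_c, dfd_c, lower.tail = FALSE)

  structure(list(
    F = Fval, df_num = df_num, df_den = df_den, p = p,
    mauchly_W = W, mauchly_chisq = chisq, mauchly_df = mdf,
    p_sphericity = p_sph, gg_epsilon = eps,
    df_num_corrected = dfn_c, df_den_corrected = dfd_c,
    p_corrected = p_corr, sphericity_violated = violated,
    ss = c(total = ss_total, subjects = ss_subj, conditions = ss_cond,
           error = ss_err),
    n_subjects = s, n_conditions = c), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Mauchly's test: W = %.4f, X2(%d) = %.3f, p = %.3f\n",
              x$mauchly_W, x$mauchly_df, x$mauchly_chisq, x$p_sphericity))
  if (x$sphericity_violated) {
    cat(sprintf(
      "sphericity violated; Greenhouse-Geisser corrected (epsilon = %.3f):\n",
      x$gg_epsilon))
    cat(sprintf("F(%.2f, %.2f) = %.3f, p = %.3f\n",
                x$df_num_corrected, x$df_den_corrected, x$F, x$p_corrected))
  } else {
    cat(sprintf("sphericity met; F(%d, %d) = %.3f, p = %.3f\n",
                x$df_num, x$df_den, x$F, x$p))
  }
  invisible(x)
}
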