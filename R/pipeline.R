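# Experiment driver: outcome coding, the session 1-2 / session 3 split,
# Pearson-r evaluation with k / (n - k - 1) degrees of freedom, channel x band
# correlation topographies, and the end-to-end two-model run.

#' Numeric outcome coding for a response category
#'
#' \code{accuracy} mode is the binary first-attempt coding: \code{Correct}
#' maps to 1 and every other category (including self-corrections) to 0.
#' \code{error_correction} mode is the ordinal three-level coding:
#' \code{Correct} 2, the three self-corrected categories 1, uncorrected
#' fragment/semantic/phonological errors 0; no-response, circumlocution and
#' perseveration trials are excluded (NA). Because model quality is measured
#' by Pearson correlation, any increasing affine recoding of the three levels
#' gives identical results.
#'
#' @param category Character vector of category codes.
#' @param mode \code{"accuracy"} or \code{"error_correction"}.
#' @return Numeric vector; NA marks excluded trials (error-correction mode
#'   only).
#' @export
encode_outcome <- function(category, mode = c("accuracy", "error_correction")) {
  mode <- match.arg(mode)
  .check_category(category)
  if (mode == "accuracy") return(as.numeric(category == "Correct"))
  map <- c(Correct = 2,
           SelfCorrectedFragment = 1, SelfCorrectedSemantic = 1,
           SelfCorrectedPhonological = 1,
           FragmentIncorrect = 0, SemanticError = 0,
           PhonologicalNeologistic = 0,
           NoResponse = NA, Circumlocution = NA, Perseveration = NA)
  unname(map[category])
}

#' Split per-session feature tables into training and test sets
#'
#' Sessions 1 and 2 form the training set; session 3 is the test set. Row
#' order within each split is preserved and the splits are disjoint.
#'
#' @param table A [build_feature_table()] result covering exactly sessions
#'   1, 2 and 3.
#' @return List with \code{train} and \code{test} feature tables.
#' @export
split_sessions <- function(table) {
  present <- sort(unique(table$session))
  if (!identical(as.integer(present), 1:3))
    stop("expected exactly sessions 1, 2 and 3; got ",
         paste(present, collapse = ", "))
  keep_attrs <- attributes(table)[c("channels", "feature_cols")]
  sel <- function(rows) {
    out <- table[rows, , drop = FALSE]
    attributes(out)[names(keep_attrs)] <- keep_attrs
    out
  }
  list(train = sel(table$session %in% 1:2), test = sel(table$session == 3))
}

.significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE)
}

#' Evaluate predictions by Pearson correlation
#'
#' Pearson r between predicted and observed values, with residual degrees of
#' freedom \eqn{n - k - 1} for \eqn{k} selected features, a two-sided p-value
#' from \eqn{t = r \sqrt{df / (1 - r^2)}}, and a significance tier
#' (* p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001).
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 3); the
#'   observed vector must not be constant.
#' @param k Number of selected model features.
#' @param mode,channel_set Optional labels carried into the result.
#' @return Object of class \code{prediction_evaluation}: \code{r},
#'   \code{df_pair} (k, n - k - 1), \code{p}, \code{tier}, \code{n}.
#' @export
evaluate_predictions <- function(predicted, observed, k, mode = NA,
                                 channel_set = NA) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  n <- length(observed)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::var(observed) == 0)
    stop("observed outcome is constant; correlation undefined")
  r <- if (stats::var(predicted) == 0) 0
       else stats::cor(predicted, observed)
  df <- n - k - 1
  if (df < 1) stop("residual degrees of freedom < 1")
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, df_pair = c(k = k, residual = df), p = p,
                 tier = as.character(.significance_tier(p)), n = n,
                 mode = mode, channel_set = channel_set),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat(sprintf("r = %.4f%s (df %d/%d, p = %.3g, n = %d)\n",
              x$r, x$tier, x$df_pair["k"], x$df_pair["residual"], x$p, x$n))
  invisible(x)
}

#' Channel x band correlation topography
#'
#' Point-biserial Pearson correlation between each single-trial (channel,
#' band) amplitude and the binary accuracy coding, over all trials of the
#' table. Positive r means higher amplitude on correct trials (rendered blue
#' by [plot.topography_map()]). Constant feature columns are recorded as
#' r = 0 and flagged.
#'
#' @param table A full-montage (16-channel) [build_feature_table()] result.
#' @param outcome Numeric accuracy coding aligned with the table rows
#'   (defaults to the accuracy coding of the table's categories).
#' @param layout Montage for channel positions.
#' @return Data frame of class \code{topography_map}: \code{channel},
#'   \code{band}, \code{r}, \code{flagged}, \code{x}, \code{y}.
#' @export
topography_correlations <- function(table,
                                    outcome = encode_outcome(table$category),
                                    layout = channel_layout_1020()) {
  keep <- !table$excluded & !is.na(outcome)
  X <- feature_matrix(table)[keep, , drop = FALSE]
  yv <- outcome[keep]
  if (stats::var(yv) == 0) stop("outcome is constant over included trials")
  cols <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, length(cols))
  r[sds > 0] <- as.numeric(stats::cor(X[, sds > 0, drop = FALSE], yv))
  parts <- regmatches(cols, regexpr("_", cols), invert = TRUE)
  out <- data.frame(
    channel = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    r = r, flagged = sds == 0, stringsAsFactors = FALSE)
  pos <- layout$positions[out$channel, , drop = FALSE]
  out$x <- pos[, "x"]; out$y <- pos[, "y"]
  structure(out, class = c("topography_map", "data.frame"))
}

#' @rdname topography_correlations
#' @param x A \code{topography_map}.
#' @param bands Band labels to draw (default alpha 10-13 and beta 22-25).
#' @param ... Unused.
#' @export
plot.topography_map <- function(x, bands = c("10-13", "22-25"), ...) {
  pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(101)
  lim <- max(abs(x$r), 1e-6)
  old <- graphics::par(mfrow = c(1, length(bands)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  for (b in bands) {
    sub <- x[x$band == b, ]
    graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
                   xlab = "", ylab = "", asp = 1,
                   main = paste0(b, " Hz band"))
    graphics::symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE)
    col <- pal[round(50 * (sub$r / lim)) + 51]
    graphics::points(sub$x, sub$y, pch = 21, bg = col, cex = 3)
    graphics::text(sub$x, sub$y - 0.18, sub$channel, cex = 0.7)
  }
  invisible(x)
}

#' Run the full prediction experiment for one participant
#'
#' Extracts trial-averaged spectral features for all three sessions, codes
#' the outcome, drops excluded trials (too-short epochs, and NA-coded
#' categories in error-correction mode) from both fitting and evaluation,
#' selects both penalties by embedded cross-validation on the session 1-2
#' training set, and evaluates the in-sample training fit and the session-3
#' generalization by Pearson r.
#'
#' @param sessions List of the participant's three \code{eeg_session}s.
#' @param channel_set \code{"3"} (Fz, Cz, Pz) or \code{"9"} (adds F3, F4,
#'   C3, C4, P3, P4).
#' @param mode Outcome coding, \code{"accuracy"} or \code{"error_correction"}.
#' @param config A [spectral_config()].
#' @param seed Seed for the embedded cross-validation folds.
#' @param table Optional precomputed feature table (skips extraction).
#' @param ... Passed to [cross_validate_penalties()].
#' @return Object of class \code{naming_experiment}: the fitted \code{model},
#'   \code{cv} result, \code{train}/\code{test} [evaluate_predictions()]
#'   objects, the coefficient listing (\code{coefficients} data frame) and a
#'   one-row \code{summary} in the train/test layout of the published
#'   correlation tables.
#' @export
run_experiment <- function(sessions, channel_set = "3",
                           mode = c("accuracy", "error_correction"),
                           config = spectral_config(), seed = 1,
                           table = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(table)) table <- build_feature_table(sessions, channel_set, config)
  y_all <- encode_outcome(table$category, mode)
  include <- !table$excluded & !is.na(y_all)
  tab <- table[include, , drop = FALSE]
  attributes(tab)[c("channels", "feature_cols")] <-
    attributes(table)[c("channels", "feature_cols")]
  y <- y_all[include]

  split <- split_sessions(tab)
  y_train <- y[tab$session %in% 1:2]
  y_test <- y[tab$session == 3]
  if (nrow(split$train) == 0 || nrow(split$test) == 0)
    stop("empty training or test split after exclusions")

  X_train <- feature_matrix(split$train)
  X_test <- feature_matrix(split$test)
  cv <- cross_validate_penalties(design_matrix(X_train, y_train),
                                 seed = seed, ...)
  model <- cv$model
  k <- count_selected(model)
  train_eval <- evaluate_predictions(predict(model, X_train), y_train, k,
                                     mode = mode, channel_set = channel_set)
  test_eval <- evaluate_predictions(predict(model, X_test), y_test, k,
                                    mode = mode, channel_set = channel_set)

  coefs <- data.frame(
    feature = c("Intercept", names(model$beta)),
    coefficient = c(model$intercept, unname(model$beta_std)),
    stringsAsFactors = FALSE)
  summary_row <- data.frame(
    participant = sessions[[1]]$participant_id, mode = mode,
    channel_set = channel_set,
    r_train = train_eval$r, tier_train = train_eval$tier,
    r_test = test_eval$r, tier_test = test_eval$tier,
    k = k, df_train = sprintf("%d/%d", k, train_eval$df_pair["residual"]),
    df_test = sprintf("%d/%d", k, test_eval$df_pair["residual"]),
    stringsAsFactors = FALSE)
  structure(list(model = model, cv = cv, train = train_eval,
                 test = test_eval, coefficients = coefs,
                 summary = summary_row, mode = mode,
                 channel_set = channel_set, n_excluded = sum(!include),
                 seed = seed),
            class = "naming_experiment")
}

#' @export
print.naming_experiment <- function(x, ...) {
  cat(sprintf("<naming_experiment> mode=%s, %s-channel, %d excluded trial(s)\n",
              x$mode, x$channel_set, x$n_excluded))
  cat("  train: "); print(x$train)
  cat("  test:  "); print(x$test)
  nz <- x$coefficients[x$coefficients$coefficient != 0, ]
  cat(sprintf("  %d selected feature(s); intercept %.4f\n",
              count_selected(x$model), x$model$intercept))
  if (nrow(nz) > 1)
    for (i in 2:nrow(nz))
      cat(sprintf("    %-12s %+.4f\n", nz$feature[i], nz$coefficient[i]))
  cat("  significance tiers: * p<0.05  ** p<0.01  *** p<0.001  **** p<0.0001",
      "(no multiplicity correction)\n")
  invisible(x)
}

#' Write the coefficient listing as TSV
#'
#' @param experiment A \code{naming_experiment}.
#' @param path Output path.
#' @export
write_coefficients_tsv <- function(experiment, path) {
  utils::write.table(experiment$coefficients, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
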