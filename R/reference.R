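#' Reference coefficient listings
#'
#' Loads previously reported 3-channel accuracy models (one column per
#' model, standardized feature scale, blank = unselected) and builds
#' [elastic_net_model()] objects from them. Applying such a model to the
#' all-zero point of its standardized feature space returns its intercept.
#'
#' @param path TSV path; defaults to the listing shipped with the package.
#' @return Named list of \code{elastic_net_model} objects.
#' @export
read_reference_models <- function(path = system.file("extdata",
                                                     "reference_models.tsv",
                                                     package = "eegnaming")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           fill = TRUE, stringsAsFactors = FALSE)
  stopifnot(tab$feature[1] == "Intercept")
  models <- lapply(names(tab)[-1], function(col) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    vals[is.na(vals)] <- 0
    beta <- vals[-1]
    names(beta) <- tab$feature[-1]
    elastic_net_model(intercept = vals[1], beta = beta)
  })
  names(models) <- names(tab)[-1]
  models
}
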