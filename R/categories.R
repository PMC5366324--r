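#' The 10-category naming-response scoring schema
#'
#' Picture-naming responses are scored into ten mutually exclusive categories
#' covering correct productions, the major aphasic error types (semantic,
#' phonological/neologistic, fragment, circumlocution, perseveration,
#' no-response) and the self-corrected variants of the three correctable
#' error families. Each category carries the numeric keypad value used by the
#' scorer during testing (assigned 0-9 in schema row order) and the error
#' family it belongs to.
#'
#' @return A data frame with one row per category and columns
#'   \code{code} (canonical identifier), \code{keypad} (integer 0-9),
#'   \code{label} (human-readable description), \code{self_corrected}
#'   (logical) and \code{family} (\code{"correct"}, \code{"none"},
#'   \code{"fragment"}, \code{"semantic"}, \code{"phonological"},
#'   \code{"circumlocution"} or \code{"perseveration"}).
#' @examples
#' response_categories()
#' @export
response_categories <- function() {
  data.frame(
    code = c("NoResponse", "Correct", "SelfCorrectedFragment",
             "FragmentIncorrect", "SemanticError", "SelfCorrectedSemantic",
             "Circumlocution", "PhonologicalNeologistic",
             "SelfCorrectedPhonological", "Perseveration"),
    keypad = 0:9,
    label = c(
      "no response within the 10-s display window",
      "noun matches target on first production attempt",
      "self-interrupted fragment, corrected to target",
      "self-interrupted fragment, incorrect response",
      "semantic error (conceptually related noun)",
      "semantic error, self-corrected within the trial",
      "circumlocution (describes without naming)",
      "phonological or neologistic error",
      "phonological/neologistic error, self-corrected",
      "perseveration of a previous response"),
    self_corrected = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                       FALSE, FALSE, TRUE, FALSE),
    family = c("none", "correct", "fragment", "fragment", "semantic",
               "semantic", "circumlocution", "phonological", "phonological",
               "perseveration"),
    stringsAsFactors = FALSE
  )
}

#' @rdname response_categories
#' @return \code{category_codes()}: the ten canonical category codes, in
#'   keypad order.
#' @export
category_codes <- function() response_categories()$code

.check_category <- function(category) {
  codes <- category_codes()
  bad <- setdiff(unique(category), codes)
  if (length(bad) > 0)
    stop("unknown response category: ", paste(bad, collapse = ", "))
  invisible(category)
}

#' Is a response category a self-correction?
#'
#' Self-corrected categories are responses that started out as errors but were
#' independently corrected by the participant before the end of the trial:
#' self-corrected fragments, self-corrected semantic errors and self-corrected
#' phonological/neologistic errors.
#'
#' @param category Character vector of category codes (see
#'   [response_categories()]).
#' @return Logical vector, \code{TRUE} exactly for the three self-corrected
#'   categories.
#' @examples
#' category_is_self_corrected(c("Correct", "SelfCorrectedSemantic"))
#' @export
category_is_self_corrected <- function(category) {
  .check_category(category)
  schema <- response_categories()
  schema$self_corrected[match(category, schema$code)]
}

#' Write or read the category schema as JSON
#'
#' Serializes the full schema (codes, keypad values, labels, flags) so that
#' event tables scored elsewhere can be validated against it.
#'
#' @param path File path for the JSON schema.
#' @return \code{write_category_schema} returns \code{path} invisibly;
#'   \code{read_category_schema} returns the schema data frame.
#' @export
write_category_schema <- function(path) {
  jsonlite::write_json(response_categories(), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_category_schema
#' @export
read_category_schema <- function(path) {
  schema <- jsonlite::fromJSON(path)
  stopifnot(identical(schema$code, category_codes()))
  schema
}
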