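# Stimulus-set machinery: normed picture items, the agreement/familiarity
# exclusion rule, and the randomized 9 x 100 set partition with repeat-name
# trading.

#' Simulate a pool of normed picture-naming stimuli
#'
#' Emulates a photograph database normed for object name and familiarity:
#' each item has a modal name, a naming-agreement proportion in [0, 1] and a
#' mean familiarity rating on a 1-5 scale. A controllable fraction of items
#' share a name with another item (e.g. two different clocks), which is what
#' the set partition's repeat-name trading has to resolve.
#'
#' @param n Number of items (default 1469, a full database-sized pool).
#' @param seed Integer seed.
#' @param dup_rate Fraction of items whose name duplicates another item's.
#' @return Data frame with columns \code{name}, \code{naming_agreement},
#'   \code{familiarity}.
#' @export
simulate_stimulus_pool <- function(n = 1469, seed = 1, dup_rate = 0.03) {
  set.seed(seed)
  name <- sprintf("object%04d", seq_len(n))
  ndup <- round(dup_rate * n)
  if (ndup > 0) {
    dup_at <- sample(n, ndup)
    name[dup_at] <- sample(name[-dup_at], ndup, replace = TRUE)
  }
  data.frame(
    name = name,
    naming_agreement = stats::rbeta(n, 2.5, 1),
    familiarity = 1 + 4 * stats::rbeta(n, 3.5, 1),
    stringsAsFactors = FALSE)
}

#' Filter stimulus items on naming agreement and familiarity
#'
#' Retains items with at least 20% naming agreement and a mean familiarity
#' rating of at least 75% of the scale maximum (3.75 out of 5); items below
#' either threshold are excluded. Both bounds are inclusive.
#'
#' @param items Data frame with \code{naming_agreement} and
#'   \code{familiarity} columns.
#' @return The retained subset, same columns.
#' @export
filter_stimulus_items <- function(items) {
  stopifnot(all(c("naming_agreement", "familiarity") %in% names(items)))
  if (any(items$naming_agreement < 0 | items$naming_agreement > 1))
    stop("naming_agreement must lie in [0, 1]")
  if (any(items$familiarity < 1 | items$familiarity > 5))
    stop("familiarity must lie in [1, 5]")
  items[items$naming_agreement >= 0.20 & items$familiarity >= 3.75, ,
        drop = FALSE]
}

# Sets 3s-2, 3s-1, 3s form session s's stimuli.
.session_of_set <- function(set_index) (set_index - 1L) %/% 3L + 1L

#' Partition 900 stimulus items into nine sets of 100
#'
#' Items are assigned uniform random keys, sorted, and split into nine sets
#' of 100. Because sets 1-3, 4-6 and 7-9 are administered within single
#' sessions, item names must not repeat within a session's three sets: any
#' repeat name is traded with an item from a set in another session. The
#' trading pass is deterministic given the seed; if the pool is too
#' duplicate-heavy for a valid assignment the function fails after a bounded
#' number of passes.
#'
#' @param items Data frame of exactly 900 retained items (column \code{name}).
#' @param seed Integer seed for the random sort keys.
#' @param max_passes Bound on repeat-name trading passes.
#' @return \code{items} with an added integer \code{set_index} column (1-9;
#'   100 items per set), rows in set order.
#' @export
partition_stimulus_sets <- function(items, seed = 1, max_passes = 50) {
  if (nrow(items) != 900)
    stop("exactly 900 items are required, got ", nrow(items))
  set.seed(seed)
  key <- stats::runif(nrow(items))
  items <- items[order(key), , drop = FALSE]
  items$set_index <- rep(1:9, each = 100)

  session_names <- function(it, s) it$name[.session_of_set(it$set_index) == s]
  for (pass in seq_len(max_passes)) {
    traded <- FALSE
    for (s in 1:3) {
      in_sess <- which(.session_of_set(items$set_index) == s)
      dup <- in_sess[duplicated(items$name[in_sess])]
      for (i in dup) {
        nm <- items$name[i]
        # candidate partners: items in other sessions whose name is absent
        # from this session and which can absorb nm without a new repeat
        cand <- which(.session_of_set(items$set_index) != s)
        ok <- vapply(cand, function(j) {
          s2 <- .session_of_set(items$set_index[j])
          !(items$name[j] %in% items$name[in_sess]) &&
            sum(session_names(items, s2) == nm) == 0
        }, logical(1))
        cand <- cand[ok]
        if (length(cand) == 0) next
        j <- cand[1]
        tmp <- items$set_index[i]
        items$set_index[i] <- items$set_index[j]
        items$set_index[j] <- tmp
        traded <- TRUE
      }
    }
    conflicts <- sum(vapply(1:3, function(s) {
      nm <- session_names(items, s)
      sum(duplicated(nm))
    }, numeric(1)))
    if (conflicts == 0) break
    if (!traded || pass == max_passes)
      stop("could not resolve repeat names within sessions: the item pool ",
           "has too many duplicated names")
  }
  items[order(items$set_index), , drop = FALSE]
}
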