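#' Person-by-item response matrix
#'
#' The universal input container: an N-person by I-item matrix of
#' non-negative integer scores with missing values allowed.  Missing
#' responses are treated as *not administered* — they are excluded from
#' likelihood and pairwise classical statistics, never scored as wrong.
#' Each item `i` carries a maximum category `m[i]` (1 for dichotomous
#' items); valid scores lie in `0..m[i]`.
#'
#' @param data A data frame or tibble whose columns are items (integer
#'   scores, `NA` for not administered).  A column named `person_id` is
#'   used for person identifiers; a column named `group` is rejected here
#'   (use [grouped_responses()]).
#' @param declared_max Optional named integer vector of per-item maximum
#'   categories.  Defaults to the maximum observed score per item.
#' @return A `response_matrix` object: a list with `scores` (integer
#'   matrix), `person_ids`, `item_ids`, `max_score` (named vector
#'   `m[i]`), and `zero_variance` (items retained but flagged for having
#'   a single observed value).
#' @examples
#' df <- tibble::tibble(i1 = c(0, 1, 1, 0), i2 = c(1, 1, 0, 0), i3 = c(0, 1, 0, 1))
#' rm <- response_matrix(df)
#' rm$max_score
#' @export
response_matrix <- function(data, declared_max = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if ("group" %in% names(data)) {
    abort("column `group` found; use grouped_responses() / read_grouped_csv() for grouped data")
  }
  if ("person_id" %in% names(data)) {
    person_ids <- as.character(data$person_id)
    data <- data[setdiff(names(data), "person_id")]
  } else {
    person_ids <- as.character(seq_len(nrow(data)))
  }
  item_ids <- names(data)
  scores <- as.matrix(data)
  if (!is.numeric(scores)) {
    bad <- which(!vapply(data, is.numeric, logical(1)))
    abort(paste0("non-numeric item column(s): ", paste(item_ids[bad], collapse = ", ")))
  }
  storage.mode(scores) <- "double"
  new_response_matrix(scores, person_ids, item_ids, declared_max)
}

new_response_matrix <- function(scores, person_ids, item_ids, declared_max = NULL) {
  n <- nrow(scores); k <- ncol(scores)
  if (k < 2L) abort("validation error: at least 2 items are required")
  if (n < 2L) abort("validation error: at least 2 persons are required")
  obs <- scores[!is.na(scores)]
  if (length(obs) == 0L) abort("validation error: all responses missing")
  if (any(obs != round(obs))) abort("parse error: non-integer score present")
  if (any(obs < 0)) abort("validation error: negative score present")

  observed_max <- apply(scores, 2L, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  if (is.null(declared_max)) {
    max_score <- pmax(observed_max, 1)  # an all-zero item is still scored 0/1
  } else {
    declared_max <- unlist(declared_max)
    if (is.null(names(declared_max)) && length(declared_max) == k) {
      names(declared_max) <- item_ids
    }
    max_score <- pmax(observed_max, 1, na.rm = TRUE)
    hit <- intersect(names(declared_max), item_ids)
    max_score[match(hit, item_ids)] <- declared_max[hit]
    over <- which(!is.na(observed_max) & observed_max > max_score)
    if (length(over)) {
      abort(paste0("validation error: observed score exceeds declared max for item(s): ",
                   paste(item_ids[over], collapse = ", ")))
    }
  }
  max_score <- as.integer(round(max_score))
  if (any(max_score < 1L)) abort("validation error: every item needs max score >= 1")
  names(max_score) <- item_ids
  zero_variance <- apply(scores, 2L, function(x) length(unique(x[!is.na(x)])) <= 1L)

  dimnames(scores) <- list(person_ids, item_ids)
  structure(
    list(scores = scores, person_ids = person_ids, item_ids = item_ids,
         max_score = max_score, zero_variance = zero_variance),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$scores), " persons x ", ncol(x$scores), " items\n", sep = "")
  cat("  max categories: ", paste(unique(x$max_score), collapse = ", "),
      "; missing cells: ", sum(is.na(x$scores)), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.response_matrix <- function(x, ...) {
  as.data.frame(dplyr::bind_cols(tibble::tibble(person_id = x$person_ids),
                                 tibble::as_tibble(x$scores)))
}

#' @rdname response_matrix
#' @param x An object to coerce.
#' @export
as_response_matrix <- function(x, declared_max = NULL) {
  if (inherits(x, "response_matrix")) return(x)
  if (inherits(x, "grouped_responses")) return(x$base)
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("I", seq_len(ncol(x)))
    return(new_response_matrix(x, as.character(seq_len(nrow(x))), colnames(x), declared_max))
  }
  if (is.data.frame(x)) return(response_matrix(x, declared_max))
  abort("cannot interpret input as a response matrix")
}

#' Grouped person-by-item responses
#'
#' Couples a [response_matrix()] with a per-person categorical group
#' label (e.g. `1` = male, `2` = female), the input of the many-facets
#' differential item functioning analysis.  Labels are preserved
#' verbatim.
#'
#' @param data Data frame whose *first* column (or a column named
#'   `group`) holds group membership; remaining columns are items.
#' @param declared_max As in [response_matrix()].
#' @return A `grouped_responses` object with fields `base`
#'   (`response_matrix`) and `group` (character vector).
#' @export
grouped_responses <- function(data, declared_max = NULL) {
  stopifnot(is.data.frame(data), ncol(data) >= 3L)
  data <- tibble::as_tibble(data)
  gcol <- if ("group" %in% names(data)) "group" else names(data)[1L]
  group <- as.character(data[[gcol]])
  rest <- data[setdiff(names(data), gcol)]
  base <- response_matrix(rest, declared_max)
  if (length(unique(group)) < 2L) {
    abort("single group present; use the uni-dimensional analysis instead")
  }
  if (anyNA(group)) abort("validation error: missing group label")
  structure(list(base = base, group = group), class = "grouped_responses")
}

#' @export
print.grouped_responses <- function(x, ...) {
  tab <- table(x$group)
  cat("<grouped_responses> groups: ",
      paste(names(tab), "(", as.integer(tab), ")", sep = "", collapse = ", "), "\n", sep = "")
  print(x$base)
  invisible(x)
}

#' Read a person-by-item score CSV
#'
#' Expects a header row of item labels and integer cells; empty cells or
#' `NA` mark not-administered responses.  Any other non-integer cell is
#' a parse error naming its row and column.
#'
#' @param path CSV file path.
#' @param declared_max Optional per-item maximum category (named vector).
#' @return A [response_matrix()].
#' @export
read_response_csv <- function(path, declared_max = NULL) {
  response_matrix(read_score_table(path), declared_max)
}

#' Read a grouped score CSV for DIF analysis
#'
#' As [read_response_csv()] but the first column holds group membership.
#'
#' @inheritParams read_response_csv
#' @return A [grouped_responses()] object.
#' @export
read_grouped_csv <- function(path, declared_max = NULL) {
  raw <- read_score_table(path, first_col_character = TRUE)
  grouped_responses(raw, declared_max)
}

# Shared strict CSV reader: all-character read, then per-cell integer
# validation so errors can name the offending row/column.
read_score_table <- function(path, first_col_character = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (nrow(raw) == 0L) abort("validation error: no data rows")
  item_cols <- if (first_col_character) names(raw)[-1L] else names(raw)
  out <- raw
  for (cn in item_cols) {
    cell <- trimws(raw[[cn]])
    cell[cell %in% c("", "NA")] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & (is.na(num) | num != round(num)))
    if (length(bad)) {
      abort(paste0("parse error: non-integer cell at row ", bad[1L],
                   ", column '", cn, "' (value '", cell[bad[1L]], "')"))
    }
    out[[cn]] <- num
  }
  if (first_col_character) names(out)[1L] <- "group"
  out
}
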