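#' Define an item's measurement model
#'
#' An item spec records which Rasch family an item belongs to and its score
#' range. Dichotomous items are scored 0/1; partial-credit items are scored
#' 0..`max_score` with item-specific step thresholds.
#'
#' @param item_id Single character id, unique within a test.
#' @param family `"dichotomous"` or `"partial_credit"`.
#' @param max_score Highest attainable score (1 for dichotomous items).
#' @param category_labels Optional character vector of length `max_score + 1`.
#' @return An object of class `item_spec`.
#' @export
#' @examples
#' item_spec("Q1", "dichotomous")
#' item_spec("Q2", "partial_credit", max_score = 3)
item_spec <- function(item_id, family = c("dichotomous", "partial_credit"),
                      max_score = 1L, category_labels = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(item_id), length(item_id) == 1L, nzchar(item_id))
  max_score <- as.integer(max_score)
  if (max_score < 1L) stop("max_score must be >= 1", call. = FALSE)
  if (family == "dichotomous" && max_score != 1L)
    stop("dichotomous items have max_score 1", call. = FALSE)
  if (family == "partial_credit" && max_score < 2L)
    stop("partial_credit items need max_score >= 2", call. = FALSE)
  if (!is.null(category_labels) && length(category_labels) != max_score + 1L)
    stop("category_labels must have length max_score + 1", call. = FALSE)
  structure(list(item_id = item_id, family = family, max_score = max_score,
                 category_labels = category_labels),
            class = "item_spec")
}

#' @export
print.item_spec <- function(x, ...) {
  cat(sprintf("<item_spec> %s [%s, 0..%d]\n", x$item_id, x$family, x$max_score))
  invisible(x)
}

#' Bundle item specs into a test specification
#'
#' @param ... `item_spec` objects, or a single list of them.
#' @return A list of class `test_spec`.
#' @export
test_spec <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "item_spec")) specs <- specs[[1L]]
  if (!all(vapply(specs, inherits, logical(1), "item_spec")))
    stop("all elements must be item_spec objects", call. = FALSE)
  ids <- vapply(specs, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("duplicate item ids", call. = FALSE)
  names(specs) <- ids
  structure(specs, class = "test_spec")
}

#' @export
print.test_spec <- function(x, ...) {
  cat(sprintf("<test_spec> %d items, %d raw score points\n",
              length(x), sum(vapply(x, `[[`, integer(1), "max_score"))))
  invisible(x)
}

item_ids <- function(specs) vapply(specs, `[[`, character(1), "item_id")
max_scores <- function(specs) vapply(specs, `[[`, integer(1), "max_score")

#' Read / write item specs as CSV
#'
#' The CSV dialect has columns `item_id`, `family`, `max_score`.
#'
#' @param path File path.
#' @return `read_item_specs()` returns a `test_spec`.
#' @export
read_item_specs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "family", "max_score")
  if (!all(need %in% names(df))) stop("item spec CSV needs columns: ",
                                      paste(need, collapse = ", "), call. = FALSE)
  test_spec(lapply(seq_len(nrow(df)), function(i)
    item_spec(df$item_id[i], df$family[i], df$max_score[i])))
}

#' @rdname read_item_specs
#' @param specs A `test_spec`.
#' @export
write_item_specs <- function(specs, path) {
  df <- data.frame(item_id = item_ids(specs),
                   family = vapply(specs, `[[`, character(1), "family"),
                   max_score = max_scores(specs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
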