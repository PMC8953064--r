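#' Construct a person-by-item response matrix
#'
#' The universal input of the pipeline: an integer score matrix with one row
#' per person and one column per item, plus the item specs. Missing responses
#' are encoded as `NA` and treated as not administered throughout (skipped in
#' all likelihood and expectation sums, never imputed).
#'
#' @param scores Integer matrix, persons x items; `NA` marks missing.
#' @param specs A [test_spec()] whose order matches the columns.
#' @param person_ids Character vector of unique person ids; defaults to
#'   rownames or `P1..Pn`.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(scores, specs, person_ids = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (!inherits(specs, "test_spec")) specs <- test_spec(specs)
  if (ncol(scores) != length(specs))
    stop("number of columns must equal number of item specs", call. = FALSE)
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    stop("need at least 2 persons and 2 items", call. = FALSE)
  if (is.null(person_ids)) {
    person_ids <- rownames(scores)
    if (is.null(person_ids)) person_ids <- paste0("P", seq_len(nrow(scores)))
  }
  person_ids <- as.character(person_ids)
  if (length(person_ids) != nrow(scores)) stop("person_ids length mismatch", call. = FALSE)
  if (anyDuplicated(person_ids)) stop("duplicate person ids", call. = FALSE)
  m <- max_scores(specs)
  for (j in seq_along(specs)) {
    x <- scores[, j]
    bad <- !is.na(x) & (x < 0L | x > m[j])
    if (any(bad))
      stop(sprintf("item %s has scores outside 0..%d", item_ids(specs)[j], m[j]),
           call. = FALSE)
  }
  dimnames(scores) <- list(person_ids, item_ids(specs))
  structure(list(scores = scores, specs = specs, person_ids = person_ids),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items (%d%% missing)\n",
              nrow(x$scores), ncol(x$scores),
              round(100 * mean(is.na(x$scores)))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$scores)

#' Subset a response matrix
#'
#' @param x A `response_matrix`.
#' @param persons,items Index vectors (ids, positions or logical) selecting
#'   rows / columns; `NULL` keeps all.
#' @return A `response_matrix`.
#' @export
subset_responses <- function(x, persons = NULL, items = NULL) {
  stopifnot(inherits(x, "response_matrix"))
  pi <- if (is.null(persons)) seq_len(nrow(x$scores)) else persons
  ii <- if (is.null(items)) seq_len(ncol(x$scores)) else items
  sc <- x$scores[pi, ii, drop = FALSE]
  specs <- test_spec(unname(unclass(x$specs)[ii]))
  response_matrix(sc, specs, person_ids = rownames(sc))
}

#' Read / write response matrices as CSV
#'
#' Dialect: first column is the person id, remaining columns are item ids;
#' blank cells are missing.
#'
#' @param path File path.
#' @param specs A `test_spec`; if `NULL`, all items are assumed dichotomous
#'   unless scores above 1 are observed (then the observed maximum is used).
#' @return `read_responses()` returns a `response_matrix`.
#' @export
read_responses <- function(path, specs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  sc <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(sc) <- "integer"
  if (is.null(specs)) {
    specs <- test_spec(lapply(colnames(sc), function(id) {
      mx <- suppressWarnings(max(sc[, id], na.rm = TRUE))
      if (is.finite(mx) && mx > 1L) item_spec(id, "partial_credit", mx)
      else item_spec(id, "dichotomous")
    }))
  } else {
    sc <- sc[, item_ids(specs), drop = FALSE]
  }
  response_matrix(sc, specs, person_ids = ids)
}

#' @rdname read_responses
#' @param x A `response_matrix`.
#' @export
write_responses <- function(x, path) {
  df <- data.frame(person_id = x$person_ids, x$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Raw total scores per person or item
#'
#' Totals are over administered (non-missing) responses.
#'
#' @param x A `response_matrix`.
#' @param margin `"persons"` or `"items"`.
#' @return Named numeric vector of totals.
#' @export
raw_totals <- function(x, margin = c("persons", "items")) {
  margin <- match.arg(margin)
  if (margin == "persons") rowSums(x$scores, na.rm = TRUE)
  else colSums(x$scores, na.rm = TRUE)
}
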