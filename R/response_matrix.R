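#' Construct a response matrix of ordinal item scores
#'
#' The universal input container of the package: an integer matrix of
#' persons (rows) by items (columns) holding 0-based category codes, with
#' `NA` marking missing responses. Each item `i` has `n_categories[i]`
#' ordered categories coded `0 .. n_categories[i] - 1`.
#'
#' @param values integer matrix (persons x items); `NA` = missing.
#' @param n_categories integer vector of per-item category counts. Defaults
#'   to `max observed code + 1` per item.
#' @param item_ids character vector of unique item labels. Defaults to the
#'   column names of `values`, or `item1, item2, ...`.
#' @return An object of class `"response_matrix"` with fields `values`,
#'   `missing_mask`, `item_ids`, `n_categories`.
#' @examples
#' R <- response_matrix(rbind(c(0, 1), c(2, 1), c(1, 0)), n_categories = c(3, 2))
#' n_persons(R)
#' @export
response_matrix <- function(values, n_categories = NULL, item_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("response matrix needs at least one person and one item", call. = FALSE)
  storage.mode(values) <- "integer"
  if (is.null(item_ids)) item_ids <- colnames(values)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(values)))
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids))
    stop("item ids must be unique", call. = FALSE)
  if (length(item_ids) != ncol(values))
    stop("item_ids length must match number of columns", call. = FALSE)
  if (is.null(n_categories)) {
    n_categories <- apply(values, 2L, function(x) {
      if (all(is.na(x))) 2L else max(x, na.rm = TRUE) + 1L
    })
  }
  n_categories <- as.integer(n_categories)
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, ncol(values))
  if (length(n_categories) != ncol(values))
    stop("n_categories length must match number of items", call. = FALSE)
  if (any(n_categories < 2L))
    stop("every item needs at least 2 categories", call. = FALSE)
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    bad <- which(!is.na(x) & (x < 0L | x >= n_categories[j]))
    if (length(bad))
      stop(sprintf("code %d outside [0, %d] for item '%s' at row %d",
                   x[bad[1L]], n_categories[j] - 1L, item_ids[j], bad[1L]),
           call. = FALSE)
  }
  colnames(values) <- item_ids
  rownames(values) <- NULL
  structure(list(values = values,
                 missing_mask = is.na(values),
                 item_ids = item_ids,
                 n_categories = n_categories),
            class = "response_matrix")
}

#' @rdname response_matrix
#' @param x object to test or summarise.
#' @export
is_response_matrix <- function(x) inherits(x, "response_matrix")

#' @rdname response_matrix
#' @export
n_persons <- function(x) nrow(x$values)

#' @rdname response_matrix
#' @export
n_items <- function(x) ncol(x$values)

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %d missing cells\n",
              n_persons(x), n_items(x), sum(x$missing_mask)))
  cat("items:", paste0(x$item_ids, "(", x$n_categories, ")", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' Define an instrument: item ids, category counts, missing sentinel
#'
#' @param name instrument label.
#' @param items data frame with columns `id` and `n_categories`, or a named
#'   integer vector of category counts.
#' @param missing_code sentinel string marking missing cells in CSV input.
#' @return An `"instrument_spec"` object.
#' @examples
#' instrument_spec("PHQ9", c(PHQ1 = 4, PHQ2 = 4))
#' @export
instrument_spec <- function(name, items, missing_code = "NA") {
  if (!is.data.frame(items)) {
    items <- data.frame(id = names(items), n_categories = as.integer(items),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "n_categories") %in% names(items)))
  items$id <- as.character(items$id)
  items$n_categories <- as.integer(items$n_categories)
  if (any(items$n_categories < 2L))
    stop("every item needs n_categories >= 2", call. = FALSE)
  if (anyDuplicated(items$id)) stop("item ids must be unique", call. = FALSE)
  structure(list(name = as.character(name), items = items,
                 missing_code = as.character(missing_code)),
            class = "instrument_spec")
}

#' Read an instrument specification from JSON or YAML
#'
#' The file must contain `name`, `items` (list of `{id, n_categories}` or a
#' map id -> count) and optionally `missing_code`.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return An [instrument_spec()].
#' @export
read_instrument_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML specs", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("unsupported spec format: ", ext, call. = FALSE)
  items <- raw$items
  if (is.data.frame(items)) {
    it <- items
  } else if (!is.null(names(items)) && all(vapply(items, is.numeric, TRUE))) {
    it <- data.frame(id = names(items),
                     n_categories = as.integer(unlist(items)),
                     stringsAsFactors = FALSE)
  } else {
    it <- do.call(rbind, lapply(items, function(e)
      data.frame(id = as.character(e$id),
                 n_categories = as.integer(e$n_categories),
                 stringsAsFactors = FALSE)))
  }
  instrument_spec(raw$name %||% "instrument", it,
                  missing_code = raw$missing_code %||% "NA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a wide-format response CSV against an instrument specification
#'
#' The CSV must have a header row of item ids matching the spec (order is
#' taken from the file); cells hold integer category codes or the missing
#' sentinel. Row order is preserved.
#'
#' @param path CSV file path.
#' @param spec an [instrument_spec()].
#' @return A [response_matrix()].
#' @export
load_responses <- function(path, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty response file: ", path, call. = FALSE)
  ids <- names(df)
  unknown <- setdiff(ids, spec$items$id)
  if (length(unknown))
    stop("unknown item id(s) in header: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ncat <- spec$items$n_categories[match(ids, spec$items$id)]
  vals <- matrix(NA_integer_, nrow(df), length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    cell <- df[[j]]
    miss <- is.na(cell) | cell == spec$missing_code | cell == ""
    num <- suppressWarnings(as.integer(cell[!miss]))
    if (anyNA(num))
      stop(sprintf("non-integer code in column '%s'", ids[j]), call. = FALSE)
    out <- which(num < 0L | num >= ncat[j])
    if (length(out)) {
      row <- which(!miss)[out[1L]]
      stop(sprintf("code %d outside [0, %d] at row %d, item '%s'",
                   num[out[1L]], ncat[j] - 1L, row, ids[j]), call. = FALSE)
    }
    vals[!miss, j] <- num
  }
  response_matrix(vals, n_categories = ncat, item_ids = ids)
}

#' Write a response matrix to wide CSV
#'
#' @param R a [response_matrix()].
#' @param path output file path.
#' @param missing_code sentinel written for missing cells.
#' @return `path`, invisibly.
#' @export
write_responses <- function(R, path, missing_code = "NA") {
  stopifnot(is_response_matrix(R))
  df <- as.data.frame(R$values)
  utils::write.csv(df, path, row.names = FALSE, na = missing_code)
  invisible(path)
}

#' Merge response categories of one item with a monotone mapping
#'
#' Sparsely used categories can be pooled before model fitting, e.g. a
#' 7-category item recoded with `c(0, 0, 1, 1, 2, 2, 2)` to 3 categories.
#' The mapping must be non-decreasing and onto `0..m'` (no gaps), so the
#' category order is preserved.
#'
#' @param R a [response_matrix()].
#' @param item item id or column index.
#' @param mapping integer vector of length `n_categories[item]`; entry `k+1`
#'   is the new code for old code `k`.
#' @return A new [response_matrix()] with the item recoded.
#' @export
merge_categories <- function(R, item, mapping) {
  stopifnot(is_response_matrix(R))
  j <- item_index(R, item)
  mapping <- as.integer(mapping)
  if (length(mapping) != R$n_categories[j])
    stop("mapping length must equal the item's category count", call. = FALSE)
  if (any(diff(mapping) < 0L))
    stop("mapping must be non-decreasing", call. = FALSE)
  if (mapping[1L] != 0L || any(diff(mapping) > 1L))
    stop("mapping must be onto 0..m' (no gaps, start at 0)", call. = FALSE)
  vals <- R$values
  old <- vals[, j]
  vals[, j] <- ifelse(is.na(old), NA_integer_, mapping[old + 1L])
  ncat <- R$n_categories
  ncat[j] <- max(mapping) + 1L
  response_matrix(vals, n_categories = ncat, item_ids = R$item_ids)
}

item_index <- function(R, item) {
  if (is.character(item)) {
    j <- match(item, R$item_ids)
    if (is.na(j)) stop("unknown item id: ", item, call. = FALSE)
  } else {
    j <- as.integer(item)
    if (j < 1L || j > n_items(R)) stop("item index out of range", call. = FALSE)
  }
  j
}

#' Marginal category frequencies per item
#'
#' @param R a [response_matrix()].
#' @return A data frame with one row per item: `item`, `c0 ... c<max>`
#'   category counts (NA where the item has fewer categories), and `missing`.
#'   For every item the category counts plus missing sum to the person count.
#' @export
marginal_frequencies <- function(R) {
  stopifnot(is_response_matrix(R))
  mmax <- max(R$n_categories)
  counts <- matrix(NA_integer_, n_items(R), mmax,
                   dimnames = list(NULL, paste0("c", seq_len(mmax) - 1L)))
  for (j in seq_len(n_items(R))) {
    x <- R$values[, j]
    counts[j, seq_len(R$n_categories[j])] <-
      tabulate(x[!is.na(x)] + 1L, nbins = R$n_categories[j])
  }
  out <- data.frame(item = R$item_ids, counts,
                    missing = colSums(R$missing_mask),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Drop persons with any missing response (listwise deletion)
#'
#' @param R a [response_matrix()].
#' @return A [response_matrix()] of the complete rows, with attribute
#'   `n_removed` giving the number of dropped persons.
#' @export
complete_cases <- function(R) {
  stopifnot(is_response_matrix(R))
  keep <- !apply(R$missing_mask, 1L, any)
  if (!any(keep))
    stop("no complete cases remain after listwise deletion", call. = FALSE)
  out <- response_matrix(R$values[keep, , drop = FALSE],
                         n_categories = R$n_categories,
                         item_ids = R$item_ids)
  attr(out, "n_removed") <- sum(!keep)
  out
}
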