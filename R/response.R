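#' Respondent-by-item response matrix
#'
#' Container for ordered categorical item responses: an `N x J` integer
#' matrix with values in `0 .. K_j - 1` (NA for missing), optional
#' per-respondent group labels, and per-item category counts.
#'
#' @param responses Integer matrix or data frame, one row per respondent,
#'   values `0 .. K-1` or NA.
#' @param groups Optional character/factor vector of length N.
#' @param item_labels Optional item labels; defaults to column names or
#'   `item1 ...`.
#' @param n_cat Number of ordered categories per item.  A single integer is
#'   recycled; default 5.
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, groups = NULL, item_labels = NULL,
                            n_cat = 5L) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.numeric(responses)) stop("responses must be numeric", call. = FALSE)
  if (nrow(responses) < 1L) stop("need at least one respondent", call. = FALSE)
  storage.mode(responses) <- "integer"
  J <- ncol(responses)
  n_cat <- rep_len(as.integer(n_cat), J)
  if (is.null(item_labels))
    item_labels <- colnames(responses)
  if (is.null(item_labels))
    item_labels <- paste0("item", seq_len(J))
  item_labels <- unname(item_labels)
  colnames(responses) <- item_labels
  for (j in seq_len(J)) {
    v <- responses[, j]
    bad <- !is.na(v) & (v < 0L | v >= n_cat[j])
    if (any(bad))
      stop(sprintf("item %s has responses outside 0..%d (e.g. value %d)",
                   item_labels[j], n_cat[j] - 1L, v[which(bad)[1]]),
           call. = FALSE)
  }
  if (!is.null(groups)) {
    if (length(groups) != nrow(responses))
      stop("`groups` must have one label per respondent", call. = FALSE)
    groups <- as.character(groups)
  }
  structure(list(responses = responses, groups = groups,
                 item_labels = item_labels, n_cat = n_cat),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items", nrow(x$responses),
              ncol(x$responses)))
  mr <- missing_rates(x)
  if (any(mr > 0)) cat(sprintf(", missing %.1f-%.1f%% per item",
                               100 * min(mr), 100 * max(mr)))
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat(sprintf("; groups: %s",
                paste(sprintf("%s (%d)", names(tb), tb), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Per-item missing fractions
#' @param data A `response_matrix`.
#' @return Named numeric vector of per-item missing proportions.
#' @export
missing_rates <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  colMeans(is.na(data$responses))
}

#' Read / write respondent response files
#'
#' Delimited text, one row per respondent, integer-coded item columns and an
#' optional group column.  Items coded 1-5 instead of 0-4 can be recoded on
#' the way in.
#'
#' @param path File path.
#' @param group_col Name of the group column, if any (`NULL` to auto-detect
#'   a column named `"group"`).
#' @param recode_1_5 If `TRUE`, subtract 1 from every response (for data
#'   coded 1..K instead of 0..K-1).
#' @param na Token representing missing values.
#' @param sep Field separator.
#' @param n_cat Categories per item, passed to [response_matrix()].
#' @return A `response_matrix`.
#' @export
read_responses <- function(path, group_col = NULL, recode_1_5 = FALSE,
                           na = "NA", sep = ",", n_cat = 5L) {
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("response file is empty", call. = FALSE)
  if (is.null(group_col) && "group" %in% names(df)) group_col <- "group"
  groups <- NULL
  if (!is.null(group_col)) {
    if (!group_col %in% names(df))
      stop(sprintf("no column named `%s` in %s", group_col, path), call. = FALSE)
    groups <- as.character(df[[group_col]])
    df[[group_col]] <- NULL
  }
  if ("id" %in% names(df)) df[["id"]] <- NULL
  nonnum <- !vapply(df, is.numeric, logical(1))
  if (any(nonnum)) {
    bad <- which(nonnum)
    for (j in bad) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (all(is.na(v) == is.na(df[[j]])))
        df[[j]] <- v
      else {
        rows <- which(!is.na(df[[j]]) & is.na(v))
        stop(sprintf("malformed values in column `%s` (rows %s)",
                     names(df)[j],
                     paste(utils::head(rows, 5L), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  m <- as.matrix(df)
  if (recode_1_5) m <- m - 1L
  response_matrix(m, groups = groups, n_cat = n_cat)
}

#' @rdname read_responses
#' @param data A `response_matrix` to write.
#' @export
write_responses <- function(data, path, sep = ",", na = "NA") {
  stopifnot(inherits(data, "response_matrix"))
  df <- as.data.frame(data$responses)
  if (!is.null(data$groups)) df$group <- data$groups
  utils::write.table(df, path, sep = sep, na = na, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## unique response patterns with counts; groups kept if present
collapse_patterns <- function(data) {
  m <- data$responses
  key <- do.call(paste, c(as.data.frame(m), sep = ","))
  if (!is.null(data$groups)) key <- paste(data$groups, key, sep = "|")
  ux <- !duplicated(key)
  cnt <- as.vector(table(factor(key, levels = key[ux])))
  list(patterns = m[ux, , drop = FALSE],
       groups = if (!is.null(data$groups)) data$groups[ux],
       counts = cnt,
       index = match(key, key[ux]))
}
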