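#' Behavioral ratings table
#'
#' Concept x dimension saliency ratings on a bounded scale (default 1-7),
#' used both to validate factor interpretations and as predictors in the
#' rating-based encoding model.
#'
#' @param values numeric matrix, concepts in rows (rownames required),
#'   rating dimensions in columns (colnames required).
#' @param scale_min,scale_max scale bounds.
#' @param rater_group free-form tag (e.g. "english", "mandarin", "averaged").
#' @return An object of class `ratings_table`.
#' @export
ratings_table <- function(values, scale_min = 1, scale_max = 7,
                          rater_group = "averaged") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("ratings need concept rownames and dimension colnames")
  if (any(values < scale_min | values > scale_max))
    stop("ratings outside [scale_min, scale_max]")
  structure(list(values = values, scale_min = scale_min,
                 scale_max = scale_max, rater_group = rater_group),
            class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("ratings_table (%s): %d concepts x %d dimensions on [%g, %g]\n",
              x$rater_group, nrow(x$values), ncol(x$values),
              x$scale_min, x$scale_max))
  invisible(x)
}

#' Average two rater groups' tables
#'
#' When both language groups rate the concepts and the group means agree,
#' the averaged ratings are used as the encoding-model input.
#'
#' @param a,b [ratings_table()] objects over the same concepts and dimensions.
#' @return A [ratings_table()] tagged "averaged".
#' @export
average_ratings <- function(a, b) {
  stopifnot(inherits(a, "ratings_table"), inherits(b, "ratings_table"))
  if (!setequal(rownames(a$values), rownames(b$values)) ||
      !setequal(colnames(a$values), colnames(b$values)))
    stop("ratings tables must share concepts and dimensions")
  bv <- b$values[rownames(a$values), colnames(a$values), drop = FALSE]
  ratings_table((a$values + bv) / 2,
                scale_min = min(a$scale_min, b$scale_min),
                scale_max = max(a$scale_max, b$scale_max),
                rater_group = "averaged")
}

#' Read / write a ratings table as CSV
#' @param path CSV path (first column concept labels, header = dimensions).
#' @param rater_group tag stored on the result.
#' @return [read_ratings()]: a [ratings_table()]; [write_ratings()]: `path`.
#' @export
read_ratings <- function(path, rater_group = "averaged") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  ratings_table(m, rater_group = rater_group)
}

#' @param rt a [ratings_table()].
#' @rdname read_ratings
#' @export
write_ratings <- function(rt, path) {
  df <- data.frame(concept = rownames(rt$values), rt$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
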