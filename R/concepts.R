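#' Concept set
#'
#' A `concept_set` holds the ordered stimulus labels, their semantic category,
#' and a per-concept word-length measure (characters for alphabetic scripts,
#' strokes for logographic ones). All downstream stages align data by concept
#' label, never by row position.
#'
#' @param labels character vector of unique concept identifiers.
#' @param categories named character vector mapping each concept to a category.
#' @param word_length optional named numeric vector of nonnegative lengths.
#' @return An object of class `concept_set`.
#' @seealso [default_concepts()] for the 28-concept stimulus set.
#' @export
concept_set <- function(labels, categories, word_length = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("concept labels must be unique")
  categories <- categories[labels]
  if (anyNA(categories))
    stop("every concept needs a category")
  if (!is.null(word_length)) {
    word_length <- word_length[labels]
    if (anyNA(word_length) || any(word_length < 0))
      stop("word_length must be nonnegative and cover all concepts")
  }
  structure(
    list(labels = labels, categories = categories, word_length = word_length),
    class = "concept_set"
  )
}

#' The default 28-concept abstract stimulus set
#'
#' Twenty-eight abstract concepts in seven categories (mathematics,
#' scientific, social, emotion, law, metaphysics, religiosity; four concepts
#' each), in canonical category-block order. Word length defaults to the
#' character count of the English label.
#'
#' @return A [concept_set()] with 28 concepts.
#' @export
default_concepts <- function() {
  cats <- c("mathematics", "scientific", "social", "emotion",
            "law", "metaphysics", "religiosity")
  concepts <- list(
    mathematics = c("subtraction", "equality", "probability", "multiplication"),
    scientific  = c("gravity", "force", "heat", "acceleration"),
    social      = c("gossip", "intimidation", "forgiveness", "compliment"),
    emotion     = c("happiness", "sadness", "anger", "pride"),
    law         = c("contract", "ethics", "crime", "exoneration"),
    metaphysics = c("causality", "consciousness", "truth", "necessity"),
    religiosity = c("deity", "spirituality", "sacrilege", "faith")
  )
  labels <- unlist(concepts[cats], use.names = FALSE)
  categories <- stats::setNames(rep(cats, each = 4L), labels)
  lengths <- stats::setNames(nchar(labels), labels)
  concept_set(labels, categories, lengths)
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("concept_set: %d concepts, %d categories\n",
              length(x$labels), length(unique(x$categories))))
  invisible(x)
}

#' Word-length measure across scripts
#'
#' Word length is script-specific (characters vs strokes), so cross-language
#' analyses use a relative measure: each language's lengths are z-scored and
#' the standardized values averaged per concept.
#'
#' @param concepts a [concept_set()] (modes `"single"`) whose `word_length` is
#'   used directly, or a list of two concept sets (mode `"combined"`).
#' @param mode `"single"` or `"combined"`.
#' @return Named numeric vector of per-concept lengths (raw for `"single"`,
#'   z-score average for `"combined"`).
#' @export
word_length_measure <- function(concepts, mode = c("single", "combined")) {
  mode <- match.arg(mode)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(stats::setNames(rep(0, length(v)), names(v)))
    (v - mean(v)) / s
  }
  if (mode == "single") {
    if (is.null(concepts$word_length))
      stop("concept set carries no word lengths")
    return(concepts$word_length)
  }
  if (!is.list(concepts) || length(concepts) != 2L)
    stop("mode 'combined' requires a list of two concept sets")
  a <- concepts[[1L]]; b <- concepts[[2L]]
  if (is.null(a$word_length) || is.null(b$word_length))
    stop("mode 'combined' requires word lengths in both concept sets")
  if (!identical(sort(a$labels), sort(b$labels)))
    stop("concept sets must cover the same labels")
  za <- zscore(a$word_length)
  zb <- zscore(b$word_length)[names(za)]
  (za + zb) / 2
}
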