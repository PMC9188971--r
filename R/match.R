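#' Match factors across two solutions
#'
#' Finds the one-to-one assignment between the factors of two solutions that
#' maximizes the total |correlation| of their factor scores (exact search
#' over assignments; factor counts here never exceed seven), flips signs so
#' matched correlations are positive, and reports the full cross-correlation
#' matrix. With unequal factor counts the extra factors are left unmatched
#' and flagged.
#'
#' @param solA,solB `fa_solution`s (or plain score matrices) over the same
#'   observations.
#' @return An object of class `factor_match`: `pairs` data frame
#'   (`factor_a`, `factor_b`, `r` after sign alignment, `abs_r`),
#'   `cross_correlation` (A x B, signed), `unmatched`.
#' @export
match_factors <- function(solA, solB) {
  sa <- if (inherits(solA, "fa_solution")) solA$factor_scores else as.matrix(solA)
  sb <- if (inherits(solB, "fa_solution")) solB$factor_scores else as.matrix(solB)
  if (nrow(sa) != nrow(sb))
    stop("solutions must share the observation set")
  if (is.null(colnames(sa))) colnames(sa) <- paste0("A", seq_len(ncol(sa)))
  if (is.null(colnames(sb))) colnames(sb) <- paste0("B", seq_len(ncol(sb)))
  if (!is.null(rownames(sa)) && !is.null(rownames(sb)))
    sb <- sb[rownames(sa), , drop = FALSE]
  C <- stats::cor(sa, sb)
  na <- ncol(sa); nb <- ncol(sb)
  if (max(na, nb) > 9L)
    stop("exact assignment search supports at most 9 factors")
  swap <- na > nb
  M <- if (swap) t(abs(C)) else abs(C)   # rows = smaller side
  best <- assignment_search(M)
  if (swap) {
    ia <- best; ib <- seq_along(best)
  } else {
    ia <- seq_along(best); ib <- best
  }
  r_signed <- C[cbind(ia, ib)]
  pairs <- data.frame(
    factor_a = colnames(sa)[ia], factor_b = colnames(sb)[ib],
    r = abs(r_signed), sign = sign(r_signed), abs_r = abs(r_signed),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(-pairs$abs_r), ]
  rownames(pairs) <- NULL
  unmatched <- if (na > nb) setdiff(colnames(sa), pairs$factor_a)
               else setdiff(colnames(sb), pairs$factor_b)
  structure(list(pairs = pairs, cross_correlation = C,
                 unmatched = unmatched),
            class = "factor_match")
}

# exact best assignment of each row of M (n_small x n_large) to a distinct
# column, maximizing the sum; returns column index per row
assignment_search <- function(M) {
  n <- nrow(M); m <- ncol(M)
  best_val <- -Inf
  best_asn <- integer(n)
  asn <- integer(n)
  used <- logical(m)
  # order rows by best available value to prune early
  recurse <- function(row, total) {
    if (row > n) {
      if (total > best_val) {
        best_val <<- total
        best_asn <<- asn[seq_len(n)]
      }
      return(invisible())
    }
    # upper bound: remaining rows at their max
    ub <- total + sum(apply(M[row:n, !used, drop = FALSE], 1L, max))
    if (ub <= best_val) return(invisible())
    for (j in order(-M[row, ])) {
      if (used[j]) next
      used[j] <<- TRUE
      asn[row] <<- j
      recurse(row + 1L, total + M[row, j])
      used[j] <<- FALSE
    }
  }
  recurse(1L, 0)
  best_asn
}

#' @export
print.factor_match <- function(x, ...) {
  cat(sprintf("factor_match: %d pair(s), mean matched |r| = %.3f\n",
              nrow(x$pairs), mean(x$pairs$abs_r)))
  for (i in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s ~ %s  |r| = %.3f\n", x$pairs$factor_a[i],
                x$pairs$factor_b[i], x$pairs$abs_r[i]))
  if (length(x$unmatched))
    cat("  unmatched:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}
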