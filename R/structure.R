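#' Parse a dot-bracket secondary structure
#'
#' Parses a pseudoknot-free RNA secondary structure written in dot-bracket
#' ("dot-parenthesis") notation, where `.` marks an unpaired base and a
#' matched `(`/`)` pair marks a base pair between the two positions.
#' Coordinates are 1-based and inclusive throughout the package.
#'
#' Validation enforces balanced parentheses and the folding-engine convention
#' that a hairpin loop spans at least 3 unpaired bases (a pair `i.j` requires
#' `j - i - 1 >= 3` when nothing is nested inside it).
#'
#' @param text A single dot-bracket string over `(`, `)` and `.`.
#' @return An object of class `rna_structure`: a list with elements
#'   `dotbracket` (the input string), `length` (number of positions) and
#'   `pairs` (integer vector `p` with `p[i] = j` if `i` pairs with `j`,
#'   `0` if unpaired; symmetric).
#' @examples
#' s <- rna_structure("((...))")
#' s$pairs
#' @export
rna_structure <- function(text) {
  if (inherits(text, "rna_structure")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty dot-bracket string", call. = FALSE)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (expected '(', ')' or '.')",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  n <- length(chars)
  pairs <- integer(n)
  stack <- integer(0)
  hairpin_bad <- NULL
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        stop(sprintf("unbalanced structure: unmatched ')' at position %d", i),
             call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j - 1L < 3L && is.null(hairpin_bad)) hairpin_bad <- c(j, i)
      pairs[j] <- i
      pairs[i] <- j
    }
  }
  ## balance errors take precedence over loop-size errors
  if (length(stack)) {
    stop(sprintf("unbalanced structure: unclosed '(' at position %d", stack[1]),
         call. = FALSE)
  }
  if (!is.null(hairpin_bad)) {
    stop(sprintf("hairpin closed by pair %d.%d has fewer than 3 unpaired bases",
                 hairpin_bad[1], hairpin_bad[2]), call. = FALSE)
  }
  structure(
    list(dotbracket = text, length = n, pairs = pairs),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> length", x$length, "with", sum(x$pairs > 0) / 2, "pairs\n")
  cat(x$dotbracket, "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) x$dotbracket

#' Base pairs of a structure as a two-column matrix
#'
#' @param s An [rna_structure] (or dot-bracket string).
#' @return Integer matrix with columns `i` and `j`, one row per pair, `i < j`,
#'   ordered by `i`.
#' @export
structure_pairs <- function(s) {
  s <- rna_structure(s)
  i <- which(s$pairs > seq_len(s$length))
  cbind(i = i, j = s$pairs[i])
}

#' Hamming distance between two equal-length dot-bracket strings
#'
#' The number of positions at which the two structure strings differ; this is
#' the fitness used by the evolutionary search.
#'
#' @param a,b [rna_structure] objects or dot-bracket strings of equal length.
#' @return A non-negative integer.
#' @examples
#' structure_hamming("((...))", "(.....)")
#' @export
structure_hamming <- function(a, b) {
  da <- if (inherits(a, "rna_structure")) a$dotbracket else a
  db <- if (inherits(b, "rna_structure")) b$dotbracket else b
  if (nchar(da) != nchar(db)) {
    stop(sprintf("structures have different lengths (%d vs %d)",
                 nchar(da), nchar(db)), call. = FALSE)
  }
  ca <- strsplit(da, "", fixed = TRUE)[[1]]
  cb <- strsplit(db, "", fixed = TRUE)[[1]]
  sum(ca != cb)
}
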