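#' Expected time per successful design
#'
#' `E_T = total execution time / SC`. When no run succeeded (`sc = 0`) the
#' quantity is undefined and reported as `Inf`, the benchmark-table
#' convention for "no result".
#'
#' @param total_time Total execution time in seconds.
#' @param sc Success count (non-negative integer).
#' @return Seconds per success, or `Inf` when `sc = 0`.
#' @export
expected_time <- function(total_time, sc) {
  stopifnot(total_time >= 0, sc >= 0)
  if (sc == 0) return(Inf)
  total_time / sc
}

#' Expected energy distance between designed and natural sequences
#'
#' `E_ED = mean |E_designed − E_natural|` over matched successes.
#'
#' @param designed,natural Numeric energy vectors of equal length (kcal/mol).
#' @return Mean absolute difference, or `Inf` when empty.
#' @export
expected_energy_distance <- function(designed, natural) {
  if (length(designed) != length(natural)) {
    stop("designed and natural energy vectors must be matched", call. = FALSE)
  }
  if (!length(designed)) return(Inf)
  mean(abs(designed - natural))
}

#' Needleman-Wunsch percent identity between two sequences
#'
#' Global (end-to-end) alignment under the EMBOSS-needle default scheme:
#' EDNAFULL-equivalent nucleotide scoring (match 5, mismatch −4), gap open
#' 10, gap extend 0.5. Identity is `matches / alignment length × 100`, the
#' denominator counting gap columns (needle's convention). With
#' `type = "similarity"` the numerator instead counts positively scoring
#' columns, which for a nucleotide matrix coincides with matches.
#'
#' @param a,b Non-empty sequences (RNA or DNA; `U` and `T` are equivalent).
#' @param type `"identity"` (default) or `"similarity"`.
#' @return Percent in `[0, 100]`.
#' @examples
#' seq_similarity("ACGU", "ACGU")
#' @export
seq_similarity <- function(a, b, type = c("identity", "similarity")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  da <- gsub("U", "T", toupper(a), fixed = TRUE)
  db <- gsub("U", "T", toupper(b), fixed = TRUE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(da, db, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 0.5)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  matches <- sum(pc == sc & pc != "-")
  100 * matches / length(pc)
}

#' Expected pairwise similarity within design groups
#'
#' For each target structure with at least two successfully designed
#' sequences, the mean Needleman-Wunsch identity over all `SC(SC−1)/2`
#' pairs; then the mean over structures. Lower values mean the method
#' explores a more diverse part of sequence space.
#'
#' @param groups List of character vectors, one vector of designed
#'   sequences per structure. Groups with fewer than 2 sequences are
#'   skipped.
#' @return Percent in `[0, 100]`.
#' @export
expected_similarity_within <- function(groups) {
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (!length(groups)) {
    stop("no group has at least two sequences", call. = FALSE)
  }
  per_group <- vapply(groups, function(g) {
    pairs <- utils::combn(length(g), 2)
    mean(apply(pairs, 2, function(ij) seq_similarity(g[ij[1]], g[ij[2]])))
  }, numeric(1))
  mean(per_group)
}

#' Expected similarity of designed sequences to their natural counterparts
#'
#' Mean Needleman-Wunsch identity of each designed sequence to the natural
#' sequence of the same structure.
#'
#' @param designed,natural Matched character vectors (length >= 1).
#' @return Percent in `[0, 100]`.
#' @export
expected_similarity_to_natural <- function(designed, natural) {
  if (length(designed) != length(natural) || !length(designed)) {
    stop("designed and natural must be matched, non-empty vectors", call. = FALSE)
  }
  mean(mapply(seq_similarity, designed, natural))
}

#' Nucleotide and base-pair distribution of sequences over structures
#'
#' Counts paired positions as unordered pair classes (AU, GC, GU; anything
#' non-canonical goes to an `other` bucket that is excluded from the
#' normalisation and reported via a warning), unpaired positions per base,
#' and the total composition per base.
#'
#' @param seqs Character vector of sequences.
#' @param structures Matched dot-bracket strings.
#' @return Tibble with columns `region` (`paired`/`unpaired`/`total`),
#'   `symbol`, `count`, `fraction`. Within each region with a positive
#'   denominator the fractions sum to 1.
#' @export
nucleotide_distribution <- function(seqs, structures) {
  if (length(seqs) != length(structures)) {
    stop("seqs and structures must be matched", call. = FALSE)
  }
  pair_counts <- c(AU = 0, GC = 0, GU = 0)
  other <- 0
  unpaired <- c(A = 0, C = 0, G = 0, U = 0)
  total <- c(A = 0, C = 0, G = 0, U = 0)
  for (k in seq_along(seqs)) {
    s <- rna_structure(structures[k])
    sq <- check_rna_seq(seqs[k])
    if (nchar(sq) != s$length) {
      stop(sprintf("sequence %d length does not match its structure", k),
           call. = FALSE)
    }
    chars <- strsplit(sq, "", fixed = TRUE)[[1]]
    tb <- table(factor(chars, levels = names(total)))
    total <- total + as.numeric(tb)
    unp <- chars[s$pairs == 0L]
    if (length(unp)) {
      tb <- table(factor(unp, levels = names(unpaired)))
      unpaired <- unpaired + as.numeric(tb)
    }
    pr <- structure_pairs(s)
    if (nrow(pr)) {
      cls <- paste0(pmin(chars[pr[, 1]], chars[pr[, 2]]),
                    pmax(chars[pr[, 1]], chars[pr[, 2]]))
      cls[cls == "AU"] <- "AU"; cls[cls == "CG"] <- "GC"; cls[cls == "GU"] <- "GU"
      known <- cls %in% c("AU", "GC", "GU")
      other <- other + sum(!known)
      tb <- table(factor(cls[known], levels = names(pair_counts)))
      pair_counts <- pair_counts + as.numeric(tb)
    }
  }
  if (other > 0) {
    warning(other, " non-canonical pair(s) excluded from the paired distribution")
  }
  frac <- function(x) if (sum(x) > 0) x / sum(x) else rep(NA_real_, length(x))
  dplyr::bind_rows(
    tibble::tibble(region = "paired", symbol = names(pair_counts),
                   count = unname(pair_counts),
                   fraction = unname(frac(pair_counts))),
    tibble::tibble(region = "unpaired", symbol = names(unpaired),
                   count = unname(unpaired), fraction = unname(frac(unpaired))),
    tibble::tibble(region = "total", symbol = names(total),
                   count = unname(total), fraction = unname(frac(total)))
  )
}
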