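#' Generate a synthetic RNA corpus with naturalistic base composition
#'
#' Produces random RNA sequences whose expected base composition matches the
#' totals observed in natural RNA (A 0.27, C 0.22, G 0.25, U 0.26). The
#' corpus stands in for a database of natural sequences when building
#' fragment pools; it reproduces natural mononucleotide composition but not
#' the dinucleotide correlations or conserved motifs of real RNA.
#'
#' @param n_sequences Number of sequences (>= 1).
#' @param length_range Integer interval `c(min, max)` of sequence lengths,
#'   drawn uniformly.
#' @return Named character vector of RNA sequences (`synth_0001`, ...).
#' @examples
#' set.seed(1); synthetic_corpus(3, c(20, 30))
#' @export
synthetic_corpus <- function(n_sequences, length_range = c(50, 150)) {
  if (!is.numeric(n_sequences) || n_sequences < 1) {
    stop("n_sequences must be >= 1", call. = FALSE)
  }
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[1] > length_range[2]) {
    stop("length_range must be an increasing positive interval", call. = FALSE)
  }
  lens <- sample(seq.int(length_range[1], length_range[2]), n_sequences,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(NATURAL_TOTAL), L, replace = TRUE, prob = NATURAL_TOTAL),
          collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("synth_%04d", seq_along(seqs)))
}

#' Generate a random valid secondary structure
#'
#' Stochastic recursive generator of pseudoknot-free structures with minimum
#' hairpin length 3. Used for property tests and for exercising the design
#' loop on arbitrary targets.
#'
#' @param n Structure length (>= 1).
#' @param p_helix Probability of opening a helix when there is room.
#' @param require_multiloop If `TRUE`, resample until the structure contains
#'   at least one multi-loop (requires `n >= 18` or so to terminate quickly).
#' @param max_tries Resampling cap for `require_multiloop`.
#' @return A dot-bracket string of length `n`.
#' @export
random_structure <- function(n, p_helix = 0.6, require_multiloop = FALSE,
                             max_tries = 1000L) {
  gen_span <- function(len) {
    out <- character(0)
    rem <- len
    while (rem > 0L) {
      if (rem >= 5L && stats::runif(1) < p_helix) {
        k <- sample.int(min(3L, (rem - 3L) %/% 2L), 1L)
        inner_max <- rem - 2L * k
        inner <- sample(seq.int(3L, inner_max), 1L)
        out <- c(out, strrep("(", k), gen_span(inner), strrep(")", k))
        rem <- rem - 2L * k - inner
      } else {
        out <- c(out, ".")
        rem <- rem - 1L
      }
    }
    paste(out, collapse = "")
  }
  for (try in seq_len(max_tries)) {
    db <- gen_span(n)
    s <- tryCatch(rna_structure(db), error = function(e) NULL)
    if (is.null(s)) next
    if (!require_multiloop) return(db)
    comps <- rna_components(s)
    if (any(comps$kind == "MULTI")) return(db)
  }
  stop("could not generate a structure satisfying the request in ",
       max_tries, " tries", call. = FALSE)
}

#' Generate a random stem-loop (single-arch) structure
#'
#' One outer helix, optionally interrupted by bulges or internal loops,
#' ending in a hairpin — the classic stem-loop shape. Helix segments
#' between imperfections always hold at least two stacked pairs, as in
#' natural stem-loops; isolated lonely pairs next to 1-nt bulges make
#' targets that often admit no exact minimum-free-energy design at all.
#'
#' @param n Total length (>= 9); the result has exactly this length.
#' @return A dot-bracket string.
#' @export
random_stem_loop <- function(n) {
  if (n < 9L) stop("stem-loop targets need n >= 9", call. = FALSE)
  hairpin <- sample(3:6, 1L)
  budget <- n - hairpin
  left <- character(0); right <- character(0)
  consec <- 0L   # stacked pairs since the last imperfection
  while (budget >= 2L) {
    ## an imperfection needs >= 2 stacked pairs on each side of it
    if (budget >= 6L && consec >= 2L && stats::runif(1) < 0.3) {
      l <- sample(0:2, 1L); r <- sample(0:2, 1L)
      if (l + r == 0L || l + r > budget - 4L) next
      left <- c(left, strrep(".", l)); right <- c(strrep(".", r), right)
      budget <- budget - l - r
      consec <- 0L
    } else {
      left <- c(left, "("); right <- c(")", right)
      budget <- budget - 2L
      consec <- consec + 1L
    }
  }
  pad <- strrep(".", budget)  # leftover single position dangles 5'
  db <- paste0(pad, paste(left, collapse = ""), strrep(".", hairpin),
               paste(right, collapse = ""))
  ## imperfections adjacent to the hairpin merge into it; re-validate
  tryCatch({
    rna_structure(db)
    db
  }, error = function(e) random_stem_loop(n))
}

#' Random sequence compatible with a structure's pairing
#'
#' Unpaired positions draw from the natural unpaired base distribution;
#' paired positions draw a pair class from the natural paired distribution
#' (AU 0.39, GC 0.49, GU 0.12, orientations equiprobable).
#'
#' @param s An [rna_structure] or dot-bracket string.
#' @return An RNA sequence string of the same length.
#' @export
random_compatible_sequence <- function(s) {
  s <- rna_structure(s)
  chars <- character(s$length)
  unp <- which(s$pairs == 0L)
  if (length(unp)) {
    chars[unp] <- sample(names(NATURAL_UNPAIRED), length(unp), replace = TRUE,
                         prob = NATURAL_UNPAIRED)
  }
  pr <- structure_pairs(s)
  if (nrow(pr)) {
    classes <- c("AU", "UA", "GC", "CG", "GU", "UG")
    w <- c(0.39, 0.39, 0.49, 0.49, 0.12, 0.12) / 2
    picks <- sample(classes, nrow(pr), replace = TRUE, prob = w)
    chars[pr[, 1]] <- substr(picks, 1, 1)
    chars[pr[, 2]] <- substr(picks, 2, 2)
  }
  paste(chars, collapse = "")
}
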