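#' Decompose a secondary structure into its structural components
#'
#' Any pseudoknot-free secondary structure decomposes uniquely into stems
#' (maximal helices of stacked pairs), hairpin loops, internal loops, bulge
#' loops, multi-loops and the external loop. Stems carry all paired
#' positions; each loop carries the unpaired positions it encloses, so the
#' components partition positions `1..n` exactly.
#'
#' Each component gets a *geometry key*, a string encoding its kind and
#' integer signature (stem: number of stacked pairs; hairpin: loop length;
#' bulge: strand length; internal loop: left and right lengths; multi-loop:
#' branch count plus the unpaired segment lengths 5'→3' after the closing
#' pair; external loop: the unpaired segment lengths). Fragments with the
#' same key are interchangeable when assembling sequences.
#'
#' @param s An [rna_structure] or dot-bracket string.
#' @param external `"single"` (default) keys all dangling exterior bases as
#'   one external-loop component; `"segments"` emits one component per
#'   contiguous exterior run.
#' @return A tibble with one row per component: `kind` (`STEM`, `HAIRPIN`,
#'   `INTERNAL`, `BULGE`, `MULTI`, `EXTERNAL`), `key` (geometry key),
#'   `positions` (list of integer vectors, one per strand/segment, 5'→3'),
#'   `closing` (list of two-column pair matrices bounding the component).
#' @examples
#' rna_components("((...))")
#' @export
rna_components <- function(s, external = c("single", "segments")) {
  s <- rna_structure(s)
  external <- match.arg(external)
  p <- s$pairs
  n <- s$length
  rows <- list()

  ## stems: maximal runs of stacked pairs
  i <- 1L
  while (i <= n) {
    j <- p[i]
    if (j > i) {
      start <- i
      k <- 1L
      while (i + k <= n && p[i + k] == j - k && j - k > i + k) k <- k + 1L
      rows[[length(rows) + 1L]] <- list(
        kind = "STEM",
        key = paste0("STEM/", k),
        positions = list(seq.int(start, start + k - 1L),
                         seq.int(j - k + 1L, j)),
        closing = list(cbind(i = start, j = j))
      )
      i <- i + k
    } else {
      i <- i + 1L
    }
  }

  ## loops: every pair whose interior is not a stem continuation closes one
  pair_starts <- which(p > seq_len(n))
  for (a in pair_starts) {
    b <- p[a]
    if (a + 1L < b && p[a + 1L] == b - 1L) next  # stacked: interior is stem
    branches <- NULL
    segs <- list()
    seg_start <- a + 1L
    pos <- a + 1L
    while (pos < b) {
      if (p[pos] > pos) {
        segs[[length(segs) + 1L]] <- if (pos > seg_start) seq.int(seg_start, pos - 1L) else integer(0)
        branches <- rbind(branches, c(pos, p[pos]))
        pos <- p[pos] + 1L
        seg_start <- pos
      } else {
        pos <- pos + 1L
      }
    }
    segs[[length(segs) + 1L]] <- if (b > seg_start) seq.int(seg_start, b - 1L) else integer(0)
    nb <- if (is.null(branches)) 0L else nrow(branches)
    if (nb == 0L) {
      rows[[length(rows) + 1L]] <- list(
        kind = "HAIRPIN",
        key = paste0("HAIRPIN/", b - a - 1L),
        positions = segs[1],
        closing = list(cbind(i = a, j = b))
      )
    } else if (nb == 1L) {
      left <- length(segs[[1]])
      right <- length(segs[[2]])
      cl <- list(cbind(i = c(a, branches[1, 1]), j = c(b, branches[1, 2])))
      if (left == 0L || right == 0L) {
        strand <- if (left > 0L) segs[1] else segs[2]
        rows[[length(rows) + 1L]] <- list(
          kind = "BULGE",
          key = paste0("BULGE/", left + right),
          positions = strand,
          closing = cl
        )
      } else {
        rows[[length(rows) + 1L]] <- list(
          kind = "INTERNAL",
          key = paste0("INTERNAL/", left, ",", right),
          positions = segs,
          closing = cl
        )
      }
    } else {
      lens <- vapply(segs, length, integer(1))
      rows[[length(rows) + 1L]] <- list(
        kind = "MULTI",
        key = paste0("MULTI/", nb, ":", paste(lens, collapse = ",")),
        positions = segs,
        closing = list(cbind(i = c(a, branches[, 1]), j = c(b, branches[, 2])))
      )
    }
  }

  ## external loop: exterior unpaired runs
  ch <- strsplit(s$dotbracket, "", fixed = TRUE)[[1]]
  depth <- cumsum((ch == "(") - (ch == ")"))
  exterior <- which(p == 0L & depth == 0L)
  if (length(exterior)) {
    runs <- split(exterior, cumsum(c(1L, diff(exterior) != 1L)))
    runs <- unname(runs)
    if (external == "single") {
      lens <- vapply(runs, length, integer(1))
      rows[[length(rows) + 1L]] <- list(
        kind = "EXTERNAL",
        key = paste0("EXTERNAL/", paste(lens, collapse = ",")),
        positions = runs,
        closing = list(NULL)
      )
    } else {
      for (r in runs) {
        rows[[length(rows) + 1L]] <- list(
          kind = "EXTERNAL",
          key = paste0("EXTERNAL/", length(r)),
          positions = list(r),
          closing = list(NULL)
        )
      }
    }
  }

  tibble::tibble(
    kind = vapply(rows, `[[`, character(1), "kind"),
    key = vapply(rows, `[[`, character(1), "key"),
    positions = lapply(rows, `[[`, "positions"),
    closing = lapply(rows, function(r) r$closing[[1]])
  )
}

#' Extract a component's sub-sequence strands from a full sequence
#'
#' @param seq Character scalar RNA sequence.
#' @param positions List of integer position vectors (as in the `positions`
#'   column of [rna_components()]).
#' @return Character vector, one strand per segment (may contain empty
#'   strings for zero-length multi-loop segments).
#' @export
component_strands <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  vapply(positions, function(ps) paste(chars[ps], collapse = ""), character(1))
}

#' Write fragment strands into a sequence at a component's positions
#'
#' @param seq Character scalar RNA sequence.
#' @param positions List of integer position vectors.
#' @param strands Character vector of replacement strands matching
#'   `positions` lengths.
#' @return The modified sequence.
#' @export
place_strands <- function(seq, positions, strands) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (k in seq_along(positions)) {
    ps <- positions[[k]]
    if (length(ps) != nchar(strands[k])) {
      stop("strand length does not match component geometry", call. = FALSE)
    }
    if (length(ps)) chars[ps] <- strsplit(strands[k], "", fixed = TRUE)[[1]]
  }
  paste(chars, collapse = "")
}
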