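#' Tag and breaking base pairs of a structure's multi-loops
#'
#' Closing pairs of a multi-loop are ordered by their 5' index
#' (`i_a.j_a < i_b.j_b` iff `i_a < i_b`). For each multi-loop the
#' order-minimum closing pair is the *tag base pair*; the stem containing it
#' is the *tag stem*; and the order-minimum pair of the tag stem is the
#' *breaking base pair*, the point at which the structure is split during
#' hierarchical decomposition.
#'
#' @param s An [rna_structure] or dot-bracket string.
#' @return Tibble with one row per multi-loop: `tag_i`, `tag_j` (tag pair),
#'   `break_i`, `break_j` (breaking pair). Zero rows when the structure has
#'   no multi-loop.
#' @export
find_breaking_pairs <- function(s) {
  s <- rna_structure(s)
  comps <- rna_components(s)
  multis <- comps[comps$kind == "MULTI", ]
  if (!nrow(multis)) {
    return(tibble::tibble(tag_i = integer(0), tag_j = integer(0),
                          break_i = integer(0), break_j = integer(0)))
  }
  stems <- comps[comps$kind == "STEM", ]
  out <- purrr::map_dfr(multis$closing, function(cl) {
    tag <- cl[which.min(cl[, "i"]), , drop = TRUE]
    ## tag stem: the stem whose pairs include the tag pair
    owner <- which(vapply(seq_len(nrow(stems)), function(r) {
      p5 <- stems$positions[[r]][[1]]
      p3 <- stems$positions[[r]][[2]]
      any(p5 == tag["i"]) && any(rev(p3) == tag["j"])
    }, logical(1)))[1]
    p5 <- stems$positions[[owner]][[1]]
    p3 <- stems$positions[[owner]][[2]]
    ## order-minimum pair of the tag stem = smallest 5' index = outermost pair
    tibble::tibble(tag_i = unname(tag[["i"]]), tag_j = unname(tag[["j"]]),
                   break_i = unname(p5[1]), break_j = unname(p3[length(p3)]))
  })
  dplyr::arrange(out, .data$break_i)
}

#' Hierarchically decompose a target structure (and compatible sequence)
#'
#' Recursively splits the structure at breaking base pairs (see
#' [find_breaking_pairs()]). A split at pair `i.j` produces one child for
#' the enclosed region `i..j` (a closed sub-structure that keeps the
#' breaking pair) and one for the remainder `1..i-1, j+1..n`; removing the
#' whole arch keeps the remainder balanced and valid, and the two children
#' partition the parent's positions exactly. When
#' several multi-loops offer breaking pairs at one level, the pair whose
#' split yields the most balanced part lengths is chosen (ties: lowest 5'
#' index). Recursion stops when a part has no multi-loop or is shorter than
#' `min_split`.
#'
#' @param s Target [rna_structure] or dot-bracket string.
#' @param seq Optional compatible sequence, sliced at the same positions.
#' @param min_split Minimum part length worth splitting further (default 40
#'   nt; splitting exists to tame the cubic cost of folding, so tiny parts
#'   gain nothing).
#' @return An `erd_hierarchy` node: list with `dotbracket`, `seq` (or NULL),
#'   `positions` (original coordinates of this node's characters),
#'   `breaking_pair` (the pair at which its children were split, or NULL)
#'   and `children` (list, empty for leaves).
#' @export
decompose_hierarchy <- function(s, seq = NULL, min_split = 40L) {
  s <- rna_structure(s)
  if (!is.null(seq) && nchar(seq) != s$length) {
    stop("sequence length does not match structure", call. = FALSE)
  }
  node <- build_node(s$dotbracket, seq, seq_len(s$length), min_split)
  class(node) <- "erd_hierarchy"
  node
}

build_node <- function(db, seq, positions, min_split) {
  n <- nchar(db)
  node <- list(dotbracket = db, seq = seq, positions = positions,
               breaking_pair = NULL, children = list())
  if (n < min_split) return(node)
  bp <- find_breaking_pairs(db)
  if (!nrow(bp)) return(node)
  ## candidate breaking pairs, most balanced split first; a pair enclosing
  ## the whole structure leaves no remainder and is not usable
  inner_len <- bp$break_j - bp$break_i + 1L
  imbalance <- abs(inner_len - (n - inner_len))
  usable <- !(bp$break_i == 1L & bp$break_j == n)
  if (!any(usable)) return(node)
  bp <- bp[usable, ][order(imbalance[usable], bp$break_i[usable]), ]

  slice <- function(idx) {
    list(db = paste(strsplit(db, "", fixed = TRUE)[[1]][idx], collapse = ""),
         sq = if (is.null(seq)) NULL else
           paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = ""),
         pos = positions[idx])
  }
  for (r in seq_len(nrow(bp))) {
    i <- bp$break_i[r]; j <- bp$break_j[r]
    idx_in <- seq.int(i, j)
    idx_out <- c(seq_len(i - 1L), if (j < n) seq.int(j + 1L, n))
    a <- slice(idx_in); b <- slice(idx_out)
    ## removing the arch can leave the remainder with an under-sized loop
    ## (e.g. a pair that enclosed little besides the arch); such a remainder
    ## is not an independently foldable structure, so skip this candidate
    remainder_ok <- !inherits(tryCatch(rna_structure(b$db),
                                       error = function(e) e), "error")
    if (!remainder_ok) next
    node$breaking_pair <- c(i = positions[i], j = positions[j])
    node$children <- list(
      build_node(a$db, a$sq, a$pos, min_split),
      build_node(b$db, b$sq, b$pos, min_split)
    )
    return(node)
  }
  node
}

#' @export
print.erd_hierarchy <- function(x, ...) {
  show <- function(node, indent) {
    cat(strrep("  ", indent), node$dotbracket,
        if (!is.null(node$breaking_pair))
          sprintf("  [split at %d.%d]", node$breaking_pair["i"],
                  node$breaking_pair["j"]) else "", "\n", sep = "")
    for (ch in node$children) show(ch, indent + 1)
  }
  show(x, 0)
  invisible(x)
}

#' Leaves of a decomposition hierarchy
#'
#' @param node An `erd_hierarchy` node.
#' @return List of leaf nodes in 5' order of their first position.
#' @export
hierarchy_leaves <- function(node) {
  if (!length(node$children)) return(list(node))
  leaves <- do.call(c, lapply(node$children, hierarchy_leaves))
  leaves[order(vapply(leaves, function(l) l$positions[1], integer(1)))]
}

#' Reassemble a hierarchy's leaves into the full structure and sequence
#'
#' Leaves partition the original positions, so characters are simply written
#' back at their original coordinates.
#'
#' @param node An `erd_hierarchy` node.
#' @param leaf_seqs Optional character vector of per-leaf sequences (in
#'   [hierarchy_leaves()] order) overriding the sequences stored in the tree.
#' @return List with `dotbracket` and `seq` (NULL if no sequences present).
#' @export
flatten_hierarchy <- function(node, leaf_seqs = NULL) {
  n <- length(node$positions)
  db <- character(n)
  sq <- character(n)
  leaves <- hierarchy_leaves(node)
  if (!is.null(leaf_seqs) && length(leaf_seqs) != length(leaves)) {
    stop("leaf_seqs must have one sequence per leaf", call. = FALSE)
  }
  for (k in seq_along(leaves)) {
    l <- leaves[[k]]
    db[l$positions] <- strsplit(l$dotbracket, "", fixed = TRUE)[[1]]
    if (!is.null(leaf_seqs)) {
      sq[l$positions] <- strsplit(leaf_seqs[k], "", fixed = TRUE)[[1]]
    } else if (!is.null(l$seq)) {
      sq[l$positions] <- strsplit(l$seq, "", fixed = TRUE)[[1]]
    }
  }
  list(dotbracket = paste(db, collapse = ""),
       seq = if (any(nzchar(sq))) paste(sq, collapse = "") else NULL)
}
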