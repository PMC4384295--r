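## Independent brute-force oracles. These deliberately re-derive quantities
## from first principles with different algorithms than the package uses.

## all nested pairings of 1..n with minimum hairpin length 3, as a list of
## two-column matrices (enumeration, not DP)
oracle_all_pairings <- function(n) {
  rec <- function(lo, hi) {
    if (hi - lo < 4L) return(list(matrix(integer(0), ncol = 2)))
    out <- list()
    ## lo unpaired
    for (rest in rec(lo + 1L, hi)) out[[length(out) + 1L]] <- rest
    ## lo paired with k
    for (k in seq.int(lo + 4L, hi)) {
      inner <- rec(lo + 1L, k - 1L)
      outer <- rec(k + 1L, hi)
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- rbind(c(lo, k), a, b)
      }
    }
    out
  }
  if (n < 5L) return(list(matrix(integer(0), ncol = 2)))
  rec(1L, n)
}

ORACLE_PAIRS_CACHE <- new.env()

## maximum number of complementary pairs over all explicit pairings
oracle_max_pairs <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  key <- as.character(n)
  if (is.null(ORACLE_PAIRS_CACHE[[key]])) {
    ORACLE_PAIRS_CACHE[[key]] <- oracle_all_pairings(n)
  }
  comp <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE, GU = TRUE, UG = TRUE)
  best <- 0L
  for (pm in ORACLE_PAIRS_CACHE[[key]]) {
    if (!nrow(pm)) next
    keys <- paste0(chars[pm[, 1]], chars[pm[, 2]])
    if (all(keys %in% names(comp))) best <- max(best, nrow(pm))
  }
  best
}

## literal application of the tag/breaking base pair definitions using an
## independent parser and multi-loop scan
oracle_breaking_pairs <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(chars)
  p <- integer(n); stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") { j <- stack[length(stack)]
      stack <- stack[-length(stack)]; p[j] <- i; p[i] <- j }
  }
  res <- NULL
  for (a in which(p > seq_len(n))) {
    b <- p[a]
    ## direct branches inside (a, b)
    branches <- NULL
    pos <- a + 1L
    while (pos < b) {
      if (p[pos] > pos) { branches <- rbind(branches, c(pos, p[pos]))
        pos <- p[pos] + 1L } else pos <- pos + 1L
    }
    if (is.null(branches) || nrow(branches) < 2L) next
    closing <- rbind(c(a, b), branches)
    tag <- closing[which.min(closing[, 1]), ]
    ## stem containing the tag pair: walk stacked pairs outward and inward
    lo <- tag[1]; hi <- tag[2]
    while (lo - 1L >= 1L && p[lo - 1L] == hi + 1L) { lo <- lo - 1L; hi <- hi + 1L }
    stem <- cbind(lo, hi)
    while (p[stem[nrow(stem), 1] + 1L] == stem[nrow(stem), 2] - 1L &&
           stem[nrow(stem), 1] + 1L < stem[nrow(stem), 2] - 1L) {
      stem <- rbind(stem, c(stem[nrow(stem), 1] + 1L, stem[nrow(stem), 2] - 1L))
    }
    brk <- stem[which.min(stem[, 1]), ]
    res <- rbind(res, c(tag, brk))
  }
  if (is.null(res)) {
    return(data.frame(tag_i = integer(0), tag_j = integer(0),
                      break_i = integer(0), break_j = integer(0)))
  }
  res <- res[order(res[, 3]), , drop = FALSE]
  data.frame(tag_i = res[, 1], tag_j = res[, 2],
             break_i = res[, 3], break_j = res[, 4])
}

## independent affine-gap global alignment (three-state memoised recursion);
## returns the optimal score and the set of percent identities achievable by
## optimal alignments (gap cost: open + L * extend, as in the package)
oracle_nw <- function(a, b, match = 5, mismatch = -4, open = 10, extend = 0.5) {
  x <- strsplit(toupper(gsub("U", "T", a, fixed = TRUE)), "")[[1]]
  y <- strsplit(toupper(gsub("U", "T", b, fixed = TRUE)), "")[[1]]
  n <- length(x); m <- length(y)
  sub <- function(i, j) if (x[i] == y[j]) match else mismatch
  NEG <- -1e9
  ## state 1 = match/mismatch, 2 = gap in y (x consumed), 3 = gap in x
  M <- array(NA_real_, c(n + 1, m + 1, 3))
  M[1, 1, ] <- c(0, NEG, NEG)
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    M[i + 1, j + 1, 1] <- if (i > 0 && j > 0)
      max(M[i, j, ]) + sub(i, j) else NEG
    M[i + 1, j + 1, 2] <- if (i > 0)
      max(M[i, j + 1, 1] - open - extend, M[i, j + 1, 2] - extend,
          M[i, j + 1, 3] - open - extend) else NEG
    M[i + 1, j + 1, 3] <- if (j > 0)
      max(M[i + 1, j, 1] - open - extend, M[i + 1, j, 3] - extend,
          M[i + 1, j, 2] - open - extend) else NEG
  }
  best <- max(M[n + 1, m + 1, ])
  ## enumerate all optimal alignments, collecting identities
  idents <- new.env(); idents$v <- numeric(0)
  eps <- 1e-9
  walk <- function(i, j, st, matches, len) {
    sc <- M[i + 1, j + 1, st]
    if (i == 0 && j == 0) {
      if (st == 1 || len == 0) idents$v <- c(idents$v, 100 * matches / max(len, 1))
      return(invisible())
    }
    if (st == 1 && i > 0 && j > 0) {
      s <- sub(i, j)
      for (pst in 1:3) if (abs(M[i, j, pst] + s - sc) < eps) {
        walk(i - 1, j - 1, pst, matches + (x[i] == y[j]), len + 1)
      }
    } else if (st == 2 && i > 0) {
      if (abs(M[i, j + 1, 1] - open - extend - sc) < eps) walk(i - 1, j, 1, matches, len + 1)
      if (abs(M[i, j + 1, 2] - extend - sc) < eps) walk(i - 1, j, 2, matches, len + 1)
      if (abs(M[i, j + 1, 3] - open - extend - sc) < eps) walk(i - 1, j, 3, matches, len + 1)
    } else if (st == 3 && j > 0) {
      if (abs(M[i + 1, j, 1] - open - extend - sc) < eps) walk(i, j - 1, 1, matches, len + 1)
      if (abs(M[i + 1, j, 3] - extend - sc) < eps) walk(i, j - 1, 3, matches, len + 1)
      if (abs(M[i + 1, j, 2] - open - extend - sc) < eps) walk(i, j - 1, 2, matches, len + 1)
    }
  }
  for (st in 1:3) if (abs(M[n + 1, m + 1, st] - best) < eps) walk(n, m, st, 0, 0)
  list(score = best, identities = sort(unique(round(idents$v, 9))))
}

## random IUPAC mask fixing a fraction of positions to the bases of a
## compatible sequence (mirrors fixed-position constraint benchmarks)
make_fixed_mask <- function(seq, fraction) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  fix <- sample.int(n, max(1L, round(fraction * n)))
  mask <- rep("N", n)
  mask[fix] <- chars[fix]
  paste(mask, collapse = "")
}

## tiny deterministic pools for unit tests
tiny_pools <- function(keys, strands) {
  pool <- tibble::tibble(key = keys, strands = strands)
  attr(pool, "source") <- "synthetic"
  class(pool) <- c("erd_pools", class(pool))
  pool
}

## scripted engine: prescribed energies and folds keyed by sequence, for
## testing selection logic in isolation
scripted_engine <- function(energies, folds) {
  structure(list(
    name = "scripted", version = "test",
    fold_many = function(seqs) tibble::tibble(
      seq = seqs, structure = unname(folds[seqs]),
      energy = unname(energies[seqs])),
    energy_many = function(seqs, structures) unname(energies[seqs])
  ), class = "fold_engine")
}
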