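#' Folding engines
#'
#' The design loop only needs two operations from a thermodynamic engine:
#' predicting the minimum-free-energy (MFE) structure of a sequence, and
#' evaluating the free energy of a sequence over a fixed structure. Two
#' engines implement this contract:
#'
#' * [vienna_engine()] — adapter over the ViennaRNA command-line tools
#'   (`RNAfold` / `RNAeval`), i.e. the nearest-neighbour Turner energy model.
#'   Calls are batched over stdin, so folding a whole population costs one
#'   process.
#' * [toy_engine()] — a deterministic maximum-base-pairing (Nussinov-style)
#'   folder scoring −1 per canonical pair with minimum hairpin length 3,
#'   ties broken toward 5'-most pairing. It needs no external software and
#'   keeps unit tests hermetic; its "energies" are pair counts, not kcal/mol.
#'
#' @param temperature Folding temperature in degrees Celsius (Vienna engine).
#' @return An object of class `fold_engine` with elements `name`, `version`,
#'   `fold_many(seqs)` and `energy_many(seqs, structures)`.
#' @name fold_engines
NULL

new_fold_engine <- function(name, version, fold_many, energy_many) {
  structure(list(name = name, version = version,
                 fold_many = fold_many, energy_many = energy_many),
            class = "fold_engine")
}

#' @export
print.fold_engine <- function(x, ...) {
  cat(sprintf("<fold_engine> %s (%s)\n", x$name, x$version))
  invisible(x)
}

check_rna_seq <- function(seqs) {
  seqs <- gsub("T", "U", toupper(seqs), fixed = TRUE)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/U: ", seqs[bad][1],
         call. = FALSE)
  }
  seqs
}

#' @rdname fold_engines
#' @export
vienna_engine <- function(temperature = 37) {
  ver <- tryCatch(
    sub("^RNAfold\\s+", "", system2("RNAfold", "--version", stdout = TRUE)[1]),
    error = function(e) stop("RNAfold not found on the PATH", call. = FALSE),
    warning = function(w) "unknown"
  )
  targs <- if (!identical(temperature, 37)) c("-T", as.character(temperature)) else character(0)

  parse_out <- function(out, k) {
    ## output alternates: sequence line, then "structure ( energy)"
    res <- out[seq.int(2L, by = 2L, length.out = k)]
    m <- regmatches(res, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", res))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) stop("unparseable engine output: ", res[bad][1], call. = FALSE)
    tibble::tibble(
      structure = vapply(m, `[`, character(1), 2),
      energy = as.numeric(vapply(m, `[`, character(1), 3))
    )
  }

  fold_many <- function(seqs) {
    seqs <- check_rna_seq(seqs)
    out <- system2("RNAfold", c("--noPS", targs),
                   input = seqs, stdout = TRUE, stderr = FALSE)
    dplyr::mutate(parse_out(out, length(seqs)), seq = seqs, .before = 1)
  }

  energy_many <- function(seqs, structures) {
    seqs <- check_rna_seq(seqs)
    structures <- vapply(structures, function(s) rna_structure(s)$dotbracket,
                         character(1), USE.NAMES = FALSE)
    if (length(structures) == 1L) structures <- rep(structures, length(seqs))
    stopifnot(length(seqs) == length(structures),
              all(nchar(seqs) == nchar(structures)))
    out <- system2("RNAeval", targs,
                   input = as.vector(rbind(seqs, structures)),
                   stdout = TRUE, stderr = FALSE)
    parse_out(out, length(seqs))$energy
  }

  new_fold_engine("vienna", ver, fold_many, energy_many)
}

#' @rdname fold_engines
#' @export
toy_engine <- function() {
  fold_many <- function(seqs) {
    seqs <- check_rna_seq(seqs)
    res <- lapply(seqs, nussinov_fold)
    tibble::tibble(
      seq = seqs,
      structure = vapply(res, `[[`, character(1), "structure"),
      energy = vapply(res, `[[`, numeric(1), "energy")
    )
  }
  energy_many <- function(seqs, structures) {
    seqs <- check_rna_seq(seqs)
    structures <- vapply(structures, function(s) rna_structure(s)$dotbracket,
                         character(1), USE.NAMES = FALSE)
    if (length(structures) == 1L) structures <- rep(structures, length(seqs))
    stopifnot(length(seqs) == length(structures))
    mapply(function(sq, st) {
      pr <- structure_pairs(st)
      if (!nrow(pr)) return(0)
      chars <- strsplit(sq, "", fixed = TRUE)[[1]]
      -sum(bases_complementary(chars[pr[, 1]], chars[pr[, 2]]))
    }, seqs, structures, USE.NAMES = FALSE)
  }
  new_fold_engine("toy-maxpair", "1.0", fold_many, energy_many)
}

## Nussinov-style maximum pairing with minimum hairpin 3; score -1 per pair.
## Traceback prefers pairing the 5'-most position, with the smallest partner,
## so results are deterministic.
nussinov_fold <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 5L) {
    return(list(structure = strrep(".", n), energy = 0))
  }
  can <- function(i, j) bases_complementary(chars[i], chars[j])
  M <- matrix(0L, n, n)
  for (span in 4L:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]                       # i unpaired
      ks <- seq.int(i + 4L, j)
      for (k in ks) {
        if (can(i, k)) {
          v <- 1L + (if (k - i >= 5L) M[i + 1L, k - 1L] else 0L) +
            (if (k < j) M[k + 1L, j] else 0L)
          if (v > best) best <- v
        }
      }
      M[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i < 4L) return(invisible())
      target <- M[i, j]
      paired <- FALSE
      for (k in seq.int(i + 4L, j)) {
        if (can(i, k)) {
          v <- 1L + (if (k - i >= 5L) M[i + 1L, k - 1L] else 0L) +
            (if (k < j) M[k + 1L, j] else 0L)
          if (v == target) {
            db[i] <<- "("; db[k] <<- ")"
            if (k - i >= 5L) trace(i + 1L, k - 1L)
            i <- k + 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  trace(1L, n)
  structure_str <- paste(db, collapse = "")
  list(structure = structure_str, energy = -sum(db == "("))
}

#' Fold sequences to their MFE structures
#'
#' @param seqs Character vector of RNA sequences.
#' @param engine A `fold_engine` (default [vienna_engine()]).
#' @return Tibble with columns `seq`, `structure` (dot-bracket), `energy`.
#' @export
fold_rna <- function(seqs, engine = vienna_engine()) {
  stopifnot(inherits(engine, "fold_engine"), length(seqs) >= 1L)
  engine$fold_many(seqs)
}

#' Free energy of sequences evaluated over fixed structures
#'
#' @param seqs Character vector of RNA sequences.
#' @param structures Dot-bracket string(s); a single structure is recycled.
#' @param engine A `fold_engine`.
#' @return Numeric vector of energies (kcal/mol for the Vienna engine).
#' @export
energy_of <- function(seqs, structures, engine = vienna_engine()) {
  stopifnot(inherits(engine, "fold_engine"))
  engine$energy_many(seqs, structures)
}
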