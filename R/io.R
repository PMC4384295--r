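#' Read a design input file (dot-bracket structure plus optional mask)
#'
#' The file holds the target structure on the first non-comment line and an
#' optional IUPAC constraint mask of the same length on the second. Lines
#' starting with `#` or `>` are ignored.
#'
#' @param path Input file path.
#' @return List with `structure` ([rna_structure]) and `mask` (string or
#'   `NULL`).
#' @export
read_structure_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, ">")]
  if (!length(lines)) stop("no structure line found in ", path, call. = FALSE)
  s <- rna_structure(lines[1])
  mask <- NULL
  if (length(lines) >= 2L) {
    mask <- gsub("T", "U", toupper(lines[2]), fixed = TRUE)
    if (nchar(mask) != s$length) {
      stop(sprintf("mask length %d does not match structure length %d (line 2 of %s)",
                   nchar(mask), s$length, path), call. = FALSE)
    }
  }
  list(structure = s, mask = mask)
}

#' Read an RNA sequence corpus from a FASTA file
#'
#' Sequences are uppercased and `T` is normalised to `U`.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences.
#' @export
read_fasta_corpus <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  had_t <- any(grepl("T", seqs, fixed = TRUE))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  if (had_t) message("corpus contained T characters; normalised to U")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param header Optional character vector of `;`-style comment lines
#'   written before the records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste(";", header), con)
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq_%03d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), unname(seqs))), con)
  invisible(path)
}

#' Write a sequence/structure pair in CT (connectivity table) format
#'
#' Standard 6-column CT: position, base, previous index (0 at the 5' end),
#' next index (0 at the 3' end), pairing partner (0 if unpaired), position.
#'
#' @param seq RNA sequence.
#' @param s Matching [rna_structure] or dot-bracket string.
#' @param path Output path.
#' @param title Title placed on the header line after the length.
#' @return `path`, invisibly.
#' @export
write_ct <- function(seq, s, path, title = "erd design") {
  s <- rna_structure(s)
  if (nchar(seq) != s$length) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- s$length
  lines <- c(
    paste(n, title),
    sprintf("%d %s %d %d %d %d", seq_len(n), chars, seq_len(n) - 1L,
            ifelse(seq_len(n) == n, 0L, seq_len(n) + 1L), s$pairs, seq_len(n))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a CT file back into a sequence and structure
#'
#' @param path CT file written by [write_ct()] (or any standard 6-column CT
#'   of a pseudoknot-free structure).
#' @return List with `seq` and `structure` ([rna_structure]).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- lines[2:(n + 1L)]
  f <- strsplit(trimws(body), "\\s+")
  base <- vapply(f, `[`, character(1), 2)
  partner <- as.integer(vapply(f, `[`, character(1), 5))
  db <- rep(".", n)
  db[partner > seq_len(n)] <- "("
  db[partner > 0L & partner < seq_len(n)] <- ")"
  list(seq = paste(base, collapse = ""),
       structure = rna_structure(paste(db, collapse = "")))
}

#' Run a batch of designs and write the results
#'
#' Runs [design()] `n` times with per-run seeds derived from `seed`, and
#' writes the designed sequences with their distances, energies, iteration
#' counts and per-run seeds. Every output starts with a provenance header
#' carrying the package version, engine, seed and full configuration, so a
#' rerun with the same configuration reproduces the files byte for byte.
#'
#' @param target Target structure (dot-bracket string or [rna_structure]).
#' @param out Output file path.
#' @param n Number of designs.
#' @param cs [erd_constraints] or `NULL`.
#' @param pools `erd_pools` or `NULL`.
#' @param engine A `fold_engine`.
#' @param seed Base seed (integer).
#' @param format `"fasta"`, `"ct"` (one file per design, suffixed) or
#'   `"tsv"`.
#' @param max_iter,hierarchical Passed to [design()].
#' @return Tibble of per-run results (also written to `out`), invisibly
#'   carrying attribute `n_success`.
#' @export
run_design <- function(target, out, n = 10L, cs = NULL, pools = NULL,
                       engine = vienna_engine(), seed = 1L,
                       format = c("fasta", "ct", "tsv"),
                       max_iter = 250L, hierarchical = TRUE) {
  format <- match.arg(format)
  target <- rna_structure(target)
  runs <- purrr::map_dfr(seq_len(n), function(k) {
    d <- design(target, cs = cs, pools = pools, engine = engine,
                max_iter = max_iter, seed = seed + k - 1L,
                hierarchical = hierarchical)
    tibble::tibble(id = sprintf("design_%03d", k), seq = d$seq,
                   distance = d$distance, energy = d$energy_on_target,
                   iterations = d$iterations_used, seed = seed + k - 1L,
                   success = d$success)
  })
  header <- c(
    paste("erd", as.character(utils::packageVersion("erd"))),
    paste("engine:", engine$name, engine$version),
    paste("target:", target$dotbracket),
    paste("mask:", if (is.null(cs) || is.null(cs$mask)) "(none)" else cs$mask),
    paste("energy interval:", if (is.null(cs)) "[-Inf, 0]" else
      sprintf("[%s, %s]", cs$energy_min, cs$energy_max)),
    paste("seed:", seed), paste("n:", n), paste("max_iter:", max_iter)
  )
  if (format == "fasta") {
    nm <- sprintf("%s dist=%d energy=%.2f iters=%d seed=%d", runs$id,
                  runs$distance, runs$energy, runs$iterations, runs$seed)
    write_fasta(stats::setNames(runs$seq, nm), out, header = header)
  } else if (format == "tsv") {
    con <- file(out, "w")
    writeLines(paste("#", header), con)
    writeLines(paste(names(runs), collapse = "\t"), con)
    close(con)
    utils::write.table(runs, out, append = TRUE, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    for (k in seq_len(nrow(runs))) {
      write_ct(runs$seq[k], target,
               sub("(\\.[^.]*)?$", sprintf("_%03d.ct", k), out, perl = TRUE),
               title = paste("erd", runs$id[k]))
    }
  }
  attr(runs, "n_success") <- sum(runs$success)
  invisible(runs)
}
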