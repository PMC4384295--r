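## Natural composition used for de-novo fragment generation and the
## synthetic corpus: fractions observed in natural sequences for paired
## classes (AU, GC, GU), unpaired bases and overall totals.
NATURAL_PAIRED <- c(AU = 0.39, GC = 0.49, GU = 0.12)
NATURAL_UNPAIRED <- c(A = 0.38, C = 0.19, G = 0.17, U = 0.26)
NATURAL_TOTAL <- c(A = 0.27, C = 0.22, G = 0.25, U = 0.26)

#' Build fragment pools from a sequence corpus
#'
#' Folds every corpus sequence to its MFE structure, decomposes the structure
#' into components, and bins each component's sub-sequence by geometry key.
#' Duplicate fragments are kept, so sampling is frequency-weighted.
#'
#' @param corpus Character vector of RNA sequences (`T` normalised to `U`;
#'   sequences too short to fold at all, under 5 nt, are skipped with a
#'   warning).
#' @param engine A `fold_engine` used for the MFE prediction.
#' @param external Passed to [rna_components()].
#' @return An `erd_pools` object: a tibble with columns `key` and `strands`
#'   (list of character vectors), plus attributes `source` and `engine`.
#' @export
build_pools <- function(corpus, engine = vienna_engine(),
                        external = c("single", "segments")) {
  external <- match.arg(external)
  if (!length(corpus)) stop("corpus is empty", call. = FALSE)
  corpus <- check_rna_seq(corpus)
  short <- nchar(corpus) < 5L
  if (any(short)) {
    warning(sum(short), " corpus sequence(s) too short to fold skipped")
    corpus <- corpus[!short]
    if (!length(corpus)) stop("corpus is empty after filtering", call. = FALSE)
  }
  folded <- engine$fold_many(corpus)
  keys <- list(); strands <- list()
  for (r in seq_len(nrow(folded))) {
    comps <- tryCatch(rna_components(folded$structure[r], external = external),
                      error = function(e) {
                        warning("skipping unparseable fold for sequence ", r)
                        NULL
                      })
    if (is.null(comps)) next
    keys[[r]] <- comps$key
    strands[[r]] <- lapply(comps$positions, component_strands,
                           seq = folded$seq[r])
  }
  pool <- tibble::tibble(key = unlist(keys),
                         strands = do.call(c, strands))
  attr(pool, "source") <- "corpus"
  attr(pool, "engine") <- engine$name
  class(pool) <- c("erd_pools", class(pool))
  pool
}

#' @export
print.erd_pools <- function(x, ...) {
  cat(sprintf("<erd_pools> %d fragments, %d distinct geometry keys (source: %s)\n",
              nrow(x), dplyr::n_distinct(x$key), attr(x, "source") %||% "?"))
  NextMethod()
}

## parse "KIND/sig" back into kind + integer signature
parse_geometry_key <- function(key) {
  kind <- sub("/.*$", "", key)
  sig <- sub("^[A-Z]+/", "", key)
  if (kind == "MULTI") {
    nb <- as.integer(sub(":.*$", "", sig))
    lens <- as.integer(strsplit(sub("^.*:", "", sig), ",")[[1]])
    list(kind = kind, branches = nb, lengths = lens)
  } else if (kind == "STEM") {
    list(kind = kind, lengths = as.integer(sig))
  } else {
    list(kind = kind, lengths = as.integer(strsplit(sig, ",")[[1]]))
  }
}

## expected strand lengths for a geometry key
key_strand_lengths <- function(key) {
  g <- parse_geometry_key(key)
  if (g$kind == "STEM") c(g$lengths, g$lengths) else g$lengths
}

strands_match_mask <- function(strands, mask_strands) {
  if (is.null(mask_strands)) return(TRUE)
  all(mapply(function(st, mk) {
    if (!nchar(st)) return(TRUE)
    all(iupac_matches(strsplit(mk, "", fixed = TRUE)[[1]],
                      strsplit(st, "", fixed = TRUE)[[1]]))
  }, strands, mask_strands))
}

#' Sample a fragment for a geometry key
#'
#' Draws uniformly among pool fragments under the key that are compatible
#' with the IUPAC mask slice. When the key is missing or no stored fragment
#' is compatible, a fragment is generated de novo honouring the mask and
#' stem complementarity, with paired bases drawn from the natural pair-class
#' distribution (AU 0.39, GC 0.49, GU 0.12) and unpaired bases from the
#' natural unpaired distribution. Multi-loop keys additionally fall back to
#' relaxed matching (same branch count and total unpaired length, segments
#' re-chunked) before de-novo generation.
#'
#' @param pools An `erd_pools` object (may be `NULL` for pure de-novo).
#' @param key Geometry key string, e.g. `"STEM/3"` or `"INTERNAL/2,1"`.
#' @param mask_strands Optional character vector of IUPAC strings, one per
#'   strand, matching the key's strand lengths.
#' @return Character vector of strands (one per segment; stems: 5' then 3'
#'   strand).
#' @export
sample_fragment <- function(pools, key, mask_strands = NULL) {
  want <- key_strand_lengths(key)
  if (!is.null(mask_strands) && !identical(nchar(mask_strands), as.integer(want))) {
    stop("mask slice does not match geometry of key ", key, call. = FALSE)
  }
  if (!is.null(pools)) {
    hits <- pools$strands[pools$key == key]
    if (length(hits)) {
      ok <- vapply(hits, strands_match_mask, logical(1), mask_strands)
      if (any(ok)) {
        hits <- hits[ok]
        return(hits[[sample.int(length(hits), 1L)]])
      }
    }
    ## relaxed multi-loop fallback: same branch count + total unpaired length
    g <- parse_geometry_key(key)
    if (g$kind == "MULTI") {
      pref <- paste0("MULTI/", g$branches, ":")
      cand <- pools$strands[startsWith(pools$key, pref)]
      cand <- cand[vapply(cand, function(st) sum(nchar(st)) == sum(g$lengths),
                          logical(1))]
      if (length(cand)) {
        reord <- lapply(cand, function(st) {
          chars <- strsplit(paste(st, collapse = ""), "", fixed = TRUE)[[1]]
          ends <- cumsum(g$lengths)
          starts <- ends - g$lengths + 1L
          vapply(seq_along(g$lengths), function(k) {
            if (g$lengths[k] == 0L) "" else
              paste(chars[starts[k]:ends[k]], collapse = "")
          }, character(1))
        })
        ok <- vapply(reord, strands_match_mask, logical(1), mask_strands)
        if (any(ok)) {
          reord <- reord[ok]
          return(reord[[sample.int(length(reord), 1L)]])
        }
      }
    }
  }
  denovo_fragment(key, mask_strands)
}

## de-novo fragment generation honouring mask + complementarity
denovo_fragment <- function(key, mask_strands = NULL) {
  g <- parse_geometry_key(key)
  want <- key_strand_lengths(key)
  if (is.null(mask_strands)) mask_strands <- vapply(want, strrep, character(1), x = "N")
  if (g$kind == "STEM") {
    k <- g$lengths[1]
    m5 <- strsplit(mask_strands[1], "", fixed = TRUE)[[1]]
    m3 <- strsplit(mask_strands[2], "", fixed = TRUE)[[1]]
    s5 <- character(k); s3 <- character(k)
    class_w <- c(AU = 0.39 / 2, UA = 0.39 / 2, GC = 0.49 / 2, CG = 0.49 / 2,
                 GU = 0.12 / 2, UG = 0.12 / 2)
    for (t in seq_len(k)) {
      ## pair between 5' strand position t and 3' strand position k+1-t
      cands <- paste0(CANONICAL_PAIRS[, 1], CANONICAL_PAIRS[, 2])
      feas <- vapply(cands, function(pc) {
        x <- substr(pc, 1, 1); y <- substr(pc, 2, 2)
        iupac_matches(m5[t], x) && iupac_matches(m3[k + 1L - t], y)
      }, logical(1))
      if (!any(feas)) {
        stop(sprintf("constraint conflict: no canonical pair satisfies mask at stem position %d of %s",
                     t, key), call. = FALSE)
      }
      w <- class_w[cands][feas]
      pick <- sample(cands[feas], 1L, prob = w)
      s5[t] <- substr(pick, 1, 1)
      s3[k + 1L - t] <- substr(pick, 2, 2)
    }
    c(paste(s5, collapse = ""), paste(s3, collapse = ""))
  } else {
    vapply(seq_along(want), function(kk) {
      if (want[kk] == 0L) return("")
      mk <- strsplit(mask_strands[kk], "", fixed = TRUE)[[1]]
      paste(vapply(mk, function(cd) {
        allowed <- IUPAC_SETS[[cd]]
        w <- NATURAL_UNPAIRED[allowed]
        sample(allowed, 1L, prob = w)
      }, character(1)), collapse = "")
    }, character(1))
  }
}

#' Serialise fragment pools to a tab-separated file
#'
#' One record per fragment: geometry key, then the strands joined by `|`.
#' A `# erd-pools v1` header line carries the format version.
#'
#' @param pools An `erd_pools` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pools <- function(pools, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# erd-pools v1 source=%s engine=%s",
                     attr(pools, "source") %||% "unknown",
                     attr(pools, "engine") %||% "unknown"), con)
  writeLines(paste(pools$key,
                   vapply(pools$strands, paste, character(1), collapse = "|"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read fragment pools written by [write_pools()]
#'
#' @param path Pool cache file.
#' @return An `erd_pools` object.
#' @export
read_pools <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# erd-pools v1")) {
    stop("not an erd-pools v1 file: ", path, call. = FALSE)
  }
  lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pool <- tibble::tibble(
    key = vapply(parts, `[`, character(1), 1),
    strands = lapply(parts, function(p) {
      st <- strsplit(p[2], "|", fixed = TRUE)[[1]]
      ## trailing empty segments are dropped by strsplit; pad back
      want <- length(key_strand_lengths(p[1]))
      c(st, rep("", want - length(st)))
    })
  )
  attr(pool, "source") <- path
  class(pool) <- c("erd_pools", class(pool))
  pool
}
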