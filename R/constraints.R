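## IUPAC nucleotide ambiguity codes over the RNA alphabet
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

## canonical base pairs (Watson-Crick + wobble)
CANONICAL_PAIRS <- matrix(c("A","U", "U","A", "G","C", "C","G", "G","U", "U","G"),
                          ncol = 2, byrow = TRUE)

#' Does a base satisfy an IUPAC symbol?
#'
#' Standard IUPAC semantics: `N` matches any base, `R` = A/G, `Y` = C/U, etc.
#' `T` in either argument is treated as `U`.
#'
#' @param code IUPAC symbol(s).
#' @param base Nucleotide(s) in `A`,`C`,`G`,`U`.
#' @return Logical vector (recycled elementwise).
#' @examples
#' iupac_matches("R", "A")
#' @export
iupac_matches <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  code[code == "T"] <- "U"; base[base == "T"] <- "U"
  if (any(!code %in% names(IUPAC_SETS))) {
    stop("unknown IUPAC symbol: ",
         paste(unique(code[!code %in% names(IUPAC_SETS)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!base %in% c("A", "C", "G", "U"))) {
    stop("invalid nucleotide: ",
         paste(unique(base[!base %in% c("A", "C", "G", "U")]), collapse = ", "),
         call. = FALSE)
  }
  mapply(function(cd, b) b %in% IUPAC_SETS[[cd]], code, base, USE.NAMES = FALSE)
}

#' Create a design constraint set
#'
#' Bundles the optional per-position IUPAC mask with the free-energy interval
#' constraint. The energy interval bounds (kcal/mol, inclusive) apply to the
#' free energy of the designed sequence evaluated *on the target structure*;
#' the defaults (−Inf, 0] only require the sequence to be stabilising.
#'
#' @param mask Optional IUPAC string (same length as the target structure).
#'   `T` is normalised to `U`.
#' @param energy_min,energy_max Energy interval in kcal/mol.
#' @return An object of class `erd_constraints`.
#' @export
erd_constraints <- function(mask = NULL, energy_min = -Inf, energy_max = 0) {
  if (!is.null(mask)) {
    mask <- toupper(mask)
    mask <- gsub("T", "U", mask, fixed = TRUE)
    sym <- unique(strsplit(mask, "", fixed = TRUE)[[1]])
    if (any(!sym %in% names(IUPAC_SETS))) {
      stop("mask contains non-IUPAC symbols: ",
           paste(setdiff(sym, names(IUPAC_SETS)), collapse = ", "), call. = FALSE)
    }
  }
  if (energy_min > energy_max) {
    stop("energy_min must not exceed energy_max", call. = FALSE)
  }
  structure(list(mask = mask, energy_min = energy_min, energy_max = energy_max),
            class = "erd_constraints")
}

#' @export
print.erd_constraints <- function(x, ...) {
  cat("<erd_constraints>\n")
  cat("  mask:", if (is.null(x$mask)) "(none)" else x$mask, "\n")
  cat(sprintf("  energy interval: [%s, %s] kcal/mol\n", x$energy_min, x$energy_max))
  invisible(x)
}

#' Does a sequence satisfy the IUPAC mask of a constraint set?
#'
#' @param seq RNA sequence (character scalar).
#' @param cs An [erd_constraints] object (or `NULL`, always satisfied).
#' @return `TRUE` iff every position matches its mask symbol.
#' @export
sequence_satisfies <- function(seq, cs) {
  if (is.null(cs) || is.null(cs$mask)) return(TRUE)
  if (nchar(seq) != nchar(cs$mask)) {
    stop(sprintf("sequence length %d does not match mask length %d",
                 nchar(seq), nchar(cs$mask)), call. = FALSE)
  }
  all(iupac_matches(strsplit(cs$mask, "", fixed = TRUE)[[1]],
                    strsplit(seq, "", fixed = TRUE)[[1]]))
}

#' Is an energy inside the constraint interval?
#'
#' @param e Energy (kcal/mol); vectorised.
#' @param cs An [erd_constraints] object (or `NULL`, always `TRUE`).
#' @return Logical: `energy_min <= e <= energy_max` (inclusive endpoints).
#' @export
energy_in_range <- function(e, cs) {
  if (is.null(cs)) return(rep(TRUE, length(e)))
  e >= cs$energy_min & e <= cs$energy_max
}

## TRUE iff a finite interval was given, so the energy-centre selection rule
## applies during evolution
has_energy_interval <- function(cs) {
  !is.null(cs) && is.finite(cs$energy_min) && is.finite(cs$energy_max)
}

energy_interval_center <- function(cs) (cs$energy_min + cs$energy_max) / 2

#' Find base pairs whose IUPAC constraints admit no canonical pairing
#'
#' A pair `i.j` is infeasible when no combination of bases allowed by the two
#' mask symbols is complementary under `{AU, UA, GC, CG, GU, UG}`. A
#' non-empty result means the design problem is unsatisfiable as posed.
#'
#' @param s Target [rna_structure] (or dot-bracket string).
#' @param mask IUPAC string of the same length.
#' @return Tibble with columns `i`, `j`, `code_i`, `code_j`; zero rows means
#'   feasible.
#' @export
detect_conflicts <- function(s, mask) {
  s <- rna_structure(s)
  mask <- gsub("T", "U", toupper(mask), fixed = TRUE)
  if (nchar(mask) != s$length) {
    stop(sprintf("mask length %d does not match structure length %d",
                 nchar(mask), s$length), call. = FALSE)
  }
  codes <- strsplit(mask, "", fixed = TRUE)[[1]]
  pr <- structure_pairs(s)
  ok <- function(ci, cj) {
    xi <- IUPAC_SETS[[ci]]; xj <- IUPAC_SETS[[cj]]
    any(apply(CANONICAL_PAIRS, 1, function(p) p[1] %in% xi && p[2] %in% xj))
  }
  bad <- which(!mapply(function(i, j) ok(codes[i], codes[j]), pr[, 1], pr[, 2]))
  tibble::tibble(
    i = unname(pr[bad, 1]), j = unname(pr[bad, 2]),
    code_i = codes[pr[bad, 1]], code_j = codes[pr[bad, 2]]
  )
}

## complementarity test for base characters (vectorised)
bases_complementary <- function(x, y) {
  paste0(x, y) %in% paste0(CANONICAL_PAIRS[, 1], CANONICAL_PAIRS[, 2])
}

#' Is a sequence pairing-compatible with a structure?
#'
#' Every paired position must hold complementary bases (Watson-Crick or GU
#' wobble).
#'
#' @param seq RNA sequence.
#' @param s Target structure.
#' @return Logical scalar.
#' @export
pairing_compatible <- function(seq, s) {
  s <- rna_structure(s)
  if (nchar(seq) != s$length) return(FALSE)
  pr <- structure_pairs(s)
  if (!nrow(pr)) return(TRUE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  all(bases_complementary(chars[pr[, 1]], chars[pr[, 2]]))
}
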