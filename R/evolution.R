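## slice a full-length IUPAC mask into per-strand pieces for a component
mask_slices <- function(mask, positions) {
  if (is.null(mask)) return(NULL)
  chars <- strsplit(mask, "", fixed = TRUE)[[1]]
  vapply(positions, function(ps) paste(chars[ps], collapse = ""), character(1))
}

## assemble one candidate sequence by sampling a fragment per component
assemble_sequence <- function(comps, pools, mask) {
  chars <- rep("A", sum(vapply(comps$positions, function(p) sum(lengths(p)),
                               integer(1))))
  seq <- paste(chars, collapse = "")
  for (r in seq_len(nrow(comps))) {
    frag <- sample_fragment(pools, comps$key[r],
                            mask_slices(mask, comps$positions[[r]]))
    seq <- place_strands(seq, comps$positions[[r]], frag)
  }
  seq
}

#' Construct an initial sequence compatible with the target structure
#'
#' Fills every structural component of the target with a fragment sampled
#' from the pools (mask-compatible by construction), assembles the full
#' sequence, and then enforces the constraints with the two retry loops:
#' up to 1000 resampling attempts for the sequence constraints, then up to
#' 1000 further attempts for the energy-interval constraint (energies
#' evaluated over the target structure). If the energy loop is exhausted the
#' attempt with energy closest to the interval is returned, flagged unmet.
#'
#' @param target [rna_structure] or dot-bracket string.
#' @param pools An `erd_pools` object (or `NULL` for pure de-novo sampling).
#' @param cs [erd_constraints] or `NULL`.
#' @param engine A `fold_engine`.
#' @param max_tries Retry cap for each constraint loop (default 1000).
#' @return List: `seq`, `energy` (over the target), `sequence_ok`,
#'   `energy_ok`.
#' @export
build_initial_sequence <- function(target, pools, cs = NULL,
                                   engine = vienna_engine(),
                                   max_tries = 1000L) {
  target <- rna_structure(target)
  if (!is.null(cs) && !is.null(cs$mask)) {
    conf <- detect_conflicts(target, cs$mask)
    if (nrow(conf)) {
      stop("constraint conflict: pair(s) ",
           paste(sprintf("%d.%d (%s/%s)", conf$i, conf$j, conf$code_i, conf$code_j),
                 collapse = ", "),
           " admit no canonical base pair", call. = FALSE)
    }
  }
  comps <- rna_components(target)
  mask <- if (is.null(cs)) NULL else cs$mask

  ## loop 1: sequence constraints (sampling is mask-filtered, so this
  ## normally passes first time; the loop guards the fallback paths)
  seq <- NULL; sequence_ok <- FALSE
  for (t in seq_len(max_tries)) {
    seq <- assemble_sequence(comps, pools, mask)
    if (sequence_satisfies(seq, cs)) { sequence_ok <- TRUE; break }
  }

  ## loop 2: energy interval, evaluated in batches to bound engine calls
  e <- energy_of(seq, target$dotbracket, engine)
  if (energy_in_range(e, cs)) {
    return(list(seq = seq, energy = e, sequence_ok = sequence_ok,
                energy_ok = TRUE))
  }
  center <- if (has_energy_interval(cs)) energy_interval_center(cs) else
    min(cs$energy_max, 0)
  best_seq <- seq; best_e <- e
  tried <- 1L
  chunk <- 50L
  while (tried < max_tries) {
    m <- min(chunk, max_tries - tried)
    cands <- vapply(seq_len(m), function(k) assemble_sequence(comps, pools, mask),
                    character(1))
    es <- energy_of(cands, target$dotbracket, engine)
    tried <- tried + m
    hit <- which(energy_in_range(es, cs))[1]
    if (!is.na(hit)) {
      return(list(seq = cands[hit], energy = es[hit],
                  sequence_ok = sequence_ok, energy_ok = TRUE))
    }
    k <- which.min(abs(es - center))
    if (abs(es[k] - center) < abs(best_e - center)) {
      best_seq <- cands[k]; best_e <- es[k]
    }
  }
  list(seq = best_seq, energy = best_e, sequence_ok = sequence_ok,
       energy_ok = FALSE)
}

#' Generate offspring by component-level mutation
#'
#' Compares the parent's MFE structure with the target; every component of
#' the target containing a mismatched position spawns one offspring in which
#' that component's fragment is resampled from the pools (mask-compatible).
#' Mutation acts only at component level; the parent itself is included.
#'
#' @param parent_seq Parent RNA sequence.
#' @param parent_structure The parent's MFE structure (dot-bracket).
#' @param target Target [rna_structure].
#' @param comps Pre-computed [rna_components()] of the target.
#' @param pools,cs As in [build_initial_sequence()].
#' @param cap Maximum number of offspring per parent; when more components
#'   mismatch, `cap` of them are sampled uniformly.
#' @return Character vector of candidate sequences, parent first.
#' @export
make_population <- function(parent_seq, parent_structure, target, comps,
                            pools, cs = NULL, cap = 30L) {
  target <- rna_structure(target)
  tchars <- strsplit(target$dotbracket, "", fixed = TRUE)[[1]]
  pchars <- strsplit(parent_structure, "", fixed = TRUE)[[1]]
  diff_pos <- which(tchars != pchars)
  if (!length(diff_pos)) return(parent_seq)
  hit <- which(vapply(comps$positions, function(ps) {
    any(unlist(ps) %in% diff_pos)
  }, logical(1)))
  if (length(hit) > cap) hit <- sort(sample(hit, cap))
  mask <- if (is.null(cs)) NULL else cs$mask
  offspring <- vapply(hit, function(r) {
    frag <- sample_fragment(pools, comps$key[r],
                            mask_slices(mask, comps$positions[[r]]))
    place_strands(parent_seq, comps$positions[[r]], frag)
  }, character(1))
  c(parent_seq, offspring)
}

#' Evaluate a population and select the three survivors
#'
#' All candidates are scored by free energy over the target structure and
#' sorted ascending — or, when a finite energy interval is specified, by
#' distance to the interval centre. The best three are folded; their Hamming
#' distances to the target (together with the incumbent best) decide the
#' three survivors and the new incumbent (smallest distance; ties by the
#' energy criterion, then input order).
#'
#' @param pop Character vector of candidate sequences.
#' @param target Target [rna_structure].
#' @param best Incumbent best as a list `(seq, structure, distance, energy)`
#'   or `NULL`.
#' @param cs [erd_constraints] or `NULL`.
#' @param engine A `fold_engine`.
#' @return List with `survivors` (tibble: seq, structure, distance, energy)
#'   and `best` (one-row list like the incumbent).
#' @export
evaluate_and_select <- function(pop, target, best = NULL, cs = NULL,
                                engine = vienna_engine()) {
  target <- rna_structure(target)
  energies <- energy_of(pop, target$dotbracket, engine)
  score <- if (has_energy_interval(cs)) {
    abs(energies - energy_interval_center(cs))
  } else {
    energies
  }
  ord <- order(score)           # stable: ties keep input order
  top <- utils::head(ord, 3L)
  folded <- fold_rna(pop[top], engine)
  cand <- tibble::tibble(
    seq = pop[top],
    structure = folded$structure,
    distance = vapply(folded$structure, structure_hamming, integer(1),
                      b = target$dotbracket, USE.NAMES = FALSE),
    energy = energies[top],
    score = score[top]
  )
  if (!is.null(best)) {
    bscore <- if (has_energy_interval(cs)) {
      abs(best$energy - energy_interval_center(cs))
    } else {
      best$energy
    }
    cand <- dplyr::bind_rows(
      cand,
      tibble::tibble(seq = best$seq, structure = best$structure,
                     distance = best$distance, energy = best$energy,
                     score = bscore)
    )
  }
  cand <- cand[order(cand$distance, cand$score), ]
  survivors <- utils::head(cand, 3L)
  list(survivors = survivors[, c("seq", "structure", "distance", "energy")],
       best = as.list(survivors[1, c("seq", "structure", "distance", "energy")]))
}

## one evolutionary optimisation loop over a single (sub-)target
optimize_loop <- function(target, pools, cs, engine, max_iter, cap,
                          init = NULL) {
  target <- rna_structure(target)
  comps <- rna_components(target)
  if (is.null(init)) {
    init <- build_initial_sequence(target, pools, cs, engine)
  }
  f0 <- fold_rna(init$seq, engine)
  best <- list(seq = init$seq, structure = f0$structure[1],
               distance = structure_hamming(f0$structure[1], target$dotbracket),
               energy = energy_of(init$seq, target$dotbracket, engine))
  survivors <- tibble::tibble(seq = best$seq, structure = best$structure,
                              distance = best$distance, energy = best$energy)
  done <- function(b) {
    b$distance == 0L && energy_in_range(b$energy, cs) &&
      sequence_satisfies(b$seq, cs)
  }
  iters <- 0L
  while (iters < max_iter && !done(best)) {
    iters <- iters + 1L
    pop <- unique(unlist(lapply(seq_len(nrow(survivors)), function(r) {
      make_population(survivors$seq[r], survivors$structure[r], target,
                      comps, pools, cs, cap = cap)
    })))
    sel <- evaluate_and_select(pop, target, best, cs, engine)
    survivors <- sel$survivors
    best <- sel$best
  }
  list(best = best, iterations = iters)
}

#' Design an RNA sequence folding into a target structure
#'
#' The full evolutionary design procedure: fragment pools supply natural
#' sub-sequences per structural component; an initial compatible sequence is
#' assembled and then improved by component-level mutation, three-best
#' selection, and Hamming-distance fitness, until the MFE structure matches
#' the target (distance 0, constraints satisfied) or the iteration cap is
#' reached. Large targets containing multi-loops are first split
#' hierarchically at breaking base pairs; each leaf sub-structure is
#' optimised independently, the parts are reassembled, and the full sequence
#' is polished by the same loop.
#'
#' @param target Target structure ([rna_structure] or dot-bracket string).
#' @param cs [erd_constraints] (IUPAC mask and/or energy interval), or
#'   `NULL` for the defaults (no mask, energy in (−Inf, 0]).
#' @param pools An `erd_pools` object, or `NULL` to sample all fragments de
#'   novo from the natural base distributions.
#' @param engine A `fold_engine`.
#' @param max_iter Iteration cap per optimisation loop (default 250).
#' @param seed Optional integer seed; recorded in the result.
#' @param hierarchical Split at multi-loops before optimising (default TRUE).
#' @param min_split Minimum part length worth splitting (default 40 nt).
#' @param pop_cap Offspring cap per parent per generation (default 30).
#' @return An `erd_design` object: list with `seq`, `distance`,
#'   `energy_on_target`, `mfe_structure`, `iterations_used`,
#'   `sequence_constraints_met`, `energy_constraint_met`, `success`
#'   (distance 0 and both constraints met), plus `target`, `engine`,
#'   `seed` and the run parameters.
#' @examples
#' \dontrun{
#' d <- design("((((...))))", engine = vienna_engine(), seed = 1)
#' d$success
#' }
#' @export
design <- function(target, cs = NULL, pools = NULL, engine = vienna_engine(),
                   max_iter = 250L, seed = NULL, hierarchical = TRUE,
                   min_split = 40L, pop_cap = 30L) {
  target <- rna_structure(target)
  if (is.null(cs)) cs <- erd_constraints()
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(cs$mask)) {
    if (nchar(cs$mask) != target$length) {
      stop(sprintf("mask length %d does not match target length %d",
                   nchar(cs$mask), target$length), call. = FALSE)
    }
    conf <- detect_conflicts(target, cs$mask)
    if (nrow(conf)) {
      stop("constraint conflict at pair(s) ",
           paste(sprintf("%d.%d", conf$i, conf$j), collapse = ", "),
           call. = FALSE)
    }
  }

  total_iters <- 0L
  init <- NULL
  tree <- if (hierarchical) decompose_hierarchy(target, min_split = min_split)
          else NULL
  if (!is.null(tree) && length(tree$children)) {
    leaves <- hierarchy_leaves(tree)
    leaf_seqs <- character(length(leaves))
    for (k in seq_along(leaves)) {
      l <- leaves[[k]]
      leaf_cs <- erd_constraints(
        mask = if (is.null(cs$mask)) NULL else
          paste(strsplit(cs$mask, "", fixed = TRUE)[[1]][l$positions],
                collapse = ""),
        energy_min = -Inf, energy_max = Inf  # interval applies to the full sequence
      )
      res <- optimize_loop(l$dotbracket, pools, leaf_cs, engine, max_iter,
                           pop_cap)
      leaf_seqs[k] <- res$best$seq
      total_iters <- total_iters + res$iterations
    }
    full <- flatten_hierarchy(tree, leaf_seqs)$seq
    e <- energy_of(full, target$dotbracket, engine)
    init <- list(seq = full, energy = e,
                 sequence_ok = sequence_satisfies(full, cs),
                 energy_ok = energy_in_range(e, cs))
  }
  res <- optimize_loop(target, pools, cs, engine, max_iter, pop_cap,
                       init = init)
  total_iters <- total_iters + res$iterations
  best <- res$best
  seq_ok <- sequence_satisfies(best$seq, cs)
  e_ok <- energy_in_range(best$energy, cs)
  out <- list(
    seq = best$seq,
    distance = best$distance,
    energy_on_target = best$energy,
    mfe_structure = best$structure,
    iterations_used = total_iters,
    sequence_constraints_met = seq_ok,
    energy_constraint_met = e_ok,
    success = best$distance == 0L && seq_ok && e_ok,
    target = target$dotbracket,
    constraints = cs,
    engine = paste0(engine$name, " ", engine$version),
    seed = seed,
    params = list(max_iter = max_iter, hierarchical = hierarchical,
                  min_split = min_split, pop_cap = pop_cap)
  )
  class(out) <- "erd_design"
  out
}

#' @export
print.erd_design <- function(x, ...) {
  cat("<erd_design>", if (x$success) "success" else "best effort", "\n")
  cat("  target:", x$target, "\n")
  cat("  seq:   ", x$seq, "\n")
  cat("  mfe:   ", x$mfe_structure, "\n")
  cat(sprintf("  distance %d | energy %.2f | iterations %d | engine %s\n",
              x$distance, x$energy_on_target, x$iterations_used, x$engine))
  invisible(x)
}
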