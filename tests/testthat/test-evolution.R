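toy <- toy_engine()

test_that("initial sequence assembly uses the pools and checks constraints", {
  pool <- tiny_pools(c("STEM/2", "HAIRPIN/3"), list(c("GC", "GC"), "AAA"))
  init <- build_initial_sequence("((...))", pool, NULL, toy)
  expect_equal(init$seq, "GCAAAGC")
  expect_true(init$sequence_ok)
  expect_true(init$energy_ok)
  expect_equal(init$energy, -2)

  ## mask consistent with the single possible assembly
  init2 <- build_initial_sequence("((...))", pool,
                                  erd_constraints("GNNNNNC"), toy)
  expect_equal(init2$seq, "GCAAAGC")

  ## infeasible pair constraint errors before sampling
  expect_error(build_initial_sequence("((...))", pool,
                                      erd_constraints("ANNNNNC"), toy),
               "constraint conflict")

  ## unreachable energy interval: best effort returned, flagged unmet
  init3 <- build_initial_sequence("((...))", pool,
                                  erd_constraints(energy_min = -100,
                                                  energy_max = -50),
                                  toy, max_tries = 60L)
  expect_false(init3$energy_ok)
  expect_equal(init3$seq, "GCAAAGC")
})

test_that("population generation mutates only mismatched components", {
  pool <- tiny_pools(c("STEM/2", "HAIRPIN/3", "HAIRPIN/3"),
                     list(c("GC", "GC"), "AAA", "ACA"))
  target <- rna_structure("((...))")
  comps <- rna_components(target)

  ## parent already at distance 0: population is just the parent
  pop0 <- make_population("GCAAAGC", "((...))", target, comps, pool)
  expect_identical(pop0, "GCAAAGC")

  ## mismatch confined to hairpin positions 4-5: parent + exactly one
  ## variant, and only the hairpin strand changes
  set.seed(4)
  pop1 <- make_population("GCAAAGC", "((.()))", target, comps, pool)
  expect_length(pop1, 2L)
  expect_equal(pop1[1], "GCAAAGC")
  expect_equal(substr(pop1[2], 1, 2), "GC")
  expect_equal(substr(pop1[2], 6, 7), "GC")
  expect_true(substr(pop1[2], 3, 5) %in% c("AAA", "ACA"))

  ## offspring stay mask-compliant and pairing-compatible on random runs
  set.seed(6)
  for (rep in 1:20) {
    db <- random_structure(sample(20:50, 1))
    tgt <- rna_structure(db)
    cps <- rna_components(tgt)
    base <- random_compatible_sequence(db)
    mask <- make_fixed_mask(base, 0.15)
    cs <- erd_constraints(mask)
    parent <- erd:::assemble_sequence(cps, NULL, mask)
    other <- random_structure(nchar(db))
    pop <- make_population(parent, other, tgt, cps, NULL, cs)
    for (child in pop) {
      expect_true(sequence_satisfies(child, cs))
      expect_true(pairing_compatible(child, tgt))
    }
  }
})

test_that("selection sorts by energy, folds the top three, keeps least distance", {
  target <- "((...))"
  seqs <- c("AAUUUUU", "CCUUUGG", "GGUUUCC", "UUUUUUA")
  energies <- c("AAUUUUU" = -5, "CCUUUGG" = -3, "GGUUUCC" = -9, "UUUUUUA" = -1)
  folds <- c("AAUUUUU" = ".......", "CCUUUGG" = "((...))",
             "GGUUUCC" = "((...))", "UUUUUUA" = ".......")
  eng <- scripted_engine(energies, folds)

  sel <- evaluate_and_select(seqs, target, best = NULL, cs = NULL, engine = eng)
  ## lowest three energies -9, -5, -3 are folded; among them the two
  ## distance-0 candidates rank first
  expect_equal(sel$best$seq, "GGUUUCC")
  expect_equal(sel$best$distance, 0L)
  expect_setequal(sel$survivors$seq, c("GGUUUCC", "CCUUUGG", "AAUUUUU"))

  ## with interval [-6, -2] (centre -4) the fold order becomes -5, -3, -9
  cs <- erd_constraints(energy_min = -6, energy_max = -2)
  sel2 <- evaluate_and_select(seqs, target, best = NULL, cs = cs, engine = eng)
  expect_equal(sel2$survivors$seq[1:2], c("CCUUUGG", "AAUUUUU"))
  expect_equal(sel2$best$seq, "CCUUUGG")  # distance 0, |e - c| = 1

  ## population of one survives trivially
  sel3 <- evaluate_and_select("AAUUUUU", target, engine = eng)
  expect_equal(sel3$best$seq, "AAUUUUU")
})

test_that("a fully fixed mask whose sequence folds right is returned as-is", {
  d <- design("(((...)))", cs = erd_constraints("GGGAAACCC"), pools = NULL,
              engine = toy, seed = 5, hierarchical = FALSE, max_iter = 20)
  expect_true(d$success)
  expect_equal(d$seq, "GGGAAACCC")
  expect_equal(d$distance, 0L)
  expect_lte(d$iterations_used, 1L)
})

test_that("infeasible energy intervals surface as flags, not errors", {
  d <- design("((((((...))))))",
              cs = erd_constraints(energy_min = -0.5, energy_max = -0.4),
              pools = NULL, engine = toy, seed = 9, hierarchical = FALSE,
              max_iter = 5)
  expect_false(d$success)
  expect_false(d$energy_constraint_met)
  expect_s3_class(glance(d), "tbl_df")
})

test_that("design is deterministic under a fixed seed", {
  set.seed(1)
  corpus <- synthetic_corpus(30, c(20, 60))
  pools <- build_pools(corpus, toy)
  d1 <- design("((..((...))..((...))..))", pools = pools, engine = toy,
               seed = 42, max_iter = 10, min_split = 10)
  d2 <- design("((..((...))..((...))..))", pools = pools, engine = toy,
               seed = 42, max_iter = 10, min_split = 10)
  expect_identical(d1[names(d1) != "constraints"],
                   d2[names(d2) != "constraints"])
})

test_that("returned sequences are always mask-compliant and pairing-compatible", {
  set.seed(8)
  corpus <- synthetic_corpus(30, c(20, 60))
  pools <- build_pools(corpus, toy)
  for (rep in 1:25) {
    db <- random_structure(sample(20:45, 1))
    base <- random_compatible_sequence(db)
    mask <- make_fixed_mask(base, stats::runif(1, 0.1, 0.3))
    d <- design(db, cs = erd_constraints(mask), pools = pools, engine = toy,
                max_iter = 8, hierarchical = FALSE)
    expect_true(sequence_satisfies(d$seq, erd_constraints(mask)))
    expect_true(pairing_compatible(d$seq, db))
    if (d$success) {
      expect_equal(fold_rna(d$seq, toy)$structure, db)
    }
  }
})

test_that("tidy and autoplot expose the per-position comparison", {
  d <- design("(((...)))", cs = erd_constraints("GGGAAACCC"), engine = toy,
              seed = 2, hierarchical = FALSE, max_iter = 5)
  td <- tidy(d)
  expect_equal(nrow(td), 9L)
  expect_true(all(td$match))
  p <- autoplot(d)
  expect_s3_class(p, "ggplot")
})
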