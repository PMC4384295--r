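test_that("expected time divides total time by success count", {
  expect_equal(expected_time(100, 50), 2)
  expect_equal(expected_time(17.3, 1), 17.3)
  expect_identical(expected_time(100, 0), Inf)
})

test_that("expected energy distance is the mean absolute gap", {
  expect_equal(expected_energy_distance(c(-10, -12), c(-11, -11)), 1)
  expect_equal(expected_energy_distance(c(-7, -3), c(-7, -3)), 0)
  expect_identical(expected_energy_distance(numeric(0), numeric(0)), Inf)
  expect_error(expected_energy_distance(1:3, 1:2), "matched")
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    d <- stats::rnorm(n, -50, 20); nat <- stats::rnorm(n, -50, 20)
    expect_equal(expected_energy_distance(d, nat),
                 sum(abs(d - nat)) / n, tolerance = 1e-12)
  }
})

test_that("alignment identity matches an exhaustive dynamic program", {
  expect_equal(seq_similarity("ACGU", "ACGU"), 100)
  expect_error(seq_similarity("", "ACGU"), "non-empty")

  set.seed(21)
  for (rep in 1:40) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(2:10, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(2:10, 1), TRUE), collapse = "")
    got <- seq_similarity(a, b)
    want <- oracle_nw(a, b)
    expect_true(any(abs(got - want$identities) < 1e-6),
                info = sprintf("%s vs %s: got %.4f, oracle {%s}", a, b, got,
                               paste(round(want$identities, 4), collapse = ",")))
    ## symmetry
    expect_equal(got, seq_similarity(b, a), tolerance = 1e-9)
  }
})

test_that("within-group expected similarity averages all pairs, then groups", {
  expect_equal(expected_similarity_within(list(c("ACGU", "ACGU"))), 100)
  s <- "ACGGUU"; t <- "ACGGUA"
  want <- mean(c(seq_similarity(s, s), seq_similarity(s, t), seq_similarity(s, t)))
  expect_equal(expected_similarity_within(list(c(s, s, t))), want,
               tolerance = 1e-9)
  ## groups below size 2 are skipped; all-small is an error
  expect_equal(expected_similarity_within(list("ACGU", c(s, t))),
               seq_similarity(s, t), tolerance = 1e-9)
  expect_error(expected_similarity_within(list("ACGU")), "two sequences")

  set.seed(33)
  groups <- replicate(3, replicate(sample(2:4, 1),
    paste(sample(c("A", "C", "G", "U"), 8, TRUE), collapse = "")),
    simplify = FALSE)
  brute <- mean(vapply(groups, function(g) {
    tot <- 0; cnt <- 0
    for (i in seq_along(g)) for (j in seq_along(g)) if (j > i) {
      tot <- tot + seq_similarity(g[i], g[j]); cnt <- cnt + 1
    }
    tot / cnt
  }, numeric(1)))
  expect_equal(expected_similarity_within(groups), brute, tolerance = 1e-9)
})

test_that("similarity to natural counterparts averages matched pairs", {
  expect_equal(expected_similarity_to_natural(c("ACGU", "GGCC"),
                                              c("ACGU", "GGCC")), 100)
  expect_equal(expected_similarity_to_natural("ACGGA", "ACUGA"),
               seq_similarity("ACGGA", "ACUGA"), tolerance = 1e-12)
  set.seed(44)
  d <- replicate(5, paste(sample(c("A", "C", "G", "U"), 9, TRUE), collapse = ""))
  nat <- replicate(5, paste(sample(c("A", "C", "G", "U"), 9, TRUE), collapse = ""))
  expect_equal(expected_similarity_to_natural(d, nat),
               mean(mapply(seq_similarity, d, nat)), tolerance = 1e-12)
  expect_error(expected_similarity_to_natural(character(0), character(0)),
               "non-empty")
})

test_that("nucleotide distribution separates paired classes and unpaired bases", {
  dist <- nucleotide_distribution("GCAAAGC", "((...))")
  paired <- dist[dist$region == "paired", ]
  expect_equal(paired$fraction[paired$symbol == "GC"], 1)
  unpaired <- dist[dist$region == "unpaired", ]
  expect_equal(unpaired$fraction[unpaired$symbol == "A"], 1)
  total <- dist[dist$region == "total", ]
  expect_equal(total$fraction[total$symbol == "A"], 3 / 7)

  ## all-unpaired: paired fractions undefined, totals = base composition
  d2 <- nucleotide_distribution("ACGU", "....")
  expect_true(all(is.na(d2$fraction[d2$region == "paired"])))
  expect_equal(d2$fraction[d2$region == "total"], rep(0.25, 4))

  ## UA counts as AU; GU wobble recognised; non-canonical pairs warned
  d3 <- nucleotide_distribution("UGAAACA", "((...))")
  p3 <- d3[d3$region == "paired", ]
  expect_equal(p3$count[p3$symbol == "AU"], 1)
  expect_equal(p3$count[p3$symbol == "GU"], 0)
  expect_warning(nucleotide_distribution("AGAAACA", "((...))"),
                 "non-canonical")

  ## group sums are 1 whenever denominators are positive
  set.seed(55)
  seqs <- character(5); dbs <- character(5)
  for (k in 1:5) {
    dbs[k] <- random_structure(40)
    seqs[k] <- random_compatible_sequence(dbs[k])
  }
  d4 <- nucleotide_distribution(seqs, dbs)
  sums <- tapply(d4$fraction, d4$region, sum)
  expect_true(all(abs(sums - 1) < 1e-9, na.rm = TRUE))
  expect_error(nucleotide_distribution(seqs, dbs[1:3]), "matched")
})

test_that("synthetic corpus totals match the generator targets in bulk", {
  set.seed(66)
  corpus <- synthetic_corpus(500, c(80, 120))
  dist <- nucleotide_distribution(corpus,
                                  vapply(nchar(corpus), strrep,
                                         character(1), x = "."))
  tot <- dist[dist$region == "total", ]
  target <- c(A = 0.27, C = 0.22, G = 0.25, U = 0.26)
  expect_true(all(abs(tot$fraction - target[tot$symbol]) < 0.02))
})
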