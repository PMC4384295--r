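test_that("pools bin folded corpus fragments by geometry", {
  eng <- vienna_engine()
  pools <- build_pools("GGGAAACCC", eng)
  expect_equal(sort(pools$key), c("HAIRPIN/3", "STEM/3"))
  expect_equal(pools$strands[[which(pools$key == "STEM/3")]], c("GGG", "CCC"))
  expect_equal(pools$strands[[which(pools$key == "HAIRPIN/3")]], "AAA")

  expect_error(build_pools(character(0)), "empty")

  ## duplicates kept: sampling is frequency-weighted
  pools2 <- build_pools(c("GGGAAACCC", "GGGAAACCC"), eng)
  expect_equal(sum(pools2$key == "STEM/3"), 2L)
})

test_that("build_pools is deterministic for fixed corpus and engine", {
  set.seed(99)
  corpus <- synthetic_corpus(20, c(20, 60))
  toy <- toy_engine()
  p1 <- build_pools(corpus, toy)
  p2 <- build_pools(corpus, toy)
  expect_identical(p1$key, p2$key)
  expect_identical(p1$strands, p2$strands)
})

test_that("sampled fragments always match geometry and mask", {
  pool <- tiny_pools("HAIRPIN/3", list("AAA"))
  expect_equal(sample_fragment(pool, "HAIRPIN/3"), "AAA")

  ## stem sampling with a fixed 5' strand yields only complementary 3' strands
  set.seed(1)
  for (rep in 1:50) {
    frag <- sample_fragment(NULL, "STEM/2", mask_strands = c("GC", "NN"))
    expect_equal(nchar(frag), c(2L, 2L))
    expect_equal(substr(frag[1], 1, 2), "GC")
    ## pair t of the 5' strand partners position k+1-t of the 3' strand
    expect_true(erd:::bases_complementary(substr(frag[1], 1, 1),
                                          substr(frag[2], 2, 2)))
    expect_true(erd:::bases_complementary(substr(frag[1], 2, 2),
                                          substr(frag[2], 1, 1)))
  }

  ## absent key: de-novo fallback still honours geometry and mask
  set.seed(2)
  for (key in c("HAIRPIN/4", "INTERNAL/2,1", "MULTI/2:1,0,2", "STEM/3")) {
    frag <- sample_fragment(NULL, key)
    expect_equal(nchar(frag), erd:::key_strand_lengths(key), info = key)
  }
  frag <- sample_fragment(NULL, "HAIRPIN/3", mask_strands = "RRY")
  expect_true(all(iupac_matches(c("R", "R", "Y"),
                                strsplit(frag, "")[[1]])))

  ## contradictory pair constraint surfaces as an error
  expect_error(sample_fragment(NULL, "STEM/1", mask_strands = c("A", "C")),
               "constraint conflict")
})

test_that("randomized queries never violate geometry or mask", {
  set.seed(77)
  corpus <- synthetic_corpus(40, c(30, 80))
  pools <- build_pools(corpus, toy_engine())
  codes <- c("A", "C", "G", "U", "N", "R", "Y", "N", "N")
  for (rep in 1:200) {
    key <- sample(pools$key, 1)
    lens <- erd:::key_strand_lengths(key)
    is_stem <- startsWith(key, "STEM")
    mask <- if (is_stem) {
      c(paste(sample(c("N", "R", "Y"), lens[1], TRUE), collapse = ""),
        strrep("N", lens[2]))
    } else {
      vapply(lens, function(L) paste(sample(codes, L, TRUE), collapse = ""),
             character(1))
    }
    frag <- tryCatch(sample_fragment(pools, key, mask),
                     error = function(e) e)
    if (inherits(frag, "error")) {
      expect_match(conditionMessage(frag), "conflict")
      next
    }
    expect_equal(nchar(frag), lens, info = key)
    ok <- mapply(function(st, mk) {
      !nchar(st) || all(iupac_matches(strsplit(mk, "")[[1]],
                                      strsplit(st, "")[[1]]))
    }, frag, mask)
    expect_true(all(ok), info = key)
    if (is_stem) {
      k <- lens[1]
      s5 <- strsplit(frag[1], "")[[1]]; s3 <- strsplit(frag[2], "")[[1]]
      expect_true(all(erd:::bases_complementary(s5, rev(s3))), info = key)
    }
  }
})

test_that("pool serialisation round-trips, including empty segments", {
  pool <- tiny_pools(c("STEM/2", "MULTI/2:1,0,2", "HAIRPIN/3"),
                     list(c("GC", "GC"), c("A", "", "GU"), "AAA"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pools(pool, path)
  back <- read_pools(path)
  expect_equal(back$key, pool$key)
  expect_equal(back$strands, pool$strands)
  expect_error(read_pools(withr::local_tempfile(lines = "bogus")), "erd-pools")
})
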