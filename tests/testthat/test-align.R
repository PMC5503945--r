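test_that("banded aligner recovers known gap placements and scores", {
  al <- align_pair("ACGTTTACGT", "ACGTACGT")
  expect_equal(nchar(al$a), nchar(al$b))
  expect_identical(gsub("-", "", al$a), "ACGTTTACGT")
  expect_identical(gsub("-", "", al$b), "ACGTACGT")
  ident <- align_pair("ACGTACGT", "ACGTACGT",
                      scores = list(match = 2, mismatch = -3,
                                    gap_open = -5, gap_extend = -2))
  expect_equal(ident$score, 16)
  expect_identical(ident$a, ident$b)
})

test_that("unit-cost alignment equals Levenshtein distance (adist oracle)", {
  set.seed(21)
  for (rep in 1:20) {
    a <- random_dna(sample(10:120, 1))
    b <- corrupt_read(a, channel_params(p_sub = 0.1, p_ins = 0.05,
                                        p_del = 0.05, p_revcomp = 0))
    expect_equal(dnastore:::edit_distance(a, b),
                 as.integer(adist(a, b)))
  }
})

test_that("infix distance finds approximate matches inside longer texts", {
  set.seed(22)
  pat <- random_dna(16)
  text <- paste0(random_dna(50), pat, random_dna(50))
  expect_equal(dnastore:::cpp_infix_distance(pat, text), 0L)
  mutated <- pat
  substr(mutated, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(pat, 5, 5))[1]
  text2 <- paste0(random_dna(30), mutated, random_dna(30))
  expect_lte(dnastore:::cpp_infix_distance(pat, text2), 1L)
  # oracle: minimum adist over all substrings (short case)
  pat2 <- "ACGTAC"
  text3 <- random_dna(30)
  subs <- unlist(lapply(1:nchar(text3), function(i)
    substring(text3, i, i:nchar(text3))))
  expect_equal(dnastore:::cpp_infix_distance(pat2, text3),
               min(adist(pat2, subs)))
})
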