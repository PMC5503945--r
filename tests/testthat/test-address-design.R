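test_that("generated addresses satisfy balance, distance and correlation invariants", {
  a <- generate_addresses(17)
  expect_length(a, 17L)
  expect_true(all(nchar(a) == 16L))
  # both aligned 8-windows balanced (hence GC content 8 of 16)
  expect_true(all(vapply(a, function(s)
    length(check_balance(s)) == 0L, logical(1))))
  # exhaustive pairwise Hamming distance
  d <- utils::combn(17, 2, function(ix) hamming(a[ix[1]], a[ix[2]]))
  expect_gte(min(d), 8L)
  # weak autocorrelation: no prefix-suffix self overlap of length >= 4
  expect_true(all(vapply(a, function(s)
    correlation_overlap(s, s) < 4L, logical(1))))
  # no address is another's reverse complement, none is a palindrome
  rc <- vapply(a, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  expect_false(any(rc %in% a))
})

test_that("address generation is deterministic and capacity-limited", {
  expect_identical(generate_addresses(17), generate_addresses(17))
  cap <- address_capacity()
  expect_gte(cap, 17L)
  expect_error(generate_addresses(cap + 1L),
               class = "dnastore_capacity_error")
})

test_that("correlation_overlap finds the longest suffix-prefix match", {
  expect_equal(correlation_overlap("ACGT", "GTAC"), 2L)
  expect_equal(correlation_overlap("AAAA", "CCCC"), 0L)
  # proper overlaps only when comparing a sequence with itself: brute force
  s <- "ACGTACGT"
  brute <- 0L
  for (k in 1:7) {
    if (substr(s, 8 - k + 1, 8) == substr(s, 1, k)) brute <- k
  }
  expect_equal(correlation_overlap(s, s), brute)
  expect_equal(correlation_overlap(s, s), 4L)
})

test_that("screen_payload finds planted occurrences on both strands", {
  a <- generate_addresses(4)
  set.seed(7)
  payload <- paste0(random_dna(120), a[3], random_dna(60))
  hits <- screen_payload(payload, a)
  expect_true(any(hits$address == 3 & hits$position == 121 &
                    hits$strand == "+"))
  rc3 <- paste(rev(strsplit(chartr("ACGT", "TGCA", a[3]), "")[[1]]),
               collapse = "")
  hits_rc <- screen_payload(paste0(random_dna(10), rc3), a)
  expect_true(any(hits_rc$address == 3 & hits_rc$strand == "-"))
  expect_equal(nrow(screen_payload("", a)), 0L)
})

test_that("screen_payload agrees with a naive overlapping scan", {
  a <- generate_addresses(3)
  set.seed(11)
  for (rep in 1:10) {
    payload <- paste0(random_dna(40), sample(a, 1), random_dna(40),
                      sample(a, 1), random_dna(10))
    hits <- screen_payload(payload, a)
    fwd <- hits[hits$strand == "+", ]
    for (i in seq_along(a)) {
      expect_setequal(fwd$position[fwd$address == i],
                      naive_occurrences(a[i], payload))
    }
  }
})
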