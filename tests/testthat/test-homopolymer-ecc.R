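test_that("homopolymer parsing matches the worked examples", {
  p <- parse_homopolymers("AATCCCGA")
  expect_identical(p$symbols, c("A", "T", "C", "G", "A"))
  expect_identical(p$lengths, c(2L, 1L, 3L, 1L, 1L))
  expect_identical(parse_homopolymers("ATCCGA")$lengths,
                   c(1L, 1L, 2L, 1L, 1L))
  expect_identical(parse_homopolymers("G")$symbols, "G")
  expect_error(parse_homopolymers(""), class = "dnastore_empty_profile")
})

test_that("parse/expand roundtrip is the identity", {
  set.seed(5)
  for (rep in 1:25) {
    s <- random_dna(sample(1:200, 1))
    expect_identical(expand_homopolymers(parse_homopolymers(s)), s)
  }
})

test_that("checks depend on run lengths only", {
  p1 <- parse_homopolymers("AATCCCGA")
  p2 <- parse_homopolymers("TTGAAACT")  # same lengths, different symbols
  expect_identical(p2$lengths, p1$lengths)
  expect_identical(compute_checks(p1, t = 2), compute_checks(p2, t = 2))
  ones <- parse_homopolymers("ACGTACGT")
  expect_true(all(ones$lengths %% 3L == 1L))
})

test_that("the canonical double shortening is corrected exactly", {
  orig <- parse_homopolymers("AATCCCGA")
  chk <- compute_checks(orig, t = 2)
  obs <- parse_homopolymers("ATCCGA")
  expect_equal(sum(obs$lengths != orig$lengths), 2L)
  fixed <- correct_lengths(obs, chk)
  expect_identical(fixed$lengths, orig$lengths)
  # zero-syndrome case returns the input untouched
  expect_identical(correct_lengths(orig, chk)$lengths, orig$lengths)
})

test_that("every pattern of up to t bounded shortenings is corrected (exhaustive)", {
  lengths <- c(3L, 4L, 5L, 3L, 4L, 5L, 3L, 4L, 5L, 3L)
  symbols <- rep(c("A", "C"), 5L)
  orig <- structure(list(symbols = symbols, lengths = lengths),
                    class = "homopolymer_profile")
  t <- 3L
  chk <- compute_checks(orig, t = t)
  for (k in 1:t) {
    pos_sets <- utils::combn(10L, k)
    for (ci in seq_len(ncol(pos_sets))) {
      pos <- pos_sets[, ci]
      mags <- as.matrix(expand.grid(rep(list(1:2), k)))
      for (mi in seq_len(nrow(mags))) {
        obs <- orig
        obs$lengths[pos] <- obs$lengths[pos] - mags[mi, ]
        fixed <- correct_lengths(obs, chk)
        expect_identical(fixed$lengths, orig$lengths)
      }
    }
  }
})

test_that("corrections are asymmetric increments and failures are loud", {
  orig <- structure(list(symbols = rep(c("A", "G"), 5),
                         lengths = rep(4L, 10L)),
                    class = "homopolymer_profile")
  chk <- compute_checks(orig, t = 2)
  set.seed(9)
  for (rep in 1:20) {
    obs <- orig
    pos <- sample(10, 2)
    obs$lengths[pos] <- obs$lengths[pos] - sample(1:2, 2, replace = TRUE)
    fixed <- correct_lengths(obs, chk)
    expect_true(all(fixed$lengths >= obs$lengths))
  }
  # run-count mismatch signals a structure error
  shorter <- structure(list(symbols = orig$symbols[-1],
                            lengths = orig$lengths[-1]),
                       class = "homopolymer_profile")
  expect_error(correct_lengths(shorter, chk),
               class = "dnastore_structure_error")
  # more errors than the code can locate fails rather than miscorrecting
  chk1 <- compute_checks(orig, t = 1)
  obs <- orig
  obs$lengths[1:2] <- obs$lengths[1:2] - 1L
  expect_error(correct_lengths(obs, chk1),
               class = "dnastore_decoding_failure")
})

test_that("check redundancy for a block-sized profile stays within budget", {
  set.seed(13)
  prof <- parse_homopolymers(random_codeword_seq(123))
  chk <- compute_checks(prof, t = 3)
  # 2t field symbols of 11 bits each: a few dozen bits per 1,000-base block
  bits <- length(chk$residue_syndrome) * ceiling(log2(chk$prime))
  expect_lte(bits, 96)
})
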