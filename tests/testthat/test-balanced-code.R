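test_that("balanced 8-mer enumeration is complete, sorted and balanced", {
  words <- enumerate_balanced_8mers()
  # closed form: choose(8,4) GC-position patterns x 2^4 strong x 2^4 weak
  expect_equal(length(words), choose(8, 4) * 2^4 * 2^4)
  expect_equal(words[1], "AAAACCCC")
  expect_false(anyDuplicated(words) > 0)
  expect_identical(words, sort(words, method = "radix"))
  gc <- vapply(strsplit(words, ""), function(ch)
    sum(ch %in% c("G", "C")), integer(1))
  expect_true(all(gc == 4L))
})

test_that("encode/decode is a bijection on all 16,384 messages", {
  all_words <- encode_bits14(0:16383)
  expect_false(anyDuplicated(all_words) > 0)
  expect_identical(decode_codeword(all_words), 0:16383)
  expect_identical(encode_bits14(16383L), enumerate_balanced_8mers()[16384L])
})

test_that("out-of-range and malformed inputs are rejected", {
  expect_error(encode_bits14(-1L), "range")
  expect_error(encode_bits14(16384L), "range")
  expect_error(decode_codeword("AAAAAAAA"), class = "dnastore_constraint_error")
  expect_error(decode_codeword("AAAACCC"), class = "dnastore_constraint_error")
  # balanced but beyond the first 16,384 words: the lexicographic maximum
  expect_error(decode_codeword("TTTTGGGG"), class = "dnastore_out_of_codebook")
})

test_that("check_balance flags exactly the unbalanced aligned windows", {
  expect_identical(as.integer(check_balance("AAAACCCCAAAACCCC")), integer(0))
  expect_identical(as.integer(check_balance("AAAACCCCAAAAAAAA")), 2L)
  expect_identical(as.integer(check_balance("TTTTTTTTAAAACCCC")), 1L)
  # frame offset skips the address prefix
  expect_identical(
    as.integer(check_balance(paste0("AAAAAAAA", "AAAACCCC"), 8L)),
    integer(0))
  expect_warning(check_balance("AAAACCCCAAA"), "partial")
})

test_that("codeword concatenations stay balanced with bounded runs", {
  set.seed(41)
  for (rep in 1:20) {
    seq <- random_codeword_seq(sample(5:40, 1))
    expect_length(check_balance(seq), 0L)
    expect_lte(max(rle(strsplit(seq, "")[[1]])$lengths), 8L)
  }
})
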