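test_that("payload encoding meets the block arithmetic", {
  a <- generate_addresses(2)
  set.seed(61)
  bits <- sample(0:1, 1722, replace = TRUE)
  ep <- encode_payload(bits, a)
  expect_equal(nchar(ep$payload), 984L)
  tail_bits <- sample(0:1, 1512, replace = TRUE)
  expect_equal(nchar(encode_payload(tail_bits, a)$payload), 864L)
  expect_length(check_balance(ep$payload), 0L)
  expect_equal(nrow(screen_payload(ep$payload, a)), 0L)
})

test_that("tiny inputs encode to a single short block", {
  enc <- encode_file(as.raw(1L))
  expect_length(enc$blocks, 1L)
  expect_equal(nchar(enc$blocks[[1]]), 16L + 8L)  # address + one codeword
  expect_equal(enc$sidecar$bit_length, 8L)
})

test_that("encoded blocks satisfy balance and address avoidance", {
  set.seed(62)
  enc <- encode_file(random_bytes(500))
  addrs <- vapply(enc$sidecar$blocks, `[[`, character(1), "address")
  for (i in seq_along(enc$blocks)) {
    blk <- enc$blocks[[i]]
    expect_length(check_balance(substr(blk, 17, nchar(blk))), 0L)
    hits <- screen_payload(blk, addrs)
    own <- hits$address == i & hits$position == 1 & hits$strand == "+"
    expect_equal(nrow(hits[!own, ]), 0L)
  }
})

test_that("noiseless encode/decode is the identity across sizes", {
  set.seed(63)
  for (n in c(1L, 7L, 100L, 431L)) {
    data <- random_bytes(n)
    enc <- encode_file(data)
    pool <- sample_pool(enc$blocks, coverage = 5, noiseless_params())
    dec <- decode_file(pool, enc$sidecar)
    expect_identical(dec$bytes, data)
    expect_true(all(dec$report$ecc == "clean"))
  }
})

test_that("block count and lengths follow the layout rule", {
  set.seed(64)
  data <- random_bytes(431)  # 3448 bits -> 247 words -> 3 blocks (123,123,1)
  enc <- encode_file(data)
  n_words <- ceiling(ceiling(length(data) * 8 / 14))
  expect_length(enc$blocks, ceiling(n_words / 123))
  expect_true(all(nchar(enc$blocks[-length(enc$blocks)]) == 1000L))
})

test_that("files round-trip through FASTA, JSON sidecar and FASTQ", {
  set.seed(65)
  data <- random_bytes(150)
  enc <- encode_file(data)
  fa <- tempfile(fileext = ".fasta")
  sc <- tempfile(fileext = ".json")
  fq <- tempfile(fileext = ".fastq")
  write_blocks_fasta(enc$blocks, fa)
  write_sidecar(enc$sidecar, sc)
  pool <- sample_pool(read_blocks_fasta(fa), coverage = 5,
                      noiseless_params())
  write_pool_fastq(pool, fq)
  dec <- decode_file(fq, sc)
  expect_identical(dec$bytes, data)
})

test_that("a block with no reads raises an error naming its address", {
  set.seed(66)
  data <- random_bytes(400)
  enc <- encode_file(data)
  pool <- sample_pool(enc$blocks, coverage = 5, noiseless_params())
  pool <- pool[pool$source_block != 2L, ]
  addr2 <- enc$sidecar$blocks[[2]]$address
  err <- tryCatch(decode_file(pool, enc$sidecar), error = identity)
  expect_s3_class(err, "dnastore_block_missing")
  expect_match(conditionMessage(err), addr2, fixed = TRUE)
})

test_that("random access decodes single blocks consistently with the full decode", {
  set.seed(67)
  data <- random_bytes(400)
  enc <- encode_file(data)
  pool <- sample_pool(enc$blocks, coverage = 6, noiseless_params())
  full <- decode_file(pool, enc$sidecar)
  bits <- list()
  for (b in enc$sidecar$blocks) {
    ra <- random_access_decode(pool, b$address, enc$sidecar)
    expect_equal(ra$block, b$index)
    expect_lte(ra$reads_used, nrow(pool))
    bits[[b$index]] <- ra$bits
  }
  all_bits <- unlist(bits)[seq_len(enc$sidecar$bit_length)]
  expect_identical(dnastore:::bytes_from_bits(all_bits), full$bytes)
  expect_error(random_access_decode(pool, strrep("A", 16), enc$sidecar),
               "address")
})

test_that("base64 helpers invert each other", {
  set.seed(68)
  x <- random_bytes(99)
  expect_identical(from_base64(to_base64(x)), x)
})
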