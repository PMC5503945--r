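test_that("zero-noise channel is the identity and pools conserve counts", {
  set.seed(31)
  blocks <- vapply(1:5, function(i) random_codeword_seq(12), character(1))
  expect_identical(corrupt_read(blocks[1], noiseless_params()), blocks[1])
  pool <- sample_pool(blocks, coverage = 4, noiseless_params())
  expect_equal(nrow(pool), 20L)
  expect_equal(as.vector(table(pool$source_block)), rep(4L, 5))
  pool2 <- sample_pool(blocks, coverage = c(2L, 3L, 1L, 5L, 2L),
                       noiseless_params())
  expect_equal(as.integer(table(factor(pool2$source_block, 1:5))),
               c(2L, 3L, 1L, 5L, 2L))
})

test_that("the channel is deterministic under a fixed seed", {
  blocks <- replicate(3, random_codeword_seq(20))
  set.seed(77)
  p1 <- sample_pool(blocks, 10, channel_params())
  set.seed(77)
  p2 <- sample_pool(blocks, 10, channel_params())
  expect_identical(p1, p2)
})

test_that("parameter validation rejects impossible rates", {
  expect_error(channel_params(p_sub = 1.2))
  expect_error(channel_params(p_sub = 0.5, p_ins = 0.4, p_del = 0.2))
  expect_error(channel_params(hp_del_boost = 0.5))
})

test_that("empirical error rates match the channel calibration", {
  # each error type in isolation, where the binomial count is an exact
  # oracle (in a mixed channel the alignment tally is convention-bound:
  # a deletion plus a nearby insertion is the same edit as a substitution)
  set.seed(33)
  block <- random_codeword_seq(125)  # 1,000 bases
  n <- nchar(block)
  single <- list(
    sub = channel_params(p_sub = 0.085, p_ins = 0, p_del = 0,
                         hp_del_boost = 1, p_revcomp = 0.5),
    ins = channel_params(p_sub = 0, p_ins = 0.020, p_del = 0,
                         hp_del_boost = 1, p_revcomp = 0.5),
    del = channel_params(p_sub = 0, p_ins = 0, p_del = 0.045,
                         hp_del_boost = 1, p_revcomp = 0.5))
  for (op in names(single)) {
    pool <- sample_pool(block, coverage = 300, single[[op]])
    rates <- empirical_error_rates(pool, block)
    p <- switch(op, sub = 0.085, ins = 0.020, del = 0.045)
    se <- sqrt(n * p * (1 - p) / 300)
    expect_lt(abs(rates[[op]] - n * p), 3 * se + 1)
    # a small fraction of ops re-aligns as the complementary pair
    others <- setdiff(c("sub", "ins", "del"), op)
    expect_lt(rates[[others[1]]] + rates[[others[2]]], 0.15 * n * p + 1)
  }
  # the mixed channel at default-like rates carries the full error load
  pool <- sample_pool(block, coverage = 100,
                      channel_params(hp_del_boost = 1))
  rates <- empirical_error_rates(pool, block)
  total <- rates$sub + rates$ins + rates$del
  expect_gt(total, 100)   # ~150 edits/kb generated
  expect_lt(total, 200)
})

test_that("deletions concentrate in homopolymer runs when boosted", {
  set.seed(34)
  # alternate short and long runs so both classes are well represented
  block <- paste(rep(c("AACC", "GGGGTTTT"), 40), collapse = "")
  frac_in_runs <- function(boost) {
    params <- channel_params(p_sub = 0, p_ins = 0, p_del = 0.03,
                             hp_del_boost = boost, p_revcomp = 0)
    runs <- rle(strsplit(block, "")[[1]])
    run_len <- rep(runs$lengths, runs$lengths)
    dels_long <- 0; dels <- 0
    for (r in 1:150) {
      read <- corrupt_read(block, params)
      # count deletions per position via alignment
      al <- align_pair(read, block)
      gone <- strsplit(al$a, "")[[1]] == "-"
      pos <- cumsum(strsplit(al$b, "")[[1]] != "-")[gone]
      dels <- dels + length(pos)
      dels_long <- dels_long + sum(run_len[pos] >= 4)
    }
    dels_long / dels
  }
  expect_gt(frac_in_runs(1.6), frac_in_runs(1) + 0.05)
})

test_that("FASTQ round-trips through files with truth labels", {
  set.seed(35)
  blocks <- replicate(2, random_codeword_seq(15))
  pool <- sample_pool(blocks, 5, channel_params())
  fq <- tempfile(fileext = ".fastq")
  tsv <- tempfile(fileext = ".tsv")
  write_pool_fastq(pool, fq, truth_path = tsv)
  back <- read_pool_fastq(fq, truth_path = tsv)
  back <- back[match(pool$id, back$id), ]
  expect_identical(back$bases, pool$bases)
  expect_identical(back$source_block, pool$source_block)
  # fixed seed gives a byte-identical file
  set.seed(36)
  p1 <- sample_pool(blocks, 3, channel_params())
  f1 <- tempfile(); write_pool_fastq(p1, f1)
  set.seed(36)
  p2 <- sample_pool(blocks, 3, channel_params())
  f2 <- tempfile(); write_pool_fastq(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty reads are dropped with a warning at extreme deletion rates", {
  set.seed(37)
  params <- channel_params(p_sub = 0, p_ins = 0, p_del = 0.95,
                           hp_del_boost = 1, max_run_shortening = 100L,
                           p_revcomp = 0)
  expect_warning(pool <- sample_pool("ACGT", coverage = 40, params),
                 "empty")
  expect_true(all(nzchar(pool$bases)))
})
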