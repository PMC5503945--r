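test_that("msa presets satisfy the scoring invariants", {
  for (ps in msa_presets()) {
    expect_lte(ps$gap_open, 0)
    expect_lte(ps$gap_extend, 0)
    expect_lt(ps$mismatch, ps$match)
  }
})

test_that("demultiplexing assigns by exact address match only", {
  a <- generate_addresses(3)
  set.seed(51)
  flank <- random_dna(40)
  r_good <- paste0(flank, a[2], random_dna(40))
  mut <- a[2]
  substr(mut, 8, 8) <- setdiff(c("A", "C", "G", "T"), substr(mut, 8, 8))[1]
  r_mut <- paste0(flank, mut, random_dna(40))
  r_two <- paste0(a[1], random_dna(20), a[3])
  r_rc <- paste(rev(strsplit(chartr("ACGT", "TGCA",
                                    paste0(random_dna(10), a[1])), "")[[1]]),
                collapse = "")
  pool <- data.frame(id = c("good", "mut", "two", "rc"),
                     bases = c(r_good, r_mut, r_two, r_rc))
  dm <- demultiplex(pool, a)
  expect_identical(dm$by_address[[2]]$id, "good")
  expect_true(all(c("mut", "two") %in% dm$unassigned))
  # reverse-complement hit canonicalised to forward orientation
  expect_identical(dm$by_address[[1]]$id, "rc")
  expect_true(grepl(a[1], dm$by_address[[1]]$bases, fixed = TRUE))
})

test_that("consensus of clean reads reproduces the block", {
  set.seed(52)
  block <- random_codeword_seq(30)
  expect_identical(msa_consensus(rep(block, 5)), block)
  expect_error(msa_consensus(character(0)))
})

test_that("consensus of noisy reads beats the average read", {
  set.seed(53)
  block <- random_codeword_seq(60)
  reads <- replicate(15, corrupt_read(block, channel_params(p_revcomp = 0)))
  cons <- msa_consensus(reads, msa_presets()[[1]])
  d_cons <- dnastore:::edit_distance(cons, block)
  d_reads <- vapply(reads, function(r)
    dnastore:::edit_distance(r, block), integer(1))
  expect_lt(d_cons, mean(d_reads))
})

test_that("majority-homopolymer aggregation reproduces the worked example", {
  expect_identical(
    aggregate_majority_homopolymer(c("AAATTGCC", "AATTTGCA", "AAATTGC")),
    "AAATTGCA")
  expect_identical(aggregate_majority_homopolymer(c("AAT", "AAT", "AT")),
                   "AAT")
  expect_identical(aggregate_majority_homopolymer(rep("ACGGTT", 4)),
                   "ACGGTT")
  expect_error(aggregate_majority_homopolymer("ACGT"))
})

test_that("polishing is a fixed point on clean data and restores shortenings", {
  set.seed(54)
  addr <- generate_addresses(1)
  block <- paste0(addr, random_codeword_seq(20))
  reads <- rep(block, 30)
  pol <- iterative_polish(block, reads, address = addr)
  expect_identical(pol$bases, block)
  expect_equal(pol$iteration, 1L)
  expect_equal(pol$flagged_windows, 0L)
  # shorten one long payload run by one and let unanimous votes restore it
  prof <- parse_homopolymers(block)
  long <- which(prof$lengths >= 3 &
                  cumsum(prof$lengths) > nchar(addr) + 8)[1]
  expect_false(is.na(long))  # seed chosen so a long payload run exists
  prof$lengths[long] <- prof$lengths[long] - 1L
  damaged <- expand_homopolymers(prof)
  pol2 <- iterative_polish(damaged, reads, address = addr)
  expect_identical(pol2$bases, block)
})

test_that("polishing does not increase unbalanced windows or distance to truth", {
  set.seed(55)
  addr <- generate_addresses(1)
  block <- paste0(addr, random_codeword_seq(40))
  reads <- replicate(40, corrupt_read(block, channel_params(p_revcomp = 0)))
  est0 <- msa_consensus(reads[1:10])
  est0 <- dnastore:::anchor_address(est0, addr)
  pol <- iterative_polish(est0, reads, address = addr)
  unbal <- function(s) length(check_balance(substr(s, 17, nchar(s))))
  expect_lte(suppressWarnings(unbal(pol$bases)),
             suppressWarnings(unbal(est0)))
  expect_lte(dnastore:::edit_distance(pol$bases, block),
             dnastore:::edit_distance(est0, block))
})
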