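#' End-to-end codec
#'
#' Bytes are read MSB-first into a bit stream, consumed in 14-bit words and
#' grouped 123 words per block (1,722 bits, the final block shorter). Each
#' word maps to a GC-balanced 8-base codeword, so a full block carries a
#' 984-base payload behind its 16-base address: 1,000 bases storing 1,722
#' bits, a net density of 1.72 bits/base. Payload bits are whitened with a
#' deterministic salt-keyed mask and re-whitened (salt + 1) whenever any
#' address - or its reverse complement - would appear inside the encoded
#' block, which guarantees the address-avoidance constraint by
#' construction. Homopolymer checks over the full block string, the
#' addresses, salts and the true bit length travel in a versioned JSON
#' sidecar on classical media.
#'
#' @name codec_pipeline
NULL

#' Encode a group of bits into one screened payload
#'
#' Whitens `bits` with the salt-keyed mask, maps 14-bit words to balanced
#' codewords, and retries with incremented salts until the payload contains
#' no address (or reverse-complement) occurrence.
#'
#' @param bits 0/1 integer vector, length a multiple of 14.
#' @param addresses Character vector of all block addresses.
#' @param salt Starting salt (default 0).
#' @param max_tries Salt budget before giving up (default 256; in practice
#'   the first salt almost always screens clean).
#' @return List with `payload` (base string) and `salt` (the salt used).
#' @export
encode_payload <- function(bits, addresses, salt = 0L, max_tries = 256L) {
  stopifnot(length(bits) %% 14L == 0L, length(bits) > 0L)
  words <- words14_from_bits(bits)
  for (try in seq_len(max_tries)) {
    mask <- lehmer_words(length(words), salt)
    payload <- paste(encode_bits14(xor14(words, mask)), collapse = "")
    if (nrow(screen_payload(payload, addresses)) == 0L) {
      return(list(payload = payload, salt = as.integer(salt)))
    }
    salt <- salt + 1L
  }
  stop("encode_payload: no clean salt found within the retry budget",
       call. = FALSE)
}

#' Encode a byte stream into addressed DNA blocks
#'
#' @param data Raw vector of input bytes, or a file path to read.
#' @param t Homopolymer-check correction capability per block (default 3).
#' @param words_per_block 14-bit words per full block (default 123, i.e.
#'   1,722 bits and a 1,000-base block).
#' @return List with `blocks` (named character vector of block sequences,
#'   names `block_<i>|<address>`) and `sidecar` (a `dna_sidecar`).
#' @examples
#' \donttest{
#' enc <- encode_file(as.raw(sample(0:255, 3633, replace = TRUE)))
#' length(enc$blocks)        # 17
#' nchar(enc$blocks[[17]])   # 880
#' }
#' @export
encode_file <- function(data, t = 3L, words_per_block = 123L) {
  if (is.character(data)) {
    data <- readBin(data, "raw", n = file.info(data)$size)
  }
  stopifnot(is.raw(data), length(data) > 0L)
  bits <- bits_from_bytes(data)
  words <- words14_from_bits(bits)   # zero-padded to a 14-bit multiple
  nblocks <- ceiling(length(words) / words_per_block)
  addresses <- generate_addresses(nblocks)
  blocks <- character(nblocks)
  sc_blocks <- vector("list", nblocks)
  for (i in seq_len(nblocks)) {
    lo <- (i - 1L) * words_per_block + 1L
    hi <- min(i * words_per_block, length(words))
    block_bits <- bits_from_words14(words[lo:hi])
    salt <- 0L
    for (try in 1:256) {
      ep <- encode_payload(block_bits, addresses, salt = salt)
      block <- paste0(addresses[i], ep$payload)
      hits <- screen_payload(block, addresses)
      own <- hits$address == i & hits$position == 1L & hits$strand == "+"
      if (!nrow(hits[!own, , drop = FALSE]) &&
          approx_address_clean(block, addresses, i)) break
      if (try == 256L) {
        stop("encode_file: address screen unsatisfied for block ", i,
             call. = FALSE)
      }
      salt <- ep$salt + 1L
    }
    blocks[i] <- block
    chk <- compute_checks(parse_homopolymers(block), t = t)
    sc_blocks[[i]] <- list(index = i, address = addresses[i],
                           salt = ep$salt, expected_length = nchar(block),
                           check = unclass(chk))
  }
  names(blocks) <- sprintf("block_%03d|%s", seq_len(nblocks), addresses)
  sidecar <- structure(list(version = 1L, bit_length = length(bits),
                            t = as.integer(t),
                            words_per_block = as.integer(words_per_block),
                            address_len = 16L, blocks = sc_blocks),
                       class = "dna_sidecar")
  list(blocks = blocks, sidecar = sidecar)
}

# Reject blocks that contain a near-copy (edit distance <= max_dist) of
# any address: an approximate occurrence would systematically capture the
# block's reads during approximate demultiplexing. The block's own address
# prefix is excluded by scanning from its midpoint onward.
approx_address_clean <- function(block, addresses, own, max_dist = 2L) {
  tail_part <- substr(block, 9L, nchar(block))
  for (j in seq_along(addresses)) {
    pats <- c(addresses[j], revcomp(addresses[j]))
    region <- if (j == own) tail_part else block
    for (p in pats) {
      if (cpp_infix_distance(p, region) <= max_dist) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.dna_sidecar <- function(x, ...) {
  cat(sprintf("dna_sidecar v%d: %d blocks, %d data bits, t = %d\n",
              x$version, length(x$blocks), x$bit_length, x$t))
  invisible(x)
}

#' Sidecar and block FASTA I/O
#'
#' The sidecar is versioned JSON; blocks are plain FASTA with one record
#' per block (`block_<i>|<address>`).
#'
#' @param sidecar A `dna_sidecar`.
#' @param path File path.
#' @return The path (writers, invisibly) or the loaded object (readers).
#' @export
write_sidecar <- function(sidecar, path) {
  jsonlite::write_json(unclass(sidecar), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  x$blocks <- lapply(x$blocks, function(b) {
    b$check$residue_syndrome <- as.integer(unlist(b$check$residue_syndrome))
    b$check <- structure(b$check, class = "homopolymer_check")
    b
  })
  structure(x, class = "dna_sidecar")
}

#' @rdname write_sidecar
#' @param blocks Named character vector of block sequences.
#' @export
write_blocks_fasta <- function(blocks, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(blocks), path)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_blocks_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Base64 helpers
#'
#' Thin wrappers (workflow parity with image pipelines that embed binary
#' payloads as text); the codec itself treats inputs as opaque bytes.
#'
#' @param data Raw vector (`to_base64`) or base64 string (`from_base64`).
#' @export
to_base64 <- function(data) jsonlite::base64_enc(data)

#' @rdname to_base64
#' @export
from_base64 <- function(data) jsonlite::base64_dec(data)

# Locate the address at the front of an estimate and substitute the exact
# address sequence (it is side information from demultiplexing). Small
# semi-global DP: align the address against a prefix window of the
# estimate with a free end, replace the matched span.
anchor_address <- function(est, address) {
  n <- nchar(address)
  w <- substr(est, 1L, min(nchar(est), n + 12L))
  p <- seq_chars(address)
  tc <- seq_chars(w)
  m <- length(tc)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + (p[i] != tc[j]),
                         prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  jstar <- which.min(prev) - 1L
  paste0(address, substr(est, jstar + 1L, nchar(est)))
}

# Phase-1 estimate of one block: multi-preset MSA consensus on the
# high-quality (exact-address) reads, topped up to the MSA cap with the
# closest approximate-address reads when coverage is low; consensus
# sequences merged by majority homopolymer, exact address substituted.
phase1_estimate <- function(exact_reads, backup_reads, address, opts) {
  phase1 <- exact_reads
  fallback <- length(phase1) == 0L
  if (length(phase1) < opts$msa_cap) {
    extra <- setdiff(backup_reads, phase1)
    phase1 <- c(phase1, head(extra, opts$msa_cap - length(phase1)))
  }
  if (!length(phase1)) {
    stop(dnastore_condition("dnastore_block_missing", sprintf(
      "no reads assigned to address %s", address)))
  }
  consensuses <- vapply(msa_presets(), function(ps)
    msa_consensus(phase1, ps, cap = opts$msa_cap, band = opts$band),
    character(1))
  list(estimate = anchor_address(aggregate_majority_homopolymer(consensuses),
                                 address),
       consensuses = unname(consensuses),
       fallback = fallback)
}

hp_profile <- function(symbols, lengths) {
  structure(list(symbols = symbols, lengths = as.integer(lengths)),
            class = "homopolymer_profile")
}

# Decode the payload of a corrected block string into data bits, counting
# codeword failures (balanced 8-mers outside the codebook, or unbalanced
# windows). Zero bad words is part of the block certificate.
decode_block_words <- function(seq, address_len, expected_length, salt) {
  payload <- substr(seq, address_len + 1L, expected_length)
  n_words <- (expected_length - address_len) %/% 8L
  if (nchar(payload) < n_words * 8L) {
    payload <- paste0(payload, strrep("A", n_words * 8L - nchar(payload)))
  }
  codewords <- substring(payload, 8L * (seq_len(n_words) - 1L) + 1L,
                         8L * seq_len(n_words))
  bad_words <- 0L
  ranks <- vapply(codewords, function(cw) {
    tryCatch(decode_codeword(cw), error = function(e) {
      bad_words <<- bad_words + 1L
      0L
    })
  }, integer(1), USE.NAMES = FALSE)
  data_words <- xor14(ranks, lehmer_words(n_words, salt))
  list(bits = bits_from_words14(data_words), bad_words = bad_words)
}

# Repair for compensating +1/-1 length pairs (run count unchanged, so the
# structure repair does not trigger, and the lengthened run aliases the
# asymmetric code): undo a suspected +1 by decrementing one run; the
# remaining -1 is a plain shortening the checks correct. `verify` applies
# the rest of the block certificate.
repair_length_pairs <- function(profile, check, expected_length,
                                address_len = 16L, verify = NULL,
                                max_candidates = 6L) {
  out <- list()
  if (length(profile$lengths) != check$run_count) return(out)
  starts <- cumsum(c(1L, head(profile$lengths, -1L)))
  for (k in which(profile$lengths >= 2L & starts > address_len)) {
    p <- profile
    p$lengths[k] <- p$lengths[k] - 1L
    cp <- tryCatch(correct_lengths(p, check), error = function(e) NULL)
    if (!is.null(cp) && sum(cp$lengths) == expected_length &&
        (is.null(verify) || verify(cp))) {
      if (!any(vapply(out, identical, logical(1), y = cp))) {
        out[[length(out) + 1L]] <- cp
      }
      if (length(out) >= max_candidates) break
    }
  }
  out
}

# Structure repair for estimates the length code cannot express: a wrongly
# inserted base splits a run in two (run count +2), a wrongly deleted
# single-base run merges its neighbours (run count -2). Enumerate the
# candidate merges/splits consistent with the run-count deficit and let
# the homopolymer checks certify the right one: a certified candidate must
# reproduce the stored syndromes exactly and restore the expected length.
repair_run_structure <- function(profile, check, expected_length,
                                 address_len = 16L, verify = NULL,
                                 max_candidates = 6L) {
  n <- length(profile$lengths)
  delta <- check$run_count - n
  out <- list()
  try_profile <- function(p) {
    cp <- tryCatch({
      res <- correct_lengths(p, check)
      if (sum(res$lengths) == expected_length) res else NULL
    }, error = function(e) NULL)
    if (!is.null(cp) && (is.null(verify) || verify(cp)) &&
        !any(vapply(out, identical, logical(1), y = cp))) {
      out[[length(out) + 1L]] <<- cp
    }
    length(out) >= max_candidates
  }
  if (delta == 2L) {
    # a run was lost outright: split some run X_L into X_a Y X_c; the
    # checks are blind to Y's identity, so all symbols are candidates and
    # the caller arbitrates by read support
    starts <- cumsum(c(1L, head(profile$lengths, -1L)))
    for (k in which(profile$lengths >= 2L & starts > address_len)) {
      L <- profile$lengths[k]
      for (a in seq_len(L - 1L)) {
        for (y in setdiff(DNA_BASES, profile$symbols[k])) {
          p <- hp_profile(
            append(profile$symbols, c(y, profile$symbols[k]), after = k),
            append(profile$lengths, c(1L, L - a), after = k))
          p$lengths[k] <- a
          if (try_profile(p)) return(out)
        }
      }
    }
  } else if (delta == -2L) {
    # a spurious base split a run: merge X_a Y_1 X_c back to X_(a+c)
    for (i in which(profile$lengths == 1L)) {
      if (i <= 1L || i >= n) next
      if (profile$symbols[i - 1L] != profile$symbols[i + 1L]) next
      lengths <- profile$lengths
      lengths[i - 1L] <- lengths[i - 1L] + lengths[i + 1L]
      p <- hp_profile(profile$symbols[-c(i, i + 1L)],
                      lengths[-c(i, i + 1L)])
      if (try_profile(p)) return(out)
    }
  }
  out
}

# Polish one starting estimate and attempt homopolymer correction.
# `certified` means: the syndrome decoder succeeded, the corrected block
# has the expected length, and every payload window decodes to a codebook
# word -- a strong certificate, since the corrected residues must
# reproduce the stored checks exactly.
polish_and_correct <- function(start_est, polish_reads, address, check,
                               expected_length, salt, opts) {
  alen <- nchar(address)
  word_ok <- function(cp) {
    seq <- expand_homopolymers(cp)
    nchar(seq) == expected_length &&
      decode_block_words(seq, alen, expected_length, salt)$bad_words == 0L
  }
  pol <- iterative_polish(start_est, polish_reads, address_len = alen,
                          max_iters = opts$max_iters, band = opts$band,
                          address = address)
  est <- anchor_address(pol$bases, address)
  out <- list(pol = pol, est = est, corrected = NULL, status = "ok",
              certified = FALSE)
  corrected <- tryCatch(correct_lengths(parse_homopolymers(est), check),
                        error = function(e) {
                          out$status <<- class(e)[1L]
                          NULL
                        })
  if (!is.null(corrected) && identical(expand_homopolymers(corrected), est)) {
    out$status <- "clean"
  }
  if (is.null(corrected) || !word_ok(corrected)) {
    # the length code cannot express this error pattern (or the corrected
    # block fails the word check); retry on the pileup fixed point, then
    # attempt the targeted structure / length-pair repairs
    alt <- anchor_address(pol$pileup_bases, address)
    alt_fix <- tryCatch(correct_lengths(parse_homopolymers(alt), check),
                        error = function(e) NULL)
    if (!is.null(alt_fix) && word_ok(alt_fix)) {
      out$status <- paste0(out$status, "+pileup_retry")
      out$est <- alt
      corrected <- alt_fix
    } else {
      # several repairs can satisfy the check/length/word certificate
      # (the checks are blind to run symbols); arbitrate by read support
      pick_supported <- function(cands) {
        if (length(cands) == 1L) return(cands[[1L]])
        sub <- head(polish_reads, 12L)
        support <- vapply(cands, function(cp) {
          seq <- expand_homopolymers(cp)
          sum(vapply(sub, function(r)
            cpp_align_banded(r, seq, 2, -3, -5, -2, opts$band)$score,
            numeric(1)))
        }, numeric(1))
        cands[[which.max(support)]]
      }
      for (base_est in unique(c(est, alt))) {
        prof <- parse_homopolymers(base_est)
        cands <- repair_run_structure(prof, check, expected_length, alen,
                                      verify = word_ok)
        tag <- "+structure_repair"
        if (!length(cands)) {
          cands <- repair_length_pairs(prof, check, expected_length, alen,
                                       verify = word_ok)
          tag <- "+length_pair_repair"
        }
        if (length(cands)) {
          corrected <- pick_supported(cands)
          out$status <- paste0(out$status, tag)
          out$est <- base_est
          break
        }
      }
    }
  }
  out$corrected <- corrected
  out$certified <- !is.null(corrected) && word_ok(corrected)
  out
}

# Phase 2 (iterative polish) + homopolymer correction + codeword decoding
# of one block; shared by decode_file and random_access_decode. `starts`
# is a list of phase-1 estimates tried in order: the polish basin depends
# on the starting point, and the homopolymer checks certify success, so a
# failed correction triggers a restart from the next estimate.
finish_block <- function(starts, polish_reads, n_exact, fallback, address,
                         check, expected_length, salt, opts) {
  starts <- unique(vapply(starts, anchor_address, character(1),
                          address = address))
  attempt <- NULL
  certified <- NULL
  restarts <- 0L
  extra_after_cert <- 0L
  for (s in seq_along(starts)) {
    cand <- polish_and_correct(starts[s], polish_reads, address, check,
                               expected_length, salt, opts)
    if (is.null(attempt)) attempt <- cand
    if (cand$certified && is.null(certified)) {
      certified <- cand
      restarts <- s - 1L
    }
    # a certified estimate that still needed corrections may come from a
    # basin with residual consensus errors; briefly look for a clean one
    if (!is.null(certified)) {
      if (cand$certified && cand$status == "clean") {
        certified <- cand
        restarts <- s - 1L
        break
      }
      extra_after_cert <- extra_after_cert + 1L
      if (extra_after_cert > 2L) break
    }
  }
  if (!is.null(certified)) attempt <- certified
  if (!attempt$certified) {
    # all starts derived from the same phase-1 reads can share one wrong
    # basin; decorrelate by re-polishing with read subsets and from a
    # consensus of the next tier of reads (certificate-gated, so extra
    # attempts are safe)
    extras <- list()
    if (length(polish_reads) >= 20L) {
      half <- seq_along(polish_reads) %% 2L == 0L
      extras <- c(extras,
                  list(list(start = starts[1L], reads = polish_reads[half]),
                       list(start = starts[1L], reads = polish_reads[!half])))
    }
    if (length(polish_reads) > opts$msa_cap + 3L) {
      nxt <- polish_reads[seq(opts$msa_cap + 1L,
                              min(2L * opts$msa_cap, length(polish_reads)))]
      alt0 <- anchor_address(msa_consensus(nxt, msa_presets()[[1L]],
                                           cap = opts$msa_cap,
                                           band = opts$band), address)
      extras <- c(extras, list(list(start = alt0, reads = polish_reads)))
    }
    for (e in seq_along(extras)) {
      cand <- polish_and_correct(extras[[e]]$start, extras[[e]]$reads,
                                 address, check, expected_length, salt, opts)
      if (cand$certified) {
        attempt <- cand
        restarts <- length(starts) + e - 1L
        break
      }
    }
  }
  pol <- attempt$pol
  est <- attempt$est
  ecc_status <- attempt$status
  corrected <- attempt$corrected
  if (is.null(corrected)) corrected <- parse_homopolymers(est)
  seq <- expand_homopolymers(corrected)
  length_ok <- nchar(seq) == expected_length

  dw <- decode_block_words(seq, nchar(address), expected_length, salt)
  bits <- dw$bits
  bad_words <- dw$bad_words

  list(bits = bits, estimate = est, corrected = seq,
       report = data.frame(
         address = address, n_exact = n_exact,
         n_polish = length(polish_reads), phase1_fallback = fallback,
         iterations = pol$iteration, flagged_windows = pol$flagged_windows,
         restarts = restarts, ecc = ecc_status, length_ok = length_ok,
         bad_words = bad_words))
}

# Assign reads the address scan could not place by matching them against
# the phase-1 estimates. Cheap prescreen: three 16-mer probes drawn from
# each estimate's payload are scanned against the read (both orientations)
# by infix edit distance; the best block is then confirmed with one full
# banded alignment, and the read is kept only when that alignment looks
# like a genuine (noisy) copy of the block.
recruit_by_alignment <- function(pool, unassigned_ids, estimates, opts,
                                 min_identity = 0.3) {
  sel <- which(pool$id %in% unassigned_ids & nzchar(pool$bases))
  out <- lapply(seq_along(estimates), function(i) character(0))
  if (!length(sel)) return(out)
  scores <- msa_presets()[[1L]]
  probes <- lapply(estimates, function(e) {
    L <- nchar(e)
    at <- unique(pmax(17L, pmin(L - 15L, c(floor(L * 0.2), floor(L * 0.5),
                                           floor(L * 0.8)))))
    substring(e, at, at + 15L)
  })
  probe_vec <- unlist(probes)
  probe_block <- rep(seq_along(estimates), lengths(probes))
  fwd <- pool$bases[sel]
  rev <- revcomp(fwd)
  dfwd <- cpp_infix_distance_many(probe_vec, fwd)  # reads x probes
  drev <- cpp_infix_distance_many(probe_vec, rev)
  d <- pmin(dfwd, drev)
  score_block <- vapply(seq_along(estimates), function(i)
    rowSums(d[, probe_block == i, drop = FALSE]), numeric(length(sel)))
  score_block <- matrix(score_block, nrow = length(sel))
  for (r in seq_along(sel)) {
    i <- which.min(score_block[r, ])
    use_fwd <- sum(dfwd[r, probe_block == i]) <= sum(drev[r, probe_block == i])
    cand_seq <- if (use_fwd) fwd[r] else rev[r]
    sc <- cpp_align_banded(cand_seq, estimates[i], scores$match,
                           scores$mismatch, scores$gap_open,
                           scores$gap_extend, opts$band)$score
    if (sc >= min_identity * scores$match * nchar(cand_seq)) {
      out[[i]] <- c(out[[i]], cand_seq)
    }
  }
  out
}

decode_opts <- function(msa_cap = 15L, max_iters = 5L, band = 64L,
                        max_address_dist = 3L) {
  list(msa_cap = msa_cap, max_iters = max_iters, band = band,
       max_address_dist = max_address_dist)
}

#' Decode a read pool back to bytes
#'
#' Runs the full post-processing pipeline: exact-address demultiplexing,
#' multi-preset MSA consensus, majority-homopolymer aggregation, iterative
#' balance-constrained polishing (over reads recruited by approximate
#' address match), homopolymer error correction with the sidecar checks,
#' codeword decoding and de-whitening. Blocks with no exact-match reads
#' fall back to approximately matched reads for phase one; blocks with no
#' reads at all raise an error naming the address.
#'
#' @param pool Read pool data.frame (`id`, `bases`) or a FASTQ path.
#' @param sidecar A `dna_sidecar` (or path to one).
#' @param truth_blocks Optional character vector of the true block
#'   sequences; when given, per-block error counts are added to the report.
#' @param opts Decoder options from [decode_opts()].
#' @param progress Emit per-block progress on stderr.
#' @return List with `bytes` (raw vector), `report` (per-block data.frame),
#'   `estimates` (polished pre-correction estimates) and `blocks`
#'   (post-correction sequences).
#' @export
decode_file <- function(pool, sidecar, truth_blocks = NULL,
                        opts = decode_opts(), progress = FALSE) {
  if (is.character(pool)) pool <- read_pool_fastq(pool)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  addresses <- vapply(sidecar$blocks, `[[`, character(1), "address")
  exact <- demultiplex(pool, addresses)
  fuzzy <- fuzzy_demultiplex(pool, addresses, opts$max_address_dist)

  nb <- length(sidecar$blocks)
  # phase 1: per-block rough estimates from high-quality reads
  ph1 <- lapply(seq_len(nb), function(i) {
    phase1_estimate(exact$by_address[[i]]$bases,
                    fuzzy$by_address[[i]]$bases,
                    addresses[i], opts)
  })
  # recruit the reads the address scan could not place by aligning them to
  # the estimates (the re-alignment round of phase 2)
  recruits <- recruit_by_alignment(pool, fuzzy$unassigned,
                                   vapply(ph1, `[[`, character(1), "estimate"),
                                   opts)
  bits <- vector("list", nb)
  reports <- vector("list", nb)
  estimates <- character(nb)
  corrected <- character(nb)
  for (i in seq_len(nb)) {
    b <- sidecar$blocks[[i]]
    if (progress) message(sprintf("decoding block %d/%d (%s)", i, nb, b$address))
    polish_reads <- c(fuzzy$by_address[[i]]$bases, recruits[[i]])
    res <- finish_block(c(list(ph1[[i]]$estimate), as.list(ph1[[i]]$consensuses)),
                        polish_reads,
                        n_exact = nrow(exact$by_address[[i]]),
                        fallback = ph1[[i]]$fallback,
                        b$address, b$check, b$expected_length,
                        b$salt, opts)
    bits[[i]] <- res$bits
    estimates[i] <- res$estimate
    corrected[i] <- res$corrected
    rep_i <- cbind(block = i, res$report)
    if (!is.null(truth_blocks)) {
      pre <- count_align_ops(align_pair(res$estimate, truth_blocks[i]))
      rep_i$sub <- pre["sub"]; rep_i$ins <- pre["ins"]; rep_i$del <- pre["del"]
      rep_i$errors_pre_ecc <- sum(pre)
      rep_i$errors_final <- edit_distance(res$corrected, truth_blocks[i])
    }
    reports[[i]] <- rep_i
  }
  all_bits <- unlist(bits)[seq_len(sidecar$bit_length)]
  list(bytes = bytes_from_bits(all_bits),
       report = do.call(rbind, reports),
       estimates = estimates, blocks = corrected)
}

#' Randomly access a single block by address
#'
#' The in-silico analogue of PCR selection: only reads matching the one
#' address (exactly, or within the approximate-match threshold) are
#' selected and processed; the rest of the pool is only scanned for the
#' address, never aligned.
#'
#' @param pool Read pool data.frame or FASTQ path.
#' @param address The 16-base address of the block to decode.
#' @param sidecar A `dna_sidecar` (or path).
#' @param opts Decoder options from [decode_opts()].
#' @return List with `bits` (the block's data bits), `bytes` (those bits
#'   zero-padded into bytes), `n_bits`, `block` (index), `bit_offset`
#'   (position of the first bit in the file bit stream), and `reads_used`
#'   (number of reads selected and aligned).
#' @export
random_access_decode <- function(pool, address, sidecar,
                                 opts = decode_opts()) {
  if (is.character(pool)) pool <- read_pool_fastq(pool)
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)
  addresses <- vapply(sidecar$blocks, `[[`, character(1), "address")
  i <- match(address, addresses)
  if (is.na(i)) {
    stop("random_access_decode: address not present in sidecar", call. = FALSE)
  }
  b <- sidecar$blocks[[i]]
  # selection is competitive across all sidecar addresses (as PCR primers
  # would be), but only reads assigned to the requested address are ever
  # aligned or otherwise processed
  exact <- demultiplex(pool, addresses)$by_address[[i]]$bases
  polish <- fuzzy_demultiplex(pool, addresses,
                              opts$max_address_dist)$by_address[[i]]$bases
  ph1 <- phase1_estimate(exact, polish, address, opts)
  res <- finish_block(c(list(ph1$estimate), as.list(ph1$consensuses)),
                      polish, n_exact = length(exact),
                      fallback = ph1$fallback, address, b$check,
                      b$expected_length, b$salt, opts)
  words_before <- sum(vapply(sidecar$blocks[seq_len(i - 1L)], function(x)
    (x$expected_length - sidecar$address_len) %/% 8L, integer(1)))
  nb <- length(res$bits)
  pad <- (8L - nb %% 8L) %% 8L
  list(bits = res$bits,
       bytes = bytes_from_bits(c(res$bits, integer(pad))),
       n_bits = nb, block = i, bit_offset = words_before * 14L,
       reads_used = res$report$n_polish,
       report = res$report)
}
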