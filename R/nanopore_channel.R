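#' Nanopore-like read channel
#'
#' A positionwise substitution/insertion/deletion channel calibrated to the
#' per-read error loads of MinION-class sequencers (roughly 85
#' substitutions, 20 insertions and 45 deletions per 1,000-base read at the
#' defaults), with the one dependence that matters for this codec: the
#' per-base deletion probability grows geometrically with the length of the
#' homopolymer run containing the base (`hp_del_boost` per extra base), so
#' deletions concentrate in runs of length two or more, the error mode the
#' homopolymer checks are designed for.
#'
#' @name nanopore_channel
NULL

#' Channel parameters
#'
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   probabilities (defaults 0.085, 0.020, 0.045).
#' @param hp_del_boost Multiplicative deletion-rate factor per extra base of
#'   the containing homopolymer run (default 1.5; 1 disables the bias).
#' @param max_run_shortening Cap on deletions within any single run
#'   (default 2, the bounded-magnitude regime the checks correct).
#' @param p_revcomp Probability a read is emitted as the reverse complement
#'   (default 0.5).
#' @return A validated `channel_params` object.
#' @export
channel_params <- function(p_sub = 0.085, p_ins = 0.020, p_del = 0.045,
                           hp_del_boost = 1.5, max_run_shortening = 2L,
                           p_revcomp = 0.5) {
  probs <- c(p_sub, p_ins, p_del)
  stopifnot(all(probs >= 0), all(probs < 1), sum(probs) < 1,
            hp_del_boost >= 1, max_run_shortening >= 0L,
            p_revcomp >= 0, p_revcomp <= 1)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 hp_del_boost = hp_del_boost,
                 max_run_shortening = as.integer(max_run_shortening),
                 p_revcomp = p_revcomp),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf(paste0("nanopore channel: p_sub=%.3f p_ins=%.3f p_del=%.3f ",
                     "hp_del_boost=%.2f (<=%d del/run) p_revcomp=%.2f\n"),
              x$p_sub, x$p_ins, x$p_del, x$hp_del_boost,
              x$max_run_shortening, x$p_revcomp))
  invisible(x)
}

#' Corrupt one block into a noisy read
#'
#' Applies, per position: deletion with probability
#' `p_del * hp_del_boost^(run_length - 1)` (capped at 0.95, at most
#' `max_run_shortening` deletions per run), substitution to a uniformly
#' chosen different base with `p_sub`, and insertion of a uniform base after
#' the position with `p_ins`. Uses the R RNG: seed the session for
#' reproducibility. Orientation flips are applied by [sample_pool()], not
#' here.
#'
#' @param block A base string.
#' @param params A [channel_params()] object.
#' @return The corrupted base string (possibly empty at extreme rates).
#' @export
corrupt_read <- function(block, params) {
  chars <- seq_chars(block)
  n <- length(chars)
  runs <- rle(chars)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  run_len <- rep(runs$lengths, runs$lengths)

  p_del_i <- pmin(params$p_del * params$hp_del_boost^(run_len - 1L), 0.95)
  del <- stats::runif(n) < p_del_i
  if (any(del) && params$max_run_shortening >= 0L) {
    # keep at most max_run_shortening deletions per run (first ones win)
    excess <- unlist(lapply(split(which(del), run_id[del]), function(ix) {
      if (length(ix) > params$max_run_shortening)
        ix[-seq_len(params$max_run_shortening)] else integer(0)
    }), use.names = FALSE)
    del[excess] <- FALSE
  }
  keep <- chars[!del]
  m <- length(keep)
  if (m == 0L) return("")

  sub <- stats::runif(m) < params$p_sub
  if (any(sub)) {
    keep[sub] <- vapply(keep[sub], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }

  ins <- stats::runif(m) < params$p_ins
  if (any(ins)) {
    pieces <- keep
    pieces[ins] <- paste0(keep[ins], sample(DNA_BASES, sum(ins), replace = TRUE))
    return(paste(pieces, collapse = ""))
  }
  paste(keep, collapse = "")
}

#' Sample a noisy read pool from a set of blocks
#'
#' Emits `coverage` reads per block (a scalar or one count per block),
#' flips each to the reverse complement with probability `p_revcomp`, drops
#' empty reads with a warning, and shuffles the pool. Truth labels
#' (`source_block`, `strand`) are retained for evaluation only; they are
#' not written to FASTQ.
#'
#' @param blocks Character vector of block sequences.
#' @param coverage Reads per block: scalar or vector of `length(blocks)`.
#' @param params A [channel_params()] object.
#' @return A data.frame with columns `id`, `bases`, `source_block`,
#'   `strand`.
#' @export
sample_pool <- function(blocks, coverage, params = channel_params()) {
  stopifnot(length(blocks) >= 1L, all(coverage >= 1L))
  coverage <- rep_len(as.integer(coverage), length(blocks))
  total <- sum(coverage)
  src <- rep(seq_along(blocks), coverage)
  bases <- character(total)
  for (k in seq_len(total)) {
    bases[k] <- corrupt_read(blocks[src[k]], params)
  }
  flip <- stats::runif(total) < params$p_revcomp
  bases[flip] <- revcomp(bases[flip])
  pool <- data.frame(id = sprintf("read_%05d", seq_len(total)),
                     bases = bases,
                     source_block = src,
                     strand = ifelse(flip, "-", "+"))
  empty <- !nzchar(pool$bases)
  if (any(empty)) {
    warning(sprintf("sample_pool: dropping %d empty read(s)", sum(empty)),
            call. = FALSE)
    pool <- pool[!empty, , drop = FALSE]
  }
  pool[sample.int(nrow(pool)), , drop = FALSE]
}

#' Write / read a pool as FASTQ
#'
#' Four-line FASTQ records with constant Sanger qualities (`I`). Truth
#' labels can be saved to an optional side TSV and rejoined on read.
#'
#' @param pool A read pool data.frame (`id`, `bases`, optionally
#'   `source_block`, `strand`).
#' @param path Output FASTQ path.
#' @param truth_path Optional TSV path for the truth labels.
#' @return `path`, invisibly.
#' @export
write_pool_fastq <- function(pool, path, truth_path = NULL) {
  rec <- rbind(paste0("@", pool$id),
               pool$bases,
               "+",
               vapply(nchar(pool$bases), function(n)
                 strrep("I", n), character(1)))
  writeLines(as.vector(rec), path)
  if (!is.null(truth_path)) {
    utils::write.table(pool[, intersect(c("id", "source_block", "strand"),
                                        names(pool))],
                       truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pool_fastq
#' @export
read_pool_fastq <- function(path, truth_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  pool <- data.frame(id = sub("\\s.*$", "", names(seqs)),
                     bases = as.character(seqs))
  if (!is.null(truth_path)) {
    truth <- utils::read.table(truth_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    pool <- merge(pool, truth, by = "id", all.x = TRUE, sort = FALSE)
  }
  rownames(pool) <- NULL
  pool
}

#' Empirical per-block error rates of a pool
#'
#' Aligns each read back to its source block (affine-gap, banded) and
#' tallies substitutions, insertions and deletions, mirroring the usual
#' per-read summary of sequencing runs.
#'
#' @param pool A read pool with truth labels (`source_block`; `strand` used
#'   to restore orientation when present).
#' @param truth_blocks Character vector of the true block sequences.
#' @return A data.frame with one row per block: `block`, `n_reads`, and the
#'   mean per-read `sub`, `ins`, `del` counts.
#' @export
empirical_error_rates <- function(pool, truth_blocks) {
  if (is.null(pool$source_block) || anyNA(pool$source_block)) {
    stop("empirical_error_rates: pool lacks truth labels", call. = FALSE)
  }
  scores <- msa_presets()[[1L]]
  out <- lapply(seq_along(truth_blocks), function(b) {
    sel <- pool[pool$source_block == b, , drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(block = b, n_reads = 0L, sub = NA_real_,
                        ins = NA_real_, del = NA_real_))
    }
    reads <- sel$bases
    if (!is.null(sel$strand)) {
      reads[sel$strand == "-"] <- revcomp(reads[sel$strand == "-"])
    }
    alns <- align_many(reads, truth_blocks[b], scores)
    ops <- t(vapply(alns, count_align_ops, numeric(3)))
    data.frame(block = b, n_reads = nrow(sel), sub = mean(ops[, "sub"]),
               ins = mean(ops[, "ins"]), del = mean(ops[, "del"]))
  })
  do.call(rbind, out)
}
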