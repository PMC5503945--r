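#' Consensus construction and iterative polishing
#'
#' Decoding runs in two phases. Phase one builds a rough estimate of each
#' block: reads containing an exact 16-base address match are selected
#' (high-quality reads), aligned with an in-package progressive MSA under
#' four scoring presets, and the per-preset consensus sequences are merged
#' run-by-run into a majority-homopolymer aggregate. Phase two iteratively
#' re-aligns reads to the current estimate, recomputes a plurality
#' consensus, and then revises homopolymer run lengths by majority vote
#' constrained so that every completed aligned 8-base window of the payload
#' stays GC-balanced (runs whose windows cannot be balanced are flagged,
#' never silently forced). The remaining errors are, by construction,
#' bounded-magnitude run shortenings, which [correct_lengths()] removes.
#'
#' @name consensus_pipeline
NULL

#' MSA scoring presets
#'
#' Four affine-gap scoring parameterisations of the in-package progressive
#' aligner. Running all four and aggregating their consensus sequences
#' plays the role of running several external MSA tools: each preset makes
#' different gap-placement mistakes, and the majority-homopolymer aggregate
#' averages them out.
#'
#' @return Named list of presets, each with `name`, `match`, `mismatch`,
#'   `gap_open`, `gap_extend`, and the guide `order` policy.
#' @export
msa_presets <- function() {
  mk <- function(name, match, mismatch, gap_open, gap_extend) {
    stopifnot(gap_open <= 0, gap_extend <= 0, mismatch < match)
    list(name = name, match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend, order = "identity")
  }
  list(
    balanced       = mk("balanced", 2, -3, -5, -2),
    indel_tolerant = mk("indel_tolerant", 2, -4, -3, -1),
    strict         = mk("strict", 5, -9, -12, -3),
    lenient        = mk("lenient", 1, -1, -2, -1)
  )
}

#' Demultiplex a read pool by exact address match
#'
#' A read is assigned to an address if and only if the 16-mer occurs
#' exactly in the read or in its reverse complement (reverse-complement
#' hits are canonicalised to forward orientation). Reads matching zero or
#' two or more distinct addresses are set aside.
#'
#' @param pool Read pool data.frame (`id`, `bases`).
#' @param addresses Character vector of pairwise-distinct addresses.
#' @return List with `by_address` (one data.frame of `id`, `bases` per
#'   address, canonical orientation) and `unassigned` (ids set aside).
#' @export
demultiplex <- function(pool, addresses) {
  stopifnot(!anyDuplicated(addresses))
  n <- nrow(pool)
  rc <- revcomp(pool$bases)
  fwd <- vapply(addresses, function(a) grepl(a, pool$bases, fixed = TRUE),
                logical(n))
  rev <- vapply(addresses, function(a) grepl(a, rc, fixed = TRUE),
                logical(n))
  fwd <- matrix(fwd, nrow = n)
  rev <- matrix(rev, nrow = n)
  hit <- fwd | rev
  nhits <- rowSums(hit)
  by_address <- lapply(seq_along(addresses), function(i) {
    sel <- which(nhits == 1L & hit[, i])
    if (!length(sel)) return(data.frame(id = character(0), bases = character(0)))
    data.frame(id = pool$id[sel],
               bases = ifelse(fwd[sel, i], pool$bases[sel], rc[sel]))
  })
  list(by_address = by_address,
       unassigned = pool$id[nhits != 1L])
}

#' Demultiplex by approximate address match
#'
#' Assigns each read to the address with the smallest infix edit distance
#' (over both orientations), provided that distance is at most `max_dist`
#' and the minimiser is unique. Used to recruit additional reads for the
#' polishing phase, mirroring the re-alignment of the whole pool against
#' the phase-one estimates; exact-match reads are a subset (distance 0).
#'
#' @param pool Read pool data.frame.
#' @param addresses Character vector of addresses.
#' @param max_dist Maximum edit distance of the best address match
#'   (default 3; addresses are pairwise Hamming distance >= 8 apart and
#'   encoded payloads carry no near-copy of any address within distance 2,
#'   so matches at distance 3 are still informative).
#' @return Same structure as [demultiplex()].
#' @export
fuzzy_demultiplex <- function(pool, addresses, max_dist = 3L) {
  n <- nrow(pool)
  rc <- revcomp(pool$bases)
  k <- length(addresses)
  df <- cpp_infix_distance_many(addresses, pool$bases)
  dr <- cpp_infix_distance_many(addresses, rc)
  d <- pmin(df, dr)
  best <- apply(d, 1L, min)
  nbest <- rowSums(d == best)
  assign_to <- ifelse(best <= max_dist & nbest == 1L,
                      apply(d, 1L, which.min), NA_integer_)
  by_address <- lapply(seq_len(k), function(i) {
    sel <- which(!is.na(assign_to) & assign_to == i)
    if (!length(sel)) {
      return(data.frame(id = character(0), bases = character(0),
                        dist = integer(0)))
    }
    out <- data.frame(id = pool$id[sel],
                      bases = ifelse(df[sel, i] <= dr[sel, i],
                                     pool$bases[sel], rc[sel]),
                      dist = d[sel, i])
    out[order(out$dist, out$id), , drop = FALSE]
  })
  list(by_address = by_address,
       unassigned = pool$id[is.na(assign_to)])
}

# Progressive MSA: repeatedly align the next sequence against the current
# per-column representative and thread it into the column matrix.
# Sequences whose alignment score falls below `min_identity` of a perfect
# self-match are outliers (e.g. reads captured by a spurious address
# match) and are left out of the alignment. Returns a character matrix
# (rows = sequences kept, "-" for gaps).
progressive_msa <- function(seqs, preset, band = 64L, min_identity = 0.25) {
  stopifnot(length(seqs) >= 1L)
  mat <- matrix(seq_chars(seqs[1L]), nrow = 1L)
  if (length(seqs) == 1L) return(mat)
  for (s in seqs[-1L]) {
    rep_str <- paste(column_representative(mat), collapse = "")
    aln <- cpp_align_banded(s, rep_str, preset$match, preset$mismatch,
                            preset$gap_open, preset$gap_extend, band)
    if (aln$score < min_identity * preset$match * nchar(s)) next
    ag <- seq_chars(aln$a)
    bg <- seq_chars(aln$b)
    keep <- bg != "-"
    col_of <- cumsum(keep)
    newmat <- matrix("-", nrow(mat), length(bg))
    newmat[, keep] <- mat[, col_of[keep], drop = FALSE]
    mat <- rbind(newmat, ag)
  }
  mat
}

# Plurality non-gap character per column (ties broken A < C < G < T)
base_counts_by_column <- function(mat) {
  vapply(DNA_BASES, function(b) colSums(mat == b), numeric(ncol(mat)))
}

column_representative <- function(mat) {
  counts <- matrix(base_counts_by_column(mat), ncol = 4L)
  DNA_BASES[max.col(counts, ties.method = "first")]
}

# Per-column plurality call over {A,C,G,T,-}; a column is dropped when the
# gap count strictly exceeds the best base count (ties keep the base:
# the channel is deletion-dominant).
call_columns <- function(mat) {
  counts <- matrix(base_counts_by_column(mat), ncol = 4L)
  gaps <- colSums(mat == "-")
  best <- max.col(counts, ties.method = "first")
  bestn <- counts[cbind(seq_len(nrow(counts)), best)]
  paste(DNA_BASES[best][gaps <= bestn], collapse = "")
}

#' Consensus of a read set via progressive MSA
#'
#' Aligns up to `cap` reads (those closest in length to the read-length
#' median, a proxy for read quality; deterministic tie-break on input
#' order) with the progressive aligner under `preset`, then calls the
#' per-column plurality, dropping columns where the gap is the plurality.
#'
#' @param reads Character vector of reads in canonical orientation.
#' @param preset One element of [msa_presets()].
#' @param cap Maximum number of reads entering the alignment (default 15).
#' @param band Aligner band half-width.
#' @return The consensus sequence (single string).
#' @export
msa_consensus <- function(reads, preset = msa_presets()[[1L]], cap = 15L,
                          band = 64L) {
  if (!length(reads)) stop("msa_consensus: empty read set", call. = FALSE)
  if (length(reads) > cap) {
    ord <- order(abs(nchar(reads) - median(nchar(reads))), seq_along(reads))
    reads <- reads[ord[seq_len(cap)]]
  }
  mat <- progressive_msa(reads, preset, band)
  call_columns(mat)
}

# Run decomposition of one gapped MSA row: per run, the symbol, length and
# the column interval it occupies.
row_runs <- function(row_chars) {
  nongap <- which(row_chars != "-")
  if (!length(nongap)) {
    return(data.frame(symbol = character(0), length = integer(0),
                      start = integer(0), end = integer(0)))
  }
  r <- rle(row_chars[nongap])
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(symbol = r$values, length = r$lengths,
             start = nongap[starts], end = nongap[ends])
}

#' Majority-homopolymer aggregation of consensus sequences
#'
#' Combines two or more consensus sequences of the same block run-by-run:
#' the inputs are aligned (internal progressive MSA at a fixed preset) and
#' parsed into homopolymer runs; runs are matched across inputs by symbol
#' and overlapping column span. Each matched run slot contributes a run to
#' the aggregate whenever it appears in at least one input, with length
#' equal to the modal length over the inputs containing it (ties go to the
#' longer length, since the channel predominantly deletes).
#'
#' @param consensuses Character vector of at least two sequences.
#' @return The aggregate consensus sequence.
#' @examples
#' aggregate_majority_homopolymer(c("AAATTGCC", "AATTTGCA", "AAATTGC"))
#' # "AAATTGCA"
#' @export
aggregate_majority_homopolymer <- function(consensuses) {
  if (length(consensuses) < 2L) {
    stop("aggregate_majority_homopolymer: need at least two consensus sequences",
         call. = FALSE)
  }
  mat <- progressive_msa(consensuses, msa_presets()[[1L]])
  runs <- do.call(rbind, lapply(seq_len(nrow(mat)), function(r) {
    cbind(row = r, row_runs(mat[r, ]))
  }))
  runs <- runs[order(runs$start, runs$row), , drop = FALSE]
  n <- nrow(runs)
  assigned <- logical(n)
  slot_symbol <- character(0)
  slot_length <- integer(0)
  slot_start <- integer(0)
  for (k in seq_len(n)) {
    if (assigned[k]) next
    sym <- runs$symbol[k]
    members <- k
    rows_in <- runs$row[k]
    s_end <- runs$end[k]
    assigned[k] <- TRUE
    j <- k + 1L
    while (j <= n && runs$start[j] <= s_end) {  # runs sorted by start
      if (!assigned[j] && runs$symbol[j] == sym &&
          !(runs$row[j] %in% rows_in)) {
        members <- c(members, j)
        rows_in <- c(rows_in, runs$row[j])
        s_end <- max(s_end, runs$end[j])
        assigned[j] <- TRUE
      }
      j <- j + 1L
    }
    lens <- runs$length[members]
    tab <- table(lens)
    modal <- as.integer(names(tab)[tab == max(tab)])
    slot_symbol <- c(slot_symbol, sym)
    slot_length <- c(slot_length, max(modal))  # tie -> longer
    slot_start <- c(slot_start, min(runs$start[members]))
  }
  ord <- order(slot_start)
  paste(rep(slot_symbol[ord], slot_length[ord]), collapse = "")
}

# ---- iterative polishing ----

# Pileup of reads against an estimate: plurality base (or deletion) per
# estimate position, plus majority insertions between positions (an
# insertion is made when more than half the reads insert anything at the
# anchor; the modal inserted string is used). Base and deletion votes are
# tallied over `alns`; insertion votes over `ins_alns` only -- different
# scoring presets may anchor the same insertion at different positions,
# and a split tally across presets would deadlock below the majority
# threshold, so insertions come from one consistent aligner.
pileup_consensus <- function(est, alns, ins_alns = alns) {
  L <- nchar(est)
  nreads <- length(ins_alns)
  base_counts <- matrix(0L, 5L, L)  # A C G T -
  ins_tab <- vector("list", L + 1L) # anchor 0..L
  for (aln in alns) {
    ag <- seq_chars(aln$a)
    bg <- seq_chars(aln$b)
    keep <- bg != "-"
    col <- cumsum(keep)
    # base / deletion calls at estimate positions
    pos <- col[keep]
    ch <- match(ag[keep], DNA_BASES, nomatch = 5L)
    base_counts[cbind(ch, pos)] <- base_counts[cbind(ch, pos)] + 1L
  }
  for (aln in ins_alns) {
    ag <- seq_chars(aln$a)
    bg <- seq_chars(aln$b)
    keep <- bg != "-"
    col <- cumsum(keep)
    # insertion strings keyed by anchor position
    if (any(!keep)) {
      anchors <- col[!keep]
      chars <- ag[!keep]
      sp <- split(chars, anchors)
      for (nm in names(sp)) {
        a <- as.integer(nm) + 1L
        str <- paste(sp[[nm]], collapse = "")
        ins_tab[[a]] <- c(ins_tab[[a]], str)
      }
    }
  }
  est_chars <- seq_chars(est)
  out <- character(L + 1L)
  for (a in seq_len(L + 1L)) {
    piece <- ""
    if (!is.null(ins_tab[[a]]) && length(ins_tab[[a]]) > nreads / 2) {
      tab <- table(ins_tab[[a]])
      piece <- names(tab)[which.max(tab)]
    }
    out[a] <- piece
  }
  body <- character(L)
  for (j in seq_len(L)) {
    counts <- base_counts[, j]
    if (sum(counts) == 0L) { body[j] <- est_chars[j]; next }
    bestbase <- which.max(counts[1:4])
    if (counts[5L] > counts[bestbase]) body[j] <- ""
    else body[j] <- DNA_BASES[bestbase]
  }
  paste0(paste0(out[seq_len(L)], body, collapse = ""), out[L + 1L])
}

# Per-run length votes from alignments of reads to the estimate: how many
# bases of the run's symbol each read carries across the run's span
# (aligned matches plus insertions anchored inside the run or at its
# boundaries). runs: data.frame(symbol, length, start, end) in estimate
# coordinates, contiguous. Returns a reads x runs integer matrix.
run_length_votes <- function(runs, alns) {
  nruns <- nrow(runs)
  votes <- matrix(0L, length(alns), nruns)
  first_start <- runs$start[1L]
  for (r in seq_along(alns)) {
    aln <- alns[[r]]
    ag <- seq_chars(aln$a)
    bg <- seq_chars(aln$b)
    keep <- bg != "-"
    col <- cumsum(keep)
    pos <- col[keep]       # estimate position of each aligned pair
    rb <- ag[keep]         # read char there ("-" = deletion)
    # aligned matches: run index of each estimate position
    inr <- pos >= first_start
    ridx <- findInterval(pos[inr], runs$start)
    hit <- rb[inr] == runs$symbol[ridx]
    v <- tabulate(ridx[hit], nbins = nruns)
    # insertions: anchor a sits inside run j (a in [start_j, end_j]) or at
    # the left boundary of run j+1 (a == end_j); the inserted character
    # decides which neighbour it extends (adjacent symbols differ)
    if (any(!keep)) {
      a <- col[!keep]
      ch <- ag[!keep]
      j <- findInterval(a, runs$start)  # containing run, 0 before first
      end_j <- rep(NA_integer_, length(j))
      end_j[j >= 1L] <- runs$end[j[j >= 1L]]
      sym_j <- rep(NA_character_, length(j))
      sym_j[j >= 1L] <- runs$symbol[j[j >= 1L]]
      sym_next <- rep(NA_character_, length(j))
      has_next <- j + 1L <= nruns
      sym_next[has_next] <- runs$symbol[j[has_next] + 1L]
      own <- !is.na(sym_j) & ch == sym_j
      at_boundary <- (j == 0L & a == first_start - 1L) |
        (!is.na(end_j) & a == end_j)
      nxt <- has_next & at_boundary & !is.na(sym_next) & ch == sym_next
      v <- v + tabulate(j[own], nbins = nruns) +
        tabulate(j[nxt] + 1L, nbins = nruns)
    }
    votes[r, ] <- v
  }
  votes
}

# Balance-constrained run-length assignment: choose one candidate length
# per payload run maximising total vote support, with a penalty for every
# completed aligned 8-window whose GC count is not 4. The penalty equals
# one full unanimous vote, so restoring balance is always preferred over
# vote-count ties, but a window that could only be balanced by overriding
# more than a read-set's worth of votes (i.e. a structural error the
# length code cannot express) is flagged instead of forced. Exact dynamic
# program over (position mod 8, GC count of the partial window).
# Returns list(lengths, flags = number of unbalanced windows at optimum).
balance_dp <- function(runs, votes, window = 8L, target_gc = 4L,
                       pos0 = 0L, gc0 = 0L) {
  BIG <- max(10, 2 * nrow(votes))   # log-likelihood units
  nruns <- nrow(runs)
  # runs$fixed (when present) counts leading bases that belong to the
  # address prefix: they are kept but do not advance the payload window
  fixed <- if (is.null(runs$fixed)) integer(nruns) else runs$fixed
  # candidate lengths are scored by log-likelihood under an asymmetric
  # per-base error model (deletions dominate and concentrate in long runs,
  # insertions are rare): a long run whose votes are spread over
  # {c, c-1, c-2} is still best explained by the full length c, whereas a
  # plain vote majority would systematically shorten it. The deletion rate
  # grows with run length, mirroring the homopolymer bias of nanopore
  # channels (same defaults as [channel_params()]).
  del_rate <- function(cc) pmin(0.045 * 1.5^(cc - 1), 0.5)
  log_ins <- log(0.02)
  cand <- vector("list", nruns)
  weight <- vector("list", nruns)
  for (k in seq_len(nruns)) {
    L <- runs$length[k]
    vs <- votes[, k]
    cands <- sort(unique(c(L, L + 1L,
                           vs[vs >= max(1L, L - 2L) & vs <= L + 2L])))
    cands <- cands[cands >= max(1L, fixed[k])]
    cand[[k]] <- cands
    weight[[k]] <- vapply(cands, function(cc) {
      d <- cc - vs
      lp <- ifelse(d >= 0,
                   stats::dbinom(pmin(d, cc), cc, del_rate(cc), log = TRUE),
                   -d * log_ins)
      sum(pmax(lp, -12))
    }, numeric(1))
  }
  cpp_balance_dp(cand, lapply(weight, as.numeric),
                 runs$symbol %in% c("G", "C"), as.integer(fixed),
                 as.integer(window), as.integer(target_gc), BIG,
                 as.integer(pos0), as.integer(gc0))
}

#' Iteratively polish a consensus estimate against the reads
#'
#' Each iteration re-aligns every read to the current estimate (banded
#' affine-gap alignment) and recomputes a plurality pileup consensus; at
#' the fixed point (or after `max_iters` iterations) homopolymer run
#' lengths of the payload are revised by vote majority constrained to keep
#' every completed aligned 8-base window GC-balanced. Windows that no
#' supported length assignment can balance are flagged, not forced.
#'
#' @param estimate Initial consensus sequence (string or
#'   `consensus_estimate`).
#' @param reads Character vector of reads in canonical orientation.
#' @param address_len Length of the address prefix excluded from the
#'   balance frame (default 16).
#' @param max_iters Maximum pileup iterations (default 5).
#' @param preset Aligner scoring preset.
#' @param band Aligner band half-width (default 64).
#' @param address Optional known address string; when given, the estimate's
#'   prefix is pinned to it after every pileup round (it is side
#'   information from demultiplexing) so the payload window frame cannot
#'   drift, and `address_len` is taken from it.
#' @return A `consensus_estimate`: list with `bases`, `pileup_bases` (the
#'   fixed point before run-length refinement), `run_support` (chosen
#'   length and vote count per payload run), `iteration`, and
#'   `flagged_windows`.
#' @export
iterative_polish <- function(estimate, reads, address_len = 16L,
                             max_iters = 5L, preset = msa_presets()[[1L]],
                             band = 64L, address = NULL) {
  est <- if (inherits(estimate, "consensus_estimate")) estimate$bases else estimate
  stopifnot(nzchar(est), length(reads) >= 1L)
  if (!is.null(address)) address_len <- nchar(address)
  iter <- 0L
  pileup_est <- est
  support <- data.frame(symbol = character(0), length = integer(0),
                        votes = numeric(0))
  flags <- 0L
  # outer loop: (pileup to fixed point, then balance-constrained length
  # revision), repeated until the combined operator is stable -- the length
  # revision can unmask base-level errors the next pileup then repairs.
  # Each round realigns under a different scoring preset: systematic gap
  # placements of one preset are local optima the next preset escapes.
  presets <- msa_presets()
  rotation <- list(preset, presets[[2L]], presets[[3L]], preset)
  for (outer in seq_along(rotation)) {
    outer_start <- est
    ps <- rotation[[outer]]
    ps2 <- presets[[4L]]  # cheap-gap preset: different systematic indel placement
    repeat {
      iter <- iter + 1L
      alns1 <- align_many(reads, est, ps, band)
      alns2 <- align_many(reads, est, ps2, band)
      new_est <- pileup_consensus(est, c(alns1, alns2), ins_alns = alns1)
      converged <- identical(new_est, est)
      est <- new_est
      if (converged || iter >= max_iters * outer) break
    }
    # the address is known side information: pin the prefix so the payload
    # window frame stays aligned for the balance-constrained revision
    if (!is.null(address)) est <- anchor_address(est, address)
    pileup_est <- est
    # run-length refinement with balance constraint on the payload frame
    alns <- c(align_many(reads, est, ps, band),
              align_many(reads, est, ps2, band))
    prof <- parse_homopolymers(est)
    ends <- cumsum(prof$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    runs <- data.frame(symbol = prof$symbols, length = prof$lengths,
                       start = starts, end = ends)
    # revise every run that reaches into the payload; for a run straddling
    # the address/payload seam the in-address bases are held fixed and do
    # not advance the window frame. The run containing the last address
    # base is always included: when the payload starts with that same base
    # and the seam run was shortened, extending it is the only repair.
    rev_idx <- which(runs$end >= address_len)
    payload_runs <- runs[rev_idx, , drop = FALSE]
    if (nrow(payload_runs)) {
      payload_runs$fixed <- pmax(0L, address_len - payload_runs$start + 1L)
      votes <- run_length_votes(payload_runs, alns)
      dp <- balance_dp(payload_runs, votes)
      new_lengths <- runs$length
      new_lengths[rev_idx] <- dp$lengths
      est <- paste(rep(runs$symbol, new_lengths), collapse = "")
      support <- data.frame(symbol = payload_runs$symbol,
                            length = dp$lengths,
                            votes = vapply(seq_len(nrow(payload_runs)),
                                           function(k) sum(votes[, k] == dp$lengths[k]),
                                           numeric(1)))
      flags <- dp$flags
    }
    if (identical(est, outer_start)) break
  }
  structure(list(bases = est, pileup_bases = pileup_est,
                 run_support = support, iteration = iter,
                 flagged_windows = flags),
            class = "consensus_estimate")
}

#' @export
print.consensus_estimate <- function(x, ...) {
  cat(sprintf("consensus estimate: %d bases, %d iteration(s), %d flagged window(s)\n",
              nchar(x$bases), x$iteration, x$flagged_windows))
  invisible(x)
}
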