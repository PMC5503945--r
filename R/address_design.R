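#' Block address design
#'
#' Each 1,000-base block carries a 16-base address prefix used for selective
#' retrieval (PCR in the lab, exact-match demultiplexing in silico).
#' Addresses are built from two binary component codes of length 16 and
#' minimum Hamming distance 8 (first-order Reed-Muller RM(1,4)): a GC-pattern
#' word `u` marks which positions hold a strong (G/C) base and an identity
#' word `v` picks the base within the class, via
#' psi(0,0)=A, psi(0,1)=T, psi(1,0)=G, psi(1,1)=C.
#' Because psi is a per-position bijection on the pair `(u_i, v_i)`, two
#' addresses that differ in either component inherit DNA Hamming distance
#' >= 8. GC-pattern words are restricted to those balanced on both aligned
#' 8-base windows, so every address also satisfies [check_balance()].
#' Candidates whose length->=4 prefix equals their own suffix are discarded
#' (weak autocorrelation, to avoid self-priming-like periodicity).
#'
#' @name address_design
NULL

# All 32 RM(1,4) codewords as rows of a 32 x 16 0/1 matrix; row order is the
# coefficient tuple (a0 + a1*x1 + a2*x2 + a3*x3 + a4*x4) indexed by
# a = a0 + 2*a1 + 4*a2 + 8*a3 + 16*a4, with x1 the most significant
# coordinate bit (so x1 splits the two aligned 8-windows).
rm14_codewords <- function() {
  pos <- 0:15
  x <- cbind(pos %/% 8 %% 2, pos %/% 4 %% 2, pos %/% 2 %% 2, pos %% 2)
  out <- matrix(0L, 32L, 16L)
  for (a in 0:31) {
    coef <- c(a %% 2, a %/% 2 %% 2, a %/% 4 %% 2, a %/% 8 %% 2, a %/% 16 %% 2)
    out[a + 1L, ] <- as.integer((coef[1] + x %*% coef[2:5]) %% 2)
  }
  out
}

address_candidates <- function(min_self_overlap = 4L) {
  key <- paste0("addr_", min_self_overlap)
  if (!is.null(.dnastore_cache[[key]])) return(.dnastore_cache[[key]])
  cw <- rm14_codewords()
  # GC-pattern words: weight 4 on each aligned 8-window (hence weight 8)
  half1 <- rowSums(cw[, 1:8, drop = FALSE])
  half2 <- rowSums(cw[, 9:16, drop = FALSE])
  u_set <- which(half1 == 4L & half2 == 4L)
  psi <- matrix(c("A", "G", "T", "C"), 2L, 2L)  # psi[u+1, v+1], column-major
  addrs <- character(0)
  seen_rc <- character(0)
  for (ui in u_set) {
    for (vi in seq_len(32L)) {
      bases <- psi[cbind(cw[ui, ] + 1L, cw[vi, ] + 1L)]
      addr <- paste(bases, collapse = "")
      if (correlation_overlap(addr, addr) >= min_self_overlap) next
      # addresses with long homopolymer runs are corrupted at boosted
      # deletion rates, crippling exact-match demultiplexing; keep runs <= 2
      if (max(rle(bases)$lengths) > 2L) next
      # the construction is closed under reverse complement; keeping both
      # members of an RC pair (or a palindrome) would make strand
      # assignment ambiguous and the address-avoidance screen unsatisfiable
      rc <- revcomp(addr)
      if (addr %in% seen_rc || rc == addr) next
      # cross-address edit-distance filter: an address (or its RC) that
      # approximately occurs within another address sits at a fixed block
      # position no payload re-whitening can change, so the encode-time
      # screen could never be satisfied
      clash <- FALSE
      for (prev in addrs) {
        prev_rc <- revcomp(prev)
        if (cpp_infix_distance(addr, prev) < 3L ||
            cpp_infix_distance(prev, addr) < 3L ||
            cpp_infix_distance(rc, prev) < 3L ||
            cpp_infix_distance(prev_rc, addr) < 3L) {
          clash <- TRUE
          break
        }
      }
      if (clash) next
      addrs <- c(addrs, addr)
      seen_rc <- c(seen_rc, rc)
    }
  }
  .dnastore_cache[[key]] <- addrs
  addrs
}

#' Number of addresses the construction can produce
#'
#' @param min_self_overlap Autocorrelation threshold passed through to the
#'   candidate filter (default 4).
#' @return Integer capacity of [generate_addresses()].
#' @export
address_capacity <- function(min_self_overlap = 4L) {
  length(address_candidates(min_self_overlap))
}

#' Generate block addresses
#'
#' Deterministically returns the first `count` addresses of the RM(1,4)
#' pair construction (see [address_design]). Every returned address has GC
#' count 4 on each aligned 8-window, pairwise Hamming distance >= 8 to every
#' other returned address, and prefix-suffix self-overlap < 4.
#'
#' @param count Number of addresses required.
#' @param min_self_overlap Autocorrelation threshold (default 4): candidates
#'   whose length->=threshold prefix equals their own suffix are discarded.
#' @return Character vector of `count` 16-base addresses.
#' @examples
#' a <- generate_addresses(17)
#' all(nchar(a) == 16)
#' @export
generate_addresses <- function(count, min_self_overlap = 4L) {
  stopifnot(count >= 1L)
  cand <- address_candidates(min_self_overlap)
  if (count > length(cand)) {
    stop(dnastore_condition("dnastore_capacity_error", sprintf(
      "generate_addresses: %d addresses requested but the construction holds %d",
      count, length(cand))))
  }
  cand[seq_len(count)]
}

#' Longest suffix-prefix overlap between two sequences
#'
#' Returns the largest `k >= 1` such that the length-`k` suffix of `a`
#' equals the length-`k` prefix of `b` (0 when there is none). When `a` and
#' `b` are the same string only proper overlaps (`k < nchar(a)`) are
#' considered, so the function measures autocorrelation.
#'
#' @param a,b Non-empty base strings.
#' @return Integer overlap length.
#' @examples
#' correlation_overlap("ACGT", "GTAC")  # 2
#' @export
correlation_overlap <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  kmax <- min(nchar(a), nchar(b))
  if (identical(a, b)) kmax <- kmax - 1L
  na <- nchar(a)
  for (k in rev(seq_len(kmax))) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

#' Screen a payload for address occurrences
#'
#' Finds every exact occurrence of any address, or of its reverse
#' complement, inside `payload`. Encoded payloads must screen clean so
#' address matches identify blocks unambiguously; [encode_payload()]
#' re-whitens and retries until this holds.
#'
#' @param payload A base string (possibly empty).
#' @param addresses Character vector of addresses.
#' @return A data.frame with columns `address` (index into `addresses`),
#'   `position` (1-based start in `payload`), and `strand` (`"+"` for the
#'   address itself, `"-"` for its reverse complement); zero rows when the
#'   payload is clean.
#' @export
screen_payload <- function(payload, addresses) {
  hits <- list()
  if (length(payload) == 1L && nzchar(payload)) {
    subject <- Biostrings::DNAString(payload)
    for (i in seq_along(addresses)) {
      fwd <- Biostrings::start(Biostrings::matchPattern(addresses[i], subject))
      rev <- Biostrings::start(Biostrings::matchPattern(revcomp(addresses[i]), subject))
      if (length(fwd)) hits[[length(hits) + 1L]] <-
        data.frame(address = i, position = fwd, strand = "+")
      if (length(rev)) hits[[length(hits) + 1L]] <-
        data.frame(address = i, position = rev, strand = "-")
    }
  }
  if (!length(hits)) {
    return(data.frame(address = integer(0), position = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$address), , drop = FALSE]
}
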