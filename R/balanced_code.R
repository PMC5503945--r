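#' GC-balanced constrained code: 14 bits per 8-base word
#'
#' The storage payload is built from 8-base words whose GC content is exactly
#' 4 of 8. There are \eqn{\binom{8}{4} 2^4 2^4 = 17{,}920} such words, which
#' comfortably holds \eqn{2^{14} = 16{,}384} messages, giving a coding rate of
#' \eqn{\log_2(17{,}920)/16 \approx 0.88} information bits per bit of DNA.
#' The codebook is the 16,384 lexicographically smallest balanced 8-mers
#' (A < C < G < T); concatenations of codewords keep every aligned 8-base
#' window balanced and bound any single-base run by 8.
#'
#' @name balanced_code
NULL

#' Enumerate all GC-balanced 8-mers
#'
#' Generates every length-8 string over A/C/G/T with exactly four bases in
#' \{G, C\}, in lexicographic order (A < C < G < T). There are 17,920 such
#' strings; the first 16,384 form the codebook used by [encode_bits14()].
#'
#' @return Character vector of length 17,920, lexicographically sorted.
#' @examples
#' words <- enumerate_balanced_8mers()
#' length(words)   # 17920
#' words[1]        # "AAAACCCC"
#' @export
enumerate_balanced_8mers <- function() {
  if (!is.null(.dnastore_cache$balanced8)) return(.dnastore_cache$balanced8)
  grid <- expand.grid(rep(list(DNA_BASES), 8L), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder so position 1 is
  # the most significant for lexicographic order
  grid <- grid[, 8:1, drop = FALSE]
  gc <- rowSums(grid == "G" | grid == "C")
  keep <- grid[gc == 4L, , drop = FALSE]
  words <- do.call(paste0, keep)
  words <- sort(words, method = "radix")
  .dnastore_cache$balanced8 <- words
  words
}

#' The (14-bit, 8-base) codebook
#'
#' @return Character vector of the 16,384 codewords in rank order.
#' @export
balanced_codebook <- function() {
  if (is.null(.dnastore_cache$codebook)) {
    words <- enumerate_balanced_8mers()[seq_len(16384L)]
    .dnastore_cache$codebook <- words
    .dnastore_cache$codebook_rank <- setNames(seq_along(words) - 1L, words)
  }
  .dnastore_cache$codebook
}

#' Encode a 14-bit message as a balanced 8-base codeword
#'
#' @param word Integer vector of messages in `[0, 16383]`.
#' @return Character vector of 8-base codewords.
#' @examples
#' encode_bits14(0L)  # "AAAACCCC"
#' @export
encode_bits14 <- function(word) {
  word <- as.integer(word)
  if (any(is.na(word)) || any(word < 0L) || any(word > 16383L)) {
    stop("encode_bits14: message out of range [0, 16383]", call. = FALSE)
  }
  balanced_codebook()[word + 1L]
}

#' Decode a balanced codeword back to its 14-bit message
#'
#' The inverse of [encode_bits14()]. An unbalanced input signals a
#' constraint violation; a balanced 8-mer outside the first 16,384 (the
#' codebook proper) signals an uncorrected consensus error and raises an
#' out-of-codebook error.
#'
#' @param codeword Character vector of 8-base strings.
#' @return Integer vector of messages in `[0, 16383]`.
#' @export
decode_codeword <- function(codeword) {
  if (any(nchar(codeword) != 8L) || !is_dna(codeword)) {
    stop(dnastore_condition("dnastore_constraint_error",
                            "decode_codeword: input is not an 8-base A/C/G/T string"))
  }
  gc <- vapply(strsplit(codeword, "", fixed = TRUE), gc_count, integer(1))
  if (any(gc != 4L)) {
    stop(dnastore_condition("dnastore_constraint_error",
                            "decode_codeword: codeword is not GC-balanced (4 of 8)"))
  }
  balanced_codebook()
  rank <- .dnastore_cache$codebook_rank[codeword]
  if (any(is.na(rank))) {
    stop(dnastore_condition("dnastore_out_of_codebook",
                            "decode_codeword: balanced 8-mer outside the 16,384-word codebook"))
  }
  unname(rank)
}

#' Check the 8-base GC-balance constraint over aligned windows
#'
#' Splits `seq` (from `frame_offset`) into consecutive non-overlapping
#' 8-base windows and reports those whose GC count differs from 4. A
#' trailing partial window is ignored; its presence is flagged via the
#' `"partial_window"` attribute and a warning.
#'
#' @param seq A single A/C/G/T string.
#' @param frame_offset Number of leading bases to skip before the first
#'   window (default 0; use 16 to skip a block address).
#' @return Integer vector of 1-based indices of unbalanced windows (empty
#'   when the constraint holds everywhere).
#' @examples
#' check_balance("AAAACCCCAAAACCCC")  # integer(0)
#' check_balance("AAAACCCCAAAAAAAA")  # 2
#' @export
check_balance <- function(seq, frame_offset = 0L) {
  stopifnot(length(seq) == 1L, frame_offset >= 0L)
  chars <- seq_chars(seq)
  usable <- length(chars) - frame_offset
  nwin <- usable %/% 8L
  partial <- usable %% 8L != 0L
  if (partial) {
    warning("check_balance: trailing partial window ignored", call. = FALSE)
  }
  if (nwin <= 0L) {
    out <- integer(0)
    attr(out, "partial_window") <- partial
    return(out)
  }
  idx <- frame_offset + seq_len(nwin * 8L)
  m <- matrix(chars[idx], nrow = 8L)
  gc <- colSums(m == "G" | m == "C")
  out <- which(gc != 4L)
  attr(out, "partial_window") <- partial
  out
}

dnastore_condition <- function(class, msg) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}
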