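# Internal helpers: bit packing, deterministic whitening masks, small
# sequence utilities shared across the codec.

DNA_BASES <- c("A", "C", "G", "T")

# MSB-first bit vector (0/1 integers) from a raw vector
bits_from_bytes <- function(bytes) {
  if (length(bytes) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)  # rows = LSB..MSB
  as.integer(m[8:1, , drop = FALSE])
}

# Inverse of bits_from_bytes; length(bits) must be a multiple of 8
bytes_from_bits <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(as.integer(bits), nrow = 8L)
  packBits(as.raw(m[8:1, , drop = FALSE]), type = "raw")
}

# Split an MSB-first bit vector into 14-bit integers, zero-padding the tail
words14_from_bits <- function(bits) {
  n <- length(bits)
  pad <- (14L - n %% 14L) %% 14L
  if (pad) bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 14L)
  as.integer(crossprod(m, 2^(13:0)))
}

bits_from_words14 <- function(words) {
  if (length(words) == 0L) return(integer(0))
  m <- vapply(13:0, function(s) words %/% 2^s %% 2L, numeric(length(words)))
  as.integer(t(m))
}

# Lehmer (Parker-Miller) generator: portable, R-RNG-independent stream of
# 14-bit mask words keyed by a salt.  Exact in doubles (48271 * 2^31 < 2^53).
lehmer_words <- function(n, salt) {
  a <- 48271
  m <- 2147483647
  state <- (as.numeric(salt) %% (m - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (a * state) %% m
    out[i] <- state %% 16384
  }
  as.integer(out)
}

# XOR of two vectors of 14-bit words via arithmetic (no 32-bit pitfalls)
xor14 <- function(x, y) {
  out <- integer(length(x))
  px <- x
  py <- y
  for (s in 0:13) {
    bx <- px %% 2L
    by <- py %% 2L
    out <- out + as.integer(bx != by) * 2L^s
    px <- px %/% 2L
    py <- py %/% 2L
  }
  as.integer(out)
}

# Reverse complement of plain character strings (vectorised)
revcomp <- function(x) {
  flipped <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

gc_count <- function(chars) sum(chars == "G" | chars == "C")
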