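# Shared test helpers: small random fixtures built in code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_bytes <- function(n) as.raw(sample(0:255, n, replace = TRUE))

# A random block-like sequence made of codebook words (always balanced)
random_codeword_seq <- function(n_words) {
  paste(encode_bits14(sample(0:16383, n_words, replace = TRUE)),
        collapse = "")
}

# Naive overlapping substring scan (oracle for screen_payload)
naive_occurrences <- function(pattern, text) {
  n <- nchar(pattern)
  hits <- integer(0)
  for (i in seq_len(max(0L, nchar(text) - n + 1L))) {
    if (substr(text, i, i + n - 1L) == pattern) hits <- c(hits, i)
  }
  hits
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

noiseless_params <- function() {
  channel_params(p_sub = 0, p_ins = 0, p_del = 0, hp_del_boost = 1,
                 p_revcomp = 0)
}
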