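# R-side wrappers around the banded Gotoh aligner in src/align.cpp.

#' Align two sequences with banded affine-gap scoring
#'
#' Global (end-to-end) alignment under an affine gap model, restricted to a
#' diagonal band of half-width `band` (automatically widened by the length
#' difference of the inputs, so the global path always fits).
#'
#' @param a,b Sequences to align (`a` is typically a read, `b` a reference).
#' @param scores Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (see [msa_presets()]).
#' @param band Band half-width in bases (default 64).
#' @return List with gapped strings `a` and `b` (equal length, `-` for
#'   gaps) and the alignment `score`.
#' @export
align_pair <- function(a, b, scores = msa_presets()[[1L]], band = 64L) {
  cpp_align_banded(a, b, scores$match, scores$mismatch,
                   scores$gap_open, scores$gap_extend, as.integer(band))
}

align_many <- function(reads, ref, scores, band = 64L) {
  cpp_align_many(reads, ref, scores$match, scores$mismatch,
                 scores$gap_open, scores$gap_extend, as.integer(band))
}

# Tally (substitution, insertion, deletion) operations of a gapped pair;
# insertions are bases of `a` opposite gaps in `b`.
count_align_ops <- function(aln) {
  ac <- seq_chars(aln$a)
  bc <- seq_chars(aln$b)
  c(sub = sum(ac != "-" & bc != "-" & ac != bc),
    ins = sum(bc == "-"),
    del = sum(ac == "-"))
}

# Edit distance via the aligner at unit-ish costs (used in reports/tests)
edit_distance <- function(a, b, band = 96L) {
  aln <- cpp_align_banded(a, b, 0, -1, 0, -1, as.integer(band))
  as.integer(-aln$score)
}
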