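---
title: "Error-free DNA data storage over a nanopore-like channel: methods"
author: "dnastore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-free DNA data storage over a nanopore-like channel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnastore)
```

## The problem

DNA can store digital data at extraordinary density, but portable nanopore
sequencers read it back with on the order of 10-15% errors per base --
substitutions, insertions and, most characteristically, deletions
concentrated in homopolymer runs (stretches of one repeated base).
`dnastore` implements a complete write/read system designed so that,
despite this channel, the stored bytes are recovered *exactly*:

1. **Constrained encoding.** Bytes become GC-balanced DNA blocks of
   1,000 bases: a 16-base address plus 123 codewords of 8 bases, each
   codeword carrying 14 bits.
2. **Addressing.** Addresses have pairwise Hamming distance at least 8,
   balanced GC content, weak autocorrelation, and never occur inside any
   encoded payload, so single blocks can be retrieved selectively.
3. **Channel simulation.** A calibrated read simulator reproduces the
   error profile of MinION-class sequencers, including the homopolymer
   deletion bias.
4. **Decoding.** Exact-address demultiplexing, multi-preset progressive
   MSA consensus, majority-homopolymer aggregation, iterative
   balance-constrained polishing, and an algebraic homopolymer check code
   that removes the residual run-shortening errors.

## The constrained code

An 8-base word is *balanced* when exactly 4 of its bases are G or C.
There are $\binom{8}{4}2^42^4 = 17{,}920$ balanced 8-mers, enough to
carry 14 bits ($2^{14} = 16{,}384$) per word at a coding rate of
$\log_2(17{,}920)/16 \approx 0.88$. The codebook is the 16,384
lexicographically smallest balanced 8-mers; the map between ranks and
words is a bijection (`encode_bits14()` / `decode_codeword()`).

Balance is interpreted over *aligned, non-overlapping* 8-base windows: a
sliding-window constraint is impossible for a 14-bit-to-8-base block code,
and the aligned interpretation is what the 123 x 8 payload arithmetic
uses. Aligned windows give two useful side effects: any concatenation of
codewords bounds single-base runs by 8 (4 trailing + 4 leading), and any
frame shift of one base makes downstream windows almost surely
unbalanced, which is what lets the decoder detect and pin down indels.

A full block is $16 + 123 \times 8 = 1{,}000$ bases carrying
$123 \times 14 = 1{,}722$ bits: a net density of 1.72 bits/base. Input
bytes are read MSB-first, zero-padded to a multiple of 14 bits; the true
bit length travels in the sidecar so the tail is unambiguous.

### Address avoidance by whitening

Selective retrieval requires that no address occur anywhere inside
encoded data. Rather than constructing an avoidance code, the payload
bits are XOR-whitened with a deterministic Lehmer-generator mask keyed by
a per-block salt; if screening (`screen_payload()`, forward and reverse
complement) finds any address occurrence, the salt is incremented and the
block re-encoded. A hit has probability around
$2 \times 17 \times 10^3 \times 4^{-16}$ per block, so the first salt
almost always survives; the loop certifies the constraint by
construction, and the salt is stored in the sidecar.

## Addresses

Addresses pair two binary component codewords: a GC-pattern word $u$
(which positions carry a strong base) and an identity word $v$ (which
base within the class), combined per position by
$\psi(0,0)=\mathrm{A},\ \psi(0,1)=\mathrm{T},\ \psi(1,0)=\mathrm{G},\
\psi(1,1)=\mathrm{C}$. Both components come from the first-order
Reed-Muller code RM(1,4): length 16, minimum distance 8. Because $\psi$
is a per-position bijection, two addresses differing in either component
inherit DNA Hamming distance at least 8. Several filters are applied:

* $u$ must be balanced on each aligned 8-window (28 of the 30 weight-8
  RM(1,4) words), so addresses satisfy the same window constraint as
  payloads;
* candidates whose length-4-or-longer prefix equals their own suffix are
  discarded (weak autocorrelation, avoiding self-priming-like
  periodicity);
* candidates with a homopolymer run longer than 2 are discarded: the
  channel's deletion rate grows with run length, and an address that the
  sequencer itself corrupts cripples exact-match demultiplexing;
* reverse-complement duplicates and palindromes are discarded. RM(1,4)
  is closed under position reversal and complementation, so without this
  filter the set can contain $a_j = \mathrm{RC}(a_i)$, which makes strand
  assignment ambiguous and the address-avoidance screen unsatisfiable
  (block $i$ itself would contain $a_j$ on the reverse strand);
* candidates whose edit distance (either direction, either strand) to an
  already-kept address is below 3 are discarded: an address approximately
  occurring *inside another address* sits at a fixed block position that
  no payload re-whitening can change, so the encode-time screen below
  could never be satisfied.

The surviving capacity is `r address_capacity()` addresses -- far more
than the 17 blocks a 3,633-byte file needs. Generation is deterministic.

## Homopolymer check codes

The post-processing pipeline is engineered so that the only errors
surviving consensus are homopolymer runs shortened by one or two bases.
Writing a block as its run-length sequence $\ell_1,\dots,\ell_n$, such an
error is an asymmetric substitution of magnitude at most 2 on the
integers. The standard limited-magnitude reduction protects the residues
$r_i = \ell_i \bmod 3$: knowing the true residue pins the non-negative
correction increment $(r_i - \ell_i^{obs}) \bmod 3 \in \{0,1,2\}$.

Residues are protected by $2t$ power-sum syndromes over GF(2003),
$C_j = \sum_i i^j r_i \bmod 2003$, decoded with
Peterson-Gorenstein-Zierler (locator polynomial from the syndrome linear
system, Chien root search, Vandermonde solve for the error values, full
syndrome verification). This corrects any pattern of up to $t$ shortened
runs; the default $t = 3$ is comfortably above the residual error loads
observed per block in practice (at most 2). A syndrome purely over the
integers mod 3 could not identify error positions for realistic run
counts, which is why the Vandermonde-style parity field is larger; the
residue arithmetic and the applied increments remain mod 3.

The checks depend only on the length sequence, never on the run symbols,
occupy $2t$ field symbols (66 bits per block at $t=3$, about 0.5% of a
block's payload bits), and live in the JSON sidecar on classical media
together with addresses, salts and the bit length. Run-splitting or
run-merging errors (which change the run count) are outside the code's
guarantee and are handled by the decoder's certified repairs below.

## The simulated channel

`corrupt_read()` applies, per position of a block: deletion with
probability $p_{del} \cdot b^{L-1}$ where $L$ is the length of the
containing run and $b$ the homopolymer boost (capped at 0.95, at most
`max_run_shortening = 2` deletions per run); substitution to a uniformly
different base with $p_{sub}$; insertion of a uniform base after the
position with $p_{ins}$. Defaults $p_{sub}=0.085$, $p_{ins}=0.020$,
$p_{del}=0.045$, $b=1.5$ bracket per-read error loads of roughly
(85, 20, 45) per 1,000-base read, the regime of MinION-class chemistry,
with deletions concentrated in runs of length 2 or more. Reads are
emitted in either orientation with probability 0.5 and written as
four-line FASTQ with constant qualities.

What the simulator deliberately does not model: signal-level (squiggle)
behaviour, quality scores, k-mer-specific error tables, chimeric or
truncated reads, and coverage imbalance beyond what sampling induces.
Passing tests on this channel therefore demonstrate the pipeline's
tolerance of the *rate and structure* of nanopore errors (heavy indel
load, homopolymer-biased deletions, mixed strands), not of every artefact
of real flow cells; the FASTQ reader accepts real data but no guarantee
transfers automatically.

## Decoding

**Phase 1 -- rough estimates.** Reads containing an exact 16-mer address
match (either strand; reverse-complement hits are canonicalised) are the
high-quality set. When there are fewer than the MSA cap (15), the set is
topped up with the closest approximate-address reads (infix edit
distance at most 3, competitively assigned). Four affine-gap scoring
presets of the in-package progressive aligner each produce a consensus
(per-column plurality; gap-plurality columns drop), and the four
consensuses are merged run-by-run: runs are matched across inputs by
symbol and overlapping alignment span, each matched slot contributes a
run if present in *any* input, with the modal length (ties to the longer,
because the channel deletes). The known address is then substituted at
the prefix.

**Read recruitment.** Reads the address scan could not place are
assigned by content: three 16-mer probes per block estimate are scanned
against each read by infix edit distance, the best block is confirmed
with one banded alignment, and reads that look like genuine noisy copies
join that block's polish set. This mirrors re-aligning the whole pool
against the estimates.

**Phase 2 -- iterative polish.** Each outer round (up to 4) first
iterates a pileup consensus to a fixed point: every read is aligned to
the current estimate (banded affine-gap Gotoh, band 64 plus the length
difference), and per estimate position the plurality base (or deletion)
is called, with majority insertions between positions. Rounds rotate the
alignment preset: systematic gap placements of one scoring are local
optima that another scoring escapes; the exact address is re-pinned to
the prefix after each round so the payload window frame cannot drift.
Then homopolymer run lengths of the payload are revised: per-read votes
(aligned matches plus boundary insertions of the run symbol) are scored
by log-likelihood under the asymmetric length-dependent deletion model --
a plain vote majority systematically shortens long runs -- and an exact
dynamic program over (position in window, GC count of the partial window)
chooses the candidate lengths maximising total support subject to every
completed aligned 8-window being balanced. Runs straddling the
address/payload seam participate with their in-address bases held fixed.
A window no supported assignment can balance costs one read-set worth of
support and is flagged rather than forced.

**Certified correction and repairs.** The homopolymer checks give the
decoder a strong certificate: a decode is accepted when the syndrome
decoder succeeds, the corrected block has the expected length, and every
payload window decodes to a codebook word. If the first polish fails the
certificate, the decoder restarts from alternative starting points (the
individual preset consensuses, then -- because all of those share one
read set -- re-polishes with half-read subsets and with a consensus of
the next tier of reads). Two targeted repairs cover the error patterns
the length code cannot express: a spurious single-base run between equal
neighbours is merged back (run count off by two), and a suspected
one-base lengthening is decremented so the paired shortening becomes an
ordinary correctable error. Every repair and restart is gated by the
same certificate, so extra attempts cannot make a correct decode worse;
the chance that a wrong block passes all three certificate layers is
negligible (the corrected residues must reproduce six GF(2003) syndromes
exactly). Among certified candidates the decoder briefly prefers one
needing no corrections at all, which keeps the consensus stage's own
error rate low rather than leaning on the checks.

**Random access** runs the same per-block path for a single address;
selection is competitive across all sidecar addresses (as PCR primers
would be), but only reads assigned to the requested address are ever
aligned.

## Numerical and design choices

* **MSA presets** (match, mismatch, gap open, gap extend): balanced
  (2, -3, -5, -2), indel-tolerant (2, -4, -3, -1), strict (5, -9, -12,
  -3), lenient (1, -1, -2, -1). These stand in for running several
  external MSA tools; the contribution is the aggregation and polishing
  logic, not the aligners.
* **Band width** 64 (plus the sequence length difference) covers the
  ~15% per-read error drift of 1 kb reads with a wide margin.
* **Ties**: plurality ties among bases go A < C < G < T; base-versus-gap
  ties keep the base (deletion-dominant channel); modal run-length ties
  go to the longer run.
* **Vote model**: per-base deletion rate $0.045 \cdot 1.5^{L-1}$ and
  insertion rate 0.02 -- the channel defaults; they enter only as
  relative log-likelihood weights, so moderate miscalibration against
  real data shifts scores, not the balance constraint.
* **Degenerate inputs**: empty reads are dropped with a warning; a block
  with no assignable reads raises an error naming its address; a
  trailing partial balance window is flagged, never silently accepted.
* **Problem sizes** used by the test-suite: the full 17-block,
  3,633-byte configuration at coverage 50 (three seeds) and coverage 100
  for the end-to-end checks, with smaller block counts in unit tests;
  property suites use exhaustive enumeration where the space is small
  (all 16,384 codewords, all address pairs, all error patterns on a
  10-run profile).

## Limitations

* Run-structure errors beyond one certified repair per block (e.g. two
  simultaneous split/merge events that also balance every window) can
  defeat the decoder; at the default channel and coverage 50 and above we
  have not observed a miscorrected output -- failed blocks are reported,
  not silently wrong.
* The homopolymer code corrects shortenings of magnitude at most 2; a
  run shortened by 3 aliases to a legal correction and must be caught by
  the word-level certificate instead.
* The channel model is positionwise-independent apart from the run-length
  deletion boost; real nanopore error processes are sequence-dependent in
  ways this package does not attempt to emulate.
* Demultiplexing assumes the address set was generated by this package
  (reverse-complement-free, distance 8); imported address sets without
  those properties void the selectivity guarantees.
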