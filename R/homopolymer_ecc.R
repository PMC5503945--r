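#' Homopolymer check codes
#'
#' Nanopore consensus sequences predominantly err by shortening homopolymer
#' runs (maximal stretches of one base) by one or two bases. Writing the
#' block as its run-length sequence \eqn{\ell_1, \ldots, \ell_n}, such an
#' error is an asymmetric substitution of bounded magnitude on the integers:
#' \eqn{\ell_i \to \ell_i - d} with \eqn{d \in \{1, 2\}}. The standard
#' limited-magnitude reduction protects the residues \eqn{r_i = \ell_i
#' \bmod 3}: recovering the true residues pins down the (non-negative)
#' correction increment \eqn{(r_i - \ell_i^{obs}) \bmod 3 \in \{0,1,2\}}
#' exactly. Residues are protected by power-sum syndromes
#' \eqn{C_j = \sum_i i^j r_i \bmod p} (a Vandermonde-style parity over the
#' prime field GF(p), p = 2003) decoded with the
#' Peterson-Gorenstein-Zierler algorithm, which corrects any pattern of at
#' most `t` shortened runs. The checks depend only on the length sequence,
#' occupy `2t` field symbols (about 66 bits per block at t = 3), and live in
#' the sidecar metadata rather than in the DNA itself.
#'
#' @name homopolymer_ecc
NULL

HP_PRIME <- 2003L

#' Parse a sequence into homopolymer runs
#'
#' @param seq Non-empty A/C/G/T string.
#' @return An object of class `homopolymer_profile`: a list with `symbols`
#'   (one base per run, adjacent entries distinct) and `lengths` (positive
#'   integers). Expanding the profile reproduces `seq` exactly.
#' @examples
#' p <- parse_homopolymers("AATCCCGA")
#' p$lengths  # 2 1 3 1 1
#' @export
parse_homopolymers <- function(seq) {
  if (length(seq) != 1L || !nzchar(seq)) {
    stop(dnastore_condition("dnastore_empty_profile",
                            "parse_homopolymers: empty sequence"))
  }
  if (!is_dna(seq)) {
    stop("parse_homopolymers: sequence must be over A/C/G/T", call. = FALSE)
  }
  r <- rle(seq_chars(seq))
  structure(list(symbols = r$values, lengths = as.integer(r$lengths)),
            class = "homopolymer_profile")
}

#' Expand a homopolymer profile back to a sequence
#'
#' @param profile A `homopolymer_profile`.
#' @return The base string the profile represents.
#' @export
expand_homopolymers <- function(profile) {
  paste(rep(profile$symbols, profile$lengths), collapse = "")
}

#' @export
print.homopolymer_profile <- function(x, ...) {
  cat("homopolymer profile:", length(x$lengths), "runs\n")
  cat(" ", paste0(x$symbols, "(", x$lengths, ")", collapse = " "), "\n")
  invisible(x)
}

#' Compute homopolymer checks for a profile
#'
#' @param profile A `homopolymer_profile`.
#' @param t Maximum number of shortened runs the checks must correct
#'   (default 3).
#' @return An object of class `homopolymer_check`: list with `t`,
#'   `run_count`, `prime`, and `residue_syndrome` (the `2t` power sums of
#'   the mod-3 length residues over GF(prime)). Depends on the lengths
#'   only, never on the run symbols.
#' @export
compute_checks <- function(profile, t = 3L) {
  stopifnot(t >= 1L)
  n <- length(profile$lengths)
  stopifnot(n >= 1L, n < HP_PRIME)
  r <- as.numeric(profile$lengths %% 3L)
  p <- as.numeric(HP_PRIME)
  v <- as.numeric(seq_len(n)) # i^j mod p, updated per j
  syn <- numeric(2L * t)
  for (j in seq_len(2L * t)) {
    syn[j] <- sum((v * r) %% p) %% p
    v <- (v * seq_len(n)) %% p
  }
  structure(list(t = as.integer(t), run_count = n, prime = HP_PRIME,
                 residue_syndrome = as.integer(syn)),
            class = "homopolymer_check")
}

#' Correct shortened homopolymer runs
#'
#' Restores a run-length sequence in which at most `t` runs were shortened
#' by one or two bases, using checks computed from the original profile.
#' Corrections are strictly non-negative increments in \{0, 1, 2\}; the
#' decoder never shortens a run. More than `t` errors raise a decoding
#' failure rather than a silent miscorrection (beyond the usual minimum
#' distance guarantee of the syndrome code).
#'
#' @param observed A `homopolymer_profile` parsed from the (possibly
#'   erroneous) consensus. Its run count must equal `check$run_count`:
#'   a mismatch means runs were created or destroyed outright, which these
#'   checks cannot repair, and raises a structure error.
#' @param check A `homopolymer_check` from [compute_checks()].
#' @return The corrected `homopolymer_profile`.
#' @examples
#' orig <- parse_homopolymers("AATCCCGA")
#' chk  <- compute_checks(orig, t = 2)
#' obs  <- parse_homopolymers("ATCCGA")  # two runs each shortened by 1
#' correct_lengths(obs, chk)$lengths     # 2 1 3 1 1
#' @export
correct_lengths <- function(observed, check) {
  n <- check$run_count
  if (length(observed$lengths) != n) {
    stop(dnastore_condition("dnastore_structure_error", sprintf(
      "correct_lengths: observed %d runs but checks were built over %d",
      length(observed$lengths), n)))
  }
  p <- as.numeric(check$prime)
  t <- check$t
  obs_chk <- compute_checks(observed, t = t)
  s <- (check$residue_syndrome - obs_chk$residue_syndrome) %% p
  if (all(s == 0)) return(observed)

  sol <- pgz_decode(s, n, t, p)
  if (is.null(sol)) {
    stop(dnastore_condition("dnastore_decoding_failure",
                            "correct_lengths: syndrome not decodable within t errors"))
  }
  # field error values -> integer residue differences -> mod-3 increments
  delta <- ifelse(sol$values <= 2, sol$values, sol$values - p)
  if (any(delta == 0 | abs(delta) > 2)) {
    stop(dnastore_condition("dnastore_decoding_failure",
                            "correct_lengths: error magnitude outside the limited-magnitude bound"))
  }
  inc <- as.integer(delta %% 3)
  if (any(inc == 0L)) {
    stop(dnastore_condition("dnastore_decoding_failure",
                            "correct_lengths: inconsistent zero increment"))
  }
  lengths <- observed$lengths
  lengths[sol$positions] <- lengths[sol$positions] + inc
  corrected <- structure(list(symbols = observed$symbols,
                              lengths = as.integer(lengths)),
                         class = "homopolymer_profile")
  post <- compute_checks(corrected, t = t)
  if (!identical(post$residue_syndrome, check$residue_syndrome)) {
    stop(dnastore_condition("dnastore_decoding_failure",
                            "correct_lengths: corrected profile fails check verification"))
  }
  corrected
}

# ---- GF(p) syndrome decoding (Peterson-Gorenstein-Zierler) ----

modpow <- function(base, exp, p) {
  base <- base %% p
  out <- 1
  while (exp > 0) {
    if (exp %% 2 == 1) out <- (out * base) %% p
    base <- (base * base) %% p
    exp <- exp %/% 2
  }
  out
}

modinv <- function(x, p) modpow(x, p - 2, p)

# Gaussian elimination over GF(p); returns NULL when A is singular
solve_modp <- function(A, b, p) {
  n <- nrow(A)
  M <- cbind(A %% p, b %% p)
  for (col in seq_len(n)) {
    piv <- which(M[col:n, col] != 0)
    if (!length(piv)) return(NULL)
    piv <- piv[1] + col - 1L
    if (piv != col) M[c(col, piv), ] <- M[c(piv, col), ]
    M[col, ] <- (M[col, ] * modinv(M[col, col], p)) %% p
    for (row in seq_len(n)) {
      if (row != col && M[row, col] != 0) {
        M[row, ] <- (M[row, ] - M[row, col] * M[col, ]) %% p
      }
    }
  }
  M[, n + 1L]
}

# Decode power-sum syndromes s[1..2t] into <= t error positions/values.
# Returns list(positions, values) or NULL on failure.
pgz_decode <- function(s, n, t, p) {
  for (nu in seq(t, 1L)) {
    A <- outer(seq_len(nu), seq_len(nu), function(j, k) s[nu + j - k])
    b <- (-s[nu + seq_len(nu)]) %% p
    sigma <- solve_modp(matrix(A, nu, nu), b, p)
    if (is.null(sigma)) next
    # sigma(x) = 1 + sigma_1 x + ... + sigma_nu x^nu; roots are inverse locators
    positions <- integer(0)
    for (i in seq_len(n)) {
      xi <- modinv(i, p)
      acc <- 1
      xpow <- 1
      for (k in seq_len(nu)) {
        xpow <- (xpow * xi) %% p
        acc <- (acc + sigma[k] * xpow) %% p
      }
      if (acc == 0) positions <- c(positions, i)
    }
    if (length(positions) != nu) next
    # solve Vandermonde for error values
    V <- matrix(0, nu, nu)
    for (j in seq_len(nu)) for (l in seq_len(nu)) {
      V[j, l] <- modpow(positions[l], j, p)
    }
    vals <- solve_modp(V, s[seq_len(nu)] %% p, p)
    if (is.null(vals) || any(vals == 0)) next
    # verify every syndrome
    ok <- TRUE
    for (j in seq_len(2L * t)) {
      pred <- sum(vapply(seq_len(nu), function(l)
        (vals[l] * modpow(positions[l], j, p)) %% p, numeric(1))) %% p
      if (pred != s[j] %% p) { ok <- FALSE; break }
    }
    if (ok) return(list(positions = positions, values = vals))
  }
  NULL
}
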