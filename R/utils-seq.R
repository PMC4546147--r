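## Low-level sequence helpers shared across modules.
## All coordinates in this package are 0-based half-open on the plus strand;
## conversion to 1-based happens only at format boundaries (GFF3, GenBank).

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()].
#' `N` is preserved.
#'
#' @param x a single DNA string over `A,C,G,T,N`.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## stats::runif-driven random DNA with a per-base G+C probability.
## Returns a character vector of single bases (callers collapse when needed).
random_bases <- function(n, gc = 0.272) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

## Substitute a base for a different one, drawn from the background
## composition so the genome-wide G+C contract is preserved under mutation.
mutate_one <- function(b, gc = 0.272) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  keep <- setdiff(DNA_BASES, b)
  sample(keep, 1L, prob = p[keep])
}

## Mutate a base vector in place at per-base rate `rate`; substitutions only,
## always to a different base, composition-weighted.
mutate_bases <- function(bases, rate, gc = 0.272) {
  if (rate <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) bases[i] <- mutate_one(bases[i], gc)
  bases
}

collapse_seq <- function(bases) paste(bases, collapse = "")

split_seq <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Validate a DNA string; returns invisibly or stops listing offending symbols.
check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  ok <- if (allow_n) "ACGTN" else "ACGT"
  bad <- unique(split_seq(gsub(sprintf("[%s]", ok), "", x)))
  if (length(bad)) {
    stop(sprintf("%s contains non-%s characters: %s",
                 what, ok, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

## Sliding Hamming mismatch counts of `motif` against every window of `seq`.
## Vectorised over windows: one raw-vector comparison per motif position.
## `N` in the subject mismatches every motif base (raw byte inequality).
## Returns an integer vector of length nchar(seq) - nchar(motif) + 1
## (empty when the motif is longer than the sequence); entry i (1-based)
## is the mismatch count of the window starting at 0-based position i - 1.
hamming_scan <- function(seq, motif) {
  n <- nchar(seq)
  L <- nchar(motif)
  if (L > n) return(integer(0))
  sr <- charToRaw(seq)
  mr <- charToRaw(motif)
  nw <- n - L + 1L
  mm <- integer(nw)
  idx <- seq_len(nw)
  for (j in seq_len(L)) {
    mm <- mm + (sr[idx + (j - 1L)] != mr[j])
  }
  mm
}

## Positions (0-based starts) where the terminal `t` bases of the window,
## counted from side = "right" (plus-strand 3' end) or "left", match exactly.
## Used for the primer 3'-anchor rule.
hamming_scan_window <- function(seq, motif, from, to) {
  sub <- substr(motif, from, to)
  n <- nchar(seq)
  L <- nchar(motif)
  if (L > n) return(integer(0))
  sr <- charToRaw(seq)
  mr <- charToRaw(sub)
  nw <- n - L + 1L
  mm <- integer(nw)
  idx <- seq_len(nw)
  for (j in seq_along(mr)) {
    mm <- mm + (sr[idx + (from - 1L) + (j - 1L)] != mr[j])
  }
  mm
}

## Round half up to `digits` decimals (gel/table convention; avoids the
## round-half-even rule of base round()).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Derive a 32-bit-safe child seed from a base seed and an index.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}
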