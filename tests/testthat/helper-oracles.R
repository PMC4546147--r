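# Independent oracles and small fixture builders used across test files.

# Naive per-position brute-force Hamming scan over both strands.
# Deliberately written character-by-character, independently of the
# package's raw-vector implementation.
oracle_motif_scan <- function(seq, motif, max_mm) {
  n <- nchar(seq)
  L <- nchar(motif)
  sc <- strsplit(seq, "")[[1]]
  rc_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (strand in c("+", "-")) {
    mc <- strsplit(motif, "")[[1]]
    if (strand == "-") mc <- rev(unname(rc_map[mc]))
    if (L > n) next
    for (i in 0:(n - L)) {
      mm <- sum(sc[(i + 1):(i + L)] != mc)
      if (mm <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = i, end = i + L, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.272) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A genome carrying a planted tandem array: n_units copies of `unit`
# starting at `at`, embedded in random background.
planted_array_genome <- function(unit, n_units, at = 500, pad = 500,
                                 id = "plant") {
  arr <- paste(rep(unit, n_units), collapse = "")
  phage_genome(id, paste0(random_dna(at), arr, random_dna(pad)))
}

# Zero-noise scaled-down generator settings shared by recovery tests.
quiet_config <- function(seed, subgroup = "CP220like", scale = 0.25) {
  generator_config(seed = seed, subgroup_label = subgroup, scale = scale,
                   unit_mutation_rate = 0, member_divergence = 0)
}

# Reconstruct a one-phage binary host-range matrix from printed counts.
counts_to_matrix <- function(phage, infected, tested, species = "C. jejuni") {
  hostrange_matrix(
    data.frame(strain = paste0("s", seq_len(tested)),
               species = rep(species, tested)),
    phage,
    matrix(c(rep(1L, infected), rep(0L, tested - infected)), ncol = 1))
}
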