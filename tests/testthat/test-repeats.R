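test_that("core-motif scan finds the published core on both strands", {
  g <- phage_genome("g", CORE_MOTIF)
  hits <- scan_core_motif(g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 13L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  grc <- phage_genome("g", revcomp(CORE_MOTIF))  # TTGCTTTAAGTTT
  hrc <- scan_core_motif(grc)
  expect_equal(nrow(hrc), 1L)
  expect_equal(hrc$strand, "-")
  expect_equal(hrc$mismatches, 0L)

  # two mismatches exceed the allowance
  g2 <- phage_genome("g", "AAACTTAAAGCGG")
  expect_equal(nrow(scan_core_motif(g2, max_mismatches = 1)), 0L)

  expect_error(scan_core_motif(g, motif = "AAACTTAN"), "non-ACGT")
  expect_error(scan_core_motif(g, motif = "ACGTACG"), "at least 8")
})

test_that("motif scan treats N as mismatching and scans circular origins", {
  gN <- phage_genome("g", sub("C", "N", CORE_MOTIF))
  expect_equal(scan_core_motif(gN)$mismatches, 1L)

  # motif split across the origin of a circular genome
  seq <- paste0(substr(CORE_MOTIF, 7, 13), random_dna(60), substr(CORE_MOTIF, 1, 6))
  hits <- scan_core_motif(phage_genome("c", seq, topology = "circular"))
  wrap <- hits[hits$start == nchar(seq) - 6L & hits$strand == "+", ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$mismatches, 0L)
  # linear topology must not report it
  hits_lin <- scan_core_motif(phage_genome("l", seq))
  expect_false(any(hits_lin$start == nchar(seq) - 6L & hits_lin$mismatches == 0L))
})

test_that("motif scan agrees with the brute-force Hamming oracle", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(100:1500, 1)
    seq <- random_dna(n, gc = runif(1, 0.2, 0.5))
    motif <- random_dna(sample(8:15, 1), gc = 0.3)
    mm <- sample(0:2, 1)
    got <- scan_core_motif(phage_genome("r", seq), motif, mm)
    want <- oracle_motif_scan(seq, motif, mm)
    expect_equal(got[, c("start", "end", "strand", "mismatches")], want,
                 ignore_attr = TRUE)
  }
})

test_that("motif scan agrees with Biostrings matchPattern as a second route", {
  set.seed(21)
  seq <- random_dna(3000, gc = 0.27)
  hits <- scan_core_motif(phage_genome("x", seq), CORE_MOTIF, 1L)
  bs_p <- Biostrings::matchPattern(CORE_MOTIF, Biostrings::DNAString(seq),
                                   max.mismatch = 1)
  bs_m <- Biostrings::matchPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(CORE_MOTIF))),
    Biostrings::DNAString(seq), max.mismatch = 1)
  expect_setequal(hits$start[hits$strand == "+"], BiocGenerics::start(bs_p) - 1L)
  expect_setequal(hits$start[hits$strand == "-"], BiocGenerics::start(bs_m) - 1L)
})

test_that("unit building delimits tandem cores at midpoints", {
  unit <- random_dna(78 - 13)
  unit <- paste0(substr(unit, 1, 30), CORE_MOTIF, substr(unit, 31, 65))
  g <- planted_array_genome(unit, 3, at = 500, pad = 500)
  hits <- scan_core_motif(g, max_mismatches = 0)
  units <- build_units(hits, genome_length = nchar(g$seq))
  expect_equal(nrow(units), 3L)
  expect_true(all(abs((units$end - units$start) - 78L) <= 6L))
  # each unit holds exactly its own core
  expect_true(all(units$core_start >= units$start &
                  units$core_start + 13L <= units$end))

  # an isolated hit yields one default-length unit centred on the core
  single <- phage_genome("s", paste0(random_dna(300), CORE_MOTIF,
                                     random_dna(300)))
  u1 <- build_units(scan_core_motif(single, max_mismatches = 0),
                    genome_length = nchar(single$seq))
  expect_equal(nrow(u1), 1L)
  expect_equal(u1$end - u1$start, 80L)
  centre <- (u1$start + u1$end) / 2
  expect_lt(abs(centre - (300 + 6.5)), 2)

  # far-apart cores never share a unit
  far <- phage_genome("f", paste0(CORE_MOTIF, random_dna(5000), CORE_MOTIF))
  uf <- build_units(scan_core_motif(far, max_mismatches = 0),
                    max_core_spacing = 300, genome_length = nchar(far$seq))
  expect_equal(nrow(uf), 2L)
  expect_equal(build_units(scan_core_motif(far, max_mismatches = 0)[0, ]),
               build_units(scan_core_motif(far, max_mismatches = 0)[0, ]))
})

test_that("arms pair into bipartite regions across short spacers only", {
  set.seed(31)
  unit <- paste0(random_dna(25, gc = 0.5), CORE_MOTIF, random_dna(40, gc = 0.5))
  arm <- strrep(unit, 5)
  g <- phage_genome("g", paste0(random_dna(2000, gc = 0.5), arm,
                                random_dna(600, gc = 0.5), arm,
                                random_dna(2000, gc = 0.5)))
  det <- find_repeat_regions(g)
  bip <- Filter(function(r) !r$single_armed, det$regions)
  expect_length(bip, 1L)
  expect_equal(bip[[1]]$units_left, 5L)
  expect_equal(bip[[1]]$units_right, 5L)
  expect_equal(unname(bip[[1]]$inner[2] - bip[[1]]$inner[1]), 600,
               tolerance = 0.15)
  expect_equal(classify_region(bip[[1]]), "direct")

  # a 5 kb spacer exceeds inner_gap_max: two separate regions
  g2 <- phage_genome("g2", paste0(random_dna(2000, gc = 0.5), arm,
                                  random_dna(5000, gc = 0.5), arm,
                                  random_dna(2000, gc = 0.5)))
  det2 <- find_repeat_regions(g2)
  expect_length(det2$regions, 2L)
  expect_true(all(vapply(det2$regions, function(r) r$single_armed,
                         logical(1))))
  expect_error(classify_region(det2$regions[[1]]), "single-armed")
})

test_that("region orientation follows arm core strands", {
  unit <- paste0(random_dna(25), CORE_MOTIF, random_dna(40))
  arm_f <- strrep(unit, 4)
  arm_r <- revcomp(arm_f)
  inv <- phage_genome("inv", paste0(random_dna(1000), arm_f, random_dna(500),
                                    arm_r, random_dna(1000)))
  det <- find_repeat_regions(inv)
  bip <- Filter(function(r) !r$single_armed, det$regions)
  expect_length(bip, 1L)
  expect_equal(bip[[1]]$orientation, "inverted")
})

test_that("default-parameter detection reproduces the planted architecture", {
  # full-scale genome: four regions, spans within the published 1-2.9 kb
  res <- generate_genome(generator_config(seed = 42,
                                          subgroup_label = "CP21like"))
  det <- find_repeat_regions(res$genome)
  bip <- Filter(function(r) !r$single_armed, det$regions)
  expect_length(bip, 4L)
  sizes <- vapply(bip, function(r) r$end - r$start, integer(1))
  expect_true(all(sizes >= 1000L & sizes <= 2900L))
  # exactly one direct region planted for the CP21-like arrangement
  oris <- vapply(bip, classify_region, character(1))
  expect_equal(sum(oris == "direct"), 1L)
  expect_equal(oris, ifelse(res$truth$regions$orientation == "direct",
                            "direct", "inverted"))
  # per-arm unit counts match the truth exactly
  det_counts <- t(vapply(bip, function(r) c(r$units_left, r$units_right),
                         integer(2)))
  expect_equal(det_counts[, 1], res$truth$regions$units_left)
  expect_equal(det_counts[, 2], res$truth$regions$units_right)
  # scattered singletons are reported but never merged into regions
  singles <- Filter(function(r) r$single_armed, det$regions)
  expect_gte(length(singles), 1L)
})

test_that("consensus search is exhaustive and recovers the planted core", {
  # identical units: consensus is the whole unit
  unit <- paste0(random_dna(30), CORE_MOTIF, random_dna(37))
  g <- planted_array_genome(unit, 10, at = 400, pad = 400)
  units <- build_units(scan_core_motif(g, max_mismatches = 0),
                       genome_length = nchar(g$seq))
  cons <- derive_consensus(units, g, max_mismatches = 0)
  expect_gte(cons$length, 74L)   # terminal units may be trimmed by 1-2 bp
  expect_false(cons$short)

  # units sharing only the core, random flanks: consensus contains the core
  set.seed(9)
  arr <- paste(vapply(1:8, function(i) {
    paste0(random_dna(30), CORE_MOTIF, random_dna(37))
  }, character(1)), collapse = "")
  g2 <- phage_genome("g2", paste0(random_dna(300), arr, random_dna(300)))
  u2 <- build_units(scan_core_motif(g2, max_mismatches = 0),
                    genome_length = nchar(g2$seq))
  c2 <- derive_consensus(u2, g2, max_mismatches = 1)
  expect_match(c2$consensus, CORE_MOTIF, fixed = TRUE)
  expect_true(all(c2$per_unit_mismatches <= 1L))

  # no shared 8-mer: short consensus reported with the flag, not an error
  set.seed(10)
  gx <- phage_genome("gx", paste0("AAAAAAAAAACCCCCCCCCC", "GTGTGTGTGTACACACACAC"))
  ux <- data.frame(start = c(0L, 20L), end = c(20L, 40L),
                   strand = c("+", "+"), mismatches = c(0L, 0L),
                   core_start = c(0L, 20L), core_offset = c(0L, 0L))
  cx <- derive_consensus(ux, gx, max_mismatches = 0)
  expect_true(cx$short)
  expect_lt(cx$length, 8L)

  expect_error(derive_consensus(u2[1, ], g2), "at least 2")
})

test_that("genome-wide consensus over a synthetic genome is the 13-nt core", {
  # default unit divergence: some units spend their mismatch allowance on
  # a core substitution, which pins the shared sequence to the core itself
  res <- generate_genome(generator_config(seed = 3, scale = 0.25))
  det <- find_repeat_regions(res$genome)
  cons <- derive_consensus(det$units, res$genome, max_mismatches = 1)
  expect_equal(cons$consensus, CORE_MOTIF)
  expect_equal(cons$length, 13L)
})
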