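test_that("generated genomes honour the published size and composition ranges", {
  res <- generate_genome(generator_config(seed = 1,
                                          subgroup_label = "CP220like"))
  g <- res$genome; tr <- res$truth
  expect_gte(nchar(g$seq), 4 * 28000 + 4 * 1000)
  expect_lte(nchar(g$seq), 4 * 55000 + 4 * 2900)
  expect_equal(nrow(tr$regions), 4L)
  expect_true(all(tr$regions$end - tr$regions$start >= 1000))
  expect_true(all(tr$regions$end - tr$regions$start <= 2900))
  expect_true(all(tr$modules$end - tr$modules$start >= 28000))
  expect_true(all(tr$units$end - tr$units$start >= 72 - 1))
  expect_true(all(tr$units$end - tr$units$start <= 86 + 1))
  expect_true(all(table(c(tr$units$region)) <= 2 * 18))
  # G+C within one percentage point of the 27.2% target
  expect_lt(abs(genome_summary(g)$gc_percent - 27.2), 1.0)
  expect_equal(tr$signature, "A+,B+,C+,D+")
  expect_setequal(tr$trna$label, c("Arg", "Tyr"))
  expect_true(tr$gp047$deletion >= 200 && tr$gp047$deletion <= 2500)
})

test_that("CP21like genomes invert modules B and C and keep gp047 intact", {
  res <- generate_genome(generator_config(seed = 2,
                                          subgroup_label = "CP21like",
                                          scale = 0.25))
  tr <- res$truth
  expect_equal(tr$signature, "A+,B-,C-,D+")
  expect_setequal(tr$trna$label, c("Thr", "Pro"))
  expect_equal(tr$gp047$deletion, 0L)
  # exactly one direct region in the CP21 arrangement
  expect_equal(sum(tr$regions$orientation == "direct"), 1L)
  expect_equal(tr$regions$id[tr$regions$orientation == "direct"], "RR3")
})

test_that("the generator is deterministic and seed-sensitive", {
  cfg <- generator_config(seed = 5, scale = 0.25)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$regions, b$truth$regions)
  c <- generate_genome(generator_config(seed = 6, scale = 0.25))
  expect_false(identical(a$genome$seq, c$genome$seq))
  expect_identical(a$truth$signature, c$truth$signature)
})

test_that("scaling shrinks modules but preserves architecture", {
  small <- generate_genome(generator_config(seed = 1, scale = 0.1))
  big <- generate_genome(generator_config(seed = 1))
  expect_lt(nchar(small$genome$seq), nchar(big$genome$seq) / 3)
  expect_identical(small$truth$signature, big$truth$signature)
  expect_equal(nrow(small$truth$regions), nrow(big$truth$regions))
  expect_error(
    generate_genome(generator_config(seed = 1, genome_length_target = 50000)),
    "infeasible")
})

test_that("every planted unit carries the core within the mismatch cap", {
  res <- generate_genome(generator_config(seed = 7, scale = 0.25))
  g <- res$genome; tr <- res$truth
  for (i in seq_len(nrow(tr$units))) {
    s <- substr(g$seq, tr$units$start[i] + 1, tr$units$end[i])
    if (tr$units$strand[i] == "-") s <- revcomp(s)
    expect_lte(min(hamming_scan(s, CORE_MOTIF)), 1L)
  }
  # planted-truth recovery: the scan at generator settings finds a hit
  # inside every planted unit (perfect recall)
  hits <- scan_core_motif(g)
  for (i in seq_len(nrow(tr$units))) {
    inside <- hits$start >= tr$units$start[i] & hits$end <= tr$units$end[i]
    expect_true(any(inside))
  }
})

test_that("modules and regions tile every generated genome", {
  for (seed in 1:3) {
    res <- generate_genome(generator_config(seed = seed, scale = 0.25))
    tr <- res$truth
    covered <- sum(tr$modules$end - tr$modules$start) +
      sum(tr$regions$end - tr$regions$start)
    expect_equal(covered, tr$length)
    # scattered singles stay well clear of region spans
    if (nrow(tr$scattered)) {
      for (j in seq_len(nrow(tr$scattered))) {
        d <- pmin(abs(tr$scattered$start[j] - tr$regions$end),
                  abs(tr$regions$start - tr$scattered$end[j]))
        expect_gt(min(d), 1500)
      }
    }
  }
})

test_that("cohort members share architecture within and differ across subgroups", {
  cohort <- generate_cohort(2, generator_config(seed = 9, scale = 0.25))
  expect_length(cohort, 4L)
  sigs <- vapply(cohort, function(x) x$truth$signature, character(1))
  expect_equal(sigs, c("A+,B-,C-,D+", "A+,B-,C-,D+",
                       "A+,B+,C+,D+", "A+,B+,C+,D+"))
  # same-subgroup members differ in sequence
  expect_false(identical(cohort[[1]]$genome$seq, cohort[[2]]$genome$seq))
  expect_length(generate_cohort(1, generator_config(seed = 9, scale = 0.25)),
                2L)
})

test_that("truth records round-trip through TSV", {
  res <- generate_genome(generator_config(seed = 11, scale = 0.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(res$truth, f)
  back <- read_truth(f)
  expect_equal(back$genome_id, res$truth$genome_id)
  expect_equal(back$subgroup, res$truth$subgroup)
  expect_equal(back$length, res$truth$length)
  expect_equal(back$modules, res$truth$modules, ignore_attr = TRUE)
  expect_equal(back$regions, res$truth$regions, ignore_attr = TRUE)
  expect_equal(back$units, res$truth$units, ignore_attr = TRUE)
  expect_equal(back$gp047$deletion, res$truth$gp047$deletion)
  expect_equal(unname(back$sites$VspI), unname(res$truth$sites$VspI))
  expect_equal(back$signature, res$truth$signature)
})

test_that("host-range simulation respects probabilities and host species", {
  panel <- c(a1 = "CP21like", a2 = "CP21like",
             b1 = "CP220like", b2 = "CP220like")
  zero <- generate_hostrange(panel, n_jejuni = 40, n_coli = 10,
                             susceptibility = list(
                               CP21like = c(jejuni = 0, coli = 0),
                               CP220like = c(jejuni = 0, coli = 0)),
                             seed = 1)
  expect_true(all(zero$lysis == 0L))

  ones <- generate_hostrange(panel, n_jejuni = 10, n_coli = 12,
                             susceptibility = list(
                               CP21like = c(jejuni = 0, coli = 0),
                               CP220like = c(jejuni = 0, coli = 1)),
                             seed = 1)
  block <- ones$lysis[ones$strains$species == "C. coli", c("b1", "b2")]
  expect_true(all(block == 1L))

  # non-host species are always negative
  m <- generate_hostrange(panel, seed = 2)
  non_host <- !(m$strains$species %in% c("C. jejuni", "C. coli"))
  expect_true(all(m$lysis[non_host, ] == 0L))

  # empirical jejuni rates stay within binomial 95% bounds of the target
  big <- generate_hostrange(c(p = "CP220like"), n_jejuni = 227, n_coli = 18,
                            seed = 3)
  p <- 0.093
  rate <- mean(big$lysis[big$strains$species == "C. jejuni", "p"])
  expect_lt(abs(rate - p), 1.96 * sqrt(p * (1 - p) / 227))

  # shared latent makes same-subgroup profiles more alike
  sim_in <- profile_similarity(m, "a1", "a2")$jaccard
  sim_out <- profile_similarity(m, "a1", "b1")$jaccard
  expect_gt(sim_in, sim_out)
})
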