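test_that("gp047 deletion detection reports length difference and identity", {
  ref <- gp047_reference()
  host <- function(locus) {
    set.seed(27)
    phage_genome("q", paste0(random_dna(2000), locus, random_dna(2000)))
  }
  same <- detect_gp047_deletion(host(ref))
  expect_equal(same$status, "ok")
  expect_equal(same$length_difference, 0L)
  expect_false(same$deletion)
  expect_equal(same$cterm_identity, 1.0)

  # internal 1 kb deletion
  del <- paste0(substr(ref, 1, 1500), substr(ref, 2501, nchar(ref)))
  cut <- detect_gp047_deletion(host(del))
  expect_equal(cut$length_difference, 1000L)
  expect_true(cut$deletion)

  # 100 bp removed: below the 200-2500 window
  small <- paste0(substr(ref, 1, 1500), substr(ref, 1601, nchar(ref)))
  res <- detect_gp047_deletion(host(small))
  expect_equal(res$length_difference, 100L)
  expect_false(res$deletion)

  # locus on the minus strand is still found
  rc <- detect_gp047_deletion(host(revcomp(del)))
  expect_equal(rc$strand, "-")
  expect_true(rc$deletion)

  # absent locus: unresolved marker, not an exception
  missing <- detect_gp047_deletion(phage_genome("m", random_dna(5000)))
  expect_equal(missing$status, "unresolved")
  expect_error(detect_gp047_deletion(host(ref), reference_gp047 = "ACGT"),
               "1 kb")
})

test_that("the voting classifier triangulates criteria and flags dissent", {
  all21 <- classify_subgroup(signature = "A+,B-,C-,D+",
                             trna = c("Thr", "Pro"),
                             gp047 = list(status = "ok", deletion = FALSE))
  expect_equal(all21$call, "CP21_subgroup")
  expect_equal(all21$concordance, 1.0)
  expect_false(all21$atypical)

  # CP220 architecture with a dissenting marker: majority call, atypical
  mixed <- classify_subgroup(signature = "A+,B+,C+,D+",
                             trna = c("Arg", "Tyr"),
                             gp047 = list(status = "ok", deletion = FALSE))
  expect_equal(mixed$call, "CP220_subgroup")
  expect_true(mixed$atypical)
  expect_lt(mixed$concordance, 1.0)

  # no computable criterion
  none <- classify_subgroup()
  expect_equal(none$call, "unresolved")
  expect_equal(none$concordance, 0)

  # tie
  tie <- classify_subgroup(signature = "A+,B-,C-,D+",
                           trna = c("Arg", "Tyr"))
  expect_equal(tie$call, "unresolved")

  # digest criterion requires prototypes
  pat <- structure(list(enzyme = "VspI", genome = "x", topology = "linear",
                        fragments = c(500L, 300L)),
                   class = "digest_pattern")
  expect_error(classify_subgroup(digest_pattern = pat), "prototypes")
})

test_that("subgroup calls recover planted labels with full concordance", {
  cohort <- generate_cohort(2, quiet_config(28))
  res <- type_cohort(cohort)
  expect_equal(res$call,
               ifelse(res$subgroup == "CP21like", "CP21_subgroup",
                      "CP220_subgroup"))
  expect_true(all(res$concordance == 1.0))
  expect_false(any(res$atypical))
})

test_that("percentage arithmetic matches the published table convention", {
  expect_equal(percent_positive(counts_to_matrix("CP21", 17, 255),
                                "CP21")$percent, 6.7)
  expect_equal(percent_positive(counts_to_matrix("CP68", 10, 18,
                                                 "C. coli"),
                                "CP68", species = "C. coli")$percent, 55.6)
  m0 <- counts_to_matrix("x", 0, 5, "C. lari")
  expect_equal(percent_positive(m0, "x")$percent, 0.0)
  expect_error(percent_positive(m0, "x", species = "C. coli"), "no strains")
  expect_error(percent_positive(m0, "nope"), "not in matrix")
})

test_that("profile similarity is the Jaccard index with an empty-set flag", {
  strains <- data.frame(strain = paste0("s", 1:4),
                        species = rep("C. jejuni", 4))
  m <- hostrange_matrix(strains, c("a", "b", "c", "z"),
                        cbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1),
                              c = c(1, 1, 1, 0), z = c(0, 0, 0, 0)))
  expect_equal(profile_similarity(m, "a", "c")$jaccard, 1.0)
  expect_equal(profile_similarity(m, "a", "b")$jaccard, 0.5)
  dis <- hostrange_matrix(strains, c("p", "q"),
                          cbind(p = c(1, 1, 0, 0), q = c(0, 0, 1, 1)))
  expect_equal(profile_similarity(dis, "p", "q")$jaccard, 0.0)
  both0 <- profile_similarity(m, "z", "z")
  expect_equal(both0$jaccard, 1.0)
  expect_true(both0$empty)
})

test_that("the host-range permutation test detects subgroup structure", {
  panel <- stats::setNames(rep(c("CP21like", "CP220like"), each = 5),
                           paste0("phi", 1:10))
  m <- generate_hostrange(panel,
                          susceptibility = list(
                            CP21like = c(jejuni = 0.05, coli = 0.15),
                            CP220like = c(jejuni = 0.25, coli = 0.65)),
                          seed = 30)
  res <- subgroup_hostrange_test(m, panel, n_permutations = 999, seed = 31)
  expect_gt(res$observed, 0)
  expect_lte(res$p_value, 0.05)

  # identical lysis columns give a zero statistic
  strains <- data.frame(strain = paste0("s", 1:6),
                        species = rep("C. jejuni", 6))
  same <- hostrange_matrix(strains, paste0("p", 1:4),
                           matrix(rep(c(1, 0, 1, 0, 1, 1), 4), ncol = 4))
  labels <- stats::setNames(rep(c("x", "y"), each = 2), paste0("p", 1:4))
  res0 <- subgroup_hostrange_test(same, labels, n_permutations = 99,
                                  seed = 1)
  expect_equal(res0$observed, 0)

  expect_error(subgroup_hostrange_test(same, labels[1:2], 99, 1),
               "degenerate")
})

test_that("genome summaries report length and half-up rounded G+C", {
  expect_equal(genome_summary(phage_genome("g", "GGCC"))$gc_percent, 100.0)
  expect_equal(genome_summary(phage_genome("a", "ATAT"))$gc_percent, 0.0)
  # N excluded from the denominator
  expect_equal(genome_summary(phage_genome("n", "GGCCNN"))$gc_percent, 100.0)
  res <- generate_genome(generator_config(seed = 33, scale = 0.25))
  s <- genome_summary(res$genome, segment_modules(res$genome,
                                                  res$truth$regions))
  expect_lt(abs(s$gc_percent - 27.2), 1.0)
  expect_equal(sum(s$module_lengths) +
                 sum(res$truth$regions$end - res$truth$regions$start),
               s$length)
  expect_equal(genome_size_difference_kb(182761, 177493), 5.3)
  expect_equal(genome_size_difference_kb(182761, 175720), 7.0)
})

test_that("tail-fibre dendrograms separate subgroup gene variants", {
  set.seed(34)
  base <- random_dna(2000)
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- which(runif(length(v)) < rate)
    v[hit] <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(v, collapse = "")
  }
  va <- mutate(base, 0.10); vb <- mutate(base, 0.10)
  seqs <- c(a1 = mutate(va, 0.01), a2 = mutate(va, 0.01),
            b1 = mutate(vb, 0.01), b2 = mutate(vb, 0.01))
  dd <- tailfiber_dendrogram(seqs)
  grp <- stats::cutree(dd$hclust, 2)
  expect_equal(unname(grp["a1"]), unname(grp["a2"]))
  expect_equal(unname(grp["b1"]), unname(grp["b2"]))
  expect_false(grp[["a1"]] == grp[["b1"]])

  pos <- subgroup_specific_positions(seqs, c(a1 = "A", a2 = "A",
                                             b1 = "B", b2 = "B"),
                                     window = 400)
  expect_true(attr(pos, "approximate"))
  expect_gt(length(pos), 0L)
})
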