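## Subgroup typing and host-range statistics: gp047 deletion detection,
## the multi-criterion voting classifier, Table-style percentage
## arithmetic, lysis-profile similarity, a permutation test for
## subgroup-structured host ranges, and genome summary statistics.

#' Detect an internal gp047 deletion against a reference locus
#'
#' The tail-fibre (receptor-binding) gene gp047 distinguishes the two
#' subgroups: one carries an internal 0.2-2.5 kb deletion. The locus is
#' located by exact-seed anchoring: 21-mers taken from the reference 5'
#' and 3' ends (sliding inwards until a seed places uniquely, trying both
#' strands). The length difference is reference span minus query span; the
#' deletion flag requires it to fall inside the 200-2500 bp window.
#' C-terminal identity is the fraction of matching positions over the
#' end-anchored last 500 bp.
#'
#' @param query a [phage_genome].
#' @param reference_gp047 reference gp047 nucleotide sequence (>= 1 kb);
#'   default the generator's fixed reference.
#' @param seed_k seed length (default 21).
#' @return a `gp047_comparison` list: `status` (`"ok"` or `"unresolved"`),
#'   `query_interval`, `length_difference`, `deletion` flag,
#'   `cterm_identity`, `strand`.
#' @export
detect_gp047_deletion <- function(query, reference_gp047 = gp047_reference(),
                                  seed_k = 21L) {
  if (nchar(reference_gp047) < 1000L) {
    stop("reference gp047 must be at least 1 kb", call. = FALSE)
  }
  unresolved <- function(reason) {
    structure(list(status = "unresolved", reason = reason,
                   query_interval = c(NA_integer_, NA_integer_),
                   length_difference = NA_integer_, deletion = NA,
                   cterm_identity = NA_real_, strand = NA_character_),
              class = "gp047_comparison")
  }
  rlen <- nchar(reference_gp047)

  place_seed <- function(subject, from_end = FALSE) {
    ## slide inwards from the reference end until a seed hits exactly once
    for (off in seq(0L, 180L, by = 20L)) {
      seed <- if (!from_end) {
        substr(reference_gp047, off + 1L, off + seed_k)
      } else {
        substr(reference_gp047, rlen - off - seed_k + 1L, rlen - off)
      }
      pos <- which(hamming_scan(subject, seed) == 0L) - 1L
      if (length(pos) == 1L) return(list(pos = pos, ref_off = off))
      if (length(pos) > 1L) return(NULL)      # ambiguous placement
    }
    NULL
  }

  hit <- NULL; strand <- NA_character_
  for (s in c("+", "-")) {
    subject <- if (s == "+") query$seq else revcomp(query$seq)
    p5 <- place_seed(subject, from_end = FALSE)
    p3 <- place_seed(subject, from_end = TRUE)
    if (!is.null(p5) && !is.null(p3)) {
      hit <- list(subject = subject, p5 = p5, p3 = p3); strand <- s
      break
    }
  }
  if (is.null(hit)) return(unresolved("anchor seeds not uniquely placed"))

  qstart <- hit$p5$pos - hit$p5$ref_off
  qend <- hit$p3$pos + seed_k + hit$p3$ref_off
  if (qend <= qstart) return(unresolved("anchors out of order"))
  qspan <- qend - qstart
  diff <- rlen - qspan
  ## end-anchored C-terminal comparison over the last 500 bp
  w <- 500L
  ref_ct <- substr(reference_gp047, rlen - w + 1L, rlen)
  qry_ct <- substr(hit$subject, max(qend - w, 0L) + 1L, qend)
  mm <- if (nchar(qry_ct) == w) hamming_scan(qry_ct, ref_ct)[1L] else w
  structure(list(status = "ok", reason = NULL,
                 query_interval = c(qstart, qend),
                 length_difference = as.integer(diff),
                 deletion = diff >= 200L && diff <= 2500L,
                 cterm_identity = (w - mm) / w,
                 strand = strand),
            class = "gp047_comparison")
}

#' @export
print.gp047_comparison <- function(x, ...) {
  if (x$status != "ok") {
    cat("<gp047_comparison> unresolved:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<gp047_comparison> locus [%d, %d) %s: length difference %d bp, deletion %s, C-term identity %.3f\n",
      x$query_interval[1], x$query_interval[2], x$strand,
      x$length_difference, x$deletion, x$cterm_identity))
  }
  invisible(x)
}

SIG_CP220 <- "A+,B+,C+,D+"
SIG_CP21 <- "A+,B-,C-,D+"

#' Combine evidence into a phage subgroup call
#'
#' Voting classifier over up to five independent criteria, mirroring how
#' these phages are triangulated in practice: architecture signature
#' (`A+,B-,C-,D+` votes CP21; `A+,B+,C+,D+` votes CP220), tRNA gene labels
#' (Thr/Pro vs Arg/Tyr), gp047 deletion (present votes CP220), restriction
#' digest pattern (nearest prototype), and PCR junction typing profile
#' (nearest expected profile). The call is the majority of computable
#' votes; a tie is `unresolved`; with no computable criterion the call is
#' `unresolved` with zero concordance. A dissenting criterion under a
#' clear majority keeps the majority call but sets the `atypical` flag -
#' the pattern shown by distantly related subgroup members.
#'
#' @param signature architecture signature string, or `NA`.
#' @param trna character vector of tRNA amino-acid labels, or `NULL`.
#' @param gp047 a `gp047_comparison` (or `NULL`).
#' @param digest_pattern a `digest_pattern` (or `NULL`), compared against
#'   `prototypes`.
#' @param pcr_profile named logical profile from [typing_pcr()] over
#'   panels named `*_cp220` / `*_cp21` (or `NULL`).
#' @param prototypes list with elements `CP21` and `CP220`, each a
#'   `digest_pattern` (required only when `digest_pattern` is given).
#' @param size_tolerance gel tolerance for the digest criterion.
#' @return a `subgroup_call`: `phage`, `call` (`CP21_subgroup`,
#'   `CP220_subgroup` or `unresolved`), `atypical`, `concordance`, and the
#'   per-criterion `evidence` votes.
#' @export
classify_subgroup <- function(signature = NA, trna = NULL, gp047 = NULL,
                              digest_pattern = NULL, pcr_profile = NULL,
                              prototypes = NULL, size_tolerance = 0.05,
                              phage = "query") {
  votes <- c(architecture = NA_character_, trna = NA_character_,
             gp047 = NA_character_, digest = NA_character_,
             pcr = NA_character_)
  if (!is.na(signature)) {
    votes["architecture"] <- if (signature == SIG_CP21) "CP21"
      else if (signature == SIG_CP220) "CP220" else NA_character_
  }
  if (!is.null(trna) && length(trna)) {
    key <- paste(sort(trna), collapse = "/")
    votes["trna"] <- if (key == "Pro/Thr") "CP21"
      else if (key == "Arg/Tyr") "CP220" else NA_character_
  }
  if (!is.null(gp047) && gp047$status == "ok") {
    votes["gp047"] <- if (isTRUE(gp047$deletion)) "CP220" else "CP21"
  }
  if (!is.null(digest_pattern)) {
    if (is.null(prototypes) ||
        !all(c("CP21", "CP220") %in% names(prototypes))) {
      stop("digest criterion needs prototypes$CP21 and prototypes$CP220",
           call. = FALSE)
    }
    d21 <- pattern_distance(digest_pattern, prototypes$CP21, size_tolerance)
    d220 <- pattern_distance(digest_pattern, prototypes$CP220, size_tolerance)
    votes["digest"] <- if (d21 < d220) "CP21"
      else if (d220 < d21) "CP220" else NA_character_
  }
  if (!is.null(pcr_profile) && length(pcr_profile)) {
    expect220 <- grepl("_cp220$", names(pcr_profile))
    score220 <- sum(pcr_profile == expect220)
    score21 <- sum(pcr_profile == grepl("_cp21$", names(pcr_profile)))
    votes["pcr"] <- if (score21 > score220) "CP21"
      else if (score220 > score21) "CP220" else NA_character_
  }
  comp <- votes[!is.na(votes)]
  if (!length(comp)) {
    call <- "unresolved"; concordance <- 0; atypical <- FALSE
  } else {
    n21 <- sum(comp == "CP21"); n220 <- sum(comp == "CP220")
    if (n21 == n220) {
      call <- "unresolved"; concordance <- 0.5; atypical <- FALSE
    } else {
      winner <- if (n21 > n220) "CP21" else "CP220"
      call <- paste0(winner, "_subgroup")
      concordance <- max(n21, n220) / length(comp)
      atypical <- any(comp != winner)
    }
  }
  structure(list(phage = phage, call = call, atypical = atypical,
                 concordance = concordance, evidence = votes),
            class = "subgroup_call")
}

#' @export
print.subgroup_call <- function(x, ...) {
  cat(sprintf("<subgroup_call> %s: %s (concordance %.2f%s)\n", x$phage,
              x$call, x$concordance,
              if (x$atypical) ", atypical" else ""))
  ev <- x$evidence[!is.na(x$evidence)]
  if (length(ev)) {
    cat("  evidence:", paste(sprintf("%s=%s", names(ev), ev),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percentage of strains lysed by a phage
#'
#' Spot-assay positivity: `100 * infected / tested`, rounded half-up to
#' one decimal (table convention).
#'
#' @param mat a [hostrange_matrix].
#' @param phage phage id (column).
#' @param species optional species filter (exact match on the species
#'   column).
#' @return list with `infected`, `tested`, `percent`.
#' @export
percent_positive <- function(mat, phage, species = NULL) {
  if (!phage %in% mat$phages) {
    stop("phage '", phage, "' not in matrix", call. = FALSE)
  }
  col <- mat$lysis[, phage]
  if (!is.null(species)) col <- col[mat$strains$species == species]
  tested <- length(col)
  if (tested == 0L) stop("no strains tested", call. = FALSE)
  infected <- sum(col)
  list(infected = infected, tested = tested,
       percent = round_half_up(100 * infected / tested, 1L))
}

#' Jaccard similarity of two phages' lysis profiles
#'
#' `|A intersect B| / |A union B|` over the sets of lysed strains. Two
#' phages that lyse no strains at all are defined as similarity 1 with an
#' `empty` flag.
#'
#' @param mat a [hostrange_matrix].
#' @param a,b phage ids.
#' @return list with `jaccard` and `empty`.
#' @export
profile_similarity <- function(mat, a, b) {
  for (p in c(a, b)) {
    if (!p %in% mat$phages) stop("phage '", p, "' not in matrix",
                                 call. = FALSE)
  }
  va <- mat$lysis[, a] == 1L
  vb <- mat$lysis[, b] == 1L
  un <- sum(va | vb)
  if (un == 0L) return(list(jaccard = 1.0, empty = TRUE))
  list(jaccard = sum(va & vb) / un, empty = FALSE)
}

## All pairwise Jaccard similarities of lysis columns (empty pairs -> 1).
pairwise_jaccard <- function(lysis) {
  inter <- crossprod(lysis)
  un <- outer(colSums(lysis), colSums(lysis), "+") - inter
  j <- ifelse(un == 0, 1, inter / un)
  j
}

## mean within-subgroup minus mean between-subgroup pairwise Jaccard,
## over a precomputed Jaccard matrix
subgroup_jaccard_stat <- function(jac, labels) {
  same <- outer(labels, labels, "==")
  up <- upper.tri(jac)
  mean(jac[up & same]) - mean(jac[up & !same])
}

#' Permutation test for subgroup-structured host ranges
#'
#' Observed statistic: mean within-subgroup minus mean between-subgroup
#' pairwise Jaccard similarity of lysis profiles. Subgroup labels are
#' permuted over phages; `p = (1 + #{perm >= obs}) / (1 + n_permutations)`.
#' A formalisation of the qualitative observation that same-subgroup
#' phages mostly lyse the same strains; the underlying reports state no
#' test.
#'
#' @param mat a [hostrange_matrix].
#' @param calls named character vector phage id -> subgroup label (at
#'   least two phages per label).
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed.
#' @return list with `observed`, `p_value`, `n_permutations`.
#' @export
subgroup_hostrange_test <- function(mat, calls, n_permutations = 999L,
                                    seed = 1L) {
  phages <- intersect(mat$phages, names(calls))
  labels <- unname(calls[phages])
  if (length(unique(labels)) < 2L || any(table(labels) < 2L)) {
    stop("degenerate labeling: need at least two phages per subgroup",
         call. = FALSE)
  }
  lysis <- mat$lysis[, phages, drop = FALSE]
  jac <- pairwise_jaccard(lysis)
  obs <- subgroup_jaccard_stat(jac, labels)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(labels)
    if (subgroup_jaccard_stat(jac, perm) >= obs) hits <- hits + 1L
  }
  list(observed = obs, p_value = (1 + hits) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Genome summary statistics
#'
#' Length, G+C percentage (over `A,C,G,T` positions only, rounded half-up
#' to one decimal) and, when a segmentation is supplied, per-module
#' lengths.
#'
#' @param genome a [phage_genome].
#' @param modules optional module data frame from [segment_modules()].
#' @return list with `length`, `gc_percent` and optionally
#'   `module_lengths`.
#' @export
genome_summary <- function(genome, modules = NULL) {
  counts <- table(factor(split_seq(genome$seq),
                         levels = c(DNA_BASES, "N")))
  acgt <- sum(counts[DNA_BASES])
  gc <- 100 * sum(counts[c("G", "C")]) / acgt
  out <- list(length = nchar(genome$seq),
              gc_percent = round_half_up(gc, 1L))
  if (!is.null(modules)) {
    out$module_lengths <- stats::setNames(modules$length, modules$id)
  }
  out
}

#' Genome size difference in kb
#'
#' Absolute difference of two genome lengths, reported in kb rounded
#' half-up to one decimal (table convention).
#'
#' @param a_bp,b_bp genome lengths in bp.
#' @return difference in kb.
#' @export
genome_size_difference_kb <- function(a_bp, b_bp) {
  round_half_up(abs(a_bp - b_bp) / 1000, 1L)
}

#' UPGMA dendrogram of gene sequences from k-mer profiles
#'
#' Cosine distance between 8-mer count profiles, clustered by average
#' linkage - used for tail-fibre (gp047) gene trees. The tree-building
#' method behind the published gene dendrograms is unstated; this is the
#' package's own, approximate realisation.
#'
#' @param seqs named character vector of gene sequences.
#' @param k word size (default 8).
#' @return list with `hclust`, `dist`, `phylo` (as [cluster_patterns()]).
#' @export
tailfiber_dendrogram <- function(seqs, k = 8L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  profiles <- lapply(seqs, function(s) {
    n <- nchar(s)
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  all_k <- unique(unlist(lapply(profiles, names)))
  m <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(all_k)), all_k)
    v[names(p)] <- as.numeric(p)
    v
  }, numeric(length(all_k)))
  cosd <- function(x, y) 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) d[i, j] <- d[j, i] <- cosd(m[, i], m[, j])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, dist = d, phylo = ape::as.phylo(hc))
}

#' Subgroup-specific nucleotide positions in an end-anchored alignment
#'
#' Columns (counted from the 3' end over the last `window` bp) where the
#' state is uniform within each subgroup but differs between subgroups.
#' End-anchored comparison, no gaps - approximate by construction and
#' flagged as such.
#'
#' @param seqs named character vector of gene sequences.
#' @param labels named subgroup labels for `names(seqs)`.
#' @param window number of 3'-terminal bp compared (default 500).
#' @return integer vector of 1-based positions within the window
#'   (attribute `approximate = TRUE`).
#' @export
subgroup_specific_positions <- function(seqs, labels, window = 500L) {
  labels <- labels[names(seqs)]
  mat <- vapply(seqs, function(s) {
    split_seq(substr(s, nchar(s) - window + 1L, nchar(s)))
  }, character(window))
  groups <- split(seq_along(seqs), labels)
  if (length(groups) < 2L) stop("need at least 2 subgroups", call. = FALSE)
  uniform <- vapply(seq_len(window), function(i) {
    states <- vapply(groups, function(g) {
      u <- unique(mat[i, g])
      if (length(u) == 1L) u else NA_character_
    }, character(1))
    !anyNA(states) && length(unique(states)) == length(states)
  }, logical(1))
  structure(which(uniform), approximate = TRUE)
}
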