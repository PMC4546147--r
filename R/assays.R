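## In-silico counterparts of the two wet-lab typing assays: restriction
## digestion with AT-only enzymes (VspI, SmiI) and PCR with long primers.
## Both are deterministic sequence computations; fragment sizes and product
## lengths stand in for gel lanes.

#' Restriction enzymes
#'
#' Built-ins are the two AT-only cutters effective on these very AT-rich
#' phage DNAs: VspI (`AT^TAAT`, cut offset 2) and SmiI (`ATTT^AAAT`, cut
#' offset 4), per the standard enzyme definitions. Fragment sizes, not cut
#' ends, drive all downstream comparisons, so the offset is cosmetic but
#' fixed for determinism.
#'
#' @param name enzyme name.
#' @param site recognition sequence over `A,C,G,T`.
#' @param offset cut offset in bp from the site start (top strand),
#'   `0 <= offset <= nchar(site)`.
#' @return an `enzyme` object.
#' @export
enzyme <- function(name, site, offset) {
  site <- toupper(site)
  check_dna(site, allow_n = FALSE, what = sprintf("enzyme '%s' site", name))
  if (offset < 0L || offset > nchar(site)) {
    stop("cut offset must be within the recognition site", call. = FALSE)
  }
  structure(list(name = name, site = site, offset = as.integer(offset)),
            class = "enzyme")
}

#' @rdname enzyme
#' @export
builtin_enzymes <- function() {
  list(VspI = enzyme("VspI", "ATTAAT", 2L),
       SmiI = enzyme("SmiI", "ATTTAAAT", 4L))
}

resolve_enzyme <- function(enz) {
  if (inherits(enz, "enzyme")) return(enz)
  if (is.character(enz) && enz %in% names(builtin_enzymes())) {
    return(builtin_enzymes()[[enz]])
  }
  stop("unknown enzyme; use builtin_enzymes() or enzyme()", call. = FALSE)
}

#' In-silico restriction digestion
#'
#' All top-strand occurrences of the recognition site are cut at the
#' enzyme's offset (palindromic sites count once per position; `N` never
#' matches). A linear genome with `s` sites yields `s + 1` fragments; a
#' circular genome with `s >= 1` sites yields `s` fragments (and a single
#' full-length fragment when uncut). Fragments always sum to the genome
#' length.
#'
#' @param genome a [phage_genome].
#' @param enz an [enzyme()] or a built-in name (`"VspI"`, `"SmiI"`).
#' @return a `digest_pattern`: enzyme, genome id, topology and fragment
#'   lengths sorted in decreasing size (gel convention).
#' @export
digest <- function(genome, enz) {
  enz <- resolve_enzyme(enz)
  n <- nchar(genome$seq)
  sites <- which(hamming_scan(genome$seq, enz$site) == 0L) - 1L
  if (genome$topology == "circular" && n > nchar(enz$site)) {
    ext <- paste0(substr(genome$seq, n - nchar(enz$site) + 2L, n),
                  substr(genome$seq, 1L, nchar(enz$site) - 1L))
    wrap <- which(hamming_scan(ext, enz$site) == 0L) - 1L
    if (length(wrap)) {
      sites <- sort(unique(c(sites, n - nchar(enz$site) + 1L + wrap)))
    }
  }
  cuts <- sort((sites + enz$offset) %% n)
  if (genome$topology == "linear") {
    frags <- diff(c(0L, cuts, n))
    frags <- frags[frags > 0L | length(cuts) == 0L]
    if (!length(cuts)) frags <- n
  } else {
    frags <- if (!length(cuts)) n else diff(c(cuts, cuts[1L] + n))
  }
  structure(list(enzyme = enz$name, genome = genome$id,
                 topology = genome$topology,
                 fragments = sort(as.integer(frags), decreasing = TRUE)),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat(sprintf("<digest_pattern> %s / %s (%s): %d fragment(s), total %s bp\n",
              x$genome, x$enzyme, x$topology, length(x$fragments),
              format(sum(x$fragments), big.mark = ",")))
  invisible(x)
}

#' Gel-style distance between two digest patterns
#'
#' One minus the Dice coefficient of greedily matched fragments: fragments
#' are compared largest-first (how a gel is read), two fragments match when
#' their lengths differ by at most `size_tolerance` relative to the larger
#' (emulating log-scale gel resolution), and each fragment is used at most
#' once.
#'
#' @param a,b `digest_pattern`s from the same enzyme.
#' @param size_tolerance relative size tolerance (default 0.05).
#' @return a distance in `[0, 1]`; 0 for identical patterns.
#' @export
pattern_distance <- function(a, b, size_tolerance = 0.05) {
  if (a$enzyme != b$enzyme) {
    stop("patterns come from different enzymes (", a$enzyme, " vs ",
         b$enzyme, ")", call. = FALSE)
  }
  fa <- sort(a$fragments, decreasing = TRUE)
  fb <- sort(b$fragments, decreasing = TRUE)
  used <- logical(length(fb))
  matched <- 0L
  for (x in fa) {
    ok <- which(!used & abs(fb - x) <= size_tolerance * pmax(fb, x))
    if (length(ok)) {
      ## take the closest available partner
      j <- ok[which.min(abs(fb[ok] - x))]
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  1 - 2 * matched / (length(fa) + length(fb))
}

#' UPGMA clustering of digest patterns
#'
#' Average-linkage tree over pairwise [pattern_distance()]s - the
#' computable form of reading subgroup structure off a restriction gel.
#'
#' @param patterns list of >= 2 `digest_pattern`s sharing one enzyme.
#' @param size_tolerance passed to [pattern_distance()].
#' @return list with `hclust` (a [stats::hclust] tree), `dist` (the
#'   distance matrix) and `phylo` (an [ape::phylo] for Newick export).
#' @export
cluster_patterns <- function(patterns, size_tolerance = 0.05) {
  if (length(patterns) < 2L) {
    stop("clustering requires at least 2 patterns", call. = FALSE)
  }
  ids <- vapply(patterns, function(p) p$genome, character(1))
  n <- length(patterns)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- pattern_distance(patterns[[i]], patterns[[j]],
                                             size_tolerance)
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, dist = d, phylo = ape::as.phylo(hc))
}

#' Text rendering of digest patterns as gel lanes
#'
#' @param patterns list of `digest_pattern`s.
#' @param n_slots vertical resolution.
#' @return a character vector of lines (print with `cat(..., sep = "\n")`).
#' @export
render_gel <- function(patterns, n_slots = 30L) {
  sizes <- unlist(lapply(patterns, function(p) p$fragments))
  rng <- log10(range(sizes))
  slot <- function(f) {
    1L + as.integer(round((rng[2] - log10(f)) / diff(rng) * (n_slots - 1L)))
  }
  lanes <- lapply(patterns, function(p) {
    lane <- rep(" ", n_slots)
    lane[slot(p$fragments)] <- "="
    lane
  })
  ids <- vapply(patterns, function(p) p$genome, character(1))
  w <- max(nchar(ids))
  header <- paste0(formatC("", width = w), " ", "5'")
  body <- vapply(seq_len(n_slots), function(s) {
    paste0(formatC("", width = w), " |",
           paste(vapply(lanes, function(l) paste0(" ", l[s], " "),
                        character(1)), collapse = ""))
  }, character(1))
  labels <- paste0(formatC("", width = w), "  ",
                   paste(formatC(substr(ids, 1, 3), width = 3),
                         collapse = ""))
  c(header, body, labels)
}

## Primer match table: 0-based starts of windows where the primer (or its
## reverse complement, for minus-strand annealing) matches the template
## within `max_mm`, with the 3'-terminal `three_prime_exact` bases exact.
primer_matches <- function(template_seq, primer, max_mm, three_prime_exact,
                           circular = FALSE) {
  L <- nchar(primer)
  seq <- template_seq
  n <- nchar(template_seq)
  if (circular && n > L) seq <- paste0(seq, substr(template_seq, 1L, L - 1L))
  out <- list()
  for (s in c("+", "-")) {
    m <- if (s == "+") primer else revcomp(primer)
    mm <- hamming_scan(seq, m)
    ## the primer's 3' end is the window's right edge on "+", left on "-"
    tp <- if (s == "+") {
      hamming_scan_window(seq, m, L - three_prime_exact + 1L, L)
    } else {
      hamming_scan_window(seq, m, 1L, three_prime_exact)
    }
    pos <- which(mm <= max_mm & tp == 0L) - 1L
    pos <- pos[pos < n]
    if (length(pos)) {
      out[[s]] <- data.frame(start = pos, end = pos + L, strand = s,
                             mismatches = mm[pos + 1L],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0))
  }
  res
}

#' Virtual PCR
#'
#' Predicts every amplicon a primer panel can produce on a template: a
#' forward-role primer matching the plus strand paired with a reverse-role
#' primer matching the minus strand downstream of it, both within the
#' mismatch budget and with the 3'-terminal `three_prime_exact` bases
#' matching exactly, up to `max_product` bp. All qualifying products are
#' reported (multiple bands possible), sorted by product length. Circular
#' templates allow origin-spanning products (`product_end` then exceeds
#' the genome length; lengths are exact).
#'
#' The defaults (2 mismatches, 3 exact 3' bases, 6 kb ceiling) reflect the
#' tolerant annealing of very long primers on AT-rich templates and a
#' standard long-elongation protocol; thermodynamics (Tm, secondary
#' structure) are deliberately out of scope.
#'
#' @param template a [phage_genome].
#' @param panel a [primer_panel()].
#' @param max_mismatches total mismatch budget per primer (default 2).
#' @param three_prime_exact 3'-terminal bases that must match (default 3).
#' @param max_product largest product in bp (default 6000).
#' @return a data frame of amplicons: primer names, match coordinates,
#'   strands, mismatch counts, `product_start`, `product_end`, `length`.
#' @export
virtual_pcr <- function(template, panel, max_mismatches = 2L,
                        three_prime_exact = 3L, max_product = 6000L) {
  stopifnot(nrow(panel) > 0L)
  for (i in seq_len(nrow(panel))) {
    check_dna(panel$sequence[i], allow_n = FALSE,
              what = sprintf("primer '%s'", panel$name[i]))
  }
  circular <- template$topology == "circular"
  n <- nchar(template$seq)
  hits <- lapply(seq_len(nrow(panel)), function(i) {
    h <- primer_matches(template$seq, panel$sequence[i], max_mismatches,
                        three_prime_exact, circular)
    if (nrow(h)) h$primer <- panel$name[i]
    h
  })
  names(hits) <- panel$name
  fwd <- panel$name[panel$role == "forward"]
  rev <- panel$name[panel$role == "reverse"]
  out <- list()
  for (f in fwd) {
    hf <- hits[[f]]
    hf <- hf[hf$strand == "+", , drop = FALSE]
    if (!nrow(hf)) next
    for (r in rev) {
      hr <- hits[[r]]
      hr <- hr[hr$strand == "-", , drop = FALSE]
      if (!nrow(hr)) next
      for (i in seq_len(nrow(hf))) {
        for (j in seq_len(nrow(hr))) {
          fs <- hf$start[i]; re <- hr$end[j]
          len <- re - fs
          if (len <= 0L && circular) len <- len + n
          if (is.na(len) || len <= 0L) next
          ## the reverse primer's 3' end must lie downstream of the
          ## forward primer's 3' end
          if (len < hf$end[i] - fs || len < re - hr$start[j]) next
          if (len > max_product) next
          out[[length(out) + 1L]] <- data.frame(
            forward = f, reverse = r,
            forward_start = fs, forward_mismatches = hf$mismatches[i],
            reverse_start = hr$start[j],
            reverse_mismatches = hr$mismatches[j],
            product_start = fs, product_end = fs + len, length = len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(forward = character(0), reverse = character(0),
               forward_start = integer(0), forward_mismatches = integer(0),
               reverse_start = integer(0), reverse_mismatches = integer(0),
               product_start = integer(0), product_end = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Junction typing PCR
#'
#' Runs [virtual_pcr()] once per junction panel; a junction is positive
#' when it yields at least one product within `max_product`. The resulting
#' positive/negative profile over junctions is the typing evidence behind
#' subgroup assignment: primer pairs spanning a module junction amplify
#' only when the genome carries that modular arrangement.
#'
#' @param template a [phage_genome].
#' @param junction_panels named list mapping junction label to a
#'   [primer_panel()] (one forward + one reverse primer each, typically).
#' @inheritParams virtual_pcr
#' @return list with `profile` (named logical) and `lengths` (named list
#'   of product lengths per junction).
#' @export
typing_pcr <- function(template, junction_panels, max_mismatches = 2L,
                       three_prime_exact = 3L, max_product = 6000L) {
  if (!length(junction_panels)) {
    return(list(profile = stats::setNames(logical(0), character(0)),
                lengths = list()))
  }
  lens <- lapply(junction_panels, function(p) {
    virtual_pcr(template, p, max_mismatches, three_prime_exact,
                max_product)$length
  })
  list(profile = vapply(lens, function(l) length(l) > 0L, logical(1)),
       lengths = lens)
}

#' Module-junction typing panels for the two subgroup arrangements
#'
#' Derives long primers (default 36 nt) from the module-end flanks of a
#' reference genome (module coordinates from its truth record or a
#' segmentation) and combines them into junction panels for the
#' all-forward arrangement and for the B/C-inverted arrangement. The same
#' eight flank primers are reused in different combinations - only the
#' pairing differs between arrangements, so a genome yields products
#' exclusively for the panels matching its architecture.
#'
#' @param genome the reference [phage_genome].
#' @param modules data frame with `id`, `start`, `end` (`orientation`
#'   optional) in reference coordinates, all-forward frame.
#' @param primer_length primer length in nt (15-40; default 36).
#' @return named list of `primer_panel`s; names are
#'   `<left><right>_cp220` / `<left><right>_cp21` junction labels.
#' @export
design_typing_panels <- function(genome, modules, primer_length = 36L) {
  ends <- module_end_primers(genome, modules, primer_length)
  ids <- modules$id
  panels <- list()
  for (i in seq_len(nrow(modules) - 1L)) {
    a <- ids[i]; b <- ids[i + 1L]
    lab <- paste0(a, b)
    panels[[paste0(lab, "_cp220")]] <- primer_panel(
      c(paste0(a, "3_f"), paste0(b, "5_r")),
      c(ends[[a]]$right, revcomp(ends[[b]]$left)),
      c("forward", "reverse"))
    ## inverted-module arrangement: the downstream module is flipped for
    ## B and C, so its right-end flank faces the junction; flanking an
    ## inverted/forward boundary reuses the appropriate face
    inv_a <- a %in% c("B", "C"); inv_b <- b %in% c("B", "C")
    fwd_seq <- if (inv_a) revcomp(ends[[a]]$left) else ends[[a]]$right
    rev_seq <- if (inv_b) ends[[b]]$right else revcomp(ends[[b]]$left)
    panels[[paste0(lab, "_cp21")]] <- primer_panel(
      c(paste0(a, ifelse(inv_a, "5rc", "3"), "_f"),
        paste0(b, ifelse(inv_b, "3", "5"), "_r")),
      c(fwd_seq, rev_seq), c("forward", "reverse"))
  }
  panels
}

## Per-module end flank sequences of a reference genome (all-forward
## frame): `left` = first `len` bp, `right` = last `len` bp of the module.
module_end_primers <- function(genome, modules, len) {
  out <- lapply(seq_len(nrow(modules)), function(i) {
    s <- modules$start[i]; e <- modules$end[i]
    list(left = genome_subseq(genome, s, s + len),
         right = genome_subseq(genome, e - len, e))
  })
  names(out) <- modules$id
  out
}

#' Scaffolding primer panel anchored at contig ends
#'
#' For each contig, a forward primer ending `offset` bp before the contig
#' 3' end and a reverse primer starting `offset` bp after the 5' end.
#' Running [virtual_pcr()] with this panel on the (unknown) full genome
#' produces junction amplicons from which [order_contigs()] reconstructs
#' contig order, orientation and gap sizes.
#'
#' @param contigs list of [phage_genome]s.
#' @param primer_length primer length (default 36).
#' @param offset distance between primer and contig end (default 60 bp).
#' @return a [primer_panel()] with names `<id>_end_f` / `<id>_start_r`.
#' @export
design_scaffold_panel <- function(contigs, primer_length = 36L,
                                  offset = 60L) {
  names <- character(0); seqs <- character(0); roles <- character(0)
  for (ctg in contigs) {
    n <- nchar(ctg$seq)
    names <- c(names, paste0(ctg$id, "_end_f"), paste0(ctg$id, "_start_r"))
    seqs <- c(seqs,
              genome_subseq(ctg, n - offset - primer_length, n - offset),
              revcomp(genome_subseq(ctg, offset, offset + primer_length)))
    roles <- c(roles, "forward", "reverse")
  }
  primer_panel(names, seqs, roles)
}
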