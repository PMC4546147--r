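## Repeat-region detection anchored on the degenerate 13-nt core motif.
##
## Group II Campylobacter phage genomes carry long bipartite repeat regions
## whose 72-86 bp tandem units all contain the core consensus
## 5'-AAACTTAAAGCAA-3' with at most one mismatch. Detection proceeds
## bottom-up: motif hits -> repeat units (midpoint-delimited around cores)
## -> arms (runs of units) -> bipartite regions (two arms flanking a short
## unique spacer), with per-arm orientation read off the core-hit strands.

#' The 13-nt repeat-unit core consensus
#' @export
CORE_MOTIF <- "AAACTTAAAGCAA"

#' Scan a genome for a core motif allowing mismatches
#'
#' Reports every position on both strands where the Hamming distance to the
#' motif is at most `max_mismatches`. `N` in the genome mismatches every
#' motif base. For circular genomes the origin-spanning windows are scanned
#' too (hits whose `end` exceeds the genome length wrap around the origin).
#'
#' @param genome a [phage_genome].
#' @param motif DNA string over `A,C,G,T`, at least 8 nt.
#' @param max_mismatches maximum Hamming distance (default 1, the allowance
#'   under which the core was defined).
#' @return a data frame of hits sorted by start (`+` before `-` at ties):
#'   columns `genome`, `start`, `end` (0-based half-open), `strand`,
#'   `mismatches`.
#' @export
scan_core_motif <- function(genome, motif = CORE_MOTIF, max_mismatches = 1L) {
  check_dna(motif, allow_n = FALSE, what = "motif")
  if (nchar(motif) < 8L) stop("motif must be at least 8 nt", call. = FALSE)
  n <- nchar(genome$seq)
  L <- nchar(motif)
  seq <- genome$seq
  if (genome$topology == "circular" && n > L) {
    seq <- paste0(seq, substr(genome$seq, 1L, L - 1L))
  }
  hits <- list()
  for (s in c("+", "-")) {
    m <- if (s == "+") motif else revcomp(motif)
    mm <- hamming_scan(seq, m)
    pos <- which(mm <= max_mismatches) - 1L          # 0-based starts
    pos <- pos[pos < n]                              # circular: no duplicates
    if (length(pos)) {
      hits[[s]] <- data.frame(genome = genome$id, start = pos, end = pos + L,
                              strand = s, mismatches = mm[pos + 1L],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(genome = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$strand != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delimit repeat units around core-motif hits
#'
#' Consecutive core hits closer than `max_core_spacing` belong to one tandem
#' array; unit boundaries are placed at the midpoint between neighbouring
#' cores (the source data do not define the boundary rule, so the midpoint
#' is this package's convention). Terminal units of an array extend half the
#' median unit length beyond their core centre; an isolated hit yields a
#' single unit of the default length (80 bp) centred on its core. When both
#' strands hit at the same start (palindromic near-match), the hit with
#' fewer mismatches is kept, ties resolved to the plus strand.
#'
#' @param hits hit data frame from [scan_core_motif()], sorted by start.
#' @param unit_length_window expected unit length range (bp), used to bound
#'   the terminal extension; default `c(60, 100)` brackets the published
#'   72--86 bp.
#' @param max_core_spacing cores farther apart than this never share a unit
#'   boundary (default 300 bp).
#' @param genome_length clamp for terminal units (optional).
#' @return a data frame of units: `start`, `end`, `strand`, `mismatches`,
#'   `core_start`, `core_offset`.
#' @export
build_units <- function(hits, unit_length_window = c(60L, 100L),
                        max_core_spacing = 300L, genome_length = NULL) {
  if (nrow(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      core_start = integer(0), core_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  ## dedupe identical starts: fewer mismatches wins, ties -> plus strand
  hits <- hits[order(hits$start, hits$mismatches, hits$strand != "+"), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$start), , drop = FALSE]
  k <- nrow(hits)
  grp <- cumsum(c(1L, diff(hits$start) > max_core_spacing))
  default_len <- 80L
  units <- lapply(split(seq_len(k), grp), function(ix) {
    h <- hits[ix, , drop = FALSE]
    m <- nrow(h)
    centre <- (h$start + h$end) %/% 2L
    if (m == 1L) {
      s <- centre - default_len %/% 2L
      e <- s + default_len
    } else {
      b <- (h$end[-m] + h$start[-1L]) %/% 2L
      med <- if (m >= 3L) stats::median(diff(b)) else default_len
      med <- min(max(med, unit_length_window[1L]), unit_length_window[2L])
      half <- round(med / 2)
      s <- c(centre[1L] - half, b)
      e <- c(b, centre[m] + half)
    }
    data.frame(start = as.integer(s), end = as.integer(e),
               strand = h$strand, mismatches = h$mismatches,
               core_start = h$start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, units)
  out$start <- pmax(out$start, 0L)
  if (!is.null(genome_length)) out$end <- pmin(out$end, genome_length)
  out$core_offset <- out$core_start - out$start
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble repeat units into (bipartite) repeat regions
#'
#' Maximal runs of units with inter-unit gap at most `arm_gap_max` form
#' arms. Two consecutive arms, each holding at least `min_units_per_arm`
#' units and separated by a spacer no longer than `inner_gap_max`, form one
#' bipartite region with that spacer as its inner (non-repetitive) segment.
#' Any other arm becomes a single-armed region, flagged as such - scattered
#' single units surface this way and are never merged into a distant
#' region. Regions are named `RR1`, `RR2`, ... left to right.
#'
#' @param units unit data frame from [build_units()], sorted by start.
#' @param arm_gap_max largest within-arm gap (default 200 bp).
#' @param inner_gap_max largest inner-spacer length joining two arms into a
#'   bipartite region (default 1500 bp).
#' @param min_units_per_arm smallest arm eligible for pairing (default 2).
#' @return a list of `repeat_region` objects (see [region_summary()]).
#' @export
assemble_regions <- function(units, arm_gap_max = 200L,
                             inner_gap_max = 1500L, min_units_per_arm = 2L) {
  if (nrow(units) == 0L) return(list())
  units <- units[order(units$start), , drop = FALSE]
  grp <- cumsum(c(1L, diff_gap(units) > arm_gap_max))
  arms <- split(units, grp)
  arm_start <- vapply(arms, function(a) a$start[1L], integer(1))
  arm_end <- vapply(arms, function(a) a$end[nrow(a)], integer(1))
  arm_n <- vapply(arms, nrow, integer(1))

  regions <- list()
  i <- 1L
  while (i <= length(arms)) {
    pair <- i < length(arms) &&
      arm_n[i] >= min_units_per_arm && arm_n[i + 1L] >= min_units_per_arm &&
      (arm_start[i + 1L] - arm_end[i]) <= inner_gap_max
    if (pair) {
      regions[[length(regions) + 1L]] <- new_repeat_region(
        left = arms[[i]], right = arms[[i + 1L]],
        inner = c(arm_end[i], arm_start[i + 1L]))
      i <- i + 2L
    } else {
      regions[[length(regions) + 1L]] <- new_repeat_region(
        left = arms[[i]], right = NULL, inner = NULL)
      i <- i + 1L
    }
  }
  for (j in seq_along(regions)) regions[[j]]$id <- paste0("RR", j)
  regions
}

diff_gap <- function(units) {
  if (nrow(units) < 2L) return(integer(0))
  units$start[-1L] - units$end[-nrow(units)]
}

new_repeat_region <- function(left, right, inner) {
  span <- c(left$start[1L],
            if (is.null(right)) left$end[nrow(left)] else right$end[nrow(right)])
  all_units <- rbind(left, right)
  r <- list(id = NA_character_, start = span[1L], end = span[2L],
            left_arm = left, right_arm = right,
            inner = inner, single_armed = is.null(right),
            units_left = nrow(left),
            units_right = if (is.null(right)) 0L else nrow(right),
            mean_mismatch = mean(all_units$mismatches))
  r$orientation <- if (r$single_armed) NA_character_ else
    classify_region_impl(left, right)
  class(r) <- "repeat_region"
  r
}

#' @export
print.repeat_region <- function(x, ...) {
  cat(sprintf(
    "<repeat_region> %s [%d, %d) %d bp: arms (%d, %d)%s%s\n",
    x$id, x$start, x$end, x$end - x$start, x$units_left, x$units_right,
    if (x$single_armed) ", single-armed" else paste0(", ", x$orientation),
    if (!is.null(x$inner)) sprintf(", inner %d bp", x$inner[2] - x$inner[1]) else ""))
  invisible(x)
}

classify_region_impl <- function(left, right) {
  maj <- function(a) {
    p <- sum(a$strand == "+"); m <- nrow(a) - p
    if (p == m) NA_character_ else if (p > m) "+" else "-"
  }
  sl <- maj(left); sr <- maj(right)
  if (is.na(sl) || is.na(sr)) "ambiguous"
  else if (sl == sr) "direct" else "inverted"
}

#' Classify a bipartite region as direct or inverted
#'
#' Direct when the majority core-hit strand of the two arms is the same,
#' inverted when opposite; a strand tie within an arm is reported as
#' `"ambiguous"`, never silently assigned.
#'
#' @param region a `repeat_region`.
#' @return `"direct"`, `"inverted"` or `"ambiguous"`.
#' @export
classify_region <- function(region) {
  if (region$single_armed) {
    stop("single-armed region ", region$id,
         ": orientation classification requires two arms; skip it",
         call. = FALSE)
  }
  classify_region_impl(region$left_arm, region$right_arm)
}

#' Tabular summary of detected repeat regions
#'
#' One row per region: coordinates, span, per-arm unit counts, orientation
#' class, inner-spacer length, mean core mismatch (a confidence score -
#' degenerate, polymorphic unit clusters surface as single-armed or
#' high-mismatch rows and can be filtered on this column).
#'
#' @param regions list from [assemble_regions()].
#' @return a data frame.
#' @export
region_summary <- function(regions) {
  if (!length(regions)) {
    return(data.frame(id = character(0), start = integer(0), end = integer(0),
                      size = integer(0), units_left = integer(0),
                      units_right = integer(0), orientation = character(0),
                      inner_length = integer(0), single_armed = logical(0),
                      mean_mismatch = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(regions, function(r) {
    data.frame(id = r$id, start = r$start, end = r$end, size = r$end - r$start,
               units_left = r$units_left, units_right = r$units_right,
               orientation = if (is.na(r$orientation)) NA_character_ else r$orientation,
               inner_length = if (is.null(r$inner)) 0L else r$inner[2] - r$inner[1],
               single_armed = r$single_armed,
               mean_mismatch = r$mean_mismatch, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert detected regions and units to genome features
#'
#' Produces `repeat_region` and `repeat_unit` feature rows suitable for
#' [write_intervals()] (BED/GFF3 export).
#'
#' @param regions list from [assemble_regions()].
#' @return a feature data frame.
#' @export
regions_to_features <- function(regions) {
  rows <- lapply(regions, function(r) {
    units <- rbind(r$left_arm, r$right_arm)
    rbind(
      data.frame(label = r$id, start = r$start, end = r$end, strand = "+",
                 kind = "repeat_region", stringsAsFactors = FALSE),
      data.frame(label = r$id, start = units$start, end = units$end,
                 strand = units$strand, kind = "repeat_unit",
                 stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' End-to-end repeat-region detection
#'
#' Chains [scan_core_motif()], [build_units()] and [assemble_regions()] at
#' the package defaults (1 mismatch against the 13-nt core; 200 bp arm gap,
#' 1500 bp inner gap, 2 units per arm - the gap thresholds are this
#' package's calibration, chosen so that default-parameter detection
#' reproduces the published 1--2.9 kb region sizes on default synthetic
#' genomes; all are exposed).
#'
#' @param genome a [phage_genome].
#' @inheritParams scan_core_motif
#' @inheritParams build_units
#' @inheritParams assemble_regions
#' @return list with `hits`, `units`, `regions`.
#' @export
find_repeat_regions <- function(genome, motif = CORE_MOTIF,
                                max_mismatches = 1L,
                                unit_length_window = c(60L, 100L),
                                max_core_spacing = 300L,
                                arm_gap_max = 200L, inner_gap_max = 1500L,
                                min_units_per_arm = 2L) {
  hits <- scan_core_motif(genome, motif, max_mismatches)
  units <- build_units(hits, unit_length_window, max_core_spacing,
                       genome_length = nchar(genome$seq))
  regions <- assemble_regions(units, arm_gap_max, inner_gap_max,
                              min_units_per_arm)
  list(hits = hits, units = units, regions = regions)
}

#' Longest shared approximate substring of a set of repeat units
#'
#' Exhaustive consensus search: the longest sequence S such that every unit
#' (oriented by its core-hit strand) contains S within `max_mismatches`.
#' Candidates are all substrings of the first (oriented) unit, guaranteeing
#' optimality relative to that seed unit; among equal-length candidates the
#' smallest total mismatch count wins, remaining ties broken
#' lexicographically. Applied genome-wide to units from all regions this
#' recovers the 13-nt core; applied within one region it recovers most of
#' the unit, since unit interiors are related beyond the core.
#'
#' @param units unit data frame from [build_units()] (at least 2 rows).
#' @param genome the [phage_genome] the units were detected on.
#' @param max_mismatches per-unit mismatch allowance (default 1).
#' @return list with `consensus`, `length`, `per_unit_mismatches`, and
#'   `short` (TRUE when no shared sequence of at least 8 nt exists - a
#'   degenerate unit set).
#' @export
derive_consensus <- function(units, genome, max_mismatches = 1L) {
  if (nrow(units) < 2L) {
    stop("consensus derivation requires at least 2 units", call. = FALSE)
  }
  seqs <- vapply(seq_len(nrow(units)), function(i) {
    s <- genome_subseq(genome, units$start[i], units$end[i])
    if (units$strand[i] == "-") revcomp(s) else s
  }, character(1))
  first <- seqs[[1L]]
  L1 <- nchar(first)
  others <- seqs[-1L]
  for (len in seq(L1, 1L)) {
    starts <- seq_len(L1 - len + 1L)
    best <- NULL
    for (st in starts) {
      cand <- substr(first, st, st + len - 1L)
      total <- 0L
      per_unit <- integer(length(seqs))
      ok <- TRUE
      for (u in seq_along(others)) {
        mm <- hamming_scan(others[[u]], cand)
        if (!length(mm) || min(mm) > max_mismatches) { ok <- FALSE; break }
        per_unit[u + 1L] <- min(mm)
        total <- total + min(mm)
      }
      if (!ok) next
      if (is.null(best) || total < best$total ||
          (total == best$total && cand < best$consensus)) {
        best <- list(consensus = cand, total = total,
                     per_unit_mismatches = per_unit)
      }
    }
    if (!is.null(best)) {
      return(list(consensus = best$consensus, length = len,
                  per_unit_mismatches = best$per_unit_mismatches,
                  short = len < 8L))
    }
  }
  list(consensus = "", length = 0L,
       per_unit_mismatches = rep(NA_integer_, length(seqs)), short = TRUE)
}
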