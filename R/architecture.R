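## Module-level genome architecture: segmentation at repeat regions, k-mer
## dot plots, inversion-aware architecture signatures, and contig ordering
## across repeat-region gaps from junction amplicons.

#' Segment a genome into modules at its repeat regions
#'
#' Modules are the segments between consecutive repeat-region spans. On a
#' circular genome `n` regions give `n` modules (one wrapping the origin
#' when no region abuts it); on a linear genome they give `n + 1` segments
#' (the two terminal segments may be fragments of one wrapped module).
#' Modules are named alphabetically from the genome origin. Modules plus
#' region spans tile the genome exactly; this is asserted.
#'
#' @param genome a [phage_genome].
#' @param regions a list of `repeat_region`s from [assemble_regions()] or a
#'   data frame with `start`/`end` columns (e.g. a truth record's
#'   `regions`); must be sorted and non-overlapping.
#' @return a data frame of modules: `id`, `start`, `end`, `length`,
#'   `wraps`. For a wrapping module `end = start + length` exceeds the
#'   genome length (coordinates on the circle).
#' @export
segment_modules <- function(genome, regions) {
  n <- nchar(genome$seq)
  spans <- if (is.data.frame(regions)) regions[, c("start", "end")] else
    region_summary(regions)[, c("start", "end")]
  spans <- spans[order(spans$start), , drop = FALSE]
  if (nrow(spans) > 1L &&
      any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    stop("repeat regions overlap; cannot segment", call. = FALSE)
  }
  if (nrow(spans) == 0L) {
    return(data.frame(id = "A", start = 0L, end = n, length = n,
                      wraps = FALSE, stringsAsFactors = FALSE))
  }
  k <- nrow(spans)
  if (genome$topology == "circular") {
    ## wrap segment first: from the end of the last region, through the
    ## origin, to the start of the first region
    starts <- c(spans$end[k], spans$end[-k])
    ends <- spans$start
    wraps <- c(TRUE, rep(FALSE, k - 1L))
    ends[1L] <- ends[1L] + n       # circle coordinates
    lens <- ends - starts
    ## a region abutting the origin leaves a non-wrapping first segment
    if (starts[1L] == n) { starts[1L] <- 0L; ends[1L] <- ends[1L] - n
                           wraps[1L] <- FALSE }
    mods <- data.frame(id = LETTERS[seq_len(k)], start = starts, end = ends,
                       length = lens, wraps = wraps,
                       stringsAsFactors = FALSE)
  } else {
    starts <- c(0L, spans$end)
    ends <- c(spans$start, n)
    keep <- ends > starts
    mods <- data.frame(id = LETTERS[seq_len(sum(keep))],
                       start = starts[keep], end = ends[keep],
                       length = (ends - starts)[keep],
                       wraps = FALSE, stringsAsFactors = FALSE)
  }
  covered <- sum(mods$length) + sum(spans$end - spans$start)
  if (covered != n) {
    stop("internal error: modules + regions do not tile the genome (",
         covered, " vs ", n, " bp)", call. = FALSE)
  }
  mods
}

## k-mer positions (0-based) of a sequence, N-containing words removed.
kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.table::data.table(kmer = character(0), pos = integer(0)))
  pos <- 0:(n - k)
  km <- substring(seq, pos + 1L, pos + k)
  keep <- !grepl("N", km, fixed = TRUE)
  data.table::data.table(kmer = km[keep], pos = pos[keep])
}

## Chain same-diagonal k-mer matches into collinear runs. `pairs` has
## columns q, s (0-based starts on equally oriented sequences).
chain_matches <- function(pairs, k, band, chain_gap, min_run) {
  if (!nrow(pairs)) return(NULL)
  pairs$diag <- pairs$s - pairs$q
  pairs <- pairs[order(pairs$diag, pairs$q), ]
  new_chain <- c(TRUE, diff(pairs$diag) > band | diff(pairs$q) > chain_gap)
  pairs$chain <- cumsum(new_chain)
  out <- lapply(split(pairs, pairs$chain), function(p) {
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = p$q + 1L, width = k))))
    data.frame(q_start = min(p$q), q_end = max(p$q) + k,
               s_start = min(p$s), s_end = max(p$s) + k,
               matched = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[out$matched >= min_run, , drop = FALSE]
}

dotplot_seq <- function(qseq, sseq, k, band, chain_gap, min_run) {
  qt <- kmer_table(qseq, k)
  ns <- nchar(sseq)
  res <- list()
  for (ori in c("+", "-")) {
    ss <- if (ori == "+") sseq else revcomp(sseq)
    st <- kmer_table(ss, k)
    pairs <- merge(qt, st, by = "kmer", allow.cartesian = TRUE,
                   suffixes = c(".q", ".s"))
    pairs <- data.frame(q = pairs$pos.q, s = pairs$pos.s)
    ch <- chain_matches(pairs, k, band, chain_gap, min_run)
    if (is.null(ch) || !nrow(ch)) next
    if (ori == "-") {
      s2 <- ns - ch$s_end; e2 <- ns - ch$s_start
      ch$s_start <- s2; ch$s_end <- e2
    }
    ch$orientation <- ori
    res[[ori]] <- ch
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      matched = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' k-mer dot plot between two genomes
#'
#' Exact shared k-mers (both strands) chained into collinear runs: matches
#' on the same diagonal within `band`, with query gaps at most
#' `chain_gap`, form one run; runs covering fewer than `min_run` matched
#' query bases are dropped. Minus-orientation runs pair a query interval
#' with the subject interval's reverse complement.
#'
#' The defaults (k = 31, 500 bp chain gap, 50 bp band, 200 bp minimum
#' matched length) give unique anchors at the ~180 kb scale of these 27%
#' G+C genomes while tolerating a few percent of sequence divergence.
#'
#' @param query,subject [phage_genome]s (or plain DNA strings).
#' @param k word size (>= 11).
#' @param band diagonal tolerance in bp.
#' @param chain_gap largest query gap inside one run.
#' @param min_run smallest matched length kept.
#' @return a data frame of match blocks `q_start`, `q_end`, `s_start`,
#'   `s_end`, `matched`, `orientation`, sorted by query start.
#' @export
compute_dotplot <- function(query, subject, k = 31L, band = 50L,
                            chain_gap = 500L, min_run = 200L) {
  if (k < 11L) stop("k must be at least 11", call. = FALSE)
  qs <- if (inherits(query, "phage_genome")) query$seq else query
  ss <- if (inherits(subject, "phage_genome")) subject$seq else subject
  dotplot_seq(qs, ss, k, band, chain_gap, min_run)
}

#' Architecture signature of a query genome against a reference
#'
#' Assigns every query module to the subject (reference) module with the
#' greatest summed dot-plot matched length, with the majority orientation
#' of that matched length. Modules whose matched fraction stays below
#' `min_cov` are reported unassigned; a best match within 5% of the
#' runner-up is flagged ambiguous, never resolved silently. The signature
#' lists subject module ids with orientations in query order - e.g.
#' `A+,B-,C-,D+` for a genome carrying modules B and C inverted relative
#' to the reference.
#'
#' Repeat regions are excluded structurally: modules are the inter-region
#' segments, so the near-identical repeat arms can never bridge modules
#' (and scattered single units fall below `min_run`).
#'
#' @param query,subject [phage_genome]s.
#' @param query_modules,subject_modules module data frames from
#'   [segment_modules()] (or a truth record's `modules`).
#' @param k word size.
#' @param min_cov minimum matched fraction of the query module (default
#'   0.3).
#' @inheritParams compute_dotplot
#' @return list with `assignments` (data frame: `query_module`,
#'   `subject_module`, `orientation`, `matched`, `coverage`, `ambiguous`)
#'   and `signature` (string such as `"A+,B-,C-,D+"`, `?` for unassigned).
#' @export
compare_architectures <- function(query, query_modules, subject,
                                  subject_modules, k = 31L, min_cov = 0.3,
                                  band = 50L, chain_gap = 500L,
                                  min_run = 200L) {
  get_seq <- function(genome, mods, i) {
    genome_subseq(genome, mods$start[i], mods$end[i])
  }
  nq <- nrow(query_modules); ns <- nrow(subject_modules)
  rows <- vector("list", nq)
  for (i in seq_len(nq)) {
    qseq <- get_seq(query, query_modules, i)
    tot <- numeric(ns); ori <- character(ns)
    for (j in seq_len(ns)) {
      dp <- dotplot_seq(qseq, get_seq(subject, subject_modules, j), k,
                        band, chain_gap, min_run)
      tot[j] <- sum(dp$matched)
      by_ori <- tapply(dp$matched, dp$orientation, sum)
      ori[j] <- if (!length(by_ori)) NA_character_ else
        names(by_ori)[which.max(by_ori)]
    }
    best <- which.max(tot)
    cov <- tot[best] / nchar(qseq)
    second <- if (ns > 1L) max(tot[-best]) else 0
    ambiguous <- tot[best] > 0 && second >= 0.95 * tot[best]
    assigned <- cov >= min_cov
    rows[[i]] <- data.frame(
      query_module = query_modules$id[i],
      subject_module = if (assigned) subject_modules$id[best] else NA_character_,
      orientation = if (assigned) ori[best] else NA_character_,
      matched = tot[best], coverage = cov, ambiguous = ambiguous,
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  sig <- paste(ifelse(is.na(assignments$subject_module), "?",
                      paste0(assignments$subject_module,
                             assignments$orientation)),
               collapse = ",")
  list(assignments = assignments, signature = sig)
}

#' Order contigs across repeat-region gaps from junction amplicons
#'
#' Contigs become nodes; a junction amplicon whose forward primer anchors
#' near the end of contig X and whose reverse primer anchors near the
#' start of contig Y adds the directed edge X -> Y with
#' `gap = amplicon length - (distance from the forward primer to X's end)
#' - (distance from Y's start to the reverse primer)`. Primer-to-end
#' distances are measured by locating each primer on the contigs (real
#' gaps are routinely larger than assembly-predicted ones, so the gap must
#' be measured, never assumed). Contig orientation is read off the strand
#' each primer matches. A unique Hamiltonian path (or cycle, in circular
#' mode) is required; missing or conflicting junctions are an error naming
#' the junction.
#'
#' @param contigs list of [phage_genome]s.
#' @param panel the [primer_panel()] the amplicons were generated with.
#' @param amplicons amplicon data frame from [virtual_pcr()] on the full
#'   template (only `forward`, `reverse` and `length` are used, so
#'   observed gel sizes can be supplied instead).
#' @param circular expect a cycle instead of a path.
#' @param max_mismatches allowance when locating primers on contigs.
#' @return list with `order` (data frame `contig`, `orientation`), `gaps`
#'   (data frame `from`, `to`, `gap`) and `total_length`
#'   (`sum(contigs) + sum(gaps)`).
#' @export
order_contigs <- function(contigs, panel, amplicons, circular = FALSE,
                          max_mismatches = 1L) {
  ids <- vapply(contigs, function(x) x$id, character(1))
  lens <- vapply(contigs, function(x) nchar(x$seq), integer(1))
  names(lens) <- ids

  locate <- function(primer_name) {
    seq <- panel$sequence[panel$name == primer_name]
    if (!length(seq)) stop("primer '", primer_name, "' not in panel",
                           call. = FALSE)
    hits <- list()
    for (ci in seq_along(contigs)) {
      h <- primer_matches(contigs[[ci]]$seq, seq, max_mismatches,
                          three_prime_exact = 0L)
      if (nrow(h)) { h$contig <- ids[ci]; hits[[length(hits) + 1L]] <- h }
    }
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0L) {
      stop("primer '", primer_name, "' not found on any contig",
           call. = FALSE)
    }
    if (nrow(hits) > 1L) {
      stop("primer '", primer_name, "' places ambiguously (",
           nrow(hits), " hits)", call. = FALSE)
    }
    hits
  }

  edges <- list()
  for (i in seq_len(nrow(amplicons))) {
    f <- locate(amplicons$forward[i])
    r <- locate(amplicons$reverse[i])
    if (f$contig == r$contig) next            # internal product
    if (f$strand == "+") { x <- f$contig; ox <- "+"
                           off_r <- lens[x] - f$start
    } else { x <- f$contig; ox <- "-"; off_r <- f$end }
    ## the reverse primer anneals where its reverse complement lies on the
    ## contig top strand; primer_matches reports that as a "-" strand hit
    if (r$strand == "-") { y <- r$contig; oy <- "+"; off_l <- r$end
    } else { y <- r$contig; oy <- "-"; off_l <- lens[r$contig] - r$start }
    edges[[length(edges) + 1L]] <- data.frame(
      from = x, from_ori = ox, to = y, to_ori = oy,
      gap = amplicons$length[i] - off_r - off_l, stringsAsFactors = FALSE)
  }
  edges <- unique(do.call(rbind, edges))
  if (is.null(edges) || !nrow(edges)) {
    stop("no junction amplicons link any pair of contigs", call. = FALSE)
  }
  dup_from <- edges$from[duplicated(edges$from)]
  dup_to <- edges$to[duplicated(edges$to)]
  if (length(dup_from) || length(dup_to)) {
    stop("conflicting junction amplicons at: ",
         paste(unique(c(dup_from, dup_to)), collapse = ", "), call. = FALSE)
  }

  succ <- stats::setNames(edges$to, edges$from)
  need_edges <- if (circular) length(ids) else length(ids) - 1L
  if (nrow(edges) < need_edges) {
    missing_from <- setdiff(ids, edges$from)
    stop("no unique contig path: junction(s) after ",
         paste(missing_from, collapse = ", "), " unamplified",
         call. = FALSE)
  }
  start <- if (circular) ids[1L] else setdiff(ids, edges$to)
  if (length(start) != 1L) {
    stop("no unique contig path: ", length(start),
         " possible starting contigs", call. = FALSE)
  }
  path <- start
  while (length(path) < length(ids)) {
    nxt <- succ[[path[length(path)]]]
    if (is.null(nxt) || nxt %in% path) {
      stop("no unique contig path: chain breaks after ",
           path[length(path)], call. = FALSE)
    }
    path <- c(path, nxt)
  }
  ori <- stats::setNames(rep("+", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    ori[edges$from[i]] <- edges$from_ori[i]
    ori[edges$to[i]] <- edges$to_ori[i]
  }
  used <- if (circular) edges else
    edges[match(path[-length(path)], edges$from), , drop = FALSE]
  gaps <- data.frame(from = used$from, to = used$to, gap = used$gap,
                     stringsAsFactors = FALSE)
  list(order = data.frame(contig = path, orientation = ori[path],
                          stringsAsFactors = FALSE),
       gaps = gaps,
       total_length = sum(lens) + sum(gaps$gap))
}
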