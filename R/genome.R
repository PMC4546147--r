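#' Phage genome container
#'
#' The unit every pipeline stage consumes: a named nucleotide sequence with a
#' topology flag and optional feature annotations. Group II Campylobacter
#' phage DNA is circularly permuted; genomes are therefore held linearised at
#' a declared origin with `topology = "circular"` recording the underlying
#' topology. All internal coordinates are 0-based half-open on the plus
#' strand.
#'
#' @param id genome identifier.
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive; stored
#'   uppercase).
#' @param topology `"linear"` or `"circular"`.
#' @param features a data frame with columns `label`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `kind` (one of `tRNA`,
#'   `gene`, `repeat_unit`, `repeat_region`, `module`, `other`). tRNA
#'   features carry a standard amino-acid label (three-letter code).
#' @return an object of class `phage_genome`.
#' @export
phage_genome <- function(id, sequence, topology = c("linear", "circular"),
                         features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  check_dna(sequence, allow_n = TRUE, what = sprintf("genome '%s'", id))
  features <- validate_features(features, nchar(sequence))
  structure(list(id = id, seq = sequence, topology = topology,
                 features = features),
            class = "phage_genome")
}

FEATURE_KINDS <- c("tRNA", "gene", "repeat_unit", "repeat_region", "module",
                   "other")
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' @rdname phage_genome
#' @export
empty_features <- function() {
  data.frame(label = character(0), start = integer(0), end = integer(0),
             strand = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, len) {
  need <- c("label", "start", "end", "strand", "kind")
  if (!all(need %in% names(features))) {
    stop("features must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  features <- features[, need, drop = FALSE]
  if (nrow(features)) {
    if (any(features$start < 0L) || any(features$end > len) ||
        any(features$end <= features$start)) {
      stop("feature intervals must lie within [0, genome length) and be ",
           "non-empty (0-based half-open)", call. = FALSE)
    }
    if (!all(features$strand %in% c("+", "-"))) {
      stop("feature strand must be '+' or '-'", call. = FALSE)
    }
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind(s): ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "),
           call. = FALSE)
    }
    bad_trna <- features$kind == "tRNA" & !(features$label %in% AA3)
    if (any(bad_trna)) {
      stop("tRNA features must carry a standard amino-acid label; got: ",
           paste(unique(features$label[bad_trna]), collapse = ", "),
           call. = FALSE)
    }
  }
  rownames(features) <- NULL
  features
}

#' @export
print.phage_genome <- function(x, ...) {
  cat(sprintf("<phage_genome> %s: %s bp, %s, %d feature(s)\n",
              x$id, format(nchar(x$seq), big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat("  features:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.phage_genome <- function(x) nchar(x$seq)

#' Extract a subsequence in internal coordinates
#'
#' Returns `[start, end)` (0-based half-open) from a genome, wrapping the
#' origin for circular genomes when `end` exceeds the genome length.
#'
#' @param genome a [phage_genome].
#' @param start,end 0-based half-open interval.
#' @return a character scalar.
#' @export
genome_subseq <- function(genome, start, end) {
  n <- nchar(genome$seq)
  if (end <= n) return(substr(genome$seq, start + 1L, end))
  if (genome$topology != "circular") {
    stop("interval beyond the end of a linear genome", call. = FALSE)
  }
  paste0(substr(genome$seq, start + 1L, n), substr(genome$seq, 1L, end - n))
}

## Add feature rows; returns the modified genome.
add_features <- function(genome, df) {
  genome$features <- validate_features(
    rbind(genome$features, df[, names(empty_features()), drop = FALSE]),
    nchar(genome$seq))
  genome
}
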