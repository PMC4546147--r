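## External representations: FASTA / GenBank flat file (read), BED / GFF3
## (write+read), primer panel TSV, host-range CSV. Internal coordinates are
## 0-based half-open; BED shares that convention, GFF3 and GenBank are
## 1-based inclusive and converted at the boundary.

#' Read genomes from FASTA or GenBank flat files
#'
#' FASTA parsing is delegated to [Biostrings::readDNAStringSet()]; a minimal
#' GenBank flat-file reader maps `tRNA`, `gene` and `CDS` features (simple
#' `a..b` / `complement(a..b)` locations) onto genome features and reads the
#' topology from the LOCUS line.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return a single [phage_genome] for one-record files, otherwise a list of
#'   them (multi-record FASTA yields one genome per record).
#' @export
read_genome <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  genomes <- switch(format,
    fasta = read_genome_fasta(path),
    genbank = list(read_genome_genbank(path)))
  if (length(genomes) == 1L) genomes[[1L]] else genomes
}

read_genome_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (!length(set)) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    phage_genome(ids[i], as.character(set[[i]]), topology = "linear")
  })
}

## Minimal GenBank flat-file parser: LOCUS topology, FEATURES with simple
## spans, ORIGIN sequence. Compound (join/order) locations are rejected.
read_genome_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank record in ", path,
                           ": no LOCUS line", call. = FALSE)
  topology <- if (grepl("\\bcircular\\b", locus[1])) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("malformed GenBank record in ", path,
                         ": no ORIGIN section", call. = FALSE)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  feats <- empty_features()
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    ## feature headers start at column 6; qualifiers at column 22
    hdr <- grep("^ {5}\\S", block)
    for (h in seq_along(hdr)) {
      line <- block[hdr[h]]
      key <- sub("^\\s+", "", substr(line, 1, 20))
      key <- sub("\\s.*$", "", key)
      if (!key %in% c("tRNA", "gene", "CDS")) next
      loc <- trimws(substr(line, 21, nchar(line)))
      if (grepl("join|order", loc)) {
        stop("compound GenBank locations are not supported (record ", id,
             ", feature ", key, " at '", loc, "')", call. = FALSE)
      }
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) != 2L) {
        stop("cannot parse GenBank location '", loc, "' for feature ", key,
             call. = FALSE)
      }
      a <- as.integer(nums[1]); b <- as.integer(nums[2])
      qual_end <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(block)
      quals <- block[hdr[h]:qual_end]
      lab <- gb_qualifier(quals, "product")
      if (is.na(lab)) lab <- gb_qualifier(quals, "gene")
      if (is.na(lab)) lab <- key
      kind <- switch(key, tRNA = "tRNA", gene = "gene", CDS = "gene")
      if (kind == "tRNA") {
        ## "tRNA-Thr" style products -> amino-acid label
        m <- regmatches(lab, regexpr("tRNA-([A-Za-z]{3})", lab))
        if (length(m)) lab <- sub("tRNA-", "", m)
      }
      feats <- rbind(feats, data.frame(
        label = lab, start = a - 1L, end = b, strand = strand, kind = kind,
        stringsAsFactors = FALSE))
    }
  }
  phage_genome(id, sequence, topology = topology, features = feats)
}

gb_qualifier <- function(lines, name) {
  pat <- sprintf("/%s=\"([^\"]*)\"", name)
  hit <- regmatches(lines, regexpr(pat, lines))
  hit <- hit[lengths(regmatches(lines, regexpr(pat, lines))) > 0]
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) return(NA_character_)
  sub(sprintf(".*/%s=\"([^\"]*)\".*", name), "\\1", hit[1])
}

#' Write a genome to FASTA
#'
#' @param genome a [phage_genome].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Export genome features as BED or GFF3
#'
#' BED is written 0-based half-open, GFF3 1-based inclusive; re-importing a
#' written file with [read_intervals()] reproduces every interval and strand.
#'
#' @param genome a [phage_genome].
#' @param kinds character vector of feature kinds to export (subset of
#'   `tRNA, gene, repeat_unit, repeat_region, module, other`); an empty
#'   selection yields a header-only file.
#' @param path output file.
#' @param format `"bed"` or `"gff3"`.
#' @export
write_intervals <- function(genome, kinds, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  keep <- genome$features[genome$features$kind %in% kinds, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$id, nrow(keep)),
    ranges = IRanges::IRanges(start = keep$start + 1L, end = keep$end),
    strand = keep$strand)
  if (format == "bed") {
    if (nrow(keep) == 0L) {
      writeLines("track name=features", path)
      return(invisible(path))
    }
    gr$name <- paste(keep$kind, keep$label, sep = ":")
    gr$score <- rep(0L, nrow(keep))
    rtracklayer::export.bed(gr, path)
  } else {
    gr$type <- keep$kind
    gr$ID <- make.unique(paste(keep$kind, keep$label, sep = ":"))
    gr$Name <- keep$label
    rtracklayer::export.gff3(gr, path)
  }
  invisible(path)
}

#' Import intervals written by [write_intervals()]
#'
#' @param path BED or GFF3 file.
#' @param format `"bed"` or `"gff3"`.
#' @return a feature data frame in internal 0-based half-open coordinates
#'   with columns `label`, `start`, `end`, `strand`, `kind`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  gr <- if (format == "bed") rtracklayer::import.bed(path)
        else rtracklayer::import.gff3(path)
  if (!length(gr)) return(empty_features())
  nm <- if (format == "bed") gr$name else paste(gr$type, gr$Name, sep = ":")
  kind <- sub(":.*$", "", nm)
  label <- sub("^[^:]*:", "", nm)
  data.frame(label = label,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             kind = kind, stringsAsFactors = FALSE)
}

#' Primer panel
#'
#' @param name primer names.
#' @param sequence primer sequences, 15--40 nt over `A,C,G,T` (long primers,
#'   up to 40 nt, are the norm for these very AT-rich templates).
#' @param role `"forward"` or `"reverse"` for each primer.
#' @return a `primer_panel` data frame.
#' @export
primer_panel <- function(name, sequence, role) {
  sequence <- toupper(sequence)
  stopifnot(length(name) == length(sequence), length(role) == length(sequence))
  if (!all(role %in% c("forward", "reverse"))) {
    stop("primer role must be 'forward' or 'reverse'", call. = FALSE)
  }
  len <- nchar(sequence)
  if (any(len < 15L | len > 40L)) {
    stop("primer length must be in [15, 40] nt; offending: ",
         paste(name[len < 15L | len > 40L], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    check_dna(sequence[i], allow_n = FALSE, what = sprintf("primer '%s'", name[i]))
  }
  structure(data.frame(name = name, sequence = sequence, role = role,
                       stringsAsFactors = FALSE),
            class = c("primer_panel", "data.frame"))
}

#' Read a primer panel from TSV
#'
#' Expects columns `name`, `sequence`, `role`.
#'
#' @param path TSV file.
#' @return a `primer_panel`.
#' @export
read_primer_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "role")
  if (!all(need %in% names(df))) {
    stop("primer panel TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  primer_panel(df$name, df$sequence, df$role)
}

#' Write a primer panel to TSV
#' @param panel a `primer_panel`.
#' @param path output file.
#' @export
write_primer_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Host-range matrix
#'
#' Binary strain-by-phage lysis table behind spot-assay host-range screens.
#'
#' @param strains data frame with columns `strain` and `species`.
#' @param phages character vector of phage ids.
#' @param lysis binary matrix, `nrow(strains)` x `length(phages)`.
#' @return a `hostrange_matrix` object.
#' @export
hostrange_matrix <- function(strains, phages, lysis) {
  stopifnot(is.data.frame(strains), all(c("strain", "species") %in% names(strains)))
  lysis <- as.matrix(lysis)
  if (nrow(lysis) != nrow(strains) || ncol(lysis) != length(phages)) {
    stop("lysis matrix dimensions must match strain and phage lists",
         call. = FALSE)
  }
  if (!all(lysis %in% c(0, 1))) {
    stop("lysis entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(lysis) <- "integer"
  dimnames(lysis) <- list(strains$strain, phages)
  structure(list(strains = strains, phages = phages, lysis = lysis),
            class = "hostrange_matrix")
}

#' @export
print.hostrange_matrix <- function(x, ...) {
  cat(sprintf("<hostrange_matrix> %d strains x %d phages (%d lysis events)\n",
              nrow(x$lysis), ncol(x$lysis), sum(x$lysis)))
  invisible(x)
}

#' Read a host-range CSV
#'
#' Layout: header row with `strain,species,<phage ids...>`; one row per
#' strain; cells strictly `0`/`1`. Missing or non-binary cells are an error
#' (no imputation).
#'
#' @param path CSV file.
#' @return a [hostrange_matrix].
#' @export
read_hostrange <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 3L) {
    stop("host-range CSV needs strain, species and at least one phage column",
         call. = FALSE)
  }
  phages <- names(df)[-(1:2)]
  cells <- as.matrix(df[, -(1:2), drop = FALSE])
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow = nrow(cells)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-binary host-range cell '%s' at row %d (strain %s), column '%s'",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], df[[1]][bad[1, 1]],
      phages[bad[1, 2]]), call. = FALSE)
  }
  lysis <- matrix(as.integer(cells), nrow = nrow(df))
  hostrange_matrix(data.frame(strain = df[[1]], species = df[[2]],
                              stringsAsFactors = FALSE),
                   phages, lysis)
}

#' Write a host-range matrix to CSV
#' @param mat a [hostrange_matrix].
#' @param path output file.
#' @export
write_hostrange <- function(mat, path) {
  df <- cbind(mat$strains[, c("strain", "species")],
              as.data.frame(mat$lysis, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
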