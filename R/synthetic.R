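## Synthetic group II phage genomes with planted modular architecture.
##
## The generator emulates the published architecture: 150-190 kb circularly
## permuted genomes of ~27% G+C built from four modules (28-55 kb) separated
## by bipartite repeat regions (1-2.9 kb; arms of up to 18 units of 72-86 bp,
## each unit carrying the 13-nt core with <= 1 mismatch), inner spacers that
## may hold cargo ORFs, scattered single units, labelled tRNA loci, and a
## gp047 tail-fibre locus with or without an internal 0.2-2.5 kb deletion.
## Every genome comes with a machine-readable truth record so downstream
## detection can be scored exactly.

GP047_LEN <- 4000L

#' Generator configuration
#'
#' Defaults are the published study conditions: module and region size
#' ranges, unit geometry, core motif and mismatch allowance, G+C target,
#' subgroup marker states. `scale` shrinks the module size range (and the
#' genome length target) for fast simulation; repeat-region geometry is
#' deliberately never scaled, because the 13-nt core, the 72-86 bp unit
#' length and the detection gap thresholds are absolute quantities.
#'
#' @param seed integer RNG seed for this genome/cohort.
#' @param subgroup_label `"CP220like"` (all modules forward, tRNA Arg/Tyr,
#'   gp047 deletion) or `"CP21like"` (modules B and C inverted, tRNA
#'   Thr/Pro, intact gp047).
#' @param genome_length_target feasibility cap in bp (scaled by `scale`).
#' @param n_modules number of modules (default 4).
#' @param module_size_range module length range in bp (default 28-55 kb,
#'   scaled by `scale`).
#' @param region_size_range repeat-region span range in bp (default 1-2.9 kb).
#' @param units_per_arm_range units per arm (default 3-18).
#' @param unit_length_range repeat-unit length in bp (default 72-86).
#' @param core_motif the 13-nt core planted in every unit.
#' @param core_mismatches_max per-unit core mismatch cap (default 1).
#' @param gc_target per-base G+C fraction (default 0.272).
#' @param direct_regions indices of regions planted with both arms on the
#'   plus strand; `NULL` resolves to the subgroup default (CP21like: RR3;
#'   CP220like: RR1 and RR3). All other regions get inverted arms.
#' @param scattered_unit_count single repeat units planted inside module
#'   interiors, away from any region (default 3).
#' @param trna_labels two amino-acid labels; `NULL` resolves to the
#'   subgroup default (Thr/Pro vs Arg/Tyr).
#' @param gp047_deletion deletion length in bp (must be in 200-2500);
#'   `NULL` samples one per CP220like member.
#' @param scale module-size scale factor in (0, 1].
#' @param unit_mutation_rate per-base substitution rate applied to each
#'   unit's copy of its region's base unit (default 2%); core positions are
#'   mutated at most once per unit so the planted <=1-mismatch guarantee
#'   holds.
#' @param member_divergence per-base substitution rate applied to each
#'   cohort member's module backgrounds, spacers and gp047 copy (default
#'   0.5%; the within-subgroup divergence is not published, so this is the
#'   package's own setting, exposed here).
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             subgroup_label = c("CP220like", "CP21like"),
                             genome_length_target = 190000L,
                             n_modules = 4L,
                             module_size_range = c(28000L, 55000L),
                             region_size_range = c(1000L, 2900L),
                             units_per_arm_range = c(3L, 18L),
                             unit_length_range = c(72L, 86L),
                             core_motif = CORE_MOTIF,
                             core_mismatches_max = 1L,
                             gc_target = 0.272,
                             direct_regions = NULL,
                             scattered_unit_count = 3L,
                             trna_labels = NULL,
                             gp047_deletion = NULL,
                             scale = 1,
                             unit_mutation_rate = 0.02,
                             member_divergence = 0.005) {
  subgroup_label <- match.arg(subgroup_label)
  check_dna(core_motif, allow_n = FALSE, what = "core_motif")
  ranges <- list(module_size_range = module_size_range,
                 region_size_range = region_size_range,
                 units_per_arm_range = units_per_arm_range,
                 unit_length_range = unit_length_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop(nm, " must be an ordered (low, high) pair", call. = FALSE)
    }
  }
  if (gc_target <= 0 || gc_target >= 1) {
    stop("gc_target must be in (0, 1)", call. = FALSE)
  }
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
  if (!is.null(gp047_deletion) &&
      (gp047_deletion < 200L || gp047_deletion > 2500L)) {
    stop("gp047_deletion must be in [200, 2500] bp", call. = FALSE)
  }
  if (unit_length_range[1] < nchar(core_motif) + 20L) {
    stop("unit_length_range too small to hold the core motif with flanks",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), subgroup_label = subgroup_label,
                 genome_length_target = genome_length_target,
                 n_modules = as.integer(n_modules),
                 module_size_range = module_size_range,
                 region_size_range = region_size_range,
                 units_per_arm_range = units_per_arm_range,
                 unit_length_range = unit_length_range,
                 core_motif = core_motif,
                 core_mismatches_max = as.integer(core_mismatches_max),
                 gc_target = gc_target, direct_regions = direct_regions,
                 scattered_unit_count = as.integer(scattered_unit_count),
                 trna_labels = trna_labels, gp047_deletion = gp047_deletion,
                 scale = scale, unit_mutation_rate = unit_mutation_rate,
                 member_divergence = member_divergence),
            class = "generator_config")
}

## Subgroup-dependent defaults resolved at generation time.
resolve_subgroup <- function(config) {
  sg <- config$subgroup_label
  list(
    trna = if (!is.null(config$trna_labels)) config$trna_labels
           else if (sg == "CP21like") c("Thr", "Pro") else c("Arg", "Tyr"),
    direct = if (!is.null(config$direct_regions)) config$direct_regions
             else if (sg == "CP21like") 3L else c(1L, 3L),
    inverted_modules = if (sg == "CP21like") c(2L, 3L) else integer(0),
    deletion = sg == "CP220like")
}

## Run code under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

the <- new.env(parent = emptyenv())

#' The generator's fixed gp047 reference sequence
#'
#' A deterministic ~4 kb coding-like stretch (fixed internal seed, ~27%
#' G+C, free of core-motif near-matches) that anchors the deletion
#' detector. Intact in CP21like genomes; CP220like genomes carry an
#' internal deletion.
#'
#' @return a character scalar of length 4000.
#' @export
gp047_reference <- function() {
  if (is.null(the$gp047)) {
    the$gp047 <- with_seed(20470213L, {
      collapse_seq(scrub_motif(random_bases(GP047_LEN), CORE_MOTIF, 1L))
    })
  }
  the$gp047
}

## Remove near-matches (<= max_mm, both strands) to `motif` from a base
## vector so planted truth stays exhaustive. An exempt plus-strand hit at
## `exempt_start` (0-based) is preserved.
scrub_motif <- function(bases, motif, max_mm, exempt_start = NULL) {
  L <- nchar(motif)
  rc <- revcomp(motif)
  for (iter in 1:10) {
    s <- collapse_seq(bases)
    hit_p <- which(hamming_scan(s, motif) <= max_mm) - 1L
    hit_m <- which(hamming_scan(s, rc) <= max_mm) - 1L
    if (!is.null(exempt_start)) hit_p <- setdiff(hit_p, exempt_start)
    hits <- sort(unique(c(hit_p, hit_m)))
    if (!length(hits)) return(bases)
    for (p in hits) {
      cand <- (p + c(4L, 7L, 10L))            # spread >max_mm changes
      if (!is.null(exempt_start)) {
        cand <- cand[cand < exempt_start | cand >= exempt_start + L]
      }
      cand <- cand[cand >= 0L & cand < length(bases)]
      for (q in cand) {
        bases[q + 1L] <- sample(setdiff(DNA_BASES, bases[q + 1L]), 1L)
      }
    }
  }
  bases
}

## Cohort base: the ancestral sequence material every member derives from.
## Uses the caller's RNG stream.
make_cohort_base <- function(config) {
  n_mod <- config$n_modules
  msr <- round(config$module_size_range * config$scale)
  if (n_mod * msr[1] + n_mod * config$region_size_range[1] >
      config$genome_length_target * config$scale) {
    stop("infeasible config: minimum module sizes exceed genome_length_target",
         call. = FALSE)
  }
  module_len <- as.integer(round(stats::runif(n_mod, msr[1], msr[2])))
  ## the gp047 host module must hold the 4 kb locus with margins
  module_len[n_mod] <- max(module_len[n_mod], GP047_LEN + 1200L + 2000L)
  module_bg <- lapply(module_len, function(l) {
    scrub_motif(random_bases(l, config$gc_target), config$core_motif,
                config$core_mismatches_max)
  })

  regions <- lapply(seq_len(n_mod), function(r) {
    rsr <- config$region_size_range
    target <- round(stats::runif(1, rsr[1] + 250, rsr[2] - 200))
    ulen <- sample(seq(config$unit_length_range[1],
                       config$unit_length_range[2]), 1L)
    core_off <- sample(seq(15L, ulen - nchar(config$core_motif) - 15L), 1L)
    unit <- random_bases(ulen, config$gc_target)
    unit[(core_off + 1L):(core_off + nchar(config$core_motif))] <-
      split_seq(config$core_motif)
    unit <- scrub_motif(unit, config$core_motif, config$core_mismatches_max,
                        exempt_start = core_off)
    inner_len <- round(stats::runif(1, 320,
                                    min(1150, target - 2 * 3 * ulen)))
    inner_len <- max(inner_len, 320L)
    inner <- scrub_motif(random_bases(inner_len, config$gc_target),
                         config$core_motif, config$core_mismatches_max)
    total_units <- max(2L * config$units_per_arm_range[1],
                       round((target - inner_len) / ulen))
    n_left <- round(total_units * stats::runif(1, 0.35, 0.65))
    n_left <- clamp(n_left, config$units_per_arm_range)
    n_right <- clamp(total_units - n_left, config$units_per_arm_range)
    list(unit = unit, unit_len = ulen, core_offset = core_off,
         inner = inner, n_left = n_left, n_right = n_right,
         cargo = r <= 2L)
  })

  ## subgroup-ancestral gp047 variants: shared reference, 2% apart
  gp047 <- list(
    CP21like = collapse_seq(scrub_motif(
      mutate_bases(split_seq(gp047_reference()), 0.02, config$gc_target),
      config$core_motif, config$core_mismatches_max)),
    CP220like = collapse_seq(scrub_motif(
      mutate_bases(split_seq(gp047_reference()), 0.02, config$gc_target),
      config$core_motif, config$core_mismatches_max)))

  ## ancestral deletion: one event in the subgroup ancestor, shared by
  ## cohort members (sizes still span the published 0.2-2.5 kb window
  ## across cohorts)
  gp047_del <- sample(200:2500, 1L)

  trna_pos <- round(module_len[1] * c(0.10, 0.16))

  ## scattered single units: fresh units with an exact core, placed in
  ## module interiors with >= 1700 bp clearance from module edges
  scattered <- list()
  margin <- 1700L
  mod_cycle <- rep(seq_len(n_mod), length.out = max(config$scattered_unit_count, 1L))
  for (i in seq_len(config$scattered_unit_count)) {
    m <- mod_cycle[i]
    lo <- margin + (i %/% n_mod) * 2200L
    hi <- module_len[m] - margin - 100L
    if (lo >= hi) next
    ulen <- sample(seq(config$unit_length_range[1],
                       config$unit_length_range[2]), 1L)
    off <- sample(seq(15L, ulen - nchar(config$core_motif) - 15L), 1L)
    u <- random_bases(ulen, config$gc_target)
    u[(off + 1L):(off + nchar(config$core_motif))] <- split_seq(config$core_motif)
    u <- scrub_motif(u, config$core_motif, config$core_mismatches_max,
                     exempt_start = off)
    scattered[[length(scattered) + 1L]] <- list(
      module = m, pos = as.integer(round(stats::runif(1, lo, hi))),
      unit = u, strand = sample(c("+", "-"), 1L))
  }

  list(module_len = module_len, module_bg = module_bg, regions = regions,
       gp047 = gp047, gp047_del = gp047_del, trna_pos = trna_pos,
       scattered = scattered)
}

clamp <- function(x, range) as.integer(pmin(pmax(x, range[1]), range[2]))

#' Generate one synthetic phage genome with its truth record
#'
#' The genome is a concatenation module-region-module-...-region, held
#' linearised with `topology = "circular"` (the last region abuts the
#' origin, so circular segmentation recovers exactly `n_modules` modules).
#' CP21like genomes carry modules B and C in reverse-complement
#' orientation; CP220like genomes are all-forward and carry the gp047
#' deletion. Identical `config` (including seed) gives identical output.
#'
#' @param config a [generator_config()].
#' @param base internal: a shared cohort base from the same config family;
#'   `NULL` builds a private one from the config seed.
#' @param member_index internal: cohort member number, used to derive the
#'   member's private RNG stream from `(seed, index)`.
#' @param id genome id; default derives from subgroup and member index.
#' @return `list(genome = <phage_genome>, truth = <phage_truth>)`.
#' @export
generate_genome <- function(config, base = NULL, member_index = 0L,
                            id = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n_mod <- config$n_modules
  msr <- round(config$module_size_range * config$scale)
  if (n_mod * msr[1] + n_mod * config$region_size_range[1] >
      config$genome_length_target * config$scale) {
    stop("infeasible config: minimum module sizes exceed genome_length_target",
         call. = FALSE)
  }
  set.seed(child_seed(config$seed, member_index))
  if (is.null(base)) base <- make_cohort_base(config)
  sg <- resolve_subgroup(config)
  if (is.null(id)) id <- sprintf("%s_%d", config$subgroup_label,
                                 max(member_index, 1L))
  motif_len <- nchar(config$core_motif)

  ## --- member module contents (CP220 frame first) ------------------------
  mod_seq <- character(n_mod)
  mod_feats <- vector("list", n_mod)   # features in module-local coords
  gp047_truth <- NULL
  for (m in seq_len(n_mod)) {
    bg <- mutate_bases(base$module_bg[[m]], config$member_divergence,
                       config$gc_target)
    bg <- scrub_motif(bg, config$core_motif, config$core_mismatches_max)
    feats <- empty_features()
    if (m == n_mod) {
      ## splice the member's gp047 copy, preserving module length
      g <- mutate_bases(split_seq(base$gp047[[config$subgroup_label]]),
                        config$member_divergence, config$gc_target)
      g <- scrub_motif(g, config$core_motif, config$core_mismatches_max)
      del <- 0L
      if (sg$deletion) {
        del <- if (!is.null(config$gp047_deletion))
          as.integer(config$gp047_deletion)
        else base$gp047_del
        del <- min(del, GP047_LEN - 1200L)
        dstart <- 600L   # clear of both anchor-seed zones
        g <- g[-((dstart + 1L):(dstart + del))]
      }
      glen <- length(g)
      need_bg <- base$module_len[m] - glen
      at <- 1000L
      bg <- c(bg[1:at], g, bg[(at + 1L):need_bg])
      feats <- rbind(feats, data.frame(
        label = "gp047", start = at, end = at + glen, strand = "+",
        kind = "gene", stringsAsFactors = FALSE))
      gp047_truth <- list(module = m, offset = at, length = glen,
                          deletion = del)
    }
    if (m == 1L) {
      feats <- rbind(feats, data.frame(
        label = sg$trna, start = base$trna_pos, end = base$trna_pos + 76L,
        strand = "+", kind = "tRNA", stringsAsFactors = FALSE))
    }
    for (sc in base$scattered) {
      if (sc$module != m) next
      u <- if (sc$strand == "-") split_seq(revcomp(collapse_seq(sc$unit)))
           else sc$unit
      bg[(sc$pos + 1L):(sc$pos + length(u))] <- u
      feats <- rbind(feats, data.frame(
        label = "single", start = sc$pos, end = sc$pos + length(u),
        strand = sc$strand, kind = "repeat_unit", stringsAsFactors = FALSE))
    }
    s <- collapse_seq(bg)
    if (m %in% sg$inverted_modules) {
      len <- nchar(s)
      s <- revcomp(s)
      if (nrow(feats)) {
        new_start <- len - feats$end
        feats$end <- len - feats$start
        feats$start <- new_start
        feats$strand <- ifelse(feats$strand == "+", "-", "+")
      }
    }
    mod_seq[m] <- s
    mod_feats[[m]] <- feats
  }

  ## --- member repeat regions --------------------------------------------
  region_build <- lapply(seq_len(n_mod), function(r) {
    rb <- base$regions[[r]]
    ## per-member arm-size jitter (unit counts vary even within a
    ## subgroup); counts as noise, so it is off in noise-free runs
    jit <- function(n) {
      if (config$unit_mutation_rate <= 0) return(n)
      clamp(n + sample(-1:1, 1L), config$units_per_arm_range)
    }
    n_l <- jit(rb$n_left); n_r <- jit(rb$n_right)
    make_unit <- function() {
      u <- rb$unit
      core_idx <- (rb$core_offset + 1L):(rb$core_offset + motif_len)
      flank <- setdiff(seq_along(u), core_idx)
      hit <- flank[stats::runif(length(flank)) < config$unit_mutation_rate]
      for (q in hit) u[q] <- mutate_one(u[q], config$gc_target)
      if (config$unit_mutation_rate > 0 &&
          config$core_mismatches_max > 0 &&
          stats::runif(1) < min(0.3, motif_len * config$unit_mutation_rate)) {
        q <- sample(core_idx, 1L)
        u[q] <- mutate_one(u[q], config$gc_target)
      }
      u
    }
    left_units <- replicate(n_l, make_unit(), simplify = FALSE)
    right_units <- replicate(n_r, make_unit(), simplify = FALSE)
    left <- collapse_seq(unlist(left_units))
    right_f <- collapse_seq(unlist(right_units))
    inverted <- !(r %in% sg$direct)
    right <- if (inverted) revcomp(right_f) else right_f
    inner <- collapse_seq(scrub_motif(
      mutate_bases(rb$inner, config$member_divergence, config$gc_target),
      config$core_motif, config$core_mismatches_max))
    ulen <- vapply(left_units, length, integer(1))
    urlen <- vapply(right_units, length, integer(1))
    list(seq = paste0(left, inner, right),
         n_left = n_l, n_right = n_r, inverted = inverted,
         left_len = nchar(left), inner_len = nchar(inner),
         right_len = nchar(right), unit_len = ulen, unit_rlen = urlen,
         core_offset = rb$core_offset, cargo = rb$cargo)
  })

  ## --- assembly ----------------------------------------------------------
  pieces <- character(0)
  feats <- empty_features()
  truth_modules <- data.frame()
  truth_regions <- data.frame()
  truth_units <- data.frame()
  offset <- 0L
  module_ids <- LETTERS[seq_len(n_mod)]
  for (m in seq_len(n_mod)) {
    s <- mod_seq[m]
    f <- mod_feats[[m]]
    if (nrow(f)) {
      f$start <- f$start + offset; f$end <- f$end + offset
      feats <- rbind(feats, f)
    }
    ori <- if (m %in% sg$inverted_modules) "-" else "+"
    feats <- rbind(feats, data.frame(
      label = module_ids[m], start = offset, end = offset + nchar(s),
      strand = ori, kind = "module", stringsAsFactors = FALSE))
    truth_modules <- rbind(truth_modules, data.frame(
      id = module_ids[m], start = offset, end = offset + nchar(s),
      orientation = ori, stringsAsFactors = FALSE))
    pieces <- c(pieces, s)
    offset <- offset + nchar(s)

    rb <- region_build[[m]]
    rstart <- offset
    rid <- paste0("RR", m)
    feats <- rbind(feats, data.frame(
      label = rid, start = rstart, end = rstart + nchar(rb$seq),
      strand = "+", kind = "repeat_region", stringsAsFactors = FALSE))
    ## per-unit truth intervals
    lu_end <- cumsum(rb$unit_len)
    lu <- data.frame(region = rid, start = rstart + c(0L, lu_end[-rb$n_left]),
                     end = rstart + lu_end, strand = "+",
                     stringsAsFactors = FALSE)
    ru_end <- cumsum(rb$unit_rlen)
    ru_s <- c(0L, ru_end[-rb$n_right]); ru_e <- ru_end
    roff <- rstart + rb$left_len + rb$inner_len
    if (rb$inverted) {
      tot <- rb$right_len
      ru <- data.frame(region = rid, start = roff + tot - ru_e,
                       end = roff + tot - ru_s, strand = "-",
                       stringsAsFactors = FALSE)
      ru <- ru[order(ru$start), ]
    } else {
      ru <- data.frame(region = rid, start = roff + ru_s, end = roff + ru_e,
                       strand = "+", stringsAsFactors = FALSE)
    }
    units <- rbind(lu, ru)
    feats <- rbind(feats, data.frame(
      label = rid, start = units$start, end = units$end,
      strand = units$strand, kind = "repeat_unit", stringsAsFactors = FALSE))
    truth_units <- rbind(truth_units, units)
    inner_start <- rstart + rb$left_len
    if (rb$cargo) {
      pad <- round(rb$inner_len * 0.2)
      feats <- rbind(feats, data.frame(
        label = "cargo_orf", start = inner_start + pad,
        end = inner_start + rb$inner_len - pad, strand = "+",
        kind = "gene", stringsAsFactors = FALSE))
    }
    truth_regions <- rbind(truth_regions, data.frame(
      id = rid, start = rstart, end = rstart + nchar(rb$seq),
      inner_start = inner_start, inner_end = inner_start + rb$inner_len,
      units_left = rb$n_left, units_right = rb$n_right,
      orientation = if (rb$inverted) "inverted" else "direct",
      stringsAsFactors = FALSE))
    pieces <- c(pieces, rb$seq)
    offset <- offset + nchar(rb$seq)
  }

  sequence <- paste(pieces, collapse = "")
  genome <- phage_genome(id, sequence, topology = "circular",
                         features = feats)
  sites <- lapply(builtin_enzymes(), function(e) {
    which(hamming_scan(sequence, e$site) == 0L) - 1L
  })
  gp_row <- feats[feats$label == "gp047", , drop = FALSE]
  gp047_truth$start <- gp_row$start[1]
  gp047_truth$end <- gp_row$end[1]
  trna_rows <- feats[feats$kind == "tRNA", , drop = FALSE]
  scattered_rows <- feats[feats$kind == "repeat_unit" &
                          feats$label == "single", , drop = FALSE]
  truth <- structure(list(
    genome_id = id, subgroup = config$subgroup_label,
    length = nchar(sequence),
    modules = truth_modules, regions = truth_regions, units = truth_units,
    trna = data.frame(label = trna_rows$label, start = trna_rows$start,
                      end = trna_rows$end, stringsAsFactors = FALSE),
    gp047 = list(start = gp047_truth$start, end = gp047_truth$end,
                 deletion = gp047_truth$deletion),
    scattered = scattered_rows[, c("start", "end", "strand")],
    sites = sites,
    signature = paste(paste0(truth_modules$id, truth_modules$orientation),
                      collapse = ",")), class = "phage_truth")
  list(genome = genome, truth = truth)
}

#' @export
print.phage_truth <- function(x, ...) {
  cat(sprintf("<phage_truth> %s (%s): %s bp, signature %s, gp047 deletion %d bp\n",
              x$genome_id, x$subgroup, format(x$length, big.mark = ","),
              x$signature, x$gp047$deletion))
  invisible(x)
}

#' Generate a cohort of synthetic phages from both subgroups
#'
#' All members share one ancestral module/unit/gp047 sequence set drawn
#' from `seed`, then diverge by per-member point mutation and per-arm
#' unit-count jitter; subgroup membership fixes module orientations and
#' marker states. Members `1..n` are CP21like, `n+1..2n` CP220like.
#'
#' @param n_per_subgroup members per subgroup (>= 1).
#' @param base_config shared [generator_config()]; its `subgroup_label` is
#'   ignored.
#' @param seed cohort seed (defaults to `base_config$seed`).
#' @return a list of `list(genome, truth)` pairs.
#' @export
generate_cohort <- function(n_per_subgroup, base_config = generator_config(),
                            seed = base_config$seed) {
  stopifnot(n_per_subgroup >= 1L)
  set.seed(seed)
  base <- make_cohort_base(base_config)
  labels <- rep(c("CP21like", "CP220like"), each = n_per_subgroup)
  lapply(seq_along(labels), function(i) {
    cfg <- base_config
    cfg$subgroup_label <- labels[i]
    cfg$seed <- as.integer(seed)
    idx <- ((i - 1L) %% n_per_subgroup) + 1L
    generate_genome(cfg, base = base, member_index = i,
                    id = sprintf("%s_%d", labels[i], idx))
  })
}

#' Simulate a spot-assay host-range matrix for a phage panel
#'
#' Strains of the two host species are screened against every phage.
#' Within a subgroup, phages share a strain-level latent susceptibility
#' (drawn once per strain and subgroup), so same-subgroup lysis profiles
#' correlate strongly; a small per-cell redraw rate injects the minor
#' within-subgroup divergence seen in real panels. Strains of non-host
#' species (C. lari, C. fetus, C. sputorum, C. hyointestinalis) are always
#' negative. Marginal lysis probabilities equal the supplied rates.
#'
#' @param phage_subgroups named character vector mapping phage id to
#'   subgroup label, or a cohort list from [generate_cohort()].
#' @param n_jejuni,n_coli numbers of C. jejuni / C. coli strains (defaults
#'   227 and 18, the published panel sizes).
#' @param susceptibility named list `subgroup -> c(jejuni = p, coli = p)`;
#'   defaults approximate the published per-subgroup positivity rates.
#' @param redraw_rate per-cell probability of an independent redraw
#'   (default 0.05).
#' @param other_species named vector of always-negative strain counts.
#' @param seed RNG seed.
#' @return a [hostrange_matrix].
#' @export
generate_hostrange <- function(phage_subgroups,
                               n_jejuni = 227L, n_coli = 18L,
                               susceptibility = list(
                                 CP21like = c(jejuni = 0.057, coli = 0.22),
                                 CP220like = c(jejuni = 0.093, coli = 0.55)),
                               redraw_rate = 0.05,
                               other_species = c(lari = 5L, fetus = 2L,
                                                 sputorum = 2L,
                                                 hyointestinalis = 1L),
                               seed = 1L) {
  if (is.list(phage_subgroups) && !is.null(phage_subgroups[[1]]$truth)) {
    phage_subgroups <- stats::setNames(
      vapply(phage_subgroups, function(x) x$truth$subgroup, character(1)),
      vapply(phage_subgroups, function(x) x$truth$genome_id, character(1)))
  }
  phages <- names(phage_subgroups)
  sgs <- unname(phage_subgroups)
  for (p in unlist(susceptibility)) {
    if (p < 0 || p > 1) stop("lysis probabilities must be in [0, 1]",
                             call. = FALSE)
  }
  set.seed(seed)
  species <- c(rep("C. jejuni", n_jejuni), rep("C. coli", n_coli),
               rep(paste0("C. ", names(other_species)), other_species))
  host_key <- c("C. jejuni" = "jejuni", "C. coli" = "coli")
  n_strain <- length(species)
  strains <- data.frame(
    strain = paste0("S", formatC(seq_len(n_strain), width = 3, flag = "0")),
    species = species, stringsAsFactors = FALSE)
  sub_levels <- unique(sgs)
  latent <- matrix(stats::runif(n_strain * length(sub_levels)),
                   nrow = n_strain, dimnames = list(NULL, sub_levels))
  lysis <- matrix(0L, n_strain, length(phages))
  for (j in seq_along(phages)) {
    sg <- sgs[j]
    for (i in seq_len(n_strain)) {
      key <- host_key[species[i]]
      if (is.na(key)) next
      p <- susceptibility[[sg]][[key]]
      if (is.null(p)) next
      cell <- as.integer(latent[i, sg] < p)
      if (p > 0 && p < 1 && stats::runif(1) < redraw_rate) {
        cell <- as.integer(stats::runif(1) < p)
      }
      lysis[i, j] <- cell
    }
  }
  hostrange_matrix(strains, phages, lysis)
}

#' Write / read a truth record as TSV
#'
#' Long-format plain-text representation that round-trips every planted
#' interval: one row per module, region, unit, tRNA, gp047, scattered unit
#' and restriction site.
#'
#' @param truth a `phage_truth`.
#' @param path TSV file.
#' @return `write_truth` the path, invisibly; `read_truth` a `phage_truth`.
#' @export
write_truth <- function(truth, path) {
  rows <- list(
    data.frame(record = "meta", id = "subgroup", start = NA, end = NA,
               orientation = NA, value = truth$subgroup),
    data.frame(record = "meta", id = "length", start = NA, end = NA,
               orientation = NA, value = as.character(truth$length)),
    data.frame(record = "module", id = truth$modules$id,
               start = truth$modules$start, end = truth$modules$end,
               orientation = truth$modules$orientation, value = ""),
    data.frame(record = "region", id = truth$regions$id,
               start = truth$regions$start, end = truth$regions$end,
               orientation = truth$regions$orientation,
               value = sprintf("units_left=%d;units_right=%d;inner_start=%d;inner_end=%d",
                               truth$regions$units_left,
                               truth$regions$units_right,
                               truth$regions$inner_start,
                               truth$regions$inner_end)),
    data.frame(record = "unit", id = truth$units$region,
               start = truth$units$start, end = truth$units$end,
               orientation = truth$units$strand, value = ""),
    data.frame(record = "trna", id = truth$trna$label,
               start = truth$trna$start, end = truth$trna$end,
               orientation = "+", value = ""),
    data.frame(record = "gp047", id = "gp047", start = truth$gp047$start,
               end = truth$gp047$end, orientation = "+",
               value = sprintf("deletion=%d", truth$gp047$deletion)))
  if (nrow(truth$scattered)) {
    rows <- c(rows, list(data.frame(
      record = "scattered", id = "single", start = truth$scattered$start,
      end = truth$scattered$end, orientation = truth$scattered$strand,
      value = "")))
  }
  for (enz in names(truth$sites)) {
    if (length(truth$sites[[enz]])) {
      rows <- c(rows, list(data.frame(
        record = "site", id = enz, start = truth$sites[[enz]],
        end = NA, orientation = "+", value = "")))
    }
  }
  df <- do.call(rbind, rows)
  df <- cbind(genome = truth$genome_id, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(rec) df[df$record == rec, , drop = FALSE]
  meta <- pick("meta")
  reg <- pick("region")
  kv <- function(s, key) as.integer(sub(sprintf(".*%s=([0-9-]+).*", key), "\\1", s))
  un <- pick("unit")
  tr <- pick("trna")
  gp <- pick("gp047")
  sc <- pick("scattered")
  si <- pick("site")
  mo <- pick("module")
  structure(list(
    genome_id = df$genome[1],
    subgroup = meta$value[meta$id == "subgroup"],
    length = as.integer(meta$value[meta$id == "length"]),
    modules = data.frame(id = mo$id, start = mo$start, end = mo$end,
                         orientation = mo$orientation,
                         stringsAsFactors = FALSE),
    regions = data.frame(id = reg$id, start = reg$start, end = reg$end,
                         inner_start = kv(reg$value, "inner_start"),
                         inner_end = kv(reg$value, "inner_end"),
                         units_left = kv(reg$value, "units_left"),
                         units_right = kv(reg$value, "units_right"),
                         orientation = reg$orientation,
                         stringsAsFactors = FALSE),
    units = data.frame(region = un$id, start = un$start, end = un$end,
                       strand = un$orientation, stringsAsFactors = FALSE),
    trna = data.frame(label = tr$id, start = tr$start, end = tr$end,
                      stringsAsFactors = FALSE),
    gp047 = list(start = gp$start[1], end = gp$end[1],
                 deletion = kv(gp$value[1], "deletion")),
    scattered = data.frame(start = sc$start, end = sc$end,
                           strand = sc$orientation, stringsAsFactors = FALSE),
    sites = lapply(split(si$start, si$id), as.integer),
    signature = paste(paste0(mo$id, mo$orientation), collapse = ",")),
    class = "phage_truth")
}
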