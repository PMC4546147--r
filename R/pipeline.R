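## End-to-end typing: collect every computable criterion for a genome
## against a reference and call the subgroup. This is the programmatic
## equivalent of running the repeat scan, segmentation, architecture
## comparison, marker checks and assays by hand.

#' Type one phage genome against a reference genome
#'
#' Runs repeat-region detection and module segmentation on the query,
#' compares its architecture to the reference, reads tRNA labels from the
#' query's annotations, detects the gp047 deletion state, digests with
#' VspI (when prototypes are supplied) and runs junction typing PCR (when
#' panels are supplied), then combines everything with
#' [classify_subgroup()].
#'
#' @param genome query [phage_genome].
#' @param reference reference [phage_genome] (all-forward arrangement).
#' @param reference_modules module data frame for the reference; computed
#'   by detection when `NULL`.
#' @param panels junction panels from [design_typing_panels()] (optional).
#' @param prototypes list of `CP21`/`CP220` [digest()] patterns (optional).
#' @param reference_gp047 reference gp047 sequence.
#' @param k dot-plot word size.
#' @return a list with `call` (a `subgroup_call`), `signature`,
#'   `regions`, `modules`, `gp047`, `pcr`.
#' @export
type_phage <- function(genome, reference, reference_modules = NULL,
                       panels = NULL, prototypes = NULL,
                       reference_gp047 = gp047_reference(), k = 31L) {
  det <- find_repeat_regions(genome)
  bip <- det$regions[!vapply(det$regions, function(r) r$single_armed,
                             logical(1))]
  modules <- segment_modules(genome, bip)
  if (is.null(reference_modules)) {
    ref_det <- find_repeat_regions(reference)
    ref_bip <- ref_det$regions[!vapply(ref_det$regions,
                                       function(r) r$single_armed,
                                       logical(1))]
    reference_modules <- segment_modules(reference, ref_bip)
  }
  arch <- compare_architectures(genome, modules, reference,
                                reference_modules, k = k)
  trna <- genome$features$label[genome$features$kind == "tRNA"]
  gp <- detect_gp047_deletion(genome, reference_gp047)
  dp <- if (!is.null(prototypes)) digest(genome, "VspI") else NULL
  pcr <- if (!is.null(panels)) typing_pcr(genome, panels) else NULL
  call <- classify_subgroup(
    signature = arch$signature,
    trna = if (length(trna)) trna else NULL,
    gp047 = gp, digest_pattern = dp,
    pcr_profile = if (!is.null(pcr)) pcr$profile else NULL,
    prototypes = prototypes, phage = genome$id)
  list(call = call, signature = arch$signature, regions = det$regions,
       modules = modules, gp047 = gp, pcr = pcr)
}

#' Type every member of a synthetic cohort
#'
#' Uses the first CP220like member as the reference (its truth modules as
#' the reference segmentation), builds junction typing panels and VspI
#' prototypes from the cohort itself, and types every member with
#' [type_phage()].
#'
#' @param cohort list from [generate_cohort()].
#' @param use_pcr,use_digest include the PCR / digest criteria.
#' @return a data frame with one row per member: `phage`, `subgroup`
#'   (truth), `call`, `signature`, `concordance`, `atypical`.
#' @export
type_cohort <- function(cohort, use_pcr = TRUE, use_digest = TRUE) {
  sgs <- vapply(cohort, function(x) x$truth$subgroup, character(1))
  ref_i <- which(sgs == "CP220like")[1L]
  ref21_i <- which(sgs == "CP21like")[1L]
  ref <- cohort[[ref_i]]$genome
  ref_modules <- cohort[[ref_i]]$truth$modules
  panels <- if (use_pcr) design_typing_panels(ref, ref_modules) else NULL
  prototypes <- if (use_digest) {
    list(CP21 = digest(cohort[[ref21_i]]$genome, "VspI"),
         CP220 = digest(ref, "VspI"))
  } else NULL
  rows <- lapply(cohort, function(member) {
    res <- type_phage(member$genome, ref, ref_modules, panels, prototypes)
    data.frame(phage = member$genome$id, subgroup = member$truth$subgroup,
               call = res$call$call, signature = res$signature,
               concordance = res$call$concordance,
               atypical = res$call$atypical, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
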