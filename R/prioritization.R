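#' Candidate-variant filter configuration
#'
#' Thresholds for the case-only candidate filter: retain variants that are
#' rare in external reference genomes (`external_af < external_af_max`),
#' damaging, conserved (optionally), carried by at least `min_case_carriers`
#' cases and at most `max_control_carriers` controls.
#'
#' @param external_af_max Upper bound (exclusive) on external population
#'   allele frequency (default 0.05).
#' @param min_case_carriers Minimum number of case carriers (default 2).
#' @param max_control_carriers Maximum number of control carriers (default 0,
#'   i.e. case-only).
#' @param require_conserved Require the conservation flag (default TRUE).
#' @param require_novel Require absence from dbSNP (default FALSE).
#' @param strict_external_af If TRUE, variants with unknown external frequency
#'   fail the rarity rule; by default a variant absent from reference genomes
#'   is taken to be at most rare and passes.
#' @return A list of class `prioritization_config`.
#' @export
prioritization_config <- function(external_af_max = 0.05,
                                  min_case_carriers = 2L,
                                  max_control_carriers = 0L,
                                  require_conserved = TRUE,
                                  require_novel = FALSE,
                                  strict_external_af = FALSE) {
  stopifnot(external_af_max > 0, external_af_max <= 1,
            min_case_carriers >= 0, max_control_carriers >= 0)
  structure(list(external_af_max = external_af_max,
                 min_case_carriers = as.integer(min_case_carriers),
                 max_control_carriers = as.integer(max_control_carriers),
                 require_conserved = isTRUE(require_conserved),
                 require_novel = isTRUE(require_novel),
                 strict_external_af = isTRUE(strict_external_af)),
            class = "prioritization_config")
}

#' Classify a variant as damaging
#'
#' The damaging classes are frameshift, stop-gain, splice-affecting, and
#' missense predicted harmful by SIFT *or* PolyPhen2 (either predictor
#' suffices). Everything else — synonymous, inframe indels, stop-loss,
#' tolerated missense — is not damaging.
#'
#' @param annotations Annotation data.frame as from [load_annotations()].
#' @return Character vector: one of `"frameshift"`, `"stop_gain"`,
#'   `"splice"`, `"damaging_missense"`, or `NA` for non-damaging variants.
#' @export
classify_damaging <- function(annotations) {
  cons <- annotations$consequence
  out <- rep(NA_character_, length(cons))
  out[cons == "frameshift"] <- "frameshift"
  out[cons == "stop_gain"] <- "stop_gain"
  out[cons == "splice"] <- "splice"
  dm <- cons == "missense" &
    (annotations$sift_call == "damaging" | annotations$polyphen2_call == "damaging")
  out[dm] <- "damaging_missense"
  out
}

#' Tally variants by consequence class
#'
#' Exhaustive partition of the annotated variants over the eight consequence
#' classes; counts sum to the number of annotated variants.
#'
#' @param annotations Annotation data.frame.
#' @return Named integer vector over all consequence classes.
#' @export
consequence_tally <- function(annotations) {
  tab <- table(factor(annotations$consequence, levels = consequence_levels))
  out <- as.integer(tab)
  names(out) <- consequence_levels
  out
}

carrier_counts <- function(dosage, case_ids, control_ids) {
  carrier <- !is.na(dosage) & dosage >= 1L
  list(case = colSums(carrier[case_ids, , drop = FALSE]),
       control = colSums(carrier[control_ids, , drop = FALSE]))
}

#' Case-only candidate filter
#'
#' Applies, in order, the rules that define a novel candidate variant: site
#' QC already passed, rare in external genomes, damaging, conserved (if
#' required), novel (if required), carried by at least `min_case_carriers`
#' cases and at most `max_control_carriers` controls. A carrier is a sample
#' with dosage >= 1; depth is ignored once QC has passed. The full per-variant
#' rule trail is attached as attribute `"filter_trail"` so the retained set
#' can be reconstructed by replaying it.
#'
#' @param genotypes A [genotype_matrix()] restricted to the analysis set.
#' @param phenotypes Phenotype data.frame covering the samples.
#' @param annotations Annotation data.frame.
#' @param qc Site-QC data.frame from [site_qc()].
#' @param config A [prioritization_config()].
#' @return A data.frame of retained candidates (`vid`, `gene`,
#'   `damaging_class`, `case_carriers`, `control_carriers`), sorted by
#'   (gene, vid), with attribute `filter_trail`: a data.frame of per-variant
#'   pass/fail for every rule in application order.
#' @export
case_only_filter <- function(genotypes, phenotypes, annotations, qc,
                             config = prioritization_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  check_phenotypes(phenotypes, genotypes$sample_ids)
  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  case_ids <- ph$sample_id[ph$label == "case"]
  control_ids <- ph$sample_id[ph$label == "control"]

  idx <- match(genotypes$vids, annotations$vid)
  ann <- annotations[idx, , drop = FALSE]
  qc_pass <- qc$qc_pass[match(genotypes$vids, qc$vid)]
  qc_pass[is.na(qc_pass)] <- FALSE

  af <- ann$external_af
  rare_external <- ifelse(is.na(af), !config$strict_external_af,
                          af < config$external_af_max)
  dmg <- classify_damaging(ann)
  conserved_ok <- if (config$require_conserved)
    !is.na(ann$conserved) & ann$conserved else rep(TRUE, nrow(ann))
  novel_ok <- if (config$require_novel)
    !is.na(ann$novel) & ann$novel else rep(TRUE, nrow(ann))

  cc <- carrier_counts(genotypes$dosage, case_ids, control_ids)
  trail <- data.frame(
    vid = genotypes$vids,
    qc_pass = qc_pass,
    rare_external = !is.na(idx) & rare_external,
    damaging = !is.na(dmg),
    conserved = !is.na(idx) & conserved_ok,
    novel = !is.na(idx) & novel_ok,
    min_case_carriers = unname(cc$case >= config$min_case_carriers),
    max_control_carriers = unname(cc$control <= config$max_control_carriers),
    stringsAsFactors = FALSE
  )
  keep <- Reduce(`&`, trail[-1])
  out <- data.frame(
    vid = genotypes$vids[keep],
    gene = ann$gene[keep],
    damaging_class = dmg[keep],
    case_carriers = as.integer(cc$case[keep]),
    control_carriers = as.integer(cc$control[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, out$vid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_trail") <- trail
  out
}
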