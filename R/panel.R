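#' Load a candidate-variant verification panel
#'
#' Reads a TSV with columns `gene`, `vid`, and optionally `consequence` and
#' `hgvs` (informational transcript notation). Every `vid` must parse as a
#' canonical `chrom:pos:ref/alt` key.
#'
#' @param tsv_path Path to the panel TSV.
#' @return data.frame: `gene`, `vid`, `consequence`, `hgvs`.
#' @export
load_panel <- function(tsv_path) {
  pan <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("gene", "vid") %in% names(pan)))
    stop("schema error: panel file needs columns gene, vid")
  for (col in c("consequence", "hgvs"))
    if (!col %in% names(pan)) pan[[col]] <- NA_character_
  for (i in seq_len(nrow(pan))) {
    ok <- grepl("^[^:]+:[0-9]+:[^/]+/.+$", pan$vid[i])
    if (!ok) stop("schema error: unparseable panel vid at entry ", i, ": '",
                  pan$vid[i], "'")
  }
  pan[c("gene", "vid", "consequence", "hgvs")]
}

#' Verify a candidate panel against an independent cohort
#'
#' Looks up each panel variant in the cohort by exact normalized key match
#' (chromosome, position, ref, alt) and counts case and control carriers
#' (samples with dosage >= 1). Variants absent from the cohort are reported
#' with `found_in_cohort = FALSE` and zero counts. Panel order is preserved.
#'
#' @param panel data.frame from [load_panel()] (columns `gene`, `vid`).
#' @param genotypes A [genotype_matrix()] for the verification cohort.
#' @param phenotypes Phenotype data.frame covering the cohort samples.
#' @return data.frame: `gene`, `vid`, `found_in_cohort`, `case_carriers`,
#'   `control_carriers`.
#' @export
verify_panel <- function(panel, genotypes, phenotypes) {
  stopifnot(nrow(panel) > 0, inherits(genotypes, "genotype_matrix"))
  check_phenotypes(phenotypes, genotypes$sample_ids)
  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  case_ids <- ph$sample_id[ph$label == "case"]
  control_ids <- ph$sample_id[ph$label == "control"]
  idx <- match(panel$vid, genotypes$vids)
  case_n <- integer(nrow(panel)); control_n <- integer(nrow(panel))
  found <- !is.na(idx)
  if (any(found)) {
    cc <- carrier_counts(genotypes$dosage[, idx[found], drop = FALSE],
                         case_ids, control_ids)
    case_n[found] <- cc$case
    control_n[found] <- cc$control
  }
  data.frame(gene = panel$gene, vid = panel$vid, found_in_cohort = found,
             case_carriers = case_n, control_carriers = control_n,
             stringsAsFactors = FALSE)
}
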