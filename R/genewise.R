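mask_names <- c("stopgain_frameshift", "nonsynonymous")

protein_altering <- c("missense", "stop_gain", "stop_loss", "frameshift",
                      "inframe_indel", "splice")

#' Build a gene-wise collapsing mask
#'
#' Selects the qualifying variants per gene under one of two functional
#' masks, restricted to cohort-rare variants (`maf < maf_max`) that pass QC:
#' \describe{
#'   \item{stopgain_frameshift}{the damaging classes — stop-gain, frameshift,
#'     splice-affecting, and SIFT/PolyPhen2-damaging missense.}
#'   \item{nonsynonymous}{all protein-altering consequences (missense,
#'     stop-gain, stop-loss, frameshift, inframe indel, splice).}
#' }
#' The first mask is nested in the second by construction.
#'
#' @param annotations Annotation data.frame.
#' @param qc Site-QC data.frame from [site_qc()].
#' @param mask Mask name.
#' @param maf_max Cohort MAF bound for inclusion (default 0.05).
#' @return data.frame with columns `vid`, `gene`.
#' @export
build_mask <- function(annotations, qc,
                       mask = c("stopgain_frameshift", "nonsynonymous"),
                       maf_max = 0.05) {
  if (!is.character(mask) || !all(mask %in% mask_names))
    stop("config error: unknown mask name '", mask[1], "'")
  mask <- match.arg(mask)
  qrow <- match(annotations$vid, qc$vid)
  pass <- !is.na(qrow) & qc$qc_pass[qrow] &
    !is.na(qc$maf[qrow]) & qc$maf[qrow] < maf_max
  in_mask <- if (mask == "stopgain_frameshift") {
    !is.na(classify_damaging(annotations))
  } else {
    annotations$consequence %in% protein_altering
  }
  keep <- pass & in_mask & !is.na(annotations$gene)
  out <- data.frame(vid = annotations$vid[keep], gene = annotations$gene[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene, out$vid), , drop = FALSE]
}

#' Gene-wise collapsing association test
#'
#' Collapses each gene's masked variants to carrier status (via
#' [collapse_carriers()]) and tests case enrichment with the one-sided Fisher
#' exact test (via [fisher_one_sided()]) — the same engine as the burden
#' scan. Every gene in the mask is reported, with its genomic anchor
#' (chromosome and minimum variant position) for plotting.
#'
#' @param genotypes A [genotype_matrix()] restricted to the analysis set.
#' @param phenotypes Phenotype data.frame covering the samples.
#' @param mask_map data.frame `vid`, `gene` from [build_mask()].
#' @param mask_name Label carried into the results.
#' @return data.frame: `gene`, `mask`, `n_variants`, `chrom`, `pos`,
#'   carrier-table columns `a`, `b`, `c`, `d`, and `p`.
#' @export
gene_collapse_test <- function(genotypes, phenotypes, mask_map,
                               mask_name = NA_character_) {
  if (is.null(mask_map) || nrow(mask_map) == 0L) stop("empty mask")
  tables <- collapse_carriers(genotypes, phenotypes, mask_map)
  coords <- parse_vid(mask_map$vid)
  anchor <- do.call(rbind, lapply(split(coords, mask_map$gene), function(g) {
    data.frame(chrom = g$chrom[which.min(g$pos)], pos = min(g$pos),
               stringsAsFactors = FALSE)
  }))
  nv <- table(mask_map$gene)
  out <- data.frame(
    gene = tables$gene,
    mask = mask_name,
    n_variants = as.integer(nv[tables$gene]),
    chrom = anchor[tables$gene, "chrom"],
    pos = anchor[tables$gene, "pos"],
    a = tables$a, b = tables$b, c = tables$c, d = tables$d,
    p = fisher_one_sided(tables$a, tables$b, tables$c, tables$d),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  suppressWarnings(num <- as.numeric(core))
  num[core == "X"] <- 23
  num[core == "Y"] <- 24
  num[core %in% c("MT", "M")] <- 25
  num[is.na(num)] <- 26
  num
}

#' Export gene-level results for a Manhattan plot
#'
#' Plot-ready table sorted in genome order (chromosome 1..22, X, Y, then
#' position) with `-log10(p)`; the significance line is attached as attribute
#' `"significance_line"`.
#'
#' @param results data.frame from [gene_collapse_test()].
#' @param significance_line Level drawn on the plot (default 0.05).
#' @return data.frame: `chrom`, `pos`, `gene`, `p`, `neg_log10_p`.
#' @export
manhattan_export <- function(results, significance_line = 0.05) {
  if (is.null(results) || nrow(results) == 0L) stop("no results to export")
  out <- data.frame(chrom = results$chrom, pos = results$pos,
                    gene = results$gene, p = results$p,
                    neg_log10_p = -log10(results$p),
                    stringsAsFactors = FALSE)
  out <- out[order(chrom_rank(out$chrom), out$pos, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "significance_line") <- significance_line
  out
}
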