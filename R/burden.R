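#' Collapse qualifying variants to per-gene carrier counts
#'
#' A sample is a carrier of a gene when it has dosage >= 1 at one or more of
#' that gene's qualifying variants, counted once however many it carries.
#' Denominators are the analysis-set sizes (every sample in `genotypes`),
#' unless `per_gene_denominators = TRUE`, in which case samples missing at
#' every qualifying variant of a gene are excluded from that gene's
#' denominator.
#'
#' @param genotypes A [genotype_matrix()] restricted to the analysis set.
#' @param phenotypes Phenotype data.frame covering the samples.
#' @param qualifying data.frame with columns `vid`, `gene`: the qualifying
#'   (mask) variants per gene.
#' @param per_gene_denominators Use per-gene non-missing denominators instead
#'   of the fixed analysis-set sizes (default FALSE).
#' @return A data.frame with one row per gene: `gene`, `a` (case carriers),
#'   `b` (case non-carriers), `c` (control carriers), `d` (control
#'   non-carriers), sorted by gene.
#' @export
collapse_carriers <- function(genotypes, phenotypes, qualifying,
                              per_gene_denominators = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"), nrow(qualifying) > 0)
  if (!all(c("vid", "gene") %in% names(qualifying)))
    stop("qualifying map needs columns vid, gene")
  if (any(is.na(qualifying$gene)))
    stop("integrity error: qualifying vid without gene: ",
         qualifying$vid[which(is.na(qualifying$gene))[1]])
  miss <- setdiff(qualifying$vid, genotypes$vids)
  if (length(miss))
    stop("integrity error: qualifying vid not genotyped: ", miss[1])
  check_phenotypes(phenotypes, genotypes$sample_ids)
  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  is_case <- ph$label == "case"
  n_cases <- sum(is_case); n_controls <- sum(!is_case)

  genes <- sort(unique(qualifying$gene))
  rows <- lapply(genes, function(g) {
    vids <- qualifying$vid[qualifying$gene == g]
    d <- genotypes$dosage[, vids, drop = FALSE]
    carrier <- rowSums(!is.na(d) & d >= 1L) > 0L
    if (per_gene_denominators) {
      informative <- rowSums(!is.na(d)) > 0L
      nc <- sum(is_case & informative); nn <- sum(!is_case & informative)
    } else {
      nc <- n_cases; nn <- n_controls
    }
    data.frame(gene = g,
               a = sum(carrier & is_case),
               b = nc - sum(carrier & is_case),
               c = sum(carrier & !is_case),
               d = nn - sum(carrier & !is_case),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualifying variants for the gene-level burden scan
#'
#' The burden scan counts carriers at every rare, damaging variant: damaging
#' class (stop-gain, frameshift, splice, or SIFT/PolyPhen2-damaging
#' missense), rare in external reference genomes (`external_af <
#' external_af_max`, unknown frequency passing unless `strict_external_af`),
#' and passing site QC. Unlike the case-only candidate filter, no
#' conservation or carrier-count rule is applied, so control carriers are
#' counted too.
#'
#' @param annotations Annotation data.frame.
#' @param qc Site-QC data.frame from [site_qc()].
#' @param config A [prioritization_config()] supplying the external rarity
#'   rule.
#' @return data.frame `vid`, `gene`.
#' @export
burden_qualifying_map <- function(annotations, qc,
                                  config = prioritization_config()) {
  qrow <- match(annotations$vid, qc$vid)
  pass <- !is.na(qrow) & qc$qc_pass[qrow]
  af <- annotations$external_af
  rare <- ifelse(is.na(af), !config$strict_external_af,
                 af < config$external_af_max)
  keep <- pass & rare & !is.na(classify_damaging(annotations)) &
    !is.na(annotations$gene)
  out <- data.frame(vid = annotations$vid[keep],
                    gene = annotations$gene[keep], stringsAsFactors = FALSE)
  out[order(out$gene, out$vid), , drop = FALSE]
}

#' One-sided Fisher exact test on a carrier table
#'
#' Upper-tail exact probability of observing at least the seen number of case
#' carriers with all margins fixed: `p = P(X >= a)` where `X` is
#' hypergeometric with population `a+b+c+d`, `a+c` carriers, and `a+b` case
#' draws — Fisher's exact test with `alternative = "greater"` on the 2x2
#' carrier table. Vectorized over rows.
#'
#' @param a,b,c,d Non-negative integer vectors: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @return Numeric vector of one-sided p-values in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("domain error: negative cell count")
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Gene-level burden scan
#'
#' Tests every carrier table with the one-sided Fisher exact test, reports
#' raw p-values as primary (flagging genes with `p < alpha`) together with
#' Bonferroni and Benjamini-Hochberg adjusted columns, and sorts by ascending
#' p then gene.
#'
#' @param tables Carrier-table data.frame from [collapse_carriers()].
#' @param alpha Flagging level on the raw p-value (default 0.05).
#' @return A data.frame: `gene`, `case_carriers`, `case_total`,
#'   `control_carriers`, `control_total`, `p`, `p_bonferroni`, `p_bh`,
#'   `significant`.
#' @export
burden_scan <- function(tables, alpha = 0.05) {
  if (is.null(tables) || nrow(tables) == 0L) {
    return(data.frame(gene = character(0), case_carriers = integer(0),
                      case_total = integer(0), control_carriers = integer(0),
                      control_total = integer(0), p = numeric(0),
                      p_bonferroni = numeric(0), p_bh = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  p <- fisher_one_sided(tables$a, tables$b, tables$c, tables$d)
  out <- data.frame(
    gene = tables$gene,
    case_carriers = tables$a, case_total = tables$a + tables$b,
    control_carriers = tables$c, control_total = tables$c + tables$d,
    p = p,
    p_bonferroni = stats::p.adjust(p, "bonferroni"),
    p_bh = stats::p.adjust(p, "BH"),
    significant = p < alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
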