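#' Genotype contingency counts at a variant
#'
#' Case and control counts by alt-allele dosage (0/1/2), excluding missing
#' genotypes.
#'
#' @param dosage Integer dosage vector (0, 1, 2, NA), named by sample.
#' @param phenotypes Phenotype data.frame covering the samples.
#' @return A list with `r` (case counts by dosage) and `s` (control counts),
#'   each a length-3 integer vector.
#' @export
genotype_contingency <- function(dosage, phenotypes) {
  check_phenotypes(phenotypes)
  lab <- phenotypes$label[match(names(dosage), phenotypes$sample_id)]
  if (anyNA(lab)) stop("integrity error: sample without phenotype")
  keep <- !is.na(dosage)
  r <- tabulate(dosage[keep & lab == "case"] + 1L, nbins = 3L)
  s <- tabulate(dosage[keep & lab == "control"] + 1L, nbins = 3L)
  list(r = r, s = s)
}

sva_result <- function(vid, model, statistic, df, p, note = NA_character_) {
  data.frame(vid = vid, model = model, statistic = statistic,
             df = as.integer(df), p = p, note = note,
             stringsAsFactors = FALSE)
}

sva_undefined <- function(vid, model, note) {
  sva_result(vid, model, NA_real_, NA_integer_, NA_real_, note)
}

#' Cochran-Armitage trend test
#'
#' Score test for a linear trend in case proportion across genotype dosages
#' with weights (0, 1, 2); chi-square with 1 df. Degenerate tables (a single
#' occupied genotype column, or no cases / no controls) yield an undefined
#' result with `NA` statistic and p.
#'
#' @param t A genotype contingency as from [genotype_contingency()].
#' @param vid Variant key carried into the result (default `NA`).
#' @return One-row data.frame: `vid`, `model`, `statistic`, `df`, `p`,
#'   `note`.
#' @export
trend_test <- function(t, vid = NA_character_) {
  n <- t$r + t$s
  occupied <- n > 0L
  if (sum(occupied) < 2L)
    return(sva_undefined(vid, "trend", "single occupied genotype column"))
  if (sum(t$r) == 0L || sum(t$s) == 0L)
    return(sva_undefined(vid, "trend", "one phenotype group empty"))
  ct <- suppressWarnings(
    stats::prop.trend.test(t$r[occupied], n[occupied],
                           score = (0:2)[occupied]))
  stat <- unname(ct$statistic)
  sva_result(vid, "trend", stat, 1L, unname(ct$p.value))
}

#' Allelic, dominant and recessive 2x2 model tests
#'
#' Reduces the genotype contingency to the model's 2x2 table — allele counts
#' (allelic), carriers vs non-carriers (dominant), hom-alt vs rest
#' (recessive) — and applies the Pearson chi-square test with 1 df, without
#' continuity correction. A zero margin yields an undefined result.
#'
#' @param t A genotype contingency.
#' @param model One of `"allelic"`, `"dominant"`, `"recessive"`.
#' @param vid Variant key carried into the result.
#' @param fisher_fallback If TRUE and any expected cell is below 5, the
#'   p-value is replaced by the two-sided Fisher exact probability (the
#'   chi-square statistic is still reported).
#' @return One-row data.frame as in [trend_test()].
#' @export
model_test <- function(t, model = c("allelic", "dominant", "recessive"),
                       vid = NA_character_, fisher_fallback = FALSE) {
  model <- match.arg(model)
  r <- t$r; s <- t$s
  tab <- switch(model,
    allelic = rbind(case = c(2 * r[1] + r[2], r[2] + 2 * r[3]),
                    control = c(2 * s[1] + s[2], s[2] + 2 * s[3])),
    dominant = rbind(case = c(r[1], r[2] + r[3]),
                     control = c(s[1], s[2] + s[3])),
    recessive = rbind(case = c(r[1] + r[2], r[3]),
                      control = c(s[1] + s[2], s[3]))
  )
  if (sum(tab) == 0L || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(sva_undefined(vid, model, "zero margin"))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p <- unname(ct$p.value)
  note <- NA_character_
  if (fisher_fallback && any(ct$expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    note <- "fisher_fallback"
  }
  sva_result(vid, model, unname(ct$statistic), 1L, p, note)
}

#' Genotypic (2x3) model test
#'
#' Pearson chi-square on the 2-by-k table of occupied genotype columns,
#' without continuity correction; df = occupied columns minus 1. A single
#' occupied column, or an empty phenotype group, yields an undefined result.
#'
#' @param t A genotype contingency.
#' @param vid Variant key carried into the result.
#' @return One-row data.frame as in [trend_test()].
#' @export
genotypic_test <- function(t, vid = NA_character_) {
  n <- t$r + t$s
  occupied <- n > 0L
  if (sum(occupied) < 2L)
    return(sva_undefined(vid, "genotypic", "single occupied genotype column"))
  if (sum(t$r) == 0L || sum(t$s) == 0L)
    return(sva_undefined(vid, "genotypic", "one phenotype group empty"))
  tab <- rbind(case = t$r[occupied], control = t$s[occupied])
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  sva_result(vid, "genotypic", unname(ct$statistic),
             sum(occupied) - 1L, unname(ct$p.value))
}

sva_models <- c("trend", "allelic", "dominant", "recessive", "genotypic")

#' Single-variant association scan
#'
#' Runs the five genetic-model tests (trend, allelic, dominant, recessive,
#' genotypic) on every QC-passing variant in the requested MAF strata.
#' HWE-failing and depth-failing variants are excluded before testing.
#'
#' @param genotypes A [genotype_matrix()] restricted to the analysis set.
#' @param phenotypes Phenotype data.frame covering the samples.
#' @param qc Site-QC data.frame from [site_qc()].
#' @param strata Strata to test (default common and low-frequency, tested
#'   together; call per stratum to mirror a stratified analysis).
#' @param models Subset of the five models (default all).
#' @param fisher_fallback Passed to [model_test()].
#' @return A data.frame with one row per variant-model pair: `vid`, `maf`,
#'   `stratum`, `model`, `statistic`, `df`, `p`, `note`.
#' @export
sva_scan <- function(genotypes, phenotypes, qc,
                     strata = c("common", "low_frequency"),
                     models = sva_models, fisher_fallback = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  models <- match.arg(models, sva_models, several.ok = TRUE)
  check_phenotypes(phenotypes, genotypes$sample_ids)
  qc <- qc[match(genotypes$vids, qc$vid), ]
  keep <- qc$qc_pass & !is.na(qc$stratum) & qc$stratum %in% strata
  vids <- genotypes$vids[keep]
  if (length(vids) == 0L) {
    return(data.frame(vid = character(0), maf = numeric(0),
                      stratum = character(0), model = character(0),
                      statistic = numeric(0), df = integer(0), p = numeric(0),
                      note = character(0), stringsAsFactors = FALSE))
  }
  res <- lapply(vids, function(v) {
    dos <- genotypes$dosage[, v]
    names(dos) <- genotypes$sample_ids
    ct <- genotype_contingency(dos, phenotypes)
    rows <- list()
    if ("trend" %in% models) rows <- c(rows, list(trend_test(ct, v)))
    for (m in intersect(models, c("allelic", "dominant", "recessive")))
      rows <- c(rows, list(model_test(ct, m, v, fisher_fallback)))
    if ("genotypic" %in% models) rows <- c(rows, list(genotypic_test(ct, v)))
    do.call(rbind, rows)
  })
  res <- do.call(rbind, res)
  qrow <- match(res$vid, qc$vid)
  out <- cbind(res[1], maf = qc$maf[qrow], stratum = qc$stratum[qrow],
               res[-1])
  rownames(out) <- NULL
  out
}
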