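#' Site and sample QC configuration
#'
#' Thresholds for the deep-filtering stage: a site passes depth filtering when
#' at least `min_fraction_at_depth` of the samples reach `min_depth` reads,
#' and is excluded when its exact Hardy-Weinberg equilibrium p-value falls
#' below `hwe_alpha`. Minor-allele-frequency strata: common (`maf >=
#' maf_common`), low-frequency (`maf_low <= maf < maf_common`), rare
#' otherwise.
#'
#' @param min_depth Integer read-depth threshold per sample (default 10).
#' @param min_fraction_at_depth Fraction of samples that must reach
#'   `min_depth` (default 0.95).
#' @param hwe_alpha HWE exclusion level (default 1e-5).
#' @param maf_common MAF threshold for the common stratum (default 0.05).
#' @param maf_low MAF threshold for the low-frequency stratum (default 0.01).
#' @param sample_call_rate_min Minimum per-sample non-missing call rate;
#'   samples below it are dropped from the analysis set (default 0.9).
#' @param hwe_population Population on which the HWE test is computed:
#'   `"all"` samples (default) or `"controls"` only.
#' @return A list of class `site_qc_config`.
#' @export
site_qc_config <- function(min_depth = 10L, min_fraction_at_depth = 0.95,
                           hwe_alpha = 1e-5, maf_common = 0.05,
                           maf_low = 0.01, sample_call_rate_min = 0.9,
                           hwe_population = c("all", "controls")) {
  hwe_population <- match.arg(hwe_population)
  stopifnot(min_depth >= 0, min_fraction_at_depth > 0,
            min_fraction_at_depth <= 1, hwe_alpha > 0, hwe_alpha < 1,
            maf_low >= 0, maf_low < maf_common, maf_common <= 0.5,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_fraction_at_depth = min_fraction_at_depth,
                 hwe_alpha = hwe_alpha, maf_common = maf_common,
                 maf_low = maf_low,
                 sample_call_rate_min = sample_call_rate_min,
                 hwe_population = hwe_population),
            class = "site_qc_config")
}

#' Depth-based call-rate filter
#'
#' A site passes when the fraction of samples sequenced to at least
#' `min_depth` reads is at least `min_fraction_at_depth` — e.g. with the
#' defaults, at least 95% of samples at 10x.
#'
#' @param genotypes A [genotype_matrix()].
#' @param config A [site_qc_config()].
#' @return Named logical vector, one element per variant.
#' @export
depth_call_rate_filter <- function(genotypes, config = site_qc_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (length(genotypes$sample_ids) == 0L) stop("cohort has no samples")
  colMeans(genotypes$depth >= config$min_depth) >= config$min_fraction_at_depth
}

# Conditional probabilities of every attainable heterozygote count given
# n genotypes and n_a copies of the minor allele, under random mating.
# Direct multinomial form; used by the exact test below via a numerically
# stabler recurrence, and independently by the test-suite oracle.
hwe_het_support <- function(n, n_a) {
  h <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  h[(n_a - h) %% 2L == 0L & (n_a - h) / 2L + h <= n]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test of HWE genotype proportions given the observed
#' allele counts: with `n` genotypes and the minor-allele count fixed, all
#' attainable heterozygote counts are enumerated, and the p-value is the sum
#' of the conditional probabilities of every configuration no more probable
#' than the observed one (two-sided by probability ordering). Probabilities
#' follow the standard recurrence over adjacent heterozygote counts.
#' Monomorphic sites have a single attainable configuration and p = 1.
#'
#' @param hom_ref,het,hom_alt Non-negative genotype counts.
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  if (any(c(hom_ref, het, hom_alt) < 0)) stop("domain error: negative count")
  n <- hom_ref + het + hom_alt
  if (n < 1) stop("domain error: no genotypes")
  n_a <- min(2L * hom_ref + het, 2L * hom_alt + het)
  if (n_a <= 1L) return(1)     # at most one attainable configuration
  hs <- hwe_het_support(n, n_a)
  if (length(hs) == 1L) return(1)
  # recurrence: P(h+2)/P(h) = n_a_rem... derived from the multinomial ratio
  # P(h-2)/P(h) = h*(h-1) / ((n_rare - h + 2)*(n_common - h + 2)) with
  # n_rare = n_a, n_common = 2n - n_a (Wigginton-style, unnormalized).
  n_common <- 2L * n - n_a
  k <- length(hs)
  logp <- numeric(k)
  for (i in 2:k) {
    h <- hs[i]
    # ratio P(h)/P(h-2) = (n_a - h + 2)(n_common - h + 2) / (h (h - 1))
    logp[i] <- logp[i - 1] +
      log(n_a - h + 2) + log(n_common - h + 2) - log(h) - log(h - 1)
  }
  p_rel <- exp(logp - max(logp))
  probs <- p_rel / sum(p_rel)
  obs <- match(het, hs)
  if (is.na(obs)) stop("domain error: heterozygote count ", het,
                       " not attainable with these allele counts")
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-9)])
  min(1, p)
}

#' Minor allele frequency at a variant
#'
#' Alt-allele frequency over non-missing genotypes, folded to the minor
#' allele: `maf = min(f_alt, 1 - f_alt)`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param vid Variant key; `NULL` computes all variants.
#' @return Named numeric vector of MAFs in `[0, 0.5]`; `NA` where every
#'   genotype is missing.
#' @export
compute_maf <- function(genotypes, vid = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (!is.null(vid)) {
    if (!all(vid %in% genotypes$vids)) stop("unknown vid")
    d <- d[, vid, drop = FALSE]
  }
  f_alt <- colMeans(d, na.rm = TRUE) / 2
  f_alt[is.nan(f_alt)] <- NA_real_
  pmin(f_alt, 1 - f_alt)
}

#' Assign a MAF stratum
#'
#' @param maf Numeric vector of folded MAFs in `[0, 0.5]`.
#' @param config A [site_qc_config()].
#' @return Character vector in `{common, low_frequency, rare}` (`NA` in,
#'   `NA` out).
#' @export
stratify_maf <- function(maf, config = site_qc_config()) {
  stopifnot(all(maf >= 0 & maf <= 0.5, na.rm = TRUE))
  out <- ifelse(maf >= config$maf_common, "common",
                ifelse(maf >= config$maf_low, "low_frequency", "rare"))
  out
}

genotype_counts <- function(dosage_col) {
  c(hom_ref = sum(dosage_col == 0L, na.rm = TRUE),
    het = sum(dosage_col == 1L, na.rm = TRUE),
    hom_alt = sum(dosage_col == 2L, na.rm = TRUE))
}

#' Per-sample call-rate QC
#'
#' Samples whose overall non-missing genotype call rate falls below
#' `sample_call_rate_min` are dropped, yielding the analysis set whose sizes
#' are the fixed denominators of all downstream carrier tables.
#'
#' @param genotypes A [genotype_matrix()].
#' @param config A [site_qc_config()].
#' @return Character vector of retained sample ids.
#' @export
sample_qc <- function(genotypes, config = site_qc_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  rate <- rowMeans(!is.na(genotypes$dosage))
  genotypes$sample_ids[rate >= config$sample_call_rate_min]
}

#' Run site-level QC
#'
#' Applies the depth call-rate filter, the exact HWE test (on all samples or
#' controls only, per `config$hwe_population`) and MAF computation with
#' stratification to every variant.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Phenotype data.frame (`sample_id`, `label`); required
#'   when `config$hwe_population == "controls"`.
#' @param config A [site_qc_config()].
#' @return A data.frame with one row per variant: `vid`, `call_rate_pass`,
#'   `hwe_p`, `hwe_pass`, `maf`, `stratum`, `qc_pass`.
#' @export
site_qc <- function(genotypes, phenotypes = NULL, config = site_qc_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  crp <- depth_call_rate_filter(genotypes, config)
  hwe_rows <- genotypes$sample_ids
  if (config$hwe_population == "controls") {
    if (is.null(phenotypes))
      stop("phenotypes required for controls-only HWE")
    check_phenotypes(phenotypes, genotypes$sample_ids)
    hwe_rows <- phenotypes$sample_id[phenotypes$label == "control"]
  }
  d_hwe <- genotypes$dosage[hwe_rows, , drop = FALSE]
  hwe_p <- apply(d_hwe, 2L, function(col) {
    cnt <- genotype_counts(col)
    if (sum(cnt) < 1) return(NA_real_)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  })
  maf <- compute_maf(genotypes)
  data.frame(
    vid = genotypes$vids,
    call_rate_pass = unname(crp),
    hwe_p = unname(hwe_p),
    hwe_pass = unname(is.na(hwe_p) | hwe_p >= config$hwe_alpha),
    maf = unname(maf),
    stratum = unname(stratify_maf(maf, config)),
    qc_pass = unname(crp & (is.na(hwe_p) | hwe_p >= config$hwe_alpha)),
    stringsAsFactors = FALSE
  )
}
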