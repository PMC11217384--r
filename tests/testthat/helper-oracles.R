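# Independent brute-force oracles; deliberately share no code with the
# package implementations they check.

# Upper-tail Fisher probability by enumerating every 2x2 table with the
# observed margins and summing conditional hypergeometric probabilities.
oracle_fisher_greater <- function(a, b, c, d) {
  n_case <- a + b
  m <- a + c
  N <- a + b + c + d
  a_vals <- max(0, m - (c + d)):min(n_case, m)
  logp <- lchoose(n_case, a_vals) + lchoose(c + d, m - a_vals) -
    lchoose(N, m)
  sum(exp(logp[a_vals >= a]))
}

# Exact HWE p by direct multinomial enumeration of heterozygote counts
# conditional on the allele counts.
oracle_hwe <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  n_a <- min(2 * hom_ref + het, 2 * hom_alt + het)
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hs, function(h) {
    ha <- (n_a - h) / 2
    hr <- n - h - ha
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(ha) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(het, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Cochran-Armitage trend chi-square evaluated directly from the score-test
# formula with weights (0, 1, 2).
oracle_trend_chisq <- function(r, s) {
  w <- 0:2
  n_i <- r + s
  N <- sum(n_i)
  R <- sum(r)
  num <- (N * sum(w * r) - R * sum(w * n_i))^2
  den <- R * (N - R) * (N * sum(w^2 * n_i) - sum(w * n_i)^2)
  N * num / den
}

# textbook Pearson chi-square, sum((O - E)^2 / E)
oracle_pearson_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# --- fixture builders -------------------------------------------------------

make_gm <- function(dosage, depth = NULL, samples = NULL, vids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(dosage)))
  if (is.null(vids)) vids <- sprintf("1:%d:A/G", 1000 + seq_len(ncol(dosage)))
  dimnames(dosage) <- list(samples, vids)
  if (is.null(depth)) depth <- matrix(30L, nrow(dosage), ncol(dosage),
                                      dimnames = dimnames(dosage))
  genotype_matrix(dosage, depth)
}

make_phenotypes <- function(samples, n_cases) {
  data.frame(sample_id = samples,
             label = rep(c("case", "control"),
                         c(n_cases, length(samples) - n_cases)),
             stringsAsFactors = FALSE)
}

# dosage matrix realizing exact per-gene carrier counts: one variant,
# carriers heterozygous
carrier_fixture <- function(case_carriers, n_cases, control_carriers,
                            n_controls) {
  dos <- c(rep(1L, case_carriers), rep(0L, n_cases - case_carriers),
           rep(1L, control_carriers), rep(0L, n_controls - control_carriers))
  gm <- make_gm(matrix(dos, ncol = 1))
  list(genotypes = gm,
       phenotypes = make_phenotypes(gm$sample_ids, n_cases))
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_3x2 <- function() {
  write_vcf_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", ".", "A", "G", ".", "PASS", ".", "GT:DP",
          "0/0:20", "0/1:25", "1/1:30", sep = "\t"),
    paste("2", "200", ".", "C", "T", ".", "PASS", ".", "GT:DP",
          "0/1:15", "./.:0", "./1:22", sep = "\t")))
}

vcf_multiallelic <- function() {
  write_vcf_fixture(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("7", "500", ".", "T", "A,G", ".", "PASS", ".", "GT:DP",
          "1/2:40", "0/1:33", "2/2:28", sep = "\t")))
}

# small annotation TSV writer
write_ann_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# null cohort spec (no planted signal of any kind) used by calibration tests
null_spec <- function(seed, n_genes = 15L, variants_per_gene = 2,
                      maf_spectrum = list(list(weight = 1, type = "beta",
                                               shape1 = 0.4, shape2 = 60))) {
  cohort_spec(n_genes = n_genes, variants_per_gene = variants_per_gene,
              maf_spectrum = maf_spectrum,
              planted_risk_genes = NULL,
              hwe_violation = list(n_sites = 0L, f = 0),
              depth_model = list(mean = 120, size = 8,
                                 low_depth_fraction = 0, low_depth_mean = 5),
              missing_rate = 0.01, seed = seed)
}
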