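#' Synthetic cohort specification
#'
#' Parameters of the synthetic case-control exome generator. The defaults
#' emulate the structure of a small high-altitude isolate cohort: 47 cases
#' and 53 controls, a rare-heavy site-frequency spectrum, consequence-class
#' proportions dominated by missense with stop-loss rarest, deep exome
#' coverage (mean 120x) with a small fraction of poorly covered sites, sparse
#' missingness, a couple of planted case-enriched risk genes and a few
#' planted Hardy-Weinberg-violating sites.
#'
#' @param n_cases,n_controls Cohort sizes (defaults 47, 53).
#' @param n_genes Number of genes (default 60).
#' @param variants_per_gene Mean extra variants per gene; each gene gets
#'   `1 + rpois(mean - 1)` variants (default mean 3).
#' @param maf_spectrum List of mixture components, each
#'   `list(weight=, type=, ...)` with `type` one of `"beta"`
#'   (`shape1`, `shape2`), `"uniform"` (`min`, `max`), `"point"` (`value`);
#'   alt-allele frequencies are drawn from the mixture and truncated to
#'   (0, 0.5].
#' @param consequence_probs Named probabilities over the eight consequence
#'   classes.
#' @param sift_probs,polyphen2_probs Probabilities of
#'   `(damaging, tolerated/benign, unknown)` calls for missense variants.
#' @param conserved_prob Probability a variant carries the conservation flag.
#' @param novel_prob Probability a variant is absent from dbSNP.
#' @param external_af_known_prob Probability the external population
#'   frequency of a rare variant (true frequency below 1%) is reported;
#'   variants at 1% or more are always reported, since a panel of reference
#'   genomes catalogues them. Known frequencies track the true frequency
#'   with multiplicative noise.
#' @param planted_risk_genes data.frame `gene`, `case_prob`, `control_prob`:
#'   per-sample carrier probabilities (case >= control) for planted
#'   case-enriched genes.
#' @param planted_variants_per_gene Signal variants per planted gene; every
#'   carrier carries the first and each further one with probability 0.5,
#'   exercising idempotent carrier counting (default 1).
#' @param hwe_violation List `n_sites`, `f`: number of planted
#'   HWE-violating sites and the Wright-style inbreeding distortion
#'   `f` in (-1, 1) applied to the heterozygote probability
#'   (`P(het) = 2pq(1 - f)`; positive f = heterozygote deficit).
#' @param missing_rate Per-genotype missingness probability (default 0.02).
#' @param depth_model List `mean`, `size` (negative-binomial per-site depth),
#'   `low_depth_fraction`, `low_depth_mean` (sites whose coverage collapses,
#'   exercising the depth filter).
#' @param planted_sva Optional list `maf`, `odds_ratio`, `n_variants`:
#'   common variants with an additive (per-allele) case-control effect, for
#'   single-variant power studies.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 47L, n_controls = 53L, n_genes = 60L,
                        variants_per_gene = 3,
                        maf_spectrum = list(
                          list(weight = 0.6, type = "beta",
                               shape1 = 0.4, shape2 = 60),
                          list(weight = 0.2, type = "uniform",
                               min = 0.01, max = 0.05),
                          list(weight = 0.2, type = "uniform",
                               min = 0.05, max = 0.5)),
                        consequence_probs = c(
                          missense = 0.55, synonymous = 0.27, other = 0.06,
                          inframe_indel = 0.035, frameshift = 0.03,
                          splice = 0.025, stop_gain = 0.025,
                          stop_loss = 0.005),
                        sift_probs = c(damaging = 0.25, tolerated = 0.65,
                                       unknown = 0.10),
                        polyphen2_probs = c(damaging = 0.25, benign = 0.65,
                                            unknown = 0.10),
                        conserved_prob = 0.4, novel_prob = 0.13,
                        external_af_known_prob = 0.85,
                        planted_risk_genes = data.frame(
                          gene = c("GENE001", "GENE002"),
                          case_prob = c(0.28, 0.10),
                          control_prob = c(0.04, 0.00),
                          stringsAsFactors = FALSE),
                        planted_variants_per_gene = 1L,
                        hwe_violation = list(n_sites = 3L, f = 0.9),
                        missing_rate = 0.02,
                        depth_model = list(mean = 120, size = 8,
                                           low_depth_fraction = 0.05,
                                           low_depth_mean = 5),
                        planted_sva = NULL,
                        seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_genes >= 1,
            variants_per_gene >= 1, missing_rate >= 0, missing_rate < 1,
            conserved_prob >= 0, conserved_prob <= 1,
            abs(sum(consequence_probs) - 1) < 1e-8,
            hwe_violation$f > -1, hwe_violation$f < 1)
  if (!is.null(planted_risk_genes) && nrow(planted_risk_genes)) {
    stopifnot(all(c("gene", "case_prob", "control_prob") %in%
                    names(planted_risk_genes)),
              all(planted_risk_genes$case_prob >=
                    planted_risk_genes$control_prob),
              all(planted_risk_genes$case_prob >= 0),
              all(planted_risk_genes$case_prob <= 1))
    if (!all(planted_risk_genes$gene %in% sprintf("GENE%03d", 1:n_genes)))
      stop("spec error: planted gene outside GENE001..GENE",
           sprintf("%03d", n_genes))
  }
  structure(as.list(environment()), class = "cohort_spec")
}

draw_maf <- function(n, spectrum) {
  w <- vapply(spectrum, `[[`, numeric(1), "weight")
  comp <- sample.int(length(spectrum), n, replace = TRUE, prob = w)
  f <- numeric(n)
  for (k in seq_along(spectrum)) {
    idx <- comp == k
    if (!any(idx)) next
    sp <- spectrum[[k]]
    f[idx] <- switch(sp$type,
      beta = stats::rbeta(sum(idx), sp$shape1, sp$shape2),
      uniform = stats::runif(sum(idx), sp$min, sp$max),
      point = rep(sp$value, sum(idx)),
      stop("spec error: unknown maf_spectrum component type '", sp$type, "'"))
  }
  pmin(pmax(f, 1e-4), 0.5)
}

ref_alt_pair <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  cbind(ref, alt)
}

hwe_distorted_dosage <- function(n, f_alt, f) {
  q <- f_alt; p <- 1 - q
  het <- max(0, 2 * p * q * (1 - f))
  probs <- c(p^2 + f * p * q, het, q^2 + f * p * q)
  probs <- pmax(probs, 0); probs <- probs / sum(probs)
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Simulate a synthetic case-control exome cohort
#'
#' Draws genotypes per sample under Hardy-Weinberg equilibrium at each
#' variant's alt-allele frequency, except at planted HWE-violating sites
#' (heterozygote probability distorted by the spec's `f`) and at planted
#' risk-gene signal variants (per-sample carrier status drawn per group
#' probability and realized as a heterozygote). Per-sample-per-site depth is
#' negative-binomial; dosages are masked missing at the spec's rate. All
#' randomness is fixed by `spec$seed`: the same seed yields byte-identical
#' output files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory; when given, the cohort is also
#'   written as `cohort.vcf`, `annotations.tsv`, `phenotypes.tsv`,
#'   `truth_variants.tsv` and `truth_genes.tsv` (see [write_cohort()]).
#' @return A list of class `synthetic_cohort`: `variants`, `genotypes` (a
#'   [genotype_matrix()]), `annotations`, `phenotypes`, `truth` (see
#'   [realized_truth()]), `spec`, and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- withr::with_seed(spec$seed, simulate_cohort_impl(spec))
  if (!is.null(dir)) cohort$paths <- write_cohort(cohort, dir)
  cohort
}

simulate_cohort_impl <- function(spec) {
  n <- spec$n_cases + spec$n_controls
  sample_ids <- c(sprintf("CASE%03d", seq_len(spec$n_cases)),
                  sprintf("CTRL%03d", seq_len(spec$n_controls)))
  is_case <- rep(c(TRUE, FALSE), c(spec$n_cases, spec$n_controls))
  phenotypes <- data.frame(sample_id = sample_ids,
                           label = ifelse(is_case, "case", "control"),
                           stringsAsFactors = FALSE)

  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
  gene_chrom <- as.character((seq_len(spec$n_genes) - 1L) %% 22L + 1L)
  nvar <- 1L + stats::rpois(spec$n_genes, max(0, spec$variants_per_gene - 1))
  planted <- spec$planted_risk_genes
  has_planted <- !is.null(planted) && nrow(planted) > 0
  if (has_planted) {
    need <- spec$planted_variants_per_gene
    gi <- match(planted$gene, genes)
    nvar[gi] <- pmax(nvar[gi], need)
  }

  gene_of <- rep(genes, nvar)
  chrom <- rep(gene_chrom, nvar)
  within_chrom <- stats::ave(seq_len(spec$n_genes), gene_chrom,
                             FUN = seq_along)
  gene_base <- 1e6 + (within_chrom - 1L) * 1e5
  pos <- unlist(lapply(seq_len(spec$n_genes), function(i)
    gene_base[i] + (seq_len(nvar[i]) - 1L) * 150L))
  m <- length(gene_of)
  ra <- ref_alt_pair(m)
  vid <- make_vid(chrom, as.integer(pos), ra[, 1], ra[, 2])
  stopifnot(!anyDuplicated(vid))

  f_alt <- draw_maf(m, spec$maf_spectrum)
  consequence <- sample(names(spec$consequence_probs), m, replace = TRUE,
                        prob = spec$consequence_probs)
  role <- rep("background", m)

  # planted risk-gene signal variants: first variant(s) of the gene
  signal_idx <- integer(0)
  if (has_planted) {
    for (k in seq_len(nrow(planted))) {
      gvars <- which(gene_of == planted$gene[k])
      sig <- gvars[seq_len(spec$planted_variants_per_gene)]
      role[sig] <- "planted"
      consequence[sig] <- "missense"
      signal_idx <- c(signal_idx, sig)
    }
  }

  # planted HWE-violating sites: synonymous, common enough for the exact
  # test to have resolution
  if (spec$hwe_violation$n_sites > 0) {
    pool <- which(role == "background")
    hwe_idx <- pool[sample.int(length(pool),
                               min(spec$hwe_violation$n_sites, length(pool)))]
    role[hwe_idx] <- "hwe_violation"
    f_alt[hwe_idx] <- stats::runif(length(hwe_idx), 0.25, 0.5)
    consequence[hwe_idx] <- "synonymous"
  }

  # optional common variants with an additive case-control effect
  if (!is.null(spec$planted_sva)) {
    ps <- spec$planted_sva
    extra <- ps$n_variants %||% 1L
    sva_idx <- setdiff(which(role == "background"), signal_idx)[seq_len(extra)]
    role[sva_idx] <- "planted_sva"
    f_alt[sva_idx] <- ps$maf
  }

  dosage <- matrix(NA_integer_, n, m, dimnames = list(sample_ids, vid))
  for (j in seq_len(m)) {
    dosage[, j] <- switch(role[j],
      background = stats::rbinom(n, 2L, f_alt[j]),
      hwe_violation = hwe_distorted_dosage(n, f_alt[j],
                                           spec$hwe_violation$f),
      planted = NA_integer_,   # filled below per gene
      planted_sva = {
        p0 <- f_alt[j]
        o <- spec$planted_sva$odds_ratio * p0 / (1 - p0)
        p1 <- o / (1 + o)
        ifelse(is_case, stats::rbinom(n, 2L, p1), stats::rbinom(n, 2L, p0))
      })
  }

  if (has_planted) {
    for (k in seq_len(nrow(planted))) {
      gvars <- which(gene_of == planted$gene[k] & role == "planted")
      pr <- ifelse(is_case, planted$case_prob[k], planted$control_prob[k])
      carrier <- stats::rbinom(n, 1L, pr) == 1L
      for (jj in seq_along(gvars)) {
        j <- gvars[jj]
        if (jj == 1L) {
          dosage[, j] <- ifelse(carrier, 1L, 0L)
        } else {
          also <- carrier & stats::rbinom(n, 1L, 0.5) == 1L
          dosage[, j] <- ifelse(also, 1L, 0L)
        }
      }
      f_alt[gvars] <- colMeans(dosage[, gvars, drop = FALSE]) / 2
    }
  }

  # depth: per-site mean, collapsed at designated low-coverage sites
  dm <- spec$depth_model
  site_mean <- rep(dm$mean, m)
  n_low <- round(dm$low_depth_fraction * m)
  if (n_low > 0) {
    pool <- setdiff(seq_len(m), signal_idx)
    low_idx <- pool[sample.int(length(pool), min(n_low, length(pool)))]
    site_mean[low_idx] <- dm$low_depth_mean
  }
  depth <- matrix(stats::rnbinom(n * m, size = dm$size,
                                 mu = rep(site_mean, each = n)),
                  n, m, dimnames = list(sample_ids, vid))

  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)
    mask[, signal_idx] <- FALSE   # planted signal stays fully observed
    dosage[mask] <- NA_integer_
  }

  # annotations
  sift <- sample(names(spec$sift_probs), m, replace = TRUE,
                 prob = spec$sift_probs)
  poly <- sample(names(spec$polyphen2_probs), m, replace = TRUE,
                 prob = spec$polyphen2_probs)
  sift[consequence != "missense"] <- "unknown"
  poly[consequence != "missense"] <- "unknown"
  conserved <- stats::runif(m) < spec$conserved_prob
  novel <- stats::runif(m) < spec$novel_prob
  # variants at appreciable population frequency are always catalogued in
  # reference genome panels; only genuinely rare variants can be absent
  ext_known <- f_alt >= 0.01 | stats::runif(m) < spec$external_af_known_prob
  external_af <- ifelse(ext_known,
                        pmin(1, f_alt * stats::runif(m, 0.5, 1.5)), NA)
  if (length(signal_idx)) {
    sift[signal_idx] <- "damaging"
    conserved[signal_idx] <- TRUE
    novel[signal_idx] <- TRUE
    external_af[signal_idx] <- 0.001
  }
  annotations <- data.frame(
    vid = vid, gene = gene_of, consequence = consequence,
    sift_call = sift, polyphen2_call = poly, conserved = conserved,
    external_af = external_af, novel = novel, stringsAsFactors = FALSE)

  variants <- data.frame(vid = vid, chrom = chrom, pos = as.integer(pos),
                         ref = ra[, 1], alt = ra[, 2],
                         stringsAsFactors = FALSE)
  genotypes <- genotype_matrix(dosage, depth)

  # truth: per-variant facts plus per-gene realized carrier counts over the
  # qualifying set (damaging + conserved + rare by realized frequency, or a
  # planted signal variant)
  damaging <- !is.na(classify_damaging(annotations))
  realized_maf <- compute_maf(genotypes)
  qualifies <- (damaging & conserved &
                  !is.na(realized_maf) & realized_maf < 0.05) |
    role == "planted"
  truth_variants <- data.frame(
    vid = vid, gene = gene_of, true_af = f_alt, consequence = consequence,
    damaging = damaging, hwe_violating = role == "hwe_violation",
    planted = role %in% c("planted", "planted_sva"),
    qualifying = qualifies, stringsAsFactors = FALSE)

  qual_map <- truth_variants[qualifies, c("vid", "gene")]
  gene_tab <- data.frame(gene = genes, planted = genes %in%
                           (if (has_planted) planted$gene else character(0)),
                         a = 0L, b = spec$n_cases, c = 0L,
                         d = spec$n_controls, stringsAsFactors = FALSE)
  if (nrow(qual_map)) {
    cc <- collapse_carriers(genotypes, phenotypes, qual_map)
    gi <- match(cc$gene, gene_tab$gene)
    gene_tab$a[gi] <- cc$a; gene_tab$b[gi] <- cc$b
    gene_tab$c[gi] <- cc$c; gene_tab$d[gi] <- cc$d
  }
  truth <- structure(list(variants = truth_variants, genes = gene_tab,
                          qualifying = qual_map), class = "cohort_truth")

  structure(list(variants = variants, genotypes = genotypes,
                 annotations = annotations, phenotypes = phenotypes,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realized carrier table of a gene in the planted truth
#'
#' Carrier counts computed from the emitted genotypes over the gene's
#' qualifying variants — not from the planting probabilities — so they are
#' exactly what [collapse_carriers()] reproduces from the written files.
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param gene Gene symbol.
#' @return One-row data.frame `gene`, `a`, `b`, `c`, `d`.
#' @export
realized_truth <- function(truth, gene) {
  stopifnot(inherits(truth, "cohort_truth"))
  row <- truth$genes[truth$genes$gene == gene, c("gene", "a", "b", "c", "d")]
  if (nrow(row) == 0L) stop("lookup error: unknown gene '", gene, "'")
  rownames(row) <- NULL
  row
}

#' Write a synthetic cohort to disk
#'
#' Emits the exact input formats of the loading stage: a VCF 4.2 with GT and
#' per-sample DP, the annotation TSV, the phenotype TSV, and two truth TSVs.
#' Output is deterministic given the cohort object.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                annotations = file.path(dir, "annotations.tsv"),
                phenotypes = file.path(dir, "phenotypes.tsv"),
                truth_variants = file.path(dir, "truth_variants.tsv"),
                truth_genes = file.path(dir, "truth_genes.tsv"))
  write_vcf(cohort$variants, cohort$genotypes, paths$vcf)
  write_table(cohort$annotations, paths$annotations)
  write_table(cohort$phenotypes, paths$phenotypes)
  write_table(cohort$truth$variants, paths$truth_variants)
  write_table(cohort$truth$genes, paths$truth_genes)
  paths
}

gt_string <- function(dosage) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "0/0"
  out[!is.na(dosage) & dosage == 1L] <- "0/1"
  out[!is.na(dosage) & dosage == 2L] <- "1/1"
  out
}

write_vcf <- function(variants, genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            identical(variants$vid, genotypes$vids))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=exburden-synthetic-cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(j) {
    fields <- paste0(gt_string(genotypes$dosage[, j]), ":",
                     genotypes$depth[, j])
    paste(c(variants$chrom[j], variants$pos[j], ".", variants$ref[j],
            variants$alt[j], ".", "PASS", ".", "GT:DP", fields),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
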