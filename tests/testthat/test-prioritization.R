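ann_row <- function(consequence, sift = "unknown", poly = "unknown") {
  data.frame(vid = "1:1:A/C", gene = "G", consequence = consequence,
             sift_call = sift, polyphen2_call = poly, conserved = TRUE,
             external_af = 0.001, novel = FALSE, stringsAsFactors = FALSE)
}

test_that("damaging classification follows the consequence and predictor rules", {
  expect_equal(classify_damaging(ann_row("stop_gain")), "stop_gain")
  expect_equal(classify_damaging(ann_row("frameshift")), "frameshift")
  expect_equal(classify_damaging(ann_row("splice")), "splice")
  # either predictor suffices for missense
  expect_equal(classify_damaging(ann_row("missense", "tolerated", "damaging")),
               "damaging_missense")
  expect_equal(classify_damaging(ann_row("missense", "damaging", "benign")),
               "damaging_missense")
  expect_true(is.na(classify_damaging(ann_row("missense", "tolerated", "benign"))))
  expect_true(is.na(classify_damaging(ann_row("synonymous"))))
  expect_true(is.na(classify_damaging(ann_row("stop_loss"))))
  expect_true(is.na(classify_damaging(ann_row("inframe_indel"))))
})

test_that("consequence tally partitions the annotated variants exhaustively", {
  empty <- consequence_tally(data.frame(consequence = character(0)))
  expect_true(all(empty == 0L))
  ann <- data.frame(consequence = c(rep("missense", 3), "stop_gain"))
  tal <- consequence_tally(ann)
  expect_equal(tal[["missense"]], 3L)
  expect_equal(tal[["stop_gain"]], 1L)
  expect_equal(sum(tal), 4L)
  # tally on a synthetic cohort matches the generator truth exactly
  co <- simulate_cohort(cohort_spec(n_genes = 25L, seed = 9L))
  tal2 <- consequence_tally(co$annotations)
  truth <- table(factor(co$truth$variants$consequence,
                        levels = names(tal2)))
  expect_equal(as.integer(tal2), as.integer(truth))
  expect_equal(sum(tal2), nrow(co$annotations))
})

case_only_fixture <- function(case_carrier_counts, control_carrier_counts,
                              n_cases = 5, n_controls = 5, ...) {
  m <- length(case_carrier_counts)
  dos <- matrix(0L, n_cases + n_controls, m)
  for (j in seq_len(m)) {
    dos[seq_len(case_carrier_counts[j]), j] <- 1L
    dos[n_cases + seq_len_safe(control_carrier_counts[j]), j] <- 1L
  }
  gm <- make_gm(dos)
  ann <- data.frame(vid = gm$vids, gene = paste0("G", seq_len(m)),
                    consequence = "missense", sift_call = "damaging",
                    polyphen2_call = "benign", conserved = TRUE,
                    external_af = 0.001, novel = TRUE,
                    stringsAsFactors = FALSE)
  qc <- data.frame(vid = gm$vids, qc_pass = TRUE)
  list(genotypes = gm, phenotypes = make_phenotypes(gm$sample_ids, n_cases),
       annotations = ann, qc = qc)
}

seq_len_safe <- function(n) if (n > 0) seq_len(n) else integer(0)

test_that("case-only filter retains exactly the rare damaging case-enriched variants", {
  fx <- case_only_fixture(c(2, 1, 2), c(0, 0, 1))
  out <- case_only_filter(fx$genotypes, fx$phenotypes, fx$annotations, fx$qc)
  # 2 cases / 0 controls retained; 1 case dropped; 2 cases / 1 control dropped
  expect_equal(out$gene, "G1")
  expect_equal(out$case_carriers, 2L)
  expect_equal(out$control_carriers, 0L)
  trail <- attr(out, "filter_trail")
  expect_equal(nrow(trail), 3L)
  expect_false(trail$min_case_carriers[2])
  expect_false(trail$max_control_carriers[3])
})

test_that("filters outside the carrier rules drop candidates as specified", {
  fx <- case_only_fixture(c(2, 2, 2, 2), c(0, 0, 0, 0))
  fx$annotations$external_af[2] <- 0.2       # common in external genomes
  fx$annotations$conserved[3] <- FALSE
  fx$qc$qc_pass[4] <- FALSE
  out <- case_only_filter(fx$genotypes, fx$phenotypes, fx$annotations, fx$qc)
  expect_equal(out$gene, "G1")
  # unknown external frequency passes by default, fails in strict mode
  fx$annotations$external_af[1] <- NA
  out2 <- case_only_filter(fx$genotypes, fx$phenotypes, fx$annotations, fx$qc)
  expect_equal(out2$gene, "G1")
  out3 <- case_only_filter(fx$genotypes, fx$phenotypes, fx$annotations, fx$qc,
                           prioritization_config(strict_external_af = TRUE))
  expect_equal(nrow(out3), 0L)
})

test_that("the filter is monotone in each threshold", {
  set.seed(404)
  for (rep in 1:5) {
    co <- simulate_cohort(cohort_spec(n_genes = 20L, seed = 500L + rep))
    qc <- site_qc(co$genotypes, co$phenotypes)
    base_cfg <- prioritization_config()
    base <- case_only_filter(co$genotypes, co$phenotypes, co$annotations, qc,
                             base_cfg)
    relaxed <- list(
      prioritization_config(external_af_max = 0.5),
      prioritization_config(min_case_carriers = 1L),
      prioritization_config(max_control_carriers = 3L),
      prioritization_config(require_conserved = FALSE)
    )
    for (cfg in relaxed) {
      out <- case_only_filter(co$genotypes, co$phenotypes, co$annotations,
                              qc, cfg)
      expect_true(all(base$vid %in% out$vid))
    }
  }
})

test_that("replaying the filter trail reproduces the retained set", {
  co <- simulate_cohort(cohort_spec(n_genes = 30L, seed = 88L))
  qc <- site_qc(co$genotypes, co$phenotypes)
  out <- case_only_filter(co$genotypes, co$phenotypes, co$annotations, qc)
  trail <- attr(out, "filter_trail")
  replay <- trail$vid[Reduce(`&`, trail[setdiff(names(trail), "vid")])]
  expect_setequal(replay, out$vid)
})

test_that("with planted case-only damaging variants and no noise the retained set is the planted set", {
  spec <- cohort_spec(
    n_genes = 20L,
    consequence_probs = c(missense = 0, synonymous = 0.9, other = 0.1,
                          inframe_indel = 0, frameshift = 0, splice = 0,
                          stop_gain = 0, stop_loss = 0),
    planted_risk_genes = data.frame(gene = c("GENE003", "GENE007"),
                                    case_prob = c(0.3, 0.25),
                                    control_prob = c(0, 0)),
    hwe_violation = list(n_sites = 0L, f = 0),
    missing_rate = 0,
    depth_model = list(mean = 120, size = 8, low_depth_fraction = 0,
                       low_depth_mean = 5),
    seed = 61L)
  co <- simulate_cohort(spec)
  qc <- site_qc(co$genotypes, co$phenotypes)
  out <- case_only_filter(co$genotypes, co$phenotypes, co$annotations, qc)
  planted_vids <- co$truth$variants$vid[
    co$truth$variants$planted & !co$truth$variants$hwe_violating]
  expect_setequal(out$vid, planted_vids)
  expect_true(all(out$control_carriers == 0L))
  expect_true(all(out$case_carriers >= 2L))
})
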