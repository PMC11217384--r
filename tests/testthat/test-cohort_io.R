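test_that("dosage is the alt-allele count and missing calls propagate", {
  co <- load_cohort(vcf_3x2())
  expect_equal(co$variants$vid, c("1:100:A/G", "2:200:C/T"))
  expect_equal(unname(co$genotypes$dosage[, "1:100:A/G"]), c(0L, 1L, 2L))
  expect_equal(unname(co$genotypes$depth[, "1:100:A/G"]), c(20L, 25L, 30L))
  # fully and half-missing genotypes are both missing; depth kept separately
  expect_equal(unname(co$genotypes$dosage[, "2:200:C/T"]),
               c(1L, NA_integer_, NA_integer_))
  expect_equal(unname(co$genotypes$depth[, "2:200:C/T"]), c(15L, 0L, 22L))
})

test_that("multi-allelic sites decompose into per-alt records conserving alt counts", {
  co <- load_cohort(vcf_multiallelic())
  expect_equal(nrow(co$variants), 2L)
  expect_equal(co$variants$chrom, c("7", "7"))
  expect_equal(co$variants$pos, c(500L, 500L))
  expect_equal(co$variants$ref, c("T", "T"))
  expect_setequal(co$variants$alt, c("A", "G"))
  # GT 1/2, 0/1, 2/2 -> alt A dosages (1,1,0); alt G dosages (1,0,2)
  expect_equal(unname(co$genotypes$dosage[, "7:500:T/A"]), c(1L, 1L, 0L))
  expect_equal(unname(co$genotypes$dosage[, "7:500:T/G"]), c(1L, 0L, 2L))
  # decomposition conserves total alt-allele count at the site (here 5)
  expect_equal(sum(co$genotypes$dosage), 5L)
  # decomposed records inherit the site depth
  expect_equal(unname(co$genotypes$depth[, "7:500:T/A"]),
               unname(co$genotypes$depth[, "7:500:T/G"]))
})

test_that("generator output round-trips through the VCF loader exactly", {
  for (seed in c(11L, 202L)) {
    dir <- withr::local_tempdir()
    co <- simulate_cohort(cohort_spec(n_genes = 12L, seed = seed), dir = dir)
    loaded <- load_cohort(file.path(dir, "cohort.vcf"))
    expect_identical(loaded$genotypes$dosage, co$genotypes$dosage)
    expect_identical(loaded$genotypes$depth, co$genotypes$depth)
    expect_identical(loaded$variants, co$variants)
  }
})

test_that("annotation loading populates records and maps blanks to unknowns", {
  path <- write_ann_fixture(data.frame(
    vid = c("12:46244485:A/G", "1:500:C/T"),
    gene = c("ARID2", "GENEX"),
    consequence = c("missense", "synonymous"),
    sift_call = c("damaging", ""),
    polyphen2_call = c("damaging", ""),
    conserved = c("TRUE", ""),
    external_af = c("0.001", ""),
    novel = c("FALSE", "")))
  ann <- load_annotations(path, cohort_vids = "12:46244485:A/G")
  rec <- ann[ann$vid == "12:46244485:A/G", ]
  expect_equal(rec$gene, "ARID2")
  expect_equal(rec$consequence, "missense")
  expect_equal(rec$sift_call, "damaging")
  expect_true(rec$conserved)
  expect_equal(rec$external_af, 0.001)
  expect_false(rec$novel)
  expect_true(rec$in_cohort)
  blank <- ann[ann$vid == "1:500:C/T", ]
  expect_equal(blank$sift_call, "unknown")
  expect_equal(blank$polyphen2_call, "unknown")
  expect_true(is.na(blank$conserved))
  expect_true(is.na(blank$external_af))
  expect_true(is.na(blank$novel))
  expect_false(blank$in_cohort)
})

test_that("annotation schema is enforced and empty files are fine", {
  bad <- write_ann_fixture(data.frame(vid = "1:2:A/C", gene = "G"))
  expect_error(load_annotations(bad), "schema error.*consequence")
  hdr_only <- write_ann_fixture(data.frame(vid = character(0),
                                           gene = character(0),
                                           consequence = character(0)))
  expect_equal(nrow(load_annotations(hdr_only)), 0L)
})

test_that("result serialization is deterministic and round-trips p-values", {
  tab <- published_burden_counts()[1, ]
  res <- burden_scan(data.frame(gene = tab$gene, a = tab$case_carriers,
                                b = tab$case_total - tab$case_carriers,
                                c = tab$control_carriers,
                                d = tab$control_total - tab$control_carriers))
  path <- tempfile(fileext = ".tsv")
  write_table(res, path)
  lines <- readLines(path)
  expect_match(lines[2], "0.000920854", fixed = TRUE)
  # empty result set -> header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_table(res[0, ], p2)
  expect_length(readLines(p2), 1L)
  # write -> read -> write is byte-identical
  back <- utils::read.delim(path, colClasses = "character")
  back$p <- as.numeric(back$p)
  back$p_bonferroni <- as.numeric(back$p_bonferroni)
  back$p_bh <- as.numeric(back$p_bh)
  p3 <- tempfile(fileext = ".tsv")
  write_table(back, p3)
  expect_identical(readLines(p3), lines)
})

test_that("phenotype loading validates labels and coverage", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = c("S1", "S2"),
                                label = c("case", "control")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- load_phenotypes(path, sample_ids = c("S1", "S2"))
  expect_equal(ph$label, c("case", "control"))
  expect_error(load_phenotypes(path, sample_ids = c("S1", "S2", "S3")),
               "integrity error")
})
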