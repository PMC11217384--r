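# Canonical variant key: "chrom:pos:ref/alt", the sole join key between
# genotypes, annotations and panels.
make_vid <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, "/", alt)
}

#' Parse canonical variant identifiers
#'
#' Splits keys of the form `"chrom:pos:ref/alt"` (e.g. `"12:46244485:A/G"`)
#' into their components.
#'
#' @param vid Character vector of variant identifiers.
#' @return A data.frame with columns `vid`, `chrom`, `pos` (integer), `ref`,
#'   `alt`.
#' @examples
#' parse_vid("12:46244485:A/G")
#' @export
parse_vid <- function(vid) {
  m <- regmatches(vid, regexec("^([^:]+):([0-9]+):([^/]+)/(.+)$", vid))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("unparseable variant id at index ", which(bad)[1], ": '",
         vid[which(bad)[1]], "' (expected chrom:pos:ref/alt)")
  }
  data.frame(
    vid = vid,
    chrom = vapply(m, `[`, character(1), 2L),
    pos = as.integer(vapply(m, `[`, character(1), 3L)),
    ref = vapply(m, `[`, character(1), 4L),
    alt = vapply(m, `[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
}

#' Construct a genotype matrix object
#'
#' Container for per-sample alternate-allele dosages and sequencing depth.
#' Rows are samples, columns are bi-allelic variants keyed by `vid`.
#'
#' @param dosage Integer matrix of alt-allele dosages in `{0, 1, 2}` with `NA`
#'   for missing genotypes; rownames are sample ids, colnames are vids.
#' @param depth Non-negative integer matrix of read depths, same shape as
#'   `dosage`. A missing genotype may carry any depth; an absent depth is 0.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, depth) {
  stopifnot(is.matrix(dosage), is.matrix(depth),
            identical(dim(dosage), dim(depth)))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must have sample rownames and vid colnames")
  if (anyDuplicated(colnames(dosage)))
    stop("integrity error: duplicate vid in genotype matrix: ",
         colnames(dosage)[anyDuplicated(colnames(dosage))])
  if (anyDuplicated(rownames(dosage)))
    stop("integrity error: duplicate sample id")
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  depth[is.na(depth)] <- 0L
  storage.mode(dosage) <- "integer"
  storage.mode(depth) <- "integer"
  dimnames(depth) <- dimnames(dosage)
  structure(
    list(dosage = dosage, depth = depth,
         sample_ids = rownames(dosage), vids = colnames(dosage)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      length(x$vids), " variants; missing rate ",
      signif(mean(is.na(x$dosage)), 3), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Dosage of one GT string for alt allele index k ("1" for the first alt).
# Any genotype containing "." (including half-missing "./1") is missing.
gt_dosage <- function(gt, allele) {
  toks <- strsplit(gt, "[/|]")
  vapply(toks, function(tk) {
    if (length(tk) == 0L || any(tk == ".") || any(is.na(tk))) return(NA_integer_)
    sum(tk == allele)
  }, integer(1))
}

#' Load a multi-sample VCF into the pipeline data model
#'
#' Reads GT and per-sample DP from a VCF 4.x file. Multi-allelic sites are
#' decomposed into one bi-allelic record per alternate allele; decomposed
#' records inherit the site's per-sample depth. Dosage is the count of that
#' alternate allele in the genotype; genotypes containing `.` (including
#' half-missing calls such as `./1`) are recorded as missing. A missing DP
#' field is recorded as depth 0 (distinct from a missing genotype).
#'
#' @param vcf_path Path to a VCF file (plain text or gzipped).
#' @return A list with elements
#'   \describe{
#'     \item{variants}{data.frame of `vid`, `chrom`, `pos`, `ref`, `alt`.}
#'     \item{genotypes}{a [genotype_matrix()].}
#'   }
#' @export
load_cohort <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) stop("VCF parse error in '", vcf_path,
                                         "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_site <- nrow(fix)
  if (n_site == 0L) stop("VCF parse error: no variant records in ", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(0, nrow = n_site, ncol = ncol(gt))
  dp[is.na(dp)] <- 0
  samples <- colnames(gt)

  chrom <- character(0); pos <- integer(0); ref <- character(0); alt <- character(0)
  dos_cols <- list(); dep_cols <- list()
  for (i in seq_len(n_site)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & alts != "."]
    if (length(alts) == 0L) next
    toks_row <- gt[i, ]
    for (k in seq_along(alts)) {
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, fix[i, "REF"])
      alt <- c(alt, alts[k])
      dos_cols[[length(dos_cols) + 1L]] <- gt_dosage(toks_row, as.character(k))
      dep_cols[[length(dep_cols) + 1L]] <- as.integer(round(dp[i, ]))
    }
  }
  vid <- make_vid(chrom, pos, ref, alt)
  if (anyDuplicated(vid))
    stop("integrity error: duplicate variant id '", vid[anyDuplicated(vid)], "'")
  dosage <- do.call(cbind, dos_cols)
  depth <- do.call(cbind, dep_cols)
  dimnames(dosage) <- dimnames(depth) <- list(samples, vid)
  list(
    variants = data.frame(vid = vid, chrom = chrom, pos = pos, ref = ref,
                          alt = alt, stringsAsFactors = FALSE),
    genotypes = genotype_matrix(dosage, depth)
  )
}

ann_columns <- c("vid", "gene", "consequence", "sift_call", "polyphen2_call",
                 "conserved", "external_af", "novel")

consequence_levels <- c("missense", "stop_gain", "stop_loss", "frameshift",
                        "inframe_indel", "splice", "synonymous", "other")

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | x == "." | toupper(x) == "NA"] <- NA_character_
  x
}

#' Load a sidecar variant-annotation table
#'
#' Reads a tab-separated annotation file with columns `vid`, `gene`,
#' `consequence` (mandatory) and `sift_call`, `polyphen2_call`, `conserved`,
#' `external_af`, `novel` (optional). Empty cells map to each field's unknown
#' value (`"unknown"` for predictor calls, `NA` for `conserved`, `external_af`
#' and `novel`). Annotations whose `vid` is absent from `cohort_vids` are kept
#' but flagged `in_cohort = FALSE`.
#'
#' @param tsv_path Path to the annotation TSV.
#' @param cohort_vids Optional character vector of vids present in the cohort.
#' @return A data.frame with one row per annotation record.
#' @export
load_annotations <- function(tsv_path, cohort_vids = NULL) {
  ann <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  mandatory <- c("vid", "gene", "consequence")
  miss <- setdiff(mandatory, names(ann))
  if (length(miss))
    stop("schema error: annotation file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(ann_columns, names(ann)))
    ann[[col]] <- rep(NA_character_, nrow(ann))
  ann <- ann[ann_columns]
  if (nrow(ann) == 0L) {
    out <- data.frame(vid = character(0), gene = character(0),
                      consequence = character(0), sift_call = character(0),
                      polyphen2_call = character(0), conserved = logical(0),
                      external_af = numeric(0), novel = logical(0),
                      in_cohort = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    vid = blank_to_na(ann$vid),
    gene = blank_to_na(ann$gene),
    consequence = blank_to_na(ann$consequence),
    sift_call = blank_to_na(ann$sift_call),
    polyphen2_call = blank_to_na(ann$polyphen2_call),
    conserved = as.logical(blank_to_na(ann$conserved)),
    external_af = as.numeric(blank_to_na(ann$external_af)),
    novel = as.logical(blank_to_na(ann$novel)),
    stringsAsFactors = FALSE
  )
  out$sift_call[is.na(out$sift_call)] <- "unknown"
  out$polyphen2_call[is.na(out$polyphen2_call)] <- "unknown"
  if (anyDuplicated(out$vid))
    stop("integrity error: duplicate annotation for vid '",
         out$vid[anyDuplicated(out$vid)], "'")
  bad_cons <- !out$consequence %in% consequence_levels
  if (any(bad_cons))
    stop("schema error: unknown consequence '",
         out$consequence[bad_cons][1], "' (allowed: ",
         paste(consequence_levels, collapse = ", "), ")")
  if (any(!is.na(out$external_af) & (out$external_af < 0 | out$external_af > 1)))
    stop("schema error: external_af outside [0, 1]")
  out$in_cohort <- if (is.null(cohort_vids)) NA else out$vid %in% cohort_vids
  out
}

#' Load a phenotype table
#'
#' Reads a two-column TSV mapping `sample_id` to a `label` in
#' `{case, control}`. When `sample_ids` is supplied the table must cover every
#' genotyped sample and contain at least one case and one control.
#'
#' @param tsv_path Path to the phenotype TSV.
#' @param sample_ids Optional character vector of genotyped sample ids.
#' @return A data.frame with columns `sample_id`, `label`.
#' @export
load_phenotypes <- function(tsv_path, sample_ids = NULL) {
  ph <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "label") %in% names(ph)))
    stop("schema error: phenotype file needs columns sample_id, label")
  ph <- ph[c("sample_id", "label")]
  check_phenotypes(ph, sample_ids)
  ph
}

check_phenotypes <- function(phenotypes, sample_ids = NULL) {
  if (!all(phenotypes$label %in% c("case", "control")))
    stop("integrity error: phenotype labels must be 'case' or 'control'")
  if (anyDuplicated(phenotypes$sample_id))
    stop("integrity error: duplicate sample_id in phenotype table")
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, phenotypes$sample_id)
    if (length(miss))
      stop("integrity error: sample(s) without phenotype: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  if (!any(phenotypes$label == "case") || !any(phenotypes$label == "control"))
    stop("integrity error: need at least one case and one control")
  invisible(phenotypes)
}

# Render a numeric value with at most 9 decimal places, trailing zeros
# dropped, never scientific — so burden p-values round-trip at the precision
# at which published carrier-count tables print them.
format_result_number <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- "NA"
  whole <- !na & x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%.0f", x[whole])
  rest <- !na & !whole
  s <- sprintf("%.9f", x[rest])
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  out[rest] <- s
  out
}

#' Write a result table deterministically
#'
#' Serializes a result data.frame as TSV with a fixed column order, rows
#' sorted by `sort_by` (default: all character/integer key columns in order),
#' and numeric columns rendered with at most nine decimal places so that
#' published burden p-values such as 0.000920854 round-trip byte-identically.
#'
#' @param rows A data.frame of homogeneous result records.
#' @param path Output file path.
#' @param sort_by Character vector of column names to sort rows by; `NULL`
#'   keeps the input order.
#' @return Invisibly, the path written.
#' @export
write_table <- function(rows, path, sort_by = NULL) {
  stopifnot(is.data.frame(rows))
  if (!is.null(sort_by) && nrow(rows)) {
    ord <- do.call(order, unname(rows[sort_by]))
    rows <- rows[ord, , drop = FALSE]
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_result_number(out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                                                 ifelse(out[[j]], "TRUE", "FALSE"))
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error opening '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
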