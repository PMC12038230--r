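#' Default allele-specific expression thresholds
#'
#' Significant ASE requires TPM >= 2 for the expressed allele and
#' |log2 fold change| >= 2 between the paired alleles.
#'
#' @param tpm_min minimum TPM (default 2).
#' @param lfc_min minimum |log2FC| (default 2).
#' @param tpm_rule `"max"`: the larger allele TPM must pass `tpm_min`
#'   (default; keeps one-zero pairs callable); `"both"`: both alleles
#'   must pass.
#' @return list of thresholds.
#' @export
ase_thresholds <- function(tpm_min = 2, lfc_min = 2,
                           tpm_rule = c("max", "both")) {
  assert_that(tpm_min > 0, "'tpm_min' must be > 0")
  assert_that(lfc_min >= 0, "'lfc_min' must be >= 0")
  list(tpm_min = tpm_min, lfc_min = lfc_min, tpm_rule = match.arg(tpm_rule))
}

#' Read a synteny anchors table
#'
#' Tab-separated `gene1 gene2 score` rows; lines starting `#` are
#' block separators and are skipped.
#'
#' @param path anchors file path.
#' @return `data.frame` with `gene1`, `gene2`, `score`.
#' @export
read_anchors <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(f) >= 2), "anchors rows need >= 2 fields")
  data.frame(gene1 = vapply(f, `[`, "", 1L),
             gene2 = vapply(f, `[`, "", 2L),
             score = vapply(f, function(x)
               if (length(x) >= 3) suppressWarnings(as.numeric(x[3])) else NA_real_,
               numeric(1)),
             stringsAsFactors = FALSE)
}

#' Pair alleles across two haplotype genomes from collinearity anchors
#'
#' Builds one-to-one hap1/hap2 gene pairs.  A gene appearing in
#' several anchor rows is kept only in the highest-scoring row (ties:
#' first occurrence).  Rows referencing genes absent from the
#' annotations are skipped with a warning.
#'
#' @param anchors anchors `data.frame` from [read_anchors()].
#' @param genes_hap1,genes_hap2 character vectors of annotated gene
#'   ids for the two haplotypes (the pairing-rate denominator).
#' @return list with `pairs` (`data.frame`: `hap1_gene`, `hap2_gene`,
#'   `score`) and `pairing_rate` = paired genes / total annotated.
#' @export
pair_alleles <- function(anchors, genes_hap1, genes_hap2) {
  known <- anchors$gene1 %in% genes_hap1 & anchors$gene2 %in% genes_hap2
  if (any(!known))
    warning(sum(!known), " anchor row(s) reference unknown genes; skipped")
  a <- anchors[known, , drop = FALSE]
  a$score[is.na(a$score)] <- -Inf
  a <- a[order(-a$score), , drop = FALSE]  # stable: ties keep file order
  keep <- !duplicated(a$gene1) & !duplicated(a$gene2)
  pairs <- data.frame(hap1_gene = a$gene1[keep], hap2_gene = a$gene2[keep],
                      score = a$score[keep], stringsAsFactors = FALSE)
  total <- length(genes_hap1) + length(genes_hap2)
  list(pairs = pairs,
       pairing_rate = if (total) 2 * nrow(pairs) / total else 0)
}

#' Call per-condition allele-specific expression for allele pairs
#'
#' Replicate TPMs are averaged per condition; a pair is significant in
#' a condition iff the TPM rule passes and |log2FC| >= `lfc_min`.  The
#' fold change uses the raw ratio when both TPMs are positive
#' (positive log2FC = hap1-biased).  When exactly one TPM is zero the
#' pair is significant iff the expressed allele passes `tpm_min` (an
#' infinite-fold bias); both zero is never significant.
#'
#' @param pairs allele-pair `data.frame` (`hap1_gene`, `hap2_gene`).
#' @param tpm_matrix numeric matrix, genes x samples, TPM units.
#' @param conditions named character vector mapping sample (column)
#'   names to condition labels.
#' @param thresholds an [ase_thresholds()] list.
#' @return `data.frame`, one row per pair x condition: `hap1_gene`,
#'   `hap2_gene`, `condition`, `tpm1`, `tpm2`, `log2fc`, `significant`,
#'   `direction` (`"hap1"`, `"hap2"`, `"none"`).
#' @export
call_ase <- function(pairs, tpm_matrix, conditions,
                     thresholds = ase_thresholds()) {
  assert_that(all(names(conditions) %in% colnames(tpm_matrix)),
              "conditions name samples absent from the TPM matrix")
  present <- pairs$hap1_gene %in% rownames(tpm_matrix) &
             pairs$hap2_gene %in% rownames(tpm_matrix)
  if (any(!present))
    warning(sum(!present), " pair(s) missing from the TPM matrix; dropped")
  pairs <- pairs[present, , drop = FALSE]
  cond_levels <- unique(unname(conditions))
  # average replicates per condition
  cond_means <- sapply(cond_levels, function(cc) {
    cols <- names(conditions)[conditions == cc]
    rowMeans(tpm_matrix[, cols, drop = FALSE])
  })
  rows <- vector("list", length(cond_levels))
  for (i in seq_along(cond_levels)) {
    t1 <- cond_means[pairs$hap1_gene, i]
    t2 <- cond_means[pairs$hap2_gene, i]
    lfc <- ifelse(t1 > 0 & t2 > 0, log2(t1 / t2),
           ifelse(t1 > 0, Inf, ifelse(t2 > 0, -Inf, NA_real_)))
    tpm_ok <- if (thresholds$tpm_rule == "max")
      pmax(t1, t2) >= thresholds$tpm_min
    else
      pmin(t1, t2) >= thresholds$tpm_min
    sig <- tpm_ok & !is.na(lfc) & abs(lfc) >= thresholds$lfc_min
    rows[[i]] <- data.frame(
      hap1_gene = pairs$hap1_gene, hap2_gene = pairs$hap2_gene,
      condition = cond_levels[i], tpm1 = unname(t1), tpm2 = unname(t2),
      log2fc = unname(lfc), significant = unname(sig),
      direction = ifelse(sig, ifelse(t1 > t2, "hap1", "hap2"), "none"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' ASE consistency categories (fixed order)
#' @export
ASE_CATEGORIES <- c("consistent_hap1", "consistent_hap2", "inconsistent",
                    "not_ase")

#' Classify allele pairs by cross-condition ASE consistency
#'
#' `consistent_hap1`/`consistent_hap2`: significant with the same
#' direction in every condition; `not_ase`: significant in none;
#' `inconsistent`: everything else (direction flips as well as partial
#' significance, under the strict reading of "in all transcriptomes").
#' Set `partial = "direction"` to relax: pairs significant in some
#' conditions, always in the same direction, count as consistent.
#'
#' @param calls output of [call_ase()].
#' @param partial `"strict"` (default) or `"direction"`.
#' @return object of class `ase_classification`: list with `category`
#'   (`data.frame`: `hap1_gene`, `hap2_gene`, `category`) and `counts`.
#' @export
classify_consistency <- function(calls, partial = c("strict", "direction")) {
  partial <- match.arg(partial)
  n_cond <- length(unique(calls$condition))
  if (n_cond < 2)
    stop("consistency needs >= 2 conditions, got ", n_cond)
  key <- paste(calls$hap1_gene, calls$hap2_gene, sep = "\r")
  sp <- split(seq_len(nrow(calls)), factor(key, levels = unique(key)))
  first <- vapply(sp, `[`, 0L, 1L)
  cat_of <- vapply(sp, function(i) {
    sig <- calls$significant[i]
    dir <- calls$direction[i]
    if (!any(sig)) return("not_ase")
    dirs <- unique(dir[sig])
    if (length(dirs) > 1L) return("inconsistent")
    all_sig <- all(sig)
    if (all_sig || partial == "direction")
      return(paste0("consistent_", dirs))
    "inconsistent"
  }, character(1))
  category <- data.frame(hap1_gene = calls$hap1_gene[first],
                         hap2_gene = calls$hap2_gene[first],
                         category = factor(cat_of, levels = ASE_CATEGORIES),
                         stringsAsFactors = FALSE)
  rownames(category) <- NULL
  counts <- table(category$category)
  structure(list(category = category,
                 counts = setNames(as.integer(counts), names(counts)),
                 n_conditions = n_cond, partial = partial),
            class = "ase_classification")
}

#' @export
print.ase_classification <- function(x, ...) {
  cat(sprintf("ase_classification over %d pairs, %d conditions:\n",
              sum(x$counts), x$n_conditions))
  for (cc in ASE_CATEGORIES)
    cat(sprintf("  %-15s %6d\n", cc, x$counts[[cc]]))
  invisible(x)
}

#' Per-chromosome bias of consistent ASE genes
#'
#' Counts consistent pairs biased toward each haplotype per (hap1)
#' chromosome and labels the dominant haplotype (`"tie"` on equality).
#'
#' @param classification an [classify_consistency()] result.
#' @param chrom_map named character vector: hap1 gene id -> chromosome.
#' @return `data.frame`: `chrom`, `consistent_hap1`, `consistent_hap2`,
#'   `dominant`.
#' @export
chromosome_bias_summary <- function(classification, chrom_map) {
  stopifnot(inherits(classification, "ase_classification"))
  cc <- classification$category
  cons <- cc[cc$category %in% c("consistent_hap1", "consistent_hap2"), ,
             drop = FALSE]
  chrom <- chrom_map[cons$hap1_gene]
  tab <- table(chrom = chrom, category = droplevels(cons$category))
  chroms <- rownames(tab)
  h1 <- if ("consistent_hap1" %in% colnames(tab)) tab[, "consistent_hap1"] else
    rep(0L, length(chroms))
  h2 <- if ("consistent_hap2" %in% colnames(tab)) tab[, "consistent_hap2"] else
    rep(0L, length(chroms))
  data.frame(chrom = chroms,
             consistent_hap1 = as.integer(h1),
             consistent_hap2 = as.integer(h2),
             dominant = ifelse(h1 > h2, "hap1", ifelse(h2 > h1, "hap2", "tie")),
             stringsAsFactors = FALSE)
}

#' Overlap of ASE genes with SV gene sets
#'
#' Intersects significant ASE genes (hap1-side ids: every pair not
#' classified `not_ase`) with the SV+ body and upstream-2kb gene sets.
#'
#' @param classification an [classify_consistency()] result.
#' @param sv_plus_genes character vector: genes with SV in the body.
#' @param upstream_sv_genes character vector: genes with SV in the
#'   upstream 2 kb window.
#' @return list: `n_ase`, `n_body`, `frac_body`, `n_upstream`,
#'   `frac_upstream`.
#' @export
ase_sv_overlap <- function(classification, sv_plus_genes,
                           upstream_sv_genes = character()) {
  stopifnot(inherits(classification, "ase_classification"))
  cc <- classification$category
  ase_genes <- cc$hap1_gene[cc$category != "not_ase"]
  n <- length(ase_genes)
  nb <- length(intersect(ase_genes, sv_plus_genes))
  nu <- length(intersect(ase_genes, upstream_sv_genes))
  list(n_ase = n, n_body = nb, frac_body = if (n) nb / n else 0,
       n_upstream = nu, frac_upstream = if (n) nu / n else 0)
}
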