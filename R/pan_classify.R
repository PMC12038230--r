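#' Pan-category thresholds for a genome panel
#'
#' The four occupancy bands used for an n-genome pan-genome:
#' core = all n genomes; softcore = at least `ceil(softcore_frac * n)`
#' but not all; private = exactly one genome; dispensable = everything
#' in between.  With 14 genomes and the default 0.8 fraction the
#' softcore band is occupancy 12-13, matching the "over 80%" convention.
#' For small panels the softcore band can be empty (its count is then
#' always zero).
#'
#' @param n number of genomes (>= 2).
#' @param softcore_frac minimum occupancy fraction for softcore
#'   (default 0.8).
#' @return list with `n`, `softcore_min` and the category bands.
#' @export
pan_thresholds <- function(n, softcore_frac = 0.8) {
  assert_count(n, "n", min = 2L)
  assert_that(softcore_frac > 0 && softcore_frac <= 1,
              "'softcore_frac' must be in (0, 1]")
  softcore_min <- max(2L, as.integer(ceiling(softcore_frac * n)))
  list(n = as.integer(n), softcore_min = softcore_min,
       bands = list(core = c(n, n),
                    softcore = c(softcore_min, n - 1L),
                    dispensable = c(2L, softcore_min - 1L),
                    private = c(1L, 1L)))
}

#' Pan-category vocabulary (fixed order)
#' @export
PAN_CATEGORIES <- c("core", "softcore", "dispensable", "private")

#' Classify gene families into pan categories
#'
#' Families are classified by occupancy: `core` when present in all
#' genomes, `softcore` when present in at least `softcore_min` but not
#' all, `private` when present in exactly one, and `dispensable`
#' otherwise.  A family with occupancy 0 is an error (filter upstream).
#'
#' @param fm a [family_matrix].
#' @param thresholds a [pan_thresholds()] list; default derives from
#'   `fm` with the standard 0.8 softcore fraction.
#' @return object of class `pan_classification`: list with `category`
#'   (named factor over families), `counts`, `fractions`, `thresholds`.
#' @export
classify_families <- function(fm, thresholds = NULL) {
  stopifnot(inherits(fm, "family_matrix"))
  thresholds <- thresholds %||% pan_thresholds(length(fm$genomes))
  occ <- occupancy(fm)
  if (any(occ == 0L))
    stop("family with occupancy 0: ", names(occ)[occ == 0L][1L])
  n <- thresholds$n
  assert_that(n == length(fm$genomes), "thresholds n != genome count")
  cat_chr <- ifelse(occ == n, "core",
             ifelse(occ == 1L, "private",
             ifelse(occ >= thresholds$softcore_min, "softcore",
                    "dispensable")))
  category <- factor(cat_chr, levels = PAN_CATEGORIES)
  names(category) <- fm$families
  counts <- table(category)
  counts <- setNames(as.integer(counts), names(counts))
  fractions <- counts / sum(counts)
  structure(list(category = category, counts = counts,
                 fractions = fractions, thresholds = thresholds),
            class = "pan_classification")
}

#' @export
print.pan_classification <- function(x, ...) {
  cat(sprintf("pan_classification over %d families (n = %d genomes):\n",
              sum(x$counts), x$thresholds$n))
  for (cat_ in PAN_CATEGORIES)
    cat(sprintf("  %-11s %7d (%5.1f%%)\n", cat_, x$counts[[cat_]],
                100 * x$fractions[[cat_]]))
  invisible(x)
}

#' Per-genome gene composition by pan category
#'
#' Counts genes (members, not families) in each genome by the category
#' of the family they belong to, and the fraction of that genome's
#' clustered genes.
#'
#' @param fm a [family_matrix].
#' @param classification a [classify_families()] result for `fm`.
#' @return `data.frame` with columns `genome`, `category`, `genes`,
#'   `fraction`.
#' @export
per_genome_composition <- function(fm, classification) {
  stopifnot(inherits(fm, "family_matrix"),
            inherits(classification, "pan_classification"))
  cat_of_fam <- classification$category
  assert_that(identical(names(cat_of_fam), fm$families),
              "classification does not match matrix families")
  m <- fm$members
  m$category <- cat_of_fam[m$family]
  tab <- table(factor(m$genome, levels = fm$genomes), m$category)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("genome", "category", "genes")
  totals <- tapply(out$genes, out$genome, sum)
  out$fraction <- out$genes / as.numeric(totals[out$genome])
  out[order(match(out$genome, fm$genomes),
            match(out$category, PAN_CATEGORIES)), , drop = FALSE]
}

#' Singleton genes
#'
#' All member genes of occupancy-1 families -- genes found in exactly
#' one genome (including appended unclustered one-gene families when
#' the matrix was built with that option).
#'
#' @param fm a [family_matrix].
#' @return character vector of gene ids.
#' @export
singleton_genes <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  occ <- occupancy(fm)
  fams <- names(occ)[occ == 1L]
  fm$members$gene[fm$members$family %in% fams]
}

#' Cross-tabulate a gene list against pan categories
#'
#' Maps each listed gene through its family to a pan category and
#' summarizes counts and fractions; genes not found in the matrix are
#' reported as `unassigned` (never fatal).
#'
#' @param gene_list character vector of gene ids (e.g. DEGs).
#' @param fm a [family_matrix].
#' @param classification matching [classify_families()] result.
#' @return `data.frame` with columns `category`, `genes`, `fraction`
#'   (fraction of the listed genes; includes an `unassigned` row).
#' @export
crosstab_categories <- function(gene_list, fm, classification) {
  stopifnot(inherits(fm, "family_matrix"),
            inherits(classification, "pan_classification"))
  gene_list <- as.character(gene_list)
  fam_of_gene <- setNames(fm$members$family, fm$members$gene)
  fam <- fam_of_gene[gene_list]
  cat_chr <- ifelse(is.na(fam), "unassigned",
                    as.character(classification$category[fam]))
  levs <- c(PAN_CATEGORIES, "unassigned")
  tab <- table(factor(cat_chr, levels = levs))
  out <- data.frame(category = levs, genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- if (length(gene_list)) out$genes / length(gene_list) else 0
  out
}
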