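#' Duplication-mode vocabulary in priority order
#'
#' Unique-mode assignment resolves multi-mode genes by the fixed
#' priority WGD > TD > PD > TRD > DSD (whole-genome, tandem, proximal,
#' transposed, dispersed duplication).
#' @export
DUP_MODES <- c("WGD", "TD", "PD", "TRD", "DSD")

#' Assign each gene a unique duplication mode
#'
#' Each gene receives the highest-priority mode among all duplicate
#' pairs containing it; genes in no pair are `singleton`.
#'
#' @param pair_lists named list, one element per mode in [DUP_MODES]
#'   (missing modes allowed), each a 2-column `data.frame`/matrix of
#'   gene-id pairs.  Self-pairs and unknown modes are errors.
#' @param all_genes character vector: the full annotated gene set.
#' @return object of class `dup_assignment`: list with `assignment`
#'   (named factor gene -> mode, levels `DUP_MODES` + `singleton`) and
#'   `mode_counts`.
#' @export
assign_unique_mode <- function(pair_lists, all_genes) {
  all_genes <- as.character(all_genes)
  assert_that(!any(duplicated(all_genes)), "duplicate ids in 'all_genes'")
  unknown_modes <- setdiff(names(pair_lists), DUP_MODES)
  if (length(unknown_modes))
    stop("unknown duplication mode(s): ", paste(unknown_modes, collapse = ", "))
  best <- rep.int(length(DUP_MODES) + 1L, length(all_genes))  # sentinel = singleton
  names(best) <- all_genes
  for (mode in intersect(DUP_MODES, names(pair_lists))) {
    pl <- pair_lists[[mode]]
    if (is.null(pl) || !nrow(pl)) next
    g1 <- as.character(pl[[1]]); g2 <- as.character(pl[[2]])
    if (any(g1 == g2)) stop("self-pair in ", mode, " list")
    g <- c(g1, g2)
    miss <- setdiff(g, all_genes)
    if (length(miss))
      stop("pair references unknown gene(s): ",
           paste(head(miss, 3), collapse = ", "))
    pri <- match(mode, DUP_MODES)
    best[g] <- pmin(best[g], pri)
  }
  levs <- c(DUP_MODES, "singleton")
  assignment <- factor(levs[best], levels = levs)
  names(assignment) <- all_genes
  counts <- table(assignment)
  structure(list(assignment = assignment,
                 mode_counts = setNames(as.integer(counts), names(counts))),
            class = "dup_assignment")
}

#' @export
print.dup_assignment <- function(x, ...) {
  cat(sprintf("dup_assignment over %d genes:\n", sum(x$mode_counts)))
  print(x$mode_counts)
  invisible(x)
}

#' Proximal-duplicate check for a gene pair
#'
#' A pair is proximal iff both genes lie on the same chromosome and are
#' separated by fewer than `max_intervals` gene intervals (rank
#' difference), but more than one interval -- adjacent genes (rank
#' difference 1) are tandem, not proximal.
#'
#' @param gene_order `data.frame` with columns `gene`, `chrom`, `rank`
#'   (gene order along the chromosome).
#' @param pair length-2 character vector of gene ids.
#' @param max_intervals the distance bound (default 10).
#' @param strict `TRUE` (default): strictly fewer than `max_intervals`;
#'   `FALSE`: allow equality.
#' @return logical scalar.
#' @export
proximal_check <- function(gene_order, pair, max_intervals = 10,
                           strict = TRUE) {
  stopifnot(length(pair) == 2)
  i <- match(pair, gene_order$gene)
  if (anyNA(i))
    stop("gene(s) lacking order rank: ", paste(pair[is.na(i)], collapse = ", "))
  if (gene_order$chrom[i[1]] != gene_order$chrom[i[2]]) return(FALSE)
  d <- abs(gene_order$rank[i[1]] - gene_order$rank[i[2]])
  within <- if (strict) d < max_intervals else d <= max_intervals
  within && d > 1
}
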