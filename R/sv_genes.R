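#' Read gene models from GFF3 or BED
#'
#' Only `gene` features are kept from GFF3.  Internal coordinates are
#' 0-based half-open (BED native; GFF3 1-based inclusive converted).
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return `data.frame` with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "bed") {
    tab <- fread(path, sep = "\t", header = FALSE, data.table = FALSE)
    assert_that(ncol(tab) >= 4, "BED gene file needs >= 4 columns")
    strand <- if (ncol(tab) >= 6) as.character(tab[[6]]) else "*"
    out <- data.frame(gene = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    assert_that(all(lengths(f) >= 9), "malformed GFF3 line (needs 9 fields)")
    typ <- vapply(f, `[`, "", 3L)
    f <- f[typ == "gene"]
    attr_id <- vapply(f, function(x) {
      m <- regmatches(x[9], regexpr("ID=[^;]+", x[9]))
      if (length(m)) sub("^ID=", "", m) else NA_character_
    }, character(1))
    out <- data.frame(gene = attr_id,
                      chrom = vapply(f, `[`, "", 1L),
                      start = as.integer(vapply(f, `[`, "", 4L)) - 1L,
                      end = as.integer(vapply(f, `[`, "", 5L)),
                      strand = vapply(f, `[`, "", 7L),
                      stringsAsFactors = FALSE)
  }
  assert_that(all(out$start < out$end), "gene with start >= end")
  out
}

#' Write gene models as GFF3 (gene features only)
#'
#' @param genes gene-model `data.frame` (internal 0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tsuperpan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene), con)
  invisible(path)
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"))
}

#' Screen genes overlapping structural variants
#'
#' A gene is SV+ iff its interval -- the gene body, its strand-aware
#' upstream 2 kb window, or either, depending on `region` -- overlaps
#' any SV reference interval by at least 1 bp (coverage-style
#' screening with any nonzero overlap).  Remaining genes are SV-.
#'
#' @param svs SV table from [extract_svs()] (reference coordinates).
#' @param genes gene-model `data.frame` from [read_gene_models()].
#' @param region `"body"`, `"upstream2k"`, or `"both"`.
#' @param upstream upstream window width in bp (default 2000).
#' @return list with character vectors `sv_plus` and `sv_minus`.
#' @export
annotate_sv_genes <- function(svs, genes,
                              region = c("body", "upstream2k", "both"),
                              upstream = 2000L) {
  region <- match.arg(region)
  if (!nrow(genes)) return(list(sv_plus = character(), sv_minus = character()))
  intervals <- NULL
  if (region %in% c("body", "both"))
    intervals <- genes
  if (region %in% c("upstream2k", "both")) {
    unknown <- !(genes$strand %in% c("+", "-"))
    if (any(unknown))
      stop("unknown strand for gene(s) with region='", region, "': ",
           paste(genes$gene[unknown][1:min(3, sum(unknown))], collapse = ", "))
    up <- genes
    up$start <- ifelse(genes$strand == "+", pmax(0L, genes$start - upstream),
                       genes$end)
    up$end <- ifelse(genes$strand == "+", genes$start, genes$end + upstream)
    up <- up[up$start < up$end, , drop = FALSE]
    intervals <- rbind(intervals, up)
  }
  if (!nrow(svs)) {
    return(list(sv_plus = character(), sv_minus = unique(genes$gene)))
  }
  sv_gr <- GenomicRanges::GRanges(
    seqnames = svs$ref_chrom,
    ranges = IRanges::IRanges(start = svs$ref_start + 1L, end = svs$ref_end))
  g_gr <- genes_to_granges(intervals)
  hits <- GenomicRanges::findOverlaps(g_gr, sv_gr, ignore.strand = TRUE)
  plus <- unique(intervals$gene[S4Vectors::queryHits(hits)])
  list(sv_plus = sort(plus),
       sv_minus = sort(setdiff(unique(genes$gene), plus)))
}

#' Detect highly diverged regions (HDR) between two haplotypes
#'
#' Tiles each reference chromosome into fixed windows, measures the
#' fraction of each window NOT covered by syntenic alignment, keeps
#' windows at or above `min_diverged_fraction`, and merges kept
#' windows separated by gaps of at most `merge_gap` bp.  Overlapping
#' genes are attached to each merged segment.
#'
#' @param records parsed alignment records ([parse_syri()]), syntenic
#'   blocks included.
#' @param window window size in bp (default 1e5).
#' @param min_diverged_fraction threshold on the non-syntenic fraction
#'   (default 0.5).
#' @param merge_gap maximum gap merged, bp (default 0 = only adjacent).
#' @param genes optional gene-model `data.frame` to attach.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   defaults to the maximum reference end seen per chromosome.
#' @return `data.frame` of segments: `chrom`, `start`, `end`,
#'   `diverged_fraction` (length-weighted mean over merged windows),
#'   `n_genes`, `gene_ids` (comma-joined).
#' @export
detect_hdr <- function(records, window = 1e5, min_diverged_fraction = 0.5,
                       merge_gap = 0, genes = NULL, chrom_lengths = NULL) {
  assert_that(window > 0, "'window' must be > 0")
  assert_that(min_diverged_fraction >= 0 && min_diverged_fraction <= 1,
              "'min_diverged_fraction' must be in [0, 1]")
  ref <- records[!is.na(records$ref_chrom), , drop = FALSE]
  chroms <- unique(ref$ref_chrom)
  segs <- list()
  for (chr in chroms) {
    rc <- ref[ref$ref_chrom == chr, , drop = FALSE]
    chr_len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
      chrom_lengths[[chr]] else max(rc$ref_end, na.rm = TRUE)
    syn <- rc[rc$syntenic & !is.na(rc$ref_start), , drop = FALSE]
    syn_ir <- IRanges::reduce(IRanges::IRanges(start = syn$ref_start + 1L,
                                               end = syn$ref_end))
    starts0 <- seq(0L, chr_len - 1L, by = window)
    ends0 <- pmin(starts0 + window, chr_len)
    win_ir <- IRanges::IRanges(start = starts0 + 1L, end = ends0)
    syn_bp <- numeric(length(win_ir))
    ov <- IRanges::findOverlaps(win_ir, syn_ir)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        win_ir[S4Vectors::queryHits(ov)], syn_ir[S4Vectors::subjectHits(ov)]))
      syn_bp <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                            levels = seq_along(win_ir)), sum))
      syn_bp[is.na(syn_bp)] <- 0
    }
    div_frac <- 1 - syn_bp / (ends0 - starts0)
    keep <- div_frac >= min_diverged_fraction
    if (!any(keep)) next
    ks <- starts0[keep]; ke <- ends0[keep]; kf <- div_frac[keep]
    # merge runs with gaps <= merge_gap
    brk <- c(TRUE, ks[-1] - ke[-length(ke)] > merge_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      i <- which(grp == g)
      w_len <- ke[i] - ks[i]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr, start = ks[i[1]], end = ke[i[length(i)]],
        diverged_fraction = sum(kf[i] * w_len) / sum(w_len),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), diverged_fraction = numeric(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out$n_genes <- 0L
  out$gene_ids <- ""
  if (!is.null(genes) && nrow(genes)) {
    seg_gr <- GenomicRanges::GRanges(out$chrom,
      IRanges::IRanges(out$start + 1L, out$end))
    g_gr <- genes_to_granges(genes)
    hits <- GenomicRanges::findOverlaps(seg_gr, g_gr, ignore.strand = TRUE)
    if (length(hits)) {
      by_seg <- split(genes$gene[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
      for (k in names(by_seg)) {
        i <- as.integer(k)
        ids <- unique(by_seg[[k]])
        out$n_genes[i] <- length(ids)
        out$gene_ids[i] <- paste(ids, collapse = ",")
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison of numeric attributes between gene groups
#'
#' The standard group test for e.g. expression of SV+ vs SV- genes or
#' CDS length of core vs dispensable genes: Welch (unequal-variance)
#' two-sided t-test.
#'
#' @param values_a,values_b numeric vectors (each n >= 2, finite).
#' @param labels length-2 character vector of group names.
#' @return list of class `group_comparison`: `labels`, `n`, `means`,
#'   `t`, `p`, `test`, `degenerate` (TRUE when both groups have zero
#'   variance and equal means; then `t = 0`, `p = 1`).
#' @export
compare_groups <- function(values_a, values_b, labels = c("A", "B")) {
  values_a <- as.numeric(values_a); values_b <- as.numeric(values_b)
  assert_that(length(values_a) >= 2 && length(values_b) >= 2,
              "each group needs n >= 2")
  assert_that(all(is.finite(values_a)) && all(is.finite(values_b)),
              "values must be finite")
  degenerate <- stats::var(values_a) == 0 && stats::var(values_b) == 0
  if (degenerate) {
    if (mean(values_a) != mean(values_b))
      stop("both groups constant with different means: t undefined")
    t_stat <- 0; p <- 1
  } else {
    ht <- t.test(values_a, values_b, var.equal = FALSE)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(labels = labels,
                 n = c(length(values_a), length(values_b)),
                 means = c(mean(values_a), mean(values_b)),
                 t = t_stat, p = p, test = "Welch two-sample t-test",
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$test, x$labels[1], x$n[1], x$means[1],
              x$labels[2], x$n[2], x$means[2]))
  cat(sprintf("  t = %.4g, p = %.4g%s\n", x$t, x$p,
              if (x$degenerate) " (degenerate: both groups constant)" else ""))
  invisible(x)
}
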