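#' Specification for a synthetic SV/synteny call set
#'
#' @param genome_length reference length in bp.
#' @param n_sv_per_type named counts over INS/DEL/INV/TRANS/DUP/CNV.
#' @param length_range_per_type named list type -> `c(min, max)` bp.
#' @param gene_count number of gene models to plant.
#' @param seed integer seed.
#' @return validated spec list of class `sv_sim_spec`.
#' @export
sv_sim_spec <- function(genome_length = 1e6,
                        n_sv_per_type = c(INS = 5, DEL = 5, INV = 5,
                                          TRANS = 5, DUP = 5, CNV = 5),
                        length_range_per_type = NULL,
                        gene_count = 60, seed = 1L) {
  types <- c("INS", "DEL", "INV", "TRANS", "DUP", "CNV")
  assert_count(genome_length, "genome_length", min = 1000L)
  full <- setNames(rep(0L, length(types)), types)
  full[names(n_sv_per_type)] <- as.integer(n_sv_per_type)
  assert_that(all(full >= 0), "SV counts must be >= 0")
  if (is.null(length_range_per_type))
    length_range_per_type <- setNames(rep(list(c(60, 5000)), length(types)),
                                      types)
  for (t in types) {
    r <- length_range_per_type[[t]] %||% c(60, 5000)
    assert_that(r[1] >= 1 && r[2] >= r[1], paste0("bad length range for ", t))
    length_range_per_type[[t]] <- r
  }
  assert_count(gene_count, "gene_count", min = 0L)
  structure(list(genome_length = as.integer(genome_length),
                 n_sv_per_type = full,
                 length_range_per_type = length_range_per_type[types],
                 gene_count = as.integer(gene_count),
                 seed = as.integer(seed)),
            class = "sv_sim_spec")
}

# rejection-sample n non-overlapping [start, start+len) intervals in [0, L)
place_intervals <- function(L, lens, occupied_starts, occupied_ends,
                            max_tries = 10000L) {
  starts <- integer(length(lens))
  s_occ <- occupied_starts; e_occ <- occupied_ends
  for (i in seq_along(lens)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - lens[i], 1L) - 1L
      e <- s + lens[i]
      if (!any(s < e_occ & e > s_occ)) {
        starts[i] <- s
        s_occ <- c(s_occ, s); e_occ <- c(e_occ, e)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("genome too short to place requested SVs without overlap")
  }
  list(starts = starts, occ_starts = s_occ, occ_ends = e_occ)
}

#' Simulate a SyRI-dialect SV table, gene models, and ground truth
#'
#' Plants non-overlapping SVs of the six types on a single reference
#' chromosome, writes syntenic blocks over the SV-free complement, and
#' places genes inside, outside, and exactly bordering SVs (half-open
#' adjacency, hence SV-).  Query coordinates track the reference with
#' a fixed offset; translocations get a random distant query locus.
#' CNVs alternate copy-gain (CPG) and copy-loss (CPL) codes.
#'
#' @param spec an [sv_sim_spec()].
#' @return list with `syri` (record table in emitted 1-based
#'   coordinates), `genes` (gene models, 0-based half-open), `truth`
#'   (list: `svs` -- planted SVs with type and 0-based half-open
#'   reference intervals and length -- and `sv_plus_genes`,
#'   `sv_minus_genes` by gene-body overlap).
#' @export
simulate_sv_calls <- function(spec) {
  stopifnot(inherits(spec, "sv_sim_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  chrom <- "Chr01"
  types <- names(spec$n_sv_per_type)
  sv_rows <- list()
  occ_s <- integer(0); occ_e <- integer(0)
  for (t in types) {
    n_t <- spec$n_sv_per_type[[t]]
    if (!n_t) next
    r <- spec$length_range_per_type[[t]]
    lens <- sample(seq(r[1], r[2]), n_t, replace = TRUE)
    # reference footprint: 1 bp anchor for INS, full length otherwise
    ref_lens <- if (t == "INS") rep(1L, n_t) else lens
    pl <- place_intervals(L, ref_lens, occ_s, occ_e)
    occ_s <- pl$occ_starts; occ_e <- pl$occ_ends
    for (j in seq_len(n_t)) {
      s <- pl$starts[j]
      ref_e <- s + ref_lens[j]
      qry_s <- if (t == "TRANS") sample.int(L, 1L) - 1L else s
      qry_len <- switch(t, INS = lens[j], DEL = 1L, lens[j])
      code <- switch(t, CNV = if (j %% 2L) "CPG" else "CPL",
                     TRANS = if (j %% 4L == 0L) "INVTR" else "TRANS",
                     DUP = if (j %% 4L == 0L) "INVDP" else "DUP",
                     t)
      sv_rows[[length(sv_rows) + 1L]] <- data.frame(
        type = t, ref_start = s, ref_end = ref_e,
        qry_start = qry_s, qry_end = qry_s + qry_len,
        length = lens[j], code = code, stringsAsFactors = FALSE)
    }
  }
  svs <- if (length(sv_rows)) do.call(rbind, sv_rows) else
    data.frame(type = character(), ref_start = integer(),
               ref_end = integer(), qry_start = integer(),
               qry_end = integer(), length = integer(), code = character(),
               stringsAsFactors = FALSE)
  if (nrow(svs)) svs <- svs[order(svs$ref_start), , drop = FALSE]
  # syntenic complement of the SV footprints
  gaps_ir <- IRanges::gaps(IRanges::reduce(
    IRanges::IRanges(start = svs$ref_start + 1L, end = svs$ref_end)),
    start = 1L, end = L)
  syn <- data.frame(start = IRanges::start(gaps_ir) - 1L,
                    end = IRanges::end(gaps_ir))
  syn <- syn[syn$end > syn$start, , drop = FALSE]

  genes <- simulate_gene_models(spec, svs, syn, chrom)
  truth_plus <- character(0)
  if (nrow(genes) && nrow(svs)) {
    ov <- outer(genes$start, svs$ref_end, `<`) &
          outer(genes$end, svs$ref_start, `>`)
    truth_plus <- genes$gene[rowSums(ov) > 0]
  }
  syri <- build_syri_table(svs, syn, chrom)
  truth_svs <- svs
  rownames(truth_svs) <- NULL
  list(syri = syri, genes = genes,
       truth = list(svs = truth_svs,
                    sv_plus_genes = sort(truth_plus),
                    sv_minus_genes = sort(setdiff(genes$gene, truth_plus))))
}

simulate_gene_models <- function(spec, svs, syn, chrom) {
  n_genes <- spec$gene_count
  if (!n_genes)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  gene_len <- 600L
  rows <- list()
  kinds <- rep(c("inside", "outside", "border"), length.out = n_genes)
  big_syn <- syn[syn$end - syn$start >= 3L * gene_len + 10L, , drop = FALSE]
  assert_that(nrow(big_syn) > 0, "no syntenic gap large enough for genes")
  inside_svs <- svs[svs$ref_end - svs$ref_start > gene_len + 2L, , drop = FALSE]
  used <- IRanges::IRanges()
  for (i in seq_len(n_genes)) {
    kind <- kinds[i]
    if (kind == "inside" && nrow(inside_svs)) {
      sv <- inside_svs[sample.int(nrow(inside_svs), 1L), ]
      s <- sv$ref_start + sample.int(sv$ref_end - sv$ref_start - gene_len, 1L)
    } else if (kind == "border" && nrow(svs)) {
      sv <- svs[sample.int(nrow(svs), 1L), ]
      s <- sv$ref_end  # gene starts exactly at the SV end: half-open SV-
      if (s + gene_len > spec$genome_length) s <- max(0L, sv$ref_start - gene_len)
      # bordering gene must not stray into another SV
      if (nrow(svs) && any(s < svs$ref_end & s + gene_len > svs$ref_start)) {
        kind <- "outside"
      }
    } else kind <- "outside"
    if (kind == "outside") {
      for (try in 1:200) {
        blk <- big_syn[sample.int(nrow(big_syn), 1L), ]
        s <- blk$start + sample.int(blk$end - blk$start - gene_len, 1L)
        if (!nrow(svs) ||
            !any(s < svs$ref_end & s + gene_len > svs$ref_start)) break
      }
    }
    rows[[i]] <- data.frame(gene = sprintf("REF_g%d", i), chrom = chrom,
                            start = as.integer(s),
                            end = as.integer(s + gene_len),
                            strand = if (i %% 2L) "+" else "-",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

build_syri_table <- function(svs, syn, chrom) {
  syn_rows <- if (nrow(syn)) data.frame(
    ref_chr = chrom, ref_start = syn$start + 1L, ref_end = syn$end,
    ref_seq = "-", qry_seq = "-", qry_chr = chrom,
    qry_start = syn$start + 1L, qry_end = syn$end,
    id = sprintf("SYN%d", seq_len(nrow(syn))), parent = "-",
    code = "SYN", copy_status = "-", stringsAsFactors = FALSE) else NULL
  sv_rows <- if (nrow(svs)) data.frame(
    ref_chr = chrom, ref_start = svs$ref_start + 1L, ref_end = svs$ref_end,
    ref_seq = "-", qry_seq = "-", qry_chr = chrom,
    qry_start = svs$qry_start + 1L, qry_end = svs$qry_end,
    id = sprintf("%s%d", svs$code, seq_len(nrow(svs))), parent = "-",
    code = svs$code,
    copy_status = ifelse(svs$code == "CPG", "copygain",
                         ifelse(svs$code == "CPL", "copyloss", "-")),
    stringsAsFactors = FALSE) else NULL
  out <- rbind(syn_rows, sv_rows)
  out[order(out$ref_start), , drop = FALSE]
}

#' Write a simulated SyRI table to disk
#'
#' @param syri table from [simulate_sv_calls()]`$syri`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_syri <- function(syri, path) {
  fwrite(syri, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
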