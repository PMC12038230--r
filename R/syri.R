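#' Parse a SyRI output table
#'
#' Reads the whole-genome-alignment annotation dialect: at least 12
#' tab-separated columns (reference chromosome/start/end/seq, query
#' seq/chromosome/start/end, record id, parent id, annotation code,
#' copy status).  Input coordinates are 1-based inclusive; internally
#' everything is converted to 0-based half-open.  `-` fields become
#' `NA`.  Syntenic records (codes starting `SYN`) are retained with a
#' `syntenic` flag so that divergence analyses can use them.
#'
#' @param path path to the SyRI `.out`-style TSV (no header).
#' @return `data.frame` with columns `ref_chrom`, `ref_start`,
#'   `ref_end`, `qry_chrom`, `qry_start`, `qry_end` (0-based
#'   half-open), `id`, `parent`, `code`, `copy_status`, `syntenic`.
#' @export
parse_syri <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(ref_chrom = character(), ref_start = integer(),
                      ref_end = integer(), qry_chrom = character(),
                      qry_start = integer(), qry_end = integer(),
                      id = character(), parent = character(),
                      code = character(), copy_status = character(),
                      syntenic = logical(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad))
    stop(sprintf("malformed SyRI line %d: expected >= 11 tab-separated fields, got %d",
                 bad[1L], length(fields[[bad[1L]]])))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "-",
                            character(1))
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x)))
  r_start1 <- num(get(2)); r_end1 <- num(get(3))
  q_start1 <- num(get(7)); q_end1 <- num(get(8))
  bad_coord <- which(!is.na(r_start1) & !is.na(r_end1) & r_end1 < r_start1)
  if (length(bad_coord))
    stop(sprintf("malformed SyRI line %d: ref_end < ref_start", bad_coord[1L]))
  code <- get(11)
  known <- c("SYN", "SYNAL", "INV", "INVAL", "TRANS", "TRANSAL", "INVTR",
             "INVTRAL", "DUP", "DUPAL", "INVDP", "INVDPAL", "INS", "DEL",
             "CPG", "CPL", "SNP", "HDR", "NOTAL", "TDM")
  unknown <- setdiff(unique(code), known)
  if (length(unknown))
    warning("unknown SyRI annotation code(s) kept as-is: ",
            paste(unknown, collapse = ", "))
  out <- data.frame(
    ref_chrom = ifelse(get(1) == "-", NA, get(1)),
    ref_start = as.integer(r_start1 - 1L),
    ref_end = as.integer(r_end1),
    qry_chrom = ifelse(get(6) == "-", NA, get(6)),
    qry_start = as.integer(pmin(q_start1, q_end1, na.rm = FALSE) - 1L),
    qry_end = as.integer(pmax(q_start1, q_end1, na.rm = FALSE)),
    id = get(9), parent = get(10), code = code,
    copy_status = get(12),
    stringsAsFactors = FALSE)
  out$syntenic <- startsWith(out$code, "SYN")
  out
}

#' Default mapping from dialect annotation codes to the six SV types
#'
#' The six reported categories are INS, DEL, INV, TRANS, DUP, CNV.
#' Inverted translocations/duplications fold into TRANS/DUP; CNV is
#' derived from the copy-gain/copy-loss codes.  Alignment-level
#' (`*AL`) and syntenic records never yield SVs.
#' @export
SV_CODE_MAP <- c(INS = "INS", DEL = "DEL", INV = "INV",
                 TRANS = "TRANS", INVTR = "TRANS",
                 DUP = "DUP", INVDP = "DUP",
                 CPG = "CNV", CPL = "CNV")

#' Extract classified SV records from parsed alignment records
#'
#' Maps annotation codes to the six SV categories, computes the SV
#' length as the larger of the reference and query spans (an insertion
#' has essentially no reference span), and keeps records strictly
#' longer than `min_len` ("larger than 50 bp" is exclusive).
#'
#' @param records output of [parse_syri()].
#' @param min_len minimum length, exclusive (default 50).
#' @param types_kept SV categories retained (default all six).
#' @param code_map named map code -> category (default [SV_CODE_MAP]).
#' @return `data.frame` of SV records: `type`, coordinates (0-based
#'   half-open), `length`, `source_code`; attribute `n_filtered` gives
#'   the number of candidate SVs dropped by the length filter.
#' @export
extract_svs <- function(records, min_len = 50,
                        types_kept = c("INS", "DEL", "INV", "TRANS",
                                       "DUP", "CNV"),
                        code_map = SV_CODE_MAP) {
  assert_that(min_len >= 0, "'min_len' must be >= 0")
  type <- unname(code_map[records$code])
  cand <- !is.na(type) & type %in% types_kept & !records$syntenic
  ref_span <- records$ref_end - records$ref_start
  qry_span <- records$qry_end - records$qry_start
  ref_span[is.na(ref_span)] <- 0L
  qry_span[is.na(qry_span)] <- 0L
  len <- pmax(ref_span, qry_span)
  keep <- cand & len > min_len
  out <- data.frame(
    type = factor(type[keep], levels = c("INS", "DEL", "INV", "TRANS",
                                         "DUP", "CNV")),
    ref_chrom = records$ref_chrom[keep],
    ref_start = records$ref_start[keep],
    ref_end = records$ref_end[keep],
    qry_chrom = records$qry_chrom[keep],
    qry_start = records$qry_start[keep],
    qry_end = records$qry_end[keep],
    length = len[keep],
    source_code = records$code[keep],
    stringsAsFactors = FALSE)
  attr(out, "n_candidates") <- sum(cand)
  attr(out, "n_filtered") <- sum(cand) - sum(keep)
  out
}

#' Bin SV lengths per type
#'
#' Bins are left-open/right-closed `(edge_i, edge_{i+1}]`, consistent
#' with the strict "> 50 bp" lower cut.  SVs no longer than the first
#' edge fall into an `underflow` bucket that is reported, not dropped.
#'
#' @param svs output of [extract_svs()].
#' @param bin_edges strictly increasing numeric edges; default
#'   `c(50, 100, 500, 1e3, 5e3, 1e4, Inf)`.
#' @return `data.frame` of counts: `type`, `bin`, `count`.
#' @export
length_histogram <- function(svs, bin_edges = c(50, 100, 500, 1e3, 5e3,
                                                1e4, Inf)) {
  assert_that(all(diff(bin_edges) > 0), "'bin_edges' must be strictly increasing")
  labs <- c("underflow",
            sprintf("(%g,%g]", head(bin_edges, -1), tail(bin_edges, -1)))
  bin <- cut(svs$length, breaks = c(-Inf, bin_edges), labels = labs,
             right = TRUE)
  tab <- table(type = svs$type, bin = bin)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("type", "bin", "count")
  out$count <- as.integer(out$count)
  out
}
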