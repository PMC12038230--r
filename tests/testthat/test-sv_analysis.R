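make_syri_file <- function(lines, dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  path <- file.path(dir, "t.syri.out")
  writeLines(lines, path)
  path
}

test_that("parse_syri converts coordinates and flags synteny", {
  path <- make_syri_file(c(
    "Chr1\t1\t1000\t-\t-\tChr1\t1\t1000\tSYN1\t-\tSYN\t-",
    "Chr1\t1\t1000\t-\t-\tChr1\t1\t1000\tINV1\t-\tINV\t-",
    "Chr1\t500\t500\t-\t-\tChr1\t500\t700\tINS1\t-\tINS\t-"))
  recs <- parse_syri(path)
  expect_equal(recs$ref_start, c(0L, 0L, 499L))
  expect_equal(recs$ref_end, c(1000L, 1000L, 500L))
  expect_equal(recs$ref_end - recs$ref_start, c(1000L, 1000L, 1L))
  expect_equal(recs$syntenic, c(TRUE, FALSE, FALSE))
  # round-trip: re-emitting 1-based inclusive recovers the input spans
  expect_equal(recs$ref_start + 1L, c(1L, 1L, 500L))
})

test_that("parse_syri reports malformed lines and unknown codes", {
  path <- make_syri_file("Chr1\t1\t100")
  expect_error(parse_syri(path), "line 1")
  path2 <- make_syri_file(
    "Chr1\t1\t100\t-\t-\tChr1\t1\t100\tX1\t-\tWEIRD\t-")
  expect_warning(recs <- parse_syri(path2), "WEIRD")
  expect_equal(recs$code, "WEIRD")
  path3 <- make_syri_file(character(0))
  expect_equal(nrow(parse_syri(path3)), 0)
})

test_that("extract_svs applies the strict >50 bp filter and code map", {
  mk <- function(start, end, code, qs = start, qe = end)
    sprintf("Chr1\t%d\t%d\t-\t-\tChr1\t%d\t%d\tID\t-\t%s\t-",
            start, end, qs, qe, code)
  path <- make_syri_file(c(
    mk(1, 50, "DEL"),       # length 50 -> excluded
    mk(101, 151, "DEL"),    # length 51 -> included
    mk(201, 400, "CPG"),    # -> CNV
    mk(501, 700, "INVTR"),  # -> TRANS
    mk(801, 1000, "INVDP"), # -> DUP
    mk(1100, 1100, "INS", 1100, 1400),  # qry span 301
    mk(1500, 2500, "SYN")))
  recs <- parse_syri(path)
  svs <- extract_svs(recs, min_len = 50)
  expect_equal(nrow(svs), 5)
  expect_setequal(as.character(svs$type),
                  c("DEL", "CNV", "TRANS", "DUP", "INS"))
  expect_equal(svs$length[svs$type == "DEL"], 51)
  expect_equal(svs$length[svs$type == "INS"], 301)
  # conservation: candidates = kept + filtered
  expect_equal(attr(svs, "n_candidates"), nrow(svs) + attr(svs, "n_filtered"))
})

test_that("length_histogram bins per type with underflow reporting", {
  svs <- data.frame(type = factor(c("DEL", "INV", "DEL"),
                                  levels = c("INS", "DEL", "INV", "TRANS",
                                             "DUP", "CNV")),
                    length = c(60, 2000, 40))
  h <- length_histogram(svs)
  expect_equal(h$count[h$type == "DEL" & h$bin == "(50,100]"], 1)
  expect_equal(h$count[h$type == "INV" & h$bin == "(1000,5000]"], 1)
  expect_equal(h$count[h$type == "DEL" & h$bin == "underflow"], 1)
  expect_equal(sum(h$count), 3)
  h0 <- length_histogram(svs[0, ])
  expect_true(all(h0$count == 0))
  expect_error(length_histogram(svs, bin_edges = c(100, 50)), "increasing")
})

test_that("annotate_sv_genes uses half-open >=1 bp overlap semantics", {
  svs <- data.frame(type = "DEL", ref_chrom = "Chr1", ref_start = 150,
                    ref_end = 160, qry_chrom = "Chr1", qry_start = 150,
                    qry_end = 151, length = 10, source_code = "DEL")
  genes <- data.frame(gene = c("gA", "gB"), chrom = "Chr1",
                      start = c(100, 100), end = c(200, 200),
                      strand = c("+", "-"))
  ann <- annotate_sv_genes(svs, genes, region = "body")
  expect_setequal(ann$sv_plus, c("gA", "gB"))
  # adjacency: SV [200,210) does not touch gene [100,200)
  svs2 <- transform(svs, ref_start = 200, ref_end = 210)
  ann2 <- annotate_sv_genes(svs2, genes, region = "body")
  expect_length(ann2$sv_plus, 0)
  expect_setequal(ann2$sv_minus, c("gA", "gB"))
  # upstream 2 kb is strand-aware: SV at [50,60) hits only gA's window
  svs3 <- transform(svs, ref_start = 50, ref_end = 60)
  ann3 <- annotate_sv_genes(svs3, genes, region = "upstream2k")
  expect_equal(ann3$sv_plus, "gA")
  svs4 <- transform(svs, ref_start = 300, ref_end = 310)
  ann4 <- annotate_sv_genes(svs4, genes, region = "upstream2k")
  expect_equal(ann4$sv_plus, "gB")
  genes_bad <- transform(genes, strand = ".")
  expect_error(annotate_sv_genes(svs, genes_bad, region = "upstream2k"),
               "strand")
})

test_that("detect_hdr recovers a planted diverged block within one window", {
  # chromosome 1 Mb, syntenic except a 500 kb hole at [300k, 800k)
  lines <- c(
    "Chr1\t1\t300000\t-\t-\tChr1\t1\t300000\tSYN1\t-\tSYN\t-",
    "Chr1\t800001\t1000000\t-\t-\tChr1\t800001\t1000000\tSYN2\t-\tSYN\t-",
    "Chr1\t300001\t800000\t-\t-\tChr1\t300001\t800000\tNOTAL1\t-\tNOTAL\t-")
  recs <- parse_syri(make_syri_file(lines))
  hdr <- detect_hdr(recs, window = 1e5, min_diverged_fraction = 0.5)
  expect_equal(nrow(hdr), 1)
  expect_lte(abs(hdr$start - 3e5), 1e5)
  expect_lte(abs(hdr$end - 8e5), 1e5)
  genes <- data.frame(gene = c("in1", "out1"), chrom = "Chr1",
                      start = c(4e5, 1e5), end = c(4e5 + 1000, 1e5 + 1000),
                      strand = "+")
  hdr_g <- detect_hdr(recs, window = 1e5, min_diverged_fraction = 0.5,
                      genes = genes)
  expect_equal(hdr_g$gene_ids, "in1")
  # fully syntenic chromosome -> no HDR
  syn_only <- parse_syri(make_syri_file(lines[1:2]))
  expect_equal(nrow(detect_hdr(syn_only, window = 1e5,
                               min_diverged_fraction = 0.5)), 1)
  full <- parse_syri(make_syri_file(
    "Chr1\t1\t1000000\t-\t-\tChr1\t1\t1000000\tSYN1\t-\tSYN\t-"))
  expect_equal(nrow(detect_hdr(full, window = 1e5,
                               min_diverged_fraction = 0.5)), 0)
  expect_error(detect_hdr(recs, window = 0), "window")
})

test_that("HDR total length is non-increasing in the divergence threshold", {
  sim <- simulate_sv_calls(sv_sim_spec(genome_length = 5e5,
    n_sv_per_type = c(DEL = 20, INV = 20),
    length_range_per_type = list(DEL = c(2000, 9000), INV = c(2000, 9000)),
    gene_count = 0, seed = 17))
  tf <- withr::local_tempfile(); write_syri(sim$syri, tf)
  recs <- parse_syri(tf)
  total_len <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    h <- detect_hdr(recs, window = 1e4, min_diverged_fraction = th)
    sum(h$end - h$start)
  }, numeric(1))
  expect_true(all(diff(total_len) <= 0))
})

test_that("compare_groups implements the Welch two-sided test", {
  a <- c(1, 2, 3, 5, 8); b <- c(11, 12.5, 13, 15, 18.2)
  got <- compare_groups(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_lt(compare_groups(c(1, 2, 3), c(11, 12, 13))$p, 0.01)
  # swap negates t, preserves p
  swapped <- compare_groups(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$p, got$p)
  # identical constant groups are degenerate with t = 0, p = 1
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_true(same$degenerate)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
  expect_error(compare_groups(c(2, 2), c(3, 3)), "different means")
})
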