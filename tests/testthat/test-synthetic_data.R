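test_that("pangenome sim spec validates fractions and counts", {
  expect_error(pangenome_sim_spec(category_fractions = c(core = 0.5,
                                                         softcore = 0.1,
                                                         dispensable = 0.3,
                                                         private = 0.2)),
               "sum to 1")
  expect_error(pangenome_sim_spec(n_genomes = 1), "n_genomes")
  expect_error(pangenome_sim_spec(genes_per_family_mean = 0.5),
               "genes_per_family_mean")
})

test_that("simulated family matrix satisfies its planted truth exactly", {
  spec <- pangenome_sim_spec(n_genomes = 14, n_families = 400,
                             category_fractions = c(core = 0.44,
                                                    softcore = 0.08,
                                                    dispensable = 0.47,
                                                    private = 0.01),
                             seed = 31)
  sim <- simulate_family_matrix(spec)
  cls <- classify_families(sim$matrix)
  expect_identical(as.character(cls$category[sim$truth$family]),
                   sim$truth$category)
  # planted fractions reproduced exactly (largest-remainder allocation)
  expect_equal(unname(cls$counts),
               unname(superpan:::apportion(400, spec$category_fractions)))
})

test_that("degenerate fractions and infeasible bands behave as declared", {
  sim <- simulate_family_matrix(pangenome_sim_spec(
    n_genomes = 5, n_families = 20,
    category_fractions = c(core = 1, softcore = 0, dispensable = 0,
                           private = 0), seed = 1))
  expect_true(all(occupancy(sim$matrix) == 5))
  # n = 4: softcore band empty -> reassignment with warning, truth flagged
  expect_warning(
    sim4 <- simulate_family_matrix(pangenome_sim_spec(
      n_genomes = 4, n_families = 40,
      category_fractions = c(core = 0.25, softcore = 0.25,
                             dispensable = 0.25, private = 0.25), seed = 2)),
    "infeasible")
  expect_true(any(sim4$truth$reassigned))
  cls4 <- classify_families(sim4$matrix)
  expect_identical(as.character(cls4$category[sim4$truth$family]),
                   sim4$truth$category)
})

test_that("generators are deterministic under a fixed seed", {
  for (pair in list(
    list(function() simulate_family_matrix(pangenome_sim_spec(
      n_genomes = 6, n_families = 50, seed = 5))),
    list(function() simulate_sv_calls(sv_sim_spec(genome_length = 2e5,
      n_sv_per_type = c(DEL = 3, INV = 2), gene_count = 12, seed = 5))),
    list(function() simulate_ase_matrix(ase_sim_spec(n_pairs = 30,
      n_consistent = 5, n_inconsistent = 5, noise_cv = 0.1, seed = 5))),
    list(function() simulate_reads(read_sim_spec(genome_length = 5000,
      read_length = 50, coverage = 5, error_rate = 0.01, seed = 5))))) {
    expect_identical(pair[[1]](), pair[[1]]())
  }
})

test_that("simulated SV calls honor counts, ranges and placement", {
  spec <- sv_sim_spec(genome_length = 5e5,
                      n_sv_per_type = c(INS = 4, DEL = 4, INV = 4, TRANS = 4,
                                        DUP = 4, CNV = 4),
                      length_range_per_type = list(DEL = c(80, 120)),
                      gene_count = 30, seed = 13)
  sim <- simulate_sv_calls(spec)
  tr <- sim$truth$svs
  expect_equal(unname(table(tr$type)[c("INS", "DEL", "INV", "TRANS", "DUP",
                                       "CNV")]),
               rep(4L, 6), ignore_attr = TRUE)
  del <- tr[tr$type == "DEL", ]
  expect_true(all(del$length >= 80 & del$length <= 120))
  # non-overlapping reference footprints
  tr_ord <- tr[order(tr$ref_start), ]
  expect_true(all(diff_ok <- tr_ord$ref_start[-1] >=
                    tr_ord$ref_end[-nrow(tr_ord)]))
  # genome too short to place -> error
  expect_error(simulate_sv_calls(sv_sim_spec(genome_length = 2000,
    n_sv_per_type = c(DEL = 100),
    length_range_per_type = list(DEL = c(500, 900)), gene_count = 0,
    seed = 1)), "too short")
})

test_that("all-zero SV spec emits only syntenic records", {
  sim <- simulate_sv_calls(sv_sim_spec(genome_length = 5e4,
                                       n_sv_per_type = c(DEL = 0),
                                       gene_count = 6, seed = 3))
  expect_true(all(sim$syri$code == "SYN"))
  expect_equal(nrow(sim$truth$svs), 0)
  expect_length(sim$truth$sv_plus_genes, 0)
})

test_that("ASE generator plants guaranteed effects or refuses", {
  expect_error(ase_sim_spec(noise_cv = 0.5), "too large")
  sim <- simulate_ase_matrix(ase_sim_spec(n_pairs = 40, n_consistent = 0,
                                          n_inconsistent = 0, seed = 3))
  cls <- classify_consistency(call_ase(sim$pairs, sim$tpm, sim$conditions))
  expect_equal(sum(cls$counts) - cls$counts[["not_ase"]], 0)
})

test_that("read simulator output matches its arithmetic contract", {
  spec <- read_sim_spec(genome_length = 1e4, read_length = 100,
                        coverage = 20, error_rate = 0, seed = 8)
  sim <- simulate_reads(spec)
  expect_length(sim$reads, 2000)  # round(20 * 1e4 / 100)
  expect_equal(nchar(sim$reference), 1e4)
  # error-free reads are exact substrings of the reference (either strand)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$reference)))
  both <- paste(sim$reference, rc, sep = "NNNN")
  hits <- vapply(sim$reads[1:50], function(r) grepl(r, both, fixed = TRUE),
                 logical(1))
  expect_true(all(hits))
  # errors change bases at roughly the requested rate
  sim_err <- simulate_reads(read_sim_spec(genome_length = 1e4,
                                          read_length = 100, coverage = 10,
                                          error_rate = 0.05, seed = 8))
  hits_err <- vapply(sim_err$reads[1:100], function(r)
    grepl(r, both, fixed = TRUE), logical(1))
  expect_lt(mean(hits_err), 0.5)
})

test_that("emitted files are parseable by the package's own readers", {
  dir <- withr::local_tempdir()
  sv <- simulate_sv_calls(sv_sim_spec(genome_length = 1e5,
                                      n_sv_per_type = c(INV = 3, DEL = 3),
                                      gene_count = 9, seed = 4))
  write_syri(sv$syri, file.path(dir, "x.syri.out"))
  recs <- parse_syri(file.path(dir, "x.syri.out"))
  expect_equal(nrow(recs), nrow(sv$syri))
  write_gene_models_gff3(sv$genes, file.path(dir, "g.gff3"))
  genes2 <- read_gene_models(file.path(dir, "g.gff3"))
  expect_equal(genes2[order(genes2$gene), c("gene", "chrom", "start", "end")],
               sv$genes[order(sv$genes$gene), c("gene", "chrom", "start",
                                                "end")],
               ignore_attr = TRUE)
  r <- simulate_reads(read_sim_spec(genome_length = 2000, read_length = 50,
                                    coverage = 2, seed = 4))
  write_fastq(r$reads, file.path(dir, "r.fq"))
  back <- as.character(Biostrings::readDNAStringSet(file.path(dir, "r.fq"),
                                                    format = "fastq"))
  expect_equal(unname(back), r$reads)
})
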