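test_that("pair_alleles resolves duplicates by score and reports the rate", {
  anchors <- data.frame(gene1 = c("h1_a", "h1_a", "h1_b"),
                        gene2 = c("h2_x", "h2_y", "h2_y"),
                        score = c(100, 50, 80))
  res <- pair_alleles(anchors, genes_hap1 = c("h1_a", "h1_b", "h1_c"),
                      genes_hap2 = c("h2_x", "h2_y", "h2_z"))
  # h1_a keeps its higher-scoring partner h2_x; h1_b then pairs h2_y
  expect_equal(res$pairs$hap2_gene[res$pairs$hap1_gene == "h1_a"], "h2_x")
  expect_equal(nrow(res$pairs), 2)
  expect_equal(res$pairing_rate, 4 / 6)
  expect_warning(
    res2 <- pair_alleles(data.frame(gene1 = c("h1_a", "nope"),
                                    gene2 = c("h2_x", "h2_y"),
                                    score = c(1, 2)),
                         c("h1_a"), c("h2_x", "h2_y")),
    "unknown")
  expect_equal(nrow(res2$pairs), 1)
})

test_that("call_ase applies the TPM and fold-change thresholds exactly", {
  pairs <- data.frame(hap1_gene = c("a1", "b1", "c1", "d1"),
                      hap2_gene = c("a2", "b2", "c2", "d2"))
  tpm <- matrix(c(8, 2,     # |log2fc| = 2 exactly -> significant
                  2, 0,     # one-zero, expressed allele at tpm_min
                  1.5, 0.2, # max TPM < 2 -> not significant
                  0, 0),    # both zero
                ncol = 1,
                dimnames = list(c("a1", "a2", "b1", "b2", "c1", "c2",
                                  "d1", "d2"), "s1"))
  tpm <- cbind(tpm, s2 = tpm[, 1])
  conds <- c(s1 = "c1", s2 = "c2")
  calls <- call_ase(pairs, tpm, conds)
  c1 <- calls[calls$condition == "c1", ]
  expect_equal(c1$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(c1$direction, c("hap1", "hap1", "none", "none"))
  expect_equal(c1$log2fc[1], 2)
  expect_equal(c1$log2fc[2], Inf)
  # 'both' rule makes the one-zero pair uncallable
  calls_both <- call_ase(pairs, tpm, conds,
                         ase_thresholds(tpm_rule = "both"))
  expect_false(calls_both$significant[calls_both$hap1_gene == "b1" &
                                        calls_both$condition == "c1"])
  # replicate averaging: two reps of (6, 10) average to 8 vs 2
  tpm_rep <- matrix(c(6, 2, 10, 2), ncol = 2,
                    dimnames = list(c("a1", "a2"), c("r1", "r2")))
  calls_rep <- call_ase(pairs[1, ], tpm_rep, c(r1 = "x", r2 = "x"))
  expect_equal(calls_rep$tpm1, 8)
  expect_true(calls_rep$significant)
  # pair missing from the matrix is dropped with a warning
  expect_warning(dropped <- call_ase(
    data.frame(hap1_gene = c("a1", "zz"), hap2_gene = c("a2", "zz2")),
    tpm, conds), "dropped")
  expect_equal(unique(dropped$hap1_gene), "a1")
})

test_that("threshold monotonicity: raising cutoffs never adds calls", {
  sim <- simulate_ase_matrix(ase_sim_spec(n_pairs = 120, n_consistent = 30,
                                          n_inconsistent = 30,
                                          noise_cv = 0.1, seed = 12))
  n_sig <- function(tpm_min, lfc_min) {
    sum(call_ase(sim$pairs, sim$tpm, sim$conditions,
                 ase_thresholds(tpm_min, lfc_min))$significant)
  }
  expect_gte(n_sig(2, 2), n_sig(2, 3))
  expect_gte(n_sig(2, 2), n_sig(10, 2))
  expect_gte(n_sig(2, 3), n_sig(10, 4))
})

test_that("consistency classification follows the all-conditions rule", {
  mk_calls <- function(sig, dir) {
    data.frame(hap1_gene = "g1", hap2_gene = "g2",
               condition = sprintf("c%d", seq_along(sig)),
               tpm1 = 10, tpm2 = 1, log2fc = 3.3, significant = sig,
               direction = ifelse(sig, dir, "none"))
  }
  cls_of <- function(sig, dir, ...)
    as.character(classify_consistency(mk_calls(sig, dir), ...)$category$category)
  expect_equal(cls_of(rep(TRUE, 9), rep("hap1", 9)), "consistent_hap1")
  expect_equal(cls_of(c(TRUE, TRUE, TRUE, TRUE), c("hap1", "hap1", "hap1",
                                                   "hap2")), "inconsistent")
  expect_equal(cls_of(rep(FALSE, 3), rep("none", 3)), "not_ase")
  # partial significance, constant direction: strict -> inconsistent
  expect_equal(cls_of(c(TRUE, FALSE, TRUE), rep("hap1", 3)), "inconsistent")
  expect_equal(cls_of(c(TRUE, FALSE, TRUE), rep("hap1", 3),
                      partial = "direction"), "consistent_hap1")
  expect_error(classify_consistency(mk_calls(TRUE, "hap1")), "2 conditions")
})

test_that("classification partitions pairs and is antisymmetric in haplotypes", {
  sim <- simulate_ase_matrix(ase_sim_spec(n_pairs = 80, n_consistent = 20,
                                          n_inconsistent = 20, seed = 6))
  calls <- call_ase(sim$pairs, sim$tpm, sim$conditions)
  cls <- classify_consistency(calls)
  expect_equal(sum(cls$counts), 80)
  # swap hap1/hap2 everywhere
  pairs_sw <- data.frame(hap1_gene = sim$pairs$hap2_gene,
                         hap2_gene = sim$pairs$hap1_gene)
  cls_sw <- classify_consistency(call_ase(pairs_sw, sim$tpm, sim$conditions))
  expect_equal(cls_sw$counts[["consistent_hap1"]],
               cls$counts[["consistent_hap2"]])
  expect_equal(cls_sw$counts[["consistent_hap2"]],
               cls$counts[["consistent_hap1"]])
  expect_equal(cls_sw$counts[["inconsistent"]], cls$counts[["inconsistent"]])
  expect_equal(cls_sw$counts[["not_ase"]], cls$counts[["not_ase"]])
})

test_that("chromosome bias summary counts directions and labels ties", {
  category <- data.frame(
    hap1_gene = sprintf("g%d", 1:6),
    hap2_gene = sprintf("h%d", 1:6),
    category = factor(c("consistent_hap1", "consistent_hap1",
                        "consistent_hap1", "consistent_hap2",
                        "consistent_hap1", "consistent_hap2"),
                      levels = ASE_CATEGORIES))
  cls <- structure(list(category = category,
                        counts = table(category$category),
                        n_conditions = 2, partial = "strict"),
                   class = "ase_classification")
  chrom_map <- c(g1 = "Chr1", g2 = "Chr1", g3 = "Chr1", g4 = "Chr1",
                 g5 = "Chr2", g6 = "Chr2")
  bias <- chromosome_bias_summary(cls, chrom_map)
  expect_equal(bias$dominant[bias$chrom == "Chr1"], "hap1")
  expect_equal(bias$dominant[bias$chrom == "Chr2"], "tie")
})

test_that("ase_sv_overlap computes intersection counts and fractions", {
  sim <- simulate_ase_matrix(ase_sim_spec(n_pairs = 50, n_consistent = 10,
                                          n_inconsistent = 10, seed = 9))
  cls <- classify_consistency(call_ase(sim$pairs, sim$tpm, sim$conditions))
  ase_genes <- cls$category$hap1_gene[cls$category$category != "not_ase"]
  ov_all <- ase_sv_overlap(cls, sv_plus_genes = ase_genes)
  expect_equal(ov_all$frac_body, 1)
  ov_none <- ase_sv_overlap(cls, sv_plus_genes = "unrelated")
  expect_equal(ov_none$n_body, 0)
  expect_equal(ov_none$frac_body, 0)
  half <- ase_genes[seq_len(floor(length(ase_genes) / 2))]
  ov_half <- ase_sv_overlap(cls, half, upstream_sv_genes = ase_genes[1])
  expect_equal(ov_half$n_body, length(half))
  expect_equal(ov_half$frac_body, length(half) / length(ase_genes))
  expect_equal(ov_half$n_upstream, 1)
})
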