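#' Specification for a synthetic allele-specific expression experiment
#'
#' Defaults emulate a nine-condition (fruit developmental stage)
#' design with a moderate number of allele pairs.  Planted consistent
#' pairs carry a 16-fold bias (log2FC = 4), twice the calling
#' threshold, so calls are robust at realistic noise levels.
#'
#' @param n_pairs number of allele pairs.
#' @param n_conditions number of conditions (>= 2).
#' @param n_consistent planted always-biased pairs.
#' @param n_inconsistent planted pairs whose bias flips in one
#'   condition.
#' @param baseline_tpm baseline expression of the low allele (TPM).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise (0 = noiseless).
#' @param effect_fold fold bias of planted ASE pairs (default 16).
#' @param seed integer seed.
#' @return validated spec list of class `ase_sim_spec`.
#' @export
ase_sim_spec <- function(n_pairs = 500, n_conditions = 9,
                         n_consistent = 60, n_inconsistent = 60,
                         baseline_tpm = 20, noise_cv = 0,
                         effect_fold = 16, seed = 1L) {
  assert_count(n_pairs, "n_pairs", min = 1L)
  assert_count(n_conditions, "n_conditions", min = 2L)
  assert_count(n_consistent, "n_consistent", min = 0L)
  assert_count(n_inconsistent, "n_inconsistent", min = 0L)
  assert_that(n_consistent + n_inconsistent <= n_pairs,
              "planted pairs exceed n_pairs")
  assert_that(baseline_tpm > 0, "'baseline_tpm' must be > 0")
  assert_that(noise_cv >= 0, "'noise_cv' must be >= 0")
  assert_that(effect_fold > 1, "'effect_fold' must be > 1")
  # generation-time guarantee: the planted log2 margin must dominate the
  # noise on the two alleles (6 sigma on the log2 ratio)
  thr <- ase_thresholds()
  margin <- log2(effect_fold) - thr$lfc_min
  sigma <- sqrt(log(1 + noise_cv^2))
  if (noise_cv > 0 && margin < 6 * sqrt(2) * sigma / log(2))
    stop("noise_cv = ", noise_cv,
         " too large to guarantee planted effects at effect_fold = ",
         effect_fold)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_conditions = as.integer(n_conditions),
                 n_consistent = as.integer(n_consistent),
                 n_inconsistent = as.integer(n_inconsistent),
                 baseline_tpm = baseline_tpm, noise_cv = noise_cv,
                 effect_fold = effect_fold, seed = as.integer(seed)),
            class = "ase_sim_spec")
}

#' Simulate paired-allele TPM matrices with planted ASE ground truth
#'
#' Consistent pairs are biased toward one haplotype (alternating hap1 /
#' hap2) by `effect_fold` in every condition; inconsistent pairs flip
#' the bias direction in one randomly chosen condition; the remaining
#' (null) pairs express both alleles at the baseline.  Noise is
#' multiplicative log-normal with mean 1 and the spec's CV, applied
#' per gene x condition.  Three nominal replicates per condition share
#' the condition mean (replicate averaging is the caller's job and is
#' exercised with distinct replicate noise when `noise_cv > 0`).
#'
#' @param spec an [ase_sim_spec()].
#' @return list with `pairs` (`hap1_gene`, `hap2_gene`, `chrom`),
#'   `tpm` (matrix genes x samples), `conditions` (named map sample ->
#'   condition) and `truth` (`data.frame`: pair ids and planted
#'   `category` in [ASE_CATEGORIES]).
#' @export
simulate_ase_matrix <- function(spec) {
  stopifnot(inherits(spec, "ase_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_pairs
  n_cond <- spec$n_conditions
  hap1 <- sprintf("hap1_g%d", seq_len(n))
  hap2 <- sprintf("hap2_g%d", seq_len(n))
  chrom <- sprintf("Chr%02d", 1L + (seq_len(n) - 1L) %% 29L)
  category <- rep("not_ase", n)
  if (spec$n_consistent)
    category[seq_len(spec$n_consistent)] <-
      rep(c("consistent_hap1", "consistent_hap2"),
          length.out = spec$n_consistent)
  if (spec$n_inconsistent)
    category[spec$n_consistent + seq_len(spec$n_inconsistent)] <- "inconsistent"
  base <- spec$baseline_tpm
  fold <- spec$effect_fold
  # mean TPM per pair x condition for the two alleles
  mu1 <- matrix(base, n, n_cond)
  mu2 <- matrix(base, n, n_cond)
  hi1 <- category == "consistent_hap1"
  hi2 <- category == "consistent_hap2"
  mu1[hi1, ] <- base * fold
  mu2[hi2, ] <- base * fold
  inc <- which(category == "inconsistent")
  if (length(inc)) {
    flip_cond <- sample.int(n_cond, length(inc), replace = TRUE)
    mu1[inc, ] <- base * fold          # biased to hap1 ...
    for (j in seq_along(inc)) {        # ... except one flipped condition
      mu1[inc[j], flip_cond[j]] <- base
      mu2[inc[j], flip_cond[j]] <- base * fold
    }
  }
  n_rep <- 3L
  samples <- as.vector(t(outer(seq_len(n_cond), seq_len(n_rep),
                               function(c, r) sprintf("cond%d_rep%d", c, r))))
  conditions <- setNames(rep(sprintf("cond%d", seq_len(n_cond)),
                             each = n_rep), samples)
  sigma <- sqrt(log(1 + spec$noise_cv^2))
  noise <- function(len) if (spec$noise_cv == 0) rep(1, len) else
    rlnorm(len, meanlog = -sigma^2 / 2, sdlog = sigma)
  tpm <- matrix(0, nrow = 2L * n, ncol = length(samples),
                dimnames = list(c(hap1, hap2), samples))
  for (ci in seq_len(n_cond)) {
    cols <- which(conditions == sprintf("cond%d", ci))
    for (col in cols) {
      tpm[hap1, col] <- mu1[, ci] * noise(n)
      tpm[hap2, col] <- mu2[, ci] * noise(n)
    }
  }
  list(pairs = data.frame(hap1_gene = hap1, hap2_gene = hap2, chrom = chrom,
                          stringsAsFactors = FALSE),
       tpm = tpm, conditions = conditions,
       truth = data.frame(hap1_gene = hap1, hap2_gene = hap2,
                          category = category, stringsAsFactors = FALSE))
}
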