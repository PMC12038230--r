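# Independent brute-force oracles. Deliberately naive implementations
# that share no code with the package internals they check.

# enumerate every genome subset; pan = union of family presence,
# core = intersection; computed from member gene sets, not the counts
# matrix
oracle_saturation <- function(fm) {
  pres <- lapply(fm$genomes, function(g) {
    unique(fm$members$family[fm$members$genome == g])
  })
  names(pres) <- fm$genomes
  n <- length(fm$genomes)
  out <- list()
  for (m in seq_len(n)) {
    pans <- cores <- c()
    cmb <- utils::combn(n, m, simplify = FALSE)
    for (idx in cmb) {
      sets <- pres[idx]
      pans <- c(pans, length(Reduce(union, sets)))
      cores <- c(cores, length(Reduce(intersect, sets)))
    }
    out[[m]] <- list(pan_mean = mean(pans), core_mean = mean(cores))
  }
  out
}

# O(n*m) all-pairs interval overlap scan on 0-based half-open intervals
oracle_sv_plus <- function(svs, genes) {
  plus <- character(0)
  for (i in seq_len(nrow(genes))) {
    gs <- genes$start[i]; ge <- genes$end[i]
    for (j in seq_len(nrow(svs))) {
      if (genes$chrom[i] == svs$ref_chrom[j] &&
          gs < svs$ref_end[j] && ge > svs$ref_start[j]) {
        plus <- c(plus, genes$gene[i])
        break
      }
    }
  }
  sort(unique(plus))
}

# max-priority scan per gene over raw pair lists
oracle_dup_assignment <- function(pair_lists, all_genes) {
  priority <- c(WGD = 1, TD = 2, PD = 3, TRD = 4, DSD = 5)
  out <- setNames(rep("singleton", length(all_genes)), all_genes)
  best <- setNames(rep(6, length(all_genes)), all_genes)
  for (mode in names(pair_lists)) {
    for (r in seq_len(nrow(pair_lists[[mode]]))) {
      for (g in as.character(unlist(pair_lists[[mode]][r, ]))) {
        if (priority[[mode]] < best[[g]]) {
          best[[g]] <- priority[[mode]]
          out[[g]] <- mode
        }
      }
    }
  }
  out
}

# closed-form Welch statistic and two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df))
}

# naive canonical k-mer count from scratch (character arithmetic only)
oracle_spectrum <- function(reads, k) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  all_kmers <- c()
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in 1:(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- revcomp(km)
      all_kmers <- c(all_kmers, if (km <= rc) km else rc)
    }
  }
  table(table(all_kmers))
}

# shared tiny family matrix: 3 genomes, hand-written membership
tiny_fm <- function() {
  members <- data.frame(
    family = c("F1", "F1", "F1", "F2", "F2", "F3", "F3", "F4", "F4"),
    genome = c("A", "B", "C", "A", "B", "B", "C", "C", "A"),
    gene   = c("A_1", "B_1", "C_1", "A_2", "B_2", "B_3", "C_2", "C_3", "A_3"),
    stringsAsFactors = FALSE)
  family_matrix(members, genomes = c("A", "B", "C"))
}
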