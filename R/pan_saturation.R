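#' Pan/core saturation (rarefaction) curves
#'
#' For each subset size m = 1..n evaluates genome combinations and
#' records the pan size (families present in at least one selected
#' genome) and core size (families present in every selected genome).
#' All C(n, m) combinations are enumerated when that count does not
#' exceed `max_exhaustive`; otherwise `n_samples` distinct combinations
#' are drawn uniformly with a seeded generator.
#'
#' @param fm a [family_matrix].
#' @param max_exhaustive enumerate exhaustively when `C(n, m)` is at
#'   most this (default 10000).
#' @param n_samples combinations drawn per m in sampled mode
#'   (default 100).
#' @param seed integer seed for sampled mode.
#' @param probs quantiles reported per m (default 2.5/50/97.5%, the
#'   standard envelope for saturation plots).
#' @return object of class `saturation_curve`: a `data.frame` with one
#'   row per m (`pan_mean`, `core_mean`, quantile columns,
#'   `n_combinations`, `mode`) plus attribute `seed`.
#' @export
saturation_curves <- function(fm, max_exhaustive = 10000, n_samples = 100,
                              seed = 1L, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(fm, "family_matrix"))
  n <- length(fm$genomes)
  assert_count(n, "n genomes", min = 2L)
  assert_count(n_samples, "n_samples", min = 1L)
  pres <- fm$counts > 0L
  set.seed(seed)
  rows <- vector("list", n)
  for (m in seq_len(n)) {
    n_comb <- choose(n, m)
    if (n_comb <= max_exhaustive) {
      combos <- combn(n, m)
      mode <- "exhaustive"
    } else {
      combos <- sample_combinations(n, m, n_samples)
      mode <- "sampled"
    }
    pan <- core <- integer(ncol(combos))
    for (j in seq_len(ncol(combos))) {
      occ <- rowSums(pres[, combos[, j], drop = FALSE])
      pan[j] <- sum(occ > 0L)
      core[j] <- sum(occ == m)
    }
    q_pan <- quantile(pan, probs, names = FALSE, type = 1)
    q_core <- quantile(core, probs, names = FALSE, type = 1)
    row <- data.frame(m = m, pan_mean = mean(pan), core_mean = mean(core),
                      n_combinations = ncol(combos), mode = mode,
                      stringsAsFactors = FALSE)
    for (i in seq_along(probs)) {
      row[[sprintf("pan_q%g", 100 * probs[i])]] <- q_pan[i]
      row[[sprintf("core_q%g", 100 * probs[i])]] <- q_core[i]
    }
    rows[[m]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Draw distinct m-subsets of 1..n uniformly
#'
#' Sampling without replacement *of combinations*: duplicates are
#' rejected until `n_samples` distinct subsets are collected (or all
#' subsets are exhausted).
#' @noRd
sample_combinations <- function(n, m, n_samples) {
  max_distinct <- choose(n, m)
  target <- min(n_samples, max_distinct)
  seen <- character(0)
  out <- matrix(0L, nrow = m, ncol = target)
  got <- 0L
  while (got < target) {
    cand <- sort(sample.int(n, m))
    key <- paste(cand, collapse = ",")
    if (!(key %in% seen)) {
      got <- got + 1L
      seen <- c(seen, key)
      out[, got] <- cand
    }
  }
  out
}
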