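#' Build a canonical k-mer multiplicity spectrum from reads
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) across all reads and returns the multiplicity
#' histogram.  Ambiguous bases (`N`) break the k-mer window: no k-mer
#' spans an `N`.  Reads shorter than `k` are skipped (or an error with
#' `short_reads = "error"`).
#'
#' @param reads character vector of sequences, a `Biostrings`
#'   `DNAStringSet`, or a path to a FASTA/FASTQ file (gzip allowed).
#' @param k k-mer length (>= 1).
#' @param short_reads `"skip"` (default) or `"error"`.
#' @return object of class `kmer_spectrum`: list with `k`, `counts`
#'   (named integer vector: multiplicity -> number of distinct
#'   canonical k-mers) and `total_kmer_instances`.
#' @export
build_spectrum <- function(reads, k, short_reads = c("skip", "error")) {
  short_reads <- match.arg(short_reads)
  assert_count(k, "k", min = 1L)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  } else if (methods::is(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  reads <- toupper(reads)
  # N breaks the window: split reads into N-free fragments
  frags <- unlist(strsplit(reads, "[^ACGT]+"), use.names = FALSE)
  frags <- frags[nchar(frags) >= k]
  if (!length(frags)) {
    if (short_reads == "error")
      stop("k = ", k, " exceeds every read length")
    if (all(nchar(reads) < k))
      stop("k = ", k, " exceeds every read length")
    return(structure(list(k = as.integer(k), counts = integer(0),
                          total_kmer_instances = 0),
                     class = "kmer_spectrum"))
  }
  if (short_reads == "error" && any(nchar(reads) < k))
    stop("read(s) shorter than k = ", k)
  kmers <- extract_kmers(frags, k)
  canon <- canonical_kmers(kmers)
  mult <- table(canon)
  hist <- table(as.integer(mult))
  counts <- setNames(as.integer(hist), names(hist))
  structure(list(k = as.integer(k), counts = counts,
                 total_kmer_instances = length(kmers)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k = %d, %d distinct canonical k-mers, %g instances\n",
              x$k, sum(x$counts), x$total_kmer_instances))
  invisible(x)
}

extract_kmers <- function(seqs, k) {
  len <- nchar(seqs)
  n_win <- pmax(len - k + 1L, 0L)
  max_win <- max(n_win)
  out <- vector("list", max_win)
  for (i in seq_len(max_win)) {
    sel <- n_win >= i
    out[[i]] <- substring(seqs[sel], i, i + k - 1L)
  }
  unlist(out, use.names = FALSE)
}

canonical_kmers <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' First-local-minimum error cutoff of a k-mer histogram
#'
#' Sequencing-error k-mers form a low-multiplicity spike; the cutoff is
#' the first multiplicity m (on the zero-filled histogram) where the
#' count stops decreasing, i.e. `count(m) <= count(m + 1)`.  A
#' monotonically decreasing histogram has no such point and is an
#' error (set the cutoff manually).
#' @noRd
first_local_minimum <- function(counts) {
  mult <- as.integer(names(counts))
  dense <- integer(max(mult))
  dense[mult] <- counts
  for (m in seq_len(length(dense) - 1L))
    if (dense[m] <= dense[m + 1L]) return(m)
  stop("k-mer histogram is monotonically decreasing: no local minimum; ",
       "supply 'error_cutoff' manually")
}

#' Estimate genome size from a k-mer spectrum
#'
#' Implements the survey formula `G = N * (L - k + 1) / F`, where N is
#' the total read count, L the read length, k the k-mer length and F
#' the peak k-mer multiplicity.  F is the multiplicity of the global
#' maximum of the histogram restricted to multiplicities strictly
#' above `error_cutoff`; the default cutoff is the first local minimum
#' of the histogram (standard error-spike exclusion).
#'
#' @param spectrum a [build_spectrum()] result (non-empty).
#' @param N total number of reads.
#' @param L read length in bp (>= k).
#' @param error_cutoff `"auto"` (first local minimum) or an integer
#'   multiplicity below/at which counts are ignored.
#' @return object of class `size_estimate`: list with `G`, `N`, `L`,
#'   `k`, `F`, `error_cutoff`.
#' @export
estimate_genome_size <- function(spectrum, N, L, error_cutoff = "auto") {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  assert_that(length(spectrum$counts) > 0, "empty k-mer spectrum")
  assert_count(N, "N", min = 1L)
  assert_that(L >= spectrum$k, "'L' must be >= k")
  cutoff <- if (identical(error_cutoff, "auto"))
    first_local_minimum(spectrum$counts)
  else {
    assert_that(is.numeric(error_cutoff) && error_cutoff >= 0,
                "'error_cutoff' must be 'auto' or a non-negative number")
    as.integer(error_cutoff)
  }
  mult <- as.integer(names(spectrum$counts))
  eligible <- mult > cutoff
  assert_that(any(eligible), "no multiplicity above the error cutoff")
  Fpeak <- mult[eligible][which.max(spectrum$counts[eligible])]
  G <- N * (L - spectrum$k + 1) / Fpeak
  structure(list(G = G, N = N, L = L, k = spectrum$k, F = Fpeak,
                 error_cutoff = cutoff),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf(
    "genome size estimate: G = %.0f bp  (N = %g reads, L = %d bp, k = %d, peak F = %d, error cutoff %d)\n",
    x$G, x$N, x$L, x$k, x$F, x$error_cutoff))
  invisible(x)
}

#' LTR retrotransposon insertion time
#'
#' Dates an LTR insertion from the divergence K between its two long
#' terminal repeats: `T = K / (2 r)` years, with the per-site per-year
#' substitution rate r defaulting to the kiwifruit value 3.39e-9.
#' Vectorized over `K_div`.
#'
#' @param K_div nucleotide divergence(s), substitutions/site (>= 0).
#' @param r substitution rate, substitutions/site/year (> 0).
#' @return `data.frame` with columns `K_div`, `r`, `T_years`.
#' @export
ltr_insertion_time <- function(K_div, r = 3.39e-9) {
  assert_that(length(r) == 1 && is.finite(r) && r > 0, "'r' must be > 0")
  assert_that(all(is.finite(K_div)) && all(K_div >= 0),
              "'K_div' must be finite and >= 0")
  data.frame(K_div = K_div, r = r, T_years = K_div / (2 * r))
}
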