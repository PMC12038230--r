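#' Specification for a synthetic read set
#'
#' Single-end fixed-length reads sampled uniformly from a random
#' reference; coverage and length are chosen so that the k-mer survey
#' downstream is well determined.
#'
#' @param genome_length reference length in bp.
#' @param read_length read length in bp.
#' @param coverage mean fold coverage (> 0).
#' @param error_rate per-base substitution error rate in \[0, 1).
#' @param seed integer seed.
#' @return validated spec list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(genome_length = 1e5, read_length = 100,
                          coverage = 20, error_rate = 0, seed = 1L) {
  assert_count(genome_length, "genome_length", min = 100L)
  assert_count(read_length, "read_length", min = 10L)
  assert_that(read_length <= genome_length,
              "'read_length' must be <= genome_length")
  assert_that(coverage > 0, "'coverage' must be > 0")
  assert_that(error_rate >= 0 && error_rate < 1,
              "'error_rate' must be in [0, 1)")
  structure(list(genome_length = as.integer(genome_length),
                 read_length = as.integer(read_length),
                 coverage = coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Simulate a random reference and uniformly sampled reads
#'
#' The reference is i.i.d. uniform over ACGT.  The number of reads is
#' `round(coverage * genome_length / read_length)`; start positions
#' are uniform; half the reads are reverse-complemented (reads are
#' unstranded).  Substitution errors change each base independently
#' with probability `error_rate` to one of the three other bases.
#'
#' @param spec a [read_sim_spec()].
#' @return list with `reference` (single character string) and `reads`
#'   (character vector).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  ref_vec <- sample(bases, spec$genome_length, replace = TRUE)
  reference <- paste(ref_vec, collapse = "")
  n_reads <- round(spec$coverage * spec$genome_length / spec$read_length)
  starts <- sample.int(spec$genome_length - spec$read_length + 1L,
                       n_reads, replace = TRUE)
  reads <- substring(reference, starts, starts + spec$read_length - 1L)
  rev <- as.logical(rbinom(n_reads, 1L, 0.5))
  if (any(rev))
    reads[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[rev])))
  if (spec$error_rate > 0) {
    char_mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                       nrow = spec$read_length)
    hit <- which(matrix(runif(length(char_mat)) < spec$error_rate,
                        nrow = spec$read_length))
    if (length(hit)) {
      cur <- char_mat[hit]
      sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "")
      char_mat[hit] <- sub
      reads <- apply(char_mat, 2L, paste, collapse = "")
    }
  }
  list(reference = reference, reads = reads)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write reads as FASTQ (constant quality)
#' @param reads character vector of reads.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%d", seq_along(x))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), ""))
  qx <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeQualityScaledXStringSet(qx, path)
  invisible(path)
}
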