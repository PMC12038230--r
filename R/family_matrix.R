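#' Gene-family occupancy matrix
#'
#' A `family_matrix` holds, for every gene family (orthogroup) and every
#' genome, the list of member gene identifiers.  It is the central object
#' of the pan-genome stage: occupancy (number of genomes with at least
#' one member) drives the core/softcore/dispensable/private
#' classification.
#'
#' @param members a `data.frame` with columns `family`, `genome`, `gene`
#'   (one row per member gene); every gene id must occur exactly once.
#' @param families character vector of family ids (order preserved);
#'   defaults to those present in `members`.
#' @param genomes character vector of genome ids; defaults to those
#'   present in `members`.
#'
#' @return An object of class `family_matrix` with components:
#'   \describe{
#'     \item{families, genomes}{id vectors}
#'     \item{counts}{integer matrix (family x genome) of member counts}
#'     \item{members}{the tidy member table}
#'   }
#' @export
family_matrix <- function(members, families = NULL, genomes = NULL) {
  stopifnot(is.data.frame(members),
            all(c("family", "genome", "gene") %in% names(members)))
  members <- as.data.frame(members)[, c("family", "genome", "gene")]
  members[] <- lapply(members, as.character)
  dup <- duplicated(members$gene)
  if (any(dup))
    stop("gene id(s) appear in more than one family cell: ",
         paste(unique(members$gene[dup])[1:min(3, sum(dup))], collapse = ", "))
  families <- families %||% unique(members$family)
  genomes  <- genomes  %||% sort(unique(members$genome))
  assert_that(all(members$family %in% families), "member family not in 'families'")
  assert_that(all(members$genome %in% genomes), "member genome not in 'genomes'")
  counts <- table(factor(members$family, levels = families),
                  factor(members$genome, levels = genomes))
  counts <- matrix(as.integer(counts), nrow = length(families),
                   ncol = length(genomes),
                   dimnames = list(families, genomes))
  structure(list(families = families, genomes = genomes,
                 counts = counts, members = members),
            class = "family_matrix")
}

#' @export
print.family_matrix <- function(x, ...) {
  cat(sprintf("family_matrix: %d families x %d genomes, %d genes\n",
              length(x$families), length(x$genomes), nrow(x$members)))
  invisible(x)
}

#' Occupancy of each family
#'
#' Number of genomes in which each family has at least one member gene.
#'
#' @param fm a [family_matrix].
#' @return named integer vector over families.
#' @export
occupancy <- function(fm) {
  stopifnot(inherits(fm, "family_matrix"))
  rowSums(fm$counts > 0L)
}

#' Read an orthogroup table into a family matrix
#'
#' Parses the tab-separated orthogroups dialect: column 1 is the family
#' id, one column per genome, cells are comma(-space) separated gene id
#' lists (empty cell = absent).
#'
#' @param path path to the orthogroups TSV.
#' @param genome_ids genomes to keep (default: all columns after the
#'   first).  An id absent from the header is an error.
#' @param unclustered optional `data.frame(gene, genome)` of genes that
#'   the clustering left unassigned.
#' @param add_unclustered if `TRUE` (default) and `unclustered` is
#'   given, each unassigned gene is appended as its own one-gene family
#'   (family ids `UNCL0000001`, ...), so it is counted as private /
#'   singleton downstream.
#' @return a [family_matrix].
#' @export
read_family_matrix <- function(path, genome_ids = NULL, unclustered = NULL,
                               add_unclustered = TRUE) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               data.table = FALSE)
  header_genomes <- names(tab)[-1]
  genome_ids <- genome_ids %||% header_genomes
  missing <- setdiff(genome_ids, header_genomes)
  if (length(missing))
    stop("genome column(s) not in orthogroup header: ",
         paste(missing, collapse = ", "))
  fam_ids <- tab[[1]]
  rows <- vector("list", length(genome_ids))
  for (j in seq_along(genome_ids)) {
    cells <- tab[[genome_ids[j]]]
    genes <- strsplit(cells, ",[ ]?")
    n <- lengths(genes)
    keep <- n > 0L
    rows[[j]] <- data.frame(
      family = rep(fam_ids[keep], n[keep]),
      genome = rep(genome_ids[j], sum(n[keep])),
      gene = trimws(unlist(genes[keep], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, rows)
  members <- members[members$gene != "", , drop = FALSE]
  if (!is.null(unclustered) && add_unclustered && nrow(unclustered)) {
    extra <- data.frame(
      family = sprintf("UNCL%07d", seq_len(nrow(unclustered))),
      genome = as.character(unclustered$genome),
      gene = as.character(unclustered$gene),
      stringsAsFactors = FALSE)
    members <- rbind(members, extra)
    fam_ids <- c(fam_ids, extra$family)
  }
  fam_ids <- fam_ids[fam_ids %in% members$family]
  family_matrix(members, families = fam_ids, genomes = genome_ids)
}

#' Write a family matrix in the orthogroups TSV dialect
#'
#' @param fm a [family_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "family_matrix"))
  sp <- split(fm$members, fm$members$family)
  cells <- matrix("", nrow = length(fm$families), ncol = length(fm$genomes),
                  dimnames = list(fm$families, fm$genomes))
  for (f in names(sp)) {
    bg <- split(sp[[f]]$gene, sp[[f]]$genome)
    for (g in names(bg)) cells[f, g] <- paste(bg[[g]], collapse = ", ")
  }
  out <- data.frame(Orthogroup = fm$families, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
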