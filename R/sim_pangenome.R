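#' Specification for a synthetic pan-genome family matrix
#'
#' Defaults mirror the 14-haplotype genus panel the package targets:
#' category fractions 44% core / 8% softcore / 47% dispensable /
#' 1% private.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_families number of gene families (>= 1).
#' @param category_fractions named fractions over
#'   core/softcore/dispensable/private, summing to 1.
#' @param genes_per_family_mean mean member genes per present genome
#'   (>= 1; counts are 1 + Poisson(mean - 1)).
#' @param seed integer seed.
#' @return validated spec list of class `pangenome_sim_spec`.
#' @export
pangenome_sim_spec <- function(n_genomes = 14, n_families = 1000,
                               category_fractions = c(core = 0.44,
                                                      softcore = 0.08,
                                                      dispensable = 0.47,
                                                      private = 0.01),
                               genes_per_family_mean = 2, seed = 1L) {
  assert_count(n_genomes, "n_genomes", min = 2L)
  assert_count(n_families, "n_families", min = 1L)
  assert_that(setequal(names(category_fractions), PAN_CATEGORIES),
              "category_fractions must name exactly core/softcore/dispensable/private")
  category_fractions <- category_fractions[PAN_CATEGORIES]
  assert_that(abs(sum(category_fractions) - 1) <= 1e-9,
              "category fractions must sum to 1")
  assert_that(all(category_fractions >= 0), "fractions must be >= 0")
  assert_that(genes_per_family_mean >= 1, "'genes_per_family_mean' must be >= 1")
  structure(list(n_genomes = as.integer(n_genomes),
                 n_families = as.integer(n_families),
                 category_fractions = category_fractions,
                 genes_per_family_mean = genes_per_family_mean,
                 seed = as.integer(seed)),
            class = "pangenome_sim_spec")
}

# largest-remainder apportionment of n among fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a gene-family occupancy matrix with planted categories
#'
#' Families are allocated to the four pan categories by the spec's
#' fractions (largest-remainder rounding), each family's occupancy is
#' drawn uniformly inside its category's occupancy band for
#' `n_genomes`, present genomes are sampled uniformly and receive
#' `1 + Poisson(mean - 1)` member genes with ids `<genome>_g<index>`.
#' When a band is empty for small panels (e.g. softcore at n = 4) the
#' affected families are reassigned to the nearest feasible category
#' with a warning and flagged in the truth table.
#'
#' @param spec a [pangenome_sim_spec()].
#' @return list with `matrix` (a [family_matrix]) and `truth`
#'   (`data.frame`: `family`, `category`, `occupancy`, `reassigned`).
#' @export
simulate_family_matrix <- function(spec) {
  stopifnot(inherits(spec, "pangenome_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  th <- pan_thresholds(n)
  bands <- th$bands
  feasible <- vapply(bands, function(b) b[1] <= b[2], logical(1))
  alloc <- apportion(spec$n_families, spec$category_fractions)
  names(alloc) <- PAN_CATEGORIES
  planted <- rep(PAN_CATEGORIES, alloc)
  reassigned <- rep(FALSE, length(planted))
  fallback <- list(softcore = c("dispensable", "core"),
                   dispensable = c("core"),
                   private = character(0), core = character(0))
  for (cat_ in PAN_CATEGORIES) {
    if (feasible[[cat_]]) next
    hit <- planted == cat_
    if (!any(hit)) next
    alt <- c(fallback[[cat_]][feasible[fallback[[cat_]]]], "core")[1]
    warning(sprintf("category '%s' infeasible for n_genomes = %d; %d families reassigned to '%s'",
                    cat_, n, sum(hit), alt))
    planted[hit] <- alt
    reassigned[hit] <- TRUE
  }
  occ <- vapply(planted, function(cat_) {
    b <- bands[[cat_]]
    if (b[1] == b[2]) b[1] else sample(seq(b[1], b[2]), 1L)
  }, integer(1))
  genomes <- sprintf("G%02d", seq_len(n))
  fam_ids <- sprintf("FAM%06d", seq_along(planted))
  gene_counter <- integer(n)
  names(gene_counter) <- genomes
  mem <- vector("list", length(planted))
  for (i in seq_along(planted)) {
    present <- sample(genomes, occ[i])
    k <- 1L + rpois(occ[i], spec$genes_per_family_mean - 1)
    genome_rep <- rep(present, k)
    idx <- unlist(lapply(present, function(g) {
      start <- gene_counter[[g]]
      gene_counter[[g]] <<- start + k[match(g, present)]
      seq_len(k[match(g, present)]) + start
    }), use.names = FALSE)
    mem[[i]] <- data.frame(family = fam_ids[i], genome = genome_rep,
                           gene = sprintf("%s_g%d", genome_rep, idx),
                           stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, mem)
  fm <- family_matrix(members, families = fam_ids, genomes = genomes)
  truth <- data.frame(family = fam_ids, category = planted,
                      occupancy = unname(occ), reassigned = reassigned,
                      stringsAsFactors = FALSE)
  list(matrix = fm, truth = truth)
}
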