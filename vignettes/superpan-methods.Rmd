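---
title: "Methods and design notes for superpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for superpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superpan)
```

`superpan` implements the downstream layer of a genus-level,
haplotype-resolved pan-genome study: everything that happens after
assemblies, annotations, orthology clustering, whole-genome alignment and
expression quantification have produced their standard tables. This
vignette records the models, parameter choices and numerical conventions,
and what the synthetic-data tests do and do not establish.

## Pan-gene-family model

The unit of classification is the **gene family** (orthogroup); the
statistic is **occupancy**, the number of genomes with at least one member.
For an *n*-genome panel the bands are: core (occupancy *n*), softcore
(⌈0.8·*n*⌉ … *n* − 1), dispensable (2 … ⌈0.8·*n*⌉ − 1), private (1).
At *n* = 14 the softcore band is occupancy 12–13, the conventional
"present in over 80% but not all" definition; the 0.8 fraction is exposed
as `softcore_frac`. For small panels the softcore band can be empty (e.g.
*n* = 4, where ⌈0.8·4⌉ = 4 collides with core); the classifier then simply
never emits softcore, which is the only consistent generalization of the
band arithmetic.

Family categories and gene-level summaries are kept distinct on purpose:
categories are defined on families, but per-genome composition weights by
member-gene counts, because both views are standard reporting units.
Unclustered genes can optionally (default on, when a list is supplied) be
appended as one-gene private families so that "singleton genes" covers
both members of occupancy-1 families and genes the clustering skipped —
published singleton counts plausibly include the latter, and the flag
makes either convention available.

**Saturation curves.** For each subset size *m* the pan size is the union
and the core size the intersection of family presence over the selected
genomes. All C(*n*, *m*) combinations are enumerated while that count is
below `max_exhaustive` (default 10 000); beyond that, `n_samples` distinct
combinations are drawn by seeded rejection sampling (duplicate subsets
rejected), which keeps runs reproducible. Quantiles are reported at
2.5/50/97.5%, the usual plotting envelope. Exhaustive mode is checked in
the test suite against a brute-force enumeration that computes unions and
intersections from raw member gene sets.

## Structural variants

The parser consumes the SyRI output dialect: ≥ 11 tab-separated columns,
1-based inclusive coordinates, `-` for missing fields. Internally all
coordinates are 0-based half-open (BED is emitted as-is; GFF3 converts
back to 1-based inclusive). Design choices the upstream literature leaves
open:

- **Code mapping.** The six reported categories map from dialect codes as
  INS←INS, DEL←DEL, INV←INV, TRANS←{TRANS, INVTR}, DUP←{DUP, INVDP},
  CNV←{CPG, CPL}. Alignment-level (`*AL`) and syntenic records never
  become SVs. The map is a plain named vector argument, so other
  conventions are a one-liner.
- **Length.** SV length is max(reference span, query span): an insertion
  has a 1 bp reference anchor, so its length must come from the query
  side; for symmetric records the two agree.
- **"Larger than 50 bp" is strict.** A 50 bp deletion is excluded, a
  51 bp one included. Length-histogram bins are therefore
  left-open/right-closed, `(50, 100], (100, 500], …`, with an explicit
  underflow bucket rather than silent dropping.
- **Gene screening.** SV+ means ≥ 1 bp overlap between the gene interval
  and any SV reference interval — coverage-style screening with any
  nonzero coverage, since no minimum fraction is stated anywhere.
  Half-open adjacency (gene ends where an SV starts) is SV−. The
  upstream window is strand-aware: 2 kb 5' of the transcription start.
  Both gene-body and upstream modes exist because published "SV gene"
  definitions are ambiguous on flanks.
- **Highly diverged regions.** No published parameterization exists, so
  HDR is an explicit artifact definition: tile the reference into
  `window` bp windows (default 100 kb), call a window diverged when the
  fraction not covered by syntenic alignment is ≥ `min_diverged_fraction`
  (default 0.5), merge across gaps ≤ `merge_gap` (default 0). Reported
  HDR totals are therefore comparable only under identical parameters;
  the monotone dependence on the threshold is property-tested.
- **Group comparisons** use Welch's unequal-variance two-sided *t*-test —
  the safe default when only "t-tests" is specified. Two identical
  constant groups are reported as a degenerate comparison with t = 0,
  p = 1 rather than an error; constant groups with different means are an
  error.

## Allele-specific expression

Alleles are paired one-to-one from collinearity anchors; a gene in several
anchor rows stays in its best-scoring row (ties: first occurrence), and
the pairing rate is paired genes over total annotated genes. Calling uses
pure thresholds, not a statistical test, mirroring the threshold-only
practice for haplotype-resolved references:

- significant in a condition ⇔ TPM rule passes **and** |log₂FC| ≥ 2,
  replicates averaged per condition first;
- the TPM rule defaults to max(TPM₁, TPM₂) ≥ 2: requiring *both* alleles
  to pass would make fully silenced alleles — the clearest ASE cases —
  uncallable. `tpm_rule = "both"` restores the stricter reading.
- zeros get no pseudocount: a pseudocount would shift exact-threshold
  ratios such as 8 vs 2 (log₂FC exactly 2). A one-zero pair is significant
  when the expressed allele passes `tpm_min`; a zero-zero pair never is.
- positive log₂FC means hap1-biased.

Consistency over conditions is strict by default: *consistent* requires
significance with the same direction in **every** condition; a pair
significant in some conditions only is *inconsistent* even if the
direction never flips (`partial = "direction"` relaxes this).
With fewer than two conditions consistency is undefined and an error.

## Duplicate-gene modes

Mode discovery (homology + synteny) is out of scope; the package consumes
per-mode pair lists and applies the unique-assignment priority
WGD > TD > PD > TRD > DSD, with genes in no pair labelled singletons.
The proximal test is same chromosome and rank distance strictly below 10
gene intervals (a flag allows ≤ 10, since "fewer than 10" is ambiguous in
the field), excluding rank distance 1, which is tandem by the standard
convention.

## Genome survey

K-mers are canonical (lexicographic minimum of the k-mer and its reverse
complement) because reads are unstranded; ambiguous bases break the
window so no k-mer spans an `N`. The size formula is
G = N·(L − k + 1)/F. The only free choice is the peak multiplicity F:
sequencing errors put a spike at low multiplicity, so F is the global
maximum of the histogram restricted to multiplicities strictly above the
**first local minimum** (the first m with count(m) ≤ count(m + 1) on the
zero-filled histogram) — standard survey practice, deterministic, and
overridable with a numeric `error_cutoff`. A monotonically decreasing
histogram (no genomic peak) is an error instructing a manual cutoff.
LTR insertion dating is the forced arithmetic T = K/(2r); the default
rate r = 3.39 × 10⁻⁹ substitutions/site/year is the published kiwifruit
value and is an explicit argument for other taxa.

## Synthetic data: the stated world

The generators are first-class, tested code; their defaults encode the
panel the package targets rather than tunable knobs:

- **Pan-genome**: 14 genomes, category fractions 44/8/47/1%
  (core/softcore/dispensable/private), occupancies drawn uniformly inside
  each category's band, member counts 1 + Poisson(mean − 1), gene ids
  `<genome>_g<index>`. Fractions are allocated by largest remainder, so
  the classifier recovers them *exactly*; infeasible bands on small
  panels are reassigned with a warning and flagged in the truth table.
- **SVs**: six types, non-overlapping reference footprints placed by
  rejection sampling (keeps the overlap oracle unambiguous), lengths
  uniform in per-type ranges (default 60–5000 bp, inside the dominant
  published bins), genes planted inside, outside and exactly bordering
  SVs to pin the half-open adjacency semantics.
- **ASE**: nine conditions and three replicates by default (the fruit
  developmental design shape); planted consistent pairs carry a 16-fold
  bias — twice the calling threshold in log₂ units — on a baseline of
  20 TPM; inconsistent pairs flip direction in one random condition;
  noise is multiplicative log-normal with mean 1 and the stated CV
  (strictly positive and easy to bound). The spec constructor refuses a
  CV so large that six sigma of log₂-ratio noise could erase the planted
  margin, which keeps "planted" meaning "guaranteed at generation time".
- **Reads**: single-end fixed-length (the size formula uses a single L),
  uniform starts, random strand, i.i.d. substitution errors. Default
  100 kb genome at 20× with 100 bp reads: small enough for minute-scale
  tests, deep enough that the spectrum peak is sharp.

A green synthetic test establishes that the implementations agree with
their definitions and with independent brute-force oracles — not that the
biological conclusions of any particular study reproduce: real data add
fragmented assemblies, collapsed repeats, mapping bias and annotation
error that the generators deliberately do not model, and real headline
counts depend on the deposited sequencing data.

## Known limitations

- No GenomeScope-style mixture model: only the printed size formula, so
  heterozygosity and repeat structure are not estimated.
- HDR detection is window-based and parameter-dependent by design.
- ASE has no read-level statistical test (binomial/beta-binomial);
  thresholds only.
- The orthogroup reader loads the full table into memory; panels of tens
  of genomes and ~10⁵ families are fine, but it is not an out-of-core
  tool.
- The k-mer counter is exact and in-memory; it targets survey-sized test
  genomes, not production read sets (use a dedicated counter there and
  feed the histogram in as a `kmer_spectrum`).
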