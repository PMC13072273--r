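---
title: "Designing population-diagnostic SNP panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing population-diagnostic SNP panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptrace)
```

## The problem

Forensic traceability of trafficked wildlife asks for the *source
population* of a sample, not just its species. Mitochondrial
haplotypes — the traditional forensic marker — resolve deep
phylogeographic splits but fail at the population level because
closely related populations share haplotypes. `snptrace` implements
the nuclear alternative: scan a genome-wide SNP table for sites that
are fixed (or nearly fixed) for one allele in a focal population and
for the opposite allele everywhere else, then wrap each such site in
a PCR-ready amplicon with constraint-valid primers, so that
assignment needs only a handful of Sanger reactions.

This vignette explains the models and procedures, the tunable
parameters, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was open.

## Variant filtering

The pipeline accepts any multi-sample VCF with GT fields. Two
filter layers mirror common GATK/vcftools practice:

* **Hard filters** on INFO annotations, removing a site iff any of
  QD < 2.0, MQ < 40.0, FS > 60.0, HaplotypeScore > 13.0,
  MQRankSum < −12.5, ReadPosRankSum < −8.0 holds. Inequalities are
  strict, exactly as written: a site at QD = 2.0 survives. A site
  lacking an annotation passes that sub-filter (GATK
  VariantFiltration semantics) — HaplotypeScore in particular is
  absent from modern HaplotypeCaller output and is treated as
  optional.
* **Frequency filters**: minor allele frequency ≥ 0.05 and call rate
  ≥ 0.9, both bounds inclusive (vcftools semantics; exactly 1 alt
  allele among 20 passes). Allele frequencies are computed over
  non-missing alleles only.

Both filters are per-site predicates, hence idempotent, commuting,
and monotone in their thresholds — properties the test suite checks
on random tables.

Multiallelic records are split into one biallelic record per
alternate allele by default (`"drop"` is available). When splitting,
genotype alleles other than the focal alternate are recoded as
missing: a `2/2` genotype carries no information about the REF/ALT1
contrast. Coordinates are 1-based closed at every file boundary
(VCF, GFF3, amplicon positions); the BED export is 0-based
half-open.

## Population structure

* **Kinship** is mean identity-by-state: per shared non-missing
  site, the number of alleles two diploid genotypes share by state,
  divided by 2 (so `1 − |d1 − d2|/2` on dosages). "Normalized"
  kinship min–max rescales the matrix so the smallest off-diagonal
  value maps to 0 and self-similarity to 1; this preserves the
  ordering heatmaps display while fixing the scale. The raw matrix
  is always reported alongside, and pairs with no shared genotyped
  site are flagged undefined rather than guessed.
* **PCA** uses 0/1/2 alternate-dosage coding, per-site mean
  imputation of missing calls (no sample dropping), column
  centering, and an eigendecomposition of the sample covariance.
  Patterson scaling (`1/sqrt(p(1−p))`) is available but off by
  default; on the package's synthetic data the planted structure is
  strong enough that scaling only changes eigenvalue ratios.
* **Patterson's D** uses per-population allele frequencies with
  outgroup polarization: the outgroup's major allele is declared
  ancestral, and sites where the outgroup's minor-allele frequency
  exceeds 0.1 (configurable) are skipped as unpolarizable. ABBA and
  BABA are the standard frequency products, D their normalized
  difference, and the Z score comes from a delete-one jackknife over
  contiguous blocks of 1000 sites (configurable). Population labels
  carried by a single sample cover the per-individual use case.
* **f4-ratio**: `alpha = f4(A,O;X,C) / f4(A,O;B,C)` estimates the
  fraction of X's ancestry drawn from the B side. The roles are
  positional arguments, documented on the function; the denominator
  is the shared drift of the (A,B) ancestral branch, so A must be a
  B-side reference population.

## Gene screening

Primer design prefers genes whose local gene tree matches the
species tree — such genes reflect the population history rather than
incomplete lineage sorting, and markers inside them are less likely
to mislead.

1. Genes whose longest transcript (exon sum over 1-based closed
   intervals) strictly exceeds 2000 bp are retained.
2. Per sample, a consensus of the longest transcript is built from
   the reference: homozygous alternates substituted, heterozygotes
   encoded as IUPAC ambiguity codes, indel alleles skipped with a
   warning, minus-strand transcripts reverse-complemented. All
   consensus sequences are coordinate-aligned by construction.
3. A neighbor-joining gene tree is built on pairwise p-distances.
   IUPAC-ambiguous positions are excluded from each pair's
   denominator, so heterozygosity never inflates distance. NJ was
   chosen over maximum likelihood deliberately: the screening signal
   is purely topological concordance, NJ is deterministic and fast
   at these sizes, and externally computed Newick gene trees can be
   supplied for exact parity with an ML workflow.
4. The Robinson–Foulds distance to the species tree (supplied as
   Newick, or computed by NJ on the concatenated screened
   transcripts) is the symmetric difference of non-trivial
   bipartitions after pruning both trees to their shared leaf set —
   the implementation enumerates bipartitions directly and is tested
   against an independent oracle. Trees are pruned to the shared
   ingroup leaf set; fewer than four shared leaves is an error, not
   a zero.
5. "Relatively small RF" is made explicit as a policy object:
   default lowest quartile (order-statistic quantile), or an
   absolute cutoff. Ties rank longer transcripts first, then gene
   id, so re-runs are reproducible.

The length–RF Pearson correlation (with t-distribution p-value) is
reported because longer transcripts empirically track the species
tree better; on the synthetic data the correlation is negative, as
expected from the planted design.

## Marker discovery and primer design

The homozygous allele frequency of allele *a* in population *P* is
the fraction of *P*'s genotyped members homozygous for *a*. The
denominator counts genotyped members only — the defensible reading
when missing data exist — with `denominator = "all"` available for
the stricter variant. A site is diagnostic for *P* at threshold *t*
iff `HAF_P(a) ≥ t` and every other population has
`HAF_Q(opposite) ≥ t` (opposite-homozygote intersection). The scan
is vectorized but specified by a brute-force enumerator over (site,
population, allele), and the suite asserts exact agreement on
hundreds of random instances. Presets follow taxon structure:
t = 1.0 for well-differentiated taxa, 0.9, or 0.8 where lineage
sorting is incomplete. One global *t* per run; per-population
thresholds were considered and rejected as an invitation to
overfit the panel.

Sites are annotated with the gene whose longest-transcript exon span
contains them and gated on the target-gene set; a no-annotation mode
passes all sites through for taxa without a usable GFF. Final marker
choice per population is a deterministic ranking — target-gene sites
first, then maximal worst-case opposite fixation
(`min_other_haf`), then smallest position — replacing any manual
pick with something reproducible.

Amplicons take 900 bp of flank on each side (2·900+1 = 1801 bp);
sites closer than one flank to a contig end are skipped loudly,
never truncated. Primer pairs are enumerated within the amplicon
(left primer strictly upstream of the site, right strictly
downstream, so every product spans the diagnostic base), filtered by
the size 20/22/26, Tm 52/56/62 °C, GC 30/50/70 % constraints, product
size 150–900 bp, pair ΔTm ≤ 5 °C, and ranked by weighted deviation
from the optima (weights 1 /nt, 1 /°C, 0.2 /GC-point — GC deviations
are cheap because Tm already prices composition). Melting
temperature uses SantaLucia (1998) unified nearest-neighbor
thermodynamics with initiation and terminal-AT terms, at 50 mM
monovalent salt and 0.25 µM total strand — the frozen reference
values in the test suite were computed once with an independent
implementation of the same model. Right primers are reported 5'→3'
on the minus strand, the universal reporting convention. Secondary
structure and dimer screening are out of scope by design; any
candidate pair should still be checked in a dedicated tool before
ordering oligos.

Assignment scores each candidate population by the fraction of its
typed markers at which the query is homozygous for the focal allele;
the call requires a strictly highest score ≥ 0.8 (configurable).
Heterozygous genotypes never match, so F1 hybrids fall to
"unassigned" rather than being forced into a parent population.

## The mitochondrial comparison

Aligned mitochondrial genomes are collapsed into haplotypes:
sequences identical at every comparable column (plain A/C/G/T in
both) merge. That relation is not transitive when sequences have
missing data, so merging is greedy in input order into the earliest
compatible haplotype, back-filling the representative's masked
columns from later members; the suite pins this behavior. The
network is a minimum spanning network over pairwise Hamming
distances (comparable columns only): edges enter by increasing
weight, and *every* edge of a weight class that joins components
distinct before the class is kept, so co-minimal alternatives are
all reported. Median vectors (inferred intermediate haplotypes) are
deliberately not inserted — the resolution argument only needs
shared versus private haplotypes, which the per-population report
(`n_private`, `n_shared`, `traceable`) summarizes.

## The synthetic-data generator

`sim_config()` defaults define the reference scenario used
throughout the tests: 3 populations × 8 samples, a 60 kb contig
carrying 4 long and 2 short genes, 2000 background SNPs, 10 planted
diagnostic sites per population at focal HAF 1.0, 2 % missingness,
and a 16.5 kb mitochondrial alignment with 2 haplotypes per
population — sizes chosen so a complete pipeline run takes well
under a minute on one core while leaving every screening step
non-trivial.

Background allele frequencies follow a two-level hierarchical
Balding–Nichols model: an ancestral frequency, two ingroup clades,
then populations (drift intensity `fst = 0.1` per split); the last
population is drawn basally from the ancestral frequency so that D
and f4 analyses have a genuine outgroup to polarize against,
mirroring the ingroup-clades-plus-outgroup sampling designs used in
practice. This model is *non-genealogical*: it produces realistic
frequency covariance (hence PCA clusters, kinship blocks and
calibrated D) but no linkage, recombination or coalescent gene
trees. Consequently the tests demonstrate correctness of the
computations and recovery of planted truth — not robustness to LD,
demographic complexity, or real annotation noise.

Two constructions make the planted truth exact rather than
probable. Planted sites are placed round-robin inside long-gene
exons at least one flank from contig ends, the focal population
homozygous-alternate (heterozygous for any remainder when the
configured focal HAF is below 1) and all others homozygous-
reference, with no missingness. Every background site is forced to
carry at least one called heterozygote: a single het anywhere breaks
both focal fixation and opposite fixation for every population, so
no background site can ever satisfy the t = 1.0 criterion. Planted
recovery is therefore a sharp precision = recall = 1 check, not a
statistical tendency. Mitochondrial sharing is planted by copying
one haplotype between adjacent populations' pools, and samples cycle
through their pool so every haplotype is carried.

All generator output is bit-reproducible from `(seed, cfg)`; the
three generator stages use fixed offsets of the one seed.

## Numerical choices and degenerate inputs

* Half-missing diploid calls (e.g. `./1`) are rejected at
  construction; missingness is all-or-nothing per genotype.
* A kinship pair with zero shared genotyped sites, a D trio with
  ABBA + BABA = 0, and an f4-ratio with zero denominator are all
  flagged undefined (`NA`) rather than silently zeroed.
* `quantile(type = 1)` (order statistic) defines the RF quartile so
  the target set is always a subset of observed RF values; with all
  RF equal, all genes are targets.
* NJ on an all-identical alignment returns a star-like topology
  flagged `degenerate`.
* Primer enumeration caps pairing at the top 40 candidates per side
  by single-primer penalty before combining — at 1801 bp amplicons
  exhaustive pairing is wasteful and the optimum always lies among
  low-penalty singles under an additive score.
* The assignment minimum score (0.8) intentionally equals the
  loosest HAF preset: a query should not be called with less
  agreement than the panel's own fixation guarantee.

## Known limitations

* Gene trees are NJ on p-distance; deep or saturated divergences
  would need ML and model selection (import hook provided).
* The D/f4 machinery is population-frequency based; it does not
  implement per-genotype weighting for very small samples.
* Primer design checks composition constraints, not hybridization
  kinetics, secondary structure, or cross-amplicon multiplexing.
* The generator's independence across sites means no LD pruning is
  implemented or needed here; real panels should prune linked
  candidates before final selection.
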