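---
title: "Defensome analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defensome analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defensomics)
```

# Scope and data model

`defensomics` quantifies the anti-MGE defense repertoire of annotated
(meta)genomes. It deliberately starts *after* the heavy annotation steps:
defense-gene detection (e.g. DefenseFinder), MGE detection (plasmid,
prophage, ICE/IME, integron callers), read mapping and variant calling,
and ortholog clustering are all consumed as files, not re-implemented.
What the package owns is the downstream statistical machinery: system
assembly under organization rules, island calling from gene order,
enrichment statistics, variant summaries and pairwise dN/dS.

All coordinates are 1-based inclusive internally (the GFF convention);
BED input is converted at the boundary, and writing BED converts back, so
round trips are exact. Within each contig, genes carry a 0-based
*ordinal* — their rank by ascending start — and every distance rule in
the package is expressed in **intervening genes**: the number of genes
strictly between two features on the same contig. The source material is
ambiguous between ordinal difference and intervening count; we chose
intervening genes once and use it everywhere (system gaps, island gaps,
pair gaps), with the thresholds configurable. Overlapping genes (nested
ORFs) have no canonical order; ties on start are broken by ascending end,
then lexicographic gene id, which makes output deterministic but is a
package choice, not a community standard.

# Quality gating

`mimag_filter()` applies the MIMAG high-quality thresholds — completeness
≥ 90%, contamination ≤ 5%, ≥ 18 tRNA genes, presence of all of the 5S,
16S and 23S rRNA classes — plus an assembly-contiguity gate of
N50 ≥ 100 kb, appropriate because defense systems are multigenic and
islands span dozens of genes, so fragmented assemblies undercount both.
All comparisons are inclusive, matching the ≥/≤ wording of the
thresholds. The rRNA requirement reads "at least one class of 5S, 16S,
and 23S" as *all three classes present* (the MIMAG high-quality reading);
`qc_thresholds(required_rrna =)` relaxes it for users who read it as *any
one class*.

# System assembly

A defense family's organization rule has a set of mandatory and accessory
gene profiles and three thresholds: MG (minimum mandatory genes), SG
(minimum total genes), d_max (maximum intervening genes between
consecutive members). `assemble_systems()` chains hits of one family on
one contig greedily left-to-right while gaps stay ≤ d_max; each chain is
a system, *complete* when it has ≥ MG mandatory members and ≥ SG members
in total. A single-gene chain that is not itself a complete system is
*solitary*; multi-gene chains failing the thresholds are *incomplete*.
These three statuses partition the defense genes, which downstream
statistics rely on (inventories, the skew ratio).

This greedy engine is intentionally simpler than a full profile-based
rule interpreter: its purpose is synthetic data and users without
assembled-system output. When the input annotations already carry
`system_id` assignments from a dedicated tool, assembly is skipped and
the provided assignment is authoritative (provided systems are taken as
complete, unassigned genes as solitary). Families with no rule are
treated as single-gene system families. Hits whose profile name is
absent from their family's rule count as accessory, with a warning.

# Abundance metrics

Densities are counts per kb of the relevant denominator (genome size,
MGE span, island span, analyzed gene length). Family prevalence is the
percentage of MAGs with ≥ 1 *complete* system of the family by default;
`complete_only = FALSE` switches to any-defense-gene prevalence.
Size correlations are two-sided Spearman rank tests (average ranks on
ties, normal approximation); constant inputs are flagged rather than
correlated. Phylogenetic depth is the mean root-to-tip branch-length
path, computed by tree traversal; for a rooted tree this equals the
diagonal mean of the phylogenetic variance–covariance matrix, and the
test suite checks the two routes against each other to 1e-9. Unrooted
input is an error unless midpoint rooting is requested explicitly.

The stepwise regression of defensome abundance on standardized genome
size and phylogenetic depth is bidirectional from the intercept-only
model. The default criterion is AIC — the conventional default of the
standard stepwise routine — but note that AIC's fixed penalty of 2
admits a spurious predictor with probability ≈ 16% under the null, so an
intercept-only truth is recovered in only ~70% of null data sets with
two candidate predictors. `criterion = "BIC"` penalizes entry by log(n)
and keeps the intercept model in > 90% of null replicates at n = 100;
the test suite asserts exactly these two behaviors. The response is the
defense *gene* count by default (`response =` switches to systems), as
gene counts are the better-powered abundance measure when many systems
are incomplete.

# Defense islands

An island is a maximal array of defense units on one contig with ≤ 10
intervening genes between consecutive units, ≥ 5 units, and ≥ 3 distinct
defense families. Units are individual defense genes by default;
`unit = "system"` uses assembled systems (positioned at their first
member) plus solitary genes, with family minima counted on system
families. Genes of unknown family count toward the unit minimum but not
the family minimum. The island *span* runs from the first to the last
member inclusive of interleaved non-defensive genes — islands are mostly
non-defensive content, and the length-in-genes distribution and the
defense-content fraction are both computed over that span. Maximality is
structural: chains split exactly where a gap exceeds the threshold, so
no emitted island can be extended. The test suite proves the caller
identical to an O(n²) brute-force enumerator on hundreds of random
contigs, and exact on planted cohorts.

The skew ratio over island defense genes is
`(c − i)/(c + i)` with `c` the genes in complete systems and `i` the
genes in incomplete systems. Solitary genes are counted in the
incomplete class by default — the binary complete/incomplete split
leaves their placement open, and treating "not in a complete system" as
the biologically relevant contrast keeps the statistic defined on
solitary-rich islands; `include_solitary = FALSE` drops them instead.

Per-family island enrichment uses 2×2 Fisher tests
(`family f vs others` × `in vs out of islands`). Odds ratios are sample
odds ratios `ad/bc`, with the Haldane–Anscombe +0.5 applied only when a
cell is zero; p-values are two-sided Fisher exact with
Benjamini–Hochberg adjustment across families (a conservative addition;
raw p-values are reported alongside).

# Colocalization with MGEs and between families

MGE intervals overlapping an interval of a *different* class by ≥ 1 bp
are removed in pairs — ambiguous multi-class hits are excluded rather
than arbitrated — while same-class overlaps merge by union. A gene
belongs to an MGE class when its span overlaps a filtered interval by
≥ 1 bp; `flank_bp` (default 0, since "close vicinity" is not quantified
in the source material) widens intervals symmetrically. Chromosomal
densities exclude MGE spans from the denominator.

For the family × category table, the expected count under independence
is `E_fm = N_f × N_·m / N_··`: the family total times the marginal
fraction of *all* defense genes in that category. The source material's
verbal definition ("the fraction of defense genes *of that family*
assigned to each MGE") is circular as printed — it would force
O/E = 1 everywhere — so the standard independence margin is used; this
interpretation is deliberate and is the single most consequential
reading decision in the package. The same applies to the per-family
high-frequency-variant expectation. Because expected counts preserve the
margins, the expected-weighted mean O/E is identically 1, which the
acceptance checks verify. The global significance test is the chi-square
statistic over cells with expected ≥ 1 (configurable), on
(r−1)(c−1) degrees of freedom.

Family-pair colocalization enumerates unordered defense-gene pairs with
≤ 5 intervening genes on one contig. Pairs whose genes share a system id
are dropped: same-system genes are colocalized by construction and would
inflate every within-family association. Pairs are *inside* when both
genes fall within the span of the same island; pairs straddling an
island boundary count as outside by default (`straddle = "drop"`
discards them), and pairs spanning two different islands also count as
outside. Each family pair gets a 2×2 sample odds ratio and a two-sided
Fisher p; genes of unknown family are excluded from per-pair statistics
but retained in the totals.

# Variant enrichment

The analyzed region of a gene is its body plus 200 bp upstream of the
start codon, strand-aware. High-frequency variants require allele
frequency ≥ 0.25 *and* ≥ 10 supporting reads, both inclusive
("minimum"/"at least" semantics). SNPs inside the body are typed
synonymous/nonsynonymous by substituting the single variant base into
the reference codon under the standard genetic code — no haplotype
phasing, and start-codon special cases are ignored for substitution
typing. The upstream fraction of variants is an output statistic, never
a filter. Per-family O/E of high-frequency carriage excludes families
with fewer than 10 analyzed genes (grouping by environment, when used,
is applied before this cutoff).

# Pairwise dN/dS (NG86)

`ng86_sites()` computes per-codon synonymous site fractions by
enumerating all nine single-nucleotide neighbors, counting the fraction
synonymous *among non-stop outcomes* at each position (s; n = 3 − s).
`ng86_pair()` skips codon positions with gaps, ambiguity codes or stop
codons in either sequence, averages S and N over the two sequences, and
scores multi-difference codons by equal-weight averaging over minimal
mutational pathways, excluding pathways through stop codons (if every
pathway is blocked, all pathways are used with stop-involving steps
counted as nonsynonymous — a rare fallback). Proportions are corrected
with Jukes–Cantor, `d = −(3/4)·ln(1 − 4p/3)`; pairs with p ≥ 3/4 are
undefined and flagged, and pairs with dS > 1 are flagged as saturated
and discarded from summaries, with the discarded fraction reported.
ω = dN/dS is undefined at dS = 0 (identical-synonymous pairs) and
flagged rather than forced to a value. Only the counting method is
implemented; maximum-likelihood codon models are out of scope, as is
ortholog clustering (cluster assignments are consumed, singletons
dropped).

One estimator subtlety worth knowing: pathway averaging attributes
fractional nonsynonymous differences to some purely synonymous
histories (e.g. CTT↔TTA, both leucine, averages one synonymous and one
nonsynonymous pathway), so the estimated Nd can exceed zero even when
the true nonsynonymous substitution count is zero. At moderate
divergence this bias is small; the acceptance checks recover simulated
ω within ±20%.

# The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analyses
assume: per-contig gene grids (~150 genes per contig, ~900 bp genes),
a 20-family catalog with roughly log-uniformly decaying abundances
(half single-gene families, half two-gene families with MG = SG = 2 and
d_max = 3), two planted islands per MAG satisfying the island
definition exactly (5–8 units, gaps 0–3, ≥ 3 families), planted
complete systems, background solitary defense genes at 2% of genes, and
per-class MGE intervals with configurable defense-carriage multipliers.
In strict-spacing mode every planted feature keeps ≥ 11 intervening
genes from any other, so planted islands are recoverable with exact
boundaries; the binomial background draw is capped at what still fits,
and genuinely infeasible configurations (planted blocks exceeding the
contig) are an error. A single master seed drives per-MAG substreams,
so cohorts are bit-identical across reruns and growing a cohort leaves
earlier MAGs unchanged.

`simulate_pair_cohort()` plants a family-pair association: each contig
carries one island whose pair slots are far enough apart (7 intervening
genes) that only within-slot pairs qualify, plus isolated outside
slots; a slot is the focal pair with probability p_in inside and p_out
outside, with p_in derived from the requested odds ratio. Two filler
families guarantee the island's three-family minimum without touching
pair counts. `simulate_variants()` plants high-frequency variants
(frequency ≥ 0.25, reads ≥ 10 by construction) at per-family multiplied
rates; `simulate_codon_pairs()` evolves two descendants from a uniform
sense-codon ancestor, accepting synonymous proposals always,
nonsynonymous with probability ω, and rejecting stops.

What the generator does *not* emulate: sequence-level realism (GC and
codon-usage bias, repeat structure), annotation error, fragmented or
chimeric assemblies, phylogenetic correlation between MAGs, overlapping
genes, and real defense-family organization diversity (the rule catalog
is stylized). Passing tests therefore establish the correctness and
calibration of the *statistics* under the assumed data model — exact
island recovery, nominal test sizes, unbiased O/E and OR recovery — not
robustness to real-world annotation noise.

# Validation design and problem sizes

The test suite validates each statistic against an independent route:
the island caller against a brute-force O(n²) enumerator on 200 random
contigs of ≤ 60 genes; NG86 site counts against exhaustive mutation
enumeration over all 61 sense codons using an independent genetic-code
source; phylogenetic depth against the variance–covariance diagonal;
odds ratios, O/E cells, N50 and densities against hand arithmetic.
Calibration experiments use 1000 replicates per test with expected cell
counts ≥ 5 (2000 genes for the Fisher designs; 60 contigs ≈ 600
qualifying pairs for the pair test), sizes chosen so the asymptotic
reference distributions apply and the discrete conservatism of exact
tests stays within the 5% ± 2% acceptance band. Planted odds-ratio
recovery uses 100 contigs (~1000 qualifying pairs), putting the ±30%
requirement at ~1.8 standard errors of the log odds ratio. ω recovery
uses 200 pairs of 300 codons at t = 0.2 proposals/codon/lineage —
moderate divergence, dS ≈ 0.1–0.2, well below saturation.

# Known limitations

* The assembly engine is a deliberate simplification of profile-based
  rule interpreters; for production annotation use a dedicated detector
  and feed its system assignments in.
* Chi-square calibration assumes adequate expected counts; with many
  rare families the global test can be unreliable, and cells with
  expected < 1 are excluded from the statistic.
* Integron statistics are typically underpowered (few intervals); the
  package computes them but interpretation should be cautious.
* NG86 assumes equal base frequencies and no transition/transversion
  bias (Jukes–Cantor); strongly biased sequences will bias dS and dN.
* The pair-association test conditions on islands called from the same
  data, so island-calling errors propagate into the inside/outside
  split; on synthetic data with exact island recovery this effect is
  absent.
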