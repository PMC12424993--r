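---
title: "Phylogeny-constrained variant harmonization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-constrained variant harmonization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeharmony)
```

# The problem

Single-cell-derived tumor sublines give a clean window into subclonal
evolution: each subline is a clonal expansion of one cell, so a variant
shared by several sublines was acquired on the branch of the subline
phylogeny ancestral to exactly those sublines. In practice three things
break this picture: callers miss variants (false negatives), they invent
variants (false positives), and deletions physically remove variants from
some descendants, which makes a truly ancestral variant look absent. This
package places somatic SNVs, SVs and copy-number alterations (CNAs) onto
a given rooted subline phylogeny while modelling those three error modes,
and provides the branch-level analyses that a placement unlocks:
mutational-signature timing, cumulative dN/dS, subclonal differential
methylation with permutation tests, monotonic methylation trajectories,
selection tests on gene copy-number status, copy-neutral LOH timing and
pseudobulk benchmarking truth sets.

The tree itself is an input. The package prepares the high-confidence
genotype matrix a tree-search tool consumes (`prepare_tree_snvs()`), but
searching tree space is out of scope.

# The placement model

## Clade-support thresholds

For a variant called present in a carrier set $S$ of sublines, the
candidate branch is the most recent common ancestor (MRCA) of $S$; its
clade has $k$ leaves. Under an assumed per-subline false-negative rate
$f$ (default 0.15), the variant is accepted at that branch when

$$|S| \ge s(k) \quad\text{with}\quad
  s(k) = \begin{cases} k & k \le 2\\
  \max\!\bigl(1, \lfloor k\,(1-f) \rfloor\bigr) & k \ge 3,\end{cases}$$

i.e. $s(k)$ is the largest support whose implied dropout rate
$(k - s)/k$ still reaches $f$. Clades of one or two leaves require full
support because a single dropout there is indistinguishable from a
miscall. For $k = 3$ the implied dropout tolerance is $1/3$ — more
permissive than $f$ — which is accepted deliberately: small clades near
the tips are where tree uncertainty concentrates. `min_support()` and
`effective_fn_rate()` expose the arithmetic. Placement at the root is a
*clonal* (truncal) call, at an internal branch *subclonal*, at a leaf
*private*. The trunk is modelled as the root node itself rather than a
phantom incoming edge.

With the default false-positive rate (1e-5) the called carrier set is
trusted outright; no leave-one-out search over carrier subsets is
performed (`fp_leaveout` exists as a switch but is off).

## Loss-aware regenotyping

For each SNV the candidate carrier set is extended by every subline that
has a *loss region* (an SV deletion, or a copy-number segment at CN 0–1)
overlapping the variant position. The extended set is re-evaluated: the
rescue is accepted only if (a) the support threshold holds at the new
MRCA, (b) the *parsimony guard* passes — no other called SNV of a rescued
subline lies inside the rescuing loss span, in which case the loss is
assumed to sit on the other haplotype and the whole position is left
unregenotyped — and (c) the *reinclusion rate*, defined here as rescued
sublines divided by originally called sublines, stays below 1 (a rescue
that doubles the carrier set is a "dramatic shift" and is rejected).
Rescued sublines get the status *lost*. On rejection the original called
set and its placement stand. SVs use the same thresholding but are never
regenotyped; their absence in a subline cannot be explained by a smaller
nested loss.

The denominator of the reinclusion rate is a design choice: the rate is
anchored to the *called* set so that the 100% cap is meaningful for small
carrier sets (adding two sublines to two called ones is exactly 100% and
is rejected).

## CNA placement

Gains (CN > 2) and losses (CN < 2) relative to the diploid baseline are
extracted per subline and processed as two disjoint pools — direction is
the event identity, absolute copy number is not harmonized. Placement
runs in three phases per direction and chromosome:

1. **Bottom-up pairing.** Traversing nodes deepest-first, any two ranges
   carried up from different child subtrees that overlap spawn an overlap
   range at the meeting branch: the *intersection* of the intervals,
   carried by the *union* of the subline sets. All cross-child pairs are
   enumerated; duplicates are collapsed.
2. **Per-branch thresholding and merging.** At each branch, ranges whose
   subline set meets `min_support()` of the branch's clade size are kept,
   and mutually overlapping kept ranges are merged (*union* of intervals
   and of subline sets). Intersection in phase 1 and union in phase 2
   reflect two readings of "overlap": the shared span names the common
   event, the merge consolidates partial variants of it.
3. **Top-down assignment.** Walking root-to-leaves, spans already
   assigned to an ancestor are subtracted, splitting ranges where
   necessary; whatever per-subline residue no ancestor claimed stays on
   the terminal branch.

Two independent amplifications of overlapping regions in different
clades ("parallel events") survive as two branch ranges with their own
breakpoints whenever the union of their carrier sets misses the support
threshold at every common ancestor — which is the generic situation for
major clades under a trunk-level threshold. They are merged only if the
union itself looks like a well-supported event of the shared ancestor,
which is the intended behaviour of the threshold rule, not an accident.

# The SNV filter cascade for tree building

`prepare_tree_snvs()` applies, in order: (1) drop sites overlapping a
loss region in any subline (infinite-sites violations); (2) drop private
and clonal sites (phylogenetically uninformative); (3) mark entries with
depth ≤ 10 as *missing* (the tree builder decides); (4) drop sites whose
mean/median depth across sublines is below 20; (5) drop sites whose
mean/median VAF over present sublines is below 1/3 (heterozygous diploid
variants sit near 0.5); (6) drop sites with alternate-allele reads in at
least half of the called-absent sublines (mapping artifacts). An audit
vector reports per-rule removals.

"Mean or median below threshold" is ambiguous between *either below* and
*both below*. The default is the permissive reading (*both below* drops),
which retains more sites; `filter_logic = "either"` gives the strict
reading. Missing entries are excluded from VAF summaries (an unreliable
fraction should not dilute the signal) but included in coverage
summaries (rule 4 exists precisely to catch consistently thin sites).
Thresholds are inclusive for "≤ 10" and strict for "< 20" and "below
1/3"; any alternate read (≥ 1) counts as support in rule 6. Rule 1 uses
every provided loss region regardless of size; the caller can pre-filter
losses if a minimum-size convention is wanted.

# Differential methylation

Per-CpG modified/total read counts per subline are the input. CpGs with
coverage below 3 in any subline are excluded, then each subline's raw
fractions are smoothed with a coverage-weighted tricube kernel over a
±1000 bp window. This smoother is a deliberate contract-level stand-in
for a local-likelihood smoother: the downstream criteria depend only on
constant-invariance, locality and coverage weighting, all of which the
kernel provides; the window width and minimum-site behaviour are
package-level defaults, not an attempt to reproduce any particular
tool's tuning.

Per CpG, the signal-to-noise statistic is
$t_i = (\bar{x}_{\text{case},i} - \bar{x}_{\text{ctrl},i}) /
(\mathrm{sd}_{\text{pooled},i} + s_{0})$, where $s_0$ is the
genome-wide 75th percentile of the pooled standard deviation — a
variance floor that stops near-constant CpGs from dominating. The
"corrected" statistic is the genome-wide empirical quantile rank of
$t_i$; a DMR is a maximal run of at least 10 consecutive CpGs whose
ranks fall beyond 0.025/0.975 on the same side, with mean smoothed
difference of at least 0.2. Both groups must have at least two sublines.

The DMR-count permutation test redraws the case/control bipartition at
fixed case size; when the number of distinct assignments is within the
permutation budget they are enumerated exhaustively (23 sublines with a
case of two gives all 253), and the p value is the literal fraction of
null counts at or above the observed one, with no add-one correction.
The observed assignment is part of the exhaustive null, so the smallest
attainable p is 1/253.

## Monotonic trajectories

Within a linearly differentiating clade, nested suffix case groups
(sizes $k-3$ down to 2; a single 2-vs-2 cut when $k = 4$) are each
tested against the remainder of the clade, and the union of the per-cut
DMRs (overlapping intervals merged) forms the candidate regions. Region
mean smoothed methylation per subline is then tested for trend along the
clade ordering with Kendall's $\tau$ (tau-b, pair counting), maximised
over the orderings admissible under the tree: the base order plus each
swap of interchangeable sibling slots and their combinations. A region
is flagged at $|\tau| \ge 0.7$, which under a bivariate-normal model
corresponds to a Pearson correlation of about 0.9
(`tau_to_pearson(0.7)` = `r round(sin(pi*0.35), 3)`).

The permutation test on the number of trend-associated genes permutes
the clade ordering. Orderings are grouped into equivalence classes under
(i) exchanging the two members of an interchangeable sibling pair and
(ii) full reversal, and at most one representative per class is sampled,
the observed ordering's class excluded. A subtlety fixed the group
definition: position-based slot swaps do not commute with reversal (the
reversal of a slot swap is a swap of different slots), so the group they
generate is larger than 8 and would not yield $8!/8 = 7!$ classes.
Label-based pair transpositions do commute with reversal, give orbits of
exactly $2^{k+1}$ for $k$ swappable pairs, and reproduce the $7! = 5040$
classes for the 8-leaf clade; the package therefore defines equivalence
by label transpositions plus reversal.

# Branch dynamics

Signature timing consumes externally fitted per-mutation, per-subline
signature probability vectors. A placed mutation's label is the argmax
of the probability vectors *summed* over the sublines below its branch
(sum and mean are equivalent for the argmax; ties break by signature
name order), and a branch's activity for a signature is the fraction of
its mutations carrying that label after aggregating sub-lettered
signatures (SBS7a–d into SBS7, SBS17a–b into SBS17). Hard per-mutation
labels, rather than soft probability mass, follow from reading "most
probable signature per mutation, proportion of mutations per branch"
literally.

Cumulative dN/dS for a branch is
$(N/S) \times (\text{syn sites}/\text{nonsyn sites})$ over counts
accumulated from the trunk through the branch inclusive; it is NA when
the cumulative synonymous count is zero, and invariant to splitting a
branch in two. Branch-level group comparisons (timing class, clade) use
one-way ANOVA with Tukey HSD adjusted p values only — no further FDR
layer — and suppress contrasts involving singleton or unlabelled groups.
`tree_search_grid()` enumerates the 8 × 7 × 100 = 5600 prior/permutation
configurations of the upstream tree search.

# Copy-number selection tests

A gene's status in a subline is gain/loss only when its interval is
*entirely contained* in an altered segment; straddling a boundary is
neutral. The two enrichment tests tabulate ONC vs TSG labels against
"gained in ≥ 1 subline and lost in none" (and the mirror image) over
ONC/TSG genes impacted in at least one subline, as 2×2 chi-squared tests
without continuity correction by default (a flag enables it). The exact
complement category ("not gained-only" includes lost-only and mixed
genes) is the documented reading of an under-specified construction.

The boundary-orientation test counts adjacent ONC–TSG gene pairs, once
per study, where the ONC member sits on the higher-copy side in at least
one subline in which the two genes' absolute copy numbers differ; the
null permutes the ONC/TSG/ND labels over all genes (re-deriving pair
eligibility each time) and p is the fraction of permutations reaching
the observed count. Label overrides for literature-curated genes are a
user-supplied table, not hard-coded.

Copy-neutral LOH timing: with $H$ observed homozygous clonal SNVs and
$C$ total clonal SNVs on the chromosome, both generating scenarios (LOH
then duplication; nondisjunction then LOH) give the same bound
$2H/(C+H)$ on the fraction of trunk time before the duplication —
algebraically identical, implemented as two code paths and verified
equal to machine precision in the tests.

# Pseudobulk benchmarking

A mixture specification (name + member sublines) converts placements
into a truth set: a placed variant's carriers are the leaves below its
branch minus regenotyped (lost) sublines; clonality-in-mixture is
clonal/subclonal/private by carrier count among members; expected VAF is
carriers/(2 × members) under the heterozygous-diploid model. Unplaced
variants are excluded — they are not established false positives, and
penalizing callers for them would be unfair in either direction.
Scoring matches SNVs exactly and SVs by type within a 50 bp breakend
tolerance (insertions also within 20% length). False positives carry no
truth clonality and count only against overall precision; per-stratum
rows report TP/FN and recall. Read-level mixing of alignments is out of
scope: benchmarking is at the variant level against externally produced
candidate call sets.

# The synthetic-data generator

`simulate_dataset()` emits a complete bundle — tree, per-subline SNV
calls with depths, multi-sample SVs, CNA segments with SV-defined
boundaries, loss regions, CpG methylation counts, signature
probabilities, functional annotations — plus the ground truth needed to
score recovery. Its defaults are the study conditions the package
targets: 23 sublines in 4 clades, one 8-subline caterpillar clade with
two interchangeable cherries (linear differentiation), clonal /
subclonal / private SNV fractions of 8% / 9% / 83%, sequencing depth 30
with binomial allele sampling around VAF 0.5, a 15% false-negative rate
with half the dropouts realized as private overlapping deletions, a 1e-5
false-positive rate, CNA events bounded by emitted SV breakpoints with a
fifth organized as parallel pairs (same region, distinct breakpoints,
clades on opposite sides of the top-level split so their union can only
meet at the trunk), and beta-binomial methylation (dispersion 0.02,
coverage 20) with branch-shifted and linearly drifting regions at effect
size 0.3.

Generator choices worth knowing when interpreting test results:

* **False negatives are injected only for variants whose true clade has
  at least 3 leaves.** Variants on size-1/2 clades require full support
  by construction, so a dropout there is unrecoverable by any method;
  injecting them would only measure the generator, not the algorithm.
* **SNV positions sit on a coordinate lattice** (step ≥ 1 kb) and each
  masking deletion is a short private interval centred on its SNV, so a
  rescue span never contains another call of the same subline and the
  parsimony guard fires only when a test constructs that situation
  deliberately. Real genomes are not lattices; the guard's false-fire
  rate on real data depends on local SNV density.
* **"Deletion-masked" variants in recovery metrics are variants all of
  whose dropouts are deletion-caused.** A plain dropout carries no
  rescue signal, so mixing it into the masked class would measure the
  binomial tail of plain dropouts, not regenotyping.
* The genome model is 5 × 10 Mb with disjoint zones for SNVs, SV/CNA
  events and CpG regions; REF/ALT alleles are drawn letters, no
  reference sequence is emitted.
* A single seed fans out to per-component seeded streams, so adding a
  component does not reshuffle the others and a fixed seed reproduces
  the bundle byte-for-byte.

What passing tests on this generator do **not** show: robustness to
mapping artifacts, to clustered/correlated errors, to CNA boundary
noise, to non-diploid baselines (beyond the planted events), or to tree
error — the tree is taken as correct throughout.

Two auxiliary generators exist purely for calibration:
`simulate_exchangeable_methylation()` (subline profiles i.i.d., so every
bipartition is a null draw) and `simulate_cn_label_null()` (gene labels
independent of copy number). Both are designed to keep the discrete
count statistics dispersed — many regions, many eligible pairs — because
the literal-fraction p of a permutation test is only approximately
uniform when the statistic has few ties.

# Numerical and scale choices

Internal coordinates are 0-based half-open everywhere; conversion
happens only at I/O boundaries (VCF is 1-based; BED-like tables are
0-based). Multifurcating trees are accepted; MRCA and traversals never
assume binary. Chromosome names pass through verbatim. Deterministic
tie-breaks: argmax ties by name order; equal-threshold placement
candidates resolve to the deepest node (only reachable via
regenotyping); placement iterates variants in genome order and is
order-independent.

The test-suite and acceptance-script problem sizes are package choices
balancing statistical resolution against desk-scale runtime: 5000 SNVs
on 23 sublines for parameter recovery; 1000 random variants/vectors for
the brute-force oracles; 200 seeded replicates with 253 exhaustive
assignments (DMR null) and 300 label permutations over ~400 genes
(boundary null) for calibration; 10,000 random count pairs for the LOH
scenario identity. The headline numbers of any particular sequencing
study (total SNV counts, placement percentages, specific DMR counts and
p values) depend on tens of gigabases of reads per subline and are not
reproduction targets at this scale.

# Worked example

```{r worked}
ex <- make_worked_example()
fit <- harmonize_tree(ex$tree, snvs = ex$snvs, svs = ex$svs,
                      cnas = ex$cnas, losses = ex$losses)
fit
fit$placements[, c("variant_id", "clonality", "support", "clade_size",
                   "regenotyped_sublines")]
```

Every row can be checked by hand against `min_support()`; the help page
`?make_worked_example` walks through each variant, including the two
regenotyping rescues and the parsimony-guard rejection.

# Known limitations

* The placement engine trusts the input tree; systematic tree error
  turns into systematic placement error, flagged only indirectly as
  unplaced variants.
* Regenotyping considers the single candidate set "called ∪
  loss-overlapping"; it does not search subsets, so one spurious
  overlapping loss in an unrelated subline can push the candidate past
  its threshold-failure point and forfeit an otherwise good rescue.
* CNA placement is haplotype-unaware and treats direction as event
  identity; nested events of the same direction on the same path are
  resolved by span subtraction, not by dosage.
* The kernel smoother is not a likelihood model; with very uneven
  coverage its variance behaviour differs from a local-likelihood fit.
* Permutation p values are literal fractions; with exhaustive nulls the
  floor is 1/N, and users should not read p = 0 from sampled mode as
  exact zero.
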