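---
title: "Methods: partitioned plastome phylogenomics with plastconcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned plastome phylogenomics with plastconcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastconcord)
```

## The problem

Plastome (chloroplast genome) supermatrices are the workhorse of
family-scale plant phylogenomics, but a single concatenated alignment hides
several decisions that can change the inferred tree: whether noncoding
spacers are analyzed with or separately from protein-coding genes, whether
alignment columns containing gaps are kept, and whether codons under
positive selection are retained. `plastconcord` implements the comparison
framework used to interrogate those decisions: it builds fourteen standard
data partitions from one set of region alignments, scans every
protein-coding locus for purifying/positive selection, infers (or imports)
a bootstrapped tree per partition, and quantifies clade support,
concordance and conflict across the resulting trees.

The fourteen partitions combine four region sets — a three-gene subset
(*rbcL*, *ndhF*, *matK* plus the *trnK* intron), all coding regions, all
noncoding regions, and the complete plastome — with two column filters:
*gap stripping* (remove every column holding a gap in at least one
sequence) and *selected-site masking* (remove the three columns of every
positively selected codon). The codes and the fixed derivation graph are:

| base | gapped, unmasked | stripped | masked | masked + stripped |
|------|------------------|----------|--------|-------------------|
| three-gene | A | B = strip(A) | C = mask(A) | D = strip(C) |
| coding | E | F = strip(E) | G = mask(E) | H = strip(G) |
| noncoding | Q | R = strip(Q) | (n/a) | (n/a) |
| complete | W | X = strip(W) | Y = mask(W) | Z = strip(Y) |

Masking is always applied to the gapped matrix first, then gaps are
stripped; the two operations do not commute (a masked codon may contain
gap columns), so the order is fixed by construction. Matrix lengths after
masking depend on bookkeeping details (whether sites were removed from
per-locus alignments before or after concatenation, and how gap-bearing
codons are counted), so the suite documents its own rule — codon indices
are defined on the locus's codon-position metadata, 0-based — and makes no
promise of reproducing masked-matrix lengths produced by other toolchains.

## Selection scanning

**Per-locus test.** For each coding locus the package computes mean
pairwise dN and dS by Nei–Gojobori counting: expected synonymous site
counts per codon average the synonymous fraction of the three possible
changes at each position (changes to stop codons are excluded from the
denominator), observed differences between two codons average the
synonymous/nonsynonymous composition over all orderings of the differing
positions (orderings through stop codons excluded), and the proportions
are Jukes–Cantor corrected, $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$,
separately for the two classes. The codon-based Z-test then evaluates
$Z = (d_S - d_N)/\sqrt{\widehat{\mathrm{Var}}(d_S) +
\widehat{\mathrm{Var}}(d_N)}$ one-tailed against the purifying (or, with
the sign flipped, positive) alternative. The variance is estimated by a
seeded bootstrap over codon sites (default 1,000 pseudo-replicates):
codons are resampled with replacement and the mean pairwise dN and dS
recomputed. Analytical variance formulas exist, but the resampling route
makes the estimator's assumptions explicit and reproducible from one seed.

Degenerate and pathological inputs have fixed conventions: an alignment of
identical sequences returns verdict *neutral* with $p = 1$ (both variances
are zero); pairs whose corrected proportions saturate ($p \ge 3/4$, where
the Jukes–Cantor log is undefined) are excluded pairwise, both in the
point estimate and inside each bootstrap replicate, and a locus is
*undetermined* only when every pair is saturated or fewer than two usable
sequences remain.

**Per-site scan.** Site-wise positive selection is detected by a
counting-based (SLAC-style) scan rather than a mixed-effects likelihood
model: ancestral codon states are reconstructed by Fitch parsimony on a
supplied tree (ties broken by a seeded random draw; missing leaves inherit
the parent state), observed synonymous ($s_d$) and nonsynonymous ($n_d$)
changes are summed over edges with the same pathway averaging as above,
and a one-tailed binomial test asks whether the nonsynonymous fraction of
the $m = s_d + n_d$ changes exceeds the site's expected nonsynonymous
site fraction $N/(S+N)$ computed from its observed codon composition.
Because pathway averaging can make $n_d$ fractional while $m$ is an
integer, the binomial tail is taken from $\lceil n_d \rceil$ — a
conservative choice. Invariant sites are never flagged, and no
multiple-testing correction is applied to per-site p-values (the scan
mirrors exploratory per-site usage; $\alpha$ defaults to 0.05 and is
configurable). Counting scans are less sensitive than episodic-selection
likelihood methods on shallow data; the masking stage therefore also
accepts externally produced site lists (a TSV of locus / 0-based codon
index), so likelihood-based scans can be dropped in without touching the
rest of the pipeline.

## Tree inference and support

The built-in engine is deliberately simple and inference-agnostic
plumbing: Jukes–Cantor distances with pairwise deletion of gap/ambiguous
columns, neighbor-joining (negative branch estimates clamped to zero with
the deficit moved to the sister edge), a fixed-count nonparametric
bootstrap (default 200 replicates, column resampling, seeded), outgroup
rooting on the edge separating a declared outgroup (an error if no single
edge separates it), and support mapping by bipartition frequency on the
unrooted leaf set. Externally inferred trees (e.g. maximum-likelihood
trees with integer support labels) are first-class inputs through the
Newick reader, and all concordance machinery is indifferent to where a
tree came from. A fixed replicate count replaces adaptive bootstopping for
reproducibility.

Support of *any* taxon subset can be queried against a replicate set, so
clades absent from a best topology still receive a bootstrap percentage.
Subsets inducing trivial bipartitions (single leaves and their
complements) are present in every tree by convention and report 100.

## Concordance bookkeeping

Clades are named on a rooted reference tree (partition X by default: it
excludes neither major region set, and gap-stripped matrices avoid the
pathologies of treating indels as missing data) by deterministic preorder
numbering; clades met in non-reference trees are appended in tree-code
order. The clade-by-tree support matrix masks values below 50% in all
reports — a blank means "absent from that tree's set *or* below the
reporting threshold", and downstream statistics deliberately do not
distinguish the two. Support categories follow the conventional integer
boundaries: below 50 unsupported, 50–70 weak, 71–90 moderate, 91–100
strong.

Pairwise tree comparisons count shared clades (reported in both trees),
clades reported in exactly one tree (and how many of those reach 70), the
range, mean and absolute mean of support differences (sign convention:
second code minus first), and the identical/increased/decreased breakdown,
which always sums to the shared count.

Two clades *conflict* when their taxon sets overlap and neither contains
the other — on a common leaf set this is exactly bipartition
incompatibility. Qualifying clades must reach BP ≥ 70 in at least one
tree (both the threshold and the minimum number of trees are
configurable; the default of one tree admits conflicts supported in a
single partition). The report lists connected components of the conflict
graph. All trees must share one leaf set; mismatches are errors rather
than silently pruned, because clade identity is exact taxon-set equality.

## The simulator and what passing tests mean

The synthetic-data generator produces plastome-like data with complete
ground truth so that every stage is testable without external downloads:
a Yule tree rescaled to a chosen expected root-to-tip depth; coding loci
evolved codon-by-codon with a Gillespie scheme in which nucleotide
proposals arrive at rate 1 per site, proposals creating stops are
rejected, and synonymous/nonsynonymous proposals are accepted with
probabilities $\min(1, 1/\omega)$ and $\min(1, \omega)$, so the accepted
rate ratio is exactly $\omega$ per site without exponentiating a 61×61
generator; noncoding spacers evolved under GTR+Γ (4-category discrete
gamma) with a Poisson indel process (geometric tract lengths, insertions
and deletions equally likely) whose emitted alignment is the true
homology, making the gap-column set exact; and per-taxon genome records
with CDS/exon features at true coordinates, including a duplicated
inverted-repeat copy of one gene to exercise de-duplication.

Default study conditions: 32 taxa, six 300-codon loci, background
$\omega = 0.2$ with 5% of codons at $\omega = 5$, AT-rich base
frequencies (A 0.31, C 0.18, G 0.17, T 0.34), transition/transversion
exchangeabilities 2:1, gamma shape 0.8, indel rate 0.05 per site per unit
branch length with mean tract length 3. The default tree depth of 0.8
expected substitutions per site root-to-tip is a deliberate
deep-divergence setting: a counting-based per-site test can only reach
$p < 0.05$ when a codon site accumulates roughly ten or more changes
(e.g. $0.75^{10} \approx 0.06$), which with 32-taxon Yule trees requires a
total tree length of several substitutions per site. At that depth the
per-site scan attains ~30% sensitivity with a near-zero false-positive
rate, and the Z-test's saturation handling is exercised rather than
idle.

What the simulator does **not** emulate — and therefore what passing
tests do not establish about real data: alignment error (all simulated
gaps are true indels, whereas in real supermatrices part of the gapped
fraction reflects ambiguous alignment; gap stripping in the package is
exact regardless, but biological conclusions about stripped partitions do
not transfer), realistic gene order and inverted-repeat structure beyond
a single duplicated locus, rate variation among loci beyond gamma-across-
sites, codon usage bias, recombination, and circularity (no rotation
normalization).

## Numerical conventions and problem sizes

- Gap symbol is `-` only; `N` and IUPAC ambiguity codes are residues,
  excluded from distances and codon counts by pairwise deletion.
- Coordinates are 0-based half-open internally; GenBank input (1-based
  closed) is converted on read, and the conversion is a bijection.
- Codon indices in site lists are 0-based within each locus's codon
  frame, matching the TSV schema written and consumed by the pipeline.
- The terminal stop codon of a CDS carries no codon-position metadata, so
  masking arithmetic never counts it.
- Bootstrap percentages are stored as exact real frequencies and rounded
  to integers only for display in Newick and TSV output.
- Determinism: every stochastic stage (tree simulation, sequence
  evolution, bootstrap, Z-test variance, parsimony tie-breaks) draws from
  an explicit seed, and reruns with the same configuration are
  bit-identical apart from log timestamps.

The test suite runs the framework at desk scale, chosen to keep the full
suite under a few minutes while leaving the Monte-Carlo properties
well-resolved: 8–12 taxa for pipeline smoke tests, 100 replicates for
tree-recovery checks (10 kb alignments), 200 replicates for Z-test
type-I calibration (8 taxa, 80 codons, 300 bootstrap pseudo-replicates),
and the full 32-taxon study conditions for the 20-seed site-scan recovery
check.

## Known limitations

- The counting scan trades sensitivity for transparency; loci with few
  substitutions per site will under-report positively selected codons
  relative to likelihood methods. Import externally computed site lists
  when that matters.
- Jukes–Cantor distances under-correct for the AT-rich, rate-heterogeneous
  processes real plastomes follow; the NJ engine is a stand-in for
  model-based inference, not a replacement, and imported trees are the
  intended route for publication-grade topologies.
- Clade identity across trees requires identical leaf sets; taxon-set
  mismatches must be resolved upstream.
- Whole-matrix statistics inherit the reporting threshold's ambiguity: a
  blank cell cannot distinguish "clade contradicted" from "clade weakly
  supported", and counts of maximally supported clades are sensitive to
  rounding conventions in imported support tables (published summaries
  based on such spreadsheets occasionally disagree with one another for
  exactly this reason, which is why every statistic here is recomputed
  from the matrix rather than quoted).
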