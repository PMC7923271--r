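---
title: "Models and methods behind mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements a comparative-mitogenomics workflow: composition and
codon-usage profiling of annotated mitochondrial genomes, circular signed
gene-order comparison, parsimony ancestral reconstruction of tRNA
alignments on a fixed rooted topology, classification of compensatory
base changes (CBCs) in cloverleaf stems, congruence of CBC-derived
clusterings with a reference phylogeny, and a physicochemical-property
selection scan with a counting-method dN/dS. This vignette records the
models, the conventions, and the design decisions a maintainer would
want explained.

## Coordinates, tokens and the circular frame

Genomes carry features over the fixed 37-gene vocabulary (13
protein-coding genes, 22 tRNAs, 2 rRNAs) plus up to two control regions.
Coordinates are 0-based half-open internally and 1-based inclusive in
GenBank and feature-table files; a feature crossing the origin of the
circular molecule keeps `start > end` with a wrap flag and is treated as
one feature throughout.

A signed gene order is a circular signed permutation. Two symmetries are
quotiented out before any comparison: rotation (a circle has no start)
and mirror (the same molecule read from the other strand, which reverses
the order *and* flips every sign). Canonicalization rotates `cox1` to the
front with positive sign, applying the mirror first when `cox1` lies on
the minus strand. Flipping only the signs — without reversing — is not a
symmetry of a circular signed permutation; using the full mirror is what
makes `extract_gene_order()` invariant under reverse-complementing the
genome, which the test suite asserts.

## Composition and codon usage

AT-skew is `(A − T)/(A + T)` and GC-skew `(G − C)/(G + C)`; ambiguity
codes and gaps are excluded from every count and a zero denominator
yields `NA` rather than a value. Minus-strand genes are always summarised
on their sense (coding) strand; genome-level statistics use the plus
strand. Codon-position pools are kept separate for plus- and
minus-strand protein-coding genes because mitochondrial strand asymmetry
makes those contrasts the object of interest.

ENC is Wright's statistic generalized to the invertebrate mitochondrial
code (NCBI table 5, 62 sense codons): per amino-acid family the
homozygosity estimate \(\hat F = (n\sum p_i^2 - 1)/(n-1)\), then a sum of
family-size-class counts over class-mean \(\hat F\). Families observed
fewer than twice are omitted from their class mean; a class left empty is
imputed from the mean of the available classes (Wright's convention). The
result is capped at 62. MILC follows its defining formula:
\(M_a = 2\sum_c o_c\ln(f_c/g_c)\) and
\(\mathrm{MILC} = \sum_a M_a / L - C\) with
\(C = \sum_a (r_a - 1)/L - 0.5\) summed over the amino acids observed.
The expected within-family distribution \(g\) defaults to uniform — the
simplest assumption-free baseline; a background codon distribution can be
supplied instead, and both readings are exposed because the choice is
genuinely open in this kind of analysis. Under usage equal to the
expectation MILC sits near 0.5 for long genes, which is why ENC 62 and
MILC ≈ 0.5 are quoted together as "no bias".

GC3 of fourfold-degenerate sites considers only codons whose quartet
(first two bases fixed, third free) maps entirely to one amino acid under
the active code, so twofold families never dilute the signal.

## Gene-order comparison

The breakpoint distance counts signed adjacencies of one circle absent
from the other, with \((x, y) \equiv (-y, -x)\) since an adjacency can be
read from either strand. Conserved blocks are maximal runs contiguous in
both circles with a consistent relative orientation; the implementation
enumerates arcs directly (quadratic-cubic in the 37-gene setting, which
is immaterial at this size) and the tests verify it against an
independent exhaustive enumeration up to n = 12.

Rearrangement events act on the canonical linearization, whose first
position (the anchor) never moves: reversing or moving a block that
contains the anchor equals acting on its complement up to rotation and
mirror, so restricting blocks to positions 2..n loses no generality. The
TDRL (tandem duplication–random loss) test exploits the mechanism
directly: after duplicating the linearized circle and deleting one copy
of every gene, the copy-1 survivors form a contiguous arc, so the result
is an increasing prefix followed by an increasing suffix of source
positions, signs unchanged. This is deliberately stricter than a "two
increasing subsequences" reading, which would accept permutations (for
example source positions 2,1,4,3) that no single TDRL can produce, and it
is exactly the inverse of what `apply_event()` does.

Scenario search is a bounded breadth-first search with
rotation-and-mirror deduplication, run bidirectionally
(meet-in-the-middle) over reversals, transpositions and reverse
transpositions; TDRLs are tested as scenario-closing steps because their
neighbourhoods are exponentially large and their inverses are not TDRLs.
Ties resolve by the fixed priority reversal > transposition > reverse
transposition > TDRL, then leftmost block — a transposed block is always
also one TDRL, and deterministic reporting requires picking one. Depth 2
is tractable at 37 genes (a few seconds); deeper bounds are restricted to
orders of at most 14 tokens, which is where reduced token sets (e.g.
protein-coding genes only) are the natural object anyway.

## Ancestral reconstruction

`fitch_ancestral()` runs per-column Fitch parsimony on the fixed rooted
topology over the five-state alphabet A, C, G, U/T, gap — the gap is a
real character state because stem indels are part of the analysis, not
missing data. Uniform substitution cost is used (no
transition/transversion weighting); nothing in the downstream
classification depends on weights, and the parsimony score is recorded
per column.

Ties in the top-down pass (at the root, and wherever a node's state set
excludes its parent's state) resolve toward the state carried by the
node's first descendant leaf when that state is in the set, falling back
to the fixed alphabet order A < C < G < U < gap. The leaf-based policy is
an outgroup-style polarization and exists for a structural reason:
resolving each column independently by alphabet order picks `A` in one
column of a stem pair and `C` in the other, systematically splitting a
true both-bases change (an FCBC) on a root-adjacent branch into two
single-base changes on different branches. With the leaf-based policy the
two columns of a pair resolve consistently and the category tallies match
the simulator's event log closely; the parsimony score itself is
identical under any tie policy, which the brute-force oracle tests
assert. Parsimony cannot polarize changes on the two root-incident
branches any better than this — a maximum-likelihood reconstruction with
an explicit outgroup would; this is the main acknowledged source of
drift against reconstructions made with ML tools.

## Compensatory base changes

Of the 16 base pairings only six are stable: Watson–Crick AU, UA, GC, CG
and wobble GU, UG. A changed stem pair is classified exactly once per
branch: FCBC when both bases changed (no gaps), HCBC when exactly one
changed (no gaps), indel when any gap is involved. An HCBC that produces
a mismatch (AU → AC) stays an HCBC with subtype `result_mismatch`; the
subtype field keeps the stricter stable-result reading recoverable, since
published usage of the category is loose. FCBC tallies carry a
`changes = 2 × events` convenience column because both bases of the pair
are affected. When one branch event involves both a gap and a base
change, indel wins — the gap makes the base comparison unreliable.

Consensus cloverleaf structures force the acceptor and anticodon stems to
7 and 5 pairs at the template positions and let the D- and T-arms follow
the majority layout (an arm is dropped when at least half the sequences
lack its columns, as in D-armless tRNA-S1 and tRNA-V). The consensus
requires the majority-present column count to match a cloverleaf variant
of the family template exactly; alignments with odd insertion patterns
are rejected rather than guessed at.

The tree-free pairwise CBC matrix counts, for every taxon pair and stem
pair, a full compensatory difference (both positions differ, both duples
stable, no gaps); hemi differences are included when `fcbc_only = FALSE`.
FCBC-only is the default because the full changes are the
phylogenetically informative ones; the flag exists because the published
matrices do not always state which reading they used. tRNA-C, tRNA-Y and
tRNA-M are excluded by default from cross-species CBC analyses — in real
assemblies they flank repetitive control regions and are the most often
missing — and the exclusion is configurable.

Pairwise CBC counts between two taxa grow with their divergence: two
near-identical sequences show none. They are therefore dissimilarities,
and `hierarchical_cluster()` feeds a CBC matrix to `hclust()` directly
(complete linkage by default, the default of the heatmap tooling
standard in this literature; configurable). Treating the counts as
similarities inverts the clustering and produces anti-congruent
dendrograms, which is measurable as a negative Baker's γ against the
generating tree on simulated data.

Baker's γ compares two trees by the Spearman correlation, over all leaf
pairs, of the topological depth of the pair's lowest common ancestor
(number of internal nodes between it and the root). Depth is
topology-only, so a dendrogram and a phylogram compare without assuming
branch lengths; Spearman ties get average ranks; monotone transformations
of merge heights leave γ unchanged. The tanglegram untangles by greedy
child flips on both trees, alternating sides until no flip reduces the
crossing count — exact minimization is not attempted and the greedy
optimum is what is reported.

## Selection scan and dN/dS

The magnitude model enumerates every single-nucleotide nonsynonymous
codon pair under the code with equal weight (frequency weighting is
available as an option but the uniform baseline is the reproducible
default), takes the absolute property change of each replacement, and
bins it into 8 equal-width categories over the enumerated range
(left-closed bins, last bin closed; a constant property degenerates to
category 1). Categories 7–8 are "radical". Property values come from the
AAindex compilation shipped with seqinr — pK (COOH), accessibility
reduction ratio, proportion of residues 95% buried, isoelectric point,
surrounding hydrophobicity in folded form, average non-bonded energy per
residue, and average number of surrounding residues — with accession
numbers recorded in the documentation of `aa_property_table()`.

Replacements are read off the Fitch reconstruction codon-wise; a codon
differing at several positions is decomposed along minimal single-step
paths avoiding stop codons (paths through stops are used only when no
stop-free path exists), with ties averaged so weights may be fractional.
The gene-level statistic per property and category is
\(z_k = (o_k - Np_k)/\sqrt{Np_k(1-p_k)}\); `z > 3.09` (the one-sided
normal 0.001 point) in a radical category flags positive destabilizing
selection. The per-site track applies the same statistic inside a
sliding window, default 20 codons with step 1 — wide enough to
accumulate counts at mitochondrial divergences, narrow enough to
localize a signal; it is a display aid, not an inference unit. The
whole-tree substitution set is scanned by default; a branch subset can be
scanned by filtering the substitution table, which is the only role
branch labels play here.

ω = dN/dS uses Nei–Gojobori counting: per-codon synonymous site
fractions (a mutation to a stop codon counts as a nonsynonymous site),
pathway-averaged differences, Jukes–Cantor correction
\(d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\), undefined ω when dS = 0 and
`NA` at saturation (p ≥ 3/4). It is a pairwise counting estimate meant
for low-divergence comparisons and neutrality checks — it does not
replace likelihood branch-site machinery, which is out of scope by
design.

## The synthetic-data generator

The generator exists so that every stage has inputs with a known truth.
Its defaults emulate the study conditions of a 16-mitogenome amphipod
comparison:

* **Tree**: Yule (pure birth), 16 taxa, rescaled to a fixed *total* tree
  length (default 0.06 in event-rate units). Scaling by total length
  rather than height makes the expected whole-tree event count per stem
  pair exactly `rate × tree_length` whatever topology is drawn, which is
  what the recovery analyses need to control.
* **Stems**: pair states evolve as duples, not independent sites,
  because paired-site constraint is the object of study. FCBC events
  jump to a stable pairing differing at both positions; HCBC events
  change one base keeping stability; mismatch events change one base
  breaking it; indel events gap one position permanently. Default rates
  0.3 / 0.6 / 0.2 / 0.1 per pair per unit length give, at the default
  tree length, at most ~0.07 expected events per pair across the whole
  tree — the low-divergence regime in which parsimony recovers the
  logged events nearly one-to-one — with an FCBC:(HCBC+mismatch) balance
  of 0.375, close to the ratios reported for real amphipod tRNA stems.
  Root stem pairs are drawn slightly AT-leaning (stems around 63% A+T),
  loops at 78% A+T with rate 2.0 — the stem/loop contrast real tRNAs
  show.
* **Codons**: drawn independently from a distribution built from
  per-position base weights (defaults are the plus-strand positional A+T
  fractions and skews typical of these mitogenomes: A+T 60.6/63.7% at
  positions 1/2, GC3 0.277, AT-skews −0.047/−0.405/−0.169, GC-skews
  0.282/−0.063/0.135), with stop codons excluded and the third-position
  G+C calibrated exactly to the target by a one-dimensional root solve.
  Translations therefore never contain internal stops, and the truth log
  records the exact positional expectations of the realized
  distribution for sampling-error tests.
* **Toy genome**: the pancrustacean ground-pattern arrangement (23 plus-
  and 14 minus-strand genes), protein genes wrapped in ATG…TAA, tRNAs on
  cloverleaf templates (D-armless tRNA-S1/tRNA-V), AT-rich rRNAs and
  control regions.

What the generator does **not** emulate: rate heterogeneity across sites
and lineages, selection-driven codon usage, realistic indel length
distributions, alignment error (alignments are emitted aligned),
annotation error, and epistasis beyond the pair constraint. Passing
tests therefore demonstrate that the statistics and classifiers are
correct and that the pipeline recovers a known truth in its validated
regime — not that parsimony reconstruction is unbiased on deeply
diverged real data, where multiple hits make it conservative.

## Problem sizes and determinism

The test suite and the acceptance script use desk-scale sizes chosen to
make each comparison statistically meaningful: brute-force parsimony
oracles on 4–6 leaves; breakpoint/block enumeration up to 12 genes;
event recovery pooled over 8 replicate 16-taxon, 22-family datasets
(FCBC/HCBC counts in the tens to low hundreds, so a 10% comparison is
not dominated by single events); clustering congruence at total tree
length 0.3, where pairwise per-tRNA CBC counts reach the magnitudes seen
in real comparisons (γ and the tanglegram are tree-free statistics with
no low-divergence requirement); a 10,000-replicate Monte-Carlo null for
the Z threshold with N = 1000 replacements per replicate, keeping the
normal approximation sound for the radical-category probabilities
(0.01–0.06). Every stochastic step is driven by an explicit integer
seed, and the same seed reproduces every number exactly.

## Known limitations

* Parsimony cannot polarize events across the root edge; category
  tallies on the two root-adjacent branches can trade places with each
  other.
* The consensus cloverleaf requires the majority layout to match a
  template variant exactly; highly irregular alignments are rejected.
* Scenario search is exact only within its bound (2 events at full
  genome size); it reports the breakpoint distance when the bound is
  exceeded.
* The greedy tanglegram untangling is a local optimum.
* ω from pairwise counting saturates quickly and is undefined without
  synonymous divergence; it is a sanity statistic, not a substitute for
  codon-model likelihoods.
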