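---
title: "Methods: pan-genome inference, replicon statistics and Ka/Ks in pancore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome inference, replicon statistics and Ka/Ks in pancore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancore)
```

# Scope and model

`pancore` implements the comparative analysis used to characterise the shared
and strain-specific gene complement of multi-replicon bacteria such as
*Azospirillum*: genomes of 6-8 Mbp split over six or seven replicons, where
only the largest replicon carries an oriC-type chromosomal replication
origin, and the remaining repABC replicons are either chromids (plasmid-type
replication but carrying essential genes) or true plasmids. The pipeline has
four analytical layers:

1. **Replicon statistics** — per-replicon size/GC/ORF summaries with exact
   TOTAL rows, the extra-chromosomal genome fraction, and a rule-based
   chromosome/chromid/plasmid classifier.
2. **Protein families** — an all-vs-all protein comparison feeding a
   similarity graph that is clustered with Markov clustering (MCL), plus the
   genome-membership (Venn) partition and strain-unique proteins.
3. **Core genomes** — reciprocal-best-hit (RBH) orthologue groups under
   strict coverage/similarity floors; the ingroup core (groups present in
   every ingroup genome) and the ancestral core (the same construction with
   a deep outgroup added).
4. **Selection** — Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
   over core groups, restricted to the replicon-consistent subset, with an
   ordinary-least-squares Ka-vs-Ks regression per subset.

All four layers are exercised end-to-end on a synthetic pan-genome generator
with known ground truth, which is a first-class, tested component rather
than a fixture.

# Similarity search and e-values

Pairwise protein comparison is exact Smith-Waterman local alignment under
affine gaps (a gap of length $L$ costs $o + L\cdot e$), scored with BLOSUM62
(family layer) or BLOSUM80 (orthology layer, defaults $o=10, e=1$; BLOSUM62
uses $11/1$). `X` is accepted and scored 0. Raw scores are converted with
ungapped Karlin-Altschul statistics,

$$E = K m n e^{-\lambda S}, \qquad S' = \frac{\lambda S - \ln K}{\ln 2},$$

where $\lambda$ is calibrated at run time as the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ (residual $<10^{-9}$) under
Robinson-Robinson background frequencies, and $K$ is the published ungapped
constant for each matrix (0.134 / 0.177). Calibration reproduces the widely
tabulated ungapped values ($\lambda \approx 0.3176$ for BLOSUM62, 0.3430 for
BLOSUM80). Gapped-parameter estimation is deliberately out of scope: only
the threshold behaviour at the pipeline's cutoffs ($10^{-7}$ for the family
graph, $10^{-12}$ for orthology, $10^{-6}$ for exclusivity) matters, the
thresholds are configuration-exposed, and externally computed hit tables in
the standard 12-column tabular format can be substituted via
`readHitTable()`. $n$ is the raw residue count of the subject proteome — no
effective-length edge correction — and this is documented behaviour, not an
approximation the results are sensitive to at these cutoffs.

The all-vs-all driver aligns each unordered pair once and emits both
directed hits. By default a shared-k-mer prefilter (word size 5, at least 2
shared words) selects candidate pairs; unrelated random proteins of a few
hundred residues share on the order of 0.02 five-mers by chance, so the
filter removes essentially only pairs that could never reach the reporting
threshold. `method = "exact"` aligns every pair and is the mode the
dynamic-programming oracle tests run against. Best-hit ties are broken by
bit score, then e-value, then lexicographic subject id, so output is
byte-reproducible.

# Families: MCL on the similarity graph

Edges connect genes with any hit at $E \le 10^{-7}$; the weight is
$\min(200, -\log_{10} E)$ of the best direction (capping keeps $E = 0$
finite). Hits between two genes of the same genome are kept by default, so
in-paralogs cluster together; a flag drops them. MCL is implemented in the
package: self-loops equal to each node's maximum incident weight, column
normalisation, expansion (matrix squaring) alternating with inflation
(entrywise power, default 1.2) and renormalisation, pruning entries below
$10^{-5}$, convergence when the largest entry change drops below $10^{-6}$,
iteration cap 200 (exceeding it is an error, not a silent stop). Clusters
are read from the attractor structure; nodes joining several attractor
systems go to the largest-weight attractor, ties to the lexicographically
smallest. The computation runs per connected component, which changes
nothing mathematically but keeps the matrices small. Clusters with at least
two members become families regardless of genome composition; singletons
are reported per genome. Strain-unique proteins are a *distinct* report
(no cross-genome hit at $E < 10^{-6}$), because family non-membership and
hit-based exclusivity are different notions and both are useful.

# Orthology and core sets

A pair $(a, b)$ across genomes $A, B$ is an orthologue candidate iff $b$ is
$a$'s best hit in $B$ and vice versa, and both directional hits satisfy:
e-value $\le 10^{-12}$ under BLOSUM80, aligned region $\ge 75\%$ of *both*
sequences, and similar (positive-scoring) residues $\ge 35\%$ of *both*
lengths. "Similarity" is implemented as positives with an identities-based
switch, and single-sided coverage is available. N-way groups are assembled
in *clique* mode by default — every genome pair in the tuple must be an RBH
pair — because the target is the most conservative mutually-consistent set;
a connected-component mode is provided for comparison and is provably a
superset. Since each pairwise RBH relation is a matching, clique extraction
is deterministic; seeds are processed in descending total bit score.

The ingroup core is the set of groups spanning all ingroup genomes. Running
the same construction with a deep outgroup genome added yields the
ancestral core; ingroup-core groups absent from it are the genus-specific
core. On synthetic data the ancestral core is a subset of the ingroup core
by construction; on real data this containment is reported but not
enforced. Origin labels (ancestral / HGT / unassigned) and COG letters are
consumed from the annotation input, never computed; a group's origin is the
majority vote of its members (ties fall to unassigned), and COG tabulation
uses one reference genome's member per group, taking the first letter when
several are listed.

# Ka/Ks

Site counting follows Nei-Gojobori: each codon position contributes
(number of synonymous one-step changes)/3 to the synonymous site count,
changes creating stop codons never count as synonymous, and
$S + N = 3L$ holds exactly. Sites are averaged between the two sequences.
Differences at codons with multiple substitutions are averaged over all
substitution orderings, excluding orderings that pass through a stop codon
(in the rare case that every ordering is blocked, all orderings are used
and steps through stops count as nonsynonymous). Proportions are corrected
with Jukes-Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$; $p \ge 3/4$ is
reported as `saturated`, and $S=0$ or $N=0$ with differences present as
`undefined`; both are excluded from regressions and group means but
counted. The genetic code is the bacterial table, which is identical to the
standard code for synonymous/nonsynonymous counting.

NG86 was chosen over the multi-model averaging of dedicated Ka/Ks software
because it is fully specified, fast enough to run over thousands of pairs
in tests, and sufficient for the analysis's qualitative use — negative
selection classification and the Ka-vs-Ks regression. The estimator sits
behind a small interface (`ng86()` on a `CodonAlignment`) so other counting
methods can be added. Because the aggregation level of published Ka/Ks
scatter plots is typically unstated, both per-pair estimates and per-group
means are reported; per-pair is the default plotted set.

The regression subset is the replicon-consistent core: groups whose members
are chromosomal in every genome, or non-chromosomal in every genome; mixed
groups are excluded. This mirrors the published analysis design and avoids
averaging over replicon-transfer events.

# The synthetic pan-genome generator

The generator emulates the statistical structure the pipeline is meant to
detect, with defaults chosen once to represent the study conditions:

* 4 ingroup genomes, 750 genes each over six replicons (one oriC
  chromosome, five repABC replicons), mean gene length 250 codons
  (sd 20%, floor 60) — a desk-scale stand-in for 6-8 Mbp genomes that
  preserves the *relative* composition signals.
* 600 core families present once per genome, 65% homed on the chromosome
  and the rest on the chromid replicons, consistently across genomes (the
  published repartition is 62-65% chromosomal).
* Core origin composition fixed at 74% ancestral / 22% HGT / 4% unassigned
  — exactly the published core composition. HGT families are drawn from a
  separate ancestral pool that the outgroup never carries, so the ancestral
  core excludes them by construction and is ~95% ancestral, as observed.
* 200 accessory families, each carried by exactly two genomes (balanced
  pairing so every genome carries the same accessory load — this exactness
  is what lets emitted per-replicon gene counts match the replicon plan,
  which is asserted, not approximated), concentrated outside the chromosome
  (80% of accessory and 70% of unique genes are extra-chromosomal under the
  defaults, matching the published ">60% outside the chromosome").
* 50 strain-unique genes per genome: random codon sequences with no
  ancestry, so they must fail every similarity threshold.
* HGT genes are sampled at a GC depressed by 0.05 relative to their
  replicon target — GC is the only compositional signal used downstream.
* Essential-gene flags are placed on core families per replicon
  (defaults 60 on the chromosome, 8/3/2 on the chromids), because chromid
  classification *requires* essential genes on repABC replicons; a plan
  with zero essential genes on a replicon makes it a plasmid.

Sequences evolve from one ancestral CDS per family, drawn codon-by-codon
from a stop-free codon distribution fitted to the replicon's target GC.
Each genome applies an expected `branch_sub_rate` (default 0.05) proposed
single-nucleotide changes per site: synonymous proposals are always
accepted, nonsynonymous proposals are accepted with probability `omega`
(0.2 for core, 0.4 for accessory), and proposals creating internal stops
are rejected. Core genes receive no indels, keeping codon alignment of core
pairs trivial, exactly as NG86 assumes; accessory copies receive a short
in-frame indel with probability 0.1.

**Why the proposal kernel has no transition bias by default.** The `omega`
knob is meaningful only relative to the estimator: NG86 counts sites
assuming all three changes at a position are equally likely. A
transition-biased kernel (`tstv > 1`) hits two-fold degenerate third
positions — where transitions are synonymous — disproportionately often, so
the acceptance-probability omega no longer equals NG86's omega: at
`tstv = 2` the estimate of a neutrally evolving gene is biased down to
roughly 0.85. With `tstv = 1` (the default) the kernel matches the
counting assumption and the calibration is clean: at `omega_core = 1` and
the default branch length, the mean NG86 estimate over 320 groups is 0.999,
and at `omega_core = 0.2` it is 0.203 with every group classified under
negative selection. `tstv` remains configurable for users who want a
realistic mutation spectrum and accept that NG86's omega then measures a
different quantity.

One estimator subtlety surfaces in testing: with `omega_core = 0` the
proteins of a family are strictly identical, yet pathway averaging can
attribute *fractional* nonsynonymous differences when two synonymous
substitutions hit the same codon on different branches (e.g. CGA to AGA and
CGA to CGC meet as AGA/CGC, one of whose two orderings passes through
serine). Ka is therefore bounded near zero rather than identically zero,
and the tests assert exactly that.

The generator does **not** simulate intergenic DNA, operons,
rearrangements, IS elements or prophages; replicon lengths and GC are
derived from the gene complement plus random intergenic gaps. Consequently,
passing tests demonstrate correct recovery of family/orthology/origin/
selection structure under clean vertical descent with known noise — they do
not demonstrate robustness to fragmented assemblies, domain shuffling,
pervasive paralogy or rate heterogeneity, which real data contain.

# Numerical and design choices

* Percentages mirror printed precision: half-up rounding, one decimal for
  extra-chromosomal fractions, integers for shared-family and core
  fractions.
* GC content excludes ambiguous bases from numerator and denominator.
* GC-closeness to the chromosome (tolerance 1.5 percentage points) is
  computed and reported by the replicon classifier but is *advisory*:
  published chromid assignments retain replicons that fail it, so essential
  genes decide.
* Coordinates are 1-based inclusive; CDS files carry a terminal stop codon,
  which is trimmed on read; stored CDS are exactly 3x protein length.
* Determinism everywhere: lexicographic node ordering in MCL, explicit
  best-hit tie-breaks, seeded generation; identical configs give
  byte-identical FASTA/TSV output.
* Problem sizes in the test-suite: module tests run a 40-family
  mini-pan-genome; the recovery tests run the full default configuration
  (600 core families, four genomes plus outgroup) once and the neutral
  calibration over 320 groups — sizes chosen as the smallest at which the
  sampling error of the asserted rates is comfortably below the asserted
  tolerances.

# Known limitations

* E-values use ungapped Karlin-Altschul parameters with gapped alignments;
  absolute e-values are therefore conservative relative to gapped-calibrated
  ones. Thresholds are exposed, and external search output can be
  substituted.
* The k-mer prefilter can, in principle, miss a true-positive pair with
  pathological composition; exact mode exists and the tests compare the two.
* NG86 underestimates omega under transition-biased mutation and does not
  model rate variation among sites; saturated pairs are excluded rather
  than modelled.
* Chromid classification consumes essential-gene flags from the annotation;
  it does not perform marker-gene detection.
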