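---
title: "Methods: screen scoring, repertoire networks and IgHV replacement detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen scoring, repertoire networks and IgHV replacement detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphoscreen)
```

`lymphoscreen` implements the bespoke computations of ex vivo lymphoma
modelling in primary human germinal-centre (GC) B cells: pooled CRISPR
knockout screen scoring, barcoded-construct competition readouts, B-cell
receptor (BCR) repertoire network analysis with cluster-enforced subsampling
and parsimony clonal trees, and IgHV gene-replacement detection. This
vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## CRISPR screen scoring

For guide $i$ of gene $g$ at timepoint $t$ in replicate $r$, raw counts
$N_{igtr}$ are normalised per sample,

$$F_{igtr} = \frac{N_{igtr}}{\sum_i N_{igtr}},$$

the per-guide log2 fold change between a late culture sample $L$ and the
plasmid library $P$ is z-standardised within each replicate,

$$\mathrm{sgRNA}_{\Delta igr} = \log_2 \frac{F_{igrL}}{F_{igrP}}, \qquad
Z_{igr} = \frac{\mathrm{sgRNA}_{\Delta igr} - \overline{\mathrm{sgRNA}_{\Delta r}}}{\sigma_{\mathrm{sgRNA}_{\Delta r}}},$$

and the per-gene CRISPR score averages the z-scores over the gene's $L_g$
guides and the $R$ replicates,

$$\mathrm{score}_g = \frac{1}{R\,L_g} \sum_{r=1}^{R} \sum_{i=1}^{L_g} Z_{igr}.$$

Positive scores mean knockout confers a fitness advantage
(tumour-suppressor-like), negative scores depletion (oncogene-like).

Choices that the formulas leave open, and how this package resolves them:

* **Summation of the gene score.** The displayed normalisation $1/(R L_g)$
  only makes sense as a mean over the full guide-by-replicate grid; the
  double-sum reading above is used.
* **Standard deviation.** $\sigma$ is the population standard deviation
  (divisor $n$) over *all* guides of the replicate, non-targeting controls
  (NTCs) included. Including NTCs makes the null centring conservative; the
  population divisor matches the "Z-score of the observed set" reading.
* **Pseudofrequency.** Zero counts make the log ratio infinite. The default
  adds `0.5 / median(sample depth)` inside both numerator and denominator —
  half a read at the typical depth — which caps the dynamic range without
  distorting mid-abundance guides. It is exposed as a parameter; with
  `pseudofreq = 0` guides at zero plasmid frequency are dropped with a
  warning. Exact-arithmetic comparisons in the test suite use
  `pseudofreq = 0`.
* **One late timepoint per scoring run.** Multi-timepoint screens are scored
  per timepoint independently against the single shared plasmid reference.
* **Missing guides are an error.** A library guide absent from the count
  matrix indicates a broken upstream join, not a zero observation.

`library_uniformity()` reports the fraction of guides within a fold band
(default four-fold) of the mean frequency $1/m$, the standard QC for library
synthesis skew.

Screen-design arithmetic: `cells_required(n_guides, coverage, fraction)`
is $\lceil n \cdot c / f \rceil$ (a 6000-guide library at 1000-fold coverage
and 30% transduction needs $2\times10^7$ cells); `dna_plan()` converts cells
to genomic DNA at 6.6 µg per $10^6$ human cells and splits it into PCR
reactions under a strict 10 µg/reaction ceiling. The ceiling is strict even
for sub-microgram overflow — the per-reaction mass is stated as a maximum —
so $2\times10^7$ cells give 132 µg and 14 reactions.

## The synthetic screen generator

No generative model for the selection process is prescribed by the readout
formulas, so the generator uses the simplest model under which the scoring
chain is a consistent estimator of the gene effect:

* the realised library composition is Dirichlet around the uniform design —
  each guide's weight is Gamma with shape `1/plasmid_dispersion`, so the
  default `0.1` gives a shape of 10 and keeps ≈99% of guides within
  four-fold of the mean, matching what a well-synthesised library looks
  like;
* each guide has a knockout efficacy drawn once from Beta(8, 2) (most guides
  cut well, a tail does not); NTC efficacy is identically zero;
* the culture frequency of guide $i$ at day $t$ is proportional to its
  library frequency times $e^{\epsilon_i s_g t}$ with $s_g$ the gene's
  selection coefficient per day;
* every sequenced sample is an independent multinomial of
  `depth_per_sample` reads (default $6\times10^6$, i.e. 1000-fold coverage
  of the default library).

Defaults are `timepoints = c("d21", "d70")` with three replicates, matching
a screen read out at day 70. The planted-effect benchmark
(`planted_screen_config()`) plants ten genes at $s = +0.3$/day and ten at
$-0.3$/day; at day 70 the positively selected guides dominate the library,
which is the regime the real screens show (strong takeover by the top
hits). What this generator does *not* emulate: PCR amplification bias, UMI
structure, copy-number effects on cutting toxicity, or guide-level
off-target effects. Passing the recovery benchmarks therefore shows the
scoring chain is correct and well-calibrated under sampling and
overdispersion noise, not that it is robust to every artefact of real
screens.

The barcode-competition generator uses the same exponential-competition
structure at clone level; `noise = "none"` returns expected counts
(frequency × depth, deliberately not integerised) so the two-type logistic
trajectory can be verified to $10^{-9}$, and the multinomial/Dirichlet path
returns integer counts.

## BCR repertoire networks

Vertices are unique sequences weighted by read multiplicity; edges join
sequences at Hamming distance exactly 1 with equal length (single-nucleotide
non-indel differences — the strict reading; no indel-tolerant edges);
clusters are connected components, numbered by decreasing size with ties
broken by the lexicographically smallest member so that IDs are stable.
Sequences containing `N` stay in the vertex set but are excluded from edge
building (an `N` is an ambiguity, not an observed substitution); their count
is reported on the graph object.

Edge construction buckets sequences by their string with one position
masked: two unique equal-length sequences share a bucket if and only if they
differ exactly at the masked position, so the union over positions is
extensionally the all-pairs Hamming-1 edge set without the $O(n^2)$ scan.
The test suite checks that equality against a brute-force oracle on random
instances.

Clonality is summarised by the percentage of unique sequences (low =
expanded), the largest cluster, and the cluster-size distribution. The
clone-size law of the generator is a truncated discrete power law; its
exponent is the expansion dial (1.5 = aggressively expanded, 3 = mostly
singletons) and the default 2 sits between.

### Cluster-enforced linkage (CC) subsampling

The CC scheme downsamples a network to `n_target` vertices while keeping
the clonal structure legible. Three published steps leave their details
open; the package resolves them as follows and treats each attempt as:

1. **Vertex selection.** Vertices are drawn without replacement with
   probability proportional to vertex size (reads) — the method aims to
   preserve clonal structure, and clone mass is what the eye should see; a
   `weight = "uniform"` mode is provided. The draw is repeated (up to 100
   times) until every original cluster is represented; if rejection fails, a
   constructive draw takes one weighted vertex per cluster and fills the
   remainder. When `n_target` is below the cluster count, the largest
   clusters are prioritised, one vertex each.
2. **Cluster-vertex migration.** Within each cluster holding ≥2 selected
   vertices whose induced subgraph is disconnected, the selection is
   replaced by a breadth-first prefix (deterministic neighbour order: size
   descending, then sequence) of the same cardinality grown from the largest
   selected vertex. A BFS prefix is always connected, stays inside the
   cluster, and preserves the selected count.
3. **Induced graph formation.** Total induction: every original edge with
   both endpoints selected is kept.

Twenty attempts are made (`repeats = 20`) and the attempt whose maximum
sampled cluster size is closest to the original maximum scaled by the
sampling fraction `n_target/|V|` is retained, ties to the earliest attempt.
The unscaled original maximum cannot be "most closely represented" under
subsampling in absolute terms, so the fraction-scaled target is the
comparison; this is a declared choice, not an inference of the original
intent. Everything is deterministic given the seed.

### Parsimony clonal trees

Within-cluster lineage trees are unrooted maximum-parsimony trees with
integer branch lengths (substitution counts). Up to `max_exhaustive = 8`
leaves, every unrooted topology is enumerated and Fitch-scored and a
minimum-score tree returned; above that, a neighbour-joining start on
Hamming distances is refined by nearest-neighbour interchange. Branch
lengths are ACCTRAN assignments and sum to the parsimony score (asserted at
construction). The three-taxon case is handled directly — per column, one
change on the odd leaf's branch, or two changes when all states differ —
because ACCTRAN on the multifurcating three-star can over-assign. Two-leaf
trees are written as `(A:d,B:0);` with the full Hamming distance on the
first branch. The standard phylogenetics machinery (topology enumeration,
Fitch scoring, NNI search) is delegated to `phangorn`; the test suite
checks both search modes against an independent hand-written
enumeration-plus-Fitch oracle.

## IgHV replacement detection

The stem of an annotated BCR is the N-IgHD-N-IgHJ region starting 3 bp
downstream of the IgHV boundary (0-based suffix from `v_end + 3`). Records
whose N-D-N-J span is shorter than 8 nt are excluded first, since very short
joins can be germline-encoded. Unique BCRs are grouped by exact stem string
(no fuzzy matching — "sharing stem regions" with no stated tolerance), and
a pair within a group is a replacement event when:

* the V calls differ **and** the pairwise V-region identity is below 95% —
  the ">95% difference in sequence identity" phrasing is read as identity
  below the threshold, the only reading consistent with "different IgHV
  gene usage"; the threshold is a parameter;
* the 5′ junction strings (last 3 nt of V + N-D-N-J) differ.

Identity is the percentage of matching columns in a global alignment with
unit match/mismatch and unit linear gap costs; the argument pair is
canonicalised before aligning so co-optimal alignments cannot break
symmetry. The replacement percentage divides the unique BCRs participating
in at least one pair by the unique BCRs **after** the junction exclusion
(the denominator is ambiguous in prose; post-exclusion is used and
declared). `n_events` counts stem groups containing at least one qualifying
pair, which is the quantity compared against the generator's planted truth.

In the AIRR-style interface the `junction` column carries the last 3 V
nucleotides plus the N-D-N-J region, so `junction_length` is the span plus
3; coordinates are 0-based half-open. Annotations are consumed, never
computed: real data should come from an external V/D/J annotator.

The repertoire generator plants replacements as a second sequence family
with the identical stem, a different germline V (the synthetic germline set
is generated with pairwise identity below 90%, so discordant calls imply
discordant sequence) and an altered 5′ junction. Somatic hypermutation is
uniform per-base substitution with no hotspot bias and no indels (the
network only uses substitution differences) and may hit stems; a planted
event escapes detection only when *every* read of a family carries a stem
mutation, which at the default `shm_rate = 1e-3` is rare — the recovery
benchmark allows ±2 events for exactly this. The default junction span range
is 8–32 nt (real N-D-N-J joins are rarely shorter than 8 nt once a D segment
is present).

## Problem sizes and determinism

Every generator takes an explicit integer seed and identical seeds give
byte-identical outputs. The packaged benchmarks run at the design scale of
the screen (6000 guides × 7 samples at $6\times10^6$ reads each; 20 seeds
for the null calibration) and at moderate repertoire scale (≈250 clones,
≤500 unique sequences for the edge-oracle check; 50 seeds × 5 attempts for
the subsampling invariants; 100 random 4–6-leaf clusters for the parsimony
cross-check), sizes at which every property above is exercised while the
whole suite stays interactive.

## Known limitations

* The selection model behind the screen generator is a stand-in chosen for
  estimator consistency, not an inference of the biology; absolute score
  magnitudes from simulated screens should not be read as effect sizes.
* Gene scores come without p-values or FDR, by design; ranking is the
  output.
* The repertoire generator produces equal-length sequences per clone family
  (no indels), so the non-indel edge rule is never stressed by real indel
  artefacts.
* `NA`-handling in scoring is limited to the declared zero-plasmid drop
  path; other missingness should be cleaned upstream.
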