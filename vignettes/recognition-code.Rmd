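---
title: "Inferring a protein-DNA recognition code from local regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a protein-DNA recognition code from local regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Helix-turn-helix (HTH) regulators of the LacI type bind 14-bp palindromic
operators as dimers. Within such a family, a small number of residues of
the recognition helix make base-specific contacts, and the question this
package addresses is whether those contacts follow a consistent,
family-wide *recognition code*: a mapping from the residues at the
specificity positions (alignment columns 15 and 16 of the fixed 71-column
domain frame) to the bases at the specificity positions of each operator
half site (positions NT-5 and NT-4, counting the half site from its outer
position 7 inward to 1).

Instead of orthology-based phylogenetic footprinting — fragile at large
evolutionary distances — binding sites are searched where prokaryotic
regulators usually act: *locally*. For each regulator the strict
non-coding region upstream of its own operon (autoregulation, at most
200 bp) and optionally the region before the downstream operon are
searched. Regulators sharing the same specificity residue pair form a
*recognition class*, and each class's regions are pooled for motif
discovery, regardless of the phylogenetic distance between its members.

`footcode` implements the full procedure — class partitioning,
palindromic Gibbs site discovery, iterative PWM refinement against an
empirical null, mutual-information screening of specificity positions,
and degeneracy classification — together with a synthetic-data generator
that plants a known code so that every stage can be scored against
ground truth.

## Pipeline stages

### 1. Domain curation and recognition classes

Domains arrive as a pre-aligned set in a fixed column frame (external
aligners build the alignment; this package consumes it).
`filterDomains()` keeps sequences whose ungapped length falls in an
inclusive range (default 45–75 residues, configurable) and, optionally,
that carry the annotated core HTH domain; `dedupeDomains()` collapses
identical sequences (strain redundancy) keeping the first id in sorted
order; `dropGappyColumns()` removes columns with a gap fraction strictly
greater than 0.80. `partitionClasses()` restricts to the dominant
recognition-helix subgroup (columns 17–20 equal to T,V,S,R by default)
and partitions the rest by the residue pair at columns 15 and 16.

### 2. First site scan: a palindromic Gibbs sampler

`gibbsSearch()` runs a collapsed Gibbs sampler over the pooled strict
regions of one class with a zero-or-one site per region occupancy model
and a width-14 motif constrained to equal its own reverse complement
(the count matrix is averaged with its reverse complement at every
predictive computation).

Three numerical choices matter:

* **Occupancy prior.** The sampler parameter "expected number of sites
  equals the number of regions" is implemented the way site samplers
  parameterize it: each window carries prior probability
  `expectedSites / total windows` of starting a site, giving prior odds
  `pi/(1-pi)` for any window against region emptiness. Read naively as a
  per-region Bernoulli prior, an expectation equal to the region count
  would force occupancy probability 1 and make site absence unreachable;
  the per-window form keeps absence at real prior mass while preserving
  the stated expectation in the untruncated model.
* **Phase-shift move.** After each sweep the whole site configuration is
  translated by k in −5…5, with k sampled proportionally to a collapsed
  configuration score (palindrome-symmetrized Dirichlet-multinomial
  marginal of the count matrix, minus the background likelihood of the
  covered bases). Per-region resampling alone cannot leave a
  shifted-register mode — a standard motif-sampler pathology that is
  acute here because palindromic operators with repeated semisequences
  (e.g. a TT half-site pair) are self-similar at offsets of several
  base pairs.
* **Confidence.** The reported start of a region is the modal sampled
  start over all post-burn-in sweeps pooled across chains (leftmost on
  ties), and its confidence is the fraction of those samples placing a
  site within 2 bp of it. Sites under the confidence cutoff (default
  0.40) are discarded. Defaults: 5 chains, 2000 sweeps, 500 burn-in.

### 3. Second search: iterative PWM refinement

`refineSites()` rebuilds the motif as a position weight matrix with a
constant pseudocount `B` (cell frequency `(count + B/4)/(N + B)`,
default `B = 1`), scans the *extended* 250-bp regions (which append the
first 50 coding positions) for all windows scoring at least the weakest
seed site, and then iterates: draw `N_null` scores (default `1e5`;
benchmark runs use `2e4`) by sliding the PWM over mononucleotide-shuffled
copies of the regions; keep candidates with add-one empirical p-value
`(1 + #{null ≥ s})/(1 + N_null)` below `alpha` (default `1e-3`); resolve
overlapping survivors within a region greedily best-score-first,
suppressing overlaps of at least half a site; rebuild the PWM and rescore.
Iteration stops at the first repeated kept set. Multiple sites per region
and sites in the coding extension are allowed at this stage. Final sites
carry Z-scores against the last null; `zscoreFilter()` applies the floor
(default 4). The candidate score threshold is held fixed at the seed
minimum across iterations (with a 1e-9 slack so the weakest seed cannot
drop out through floating-point summation order).

### 4. Mutual information

`miMatrix()` computes the plug-in mutual information (base 2) between
every domain-alignment column and every site-alignment column, pairing
rows through regulator ids. Gapped pairs are dropped (pairwise deletion,
not a 21st symbol: gaps are rare at the specificity columns after
curation); a constant column yields exactly 0 bits; no small-sample bias
correction is applied by default (a Miller–Madow variant sits behind the
`correction` flag), matching the qualitative use of the ranking. Ties in
`topMICells()` break by (AA index, NT index). `miPermutationNull()`
provides the shuffled-pairing reference distribution for the matrix
maximum.

### 5. Degeneracy classification

Each site contributes one *quartet*: the (NT-5, NT-4) dinucleotide of the
left half site read on the sense strand and of the right half site read
on the complementary strand, reduced to an unordered pair. The 16
dinucleotides give 136 cells (16 palindromic + 120 mixed); counts over a
class's sites form the F matrix, and cells significantly over-represented
against the background expectation (binomial upper tail with
`p = 2 q_a q_b`, or `q_a²` on the diagonal; Benjamini–Hochberg at FDR
0.05) form the S matrix.

Classification then proceeds in three steps. (1) For every pair of
significant palindromic cells, the expected mixture count under
independent half-site pairing is `2 r_a r_b n`, with half-site
frequencies `r` estimated from palindrome counts only; mixtures
significantly *below* that expectation (binomial lower tail, BH at the
same FDR) mark an **extrinsic** degeneracy — two sub-populations of
regulators with distinct specificities hiding inside one class. (2)
Extrinsic pairs disconnect the semisequence graph; connected components
of the remaining significant cells form blocks. (3) Within a block, a
palindrome whose count significantly exceeds the block's uniform
expectation (binomial upper tail on the block maximum, Bonferroni-
corrected by the number of candidate dominants, BH across blocks) makes
the block an **asymmetric intrinsic** degeneracy with arrows minor →
dominant; otherwise the block is **symmetric intrinsic**. The Bonferroni
factor exists because the tested statistic is the block *maximum*: the
naive tail is k-fold anti-conservative and measurably over-calls
asymmetry on symmetric data. The symmetric label is the null-model
outcome — it is what remains when no significant structure is found
within a block — so "power" statements about the classifier refer to the
two departure scenarios (extrinsic and asymmetric), whose detection
probability grows with the number of sites.

Sites of width 15 carrying the central inserted base of asymmetric
natural operators are normalized by `dropCentralInsertion()` before
quartet extraction.

### 6. Code table

`assembleCodeTable()` joins classes, final sites and relations into one
table: per class the significant palindromic (NT-5, NT-4) associations
with their counts, the relation annotations, and the reporting triad
(regulators in the class / regulators with at least one site / total
sites). `consensusLogo()` builds the family-level logo from one majority
consensus per class — deliberately ignoring class sizes, so heavily
populated classes cannot dominate the picture; consensus ties break
alphabetically and are flagged.

## The synthetic generator

`generateFamily()` emulates the family structure: a gapless 71-column
alignment whose specificity columns carry each class's planted residue
pair, whose recognition-helix columns 17–20 are fixed to TVSR and whose
hinge-helix columns 51 and 54 are fixed to A and L; all other columns
draw from a per-column random consensus with conservation sampled
uniformly between 0.5 and 0.9 (prokaryotic domain alignments are largely
conserved outside the variable specificity positions; the range keeps
plug-in MI estimates of background columns well below planted signals at
the benchmark sample sizes).

`generateRegions()` plants, with probability `siteRate`, one 14-bp site
per strict region on the conserved operator backbone
T G · · A · C | G · T · · C A (NT-6 G and the central CG fixed, NT-7 and
NT-3 matching with probability 0.9, NT-2 free), with the (NT-5, NT-4)
semisequences drawn from the class's code entry under its degeneracy
spec. Extended regions embed the strict region at offset
`200 − regionLen` and append 50 coding-zone positions, both drawn from
the background (uniform by default, configurable to skewed
compositions). The background composition of real genomes is not stated
in the source conditions; uniform is the neutral stand-in and the
parameter is exposed.

Two parameterizations coexist deliberately:

* in `generateRegions()`, an asymmetric-intrinsic class plants the
  dominant palindrome with site-level probability `dominant_prob` and
  splits the residual mass uniformly over the two ordered mixtures and
  the minor palindrome (so the dominant-palindrome fraction is exactly
  `dominant_prob`);
* in `generateDegeneracySites()`, the `preferential` scenario draws the
  two half sites independently with per-half-site preference
  `dominantProb` (so equal preference gives the exact 1/4–1/4–1/2
  palindrome/palindrome/mixture split of the `both_high_affinity`
  scenario, and preference 1 removes mixtures entirely).

The generator does **not** emulate operon structure, gene annotation,
phylogenetic divergence along a tree, dimer energetics, or non-uniform
site placement within regions. Passing benchmarks therefore demonstrates
that the algorithms recover what they assume — planted palindromic sites
over an i.i.d. background — not that real intergenic sequence satisfies
those assumptions.

## Benchmark problem sizes

The shipped benchmarks run 6 classes × 8 regulators with site rate 0.8
over 150-bp strict regions, swept over 10 seeds (site recovery and code
assembly); 100 replicates per degeneracy scenario at 40 sites with power
curves at 10/40/160; 20 seeds for the mutual-information ranking; and
`2e4`-score nulls inside the pipeline runs (`1e5` remains the package
default for nulls used in isolation). These sizes put every recovery
criterion comfortably in its asymptotic regime while keeping a full
benchmark run in the low minutes on one core.

## Known limitations

* The spurious-nucleotide post-filter applied in the original protocol
  after refinement is not specified there and is exposed only as the
  `sitePredicate` hook of `refineSites()`.
* The plug-in MI estimator is biased upward for high-entropy column
  pairs at small n; the ranking use is robust to this, absolute values
  are not.
* Degeneracy calls on classes with few sites are power-limited (a
  single site can never reach significance against a 1/256 background
  expectation); the classifier reports nothing rather than guessing.
* The Gibbs confidence is a sampling frequency under one fitted model,
  not a posterior probability of site presence.
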