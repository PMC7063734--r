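---
title: "Detecting CLL-biased stereotyped rearrangements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CLL-biased stereotyped rearrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereorep)
```

## The problem

Roughly a third of chronic lymphocytic leukemia (CLL) clones carry
quasi-identical B-cell receptor immunoglobulins. These *stereotyped*
receptors are grouped into subsets, each defined by an amino-acid motif at
a fixed position within the heavy-chain CDR3, a fixed CDR3 length, and
IGHV genes from one phylogenetic clan. Whether normal B cells carry such
CLL-biased stereotyped rearrangements (CBS-IG), and in which B-cell
compartments, bears directly on where CLL clones can originate.
`stereorep` implements the full desk-side analysis: subset matching on
annotated AIRR rearrangement tables, clonal-family inference, somatic
hypermutation (SHM) status, typical/non-typical IGHV usage, and cohort
frequency statistics — plus a synthetic-repertoire generator with planted
ground truth so every stage is testable without access to raw sequencing
data.

## Stereotype matching

A CDR3 `x` (junction minus the flanking conserved C and W) is assigned to
subset `S` when all four conditions hold:

1. `nchar(x) == S$cdr3_length_aa`;
2. the rearrangement's IGHV gene belongs to the same clan as `S`
   (clan I = IGHV1/5/7, clan II = IGHV2/4/6, clan III = IGHV3);
3. identity of the pattern window
   `x[offset + 1 .. offset + nchar(pattern)]` to the consensus is
   ≥ `min_identity` (default 0.5);
4. similarity of the same window is ≥ `min_similarity` (default 0.7),
   where a position is *similar* when the residues are equal or share a
   physicochemical group.

Two choices here were genuinely open:

* **Window-anchored comparison.** The matching rule demands an identical
  pattern *offset*, which implies the scores are computed on the pattern
  window, not the whole CDR3. Full-CDR3 comparison is available via
  `full_cdr3 = TRUE` for definitions that provide full-length consensus
  patterns.
* **Similarity classes.** The exact amino-acid classes of the original
  subset-assignment algorithm are not reproduced in the primary
  literature. We ship a standard seven-group physicochemical partition —
  {G,A,V,L,I}, {F,Y,W}, {C,M}, {S,T}, {K,R,H}, {D,E,N,Q}, {P} — and make
  it fully configurable. With singleton classes, similarity degenerates to
  identity (a tested property).
* **Ambiguity.** Multi-subset hits are not discussed in the source
  literature; we resolve them deterministically by highest similarity,
  then highest identity, then smallest subset id, and record all
  candidates.
* **Consensus vs pairwise.** Matching is against a per-subset consensus
  pattern; pairwise comparison against all known subset members would
  require the member sequences themselves and is out of scope.

The nine major CLL subsets that use IGHV1 genes (#1, #1-99, #3, #5, #6,
#7H, #12, #28A, #59) ship as a *template* configuration with empty
patterns: the consensus motifs are published elsewhere and must be filled
in by the user. All package tests use synthetic definitions so that no
third-party motif data is redistributed.

## Clonal families

Two rearrangements belong to the same clonal family when they use the
same IGHV and IGHJ genes (gene level, alleles stripped), have the same
junction length, and their junctions differ by at most a threshold
fraction of positions (normalized Hamming distance; 0 = identical,
1 = entirely different). Within each V/J/length partition we take the
single-linkage transitive closure of that predicate — "maximum distance"
semantics. The clone representative is the member with the most sequenced
mRNA molecules (`duplicate_count`), ties broken by smallest sequence id.

The threshold is data-driven: for every sequence we record the minimum
distance to any other sequence in its partition. This distance-to-nearest
distribution is bimodal — clonal relatives near zero, unrelated
co-partition sequences far out — and the threshold is the density valley
between the two largest modes of a Gaussian KDE (bandwidth 0.02 on the
[0,1] axis, 512 grid points). Numerical details, all configurable and
none dictated by the source material:

* modes below 5% of the global density maximum are ignored (stray
  outliers otherwise masquerade as a second mode);
* adjacent maxima are merged unless the density between them drops below
  half the smaller peak;
* with fewer than two surviving modes, or fewer than `min_distances = 50`
  distances, the fallback threshold (default 0.15) is used and reported
  as `method = "fixed"`;
* one threshold is computed per (sample, B-cell population) stratum,
  mirroring the per-sample/per-subset practice of repertoire studies; a
  global or fixed threshold can be forced.

Distances are computed on the full junction rather than the CDR3 proper:
within a partition both give equal-length comparisons and the junction is
what the annotation carries.

## SHM status

Mutational status is called from the percent identity of the rearranged V
segment to its germline gene: *unmutated* iff identity ≥ 100 − cutoff,
boundary inclusive (the GI ≥ 98% CLL convention). The default cutoff is
1% — the stricter convention for normal-repertoire stereotyped sequences —
with 2% available for CLL-style calls. When the input carries a
`v_identity` annotation it takes precedence; otherwise identity is
recomputed under a substitution-only model (no alignment; indels are
rejected), with ambiguity characters excluded from numerator and
denominator. Re-implementing IMGT alignment is explicitly out of scope.

## Cohort statistics

All figures and tests operate at clone level: one representative per
clonal family. Frequency tables report integer counts and percentages of
the total clonal families, rounded half away from zero at a declared
precision (printed report tables mix roundings; half-away is fixed and
reproducible, and every percentage recomputes exactly from its count).

* `fisher_exact_2x2()`: two-sided p by direct hypergeometric enumeration.
* `fisher_exact_mc()`: for r×c tables, margin-preserving Monte Carlo
  (Patefield sampling via `r2dtable`), with the unbiased `(1 + hits) /
  (1 + iterations)` estimate — it never reports 0 and is bit-reproducible
  for a fixed seed.
* `kruskal_wallis()` with tie correction, `dunn_bonferroni()` post hoc
  (large-sample normal z on mean ranks, Bonferroni multiplied and capped
  at 1), and `cmh_test()` (Mantel–Haenszel 1-df chi-square, continuity
  correction off by default). The tests are authored in-package and
  cross-checked in the test suite against independent oracles
  (`fisher.test`, `kruskal.test`, `mantelhaen.test`, and hand
  enumeration) — the checks never collapse onto the implementation
  itself.

## The synthetic world

`generate_repertoire()` emits the same annotated AIRR table the reader
consumes, plus a per-sequence truth sidecar. What it emulates:

* multinomial V/J usage over nine functional IGHV1 genes (skewed toward
  IGHV1-69/1-2/1-18) and IGHJ1-6 (dominated by IGHJ4/IGHJ6);
* junction lengths on 36–66 nt (multiples of 3), unimodal around 48;
* codon-aware junctions: first codon TGT/TGC (2nd-CYS), last TGG (J-TRP),
  no stop codons, so CDR3 derivation is always consistent;
* clonal structure: clone sizes are shifted-geometric with mean 1.5
  (about two-thirds singletons, a realistic mRNA-repertoire shape);
  members drift at most `floor(d1·L/2)` substitutions from their founder
  and founders are rejection-sampled at least `(d2 + d1)·L` apart within
  each (population, V, J, length) stratum, so realized within-clone
  distances are ≤ d1 = 0.05 and between-clone distances ≥ d2 = 0.40 by
  construction (and are additionally re-measured and reported);
* stereotyped spike-ins built by mutating the subset consensus window to
  hit requested identity/similarity levels exactly (up to the 1/w
  discretization of a length-w window), with typical IGHV genes drawn at
  a configured probability;
* per-sequence SHM: a configured fraction (default 0.25) is mutated with
  identity uniform on [92, 98.9]%, the rest on [99, 100]%; optionally
  full mutated V sequences are emitted against a clearly-labelled
  *synthetic* germline reference so identity recomputation can be tested
  end to end (identity is then exactly 100·(1 − k/L) for k planted
  substitutions);
* duplicate counts from a truncated power law (exponent 2.5), isotypes
  80% IGHM / 20% IGHG.

Populations are drawn per clone, not per sequence, because clustering —
like the real analysis — runs within each sample/population stratum;
clone members must therefore share a stratum. A corollary: two spiked
clones of the same subset are nearly identical by construction, so they
are placed in distinct (population, V, J) slots; in a single stratum the
pipeline would, correctly, merge them.

What the generator does *not* emulate: sequencing error, UMI structure,
indels, biased SHM targeting (hotspots), family-level correlations
between V gene and CDR3 composition, and repertoire scale (tests run at
10^2–10^3 clones, not the 10^5 of a real study). A green test therefore
establishes algorithmic correctness on the stated statistical structure,
not performance on raw reads — upstream read processing and germline
annotation are explicitly out of scope.

## Degenerate inputs and numerical conventions

* Threshold comparisons use a 1e-9 absolute guard so that scores equal to
  a threshold pass it (e.g. identity exactly 0.5).
* `find_threshold()` on constant or unimodal input returns the fallback,
  never an arbitrary valley; too few distances raise an error directing
  the user to a fixed threshold.
* Empty files, empty post-filter datasets and singleton partitions
  degrade gracefully (warnings, empty reports, zero-length outputs).
* Rows violating record invariants are rejected *and reported*; filtering
  tallies every rejection under exactly one reason, so kept + tallied
  always equals the input size.
* All Monte Carlo routines take an explicit seed, restore the caller's
  RNG state, and are bit-reproducible.

## Known limitations

* Subset matching is only as good as the configured definitions; the
  package validates their internal consistency but cannot check
  biological accuracy.
* The substitution-only identity model rejects indel-containing V
  sequences rather than aligning them.
* The distance-to-nearest valley is undefined for repertoires without
  clonal expansion (all singletons); the fallback threshold then governs
  clustering.
* The CMH test is exposed as a generic stratified-table operation; which
  stratification a given study used must be decided by the analyst.
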