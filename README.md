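# stereorep

Detection of CLL-biased stereotyped immunoglobulin rearrangements
(CBS-IG) in normal B-cell repertoires.

## What it does, and for whom

About 30% of chronic lymphocytic leukemia (CLL) clones express
quasi-identical ("stereotyped") B-cell receptors, grouped into subsets
defined by an amino-acid motif at a fixed offset within the heavy-chain
CDR3, a fixed CDR3 length, and IGHV genes of one phylogenetic clan.
`stereorep` is for immunogenetics groups who want to scan *normal*
repertoires — e.g. sorted splenic or blood B-cell subpopulations — for
rearrangements matching CLL major stereotyped subsets, and to quantify
them at clonal level.

The pipeline consumes annotated AIRR Rearrangement TSV tables and runs:

1. **Filtering** — productive, IGHV1-family, IgM/IgG rearrangements (all
   configurable).
2. **Stereotype matching** — a CDR3 is assigned to subset *S* iff its
   length equals *S*'s, its IGHV gene is clan-consistent, and the pattern
   window reaches ≥ 50% amino-acid identity and ≥ 70% similarity
   (physicochemical-group agreement) to the subset consensus. Matched
   rearrangements are *typical* when they use an IGHV gene
   characteristic of that subset in CLL, *non-typical* otherwise.
3. **Clonal families** — same IGHV and IGHJ gene, same junction length,
   and junction Hamming distance (normalized to [0,1]) below a
   data-driven threshold: the density valley of the bimodal
   distance-to-nearest distribution, computed per sample/population.
   Single-linkage closure; the representative is the member with the
   most sequenced mRNA molecules.
4. **SHM status** — unmutated iff germline V identity ≥ 99% (1% cutoff,
   boundary inclusive; 2% CLL convention available).
5. **Statistics** — per-subset/per-population counts and percentages over
   clone representatives; Fisher's exact test (2×2 analytic, r×c Monte
   Carlo with fixed margins), Kruskal–Wallis, Dunn/Bonferroni, and
   Cochran–Mantel–Haenszel.

A fully seeded synthetic-repertoire generator plants clonal structure
(within-clone divergence ≤ d1 = 0.05, between-clone ≥ d2 = 0.40),
stereotyped spike-ins at controlled identity/similarity, SHM levels and
duplicate counts, and ships per-sequence ground truth — so the whole
pipeline is testable without any sequencing data.

## Worked example

```r
library(stereorep)

defs <- list(
  subset_definition("#S1", cdr3_length_aa = 13, pattern = "ARDANGMDV",
                    pattern_offset = 2, clan = "I",
                    typical_v_genes = "IGHV1-69"))

cfg <- simulation_config(seed = 42, n_background_clones = 200,
                         spikes = list(list(subset_id = "#S1",
                                            n_clones = 5)))
sim  <- generate_repertoire(cfg, defs)
ann  <- assign_stereotypes(sim$records, defs)
cl   <- infer_clones(ann)
reps <- annotate_shm(cl[cl$is_representative, ], cutoff_pct = 1)

n_clones <- length(unique(cl$clone_id))
attr(cl, "thresholds")
#>     group     value         method n_distances
#> 1 sim1/FM 0.1956947 density_valley          66
#> 2 sim1/GC 0.1500000          fixed          40
#> ...
frequency_table(reps, n_clones, "by_subset", decimals = 2)
#>   group count percent
#> 1   #S1     5    2.44
table(reps$shm_status)
#>   mutated unmutated
#>        39       166
evaluate_recovery(cl, sim$truth)
#> sensitivity 1.00, specificity 1.00, ARI 1.00
```

308 simulated sequences collapse into 205 clonal families; the follicular
mantle stratum had enough multi-member clones for a detected valley
(0.196, inside the planted (0.05, 0.40) window), smaller strata fall back
to the fixed 0.15 threshold — also inside the window, so all five planted
stereotyped clones are recovered with no false positives (sensitivity =
specificity = adjusted Rand index = 1). The frequency table reads: 5 of
205 clonal families (2.44%) match subset #S1. The same arithmetic on the
published survey's printed counts gives

```r
subset_percent(142, 117027, 2)   # subset #12: 142 clones -> 0.12%
#> [1] 0.12
```

i.e. 0.12% of 117,027 clonal families.

The nine IGHV1-relevant major CLL subsets ship as a template
(`inst/extdata/ighv1_subsets_template.yaml`) whose consensus patterns
must be completed from the published subset definitions; examples and
tests use synthetic definitions.

## Command line

```sh
stereorep simulate --config config.yaml --out sim/ --seed 7
stereorep run --input sim/simulated.tsv --config config.yaml \
              --out run/ --seed 7
stereorep evaluate --predictions run/annotated.tsv \
                   --truth sim/truth.tsv --out eval/
```

(`inst/bin/stereorep` is an Rscript wrapper around `stereorep_main()`.)

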