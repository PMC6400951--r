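---
title: "Methods: structural-variant lineage analysis of multi-histology tumours"
author: "svlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant lineage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svlineage)
```

## The problem

Post-pubertal testicular germ cell tumours frequently present as mixtures of
histologically distinct components — germ cell neoplasia in situ (GCNIS),
seminoma, embryonal carcinoma, teratoma, yolk sac tumour — that are believed
to be lineage related. Because chromosomal rearrangement junctions are
essentially irreversible, highly specific somatic marks, the set of junctions
two micro-dissected components share is direct evidence of a common clonal
ancestor, and the junctions private to each component measure divergence
since that ancestor. `svlineage` implements this junction-based lineage
analysis end to end: junction detection from mate-pair fragments, quality and
germline filtering, shared/unique matrices and dendrograms, arm-level
aneuploidy, copy-neutral LOH (cnLOH) and shared somatic mutations.

Real mate-pair datasets of this design run to ~90 million fragments per
sample; the package therefore ships a synthetic clone-phylogeny generator
with complete ground truth so that every stage is testable at desk scale.
The generator is a first-class, tested module, not a fixture: its defaults
*are* the study conditions the analysis assumes, and all recovery statistics
reported by the test-suite and `scripts/acceptance.R` are computed under
them.

## Junction detection

A mate-pair fragment is **discordant** when its ends map to different
chromosomes, its orientations are inconsistent with a proper pair (`+`/`-`
with the `+` end upstream), or its intrachromosomal span exceeds
`max(min_event_size, mean + 4*sd)` of the fragment-size model. The defaults
(mean 3700 bp, sd 370 bp, `min_event_size` 30 kb) describe a typical
long-insert mate-pair library and the convention of reporting only
rearrangements larger than 30 kb. The 30 kb floor is applied at
classification; applying it at reporting instead would be a one-line
configuration change, and on the simulated data the two are equivalent
because all planted events are larger.

Discordant fragments are clustered by **single linkage**: two fragments link
when both end chromosomes and both orientations agree and both positional
gaps are at most `cluster_window` (default 2 × fragment mean = 7400 bp, the
positional uncertainty of the library). Single linkage is the natural choice
here because fragment ends from one junction are spread uniformly over about
one fragment length — any fixed-radius centroid rule would split wide
clusters. The implementation is union–find over the pairwise link relation;
tests verify exact equality with a brute-force transitive closure on random
instances up to 200 fragments.

Each cluster becomes one junction. The breakpoint estimate is the
**orientation-aware innermost end**: maximal fragment-end position on a `+`
side, minimal on a `-` side — the standard mate-pair convention, since
fragment ends can only fall on the retained side of the breakpoint. Support
is the cluster size. Four junction classes are distinguished by the ordered
orientation pair: deletion-like `+/-`, duplication-like `-/+`, and the two
inversion types `+/+` and `-/-`.

## Filtering and matching

Two junctions from different samples are **the same event** when both
breakpoints agree in chromosome and orientation and both position differences
are at most `match_tolerance` = 10 kb. The tolerance is taken inclusively
(`<=`); the boundary convention is configurable and documented because the
usual prose ("within 10 kb") does not fix it. Orientation equality is
required even though a looser rule would be conceivable: orientation-blind
matching would merge distinct rearrangement classes at the same locus.

Per-sample filtering retains a junction when

1. its support is at least `min_support` = 7 (the quality threshold), **or**
2. it has at least `rescue_support` = 3 of its own and matches a junction
   with support ≥ 7 in a related sample of the same patient (cross-sample
   rescue — the algorithmic form of manually re-checking a trusted junction
   in sibling samples);

then intrachromosomal junctions of at most 50 kb are removed (small
deletions/duplications at this scale are common germline polymorphisms),
those in (50 kb, 100 kb] are kept only when a breakpoint falls in a gene
region, and interchromosomal junctions are exempt from size rules. When
several candidates match within tolerance, ties are resolved by ascending
breakpoint-distance sum, then canonical coordinate order; ambiguous
multi-matches are vanishingly rare at 10 kb tolerance on a 300 Mb genome.

**Germline subtraction** removes every tumour junction matching any junction
of the patient's matched normal. Without a normal the call set passes
through unchanged with a warning; the size rules then stand in for germline
exclusion, which is exactly why they exist.

## Lineage reconstruction

The **shared count** of two germline-subtracted components is the size of a
maximum one-to-one matching of their junctions under the match predicate
(Kuhn's augmenting-path algorithm); unique counts are the set sizes minus
the shared count. A maximal matching rather than a greedy count guarantees
symmetry and the bound `shared <= min(|A|, |B|)`; tests verify equality with
an independent maximum-matching oracle (igraph) on 500 random instances.

For dendrograms, junctions are first collapsed into **equivalence classes**
by transitive closure of cross-sample matching. A chain A~B~C with A≁C
merges into one class; at 10 kb tolerance this is rare and harmless.
Components are then agglomerated greedily: at each step the pair of clusters
sharing the most classes (classes present in *every* leaf of the merged
cluster) is joined; clusters sharing zero classes attach at the root as
independent lineages — the configuration seen when an in-situ component
shares nothing with the invasive components beside it. Each node's edge is
labelled with the number of classes present in all and only its descendant
leaves; leaf edges carry private-junction counts. On perfect-phylogeny input
(no homoplasy, no noise) the labels partition the classes and the
reconstruction is exact, which the tests assert. The greedy agglomeration is
a deliberate formalization of what is usually done by inspection; for ≤ 5
components it coincides with exhaustive parsimony search on all test cases.

Topology recovery is scored against the dendrogram the same algorithm builds
from the ground-truth somatic sets, compared as sets of clades.

## Arm-level copy number

Read depth is binned (50 bins per arm by default), summarised per arm by the
median, and normalized by a **2N baseline estimated as the modal autosomal
arm median** — the largest group of autosomal arm medians agreeing within
10%, summarised by its median. As long as more than half the autosomal arms
are disomic the baseline equals the true 2N depth, with no matched normal
required; this robustness matters in genomes as pervasively aneuploid as
these. States are `round(2 * median / baseline)` with R's ties-to-even,
floored at 0 and capped at 8 for reporting. Arms with less than 80% bin
coverage are no-called rather than guessed. Whole-arm segmentation (rather
than free changepoint detection) matches the whole-arm/whole-chromosome
character of the aneuploidy being modelled; a changepoint mode would be an
extension, not a replacement. The numeric mapping from normalized depth to
"3N–5N" is our construction — the source analyses report the states, not the
thresholds — and is validated by exact state recovery in simulation
(Poisson depth 100 per bin, 50 bins per arm, states 1–5, 100 replicates).

The pathognomonic **12p gain** is simply state ≥ 3 on arm 12p; the
synthetic genome mirrors human chromosome/arm proportions at 1/10 scale so
this logic runs against the literal arm name.

## Copy-neutral LOH

At SNP sites heterozygous in the matched normal, the reference-allele
fraction concentrates near 0.5 on balanced 2N chromosomes and near 0/1 under
cnLOH (one homolog duplicated, site-by-site which one carries the reference
allele is random). A site is **deviant** when `|ref_fraction - 0.5| > 0.15`;
a chromosome with ≥ 20 informative sites is called LOH when ≥ 80% of its
sites are deviant, and labelled `cnLOH` only when both arms sit at state 2 —
otherwise `LOH_with_loss`/`LOH_with_gain`. The 0.15/0.8 pair is our
construction, chosen once on binomial power grounds: at depth ≥ 30 a
balanced site exceeds 0.15 deviation with probability < 0.01, while a
fixated site deviates by 0.5, so the rule separates cleanly at the simulated
depth of 100; the acceptance suite measures sensitivity ≥ 95% and FPR ≤ 5%
without any threshold adjustment. Tumour-only profiles are refused: without
normal-ascertained heterozygous sites the 0.5 expectation is undefined.

## Mutations

Somatic mutation filtering keeps calls covered by ≥ 20 reads in both normal
and tumour whose consequence affects the protein product (missense,
nonsense, frameshift, splice); intronic, UTR and synonymous calls are
removed as likelier false-positive sources. Shared mutations between
components are the exact-key intersection on (chromosome, position, ref,
alt). Breakpoint–gene annotation flags junctions hitting a user-supplied
cancer-gene list; the list is a stand-in for a curated census and carries no
further interpretation.

## What the generator emulates — and what it does not

Per patient, the generator draws one of the two canonical evolution-model
phylogenies (seminoma and embryonal carcinoma arising directly from GCNIS
with teratoma/yolk sac from embryonal carcinoma; or the linear
GCNIS→seminoma→embryonal carcinoma→teratoma chain), samples 3–4 components
plus a normal, and plants events that accumulate along root-to-node paths:

* **Germline junctions** (default 5/patient) present in every component
  including the normal — matching the observed ~5 junctions in normal
  samples and providing the germline-subtraction substrate.
* **Somatic junctions** per edge (defaults echo the observed per-histology
  burden: GCNIS lowest, embryonal carcinoma highest), with class mix
  55:25:20 translocation:deletion:inversion echoing the reported
  interchromosomal majority, and intrachromosomal sizes lognormal
  (median ≈ 280 kb, truncated below 110 kb so true events clear the
  polymorphism size filter).
* **Support counts** 7 + negative binomial (mu 8, size 3): every true
  junction clears the quality threshold, as the source data's filtered call
  sets do by construction. The true support distribution is unknown; the
  floor-plus-tail form reproduces the pass/fail boundary behaviour and is
  configurable.
* **False junctions** (Poisson, rate 2/sample) with support uniform on 1–6,
  i.e. always below threshold — exercising the filter rather than defeating
  it — plus per-sample Gaussian breakpoint jitter (sd 500 bp) emulating
  breakpoint-estimation scatter between samples.
* **Aneuploidy**: arm-level gains/losses per invasive edge; every invasive
  component gets 12p at the configured level (default 4N, within the 3N–5N
  range); GCNIS and normal stay flat.
* **cnLOH** on whole autosomes that are currently 2N/2N, inherited by
  descendants; SNP allele counts binomial at the dosage the copy state
  implies, depth Poisson(100).
* **Mutations**: protein-impacting mutations per edge at good coverage, plus
  private non-impacting and low-coverage noise rows that the filters must
  remove.

Not emulated: base-level reads and sequencing error, mapping artefacts,
whole-genome-amplification chimeras, tumour purity/contamination, subclonal
mixtures within a component, and homoplasy (recurrent identical junctions).
Passing tests therefore demonstrate correctness of the algorithms under the
stated statistical model, not robustness to every failure mode of real
libraries — in particular, real micro-dissected, amplified DNA can produce
correlated false junctions that the independent-noise model here does not
generate.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally and in BED/BEDPE
  output; readers of 1-based formats would convert on ingestion.
* Junctions are kept in canonical order (breakpoint 1 ≤ breakpoint 2,
  lexicographic chromosome then position), swapping strands along.
* Empty call sets propagate as valid empty results: a junction-free GCNIS
  yields shared 0 with everything and attaches at the dendrogram root; a
  patient with a single component yields an empty matrix and no dendrogram,
  with a warning rather than an error.
* All simulation and analysis entry points are pure functions of (inputs,
  config, seed); cohort runs derive per-patient seeds deterministically from
  the master seed, and the output writers use fixed formats, so reruns are
  byte-identical — asserted in the tests.

## Problem sizes

The packaged analyses use a 24-chromosome, ~309 Mb genome (human proportions
at 1/10 scale), 10-patient cohorts, 50 depth bins per arm, 5 SNPs/Mb, and
the replicate counts quoted above (100 lineage patients, 100 karyotype
replicates, 200 cnLOH replicates, 100 detection replicates). These sizes
make every validation a minutes-scale computation while keeping the
per-stage statistics (junctions per sample, bins per arm, sites per
chromosome) in the regime the methods assume.

## Known limitations

* Greedy agglomeration can in principle differ from global parsimony for
  many components with heavy homoplasy; with 3–5 components and junction
  characters this does not arise.
* The modal-baseline karyotyper fails by design if fewer than half the
  autosomal arms are disomic (near-triploid genomes); a matched-normal
  baseline mode would be the remedy.
* cnLOH calls are whole-chromosome; segmental LOH would require per-arm or
  windowed aggregation of the same deviant-site statistic.
* Junction–CNV integration is limited to annotating junctions at arm-state
  boundaries; breakpoint-resolution copy-number segmentation is out of
  scope.
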