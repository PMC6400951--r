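# svlineage

Clonal lineage analysis of multi-histology tumours from structural-variant
junctions, with arm-level aneuploidy and copy-neutral LOH calling.

## The problem

Mixed testicular germ cell tumours contain histologically distinct components
— germ cell neoplasia in situ (GCNIS), seminoma, embryonal carcinoma,
teratoma, yolk sac tumour — whose lineage relationships are contested. A
chromosomal rearrangement junction (the fused pair of breakpoints left by a
deletion, inversion or translocation) is a near-irreversible somatic mark:
junctions shared by two micro-dissected components imply a common clonal
ancestor, and junctions private to each measure divergence since that
ancestor. `svlineage` is for analysts of multi-region / multi-component
mate-pair sequencing (MPseq) who want this junction-based lineage analysis,
plus its companions — arm-level karyotypes (including the pathognomonic
multi-copy 12p gain), copy-neutral loss of heterozygosity (cnLOH) from SNP
allele fractions, and shared somatic mutation counts — as tested, scriptable
R functions.

## Method at a glance

* **Detection.** Discordant mate-pair fragments (interchromosomal,
  orientation-inconsistent, or span > max(30 kb, mean + 4sd)) are clustered
  by single linkage: ends on identical chromosomes with identical
  orientations, both gaps ≤ 2× the 3700 bp fragment mean. A cluster becomes
  a junction with breakpoints at the orientation-aware innermost fragment
  ends and support = cluster size.
* **Filtering.** Keep junctions with support ≥ 7, or support ≥ 3 matching a
  ≥ 7 junction in a related sample (cross-sample rescue). Intrachromosomal
  junctions ≤ 50 kb are removed; 50–100 kb kept only when a breakpoint is
  genic; interchromosomal junctions are exempt. Junctions from different
  samples are "the same" when both breakpoints agree in chromosome and
  orientation within 10 kb. Junctions matching the matched normal are
  germline and removed.
* **Lineage.** Shared counts between components are maximum one-to-one
  matchings under the 10 kb rule; dendrograms come from greedy shared-class
  parsimony over cross-sample junction equivalence classes, with internal
  edges labelled by shared-junction counts and leaf edges by private counts.
* **Copy number.** Per-arm median bin depth, normalized by the modal
  autosomal arm median (no matched normal needed), rounded to integer
  states; 12p state ≥ 3 flags the multi-copy gain.
* **cnLOH.** At sites heterozygous in the normal, a chromosome with ≥ 80% of
  sites deviating from allele fraction 0.5 by > 0.15 is LOH; it is
  *copy-neutral* LOH only when both arms sit at state 2.
* **Mutations.** Keep protein-impacting calls covered ≥ 20× in both normal
  and tumour; shared mutations are exact-key intersections.

A synthetic clone-phylogeny generator (`simulate_patient()`,
`run_simulated_cohort()`) produces all of these inputs with complete ground
truth, so the whole pipeline runs and validates in minutes without any
external data.

## Worked example

Simulate one patient under the "direct" evolution model (seminoma and
embryonal carcinoma from GCNIS; teratoma and yolk sac from embryonal
carcinoma) and run the full analysis:

```r
library(svlineage)
genome <- toy_genome()
phy    <- phylogeny_model("direct")
sim    <- simulate_patient(sim_config(seed = 42), genome, phy, "P1")
res    <- run_patient(sim$call_sets, genome, sim$depth_profiles,
                      sim$allele_profiles, sim$mutation_tables)
res$lineage
```

```
lineage_result for patient P1 (5 components)
               sample_a               sample_b shared unique_a unique_b
               P1_GCNIS P1_embryonal_carcinoma      1        0        7
               P1_GCNIS            P1_seminoma      1        0        5
 P1_embryonal_carcinoma            P1_seminoma      1        7        5
 P1_embryonal_carcinoma            P1_teratoma      8        0        4
            P1_teratoma            P1_yolk_sac      8        4        4
 ...
```

The single junction GCNIS shares with everything is the event acquired on
the normal→GCNIS edge; embryonal carcinoma and teratoma share 8 junctions
(the GCNIS + embryonal path), each carrying 4 private ones. The dendrogram
makes the structure explicit — shared junctions label internal edges,
private junctions label leaves:

```r
res$dendrogram
#> junction_dendrogram: ((P1_yolk_sac:4,(P1_embryonal_carcinoma:0,
#>   P1_teratoma:4)0:0)7:7,(P1_GCNIS:0,P1_seminoma:5)0:0)1;
#>   21 junction equivalence classes over 5 components
```

Arm-level karyotypes recover the planted 12p gain in every invasive
component and in none of the in-situ/normal ones:

```r
res$i12p
#>                sample_id state_12p gain_12p
#> 1              P1_normal         2    FALSE
#> 2               P1_GCNIS         2    FALSE
#> 3 P1_embryonal_carcinoma         4     TRUE
#> 4            P1_seminoma         4     TRUE
#> 5            P1_teratoma         4     TRUE
#> 6            P1_yolk_sac         4     TRUE
```

and the cnLOH caller reports the planted whole-chromosome events, e.g.
chr4 (inherited from the embryonal lineage) with 100% deviant sites at
copy state 2.

The numbered scripts under `analysis/` run the same workflow over a
10-patient synthetic cohort: `01_simulate_cohort.R` writes every sample's
BEDPE/BED/TSV inputs with ground truth, `02_junction_lineage.R` produces
lineage matrices and dendrograms, `03_cnv_aneuploidy.R` the aneuploidy
matrix and 12p calls, `04_loh_mutations.R` cnLOH and shared-mutation tables,
and `05_fragment_detection.R` the fragment-level detection round trip.
Outputs land under `results/`.

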