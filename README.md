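# aaplr

Quantitative analysis of **antigen–antibody proximity labeling (AAPL)**
oxidative proteomics experiments.

In AAPL, an antibody carrying an Fe(III) catalytic probe is bound to its
antigen on intact cells; hydrogen peroxide then triggers hydroxyl-radical
oxidation of proteins in the immediate neighborhood of the epitope.
Label-free quantification of the oxidized and unmodified peptidoforms reads
out, per protein and labeling condition, how strongly each protein was
oxidized — and therefore how close it sits to the targeted antigen. `aaplr`
takes peptide-level quantification tables from such experiments and turns
them into ranked, typed, network-organized interactor calls. It is aimed at
proteomics groups running footprinting-style proximity labeling who need a
reproducible, scriptable scoring pipeline downstream of their search
engine.

## The quantities computed

For one tryptic peptide in one condition (replicates summed), the **degree
of oxidation** of site *p* is

    degree(p) = I_ox(p) / (I_unmod + Σ_q I_ox(q))

and the **extent of protein oxidation (EPO)** of protein *i* is

    EPO(i) = Σ I_ox(i) / Σ I_total(i)

i.e. the oxidized fraction of the protein's total MS1 intensity. EPO values
are normalized per protein to the condition with the largest EPO, and an
**EPO fold change** is formed against the mean EPO of the control
conditions (cells only; unmodified antibody; peroxide only).

The **AAPL score** adapts the topological score (TopS) used in AP-MS: with
matrix entries `v(i,c) = oxidized spectral count × EPO` over all treatment
and control conditions, expectations under row/column independence are
`E = R_i C_c / T`, and

    score(i) = v(i,c*) · ln( v(i,c*) / E(i,c*) )

read at the selected (optimal) condition *c\**. Proteins scoring above 1
are **Level 1 (L1)** interactors; scores in (0, 1] with EPO fold change
above 1.5 are **Level 2 (L2)**. Independently, proteins are typed against
a STRING-style evidence file: **T1** (direct edge to the bait, combined
score > 0.7), **T2** (direct, 0.4–0.7), **T3** (connected to a T1/T2
protein but not the bait), **T4** (the rest). The typed, scored proteins
are assembled into an annotated interaction graph (GraphML/SIF), and
glycopeptide compositions can be classified (CH/F/FS/HM/S) to stratify
interactors by glycan type in inhibitor comparisons.

A fully ground-truthed synthetic-data generator (`simulate_aapl_experiment`)
emulates proximity-dependent oxidation — treatment conditions M1–M6,
controls C1–C3, replicate noise, residue-level susceptibility, spectral
counting — so the entire pipeline can be exercised and validated without
raw mass-spectrometry data.

## Worked example

```r
library(aaplr)

sim    <- simulate_aapl_experiment(sim_params(seed = 1), experiment_design())
prof   <- oxidation_profiles(sim$measurements, sim$design)
scores <- aapl_scores(prof, sim$design)
res    <- classify_interactors(prof, scores, sim$edges, sim$bait_id, sim$design)

head(res[order(-res$aapl_score), ], 6)
#>     protein_id aapl_score epo_fc level string_type n_sites
#> 14     SYN0015      11.87   8.67    L1          T1     379
#> 187    SYN0188       7.51   7.61    L1          T4     221
#> 51     SYN0052       7.50   8.24    L1          T1     234
#> 85     SYN0086       7.38   7.21    L1          T4     319
#> 162    SYN0163       2.82   7.28    L1          T4     396
#> 43     SYN0044       2.64   7.67    L1          T4     340

table(truth = sim$truth$class[match(res$protein_id, sim$truth$protein_id)],
      called = res$level)
#>             called
#> truth         L1 none
#>   background   0  189
#>   proximal     9    1
```

Nine of the ten truly proximal proteins are recovered as L1 interactors
with zero background false calls; their EPO fold changes (7–9×) track the
simulated enrichment multiplier (8× for proximal neighbors). The bait
itself reaches EPO 0.19 in the selected condition (fold change 9.7,
BH-adjusted q = 0.006 against pooled controls) and is excluded from the
interactor list by definition. `build_network(res, sim$edges,
sim$bait_id)` returns the corresponding annotated `igraph` object (here 11
nodes, 5 edges), exportable with `write_network_graphml()` or
`write_network_sif()`.

`run_aapl_pipeline(config)` chains every stage (simulate/load → quantify →
score → classify → network → glyco) from a YAML or list configuration and
writes all result tables to a directory; `validate_config()` reports every
configuration problem at once.

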