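# chemscreen

Network-based screening of candidate drugs from chemical–chemical and
protein–chemical interaction scores.

## What it does

Given interaction tables in the STITCH "detailed links" dialect and three
disease reference sets — approved drugs, disease-related chemicals
(*S<sub>c</sub>*), and disease-related genes (*S<sub>g</sub>*, with an
explicit gene→protein mapping) — `chemscreen` runs a three-step
guilt-by-association screen for candidate (repositionable) compounds:

1. **Preliminary screening.** Keep compounds that interact (combined score
   > 0) with at least one approved drug: the pool *P<sub>c</sub>*.
2. **Association + permutation tests.** For each candidate *c*, the rating
   score *RS(c)* is the mean combined score of its links to a reference
   set (0 when none). The association test requires
   *RS<sub>c</sub>(c) > 0* and *RS<sub>g</sub>(c) > 0*. The permutation
   test draws 1,000 random reference sets of equal size and reports
   *P = W/1000*, where *W* counts sets whose rating score strictly exceeds
   the observed one. Thresholds are not arbitrary: the identical procedure
   is applied to the approved drugs and the per-channel **maximum** drug
   P-value becomes the cutoff (inclusive). On the published reference
   measurements for the ten approved NSCLC drugs shipped with the package,
   these thresholds are 0.469 (chemicals) and 0.292 (genes).
3. **EM co-clustering.** Survivors and drugs are encoded as 15 mean
   interaction-score features (5 chemical channels vs drugs, 5 vs disease
   chemicals, 5 protein channels vs disease genes; per-channel positive
   support, zero when empty) and clustered by a diagonal-covariance
   Gaussian mixture fitted by expectation–maximization, with the component
   count chosen by cross-validated likelihood. Candidates sharing the
   drugs' component survive; the loop repeats (default two rounds). The
   final survivors are the reported putative compounds.

A synthetic fixture generator (`generate_fixture()`) plants positives and
three decoy classes with known fates, so the whole pipeline is testable
offline; `generate_gmm_data()` provides planted mixtures for the
clustering code. See `vignettes/network-screening.Rmd` for the model,
parameter and design discussion.

## Worked example

```r
library(chemscreen)

bundle <- generate_fixture(fixture_spec(seed = 42), "example_fixture")
cfg <- run_config(
  chemical_links    = bundle$paths$chemical_links,
  protein_links     = bundle$paths$protein_links,
  drugs             = bundle$paths$drugs,
  disease_chemicals = bundle$paths$disease_chemicals,
  gene_map          = bundle$paths$gene_map,
  seed = 42
)
report <- run_pipeline(cfg)
print(report)
```

```
Three-step candidate screen (seed 42)
  universe         250
  preliminary      163
  association      32
  permutation      16
  cluster_round_1  8
  cluster_round_2  8
  putative         8
  P-value thresholds: chemicals <= 0.617, genes <= 0.294
```

Reading the counts: of 250 compounds in the interaction universe, 163
interact with at least one of the 10 drugs; 32 also touch both a disease
chemical and a disease gene; 16 have permutation P-values no worse than the
weakest drug on both channels; 8 co-cluster with the drugs through two EM
rounds. `report$putative` holds their per-compound measurements:

```
  compound rs_chemicals rs_genes pvalue_chemicals pvalue_genes
1     1001       612.20 595.3333            0.037        0.047
2     1002       607.90 590.5000            0.067        0.055
3     1003       642.30 595.0000            0.066        0.046
```

Rating scores are on the 0–1000 combined-score scale; P-values are
multiples of 1/1000. In this fixture the 8 putative compounds are exactly
the 8 planted positives (`bundle$manifest` carries the ground truth), and
all 30 planted decoys are rejected. `export_subnetwork(report)` returns
the weighted interaction network among putative compounds, drugs and
disease proteins for downstream graph tools.

A command-line front end covers the same ground:

```sh
exec/chemscreen fixture --out fx --seed 42
exec/chemscreen screen --chemical-links fx/chemical_links.tsv \
  --protein-links fx/protein_links.tsv --drugs fx/drugs.txt \
  --disease-chemicals fx/disease_chemicals.txt --gene-map fx/gene_map.tsv \
  --seed 42 --out results/
```

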