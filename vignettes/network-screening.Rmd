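---
title: "Network-based screening of candidate drugs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based screening of candidate drugs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemscreen)
```

## The screening problem

Finding new indications for existing compounds is far cheaper than de novo
discovery. `chemscreen` implements a guilt-by-association screen over two
interaction networks: a chemical–chemical network and a protein–chemical
network, both in the STITCH "detailed links" dialect, where every link
carries integer evidence scores on a 0–1000 scale and an integrated
`combined_score`. Throughout the package, two entities *interact* if and
only if their combined score is strictly positive; the other evidence
channels (similarity, experimental, database, textmining, prediction) are
kept for the feature encoding but never decide link existence.

The screen needs three reference sets for a disease of interest:

* the **approved drugs** for the disease (PubChem CIDs),
* **disease-related chemicals** $S_c$ (CIDs),
* **disease-related genes** $S_g$, supplied together with an explicit
  gene-to-protein mapping. The mapping is an input file rather than an
  internal inference: how gene symbols map onto protein identifiers of the
  interaction database is a curation decision we do not want to hide inside
  the package, and a gene may legitimately map to several protein
  identifiers.

## The three steps

**Step 1 — preliminary screening.** Compounds that interact with at least
one approved drug form the candidate pool $P_c$. The rationale is the usual
one for interaction networks: interacting chemicals tend to share function,
so drug neighbors are enriched for drug-like activity. The drugs themselves
are excluded from $P_c$.

**Step 2 — association and permutation tests.** For each candidate $c$ the
*rating score* against a reference set is the mean combined score over the
links that exist between $c$ and the set's members, and 0 when there is no
such link: $RS_c(c)$ against the disease chemicals (chemical links) and
$RS_g(c)$ against the disease genes (protein links, each linked protein
counted once even when shared by several genes). The association test keeps
candidates with $RS_c(c) > 0$ and $RS_g(c) > 0$.

The association test cannot distinguish a disease-specific interactor from
a promiscuous compound that touches everything. The permutation test builds
an empirical null per compound and channel: draw $B$ random reference sets
of the same size as the real one (without replacement), score $c$ against
each, and report

$$\mathrm{P\!-\!value}(c) = W / B,$$

where $W$ counts the random sets whose rating score is *strictly larger*
than the observed one — ties do not count, following the strict reading of
"larger than". $B$ defaults to 1000, so P-values are multiples of 0.001.
On tiny universes an exhaustive mode enumerates every subset and returns
the exact fraction.

Rather than imposing an arbitrary significance cutoff, the thresholds are
derived from the approved drugs themselves: every drug is pushed through
the identical association and permutation machinery (drugs failing the
association test drop out of the reference cohort), and the per-channel
threshold is the *maximum* P-value among the surviving drugs. Candidates
with both P-values less than or equal to the thresholds (boundary
inclusive) survive. This retains every candidate that looks at least as
disease-associated as the least associated approved drug.

**Step 3 — EM co-clustering.** Survivors and drugs are encoded as a
15-dimensional vector of mean interaction scores: the five chemical
channels against the drugs, the five chemical channels against the disease
chemicals, and the five protein channels against the disease genes. Each
feature averages only the partners with a strictly positive score *on that
channel* (per-channel support) and is 0 when no such partner exists. No
scaling is applied before clustering; the mixture model below carries
per-dimension variances, which absorbs scale differences between channels.

The cohort is clustered by a Gaussian mixture with diagonal covariance,
fitted by expectation–maximization; candidates assigned to the same
component as the drugs are retained, and the encode–select–fit–select loop
is repeated on the survivors. The default is two rounds: the procedure this
emulates ran exactly two passes without stating a stopping rule, so two
rounds is a faithful-but-arbitrary default; the loop also stops early when
the candidate set stops shrinking or becomes empty, and `rounds` is
configurable.

## The mixture model and its numerical choices

For $k$ components in $d$ dimensions the model is
$p(x) = \sum_{j=1}^{k} w_j \prod_{t=1}^{d} \mathcal N(x_t;\mu_{jt},\sigma^2_{jt})$.
The E-step computes posterior responsibilities under the current
parameters; the M-step performs the weighted maximum-likelihood update of
weights, means and per-dimension variances. Iteration stops when the total
log-likelihood improves by less than `tol` (default `1e-6`) or after
`max_iter` (default 100) E-steps. The log-likelihood trace is
non-decreasing by construction and is returned for inspection.

* **Initialization.** Farthest-point seeding from a seeded RNG followed by
  10 Lloyd iterations of k-means; initial variances are within-cluster
  variances. The scheme is standard, documented, and exactly reproducible
  under a fixed seed, which we prefer over an unspecified toolkit-internal
  default.
* **Variance floor.** Per-dimension variances are floored at
  `var_floor_frac` (default `1e-6`) times the per-dimension data variance,
  falling back to the mean positive variance for constant dimensions
  (all-zero feature columns do occur in sparse cohorts). The floor keeps
  degenerate components — constant data, single-point clusters — finite
  without visibly biasing non-degenerate fits.
* **Component count.** `select_k()` emulates automatic class-number
  selection by cross-validated likelihood: starting at $k = 1$, the count
  increases while the held-out log-likelihood over `folds` (default 10)
  cross-validation folds improves, returning the last improving $k$
  (capped at `k_max` and at the smallest training-split size).
* **Tie-breaking.** Hard assignments take the lowest component index on
  ties; the plurality co-cluster rule breaks drug-count ties toward the
  lower cluster index. All randomness flows from one run seed through
  deterministically derived substreams, so whole runs are bit-reproducible.
* **Co-cluster policy.** `"plurality"` (default) follows the cluster
  holding the most drugs; `"all"` demands that every drug share one
  cluster and raises a typed error carrying the drug partition otherwise —
  useful when drug coherence itself is a claim under test.

## Permutation-test design

The sampling frame is deliberately the least-assumption choice: for the
chemical channel, every compound appearing in a chemical link (minus the
assessed compound); for the gene channel, every protein appearing in a
protein link. Random gene-channel sets have the size of the *gene* set,
matching the construction of the observed score. Two behaviors the source
procedure leaves unstated are both supported: by default each compound gets
its own deterministically derived substream of random sets; with
`shared_sets = TRUE` one collection of sets is reused across compounds (in
that case the assessed compound stays in the frame so the sets remain
identical — a drawn self-id contributes nothing because compounds carry no
self links).

Empirical P-values from $B$ draws have standard error
$\sqrt{p(1-p)/B} \le 0.016$ at $B = 1000$, which is small against
thresholds in the 0.2–0.6 range; raising `n_permutations` buys resolution
linearly in time.

## What the synthetic fixtures emulate

`generate_fixture()` produces the five input files plus a ground-truth
manifest, so every stage is testable without any database download. The
defaults describe a small but structurally faithful screen: 200 candidate
compounds, 10 approved drugs, 40 disease chemicals, 15 disease genes
(1–2 proteins each), with true-link channel scores drawn as integers in
[150, 999] (150 being the customary floor of reported evidence scores) and
30% per-channel dropout so per-channel feature supports genuinely differ.

Planted classes and the construction logic behind them:

* **Positives** mimic the drugs' interaction profile — the same score
  ranges toward drugs (strong, 600–950), disease chemicals and genes
  (mid, 400–800) — so their 15-feature vectors are exchangeable with the
  drugs' and they co-cluster. They additionally carry more weak (150–300)
  background links than the drugs do. Background links never enter the
  feature encoding (features only see the reference sets), but they do
  populate the permutation null: random sets catch the weak partners, so
  the null mass sits below the observed rating score and the positives'
  P-values land well under the drug-derived thresholds.
* **No-drug decoys** replicate the positives' disease links but are never
  linked to a drug: they must vanish at step 1.
* **No-gene decoys** are drug-linked with disease-chemical links but no
  protein link to any disease gene: they must fail the association test.
* **Nonspecific decoys** link with average strength (350–650) to ~30% of
  the universe — including, incidentally, disease chemicals and genes —
  while their *strong* links point at background compounds and proteins
  outside the disease sets. Random reference sets catch those strong
  off-target partners, so the observed rating score falls in the lower
  tail of its own null and the permutation P-values concentrate near 1.
  This is the compound the permutation test exists to reject: broadly
  interactive, with its real functional neighborhood elsewhere. (A decoy
  whose links are *all* exchangeable with the null would earn a uniform
  P-value — un-rejectable by construction at any fixed threshold — so the
  class is built with the off-target asymmetry that makes "nonspecific"
  detectable.)
* **Background compounds** carry sparse random links and are left
  unconstrained; a few legitimately survive the screen, which is the
  realistic behavior of a threshold chosen to keep everything as good as
  the weakest drug.

What the fixtures do **not** emulate: real degree distributions (STITCH is
heavy-tailed; the fixture is roughly homogeneous within classes), score
correlations between channels beyond a shared jitter, stereo-isomer
identifier flavors in bulk, and any actual chemistry or biology — passing
tests demonstrate the pipeline's logic and statistics, not that a
particular real compound would be found.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run the pipeline on the default 200-compound fixture
across 5 seeds, fit mixtures on $n = 300$, 15-dimensional two-component
data at 5$\sigma$ separation across 10 seeds, and compare Monte-Carlo
(100,000 draws) against exhaustive (all 220 subsets of a 12-compound
universe, reference size 3) permutation P-values on 20 random link tables.
These sizes make the whole suite complete in about a minute while keeping
every estimate's sampling error far from its pass boundary. One
calibration note: at 5$\sigma$ Euclidean separation in 15 dimensions the
Bayes-optimal classifier itself misassigns about 0.6% of points, so
per-seed adjusted Rand indexes occasionally dip below 0.95; recovery is
therefore asserted across seeds rather than per seed.

## Known limitations

* Interaction existence is a hard `combined_score > 0` cut; no use is made
  of score magnitude at step 1.
* The permutation test is resampling-only; no analytical approximation is
  offered, and no multiple-testing correction is applied (the thresholds
  are calibrated on the drugs, not on a false-discovery target).
* The mixture model is diagonal-covariance; strongly correlated feature
  channels (e.g. textmining vs combined) are modeled as independent within
  a component. Full covariance would cost $O(d^2)$ parameters per
  component on 15-dimensional cohorts that are often smaller than that.
* Cluster counts selected by cross-validated likelihood on small cohorts
  (tens of rows) are noisy; the iterative refinement and the plurality
  rule are deliberately robust to mild over-splitting.
* A single organism code per run; cross-species transfer is out of scope.

## A minimal run

```{r example, eval = FALSE}
bundle <- generate_fixture(fixture_spec(seed = 42), tempdir())
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
network <- export_subnetwork(report)
```
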