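# cdk11net

Nominating the central node of a kinase signalling network from
siRNA-knockdown expression profiling — the computational arm of a study
design in which CDK11 is knocked down in two osteosarcoma cell lines, the
genes that respond in both lines seed a gene-network reconstruction whose
most central member (the androgen receptor in the motivating data) becomes
the mechanistic hypothesis, and a tissue-microarray (TMA) cohort tests that
gene's prognostic value.

The package is for computational biologists who want this analysis as
tested, reusable R code: every stage is a documented function, every input
can be synthesized with planted ground truth, and the recovery behaviour of
the whole pipeline is measurable.

## What it computes

* **Detection calls** — the Wilcoxon signed-rank presence/absence
  algorithm on probe-pair discrimination scores
  *R*ᵢ = (PMᵢ − MMᵢ)/(PMᵢ + MMᵢ), tested one-sided against τ = 0.015; the
  exact null distribution is enumerated over all 2ⁿ sign assignments for
  n ≤ 12 probes (P < 0.04 ≤ M < 0.06 ≤ A).
* **Preprocessing** — log2, quantile normalization, median-polish
  probe-set summarization; probe sets Absent everywhere or with max
  log2 value ≤ log2(100) are dropped.
* **Differential expression** — per line, d = control − knockdown;
  z = (d − μ)/σ; hits at |z| ≥ 3; the common hit set is the per-gene
  intersection across cell lines with probe averaging, keeping
  direction-discordant genes flagged.
* **Network reconstruction** — seed + linker subgraph components scored by
  the hypergeometric tail, anchor-containing subnetworks merged, filtered
  to bone/neoplasm-tagged nodes, and ranked by composite
  degree/betweenness centrality.
* **TMA survival** — 6-group nuclear-staining categorization (low ≤ 2+,
  high ≥ 3+), stratified summary tables, chi-square, mid-rank Spearman,
  Kaplan–Meier, log-rank, and (stepwise) Cox proportional hazards.

## Worked example

```r
library(cdk11net)

run <- runPipeline(pipelineConfig(seed = 42), outDir = "demo_run")
makeReport("demo_run")
```

The report (`demo_run/report.md`) from that exact call reads, in part:

```
- lineA: 30 hit probe sets
- lineB: 29 hit probe sets
- common genes across lines: 19

### Recovered vs planted shared responders
- planted: 20, recovered: 19, missed: 1, false: 0

- nominated central node: AR
- planted hub: AR (recovered)

- AR vs CDK11 staining chi-square: 29.182 (p = 6.59e-08)
- Spearman rho (AR vs CDK11 categories): 0.785
- log-rank AR high vs low: 9.153 (p = 0.00248)
- Cox HR, AR high vs low: 2.258
```

Reading: of 20 probe sets planted to respond to the knockdown in *both*
cell lines, 19 cleared the |z| ≥ 3 threshold in both lines' hit lists with
no false common genes; the network stage nominated the planted hub as the
central node; and on the simulated 87-patient cohort (latent staining
correlation 0.8, planted hazard ratio 2.5) the staining association and
survival statistics point the expected way.

Real data replace the simulators through the plain-text readers
(`readProbeTable()`, `readCohort()`, `readGraph()`): any conforming probe
table + sample sheet, cohort CSV, or edge list feeds the same functions.

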