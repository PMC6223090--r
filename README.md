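# tfburden

Localized somatic mutation burden at transcription factor binding sites.

In many tumors, somatic mutations are not spread evenly across non-coding
DNA: they pile up at the binding sites of lineage transcription factors —
in estrogen-receptor positive breast cancer, at estrogen receptor binding
sites. `tfburden` is an R package plus a scripted analysis workflow for
detecting and interpreting that pattern:

* **Rate profiles** — observed per-position mutation rates around
  binding-site summits (±1 kb; ±5 kb for indels), after masking coding,
  blacklisted, low-mappability and other-TF positions.
* **Context-expected rates** — a 96-class trinucleotide substitution model
  fitted to the in-window SNVs; each resampling round re-places every class's
  observed count among positions with matching sequence context, giving the
  rate expected from composition alone (1000 rounds).
* **Enrichment statistics** — core (±200 bp) vs flank (200 bp–1 kb) fold
  change with Pearson chi-square and Benjamini–Hochberg correction per
  analysis family; stratification by binding intensity quartile,
  patient-sharing class, genomic context, substitution class and outcome.
* **Covariate-corrected regression** — negative binomial GLMs (log link) for
  mutation counts and chromatin contact frequencies, Wald and
  likelihood-ratio inference, residual-based covariate removal.
* **Topology-aware expression** — target genes assigned through chromatin
  loops constrained to the site's TAD, versus a linear-proximity (50 kb)
  control, compared across site mutation groups (0/1/2/≥3) by nested
  region- and gene-sampling.
* **ChIP-seq variant screening** — pileup allele counts at known somatic
  positions with the ≥10-reads-and-both-alleles filter, summarized per
  outcome class.
* **Motif-shift scoring** — PWM likelihood-ratio scores of reference vs
  mutant alleles restricted to windows overlapping the mutation, with
  empirically calibrated (P ≤ 10⁻³) confidence thresholds.
* **A seeded synthetic-data generator** — emits every input (FASTA,
  narrowPeak, mutation TSV, BEDPE, BED, gene/pileup TSVs plus a ground-truth
  sidecar) with the statistical structure the analysis assumes, so the whole
  pipeline runs and is validated without controlled-access data.

The core statistic: with `m` mutations over `n` valid positions in the core
and flank respectively,

```
FC = (m_core / n_core) / (m_flank / n_flank),   chi2 on [[m, n - m]] rows
```

and the context-expected curve at offset k is the resampling mean of placed
counts divided by valid positions at k.

## Worked example

```r
library(tfburden)

cfg <- sim_config(seed = 20260101L)          # 12 Mb genome, 5000 sites
d   <- simulate_dataset(cfg, "results/synthetic_data")

res <- run_full_analysis("results/synthetic_data", "results/burden",
                         stages = c("rates", "enrich", "stratify"),
                         config = pipeline_config(seed = 20260102L))
```

On this dataset (planted core enrichment 1.25×) the run prints, via
`analysis/02_burden_profiles.R`:

```
core-vs-flank enrichment (all sites): FC = 1.269, q = 9.17e-61
intensity quartiles: Pearson r (mean intensity vs core rate) = 0.996
sharing classes FC: patient_specific=0.33, shared_2=0.503, shared_gt3=1.46
outcome burden means: core=1.321, good=1.257, poor_met=1.858
top-burden site: site_01003 with 8 core mutations from 8 donors
```

`FC = 1.269` is the recovered planted enrichment (the observed/expected
core-rate ratio is 1.20 after accounting for sequence context); the quartile
correlation and the monotone sharing-class fold changes reproduce the
intensity and sharing effects the generator plants; the poor/met outcome
group carries the planted extra burden. `analysis/03_regression_topology.R`
then shows the sharing effect surviving intensity correction
(Wald p = 1.4e-19) and, on a sparse one-site-per-50 kb layout, the
expression contrast that distinguishes topological from linear target
assignment:

```
topological 0 vs 3+: p = 1.87e-173 (group means 23.8, 23.7, 24.2, 62)
proximity_50kb 0 vs 3+: p = 0.415  (group means 24.4, 24.6, 24.7, 24.5)
```

The numbered scripts under `analysis/` run the full sequence
(`01_simulate_data.R` → `05_motif_shift.R`), each writing its tables under
`results/`.

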