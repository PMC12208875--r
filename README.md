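# pvresist

Predicting resistance to hydroxyurea in polycythemia vera from
pre-treatment blood counts.

## What this package is for

Polycythemia vera (PV) is a myeloproliferative neoplasm usually treated
first-line with hydroxyurea (HU). A substantial minority of patients become
HU-resistant (HU-RES) in the European LeukemiaNet sense — continued
phlebotomy need, uncontrolled hematocrit, or persistent
leukocytosis/thrombocytosis — and benefit from an early switch to
second-line therapy. `pvresist` is aimed at biostatisticians and
clinical-data scientists who want to build or audit this kind of
risk-stratification analysis on EHR-like longitudinal data:

* a **synthetic cohort generator** that reproduces published group-wise
  baseline moments (e.g. RDW 18.1% (SD 3.22) in resistant vs 17.1% (3.05)
  in non-resistant patients, 733/571 outcome split) and can plant an
  RDW x HGB interaction on resistance risk;
* the **inclusion funnel** and windowed **ELN-adapted resistance labeling**
  (6–9-month post-index window, ±14-day tolerance, no dose clause);
* a cross-validated **random-forest feature ranking** (stratified 80:20
  split, 5-fold CV, composite ROC-AUC of pooled out-of-fold predictions);
* **maximally selected log-rank threshold scans** for single variables and
  variable pairs, with the multiplicative **synergy score**

  $$S_{ab} = \frac{P_a \cdot P_b}{P_{ab}}$$

  where $P_a$, $P_b$ are the best single-variable log-rank p-values and
  $P_{ab}$ the best pairwise (quadrant-vs-rest) p-value — $S_{ab} \gg 1$
  flags super-multiplicative pairs;
* **quadrant enrichment**, Kaplan–Meier stratification, high-vs-low-RDW
  group comparisons, the fixed two-threshold RDW/HGB risk rule, and a
  reproducible end-to-end pipeline.

The methods vignette (`vignettes/hu-resistance-workflow.Rmd`) documents the
model assumptions, parameter choices and known limitations.

## Worked example

```r
library(pvresist)

cfg <- default_pipeline_config(seed = 42)
cfg$cohort$n_patients <- 800
cfg$cohort$interaction_effect <- 2.5   # plant a strong RDW x HGB interaction
rep <- run_pipeline(cfg, outdir = "pvresist_out", plots = FALSE, quiet = TRUE)
print(rep)
```

```
Hydroxyurea-resistance analysis report
Inclusion funnel:
  all                       800
  hu_index                  800
  ...
  pre_index_lab             800
Labeled resistant: 516 / 800
Composite CV ROC-AUC: 0.781 (validation 0.825)
Top synergy pair: RDW-HGB, S = 1.9e+04 at (16.9189, 15.333)
```

All 800 simulated patients pass the funnel (the generator builds eligible
timelines by default); 516 are labeled resistant from their timelines alone.
The forest separates resistant from non-resistant patients with a composite
out-of-fold ROC-AUC of 0.78, and the pairwise scan finds the planted
interaction: the best pairwise split lands at RDW ≥ 16.9% / HGB < 15.3 g/dL
— within one grid step of the planted (17, 15.5) — in the high-RDW/low-HGB
quadrant (Q1), with synergy score 1.9 × 10⁴.

```r
print(rep$quadrants)
#>   quadrant   n n_resistant enrichment
#> 1       Q1 226         217  1.4886465
#> 2       Q2 219         138  0.9769566
#> 3       Q3 204          92  0.6991944
#> 4       Q4 151          69  0.7084553
```

Resistant patients concentrate in Q1 (enrichment 1.49, i.e. the resistant
proportion inside the quadrant is 1.49 times the cohort prevalence) and are
depleted in the low-RDW quadrants — the pattern the two-threshold risk rule
(`classify_quadrant()`) turns into high / intermediate / lowest risk
classes. Single quantities work the same way:

```r
synergy_score(2.74e-9, 6.82e-3, 4.67e-15)  # 4001.456
ci_halfwidth(0.80, 120, 0.95)              # 0.07156 -> prints as ±0.072
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R --seed 7 --outdir out --no-plots
```

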