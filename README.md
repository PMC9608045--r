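# ddisignal

Detection of **multiple drug-drug-interaction (DDI) signals** — interactions
requiring three or more specific drugs — from spontaneous-reporting-system
(SRS) adverse-event data, for pharmacovigilance analysts and
pharmacoepidemiologists.

Pairwise disproportionality screens cannot express higher-order
interactions, and regression needs one term per combination. `ddisignal`
instead recursively partitions the cases using an *index drug* (the
motivating application: each of the six statins marketed in Japan, with
rhabdomyolysis, MedDRA PT 10039020, as the outcome) on binary
concomitant-drug indicators. At each node the split maximizes the
likelihood-ratio chi-square

G² = 2 Σ O ln(O/E)

over the 2×2 group-by-event table, with every node holding ≥ 10 cases. Each
resulting stratum's reporting rate k/n is then compared with the cohort's
initial rate (IR) by a two-sided exact binomial test, with
Benjamini–Hochberg adjustment at q = 0.05 across the tree's nodes.
Significant strata whose path is a pure drug-presence conjunction and whose
rate exceeds the IR are reported as candidate drug combinations.

Before any of that, cases pass a cleaning cascade: index-drug selection,
whole-case exclusion of injectable-route cases, collapse of duplicate
reports (same sex, age band and registered drug set → first-registered case
kept), and a per-case drug-timing filter against event onset (drugs started
after onset dropped; discontinued drugs kept only within 7 days of onset;
open-ended drugs kept only if started within 365 days; undated drugs kept).

## Worked example

Real SRS databases are external downloads, so the package ships a generator
that emits the same three-table layout with known ground truth. Here a
three-drug interaction (multiplier 8 on a 0.05 baseline) is planted and
recovered:

```r
library(ddisignal)

sc <- simulation_config(
  n_cases = 3000, baseline_event_prob = 0.05,
  drug_prevalence = c(rep(8, 3), rep(1, 27)),
  planted_effects = list(list(drugs = c("drug01", "drug02", "drug03"),
                              multiplier = 8)),
  seed = 42)
sim <- simulate_dataset(sc)
analyze_dataset(sim$dataset, "pitavastatin")
#> Signal report: pitavastatin
#>   Combination                         Cases  Cases(+)   Rate
#>   -                                    2749       294  0.11 (IR)
#>   drug03                               1448       240  0.17   p.adj=1.14e-10
#>   drug03 + drug02                      817        204  0.25   p.adj=1.588e-29
#>   drug03 + drug02 + drug01             484        184  0.38   p.adj=1.03e-53
```

Reading the output: of 3000 simulated cases, 2749 survive extraction and
monotherapy exclusion with 294 events — an IR of 0.11 (the planted carriers
inflate the baseline). The tree isolates the planted triple: the 484 cases
taking all of drug01+drug02+drug03 report the event at 0.38 versus the 0.11
reference, and the combination survives BH adjustment by a wide margin.
Rates are displayed with half-up rounding to 2 decimals; p-values are exact
binomial against the IR.

File-based analysis with artifacts (signal TSV, tree JSON, exclusion audit,
manifest):

```r
run_analysis("demo.csv", "drug.csv", "reac.csv",
             index_drugs = statin_names(), out_dir = "out")
```

A thin command-line wrapper lives at `inst/cli/ddisignal.R`
(`Rscript ddisignal.R {run|simulate|calibrate} ...`).

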