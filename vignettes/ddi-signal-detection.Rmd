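---
title: "Detecting multiple drug-drug-interaction signals by recursive partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multiple drug-drug-interaction signals by recursive partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddisignal)
```

## The problem

Adverse events caused by interactions of three or more specific drugs
("multiple" drug-drug interactions) are nearly invisible to the standard
pharmacovigilance toolkit: pairwise disproportionality screens cannot express
them, and logistic models need an infeasible number of interaction terms.
`ddisignal` implements an alternative that scales to higher-order
combinations: recursively partition the cases that use an *index drug* (for
the motivating application, one of the six statins marketed in Japan, with
rhabdomyolysis as the target event) on the presence/absence of each
concomitant drug, then ask whether any resulting stratum reports the event
at a rate incompatible with the cohort-wide *initial rate* (IR).

The input is a spontaneous-reporting-system (SRS) extract in the common
three-table layout — DEMO (case id, sex, age band), DRUG (case id, drug
name, route, start/end dates), REAC (case id, MedDRA preferred-term code,
onset date) — linked by a shared case identifier.

## The procedure

1. **Case extraction.** Cases with at least one index-drug record are
   selected. Cases containing any injectable-route drug are removed in full
   (injectables are typically given *to treat* an event during
   hospitalization). Cases matching on sex, age band and the complete set of
   registered drug names are treated as duplicate reports; only the
   first-registered one (DEMO row order) is kept. Finally, within each case,
   drugs are filtered by timing against the event onset date: drugs started
   after onset are dropped; drugs discontinued before onset are kept only if
   still in use within 7 days of onset; drugs with a start date but no end
   date are kept only if started within 365 days of onset; drugs spanning
   onset, and undated drugs, are kept. If the case has no onset date at all,
   every registered drug is kept. A case whose index drug fails the timing
   filter leaves the cohort. Every case-level exclusion is written to an
   audit log, so selected = survivors + per-stage exclusions always holds.
2. **Features.** Index-drug monotherapy cases are excluded; the IR is the
   event proportion over the remaining cases. Each concomitant non-statin
   drug becomes a binary indicator; the number of retained drugs per case
   (including the index drug) enters as an ordered numeric covariate.
3. **Tree.** Starting from the root (all cases), each node is split by the
   candidate — a drug indicator, or a midpoint threshold on the drug count —
   that maximizes the likelihood-ratio chi-square
   \(G^2 = 2\sum O\ln(O/E)\) of the 2×2 group-by-event table, subject to
   both children containing at least `min_node = 10` cases. Splitting stops
   at purity, at `max_depth`, or when no admissible candidate improves on
   zero. There is no pruning: screening happens in the testing step, not in
   the tree.
4. **Testing.** Every non-root node's rate \(k/n\) is compared with the IR by
   a two-sided exact binomial test with the IR as a fixed reference
   proportion; Benjamini-Hochberg adjustment is applied across all non-root
   nodes of the tree, and nodes with adjusted \(p \le q = 0.05\), a pure
   presence path, and rate above the IR form the headline signal table, each
   labeled by its drug combination ("allopurinol + valsartan" style).

```{r}
wf <- make_worked_fixture()
sig <- suppressWarnings(analyze_dataset(wf$dataset, "pitavastatin"))
sig
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `discontinuation_window_days` | 7 | days (inclusive) a discontinued drug may precede onset and still count |
| `open_start_window_days` | 365 | days (inclusive) an open-ended drug may precede onset |
| `min_node` | 10 | minimum cases per tree node, parent and child |
| `max_depth` | 10 | cap on the number of conditions in a path |
| `fdr_q` | 0.05 | Benjamini-Hochberg level |
| `event_pt_code` | "10039020" | MedDRA PT defining the outcome (rhabdomyolysis) |

Window boundaries are **inclusive** ("within one week" means
onset − end ≤ 7 days); this is the least surprising reading of the rules and
is fixed, not configurable per boundary. `min_node = 10` is the method's
published operating point: with the exact binomial test, a 10-case node
needs roughly a four-fold rate elevation over an IR near 0.1 to reach
significance, which is the size of jump the method is designed to surface.

## Design choices where the design was genuinely open

* **Split criterion.** "Maximizing the likelihood ratio" is implemented as
  the \(G^2\) likelihood-ratio chi-square, the criterion used by the
  classical partition platforms for categorical responses. Its monotone
  transform ("LogWorth", \(-\log_{10}p\)) orders a fixed 2×2 family
  identically, so the choice does not affect which split wins. Pearson
  \(\chi^2\) is available via `tree_config(criterion = "pearson")` for
  sensitivity analysis.
* **Proportion test.** A one-sample *exact* binomial test against the IR:
  node sizes run as low as 10, where normal-approximation tests misbehave. A
  chi-square variant is available behind `method = "chisq"`. The IR is
  treated as a fixed reference, not estimated with error; with node n's two
  orders of magnitude below the cohort n, the extra variance is negligible.
* **Multiplicity family.** BH runs over all non-root nodes of one index
  drug's tree; analyses of different index drugs never share state, so each
  is its own family. A joint family across index drugs would only make the
  adjustment more conservative.
* **Onset anchor.** When a case reports several events, the earliest
  non-missing onset date anchors the timing filter. This is the conservative
  choice (it excludes the most late-started drugs) and the only one that
  needs no event-to-drug attribution, which SRS data do not provide.
* **Partial dates.** Year- and month-granular dates are treated as missing
  for timing (never imputed); drugs with no usable dates are retained, since
  the rules exclude only drugs *demonstrably* started late or stopped early.
  Records whose start postdates their end are kept but their dates are
  ignored, as silently dropping such rows would bias counts.
* **Deduplication key.** The raw age-band string is matched verbatim, and
  "first registered" means DEMO row order, which is registration order in
  SRS extracts.
* **IR timing.** The IR is computed *after* monotherapy exclusion — it
  describes the population the tree actually partitions.
* **Drug-name matching** is exact after whitespace trimming. Orthographic
  variants (brand vs generic, salt suffixes) are *not* unified; on real
  extracts a harmonization pass should precede analysis. This is the main
  fidelity gap for production use.

## The synthetic generator

Real SRS databases are external downloads, so validation runs on simulated
extracts with known ground truth. `simulation_config()` defaults describe
the study conditions used throughout: 2000 cases, a 30-drug concomitant
vocabulary with mildly skewed (\(1/\sqrt{j}\)) prevalence weights, a
truncated-at-one Poisson(4) concomitant count (about five drugs per case
with the index drug, i.e. a polypharmacy population), baseline event
probability 0.10, 10% missing onset dates, 20% undated drug rows, 2%
duplicate reports and 2% injectable cases. Planted interactions are
*pure*: a risk multiplier applies only when every drug of its set is
present, so detection cannot ride on marginal main effects. Risk is
multiplicative with a cap at 0.95, which keeps planted jumps (0.05 → 0.40)
expressible in the same units as the reported rates.

The generator does **not** emulate correlated co-prescription structure,
drug-role (suspected vs concomitant) fields, MedDRA coding noise, or
reporting biases such as notoriety effects. Passing tests therefore
demonstrate that the pipeline recovers what it claims under its own model
of the data, not that real-extract signals are causal.

Two standing study designs are packaged:

* `planted_triple_config()` — 5000 cases, baseline 0.05, one planted triple
  with multiplier 8 and prevalence weights set so about 4% of cases carry
  all three drugs. `run_recovery_study()` over 20 replicate seeds measures
  how often a significant presence path covers the full triple.
* `run_null_calibration()` — 200 replicates of the no-effect default
  configuration. Because nodes are *selected* greedily before being tested,
  the BH step does not confer nominal FDR control over the reported
  combinations; post-selection inference is anticonservative by
  construction. The package therefore claims only an empirically tracked,
  deliberately lenient bound: the frequency of at least one reported signal
  under the null stays below 0.25 at \(q = 0.05\) (measured values sit
  around 0.10–0.16). The problem sizes above keep the whole validation
  suite in the minutes range on one CPU.

## Numerical conventions

* \(0\ln(0/E) = 0\) in \(G^2\); degenerate event margins give exactly 0.
* Split ties (within \(10^{-9}\) relative) break deterministically: binary
  drug splits before drug-count thresholds, then lexicographic variable
  name, then smaller threshold. Identical inputs yield byte-identical trees
  and reports.
* Published-style rates display with half-up rounding to 2 decimals
  (5/13 → 0.38, 7/16 → 0.44); internal arithmetic is full precision.
* An observation impossible under a degenerate reference (\(ir \in \{0,1\}\))
  returns the smallest positive double rather than an exact zero p-value,
  with a warning.

## Known limitations

Beyond the generator's simplifications: exact-string drug matching; the
earliest-onset anchor when multiple events are reported; no handling of the
primary-disease (HIST) table; no time-on-drug analysis (SRS date quality
rarely supports it); and, fundamentally, reporting rates in an SRS are not
incidence — a detected combination is a hypothesis for pharmacological
follow-up, not a clinical effect estimate.
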