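---
title: "Analysing the ex vivo plasma degradome from PSM tables"
author: "degradomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing the ex vivo plasma degradome from PSM tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomeR)
```

## The model

Blood plasma contains endogenous tryptic peptides: fragments cut from
plasma and cellular proteins by native trypsin-like endopeptidases,
largely *ex vivo*. An ion-trap LC–ESI–MS/MS experiment on such samples
yields, per run, hundreds of thousands of candidate MS/MS-to-peptide
correlations (PSMs) from search engines, and three distinct error
processes ride along with the signal: re-use of one spectrum under several
charge states or peptide sequences; random mis-correlations that
accumulate on the largest proteins of the library (titin-class artefacts);
and environmental contamination (source noise, laboratory dust, keratins).

`degradomeR` treats the analysis as a fixed, deterministic cascade
followed by three orthogonal statistical controls:

* **Dedup cascade.** A complex key over (spectrum, charge, peptide,
  accession) enforces that each spectrum contributes exactly one
  correlation: the best-scoring charge state, then the best-scoring
  peptide, then one accession chosen by the gene-rollup representative
  rule (the accession with the most correlations; ties are always broken
  deterministically — lower charge, lower p, lexicographic peptide,
  lexicographic accession). An intensity floor of 1000 detector counts is
  applied first; "at least one thousand" is read inclusively (`>=`), with
  a strict mode available. "Five or more independent peptides" counts
  RANK1 correlations per accession by default, since that is the
  arithmetic that connects the correlation counts to the accession filter;
  a distinct-sequence mode is a configuration flag.
* **Gene-level significance.** Peptide p-values are combined per gene
  symbol. The default is the raw product ("cumulative p-value"),
  computed in log space; the back-transformed product can underflow to
  double 0 for strongly supported genes, which downstream BH treats as
  q = 0. Fisher's method (chi-square with 2k df) is the calibrated
  alternative and the better choice when the q-values are interpreted as
  error rates, because the raw product rewards peptide count as much as
  peptide quality. Benjamini–Hochberg adjustment is applied across gene
  symbols (one combined value per symbol), not across peptides, since the
  reported inventory is per gene symbol; the peptide-level alternative is
  available by summarising the peptide table directly.
* **Null model.** Random assignment of correlations to the digest of the
  whole library, with hit probability proportional to each accession's
  tryptic-peptide count. This reproduces the giant-protein artefact
  without needing a spectrum-level random generator plus a search engine:
  the downstream statistic only consumes the count distribution, so the
  assignment-level null is sufficient and orders of magnitude cheaper.
* **Treatment ratio.** Per gene symbol,
  `((n_RT + c)/runs_RT) / ((n_ICE + c)/runs_ICE)`. The pseudocount
  `c = 1` keeps genes absent from the ICE arm finite (RT-specific genes
  are real and numerous); run normalization is on by default because the
  arms had 82 vs 88 runs. A fivefold threshold (boundary inclusive)
  defines the degradation-released list; contaminants shared by both arms
  sit near ratio 1 and fail it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_intensity` | 1000 counts | precursor intensity floor (inclusive) |
| `min_peptides` | 5 (3 for permissive screens) | RANK1 correlations per accession |
| `fold` | 5 | RT/ICE enrichment threshold |
| `fdr` | 0.01 | gene-level BH threshold |
| `pseudocount` | 1 | added to both ratio counts |
| `cumulative_method` | product | or `fisher` |
| proline rule | on | KP/RP junctions are not cleavage sites |
| proton mass | 1.007276 Da | m/z ↔ neutral mass conversion |
| χ² pooling | expected < 5 | bins pooled into the right tail |
| log10 intensity bin | 0.25 | histogram width |

The proline rule is a convention choice: the enzyme specification of the
search engines is not observable from their output, so the standard
KP/RP suppression is applied consistently to digestion, missed-cleavage
counting and terminus checks, and is toggleable everywhere. Monoisotopic
residue masses are the default; an average-mass table and per-residue
overrides exist for low-resolution realism.

## What the generator emulates

`simulation_design()` fixes the study conditions: 82 ice-preserved and 88
room-temperature runs, ~3,400 spectra per run at full scale (the
per-run depth implied by ~584k spectra over 170 runs), 74% gene-symbol
coverage of the library, Beta(0.05, 1) true-PSM p-values against
Uniform(0, 1) mis-correlations, log-normal intensities with a higher
room-temperature mean, a Normal(0, 0.4) delta mass truncated to ±2 Da,
degradation folds of 10^U(0.7, 2) (five to a hundredfold) on a configurable
fraction of genes, isoforms sharing ≥ 70% (at least 50%) of tryptic
fragments within a gene symbol, and contaminant genes — including
giant-protein stand-ins with long sequences — injected at equal per-run
rates in both arms. Every random draw descends from one mandatory seed and
the design serializes to JSON beside its outputs.

What it does **not** emulate: fragment-ion spectra, retention time and
co-elution structure, exopeptidase trimming of tryptic termini,
between-donor biological variance, and instrument drift across runs.
Passing tests on synthetic data therefore demonstrate that the *analysis*
is correct under its stated statistical assumptions, not that those
assumptions exhaust real plasma data.

## Numerical and design choices

* Tie-breaks are total and documented, so cascade output is reproducible
  bit for bit; re-running the cascade on its own survivors is a fixed
  point.
* The Pearson goodness-of-fit test scales the null histogram to the
  observed total and pools bins with expected counts below 5 into the
  right tail; its type-I error calibrates to the nominal 5% under
  resampling from its own null. When real and null identification sets
  are compared, the peptides-per-protein histogram is capped at a 20+
  tail bin: at realistic depth the raw per-protein counts are sparse and
  unique, and an uncapped histogram dissolves into singleton bins with no
  power. The comparison is run at single-run depth against a library that
  is large relative to it, the regime in which random assignment spreads
  thin while true abundances concentrate.
* The category-enrichment module is a generic hypergeometric
  reimplementation: the exact internals of external annotation servers
  are not reproducible, so their published tables are qualitative
  references only. The multiple-testing universe defaults to terms that
  overlap the query set, with an all-terms toggle.
* Recovery of degraded genes is evaluated against degraded genes that
  carry a defined gene symbol: the pipeline reports per gene symbol and
  excludes unannotated accessions from rollup by design (they are counted
  and reported separately), so symbol-less genes are unrecoverable at the
  gene level by construction, not by failure of the screen.
* The order consensus-then-fivefold is the default (`run_pipeline()`
  flag `consensus_before_fold`): restricting to cross-algorithm-supported
  genes first means the fold filter ranks only identifications both
  engines agree exist. The reverse order is one flag away.
* The spec-level command-line surface is fulfilled by the exported
  function interface (`run_pipeline()` + `pipeline_config()`); an R
  session is the natural shell for this package's users.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the generator at reduced
scale, chosen as the smallest sizes at which every property is
statistically unambiguous: 40 genes × (82 + 88) runs at 30 spectra/run for
the recovery screen (~20k correlations; tenfold degraded genes with ≥ 20
expected ICE correlations are recovered with ≥ 90% recall and ≤ 10% false
discoveries); 800 genes at 2,000 spectra for the null-model separation;
1,000 Monte-Carlo replicates for the goodness-of-fit calibration; 1,000
random tables for the dedup oracle; 10,000 random p-vectors for the BH
oracle.

## Known limitations

* SEQUEST output carries no native p-value; the package treats both
  engines' scores on a common p-value column and leaves score-to-p
  conversion to the caller.
* The product cumulative p-value is not a calibrated p-value; it is kept
  (and named) as the conventional summary, with Fisher's method provided
  for calibrated inference.
* Time-course kinetics over 0–72 h are out of scope: all room-temperature
  times are pooled, as in the underlying experimental design.
* pepXML/mzIdentML/mzML parsing and database back-ends are out of scope;
  the I/O dialect is a single strict TSV/FASTA convention.
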