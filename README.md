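# degradomeR

Analysis of the *ex vivo* degradome of human blood plasma from
peptide-spectrum-match (PSM) tables.

## The scientific problem

Normal plasma carries endogenous tryptic peptides: fragments released from
blood and cellular proteins by native trypsin-like endopeptidases, most of
them generated *ex vivo* once a sample leaves the body. Comparing plasma
collected and kept on ice (ICE, proteases quiescent) against plasma
incubated at room temperature (RT, proteases active) turns this sampling
artefact into an assay: proteins whose peptide counts rise sharply with
temperature are the substrates of endogenous proteolysis, while random
mis-correlations, source noise and laboratory dust appear equally in both
arms and cancel out of the comparison.

`degradomeR` implements the full desk side of such an experiment for
researchers working with ion-trap LC–ESI–MS/MS search-engine output
(X!TANDEM, SEQUEST):

1. **Filtering cascade** — from raw MS/MS-to-peptide correlations to a
   non-redundant gene-symbol inventory. Stages, in fixed order: precursor
   intensity ≥ 1000 counts; best-scoring charge state (2+/3+) per spectrum;
   best (lowest-p) peptide per spectrum, so no spectrum is assigned twice;
   collapse of peptides shared by isoforms to one accession per spectrum
   (RANK1); ≥ 5 correlations per accession; one representative accession
   per gene symbol. Every tie-break is deterministic (lower charge, lower
   p, lexicographic peptide, lexicographic accession).
2. **Gene-level significance** — per gene symbol the cumulative p-value
   (product of peptide p-values, or Fisher's method:
   `P(χ²_{2k} ≥ −2 Σ log pᵢ)`), with Benjamini–Hochberg q-values across
   gene symbols.
3. **Null-model comparison** — the peptides-per-protein distribution is
   tested against a random-assignment null (hits proportional to each
   protein's tryptic-peptide count, which concentrates on giant proteins
   such as TTN and NEB) with a tail-pooled Pearson goodness-of-fit test.
4. **RT/ICE enrichment** — per gene symbol the normalized ratio
   `((n_RT + c)/runs_RT) / ((n_ICE + c)/runs_ICE)`, a fivefold filter for
   degradation-released proteins, contaminant flagging against the three
   published catalogues (random mis-correlation, source noise, dust), and
   the cross-algorithm consensus rule (SEQUEST ≥ 5 peptides ∧ X!TANDEM
   ≥ 1).
5. **Category enrichment** — generic hypergeometric term enrichment with
   Bonferroni and BH corrections over a user-supplied annotation table.
6. **Synthetic data** — a fully seeded generator (`simulation_design()`,
   `make_library()`, `simulate_psm_tables()`, `simulate_null_table()`)
   producing redundant protein libraries, in-silico tryptic digests,
   paired two-algorithm PSM tables and null tables, with exported ground
   truth, so every stage is testable without raw instrument data.

## Worked example

```r
library(degradomeR)

design <- simulation_design(seed = 7, n_genes = 30, psms_per_run = 25,
                            n_ice_runs = 8L, n_rt_runs = 8L)
lib <- make_library(design)
sim <- simulate_psm_tables(lib, design)

res <- run_cascade(sim$xtandem, min_intensity = 1000, min_peptides = 3)
print(res)
#> Filtering cascade:
#>   RAW                       848
#>   INTENSITY_GE_1000         846
#>   BEST_CHARGE               787
#>   BEST_PEPTIDE              689
#>   RANK1_PEPTIDES            497
#>   ACCESSION_GE_K            469
#>   GENE_ROLLUP               298
#>   DISTINCT_GENES             18
#> 111 correlation(s) without a gene symbol excluded from rollup

ratios <- treatment_ratio(res$rank1, sim$manifest)
head(ratios, 3)
#>   gene_symbol count_rt count_ice runs_rt runs_ice    ratio
#> 1    GENE0007      197         6       8        8 28.28571
#> 2    GENE0018        3         0       8        8  4.00000
#> 3    GENE0027        3         0       8        8  4.00000

rt_enriched(ratios, fold = 5)   # genes released by room-temperature proteolysis
#> [1] "GENE0007"
```

Reading the output: 848 raw correlations deduplicate to 497 RANK1
spectrum-to-peptide assignments; 18 gene symbols survive the ≥ 3-peptide
filter; `GENE0007` shows a 28-fold normalized RT/ICE excess — in this
seeded simulation it is indeed a designed degraded gene
(`sim$truth$genes`), while the contaminants injected equally into both
arms sit near ratio 1 and are removed by the fivefold rule.

`run_pipeline()` wires all stages together and writes deterministic,
metadata-headed TSV artifacts (cascade report, gene summaries with
q-values, ratio table, contaminant-annotated enriched list, consensus
list, enrichment table).

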