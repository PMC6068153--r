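# tmtkda

Multi-plex TMT proteomics normalization, count-based differential protein
abundance, and key-driver gene-network analysis, with the phenotype and
metabolite statistics needed to tie protein changes to insulin-sensitivity
traits.

## The problem

Isobaric tandem-mass-tag (TMT) labeling quantifies up to ten samples per
mass-spectrometry run ("plex") via reporter-ion intensities. A factorial
animal study — say two genotypes × three diets × 4 replicates — spans
several plexes, each with its own multiplicative batch factor, so the
analysis must (1) make intensities comparable across plexes, (2) test
per-protein group differences with only a handful of replicates, (3)
summarize the resulting protein signatures across contrasts, and (4) place
those signatures on gene regulatory networks to nominate upstream
regulators ("key drivers"). `tmtkda` implements that pipeline for
researchers analyzing protein-level TMT exports, plus a synthetic-data
module that generates every input with planted ground truth so each stage
is testable without any external download.

## Methods at the core

- **Normalization.** Complete-case filtering (protein kept only if
  observed in every channel of every plex), sample-loading normalization
  (channel totals equalized within plex), then **internal reference
  scaling (IRS)**: per protein *i* and plex *p*, ref(*i*,*p*) is the mean
  of the reference channels, the target is the geometric mean of
  ref(*i*,·) across plexes, and all of plex *p* is scaled by
  target(*i*)/ref(*i*,*p*).
- **Differential abundance.** Intensities become library-equalized
  pseudo-counts; a single negative-binomial dispersion φ (variance
  μ + φμ²) is estimated by conditional maximum likelihood; each protein is
  tested with the **exact conditional split test** (condition on the total
  count, two-sided p = probability of splits no more probable than
  observed; φ = 0 reduces to the exact binomial test); Benjamini–Hochberg
  FDR per contrast.
- **Signatures.** FDR-thresholded protein sets with directions, Venn
  partitions, the diet-independent core (intersection, with discordance
  flags), and average-linkage Euclidean clustering of log2 sample profiles.
- **Networks & key drivers.** Consensus network keeping nodes/edges
  present in ≥ 2 study networks; every gene scored by the one-sided
  hypergeometric (Fisher) enrichment of its 1-hop neighborhood for
  signature genes; BH across testable genes; drivers called at q < 0.01,
  top 15.
- **Phenotypes.** Baseline-normalized trapezoidal AUC for tolerance
  tests, one-way ANOVA with Tukey HSD, Pearson correlation/regression for
  metabolite–protein associations.

## Worked example

```r
library(tmtkda)

# simulate a 2-genotype x 3-diet, 3-plex experiment with 10% of proteins
# planted 4-fold differential between genotypes
design <- experiment_design()                       # Csf2+/+ vs Csf2-/-, LF/HF/HFC, n = 4
sim    <- simulate_tmt_experiment(design, sim_params(n_proteins = 1000, seed = 42))

# complete cases -> sample loading -> internal reference scaling
norm <- quantify_plexes(sim$plexes, sim$metadata)
norm
#> tmt_norm: 1000 proteins x 24 samples
#>   provenance: complete_cases -> sample_loading -> irs

# contrast (a): wild type vs knockout on the low-fat diet
ct <- run_contrast(norm, contrast_specs()$a)
print(ct, n = 3)
#> contrast_table 'a': 1000 proteins, dispersion 0.09264, n = 4 + 4, 107 at q < 0.05
#>   protein log2_fold_change   p_value   q_value
#> 1  P00001      -0.70746187 0.0243234 0.1603010
#> 2  P00002      -0.03046988 0.9274174 0.9893772
#> 3  P00003       0.00000000 1.0000000 1.0000000

sig <- threshold_signature(ct, 0.05)
sig
#> tmt_signature 'a': 107 proteins at q < 0.05 (50 up, 57 down)

# three-study networks over the measured proteins, 10 planted key drivers
net  <- simulate_network(1000, n_planted_drivers = 10, enrichment = 5, seed = 43,
                         nodes = rownames(norm$values),
                         signature_genes = sim$truth$differential$protein)
cons <- consensus_network(net$networks, min_support = 2)
cons
#> gene_network: 1000 nodes, 1698 undirected edges

kd <- key_driver_analysis(cons, sig, q_cut = 0.01, top_k = 15)
head(as.data.frame(kd), 3)
#>     gene neighborhood_size signature_overlap expected_overlap fold_enrichment      p_value      q_value
#> 1 P00044                20                14             2.14        6.542056 2.588616e-10 5.531010e-08
#> 2 P00066                20                14             2.14        6.542056 2.588616e-10 5.531010e-08
#> 3 P00845                20                14             2.14        6.542056 2.588616e-10 5.531010e-08
sum(kd$gene %in% net$truth$planted_drivers)
#> [1] 8        # all 8 called drivers are planted ones

# phenotype statistics
auc_baseline(c(100, 200, 180, 150, 120))   # glucose at 0/15/30/60/120 min
#> [1] 6150                                 # mg/dL * min above baseline
correlate(c(1, 2, 3), c(2, 1, 3))$r
#> [1] 0.5
```

The dispersion line reads: the common NB dispersion estimated on this
contrast's 4 + 4 samples is ≈ 0.093 (data were generated at 0.1), and 107
of 1000 proteins pass FDR < 0.05 (100 were planted). The key-driver table
shows each candidate's 1-hop neighborhood size, its overlap with the
signature against the expected overlap for a random gene, the fold
enrichment, and the Fisher/BH significance.

A full run — simulation through report — is one call:

```r
report <- run_pipeline(list(seed = 1, output_dir = "run",
                            sim = list(n_proteins = 2000)))
```

which writes all intermediates (plex TSVs, normalized matrix, contrast
tables, signatures, Venn JSON, dendrogram, consensus edges, KDA audits,
phenotype tables) plus `report.json`. `inst/scripts/run_pipeline.R` wraps
this for the shell.

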