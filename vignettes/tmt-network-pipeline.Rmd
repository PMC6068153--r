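---
title: "From multi-plex TMT intensities to key driver genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-plex TMT intensities to key driver genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tmtkda` implements a multi-layer analysis for isobaric-label (TMT)
proteomics studies of metabolic phenotypes: normalization of reporter-ion
intensities across several TMT plexes, count-based differential protein
abundance, extraction of cross-contrast protein signatures, key-driver
analysis on consensus gene regulatory networks, and the phenotype and
metabolite statistics (tolerance-test AUC, ANOVA/Tukey, correlation) that
tie protein changes to insulin-sensitivity traits. The motivating design
is a mouse study with two genotypes (*Csf2*^+/+^ wild type and the
GM-CSF-deficient *Csf2*^−/−^ knockout), three diets (low-fat, high-fat,
high-fat + cholesterol) and n = 4 animals per group, quantified across
three TMT 10-plexes. This vignette explains each model, the tunable
parameters, the numerical choices, and what the synthetic-data module
does and does not emulate.

## Normalization: sample loading, then internal reference scaling

A TMT plex is a batch: up to ten samples are labeled, pooled and measured
in one LC-MS/MS run, so within-plex channel intensities are directly
comparable but between-plex intensities are not. Two multiplicative
corrections address this, in a fixed order enforced by a provenance
record on each table.

**Complete-case filtering** comes first: a protein is retained only if it
has strictly positive intensity in every channel of every plex. Zero is
treated as "not observed" rather than "absent", because isobaric
reporter-ion zeros are overwhelmingly missingness at the identification
level; downstream ratio-based corrections are undefined on zeros.

**Sample-loading (SL) normalization** rescales each channel within a plex
so all channel totals equal the grand mean of the totals — the in-silico
analogue of combining labeled samples in 1:1:...:1 ratios by total
reporter-ion intensity. After SL, channel totals agree to 1e-9 relative.

**Internal reference scaling (IRS)** removes the between-plex batch
factor per protein. For protein $i$ in plex $p$, the reference level is

$$\mathrm{ref}(i,p) = \text{arithmetic mean of the reference-channel
intensities},$$

and the scaling target is the geometric mean across plexes,
$T(i) = \left(\prod_p \mathrm{ref}(i,p)\right)^{1/P}$. Every intensity of
protein $i$ in plex $p$ is multiplied by $T(i)/\mathrm{ref}(i,p)$. The
geometric mean makes the factors symmetric under relabeling of plexes
(scaling plex A to B and B to A are consistent), and IRS is idempotent: a
second pass yields factors of exactly 1. Because the factor is a single
scalar per (protein, plex), within-plex between-sample ratios — the
quantities the differential test consumes — are untouched.

Two reference designs are supported, because pooled-standard channels are
common but not universal: if a plex designates reference channels those
are used; otherwise *mock-reference mode* takes the mean of all sample
channels as the reference, which removes the protein-level batch factor
in expectation but adds sampling noise proportional to the biological
spread within the plex.

## Differential abundance: an exact conditional count test

Reporter-ion intensities behave like overdispersed counts, and with
n = 4 per group an exact small-sample test is preferable to asymptotics.
The pipeline converts the normalized matrix to *pseudo-counts* — every
sample column is scaled to the geometric mean of the column totals and
rounded half-to-even to integers — so that library sizes can be treated
as equal, and then applies an exact conditional negative-binomial test:

1. **Common dispersion** $\phi$ (variance $\mu + \phi\mu^2$) is estimated
   by conditional maximum likelihood: for each protein, the distribution
   of its replicate counts given their group total does not depend on the
   mean, and the summed conditional log-likelihood over proteins is
   maximized over a single $\phi \in [0, 10]$. The $\phi = 0$ boundary is
   evaluated in closed form (the conditional law degenerates to an
   equal-probability multinomial), so perfectly replicated data return
   exactly 0.
2. **Exact split test.** For a protein with group totals $(z_A, z_B)$ and
   $n_A, n_B$ libraries, conditioning on $z = z_A + z_B$ gives a
   one-dimensional distribution over splits, proportional to
   $f(a;\,n_A/\phi)\,f(z-a;\,n_B/\phi)$ with $f$ the NB pmf. The
   two-sided p-value sums the probabilities of all splits no more
   probable than the observed one. At $\phi = 0$ this reduces exactly to
   the binomial split test: for a 2-vs-8 split of a total of 10 with
   equal sizes, $p = P(X \le 2) + P(X \ge 8) = 112/1024 = 0.109375$.
3. **Fold change** is $\log_2((\bar{y}_A + 0.5)/(\bar{y}_B + 0.5))$; the
   0.5 stabilizer keeps zero-count proteins finite. Positive values mean
   higher abundance in group A.
4. **FDR** is controlled per contrast by Benjamini–Hochberg over all
   quantified proteins.

This is deliberately the simplest member of the count-test family — a
single common dispersion and an exact conditional test — rather than
tagwise empirical-Bayes shrinkage or quasi-likelihood GLMs. With
thousands of proteins and a shared mean-variance regime the common
dispersion is estimated precisely (the test suite recovers
$\phi = 0.1$ within ±0.03 at 2000 proteins), and the exact test stays
honest at n = 4 + 4 where asymptotic tests can be anticonservative.

Numerically, the split distribution is enumerated in full for totals up
to 5000 and over a quantile-bounded window (tail mass $< 10^{-14}$,
always containing the observed split, renormalized within the window)
for larger totals; probability ties are compared with a $1 + 10^{-10}$
relative guard so that symmetric splits are counted exactly once each.
The "no more probable than observed" set is contiguous from both tails
because the conditional law is log-concave.

One practical caveat surfaced by the spike-in simulations: with 10% of
proteins spiked 4-fold (balanced up/down), total-intensity equalization
transfers a small amount of apparent change onto null proteins (the up
spikes add more total signal than the down spikes remove). The realized
FDR at q < 0.05 rises from the nominal ~0.05 to ~0.09–0.10 — still
controlled, but close to the bound; compositional corrections such as
TMM are out of scope here.

## Signatures, Venn partitions and the core set

A *signature* is the set of proteins with q-value below a cutoff
(default 0.05) in one contrast, with per-protein direction taken from
the fold-change sign. The nine standard contrasts (labeled a–i) are the
three genotype comparisons within diet and the six diet responses within
genotype. `venn_partition()` returns the exclusive regions of two or
three signatures (they always sum to the union), and `core_signature()`
intersects the genotype signatures across diets to produce the
diet-independent core. The core uses plain intersection: a protein
changing in opposite directions under different diets is retained but
flagged discordant, since requiring concordance is an additional
modeling decision the intersection itself does not imply.

`cluster_samples()` provides the standard structural check: average-
linkage agglomerative clustering of Euclidean distances between log2
sample profiles, to confirm samples group by genotype and diet rather
than by plex. Log2 first, Euclidean second — on raw intensities the
highest-abundance proteins would dominate the metric.

## Consensus networks and key-driver analysis

Gene regulatory networks from several independent studies are combined
by a support rule: the consensus keeps exactly the edges present in at
least `min_support` (default 2) study networks *and* the nodes present
in at least `min_support` study networks, with kept edges restricted to
kept nodes. Both the node and the edge filter are applied because
either alone admits elements seen in only one study. Edge identity
ignores direction by default (endpoints are stored in canonical order);
a directed mode treats A→B and B→A as distinct.

*Key-driver analysis* scans every background gene $g$: its neighborhood
is the set of nodes within `hops` steps (default 1, undirected), and the
overlap of that neighborhood with the signature is scored by the
one-sided hypergeometric (Fisher) upper tail,

$$p_g = P(X \ge k), \qquad X \sim
\mathrm{Hypergeom}(N = |\mathrm{background}|,\; K = |\mathrm{signature}|,\;
n = |\mathrm{neighborhood}|),$$

with expected overlap $nK/N$ and fold enrichment $k/(nK/N)$. BH
adjustment runs across all testable genes, and key drivers are the genes
with q below `q_cut` (default 0.01), sorted by q then fold, truncated to
`top_k` (default 15). Neighborhoods smaller than 3 are reported in the
audit table but flagged untestable and excluded from the FDR adjustment
— a 1- or 2-node neighborhood cannot carry meaningful enrichment but
would still spend multiple-testing budget. The background defaults to
all network nodes and should be intersected with the measured proteome
when one is supplied, so that enrichment is computed over genes that
could have entered the signature.

## Phenotype and metabolite statistics

- `auc_baseline()` integrates a tolerance-test curve after subtracting
  the time-0 value, by the trapezoidal rule on the measured time points
  (0, 15, 30, 60, 120 min). Net area is retained (dips below baseline
  subtract), since baseline normalization alone does not justify
  clipping. The result is invariant to adding a constant to the whole
  curve and linear in the excursion.
- `anova_tukey()` is one-way ANOVA with Tukey HSD pairwise comparisons
  via the studentized-range distribution (Tukey–Kramer for unequal n),
  through `stats::aov()`/`stats::TukeyHSD()`.
- `correlate()` returns Pearson r, r², least-squares slope/intercept and
  the two-sided p-value from the t-transform of r;
  `associate_metabolite_protein()` joins a metabolite table and a
  protein table on shared sample identifiers and applies it per
  requested pair — the workflow behind, e.g., the plasma
  2-aminoadipate vs adipose DHTKD1 association.

## The synthetic-data module

Every pipeline input can be generated with known ground truth, which is
how the package tests itself end to end.

**TMT tables.** Protein baselines are log-normal (default
`baseline_log_mean = 5.5`, `baseline_log_sd = 1`, i.e. median ~250);
reporter intensities are negative-binomial counts around the group mean
(default $\phi = 0.1$; $\phi = 0$ gives Poisson), matching the count
model the differential stage assumes — that choice is a stated
assumption of this package, not an empirical noise model. Each plex
carries a multiplicative batch factor (log-sd 0.3 by default,
protein-independent, with a protein-specific stress mode for IRS).
A configurable fraction of proteins (default 10%) is planted as
differential between the genotypes, half up and half down at a
configurable fold change (default 4). Reference channels are filled
with the rounded within-plex mean of the sample channels, emulating a
pooled standard. The baseline scale is kept count-like deliberately:
after SL and pseudo-count equalization only relative intensities matter,
and a modest count scale keeps the exact test's split enumeration cheap
without changing what is being tested.

**Networks.** A background random graph (expected degree 6) connects
non-driver nodes, so background neighborhoods contain signature genes at
the signature fraction (default 0.1). Each planted driver receives 20
dedicated neighbors of which an expected `enrichment ×
signature_fraction` are signature genes (enrichment 5 → ~50% signature
density). Driver edges appear in every study; each background edge is
shared across all studies with probability `overlap` (default 0.5) or
assigned to one random study, so a support-2 consensus keeps the planted
structure plus the shared background.

**Phenotypes.** Glucose curves are a baseline plus a group-scaled
excursion template with Gaussian noise per time point; group scales
encode the emulated pattern (high-fat diets roughly double the
excursion; the knockout's is half the wild type's on every diet, so the
pooled KO/WT AUC ratio is 0.5 by construction). Fasting glucose gets a
per-group shift that cancels out of the baseline-normalized AUC. The
metabolite and protein covariate share a latent Gaussian factor giving a
within-group correlation of −0.93 by default, with group means (low
metabolite / high protein in the knockout) that also separate the
pooled scatter.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: peptide-to-protein rollup, isotope-impurity
cross-talk between channels, intensity-dependent missingness (only
complete-case zeros), protein-protein abundance correlation, dispersion
that varies across proteins, scale-free network topology, or real mouse
physiology. Recovery results on synthetic data demonstrate correctness
of the algorithms under their stated assumptions, not performance on any
particular instrument's output.

## Pipeline orchestration and reproducibility

`run_pipeline()` executes the stages in fixed order (simulate →
normalize → differential → signatures → network/KDA → phenotype) from a
single validated config; later stages read earlier stages' files, never
the reverse, and stage toggles that would break that DAG are rejected at
validation time. All randomness derives from the single config seed
(stage-specific seeds are fixed offsets of it), and the JSON report
contains no timestamps or absolute paths, so the same config and seed
give a byte-identical report. Every number in the report is
recomputable from the stage TSV/JSON outputs alone.

Problem sizes used by the shipped checks — 2000 null proteins for the
type-I rate, five replicates of 5000 proteins for spike-in FDR and
sensitivity, ten 1000-node networks for key-driver ranking — were chosen
as the smallest scales at which the Monte-Carlo bands are narrow
relative to the properties being checked.

## Known limitations

- A single common dispersion ignores protein-specific mean-variance
  structure; strongly heteroskedastic data would benefit from tagwise
  shrinkage, which is out of scope.
- Total-intensity (SL + pseudo-count) equalization is composition-naive;
  see the FDR caveat above.
- The exact test operates on group totals after equalization, so
  replicate-level outliers are absorbed rather than downweighted.
- Consensus support counts studies, not evidence strength; edge weights
  and Bayesian-network learning are out of scope (networks are inputs).
- KDA neighborhoods default to 1 hop; deeper neighborhoods dilute
  enrichment quickly on dense graphs and should be used with the
  min-neighborhood flag in mind.
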