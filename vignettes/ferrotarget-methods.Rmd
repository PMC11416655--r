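---
title: "Methods: how ferrotarget ranks candidate ferroptosis suppressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how ferrotarget ranks candidate ferroptosis suppressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ferroptosis is an iron-dependent form of regulated cell death driven by lipid
peroxidation. Tumors that resist it — many triple-negative breast cancers do
not — are protected by suppressor genes (GPX4, GCH1, FSP1 and others), and
finding new suppressors is both a route to drug targets and a window into the
death pathway itself. `ferrotarget` implements an integrated, fully offline
re-ranking pipeline that nominates candidate suppressors from two orthogonal
kinds of evidence:

1. **Vulnerability correlations.** If a gene protects cells from ferroptosis,
   cell lines expressing more of it (or depending more on it in CRISPR
   screens) should survive ferroptosis inducers better. We fit dose-response
   curves per (cell line, drug), summarize each as an AUC, and correlate every
   gene's expression and dependency with the AUCs of the three canonical
   inducers (erastin, RSL3, FIN56) — six correlation predictors per gene.
2. **Transcriptomic similarity.** Losing a suppressor should look, at the
   transcriptome level, like inducing the death pathway. Each knockdown
   signature's most up- and down-regulated genes are tested for enrichment in
   each inducer-response profile with a competitive CAMERA-style test, scores
   are aggregated per knocked-down gene across cell contexts, and up/down
   enrichment ranks are combined into one rank-difference predictor per
   retained profile.

The predictors are rank-normalized, projected to 2-D with UMAP, and genes are
ranked by Euclidean distance to an anchor suppressor. Close neighbors of the
anchor are the candidates.

# Models and formulas

## Dose-response and AUC

Viability (% of untreated control) is modeled by the 4-parameter log-logistic
curve

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}}$$

fit by bounded multi-start least squares (`nlminb`, inflection dose seeded at
each observed dose quantile, both slope signs, asymptotes bounded to
[0, 120] %). The fit is canonicalized to $c \le d$, which the curve permits
without loss of generality. The AUC is the trapezoid integral of the fitted
curve over the observed $\log_{10}$-dose range, with viability clipped to
[0, 100] and the integral normalized by (range × 100), so constant full
viability gives AUC = 1 and high AUC means a resistant line. Only
correlations consume AUCs, and Pearson correlation is scale-invariant, so
this normalization is safe regardless of the original assay scale.

## Correlation predictors

Per gene and drug, Pearson correlation on pairwise-complete cell lines
between the gene's expression (or CRISPR dependency) and the drug's AUC
vector; genes with fewer than 3 complete pairs are set missing. Reported
gene lists use the strict thresholds $r > 0.65$ and $r < -0.65$.

## Competitive enrichment (CAMERA-style)

For a set of $m$ genes inside a universe of $G$ gene-level statistics, the
test statistic is

$$t = \frac{\bar{s}_{\text{in}} - \bar{s}_{\text{out}}}
          {s_p \sqrt{\mathrm{VIF}/m + 1/(G-m)}},\qquad
  \mathrm{VIF} = 1 + (m-1)\bar\rho,\; \mathrm{df} = G - 2$$

with $s_p^2$ the within-group pooled variance. With $\bar\rho = 0$ this is
exactly the ordinary pooled two-sample t-test (a tested identity), and the
implementation reproduces `limma::cameraPR` p-values to 1e-10. We use the
established fixed inter-gene correlation $\bar\rho = 0.01$; it is exposed in
the configuration.

## Profile selection and similarity predictors

Pairwise Pearson correlations between the inducer profiles (on the genes each
pair shares) yield a consensus score per profile: the sum of its positive
correlations to the others, normalized to [0, 100] (all equal maps to 100 —
a degenerate case real data never hits, warned about when it affects the
drop). The 3 lowest-scoring profiles are dropped, leaving 7 of 10.

Signature scores are aggregated per knocked-down gene by the maximum across
its cell contexts — the literal published rule, applied to both streams.
Because max-aggregating the *down*-stream is directionally questionable, a
`down_aggregate = "min"` alternative is provided but not default. Within
each profile, aggregated up- and down-scores are ranked ascending (average
ties; missing scores take the profile's median rank) and the final predictor
is `up_rank − down_rank`, spanning exactly $[-(N-1), N-1]$ for $N$ genes.
Ranking uses the signed statistic, not p-values: the sign carries the
direction the rank difference needs.

## Integration

Each predictor column is normalized to [0, 1] by fractional ranks (average
ties), which makes the matrix invariant to monotone transforms of any raw
column and neutralizes the $[-1,1]$ vs $\pm(N-1)$ scale mismatch. Genes
missing any predictor are dropped, not imputed (the published universe is
likewise an intersection). UMAP uses Euclidean metric, `min_dist = 0.05`,
`n_neighbors = 15` (the library default), single-threaded with a fixed seed,
so a fixed input and seed reproduce coordinates exactly. Distances to the
anchor are ranked with lexicographic tie-breaks. The aggregate ("blue hue")
score is `(rank(max(mean expr corr, mean dep corr)) + rank(mean similarity))
/ 2` on the raw values. Stability re-embeds under seeds derived
deterministically from the master seed and reports per-gene retention in the
anchor's top-k; fidelity is the Spearman correlation between predictor-space
and embedding-space distances over sampled pairs.

## Enrichment utilities

Preranked GSEA uses the weighted-KS walk (hit weight $|s|^p$, $p = 1$;
miss step $1/(G-m)$), a random-set permutation null (only rankings exist
here, so phenotype permutation is unavailable), NES = ES divided by the mean
|ES| of same-sign permutations, and the add-one empirical p-value computed
*within the same-sign permutations*. The build contract wrote the denominator
as all permutations, but that distorts the null (p concentrates below 0.5)
and contradicts its own uniformity acceptance check; the same-sign
denominator is the fgsea convention and keeps null p-values uniform — a
deliberate, documented deviation. ssGSEA follows the Barbie weighted-ECDF
difference with $\alpha = 0.25$ and optional range normalization.

## Citation-based validation

A required offline gene × term count table replaces live literature queries.
`cited_fraction` is the percentage of set members with a nonzero count per
term; `combination_scan` enumerates all $2^M - 1$ subsets of similarity
predictors (correlations always included), takes the top 50 genes by mean
normalized predictor value (the multi-column ordering is not pinned down by
the source method text; mean is the default, min-rank an option), and
`random_null` draws 2000 random 100-gene sets with add-one empirical
p-values.

# The synthetic world

Real inputs (CMAP signatures, CCLE/Achilles matrices, CTRP viability) are
multi-gigabyte downloads, so the package ships a generator that emulates
their *statistical structure* at the level the pipeline consumes:

- one latent resistance $v_\ell$ per cell line drives log-logistic viability
  curves (inflection dose log-linear in $v_\ell$, 8 doses, 3 replicates,
  4% viability noise) and hence the AUCs;
- planted suppressor genes (20 + the anchor `ANCHOR1` by default) have
  expression and dependency rows $\rho\, v + \sqrt{1-\rho^2}\,\varepsilon$
  with $\rho = 0.7$ — just above the 0.65 reporting threshold, so planted
  genes are detectable but not trivially so; background genes are pure noise;
- a latent response vector $f$ plus per-profile noise gives the 10
  fold-change profiles; p-values come from simulated 2 vs 2 replicate
  t-tests, matching the duplicate design of the source experiments;
- planted knockdown signatures are $0.8\,\tilde f + 0.6\,\varepsilon$ across
  4–9 cell contexts each (the published compendium spans 4–9 contexts per
  gene); others are standard normal noise. 500 knocked-down genes scale down
  the published 3932;
- citation counts are zero-inflated, enriched for planted genes.

Each table draws from its own positionally fixed RNG stream derived from one
master seed, so worlds are bit-reproducible and adding a table cannot perturb
another. What the generator does **not** emulate: read counts and library
sizes, batch effects, gene-gene co-expression structure, realistic AUC
scales, or biological pathway structure. A green recovery test therefore
establishes that the pipeline's statistics recover *planted linear structure
under Gaussian noise at the stated strengths* — not that it would rank any
particular real gene highly.

# Numerical choices and edge cases

- Tie-breaking is lexicographic by identifier everywhere a sort can tie;
  runs are bit-reproducible given a master seed.
- Dose-response fits with constant viability return a flagged degenerate flat
  fit rather than an error; fewer than 4 distinct doses is an error.
- Pearson predictors use pairwise-complete observations (public matrices
  miss lines); fewer than 3 pairs gives a missing value, and missing values
  propagate — only the final matrix assembly drops genes.
- The empty GCT 1.2 annotation block, trailing empty fields, and both header
  dialects are handled; dimension lines are enforced.
- Permutation p-values are never 0 (add-one rule); camera on a constant
  statistic vector returns statistic 0, p 1.
- `uwot` is run with `n_threads = 1`, `n_sgd_threads = 0`: determinism over
  speed, matching the scale of a few thousand genes.

# Known limitations

- UMAP coordinates are only reproducible for a fixed uwot version and
  platform; all checks are therefore structure-level (neighbor ranks,
  retention, fidelity), never raw coordinates.
- The down-stream max-aggregation rule is applied literally even though it
  arguably favors the least down-like context; the `"min"` option exists for
  sensitivity analyses.
- Gene identifiers are matched as exact case-sensitive strings; harmonizing
  CMAP/CCLE/Achilles symbol vocabularies is upstream curation, not handled
  here.
- The citation table is a snapshot supplied by the user; the package never
  queries the network.
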