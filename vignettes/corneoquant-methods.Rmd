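---
title: "Quantifying stratum corneum proteomes with corneoquant: model and methods"
author: "corneoquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stratum corneum proteomes with corneoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corneoquant)
```

## The problem

Tape stripping collects stratum corneum (SC) protein non-invasively: adhesive
film is applied to the skin and removed, and the adhering corneocyte protein is
analysed by label-free LC-MS/MS. In a contralateral two-arm design each subject
treats one lower leg with a lotion and the other leg with the lotion plus a
fine-fiber (FF) film, with samples taken at baseline and after 14 days. The
analysis questions are: which SC proteins change over treatment in each arm,
which change *differently* between arms, and how do those changes group by
protein function. `corneoquant` implements that analysis chain end to end,
together with the associated clinical endpoint statistics and a synthetic study
generator with planted ground truth.

The pipeline consumes post-search peptide-level intensity tables (any search
engine; one protein accession per peptide). Raw spectra processing, database
search and PSM validation are upstream of this package and out of its scope.

## Quantification model

For protein $p$ in sample $i$, the **peptide peak intensity**
$\mathrm{PPI}_{p,i}$ is the sum of the peak intensities of all observed
peptides assigned to $p$. A protein with no observed peptide in a sample is
*missing* there — never zero, since absence of evidence in MS data is not
evidence of absence.

Tape strips vary in how much protein they collect, so a per-sample loading
correction is needed. The most abundant protein of the batch — in SC tape
strips this is keratin 10 (K1C10), observed in every sample — serves as the
**standard protein**. Its abundance is assumed biologically stable, so
variation in its PPI across samples measures loading. The **weight** of sample
$i$ is

$$ w_i = \frac{\mathrm{PPI}_i(\text{std})}{\mathrm{PPI}_k(\text{std})}, $$

where $k$ is the sample attaining the maximum standard-protein PPI, giving
$w_i \in (0, 1]$ with $w_k = 1$. The **protein amount index** is

$$ \mathrm{PAI}_{p,i} = \log_{10}\frac{\mathrm{PPI}_{p,i}}{w_i}. $$

Writing it out, $\mathrm{PAI}_{p,i} = \log_{10}\mathrm{PPI}_{p,i} -
\log_{10}\mathrm{PPI}_{i}(\text{std}) + \log_{10}\mathrm{PPI}_k(\text{std})$:
a within-sample ratio to the standard plus a batch-level constant. Multiplying
every peptide intensity of a sample by a constant therefore cancels exactly
from that sample's PAI column — the property that makes PAI comparable across
samples — *provided the reference sample $k$ does not change*. A large enough
rescaling makes the rescaled sample itself the reference, which shifts every
PAI entry by the common constant $\log_{10}$(new max / old max). All
downstream quantities (differences, fold changes, tests) are invariant to that
shift, but absolute PAI values are not. For workflows that need absolute
comparability across reanalyses, `quantifyProteins(referenceSample=)` pins the
anchor sample explicitly; weights may then exceed 1.

Standard-protein selection is reproducible by construction: the protein with
the largest total PPI among proteins observed in every sample, ties broken by
smallest accession. A named accession can be forced instead
(`standardProtein=`), mirroring analyses that fix K1C10 a priori. Weights are
computed within the analysis batch — all samples of the study loaded together.
A per-arm alternative would decouple the arms' scales and break between-arm
baseline comparisons, so it is not offered.

## Baseline concordance filter

In a contralateral design the two legs should agree at baseline. Proteins
whose arms already differ before treatment (local inflammation, blood
contamination, leg-to-leg anatomical differences) cannot support a clean
between-arm comparison. For each protein the filter computes the difference of
arm-mean baseline PAI (film arm minus lotion arm, pairwise-complete over
subjects) and reports the fold $10^{|\mathrm{diff}|}$.

Retention is **count-based**: the $\lfloor 0.95 \cdot P \rfloor$ proteins with
the smallest absolute difference are kept ($P$ = proteins with a defined
difference). With $P = 172$ this keeps exactly 163 and excludes 9. We read
"within 95% of the total" as a count rule because it is the only reading that
pins the retained set size deterministically regardless of the difference
distribution; a percentile-threshold variant is available
(`method = "percentile"`). Boundary ties break by smaller difference first,
then accession, so the split never depends on input order. Proteins observed
at baseline in fewer than 2 subjects per arm are set aside as "insufficient"
rather than silently passed or excluded.

## Differential analysis

Per subject and arm, the log10 fold change of a protein is
$\Delta\mathrm{PAI} = \mathrm{PAI}(\text{day 14}) -
\mathrm{PAI}(\text{baseline})$; the arm-level fold change is
$10^{\overline{\Delta\mathrm{PAI}}}$, the mean over non-missing subjects —
a geometric-mean-style fold, the natural choice on an already-log scale.
Log2 axes used in reporting are exact conversions,
$\log_2 x = \log_{10} x / \log_{10} 2$.

**Testing.** The primary significance family is the between-arm comparison:
per protein, the per-subject difference $d_s = \Delta\mathrm{PAI}_{\rm ff}(s)
- \Delta\mathrm{PAI}_{\rm lotion}(s)$ is tested against symmetry about zero
with the paired Wilcoxon signed-rank test. Zero differences are dropped before
ranking; an all-zero vector is reported as $p = 1$ with an `untestable` flag
so degenerate (e.g. noise-free) inputs flow through rather than erroring. With
no ties and $n \le 25$ the p-value is exact — equivalent to enumerating all
$2^n$ sign assignments; at $n = 8$ subjects the smallest achievable two-sided
p is $2/256 = 0.0078125$, a floor worth keeping in mind when reading q-values.
With ties or larger $n$ the tie-corrected normal approximation with continuity
correction is used.

p-values become **Storey q-values**: $\hat\pi_0$ is estimated on the grid
$\lambda = 0.05, 0.10, \dots, 0.95$ via $\hat\pi_0(\lambda) =
\#\{p > \lambda\} / (m(1-\lambda))$, smoothed by a cubic spline (df = 3) and
evaluated at $\lambda = 0.95$, clamped to $[1/m, 1]$ (the smoother variant is
deterministic, unlike the bootstrap; the clamp keeps q-values strictly
positive). Then $q_i = \hat\pi_0 \min_{p_j \ge p_i} (m p_j / \mathrm{rank}_j)$,
monotonised and capped at 1 — with $\pi_0 = 1$ this is exactly
Benjamini–Hochberg, which the test suite verifies to $10^{-12}$. Significance
is $q < 0.05$. Within-arm change tests (each arm's $\Delta\mathrm{PAI}$
against zero) are also computed, as two *separate* q-value families, because
pooling the within- and between-arm hypotheses would make each family's FDR
statement ambiguous.

Each protein is classified by the **quadrant** of its two arm fold changes
(strict signs; an exact zero is "boundary"), and the **fold-change ratio**
$\mathrm{fc}_{\rm ff} / \mathrm{fc}_{\rm lotion}$ summarises how much more
(or less) a protein responded under the film. The scatter summary reports the
Pearson correlation of the two arms' log2 fold changes and marginal histogram
counts on shared bin edges.

## Clinical endpoints

Observer dryness scores (0–4 in 0.5 steps), conductance (SC hydration) and
immunofluorescence intensities ride along in a tidy subject × arm × day table.
Score and conductance comparisons reuse the paired Wilcoxon test in two
families per endpoint — between-arm at each day, and within-arm change from
day 0 — with Benjamini–Hochberg adjustment applied within each endpoint ×
comparison family, mirroring per-panel figure-wise correction
(`family = "endpoint"` pools them). Immunofluorescence uses the classical
paired t-test, which is the appropriate small-sample choice at $n = 3$–4
biopsies; zero-variance differences are flagged untestable rather than
reported as $p = 0$ or $p = 1$.

## The synthetic generator

`generateStudy()` emulates everything downstream of the search engine. On the
log10 scale, protein $p$ in sample $i$ has signal

$$ \log_{10} S_{p,i} = a_p + s_i + e_{p,\mathrm{arm}(i),\mathrm{tp}(i)}
   + o_{p,\mathrm{arm}(i)} + \varepsilon_{p,i}, $$

with protein abundance $a_p \sim N(3.0, 0.8)$ (log-normal protein abundance is
an assumption — the data themselves make no distributional statement — but it
is the standard working model for MS intensities), a per-sample loading factor
$s_i \sim N(0, 0.15)$ applied to *all* peptides including the standard (so the
normalisation has something real to remove), planted day-14 effects $e$,
persistent film-arm offsets $o$ for baseline-discordant proteins, and
measurement noise $\varepsilon_{p,i} \sim N(0, 0.05)$. The signal is split
across the protein's peptides (2–8 per protein, uniform) by fixed
per-protein proportions drawn once (ionisation propensity), so the PPI sum
reconstructs the signal exactly; peptide observations are then dropped
independently at the missingness rate (default 5%). A protein with all
peptides missing in a sample is missing, not zero. The designated standard
protein gets a +3.0 log10 abundance boost and 20 peptides — the most abundant
protein of a run yields many identified peptides, and a peptide-poor standard
would inject large common shocks into every sample's normalisation whenever
one of its dominant peptides dropped out.

Baseline-discordant proteins carry their offset in the film arm at *both*
timepoints: the discordance models a leg-level difference, which is persistent,
and this choice leaves day-14 fold changes undistorted — the reason such
proteins are excluded is their baseline behaviour, not their response.

Default study conditions are 8 subjects, 172 proteins, nine baseline
outliers at folds 3.8–1.9×, and a deterministic effect table whose quadrant
structure (about 76 up/up, 50 down/down, 33 film-up/lotion-down, 4
lotion-up/film-down, with ~49 strong between-arm responders) and marker folds
(SBSN 0.5×/1.9×, VIM 1.2×/2.3×, ASPRV1 1.3×/2.0×, ANXA2 decreasing) match the
scale of published SC proteome responses to occlusive treatment. The effect
*density* matters: at $n = 8$ the exact Wilcoxon p-floor is 0.0078, so a
solitary true effect among 172 proteins can never reach $q < 0.05$ — only a
study-like family of co-responding proteins can, and the generator's defaults
provide one. Clinical endpoints follow a simple linear improvement model with
subject random intercepts (scores fall, conductance rises, both about twice as
fast under the film); this is deliberately minimal — it exercises the
statistics, it does not model skin biology.

All randomness flows from one integer seed; per-table sub-seeds are drawn
deterministically from it, so studies are byte-identical across runs.

What passing tests on generated data do **not** show: real tape-strip data
have correlated peptide missingness (abundance-dependent), non-normal
heavy-tailed intensity noise, depth-dependent composition across consecutive
strips, and protein inference ambiguity from shared peptides. None of these
are simulated; conclusions about the pipeline's statistical calibration
transfer to real data only to the extent those features are benign.

## Numerical and design choices

* Exact Wilcoxon cutoff $n \le 25$: exhaustive enumeration is cheap there and
  the normal approximation is excellent beyond it.
* $\hat\pi_0$ smoother df = 3, evaluated at the top of the λ-grid; clamped to
  $[1/m, 1]$.
* Count-based filter tie-break and standard-protein tie-break are both
  deterministic (accession order) so reruns are bit-identical.
* Arm means (not per-subject leg differences) define the baseline filter,
  since the filter targets group-level discordance; a per-subject variant
  would conflate subject noise with leg effects at $n = 8$.
* Missing tokens are `NA` end to end; output TSVs use full precision, `.`
  decimals and LF endings, and every pipeline artifact is reproducible
  bit-for-bit from (inputs, config).
* Test problem sizes: FDR calibration uses 200 null studies of 150 proteins;
  parameter recovery uses 100 replicate default studies. These give
  Monte-Carlo standard errors comfortably below the margins being tested
  while keeping the suite quick to run.

## Known limitations

* One accession per peptide is assumed: protein grouping/inference is out of
  scope, and shared peptides must be resolved upstream.
* The standard-protein model treats K1C10 as biologically stable; if the
  treatment itself altered keratin 10, the normalisation would absorb a real
  effect into the weights.
* The count-based 95% rule always excludes $P - \lfloor 0.95 P\rfloor$
  proteins, even in a study with no true discordance; the excluded list should
  be read together with its fold values, not as a verdict.
* Absolute PAI values depend on the batch's reference sample; compare PAI
  *differences* across batches, or pin `referenceSample`.
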