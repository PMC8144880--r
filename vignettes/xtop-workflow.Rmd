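---
title: "Peptide-to-protein inference and absolute proteome quantification with xtopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-to-protein inference and absolute proteome quantification with xtopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtopr)
```

## The inference problem

Bottom-up proteomics measures peptides, not proteins. A DIA/SWATH
experiment delivers, for each protein, an intensity matrix $I_{ps}$ over
its peptide precursors $p$ (a peptide sequence plus charge state) and
samples $s$. Different precursors of the same protein ionize with very
different efficiencies, and low-intensity precursors drop out of the
matrix non-randomly. Turning $I_{ps}$ into one protein intensity per
sample is therefore a modeling problem, and the choice of estimator
dominates the precision of the resulting quantification.

`xtopr` implements three estimators behind a common interface:

* **TopPepN** (`toppep()`): precursors are ranked once, globally, by
  their across-sample mean intensity (missing values set to zero
  *inside the ranking only*), and the top $N$ intensities present in
  each sample are summed. `N = 1` and `N = 3` are the common TopPep1 and
  TopPep3 variants.
* **iBAQ** (`ibaq()`): the summed intensity of all present precursors
  divided by the protein's expected number of fully tryptic peptides
  (`count_tryptic_peptides()`: cleavage C-terminal to K/R, no cleavage
  before proline, zero missed cleavages, length window 6--30 residues by
  default — the window is configurable since detectability cutoffs vary
  between setups).
* **xTop** (`fit_xtop()`): the multiplicative model described next.

Shared (non-unique) peptides are retained on input but excluded from all
estimators by default; an `include_shared` flag assigns them to every
parent, which is explicitly non-standard behaviour for when a user wants
it.

## The xTop model

For one protein, each present log2 intensity is modeled as

$$y_{ps} = x_s + e_p + \varepsilon_{ps}, \qquad
  \varepsilon_{ps} \sim \mathcal N(0, \sigma_p^2),$$

where $x_s = \log_2 I_s^{\mathrm{xTop}}$ is the protein's sample
intensity and $e_p = \log_2 \epsilon_p$ the precursor's detection
efficiency relative to the strongest precursor. On the linear scale this
is $I_{ps} = I_s^{\mathrm{xTop}} \cdot \epsilon_p \cdot \text{noise}$.
The fit maximizes the posterior with

* a flat prior on each $x_s$,
* a Gaussian prior $e_p \sim \mathcal N(0, \tau^2)$ on log2
  efficiencies, and
* per-precursor noise variances $\sigma_p^2$ shrunk toward the
  protein-wide residual variance with $k$ pseudo-observations and
  floored at $\sigma_{\min}^2$.

Maximization is by block coordinate ascent; each block update is in
closed form. The protein intensity is a weighted average of
efficiency-corrected precursor intensities with weights
$w_p = 1/\sigma_p^2$, so precursors that agree with the others across
samples carry the most weight, and a precursor that is simply absent
from a sample neither contributes nor biases that sample's estimate —
the property that makes the estimator robust to missing-not-at-random
dropout. Missing entries are absent from the likelihood (a
missing-at-random treatment; no censoring term is used even though real
dropout is intensity-dependent — robustness, not explicit modeling of
the dropout mechanism, is the design goal).

### Hyperparameters

| parameter | default | units | role |
|---|---|---|---|
| `efficiency_prior_sd` ($\tau$) | 4 | log2 | weak prior keeping efficiencies of sparsely observed precursors finite; 4 log2 units spans the ~1 decade efficiency spread seen in real precursor data with room to spare |
| `noise_floor` ($\sigma_{\min}$) | 0.1 | log2 | prevents a precursor that happens to be perfectly self-consistent from acquiring unbounded weight; 0.1 log2 units ≈ 7% CV, below the technical noise of replicate injections |
| `noise_shrinkage` ($k$) | 2 | pseudo-obs. | stabilizes $\sigma_p$ for precursors observed in few samples by borrowing the protein-wide residual variance |
| `max_iter` | 100 | sweeps | proteins still moving after 100 sweeps are returned flagged (`converged = FALSE`) rather than silently accepted |
| `rel_tol` | 1e-6 | — | maximum relative parameter change per sweep at convergence |

These defaults are this package's choices; they satisfy every structural
property the estimator is designed around (Top1 anchoring,
consistency-based weighting, exact recovery on noiseless multiplicative
data) and the validation suite exercises them as-is.

### Anchoring and identifiability

The likelihood only constrains $x_s + e_p$: adding a constant to all
$x_s$ and subtracting it from all $e_p$ changes nothing except the
prior term. The reported convention is $\max_p \epsilon_p = 1$ —
intensities are expressed on the scale of the best-detected precursor,
so on data where the top precursor is complete and noiseless, xTop
coincides with TopPep1. Re-anchoring is applied after *every* sweep:
besides fixing the convention, it pins this nearly flat direction of
the posterior, along which un-anchored coordinate ascent creeps at a
geometric rate of about $1 - \sigma_{\min}^2/(n\tau^2)$ per sweep and
effectively never terminates.

One subtlety arises from dropout: the bipartite graph linking a
protein's precursors to the samples they are detected in can fall into
disconnected components. Components share no sample, so their relative
scale is determined only by the prior; a single global anchor would
leave the other components free to drift. Each connected component is
therefore anchored to its own top precursor. The global maximum
efficiency is still exactly 1, and for the typical fully connected
protein nothing changes.

Single-precursor proteins are returned verbatim (the model is
unidentifiable beyond the data themselves), with efficiency 1.

### Numerical behaviour

The fit is deterministic — no randomness enters unless the caller
requests initialization jitter. Initialization takes $x_s$ from the
top-ranked precursor where present (per-sample mean of present values
elsewhere), $e_p = 0$, and a common $\sigma_p$ from the initial
residuals. Ranking ties are broken lexicographically by (sequence,
charge) so that row order never affects any output. On complete,
noiseless multiplicative data the sample-to-sample intensity ratios are
recovered exactly (the validation suite asserts 1e-9 in log space); the
absolute anchored values carry an $O(\sigma_{\min}^2/(n\tau^2))$
residual from the efficiency prior, ~1e-4 log2 units at the defaults.

## From intensities to absolute mass fractions

Intensity-based estimators track molar amounts, so
`to_mass_fractions()` multiplies each protein's intensity by its
molecular weight and normalizes each sample to 1 over its detected
proteins, giving mass fractions $\phi_{is}$.

Relative proteomics is then calibrated against an external absolute
standard $\rho_i$ (`calibrate_to_standard()`), e.g.
ribosome-profiling-derived synthesis rates, which are proportional to
protein abundances in fast-growing bacteria where degradation is
negligible. Each protein receives a condition-independent factor
$c_i = \rho_i / \widetilde\phi_{i,\mathrm{cal}}$, with
$\widetilde\phi_{i,\mathrm{cal}}$ the geometric mean over the
calibration samples in which the protein was detected (the geometric
mean is the natural aggregate under a multiplicative error model);
proteins absent from the calibration samples or from the standard keep
$c_i = 1$. Rescaled columns are renormalized to 1 by default, since
results are reported as fractions of total *detected* protein mass;
`renormalize = FALSE` preserves the standard's absolute scale instead.
Calibration is exactly idempotent without renormalization, and with
renormalization whenever the standard covers all calibrated proteins;
with partial coverage the factor-1 proteins shift by the covered-mass
deficit on repeated application — a property documented rather than
hidden, since it follows from the factor-1 convention itself.

### Concentrations, complexes, surface densities

Mass fractions convert to cellular concentrations without knowing cell
volume or copy numbers per cell:
$c = \phi \cdot (\bar L / L) \cdot C_{\mathrm{tot}}$ proteins/µm³, with
$C_{\mathrm{tot}} = 3\times10^6$ proteins/µm³ of total protein and
$\bar L$ the abundance-weighted (number-weighted) mean protein length.
`mean_protein_length()` computes the self-consistent
$\bar L = \sum\phi_i / \sum(\phi_i/L_i)$, under which per-protein
concentrations add up exactly to $C_{\mathrm{tot}}$; the standard
cellular equivalences (0.1% of proteome mass of a 300-residue protein
≈ 2,400/µm³; $10^{-5}$ mass fraction of an average protein ≈ 30/µm³)
correspond to $\bar L \approx 240$ residues. Protein length falls back
to MW/110 Da when residue counts are unavailable.

`complex_concentration()` divides member concentrations by their
stoichiometric copy numbers: for a complex truly produced in
stoichiometric amounts, the scatter of these per-member estimates
measures the quantification error. The spread statistic is the log10
ratio of the 95th to the 5th percentile (an interdecile range robust to
a single aberrant subunit). `surface_density()` and
`occupied_area_fraction()` convert volumetric concentrations of
membrane proteins into areal densities and occupancy via the
surface-to-volume ratio and a circular footprint.

## Benchmarking statistics

All ratio statistics use log base 2, and proteins with missing values
are excluded listwise per statistic, so that all methods are always
compared on the same protein set. `protein_cv()` uses the $n-1$ sample
SD and reports percent; `replicate_logratio_variance()` is the variance
of $\log_2(I_A/I_B)$ over shared proteins — invariant under a common
rescaling of either sample. `foldchange_concordance()` compares
proteomics and standard fold changes between two conditions and reports
the Pearson correlation of the log fold changes plus the fraction of
proteins discrepant beyond a threshold (2-fold by default).

`bias_regression()` quantifies systematic quantification bias by OLS of
$\log_2(\phi_i/\rho_i)$ on log2 molecular weight and indicators for
proteins detected with exactly one or exactly two precursors. Variance
attribution is sequential (type-I sums of squares) in the fixed order
size → 1-precursor → 2-precursor; sequential attribution is
order-dependent, so the order is explicit and configurable rather than
implicit. The shares sum to $R^2$.

`proteome_distance()` is the total-variation distance
$\tfrac12\sum_i|\phi_{iA}-\phi_{iB}|$ over the union of detected
proteins, a metric on $[0,1]$ in which a protein absent from one sample
contributes its full fraction from the other.

## Proteome sectors

Growth-limitation series titrate growth via carbon uptake (C), nitrogen
assimilation / anabolism (A), or translation inhibition (R). For each
protein and series, mass fractions are normalized to the reference
condition (`normalize_to_reference()`, geometric mean over reference
replicates) and the relative abundance is fitted linearly against
growth rate, $r(\lambda) = r_0 + s\lambda$ — deliberately on $r$, not
$\log r$, taking the classification rule at face value. A negative
slope (abundance rising as growth slows) is upregulation. The triple of
responses across C/A/R maps each protein to one of $2^3 = 8$ sectors
(e.g. C-sector = C↑A↓R↓, S′-sector = C↑A↑R↑); proteins with fewer than
three data points in any series are unclassifiable (X). An exact zero
slope counts as downregulation; `slope_tol` widens this dead zone for
noisy data but defaults to 0, keeping the pure sign rule.
`sector_mass_fractions()` aggregates per-sector mass, including the
derived O-sector (C′ + A′ + S′).

## The synthetic-data generator

`simulate_peptide_matrix()` emulates the statistical structure the
estimators face, with known ground truth: peptides per protein
$1+\mathrm{Poisson}(7)$ (right-skewed, a quarter of proteins with ≤ 3
precursors), protein abundances log-uniform over 5 decades, log2
efficiency SD 1.5 (~a decade of precursor spread), log-normal
measurement noise of 0.2 log2 units, and missing-not-at-random dropout
via a logistic detection curve in log2 intensity, centered at the
intensity of the least abundant proteins, plus 2% uniform dropout —
about 18% missing entries overall at the defaults, concentrated among
low-abundance proteins, which also reproduces the fact that proteins
detected with few precursors are predominantly the rare ones. Each
protein is generated on its own seeded substream, so output is
reproducible and independent of generation order.

What it does **not** emulate: retention-time misalignment, interference
and identification error, correlated (batch) noise, shared peptides,
or censoring-induced intensity bias in the observed values. Passing
tests therefore demonstrate correctness of the estimators under the
stated generative model and robustness to MNAR dropout — not immunity
to every artifact of real chromatography.

`simulate_reference_standard()` and `simulate_limitation_series()`
provide the matching ground-truth standards and C/A/R series (growth
grids 0.33–0.91/h over 15 samples, 0.22–0.84/h and 0.36–0.98/h over 7,
reference at 0.98/h). Limitation series are converted to mass fractions
by renormalization, so the planted per-protein lines acquire the same
closure distortion real proteomes have; with balanced sector plans the
distortion is far below the minimum planted slope of 0.3 per unit
growth rate.

## Validation problem sizes

The shipped validation suite runs the full cycle at 2,000 proteins ×
7 replicate samples for the method-ordering benchmark (median CV of
xTop below TopPep3 and iBAQ; TopPep1 detecting fewer proteins), 1,000
proteins for bias-slope recovery (±10%), 400 proteins for sector
recovery (≥99% at 5% noise and |s| ≥ 0.3), and small algebraic
fixtures for the exact properties. `scripts/acceptance.R` re-runs the
whole set from scratch at any seed.

## Known limitations

* The MAR likelihood means strongly censored precursors bias single
  observed values upward; xTop mitigates this through weighting, not
  through a dropout model.
* Calibration transfers any bias of the absolute standard itself;
  against ribosome-profiling standards this assumes negligible protein
  degradation.
* `iBAQ` needs theoretical peptide counts; proteins without a sequence
  or count are skipped with a warning rather than approximated.
* Sector classification is a hard sign rule; borderline proteins with
  near-zero slopes flip sectors under noise, which is inherent to the
  binary taxonomy rather than to this implementation.
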