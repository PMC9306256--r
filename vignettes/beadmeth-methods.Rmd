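---
title: "Models and design choices in beadmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in beadmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`beadmeth` implements the computational chain of a two-channel Infinium
mouse methylation array: raw allele intensities to masked β values,
mixture deconvolution, strain genotyping, differential methylation, and
an epigenetic age clock, together with a synthetic-data generator that
makes every stage testable without real arrays. This vignette records
the models, the tunable parameters, and the decisions made where the
design was genuinely open.

## Signal model and preprocessing

An Infinium-I probe measures its M and U alleles in one known color
channel; its readings in the other channel ("out of band", OOB) contain
no target signal and act as a background sample. An Infinium-II probe
reads M in Green and U in Red.

**Detection p-values (pOOBAH).** For a measurement with in-band allele
total $x$ in channel $c$, the detection p-value is the add-one-smoothed
empirical survival fraction of the OOB pool of that channel,
$p_c(x) = (\#\{o \in \mathrm{oob}_c : o \ge x\} + 1)/(|\mathrm{oob}_c| + 1)$.
Infinium-I probes are tested in their design channel; for Infinium-II we
take the minimum of the two per-channel p-values, since each allele is
read in its own channel. The add-one smoothing keeps $p > 0$, and the
minimum is the simplest calibrated combination; both are deliberate,
documented choices rather than claims about any particular reference
implementation. P-values are computed on **raw** signals: comparing to
background is only meaningful before background is subtracted.
Channel-switch (human/mouse variant) probes are excluded from the OOB
pool — their "opposite" channel carries genuine signal from the other
species, and on a small array even 19 such probes visibly contaminate
the background moments.

**Background subtraction (noob).** We model an observed intensity as
$x = s + b$ with signal $s \sim \mathrm{Exp}(\alpha)$ and background
$b \sim N(\mu_b, \sigma_b^2)$, estimate $\mu_b, \sigma_b$ per channel by
the moments of the OOB pool, set
$\alpha = \max(\bar{x}_\text{in-band} - \mu_b, 10)$, and replace every
intensity by the posterior mean
$E[s\,|\,x] = \mu_s + \sigma_b\,\phi(\mu_s/\sigma_b)/\Phi(\mu_s/\sigma_b)$
with $\mu_s = x - \mu_b - \sigma_b^2/\alpha$, plus a fixed offset of 15
units. The Mills ratio is evaluated on the log scale, so the formula is
stable far below background; unit tests pin it to a numerical-quadrature
oracle to $10^{-6}$. A degenerate OOB spread (s.d. 0) falls back to a
floor of 1 unit with a warning.

**Dye-bias correction.** The Red and Green channels sit on different
intensity scales. Using the in-band totals of Type-I probes — the only
measurements whose channel is known by design — we form the two
empirical quantile functions and map every intensity in each channel
through $m(x) = Q_\text{target}(F_\text{channel}(x))$, where
$Q_\text{target}$ is the quantile-wise geometric mean of the two. The
map is monotone and idempotent up to interpolation error. We default to
this nonlinear variant (a global linear rescale is a special case of the
quantile map when both distributions differ by a scale factor); the map
is calibrated on totals but applied per allele, which leaves a small
distortion at the lowest quantiles where the additive offset dominates —
visible in unit tests and immaterial after β formation. Because the map
is only valid for in-band-scale values, it is *not* applied before the
species-mixture ratios below.

**β values.** β = M/(M+U) from the design channel (Type-I) or across
channels (Type-II). Probes are masked to `NA` when detection p exceeds
0.2, when the total is zero, or when the manifest flags them by default
(`uk`-prefix and multi-mapping designs); the default mask can be lifted
with `apply_default_mask = FALSE`. The mask reason is retained.
Pipeline order is fixed: detection p-values, then noob, then dye-bias
correction, then β.

## Mixture deconvolution (PDX)

Two estimators of the human DNA fraction of a human/mouse mixture:

1. **Variant-probe ratio** — channel-switch probes read the mouse allele
   in their design channel and the human allele in the opposite channel.
   Per probe $r = H/(H+M)$ on in-band totals; the sample summary is the
   median over the probes. Ratios are computed on noob-corrected (not
   dye-corrected) signals: background subtraction removes the additive
   bias that otherwise pulls extreme fractions toward 0.5, while the
   cross-channel quantile map is invalid at the background-level values
   the minority channel takes near fractions 0 and 1.
2. **Cross-array intensity ratio** — the same sample on a mouse and a
   human array: medianH/(medianH+medianM) of per-probe total intensity
   over each array's species-specific (non-syntenic) probes.

Both are calibrated through standard curves fitted to titration series
at the eleven standard fractions (0, 0.05, 0.1, 0.15, 0.25, 0.5, 0.75,
0.85, 0.9, 0.95, 1): a degree-1 LOESS of ratio on fraction per
calibration series (span 0.75 by default; the span is a free parameter
and configurable), averaged pointwise across series on a 0.005 grid,
then projected to a monotone function by isotonic regression so that a
unique linear-interpolated inverse exists. LOESS itself need not be
monotone; the projection changes nothing where it already is. Ratios
outside the fitted range are clamped to 0 or 1 with a warning —
extrapolating beyond the calibration range would manufacture precision
the curve cannot support.

## Strain genotyping

SNP (rs) probes yield an alternate-allele fraction
$v = \mathrm{alt}/(\mathrm{alt}+\mathrm{ref})$, the probe's β value with
the alt allele in the M slot. The classifier is Gaussian maximum
likelihood: $\log L(\text{strain}) = \sum_i \log N(v_i; g_i, \tau^2)$
over non-missing SNPs, with heterozygous loci expected at exactly 0.5
and a shared noise scale $\tau$ (default 0.1; a Beta observation model
would respect the bounded support but adds nothing at the noise levels
arrays produce). The reported call carries the log-likelihood margin
over the runner-up; ties break lexicographically with a warning.

**Mixture detection** searches all ordered strain pairs and a mixing
grid (step 0.01) for the likelihood of
$\pi g_A + (1-\pi) g_B$. Three safeguards keep the test honest:

- Because allele fractions are bounded, noise at homozygous loci is
  one-sided; expected fractions in this test are shrunk toward 0.5 by
  the half-normal boundary excess $\epsilon = \tau\,\phi(0)$ — in both
  the single-strain and the mixture arm, so neither is favored.
- The minor component must be at least 0.1: an admixture below the
  measurement-noise scale is indistinguishable from boundary noise, so
  near-degenerate mixtures are not searched.
- The log-likelihood improvement must exceed the per-comparison
  threshold (default 2) **plus** $\log(\#\text{ordered pairs})$, a
  Bayes-factor-style multiplicity penalty for the pair search.

With these, simulated pure strains at $\tau \le 0.1$ never trigger a
mixture call across hundreds of replicates, while F1 (π = 0.5) and 3:1
mixtures are recovered within ±0.01–0.05.

**Backcross tracing** calls each donor/recipient segregating SNP
donor-homozygous (v > 0.75), heterozygous (0.25–0.75) or
recipient-homozygous (v < 0.25) — symmetric, configurable thresholds —
and reports the mean donor allele fraction, which at backcross
generation $n$ has expectation $0.5^{n+1}$.

## Differential methylation

`fit_dml()` fits, per probe, an additive OLS model of β on the requested
predictors and tests each term by a full-vs-reduced F-test. The
implementation projects all probes at once through the QR decompositions
of the full and reduced design matrices, so thousands of probes cost a
few matrix products; probes with missing values are re-fit on their
complete cases. Effect sizes are delta-beta style: the spread of
model-adjusted level means for a categorical term (raw group means by
option — adjusted is the default because it is robust to confounding
between predictors), and |slope| × observed range for a continuous term.
BH is the only multiple-testing correction used. Thresholds: p < 0.05
with effect > 0.1 in the tissue mode; adjusted p < 0.01 with
|coefficient| > 0.1, split by sign into hyper/hypo, in the tumor/age
mode. The tumor/age pre-filter (probes missing in > 25% of samples,
constitutively unmethylated max β < 0.2 or methylated min β > 0.8, sex
chromosomes) is exposed as `dml_prefilter()`; it is applied by the
tumor/age workflow but not to signature derivation, where perfect
discrimination already implies complete data in the compared groups.

**Tissue signatures** require perfect one-vs-rest discrimination —
Mann–Whitney AUC exactly 1 (hyper) or 0 (hypo), equivalently strict
separation of the two groups' β values — ranked by |mean difference|
with ties broken by probe ID for determinism, top 200 per direction.

**Tissue/species decomposition** computes cell means per
tissue × species, takes marginal spreads (max − min) per factor, and
labels a probe species-specific when the species effect exceeds 0.4 and
dominates the tissue effect three-fold (and symmetrically for
tissue-specific). Missing cells fall back to available-cell marginals
with a warning.

**Region enrichment** represents each CpG by a 200 bp window
([pos − 100, pos + 100) in 0-based coordinates) and tests overlap
against each region set with a two-sided Fisher exact test on the
query-vs-rest 2×2 table; the odds ratio uses a 0.5 continuity correction
only when a zero cell occurs, and that case is flagged. Interval overlap
is delegated to GenomicRanges; the test suite cross-checks it against a
brute-force scan and the Fisher p against full hypergeometric
enumeration.

**Mono-allelic methylation groups.** Group I: β in (0.3, 0.7) in more
than 50% of somatic samples; Group II: additionally intermediate in more
than 90% and polarized (> 0.7 or < 0.3) in every testis sample, testis
being dominated by spermatocytes whose imprints are erased; Group III:
II and inside an ICR or secondary DMR; Group IV: II and inside an ICR.
The groups are nested by construction and the highest applicable label
is reported. Fractions are computed over non-missing somatic samples.
The stricter array-design screen (β in (0.35, 0.65) in over 65% of
samples, requiring more than six informative samples) ships as the
`design_screen` preset.

## Epigenetic clock

Elastic net (glmnet) of age in months on β values, mixing parameter 0.5,
penalty chosen as the minimum of 10-fold cross-validated mean absolute
error. We use the minimum-MAE rule rather than the one-standard-error
rule because MAE is the quantity being optimized; a fixed penalty can be
supplied to reproduce an external model. Fold assignment derives only
from the seed. Missing β values are imputed by training means — stored
with the model so prediction stays defined on masked arrays — and
predictions with more than half of the weighted probes missing are
flagged low-confidence. Whether to impute or complete-case filter before
fitting is genuinely open; mean imputation was chosen because masked
probes are the norm, not the exception, on real arrays.

## The synthetic-data generator

The generator emulates exactly the structure the pipeline assumes:
truncated-normal background per channel (mean 500, s.d. 100 arbitrary
fluorescence units), exponential true signal (mean 5000) shared by the
two alleles of a probe and split by the true β, a multiplicative Red
dye factor (default 1.3), background-only draws in out-of-band slots,
channel-switch probes whose two species' templates share one probe
efficiency, strain genotypes painted on a random phylogeny
(clade-shared branch SNPs, 10 per branch), tissue markers (Δβ = 0.5),
linear age drift (0.02 β/month, clipped), imprints (0.5 somatic,
polarized testis), low-input binomial dropout
(β′ = Binomial(n, β)/n), and per-SNP independent backcross inheritance.
Default probe counts (500 + 500 Type-I, 2000 Type-II) scale the real
array down ~100-fold while keeping enough Type-I probes that empirical
quantile maps and OOB moments are stable.

What it does **not** emulate — and therefore what passing tests do not
show about real data: probe-sequence-specific affinity differences,
spatial chip artifacts and batch effects, bisulfite-conversion failure,
cross-hybridization, linkage in backcrosses, and FFPE degradation. The
matched generative/estimation background model (truncated normal +
exponential) is intentional: it makes the noob oracle exact, at the cost
of not probing model misspecification.

## Problem sizes and numerics

The shipped test and acceptance runs use ~3,000-probe manifests, 11-point
titrations with two calibration series and one evaluation series, a
25-strain/480-SNP genotyping panel with 50 classification replicates,
backcross generations 0–6 at 200 SNPs × 20 replicates, 5 × 1,000 null
probes × 40 samples for regression calibration, and a 200-sample ×
1,000-probe aging panel with 50 planted CpGs — sizes chosen so the whole
suite completes in minutes on a laptop while every statistic is measured
with useful precision. Numerical choices of note: log-scale Mills ratio
in noob; 512-point quantile grids and clamped linear interpolation in
the dye map; isotonic projection before curve inversion with flat runs
deduplicated; RSS-based F statistics with a 10⁻¹² degeneracy guard
(constant probes report F = 0, p = 1); probe-ID replicate indices are
canonicalized integers (a leading-zero replicate would be ambiguous
with larger indices). The designability mapping-quality rule applies to
every subsequence length for both alleles — the conservative reading —
and all thresholds (mapq > 20, distances > 10 nt, fewer than six CpGs,
score > 0.3) are strict inequalities.

## Known limitations

No IDAT parsing (allele-level signal tables are the ingestion format);
no within-array Type-I/Type-II distribution harmonization or batch
correction; no CNV-aware adjustment of mixture intensities; no
haplotype/linkage-aware strain inference; signatures are produced but
mixture deconvolution over tissue signatures is not implemented; the
design score is consumed, not computed.
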