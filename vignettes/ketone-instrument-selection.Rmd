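---
title: "Selecting ketone instruments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting ketone instruments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ketomr)
```

## The screening problem

Two-sample Mendelian randomization estimates the causal effect of an
exposure on an outcome from per-variant GWAS summary statistics estimated
in non-overlapping samples. Its validity rests entirely on the instruments:
each variant must associate with the exposure, be free of confounding
paths, and affect the outcome only through the exposure. For ketone
bodies — acetone, acetoacetate and beta-hydroxybutyrate, products of
hepatic fatty-acid metabolism with a well-mapped enzymatic pathway — a
biologically driven instrument search is feasible, and `ketomr` encodes it
as four explicit, testable premises evaluated per candidate gene region:

1. the region's gene must encode a protein directly relevant to ketone
   production or utilization;
2. the lead variant must associate with all three primary ketone bodies,
   which lie on one biochemical pathway and should move together under any
   intervention on ketone metabolism;
3. the region must show no horizontal pleiotropy in a catalogue screen of
   previously reported trait associations;
4. the region's instruments must reproduce at least one effect with
   trial-level support for ketone supplementation (a positive control).

Candidate regions are discovered from an acetone GWAS at a deliberately
permissive threshold ($p < 5\times10^{-6}$): a sub-genome-wide variant in
a biologically coherent gene region is a better instrument candidate than
a genome-wide variant of unknown function, so discovery must not filter at
$5\times10^{-8}$. Genome-wide significance is still required of the
variants actually used as instruments in premise 4.

### Stepwise semantics

A region failing premise 1 or 2 is reported with the remaining premises
*not evaluated* — the dash in the rendered matrix. Once premises 1–2 pass,
premises 3 and 4 are evaluated independently of each other: a pleiotropy
failure does not suppress the positive-control analysis, since the latter
is informative about the instrument's behaviour regardless (a region can
display the pattern `✓✓×✓`). Overall validity still requires all four
passes. The stepwise counts attached to every `premise_matrix` are
monotone non-increasing by construction.

## Estimators

All estimators consume a `harmonized_set` whose rows carry
$(\hat\gamma_j, \sigma_{Xj}, \hat\Gamma_j, \sigma_{Yj})$ on a common
effect-allele frame.

* **Ratio.** $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order
  SE $\sigma_{Yj}/|\hat\gamma_j|$. The second-order delta term is not
  implemented; with the instrument strengths this package targets
  ($|\gamma|/\sigma_X \gtrsim 6$) its contribution is negligible, but the
  first-order SE is anti-conservative for genuinely weak instruments — a
  documented limitation.
* **IVW.** Algebraically the weighted least squares of $\hat\Gamma$ on
  $\hat\gamma$ through the origin with weights $\sigma_{Yj}^{-2}$,
  computed in residual form so a zero exposure beta contributes zero
  weight instead of an undefined ratio. The default model is
  multiplicative random effects: the fixed-effect SE is scaled by
  $\max(1, \sqrt{Q/(J-1)})$. The floor at 1 makes the estimator
  conservative under the null (its exact type-I error at $J = 10$,
  $\alpha = 0.05$ is 3.9% rather than 5%); this is the standard,
  deliberate trade-off for robustness to overdispersion in real summary
  data. A fixed-effect model is available by flag. With one variant the
  IVW reduces exactly to the ratio estimate.
* **MR-Egger.** Weighted regression with intercept after orienting every
  instrument so $\hat\gamma_j > 0$. Without a fixed orientation the
  intercept — the directional-pleiotropy estimate — is not identified
  consistently; the exposure-increasing-allele frame is the convention
  used here and stated in the documentation. SEs use a multiplicative
  residual scale floored at 1, and fail loudly (a domain error) when the
  oriented exposure betas are all identical, since slope and intercept are
  then inseparable.
* **Weighted median.** Ratio estimates sorted ascending; standardized
  cumulative weight midpoints $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum w$;
  linear interpolation at $s = 0.5$. The SE is the SD of the statistic
  over parametric-bootstrap resamples (normal draws centred at the
  observed $\hat\gamma_j, \hat\Gamma_j$ with their SEs). The bootstrap
  seed is a required argument: reproducibility is favoured over the
  convenience of implicit RNG state, and the global RNG is left untouched.
* **Cochran's Q** in residual form, $df = J - 1$, upper chi-square tail.

Confidence intervals are normal-approximation 95% throughout; no
small-sample $t$ correction is applied (an acknowledged option not taken —
instrument counts here are small, but the normal approximation is what the
coverage calibration below verifies).

## Harmonization

The outcome association is placed on the exposure's effect-allele frame:
identical alleles are kept; swapped alleles flip the outcome beta and
reflect its EAF; a strand complement is applied for non-palindromic
variants before the same logic. Palindromic variants (A/T, C/G) are
label-ambiguous: they are kept only when both EAFs are present and outside
the ambiguity window $[0.42, 0.58]$ (inclusive — a frequency inside it
carries no usable orientation signal), with orientation inferred from
frequency agreement; otherwise they are dropped with reason
`palindromic_ambiguous`. The window and a drop-always policy are
configurable; the default is conservative because a silently wrong sign is
far worse in MR than a lost variant. Indel alleles are compared literally
with no complementing. SEs are never altered, and every requested variant
appears either in the kept set or in the drop log.

## Region operations

Gene windows are the annotated interval $\pm$ 200 kb (1-based inclusive,
floored at position 1); a variant belongs to every window containing it.
BED input is converted from 0-based half-open coordinates in the single
reader that touches it. Lead variants minimize the p-value with
deterministic tie-breaks (smaller position, then lexicographic id), so all
downstream results are permutation-invariant. Clumping is the classic
greedy algorithm with removal at $r^2 \ge$ the threshold, making retained
pairs strictly below it ($r^2 < 0.1$ by default), and is confined to a
region's window — cross-region LD is deliberately ignored, matching the
per-gene-region logic of the screen.

## The synthetic generator

`generate_bundle()` emulates the statistical structure of the real data
sources: two acetone discovery GWAS with shared truth and independent
noise (a meta-analysis-style study of n = 130,311 and a UK-Biobank-style
study of n = 115,075 that doubles as the agnostic exposure), acetoacetate
(n = 115,075) and beta-hydroxybutyrate (n = 113,595) sharing regional
genetics through loadings, and control outcomes at their published sample
sizes (cognitive performance 257,828; two-hour glucose 63,396; insulin
fold change 53,334).

The effect model: joint causal effects $\gamma_j$ are drawn per causal
variant from $N(0, \tau^2)$ truncated to $|\gamma_j| \ge$ `gamma_floor`;
marginal (GWAS-scale) effects are $R\gamma$, propagating signal to LD
partners as for standardized genotypes; ketone $k$ has marginal effects
$\lambda_k R\gamma$; a control has $\beta_c R\gamma + R\alpha$ with
$\alpha$ the direct (horizontally pleiotropic) effect. Observed estimates
are multivariate normal with per-variant SE $1/\sqrt{2f_j(1-f_j)n}$ and
cross-variant noise correlation equal to the LD $r$ (not $r^2$) — correct
for standardized effect estimates from a shared sample, and what makes
clumping behave realistically on noisy data.

Parameter defaults, and why:

* $\tau = 0.1$ SD per allele: lead variants at NMR-metabolite loci
  commonly show per-allele effects of 0.05–0.2 SD at these sample sizes.
* `gamma_floor = 0.03`: a non-null archetype region represents a locus
  that *was* discovered in the source GWAS, so its causal effects must be
  detectable there ($0.03/\sigma_X \approx 6$ at n ≈ 115k). Loci below the
  detectability floor are what the `null` archetype is for. Set it to 0
  for an untruncated draw.
* $\lambda = (1, 0.9, 0.8)$: the three ketone bodies are tightly
  correlated products of one pathway; acetone carries loading 1 so
  estimates are per SD of acetone.
* $\beta_c = (0.10, -0.20, -0.15)$ for cognition (SD), two-hour glucose
  (mmol/L) and insulin fold change (log ratio): directions and rough
  magnitudes of the trial-reported responses to ketone supplementation.
* Pleiotropy $\alpha_j = \mathrm{sign}(\gamma_j)\,N(0.05, 0.01^2)$ on
  causal variants: directional pleiotropy is defined relative to the
  exposure-increasing allele — the frame MR-Egger operates in after its
  orientation step — so the generator draws it there.
* AR(1) LD with $\rho = 0.6$; EAF uniform on $(0.1, 0.9)$; allele
  encodings scrambled between studies (30% swapped, 10% strand-flipped,
  15% palindromic pairs, near the transversion share of real variant
  panels) to exercise harmonization.
* Archetype causal counts mirror the reported instrument sets: four
  independent signals in the valid region, a single signal in the
  pleiotropic region (whose direct effect then stays proportional across
  LD partners, as it would for one underlying causal variant), three in
  the irrelevant-gene and acetone-only regions, none in the null region.
* The acetone-only (`inconsistent`) archetype has exactly zero true effect
  on acetoacetate and beta-hydroxybutyrate. At these sample sizes any
  non-zero redrawn effect would be detected almost surely, which would
  contradict the archetype's defining premise-2 failure.

What the generator does **not** emulate: sample overlap between exposure
and outcome studies (samples are disjoint, as in the two-sample design),
population stratification, winner's-curse inflation of discovery
estimates, binary traits, multi-ancestry heterogeneity, and realistic MAF
spectra. Passing tests on these bundles therefore demonstrate the
*algorithms* behave as specified under the stated statistical model — not
that real-data analyses are free of those additional complications.

## Calibration checks and problem sizes

The test-suite and `scripts/acceptance.R` recompute, from fresh draws:

* IVW equal to an independent weighted-least-squares oracle to $10^{-10}$
  on 1,000 random instrument sets ($J \in [2, 50]$), and greedy clumping
  identical to a brute-force re-implementation on 1,000 random instances;
* mean IVW estimate within $\pm 0.005$ of a true 0.1 and 95% CI coverage
  within $[92\%, 98\%]$ over 500 replicates of a 10-instrument region at
  n = 100,000;
* premise-4 rejection of a null control within $[3.5\%, 6.5\%]$ over
  2,000 replicates (the analytic value under the floored
  random-effects model is 3.9%);
* mean MR-Egger intercept within $\pm 0.005$ of a true directional
  pleiotropy of 0.02 over 500 replicates;
* the weighted median closer to the truth than IVW in at least 90% of 500
  replicates with 3 of 10 instruments strongly pleiotropic;
* the premise matrix identical to the archetype truth table in at least
  95 of 100 bundles at n = 500,000;
* an agnostic acetoacetate-on-cognition IVW estimate recovering a true
  0.08 SD per SD from seven instrument regions at published sample sizes.

These problem sizes keep a full run in a few minutes on one core while
leaving Monte-Carlo error comfortably inside each tolerance.

## Numerical and degenerate-input policy

P-values are clipped at the smallest positive normalized double, never 0;
summary tables are parsed with base R's correctly rounded string-to-double
conversion so extreme p-values survive a write/read cycle bit-for-bit. LD
matrices are symmetrized by averaging within $10^{-8}$ (beyond that, a
data error), with the diagonal forced to 1. Invalid summary rows are
dropped with row-numbered diagnostics rather than aborting the read (a
strict mode escalates to an error), because real summary files contain
stray rows; duplicate variant ids always abort. A zero exposure beta is a
domain error for the ratio estimator, a zero-weight contribution for IVW.
All randomized routines take explicit seeds and restore the caller's RNG
state.

## Open design choices, decided

* Premise-2 sign concordance across the three ketone bodies is **off** by
  default (only the p-threshold is part of the core rule) and available as
  a flag; it is only meaningful after placing all three datasets on one
  allele frame.
* The agnostic strategy interprets "one variant per gene region" as the
  region's lead variant — an assumption, surfaced here.
* The vertical-versus-horizontal pleiotropy judgement, a human call in
  practice, is reduced to an explicit whitelist of trait names; the
  default whitelist is empty, the most conservative reading.
* Premise 2 is evaluated per discovery dataset (the verdict table is
  stratified by source), since the two acetone GWAS can legitimately
  disagree.
* Genome builds are treated as opaque: all inputs must share one, and no
  liftover is attempted.

## Limitations

No proxy-variant substitution for instruments missing from an outcome
dataset, no correlated-instrument (generalized) IVW, no MR-PRESSO or
mode-based estimators, no colocalization or Steiger filtering, no
selection-bias diagnostics. The positive-control premise can only ever
support, not prove, instrument validity: a pleiotropic region may move a
control for the wrong reason — which is exactly why the screen reports
premises separately instead of a single verdict.
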