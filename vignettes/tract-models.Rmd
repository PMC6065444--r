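---
title: "Dating admixture pulses from ancestry tract lengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating admixture pulses from ancestry tract lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixtract)
```

## The problem

A recently admixed genome is a mosaic of ancestry tracts: maximal
contiguous segments inherited from one continental source population.
Recombination breaks these tracts apart at every meiosis, so tract
lengths carry a clock — material that entered the population $t$
generations ago has survived $t$ meioses and is cut at roughly $t$
junctions per Morgan.  `admixtract` turns this into a working pipeline:
a forward simulator of admixed genomes under explicit migration
histories, tract statistics, a likelihood for dating admixture pulses,
X-versus-autosome sex-bias estimation, and ancestry-masked
subcontinental analyses.  The motivating setting is a Caribbean-style
admixture history: a founding contact between European and indigenous
American populations around fifteen generations ago, followed by one or
two later pulses of African (and possibly further Native American or
European) migration, with strongly sex-biased contributions.

## Migration histories and the simulator

A `migration_history` specifies migrant fractions $m(t, a)$ per
generation $t$ (counted backwards from the present) and ancestry $a$:
a founding generation at $t = T_{\max}$ whose fractions sum to one,
plus later single-generation pulses.  The probability that a
present-day locus descends from a migrant of ancestry $a$ entering at
$t$ is

$$p(a,t) = m(t,a) \prod_{s < t} \bigl(1 - \textstyle\sum_{a'} m(s,a')\bigr),$$

which `entry_distribution()` computes.

Two simulation engines share one meiosis primitive (Poisson crossovers
on the genetic map, no interference, uniform positions in genetic
coordinates):

* **Finite pool** (default, `pop_size = 2000` haploid genomes per
  generation): every generation each haplotype is either a fresh pure
  migrant (with the generation's total migrant probability) or the
  meiotic product of two uniformly drawn parents.  This carries genetic
  drift, which real cohorts have.
* **Branching** (`pop_size = Inf`): every parent is a fresh independent
  draw, simulated lazily along the chromosome, so present-day
  haplotypes are independent and there is no drift.  This engine
  matches the infinite-population assumptions of the analytic tract
  model and is the right oracle when comparing simulated histograms to
  analytic expectations: at any desk-scale finite size, drift moves
  ancestry fractions by $\sim\sqrt{t/N}$, which a goodness-of-fit test
  on tens of thousands of tracts registers long before the tract model
  itself is wrong.

The sexed variant (`simulate_sexed_cohort()`) assigns sexes 50/50,
applies female/male migrant fractions to the migrant draw, and
transmits the X maternally always (with recombination between the
mother's two X copies) and paternally only to daughters (intact), so
males carry one X haplotype.  In the unsexed simulator an X chromosome
recombines with probability 2/3 per transmission — the stationary
fraction of X transmissions that pass through females.

Every simulation takes a mandatory seed and is reproducible from it.
Chromosome-end tracts are flagged censored at creation; their full
lengths are unobserved.

## The analytic tract-length model

For ancestry $a$ with entry times $t$ the package models interior
(uncensored) tract lengths $x$ (Morgans) as the exponential mixture

$$f_a(x) = \sum_t w_{a,t}\, r_{a,t} e^{-r_{a,t} x}, \qquad
  r_{a,t} = t\,\bigl(1 - \bar Q_a(t)\bigr),$$

with weights $w_{a,t} \propto p(a,t)\, r_{a,t}$ (tract counts).  The
thinning factor is the package's adjacency correction: a junction
formed at meiosis $g$ ends a tract only if the material on its far side
is of a *different* ancestry, and the far side is a draw from the
ancestry pool of generation $g$.  $\bar Q_a(t)$ is the pool fraction of
ancestry $a$ averaged over the $t$ generations since entry, computable
exactly from the history because the pool composition is
piecewise-constant between migration events.  We validated this choice
against the forward simulator: with no correction ($r = t$) the
single-pulse ($t=10$, $m=0.2$) histogram is rejected catastrophically
($\chi^2 \approx 3900$ on 15 df at 40k tracts), while the corrected
rates are consistent ($p \approx 0.3$); the mean interior tract length
in that scenario is $\approx 1/(t(1-m)) = 12.5$ cM, not $1/t = 10$ cM,
in line with standard tract theory.  The uncorrected variant remains
available (`correction = "none"`), as does a $t-1$ rate convention
(`rate_offset = -1`); the default convention counts a migrant arriving
$t$ generations ago as having undergone $t$ meioses, shared exactly
with the simulator.

The approximation is accurate for ancestries whose global fraction is
at most about 0.3.  For the majority ancestry the run-merging
correction is first-order only and the histogram visibly misfits at
large tract counts; quantitative goodness-of-fit claims in the tests
are therefore made for minor ancestries, while the majority component
still participates in the likelihood (its totals, governed by the
founding fraction, remain informative).

Expected interior tract counts per histogram bin $b$ on a chromosome of
length $L_c$ include a finite-placement factor:

$$\lambda_{a,b} = N_{hap} \sum_c \sum_t p(a,t)\, r_{a,t}
  \int_b r_{a,t} e^{-r_{a,t} x} (L_c - x)_+ \, dx,$$

evaluated in closed form.  The likelihood is independent Poisson over
ancestry-by-bin cells; censored tracts are excluded from the histogram.
Bins are log-spaced from 5 to 250 cM by default (16 edges, final open
bin to the longest chromosome) — tracts under 5 cM are excluded, which
also sidesteps the scale where empirical local-ancestry calls are
unreliable.

## Fitting and model choice

`fit_pulse_model()` maximizes the Poisson likelihood with `L-BFGS-B`
from `n_restarts = 100` random starts (times in $(2, 15)$, magnitudes
in $(0.005, 0.6)$, founding fraction free; the founding time is fixed
at `G0 = 15` with an override).  A second pulse of an ancestry is kept
more recent than its first through the reparameterization
$t_2 = 2 + (t_1 - 2)v$, $v \in (0,1)$.  The five standard model shapes
(`admixture_models()`) share the EUR+NAM founding plus a first African
pulse and add second African / Native American / European pulses, with
3, 5, 5, 7 and 9 free parameters.  Models are ranked by log-likelihood
(`compare_models()`), with parameter counts and AIC reported alongside
and exact ties broken toward fewer parameters.  Confidence intervals
(68.3% by default, the one-standard-error convention) come from a
parametric bootstrap — counts resampled from the fitted expectations
and refitted from the optimum with jittered restarts — widened if
needed to contain the point estimate.  Calendar conversion uses
`year = anchor_year - 29 g`; the anchor year is deliberately a required
argument, since it is a property of the data set, not of the method.

On synthetic cohorts of 200 haploid genomes over a 35-Morgan toy map
(the problem size used throughout the tests and the acceptance script),
a single pulse at $t = 10$, $m = 0.2$ is recovered to about half a
generation and one percentage point, and a strong recent second African
pulse is preferred by every model that contains one by
$\Delta\log L \sim 100$.

## Sex-biased admixture

Per-individual autosomal and X ancestry fractions
(`compartment_ancestry()`) feed three estimators:

* `delta_admix()`: $D = \bar q_X - \bar q_A$ and
  $\Delta = D / \bar q_A$ per ancestry with individual-level bootstrap
  percentile CIs.  $\Delta > 0$ indicates excess female-specific
  contribution.  Because the ratio's exact normalization in the
  literature varies, the difference $D$ is always reported alongside.
* `wilcoxon_xa_test()`: the paired two-sided signed-rank test on
  $q_X - q_A$ (exact null for up to 25 non-zero pairs; the "unpaired"
  wording sometimes attached to this test is contradictory — the
  signed-rank test is inherently paired, and the paired version is what
  is implemented).
* `invert_sex_contributions()`: under hybrid isolation (single founding
  event, no later flow, 50/50 sex ratio) at equilibrium
  $q_A = (s_f + s_m)/2$ and $q_X = (2 s_f + s_m)/3$, inverted as
  $s_f = 3 q_X - 2 q_A$, $s_m = 4 q_A - 3 q_X$, clipped to $[0,1]$ with
  a flag.  The founding depth is fixed at 15 generations, matching the
  fitted histories; constant-flow variants are out of scope.
  `x_recursion()` exposes the underlying two-sex recursion
  ($q_f' = (q_f + q_m)/2$, $q_m' = q_f$): the individual-mean X
  ancestry converges in damped oscillation to $(2 s_f + s_m)/3$, while
  the X-copy pool mean $(2 q_f + q_m)/3$ is invariant from the start.

## Masked subcontinental analyses

`mask_panel()` sets to missing every allele whose local ancestry is not
the target, after `select_individuals()` applies boundary-inclusive
ancestry thresholds (defaults 40% European, 75% African, 15% Native
American).  `pairwise_asd()` computes allele-sharing dissimilarity
(genotype mode: $1 - \mathrm{IBS}/2$ averaged over jointly non-missing
loci; haplotype mode: mismatch fraction), with pairs under
`min_overlap` jointly observed sites (default 500) dropped rather than
imputed.  `classical_mds()` is Torgerson scaling (negative eigenvalues
reported, excluded from coordinates), and `aspca_mds()` embeds masked
haplotypes against unmasked reference panels — reducing exactly to
ASD + MDS when nothing is masked.  `wc_fst()` implements the
Weir–Cockerham variance-components estimator in its haploid form with
ratio-of-sums weighting across loci; the haploid form is the faithful
choice because masked phased data are haploid observations.

The Balding–Nichols generator (`allele_frequency_model()`) draws
per-ancestry allele frequencies around a shared ancestral frequency
with per-ancestry $F$, which calibrates these stages: $F = 0.05$ panels
give $\hat\theta \approx 0.05$, null panels give
$|\hat\theta| < 0.01$, and fixed differences give exactly 1.

## Diversity statistics

`haplotype_heterozygosity()` concatenates haplotype alleles within
non-overlapping windows of fixed genetic length (default 0.5 cM, at
least 2 SNPs — the window length is a reporting knob, since the
approach defines windows on the genetic map but no canonical size
exists) and computes unbiased heterozygosity over haplotype-string
frequencies.  `ibd_pair_summary()` totals IBD sharing (Mb) per pair
above a 3 cM floor and averages within and between groups over *all*
eligible pairs, counting pairs that share nothing as zero.

## What the synthetic data do and do not show

The generator reproduces the features the methods rely on: pulse-driven
tract-length mixtures on a genetic map, sexed X/autosome transmission,
drift (finite pool), and frequency differentiation with controllable
$F$.  It does not emulate phasing or local-ancestry call errors,
SNP-chip ascertainment, LD within ancestries beyond tract structure,
mutation, selection, or a realistic human map (toy maps only).  Tests
passing on these cohorts show the estimators are correct under the
model's assumptions — not that RFMix-style call error or reference-panel
misspecification are handled; on real data those remain the dominant
unmodelled error sources.

## Numerical choices and degenerate inputs

Tract intervals are half-open `[start, end)` cM with chromosome starts
at 0; extraction from per-site calls places boundaries at inter-site
midpoints (unbiased under symmetric call error) and extends terminal
tracts to the chromosome ends, flagged censored.  Censored tracts are
included in proportions and class statistics but excluded from the
likelihood.  The class boundary convention is (5, 50] cM short,
(50, ∞) long, (0, 5] excluded.  Count-based class proportions are
primary and length-based ones are reported alongside, since the
phrasing "proportions of tracts" is count-like but the alternative is
defensible.  Optimizer failures in all restarts raise an error rather
than returning a silent best effort; all-zero signed-rank differences
return $p = 1$ with a flag; monomorphic-everywhere FST input errors;
empty masking selections warn.  The pipeline (`run_pipeline()`) rejects
unknown configuration keys, requires explicit seeds for every
stochastic stage, and checksums all artifacts, so identical
configurations give identical outputs.

## Known limitations

* The exponential-mixture density is first-order in the minor-ancestry
  fraction; majority-ancestry histograms misfit at scale.
* Pulse times are continuous in the likelihood but generations are
  discrete in the simulator; fitted times near bin edges inherit that
  granularity.
* The bootstrap CI is parametric (Poisson resampling under the fitted
  model); it does not capture simulator drift or call-error noise.
* No continuous-migration models, no joint fitting across regions, no
  ancestry-specific recombination maps.
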