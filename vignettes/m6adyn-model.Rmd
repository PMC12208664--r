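---
title: "Semi-passive m6A dynamics: the compartment model behind m6adyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-passive m6A dynamics: the compartment model behind m6adyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6adyn)
library(dplyr)
```

## The model

Each gene's mRNA is tracked as four pools: nuclear and cytoplasmic copies
of the unmethylated (`A`) and m6A-methylated (`m6A`) species. Per species
$x \in \{A, m6A\}$:

$$\frac{dNuc_x}{dt} = \alpha_x - (\beta_x + \delta)\,Nuc_x, \qquad
  \frac{dCyt_x}{dt} = \beta_x\,Nuc_x - \gamma_x\,Cyt_x$$

with production $\alpha$, export $\beta$, optional nuclear decay $\delta$
(default 0), and cytoplasmic decay $\gamma$. The baseline
parameterization encodes one mechanistic assumption only: methylated
transcripts are degraded faster in the cytoplasm,
$\gamma^{m6A} = S\,\gamma^{A}$ with $S = 10$, while export is blind to
methylation ($\beta^{m6A} = \beta^{A}$). Everything else the package
reproduces — compartment differences in m6A level, m6A–localization and
m6A–stability couplings, perturbation responses — follows from mRNA
metabolism alone, with no targeted writing or erasing of the mark. That
is the semi-passive reading of m6A dynamics.

At steady state $Nuc_x = \alpha_x/(\beta_x + \delta)$ and
$Cyt_x = \beta_x Nuc_x/\gamma_x$, and five read-outs are derived per
gene: total abundance, the methylated fraction in the nucleus, in the
cytoplasm, and cell-wide, and the Nuc:Cyt ratio. Units are arbitrary but
mutually consistent (rates per unit time, abundances in copy units);
sampled rates sit near 1, so one time unit is roughly one mean turnover
time.

```{r}
steady_state_indices(rate_set())[c("m6a_level", "nuc_m6a_level",
                                   "cyt_m6a_level", "nuc_cyt_ratio")]
```

Because methylated transcripts are cleared selectively in the cytoplasm,
the nuclear m6A level always exceeds the whole-cell level, which exceeds
the cytoplasmic level, for every gene with $S > 1$ — the model's first
testable prediction.

## Dynamics and numerics

The system is linear, so `simulate_dynamics()` evaluates the exact
two-exponential solution per species. Two numerical choices matter:

* **Degenerate eigenvalues.** When $\beta + \delta = \gamma$ the
  two-exponential form suffers catastrophic cancellation; the
  implementation switches to the $t\,e^{-\gamma t}$ limit expression when
  $|\gamma - (\beta+\delta)| < 10^{-9}\max(\gamma, \beta+\delta)$.
* **Cross-checking.** The `"ode"` method integrates the same system with
  `deSolve::lsoda` (rtol $10^{-10}$); the test suite requires agreement
  with the closed form to a relative $10^{-6}$, including degenerate and
  nuclear-decay cases, and requires the long-time limit to reach the
  analytic steady state to $10^{-8}$.

Perturbations are instantaneous rate changes at $t = 0$ applied to a
system resting at its pre-perturbation steady state. Five presets map to
classic experiments: `actd` ($\alpha \to 0$, transcriptional shutoff),
`cpt` ($\alpha \to 0.1\alpha$), `ythdf_ko`
($\gamma^{m6A} \to \gamma^{A}$, loss of cytoplasmic readers),
`export_block` ($\beta \to 0.1\beta$, the heat-shock export collapse),
and `hs_induction` ($\alpha \to 10\alpha$). Production perturbations act
on both species jointly, since transcription does not see the mark.

A subtlety worth stating: scaling both production rates leaves every
steady-state *index* unchanged (the model is linear in $\alpha$), so
production perturbations move m6A levels only transiently — the window
over which trajectories are examined is part of the prediction. For the
export block the new steady state itself is more methylated, because the
cytoplasmic steady pools $\alpha/\gamma$ do not depend on $\beta$ while
the nuclear pools grow tenfold.

## Cohorts and the simulation experiments

`sample_rates()` draws $\alpha^A, \alpha^{m6A}, \beta, \gamma^A$
independently from a gamma distribution with shape 1 and rate 1 — the
study condition for all population-level figures — and applies a variant.
Both production rates use the same distribution; nothing in the
experiments motivates asymmetric priors. Cohort sizes follow the
simulated experiments: 2000 genes for steady-state associations, 1000 for
the export-block grid, 500 for recovery studies. The alternative export
models (`export_facilitated`, $\beta^{m6A} = 10\beta^A$;
`export_inhibited`, $\beta^{m6A} = 0.1\beta^A$) are pure alternative
mechanisms: they carry no decay selectivity ($\gamma^{m6A} = \gamma^A$).
Only then does facilitated export cleanly reverse the m6A–localization
association; retaining $S = 10$ alongside fast export collapses that
correlation to zero and tests nothing. The `nuclear_decay` variant uses
$\delta = 1$ — the same unit scale as the sampled rates — since no
specific value is prescribed anywhere; its role is robustness, not
calibration.

```{r}
cohort <- sample_rates(2000, seed = 7)
idx <- cohort_steady_state(cohort)
association(idx, m6a_level, nuc_cyt_ratio, method = "spearman")
```

Binned summaries use quantile bins with stable-rank tie-breaking (ties
resolved by input order), so heavily tied synthetic data bin
deterministically. The 25-cell stability heatmap is read as a 5 × 5
two-axis grid; the export-block grid is 6 × 6 as designed. Empty cells
are reported as missing, never as zero.

## Half-lives

`fit_half_life()` regresses natural-log abundance on time; the slope is
the decay rate $k$ and $HL = \ln 2 / (-k)$, reported only for negative
slopes with a two-sided slope-test p-value below 0.05. A zero-residual
fit is defined as $p = 0$ so that ideal simulated decay passes the
filter. Cohort half-lives are fitted on the total-RNA course after
shutoff, on a per-gene grid $\{0,1,2,4,8\}\cdot\ln 2/\gamma^A$ that
resolves each gene's own kinetics (a fixed global grid is available for
realism). The m6A-dependent stability deficit of a gene is
$HL_{KO}/HL_{WT}$, with the knockout modeled as
$\gamma^{m6A} = \gamma^A$.

Total RNA decays multi-exponentially, and the fitted half-life is
bracketed by the *loss* rates only ($\delta$, $\gamma^A$,
$\gamma^{m6A}$): export moves transcripts between compartments without
destroying them, so with $\delta = 0$ a strongly nuclear gene can decay
arbitrarily slowly. The ordering of shutoff responses also depends on
the readout: with all other rates equal, the methylated-transcript
*abundance* declines strictly faster at higher $\gamma$, whereas the
whole-cell methylated *fraction* plateaus for fast-decay genes (both
species become export-limited). `decay_ordering()` reports both; across
a sampled cohort both readouts decline faster for shorter-lived genes.

## Measurement indices

The measurement layer mirrors the assays:

* **m6A-GI** — gene-level IP/input enrichment:
  $(IP_g/N_{IP}) / (Input_g/N_{Input})$ with TMM-adjusted library sizes
  (edgeR's `calcNormFactors`, trims 0.3/0.05) computed separately within
  the IP and input fractions. Genes need 20 input reads per sample,
  mirroring the deamination coverage floor. The exact historical index
  lives in an external script; recovery tests against generated ground
  truth (rank correlation > 0.9 at depth $10^6$, dispersion 0.1) define
  this operationalization's fitness.
* **m6A-SI** — the input-weighted mean of a sample's GIs. Under
  per-sample depth normalization this mean is *identically 1* (the
  weights cancel the scales), an algebraic fact worth knowing before
  interpreting sample indices: between-sample signal exists only when
  quantification preserves IP yield, as in pooled multiplexed IP. The
  generator's `preserve_yield = TRUE` mode plus
  `normalization = "none"` models that design, under which SI estimates
  overall methylation directly.
* **GLORI-GI** — per gene, the sum of deamination-resistance scores of
  DRACH sites with coverage ≥ 20 and score strictly > 0.1, divided by
  the gene's adenosine count.
* **Nuc:Cyt LFC** — $\log_2$ ratio of TMM-normalized nuclear over
  cytoplasmic counts, pseudocount of one read on the normalized-count
  scale to keep dropout genes finite.
* **PC1 ranking** — PCA of the log2, per-gene-scaled GI matrix with
  genes as observations, complete rows only. The sign of PC1 is fixed so
  the per-sample weight profile rises along the declared sample order,
  making "induced" (positive loading) versus "repressed" (negative)
  assignments deterministic.

## The synthetic-data layer

Generators place negative-binomial counting noise (shared dispersion,
`size = 1/dispersion`, 0 = Poisson) on model-derived expectations:
fraction libraries proportional to compartment totals, input libraries
to total abundance, IP libraries to methylated plus
`ip_background`-weighted unmethylated abundance (capture modeled per
molecule, keeping the GI expectation an affine function of the
methylated fraction), deamination sites as binomial draws at the gene's
true m6A level, and shutoff courses anchored to the $t=0$ RNA pool — a
constant, spike-in-like scale, so sampled counts decay in proportion to
absolute abundance and log-linear fits are unbiased. Every generator is
a pure function of (cohort, parameters, seed) and ships its ground
truth.

What this emulates — and what it does not: counting noise, depth,
antibody background, and site-level stochasticity are represented;
mappability, positional coverage bias, isoform structure, batch effects,
and cell-to-cell heterogeneity are not. Passing recovery tests therefore
demonstrate estimator correctness under the stated noise model, not
robustness to everything real libraries contain.

## Degenerate inputs and edge conventions

* A species with zero production has empty pools; zero export *and* zero
  nuclear decay with positive production has no steady state and errors.
* An index over an empty compartment (e.g. cytoplasmic m6A level of a
  gene with nothing in the cytoplasm) is `NA`, a flagged undefined value;
  an all-zero state errors.
* Non-positive abundances fail a single half-life series, never the
  cohort pipeline; fewer than three timepoints is an error.
* Quantile bins differ in size by at most one; ties break by input
  order.
* A perturbation that removes the steady state (e.g. $\beta \to 0$) is
  simulated with a warning: the transient is well-defined.

## Known limitations

The model is deterministic and memory-free: no stochastic bursting, no
splicing or granule sequestration, no cell division, and no conversion
of existing transcripts between species (methylation enters only through
the production channel $\alpha^{m6A}$). Quantitative effect sizes of
real perturbation experiments are outside its scope; what it predicts,
and what the tests pin down, are signs, orderings, and gradients.
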