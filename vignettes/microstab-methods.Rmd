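---
title: "Methods: metabolic diversity, compensatory dynamics and wavelet-variance stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic diversity, compensatory dynamics and wavelet-variance stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

# The scientific setting

`microstab` analyses biodiversity–ecosystem-function (BEF) microcosm
experiments in which bacterial consortia of increasing species richness are
assembled from a small fixed pool, incubated on a standard detrital substrate,
and followed through (i) binary substrate-affinity profiling of each strain
(Biolog-GN-style, 95 single carbon sources), (ii) continuous multi-depth
redox-potential (Eh, mV) logging, and (iii) decomposition endpoints —
electron transport system activity (ETSA) and a dissolved-organic-carbon
(DOC) proxy. Because a 12-species pool is small, richer consortia are forced
to reuse the same resource niches: richness and functional redundancy rise
together, which is exactly the regime in which compensatory dynamics between
metabolically similar species are expected to stabilize community metabolism.

The package asks two quantitative questions of such data:

1. Does ecosystem functioning (ETSA, DOC) increase with the *breadth* of the
   community's resource niche — its community metabolic diversity (CMD)?
2. Does the *temporal stability* of community metabolism — measured as the
   reciprocal scale-averaged wavelet variance of the Eh traces, $1/V_t$ —
   increase with richness and CMD (i.e. with niche overlap)?

# Niche metrics

Species profiles are rows of a binary affinity matrix $X \in \{0,1\}^{S
\times 95}$. We use:

* **niche breadth** $b_i = \sum_s x_{is}$,
* **CMD** of a consortium $C$: $\mathrm{CMD}(C) = \left|\bigcup_{i \in C}
  \{s : x_{is} = 1\}\right|$, the number of substrates utilized by at least
  one member,
* **pairwise overlap**: the Jaccard index $J_{ij} = |A_i \cap A_j| / |A_i
  \cup A_j|$,
* **redundancy**: $1 - \mathrm{CMD}(C) / \sum_{i \in C} b_i$.

The source experiments used "overlap" and "redundancy" qualitatively; the
Jaccard index and the union/sum ratio are the simplest set-theoretic
operationalizations and are flagged as package-defined in all outputs. CMD is
computed from the union of pre-determined single-species profiles; a measured
community-level profile can be substituted by supplying it as a
single-species matrix.

**Assembly design.** `build_design()` reproduces the classic 17-consortium
nested layout (richness 2, 3, 4, 5, 7 × compositions A–C, plus single
compositions with 11 and all 12 pool species; 3 replicates each, 51
microcosms). One quirk is reproduced deliberately: the published table lists
only six strains for the richness-7/composition-C consortium. We keep the
printed membership and store the actual member count (6) as that
consortium's richness while retaining the nominal level 7 as a label;
analyses use actual member counts.

# The wavelet-variance stability statistic

Each probe's Eh series $f(x_i)$, sampled at $\Delta t = 900$ s, is
transformed with the continuous complex Morlet wavelet
$g(\eta) = \pi^{-1/4} e^{i\omega_0 \eta} e^{-\eta^2/2}$, $\omega_0 = 6$:

$$W(a, x_j) = \frac{1}{a} \sum_{i=1}^{n} f(x_i)\, g^*\!\left(\frac{x_i -
x_j}{a}\right)$$

followed by the wavelet variance per scale, its probe average, the
scale-averaged scalar and its reciprocal:

$$V(a) = \frac{1}{n} \sum_j |W(a, x_j)|^2, \qquad
V_t(a) = \frac{1}{p} \sum_{\mathrm{probes}} V(a), \qquad
V_t = \mathrm{mean}_a\, V_t(a), \qquad \mathrm{stability} = 1/V_t.$$

Choices the source description leaves open, and how this package resolves
them (all switchable):

* **Wavelet form.** The transform is named but not printed in the tradition
  this statistic comes from; we adopt the standard complex Morlet with
  $\omega_0 = 6$ (admissible in the usual approximation; values below 5 warn).
* **Normalization.** The literal prefactor is $1/a$ rather than the
  conventional energetic $1/\sqrt{a}$. `normalization = "paper"` (default)
  uses $1/a$; `"conventional"` uses $1/\sqrt{a}$. Every report records which
  was used. Under $1/a$, white noise contributes $V(a) \propto 1/a$, so the
  scale average weights short timescales more heavily than the $1/\sqrt a$
  convention would.
* **$W^2$ for a complex wavelet.** Read as $|W|^2$ (default), which is real
  and non-negative; `squared = "real"` squares the real part instead,
  matching a real-valued-transform reading.
* **Mean-centring.** Each probe series has its mean removed before the
  transform (default), so $V_t$ measures fluctuation amplitude, not offset.
  Centring is linear and therefore preserves the transform's linearity and
  quadratic-scaling properties.
* **Scale grid.** Logarithmic, `n_voices` scales per octave (default 8),
  from $2\Delta t$ up to at most a quarter of the series span. The grid keeps
  an exact $2^{1/\mathrm{voices}}$ ratio, so its top point is the last ratio
  point at or below the cap. For the default 13-day series (1248 samples)
  this is 59 scales from 1800 s to about 2.74e5 s.
* **Edge handling.** Zero padding to the next power of two, no
  cone-of-influence masking by default (none is reported in the tradition);
  `boundary = "periodic"` wraps the series instead, which makes $V_t$ of a
  periodic signal shift-invariant (checked to 1% in the tests).
* **Aggregation.** $V_t(a) \to V_t$ is an unweighted mean over the log-spaced
  grid. Probes are the averaging unit within a microcosm; replicate
  microcosms are summarized separately, and the consortium level reports
  *both* orders of averaging and reciprocal (`stability_mean_of_reciprocal`
  and `stability_reciprocal_of_mean`), since the order is not fixed by the
  source description.
* **Degenerate inputs.** A perfectly constant probe set gives $V_t = 0$;
  the scalar `stability()` operation refuses the division with a classed
  error, while the composed `treatment_stability()` flags the result
  (`degenerate = TRUE`, stability `Inf`) so screening runs are not aborted.

**Numerical implementation.** The transform is evaluated by FFT convolution
with per-scale frequency-domain kernels; the Morlet envelope is truncated at
$|\eta| \le 8$ (relative error $< 10^{-13}$) and each scale is padded far
enough that no circular wrap-around reaches the data window. The literal
double-sum of the definition is kept in the package (`cwt_direct()`) as an
independent oracle; the accelerated path matches it to better than $10^{-6}$
relative (in practice $\sim 10^{-14}$). Ties in `which.max` during scale
localization resolve to the smallest scale, R's default.

# The synthetic microcosm generator

No raw data are deposited for experiments of this design, so the generator is
a first-class module: it produces a world with the statistical structure the
analysis assumes, with known ground truth, making every downstream stage
testable. It is a *stated world*, not a tuning dial: the defaults below were
chosen once, by calibrating against the conditions the emulated experiment
reports (its design constants, its CMD saturation shape, and the magnitudes
of its six correlations), and were then frozen before the acceptance suite
was written.

**Affinity matrices.** A popularity weight vector over the 95 substrates is
drawn once per matrix from a symmetric Dirichlet (concentration
`substrate_popularity_concentration`, default 10). Each species draws its
breadth uniformly from `breadth_range` (default 40–55, the broad-generalist
range typical of Biolog GN profiles of cultivable sediment heterotrophs such
as pseudomonads and aeromonads) and samples that many substrates without
replacement with probability proportional to the weights. Lower concentration
concentrates affinity on a shared core and raises overlap. At the defaults
the mean pairwise Jaccard is ≈ 0.35 and CMD rises from ≈ 67 (richness 2) to
≈ 95, flattening around 7 species — the qualitative saturation the design is
meant to force.

**Abundance dynamics and compensation.** Member abundances follow a discrete
AR(1) mean-reverting fluctuation (timescale 1 day) around equal shares
$1/k$. Innovations are scaled by $1/\sqrt{k}$ so the *total* community
fluctuation amplitude is richness-independent when compensation is off —
this is what makes the null world flat: without compensatory dynamics,
stability carries no richness signal (a property the tests verify). With
compensation, a fraction $c \cdot \min(1, S_i)$ of species $i$'s shock
($S_i = \sum_j J_{ij}$, $c$ = `compensation_strength`, default 0.7) is
absorbed by its overlapping partners in proportion to pairwise Jaccard
overlap: partners move opposite to the shocked species, pairs of identical
species fluctuate in perfect antiphase, and — because overlapping species
hold similar resources — the community *total* metabolism is conserved.
$S_i$ crosses 1 around richness 4–5 at the default overlap level, so the
stabilizing effect saturates near the richness where the emulated experiment
reports its variance drop. Shares are truncated at zero and renormalized;
the returned paths sum to 1 at every step to $10^{-9}$. The pre-closure
("latent") deviations are kept as an attribute because compositional closure
alone forces a spurious mean pairwise correlation of $-1/(k-1)$ among
shares; independence and anti-correlation diagnostics are therefore defined
on the latent plane.

**Composite Eh.** Each species gets a redox setpoint: its mean substrate
popularity mapped linearly onto `redox_setpoint_range` (default −200 to
400 mV) plus a species-specific seeded jitter (sd 15 mV). Metabolically
similar species thus occupy similar redox niches, which is the physical
reason compensation stabilizes the composite signal. The community trace is
the share-weighted setpoint mixture, minus a total-metabolism excursion term
scaled so its uncompensated amplitude is `fluctuation_sd` (30 mV), plus an
exponential incubation settling drift (60 mV, timescale 1.5 days — "some
variation at the initial stages"). Each of the 8 probes adds a smooth AR(1)
perturbation (8 mV) mixing a shared and a probe-specific stream
(`probe_decorrelation` = 0.5) and white electrode noise (5 mV).

**Endpoints.** Per microcosm, $\mathrm{ETSA} = 0.12 \cdot \mathrm{CMD} +
\varepsilon$ and $\mathrm{DOC} = 0.4 \cdot \mathrm{CMD} + \varepsilon$,
$\varepsilon \sim N(0, 2)$, clipped at zero. With the CMD spread the default
matrices produce, these slopes give correlation magnitudes close to the
reported ones (10-seed means ≈ 0.40/0.49 for ETSA vs richness/CMD, 0.63/0.85
for DOC, 0.47/0.69 for stability, against reported values of
0.398/0.458/0.728/0.841/0.593/0.777).

**What the generator does not emulate** — and hence what a green test does
not establish: no mechanistic geochemistry (no Nernstian speciation, no
diffusion–reaction structure down the probe profile, so probe depth is
exchangeable here while real Eh profiles are strongly depth-ordered); no
community succession or competitive exclusion over the incubation; no
heavy-tailed or regime-switching abundance dynamics; endpoint noise is
Gaussian and homoscedastic. Green acceptance tests establish that the
*pipeline recovers known effects of the assumed kind*, not that the assumed
kind is how real sediments behave.

# Reproducibility and the pipeline

A single master seed drives everything. Each generator stage consumes a
named substream derived from the seed and a label (matrix, per-microcosm
abundances, per-microcosm probes, endpoints), so adding a stage never shifts
another's draws, and `simulate → write → read → analyze` equals the
in-memory analysis to serialization precision (floating-point side tables are
written with 17 significant digits). Reports are serialized at 12
significant digits with the normalization flags alongside, and two runs with
the same seed hash identically.

# Known limitations and one deliberately red check

* **Sample-path concavity of the CMD curve.** The expected CMD-vs-richness
  curve at the defaults is concave (saturating), and about 90% of individual
  discrete second differences along the nested chain are ≤ 0. But a
  *per-seed, all-pairs* concavity requirement fails in roughly half of the
  seeds: CMD is an integer set-union statistic, and near the asymptote its
  marginal gains are small counts whose sampling jitter unavoidably produces
  occasional slope upticks. Our scans show per-seed concavity above 90% is
  reachable only in a degenerate corner (breadths ≈ 80/95, CMD pinned at
  91–95, Jaccard ≈ 0.85) that removes the CMD variance and the
  richness–overlap gradient every other analysis needs. We therefore keep
  the realistic defaults and leave the strict per-seed acceptance check red,
  with the expectation-level concavity asserted separately.
* **Unit of analysis.** Whether correlations should use replicate microcosms
  (n = 51) or consortium means (n = 17) is ambiguous in designs of this
  kind; both are emitted (`correlations_replicate`, `correlations_consortium`)
  and no multiple-testing correction is applied (flagged in the output).
* **Irregular sampling is rejected, not interpolated**; gap-filling, wavelet
  significance testing against red-noise nulls, and cross-wavelet analyses
  are out of scope.
* The affinity matrix is consumed as already-binary; thresholding raw Biolog
  optical densities is upstream of this package.

# A small worked run

```{r, eval = FALSE}
cfg <- generator_config(duration = 86400, seed = 1)   # 1-day world
report <- run_microstab("simulate", config = cfg, seed = 1, n_voices = 4)
report$correlations_replicate
report$consortia[, c("consortium", "richness", "cmd", "redundancy",
                     "stability_reciprocal_of_mean")]
```

The full 13-day default world (51 microcosms × 8 probes × 1248 samples)
runs in a few seconds; the README shows its output.
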