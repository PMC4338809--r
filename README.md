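# microstab

Metabolic diversity and wavelet-variance stability of bacterial microcosms.

## The problem

In biodiversity–ecosystem-function (BEF) microcosm experiments, bacterial
consortia of increasing species richness are assembled from a small fixed
pool and followed through decomposition endpoints and continuous
redox-potential (Eh) logging. Because the pool is small, richer consortia
inevitably reuse the same resource niches, so species richness, community
metabolic diversity and functional redundancy rise together — the regime in
which compensatory metabolism between similar species is predicted to
stabilize community function. `microstab` is for microbial ecologists who
want to analyse (or simulate) such experiments end to end:

* **Niche metrics** from binary Biolog-GN-style substrate-affinity matrices
  (95 single carbon sources): per-species niche breadth, community metabolic
  diversity `CMD(C) = |∪_{i∈C} A_i|` (the union of member substrate sets),
  Jaccard niche overlap `J = |A∩B|/|A∪B|`, and functional redundancy
  `1 − CMD/Σ breadths`; plus the classic 17-consortium nested assembly
  design (richness 2–12, compositions A–C, 3 replicates = 51 microcosms).
* **Temporal stability of Eh** via the continuous Morlet wavelet transform
  `W(a, x_j) = a⁻¹ Σ_i f(x_i) g*((x_i − x_j)/a)` with
  `g(η) = π^(−1/4) e^(iω₀η) e^(−η²/2)`, the per-scale wavelet variance
  `V(a) = n⁻¹ Σ_j |W(a, x_j)|²`, its probe average `V_t(a)`, the
  scale-averaged scalar `V_t`, and the stability statistic `1/V_t`.
* **Association statistics**: the six-way Pearson battery
  {ETSA, DOC, 1/V_t} × {richness, CMD} with t-based p-values, and a cubic
  CMD-vs-richness trend.
* **A synthetic microcosm generator** (fully seeded, ground truth recorded)
  producing affinity matrices, overlap-coupled compensatory abundance
  dynamics, composite multi-probe Eh signals and endpoint tables — so the
  whole pipeline is testable without any deposited data.

See `vignette source in vignettes/microstab-methods.Rmd` for the model,
every default and its rationale, and known limitations.

## Worked example

```r
library(microstab)
cfg <- generator_config(seed = 1)               # 13-day default world
report <- run_microstab("simulate", config = cfg, seed = 1, quiet = TRUE)
report
#> run_report: 17 consortia, 51 microcosms [paper normalization]
#> replicate-level correlations:
#>   response predictor         r            p  n sig
#>       etsa  richness 0.2093076 1.404596e-01 51
#>        doc  richness 0.6888422 2.298689e-08 51  **
#>  stability  richness 0.4337987 1.471838e-03 51  **
#>       etsa       cmd 0.4104476 2.775617e-03 51  **
#>        doc       cmd 0.8900219 2.446020e-18 51  **
#>  stability       cmd 0.6539917 1.949786e-07 51  **

head(report$consortia[, c("consortium", "richness", "cmd", "redundancy",
                          "v_t", "stability_reciprocal_of_mean")], 4)
#>   consortium richness cmd redundancy      v_t stability_reciprocal_of_mean
#> 1       r02A        2  68      0.299 2.61e-05                        38242
#> 2       r02B        2  71      0.237 2.47e-05                        40476
#> 3       r02C        2  70      0.271 3.32e-05                        30102
#> 4       r03A        3  82      0.414 1.69e-05                        59143
```

Reading the output: each of the 51 replicate microcosms carries its
consortium's richness and CMD, its simulated endpoints and its measured
stability `1/V_t` (probe- and scale-averaged wavelet variance of the
mean-centred Eh traces, `1/a` normalization). DOC tracks CMD more tightly
than richness (r = 0.89 vs 0.69 here) because CMD saturates near 7 species,
and stability rises with CMD (r = 0.65) because overlapping species absorb
each other's abundance shocks. Consortium-level correlations (n = 17) and
both orders of reciprocal averaging are also in the report.

Analyze-mode runs the identical chain on files written by simulate mode (or
lab exports in the same formats: affinity TSV, design JSON, long Eh CSV,
endpoint CSV):

```r
run_microstab("analyze", affinity = "out/affinity.tsv",
              design = "out/design.json", eh = "out/eh.csv",
              endpoints = "out/endpoints_raw.csv", outdir = "out2")
```

A command-line interface wraps the same entry points:

```sh
Rscript inst/cli/microstab.R run --mode simulate --seed 42 --outdir out/
Rscript inst/cli/microstab.R stability --eh out/eh.csv --voices 8 \
    --normalization paper --omega0 6 --out out/stability.json
```

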