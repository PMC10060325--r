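# mitothermics

Chronic stress reshapes whole-body energy metabolism and skeletal-muscle
mitochondrial function. Quantifying that requires stitching together four
very different measurements: plate-format oxygen-consumption-rate (OCR)
traces from isolated mitochondria, indirect-calorimetry gas exchange from
metabolic cages, label-free proteome abundance tables, and qPCR-based
mitochondrial DNA copy number. `mitothermics` implements that full
analysis chain as a tested, reusable R package, together with a seeded
synthetic-data generator that emulates all four input kinds — so the
pipeline can be exercised, validated and power-checked without any
animal data.

It is written for bioenergetics and metabolic-phenotyping labs that want
the analysis (not the instrument software) to be reproducible: every
step from raw tick traces to final group statistics is a documented
function.

## The science in brief

**Respiration states.** A coupling assay injects ADP, oligomycin, FCCP
and antimycin A in sequence; from each well's OCR trace the package
extracts basal respiration (state 2, by the second-basal rule),
ADP-stimulated oxidative phosphorylation (state 3), oligomycin-inhibited
leak respiration (state 4o) and maximal uncoupled respiration (state
3u), then normalizes by protein load and citrate-synthase activity.

**Coupling thermodynamics.** Treating oxidative phosphorylation as a
two-flow linear energy converter, the degree of coupling is

    q = sqrt(1 − state4o / state3),        RCR = state3 / state4o

(with a deterministic batch offset rule when state-4o readings go
negative), and the optimal thermodynamic efficiency is

    η_opt = q² / (1 + sqrt(1 − q²))²

The four Stucki set points — the q at which optimal efficiency coincides
with maximal net output flow, output power, economic flow and economic
power — are derived at run time by maximizing
`F_n(q) = qⁿ·s/(1+s)ⁿ`, `s = sqrt(1−q²)`, for n = 1..4, giving
0.786, 0.910, 0.953 and 0.972. Each sample's q is classified into the
band between consecutive set points.

**Whole-body metabolism.** From 30-min cage bins: RER = VCO₂/VO₂,
energy expenditure EE = VO₂/bw^0.75 (ml/min/g^0.75), and protein-free
substrate oxidation (VO₂, VCO₂ in L/min, g/min):

    CHO = 4.585·VCO₂ − 3.2255·VO₂        FAO = 1.6946·VO₂ − 1.7012·VCO₂

summarized over the first two complete light/dark cycles (48 h).

**Proteome & copy number.** Volcano filtering (t-test on log2
abundances, > 1.5-fold and p < 0.05), EASE-style modified Fisher
enrichment (hypergeometric tail with the observed overlap decremented by
one) with Benjamini–Hochberg FDR, pathway z-score estimation statistics
against the overall experimental mean, and the mtDNA/nDNA ratio
2^(Ct_nuclear − Ct_mito) from Ct triplicates.

All group tests use a Shapiro–Wilk-gated choice between Student's
t-test and Mann–Whitney (one-way ANOVA + Tukey above two groups).

## Worked example

```r
library(mitothermics)

cfg <- generator_config(seed = 101)              # study-scale defaults
pl  <- gen_flux_plate(cfg, "coupling-CII")       # 6/group x 3 replicates
st  <- normalize_states(extract_states(pl), pl)  # protein + CS normalized
cpl <- thermodynamic_coupling(st$states$state3, st$states$state4o,
                              sample = st$states$animal_id)
cpl$group <- st$states$group
aggregate(cbind(rcr, q, eta_opt) ~ group, cpl, mean)
#>   group       rcr         q   eta_opt
#> 1  Ctrl  4.973735 0.8929087 0.3798827
#> 2   Cvs 19.733046 0.9742838 0.6323196

compare_groups(cpl$eta_opt, cpl$group)
#> t-test: statistic = 28.3, p = 7.051e-11
#> mean difference: 0.2524
#> 95% CI: [0.2326, 0.2723]

stucki_setpoints()
#> Stucki set points (degree of coupling q):
#>   q_f    (max net output flow)   = 0.786
#>   q_p    (max output power)      = 0.910
#>   q_f_ec (max economic flow)     = 0.953
#>   q_p_ec (max economic power)    = 0.972
```

The control group's complex-II coupling (mean q ≈ 0.89) sits in the
q_f–q_p band, while the stressed group's (q ≈ 0.974) lies above q_p_ec:
after chronic stress these mitochondria run near the set point of
economic net output power at optimal efficiency, and their optimal
efficiency is correspondingly higher (0.63 vs 0.38, p ≪ 0.001). The
same seed's cage simulation summarizes to EE 7.16 vs 6.28
ml/min/g^0.75 and RER 0.950 vs 0.890 (Ctrl vs stressed) — a shift from
carbohydrate toward fat oxidation.

End-to-end runs go through one config:

```r
cfg <- run_config(seed = 7, simulate = list())
run_pipeline(cfg, "results/run1")
# or: Rscript inst/scripts/mitothermics.R --config run.yaml --out results/
```

which writes per-stage CSVs plus `summary.json` and a reproducibility
`manifest.json` (identical config + seed ⇒ byte-identical summary).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and
its assumptions, every tunable parameter with units and defaults, what
the synthetic-data generator does and does not emulate, and the
numerical choices (offset rule, clamping policies, tie-breaks).
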