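# lcampscan

An R package for mining proteomes for **linear cationic α-helical
antimicrobial peptides (LCAMPs)** — short, cysteine-free, secreted
host-defense peptides whose mature region folds into an amphipathic
α-helix with a strongly cationic polar face. LCAMP families diverge too
fast for BLAST-style homology search, so `lcampscan` screens on the
conserved *physicochemical* signature instead.

## What it computes

The core quantities are helical-wheel statistics on an 18-residue sliding
window over the mature (signal-less) sequence:

- mean hydrophobicity `⟨H⟩ = (1/N) Σᵢ Hᵢ` (Fauchère–Pliska scale by
  default),
- the Eisenberg hydrophobic moment per residue at the α-helical twist
  δ = 100°,

  `μH = (1/N) √[(Σᵢ Hᵢ sin iδ)² + (Σᵢ Hᵢ cos iδ)²]`,

- net charge `z = #K + #R − #D − #E` (His neutral),

plus AGGRESCAN-style aggregation propensity (`Na⁴vSS`, the per-100-residue
normalized sum of window-averaged per-residue propensities) and Match-style
PWM scanning of upstream DNA for NF-κB-like sites (information-weighted
`core_sim`/`matrix_sim` scores in [0,1]).

`run_funnel()` chains eight screening stages in fixed order — precursor
length (50-100 aa), signal peptide, transmembrane elimination, cysteine
exclusion, cationic amphipathic window scan (H 0-0.6, μH 0.1-1.0, z +3-+10
plus composition rules), helix propensity, aggregation gate (Na⁴vSS in
[-30, 30]), and optional subcellular localization — and reports per-stage
survivor counts and a per-record report with the detected cationic segment
and anionic proregion. Trained predictors are not re-implemented: each
predictor stage takes external results via tabular adapters and falls back
to clearly-labelled rule-based heuristics so the funnel runs fully offline.

## Worked example

```r
library(lcampscan)

# Physicochemistry of a known Ciona LCAMP peptide
physchem_profile("WWLSRRRSSLFYWR")
#> physchem profile (N=14): H=0.624  muH=0.170  z=+4
#>   polar=8 uncharged(STNQH)=3 gly=0 charged=4 cys=0

# A synthetic proteome: 2 planted LCAMP-like precursors + 7 stage decoys
fx  <- make_fixture_proteome(n_planted = 2, seed = 42)
res <- run_funnel(fx$records, verbose = TRUE)
#> stage length        in=9 out=8
#> stage secretory     in=8 out=7
#> stage tm            in=7 out=6
#> stage cys           in=6 out=5
#> stage amphipathic   in=5 out=4
#> stage helical       in=4 out=3
#> stage aggregation   in=3 out=2
#> stage localization  in=2 out=2

res$report[, c("id", "stage_reached", "window_start", "window_end",
               "z", "Na4vSS", "verdict")]
#>                  id stage_reached window_start window_end  z    Na4vSS   verdict
#> 1           PLANT.1     candidate           19         48  8 -2.838667 candidate
#> 2           PLANT.2     candidate           23         49  8 -5.340617 candidate
#> 3      DECOY.length        length           NA         NA NA        NA  rejected
#> 4   DECOY.secretory     secretory           NA         NA NA        NA  rejected
#> 5          DECOY.tm            tm           NA         NA NA        NA  rejected
#> 6         DECOY.cys           cys           NA         NA NA        NA  rejected
#> 7 DECOY.amphipathic   amphipathic           NA         NA NA        NA  rejected
#> 8     DECOY.helical       helical           17         40  8        NA  rejected
#> 9 DECOY.aggregation   aggregation           21         41  8 33.628175  rejected
```

Both planted precursors reach `candidate`; every decoy is rejected exactly
at the stage it was built to fail. `window_start`/`window_end` are 1-based
coordinates of the merged cationic amphipathic segment on the precursor;
`z` is the net charge of its best window; `Na4vSS` is the aggregation score
of the segment (the aggregation decoy's 33.6 falls outside the [-30, 30]
gate).

A thin command-line wrapper ships in `inst/cli/lcampscan`
(`screen`, `physchem`, `aggrescan`, `pwm-scan`, `consensus`, `fixtures`).

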