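# rtshift

Quantifying reverse-transcription GC bias in ribosome-based 16S rRNA
amplicon surveys.

RNA-based (ribosome) amplicon sequencing needs a reverse transcription
(RT) step, and RT enzymes capture templates with an efficiency that
depends on reaction temperature and template GC content. `rtshift` is an R
package for the downstream analysis of experiments that compare RT
conditions on the same community: it takes an OTU count table, taxonomy,
representative sequences and sample metadata (enzyme, temperature,
replicate), and quantifies how strongly between-condition compositional
shifts are explained by class GC content.

## The statistic

For a taxonomic class with mean relative abundance *A* in one condition
and *B* in another (means over replicates), the normalized enrichment is

    E = (A − B) / (A + B)

bounded in [−1, 1]: 0 when the class is equally proportional, +1 / −1
when it occurs in only one condition. Its standard deviation is propagated
from the replicate standard deviations δA, δB by the first-order delta
method:

    δE = 2 · sqrt(B²·δA² + A²·δB²) / (A + B)²

Per condition pair, `rtshift` fits an ordinary least-squares regression of
*E* on abundance-weighted class GC, reporting adjusted R², the slope *t*
value and p-value with significance codes (`*`, `**`, `***` at p < 0.05,
0.01, 0.001), plus Shapiro–Wilk and Breusch–Pagan assumption diagnostics;
pairs failing the diagnostics are flagged with a caveat marker.

The pipeline also provides rarefaction to even depth, a reproducible
Bray–Curtis/MAD outlier screen, replicate equalization, class-level
profiles with a low-abundance collapse for stacked-bar figures, alpha
diversity (richness, Shannon, Pielou), and a synthetic-data generator
whose GC-dependent capture-efficiency model (`e0 · exp(−λ·gc)`) lets the
whole inference chain be validated on known truth — including null
calibration and power curves.

## Worked example

Simulate a four-condition experiment (ImProm-II at 42 and 55 °C,
SuperScript IV at 55 °C, TGIRT at 57 °C; four replicates; 9,000 reads per
sample; GC bias strongest in the low-temperature reaction) and run the
full analysis:

```r
library(rtshift)

sc  <- sim_scenario(seed = 7)          # 40 classes, GC 0.35-0.75
sim <- simulate_experiment(sc)
res <- analyze_simulation(sim, seed = 7)
res$regressions[, c("condition_a", "condition_b", "n_classes",
                    "adjusted_r2", "t_value", "p_value", "significance")]
```

```
      condition_a       condition_b n_classes adjusted_r2 t_value  p_value significance
     ImProm-II 42      ImProm-II 55        40       0.476  -6.041 5.00e-07          ***
     ImProm-II 42 SuperScript IV 55        40       0.414  -5.339 4.59e-06          ***
     ImProm-II 42          TGIRT 57        40       0.647  -8.508 2.49e-10          ***
     ImProm-II 55 SuperScript IV 55        40      -0.019  -0.516 6.09e-01
     ImProm-II 55          TGIRT 57        40       0.022  -1.365 1.80e-01
SuperScript IV 55          TGIRT 57        40      -0.021  -0.443 6.61e-01
```

Read: every pair involving the 42 °C reaction shows a strongly negative,
highly significant slope — high-GC classes are depleted in the
low-temperature condition, and class GC explains 40–65% of the variance in
enrichment. Pairs among the high-temperature conditions show no GC effect,
as constructed. The six rows are all `choose(4, 2)` condition pairs,
oriented by enzyme label then temperature.

File-based runs work the same way through `rt_config()` + `run_pipeline()`
(writing `condition_profiles.tsv`, `enrichment.tsv`, `regressions.tsv`,
`diversity.tsv`, a stacked-bar table and a JSON provenance manifest), and
a thin command-line wrapper lives at `inst/cli/rtshift.R`
(`simulate` and `run` subcommands).

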