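# polyrepsim

Stochastic simulation of very-early DNA replication in a polytene
chromosome fragment, for chromatin and replication-timing researchers who
want to test whether **initiation-rate differences alone** can explain the
dissimilar early replication patterns seen in different initiation zones.

A polytene chromosome stacks ~1024 identical chromatids in register, so
stochastic single-molecule events read out as dot-density patterns along
one axis. The package models one initiation zone (INT) — a 52-kbp
alternation of six 2-kbp interbands with four 5-kbp gray bands and one
20-kbp middle gray band — flanked by two compact black rb-bands. On each
chromatid exactly one origin fires, at a position uniform over the pooled
interband DNA, at a time drawn from one of four temporal regimes:

* synchronous: all origins at *t* = 0
* uniform windows: activation times i.i.d. uniform on [0, *T*] for
  *T* = 10, 30 or 60 min

Each origin emits two divergent forks at *v* = 2 kbp/min (genomic). The
axial dot speed is *v* divided by the local compaction *d* = kbp per
width unit, so a dot crosses an interband at 1 width/min and slows
sharply inside bands; fork positions, segment-crossing times and INT
completion times are computed in closed form (event-driven, no time
stepping). The worst-case synchronous INT completion is 52/(2·2) = 13…26
min depending on origin placement, with the analytic maximum 26 min.

On top of the simulator sit microscope-style snapshots ("red dots" = fork
positions), axial density profiles, an edge-concentration statistic, a
synthetic observation layer (detection dropout + axial localization
jitter), and a classifier that recovers the generating temporal regime
from observed profiles.

## Worked example

```r
library(polyrepsim)

model    <- build_default_int()                    # 52-kbp INT, 100-kbp flanks
scenario <- initiation_scenario(window_min = 30)   # gradual firing over 30 min
recs     <- simulate_replication(model, scenario, n_chromatids = 1024,
                                 speed = 2, seed = 42)

summary(recs$int_completion_min)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   18.38   29.11   37.00   37.02   44.97   55.57
```

Every chromatid finishes its INT between 18 and 56 min: at most 26 min of
fork travel on top of an activation time uniform on [0, 30].

```r
fraction_initiated(recs, 3)
#> [1] 0.1113281
```

Three minutes in, ~11% of strands have fired — the regime that shows up
under the microscope as ~100 scattered dots among 1024 strands.

```r
s <- snapshot(recs, 20)
nrow(s); table(s$segment_kind)
#> [1] 1328
#>       black        gray   interband middle_gray
#>         557         277         183         311
edge_concentration_index(snapshot(recs, 5))   # 0.195
edge_concentration_index(snapshot(recs, 30))  # 0.395
```

At 20 min, 1328 dots are active (2 per fired chromatid, minus none yet
stopped) and have drained out of the interbands into the DNA-rich bands;
the fraction packed against the rb-band edges doubles between 5 and
30 min.

Scenario recovery from a noisy synthetic observation (80% detection,
0.05-width jitter):

```r
obs <- make_labeled_dataset(model, default_scenarios()["win30"], 1,
                            noise_model(), seed = 8)[[1]]
res <- classify_scenario(obs, default_scenarios(), model, seed = 99)
round(res$distances, 3); res$best
#>  sync win10 win30 win60
#> 0.873 0.291 0.088 0.090
#> [1] "win30"
```

The generating 30-min window wins. Note how close the 30- and 60-min
distances are: those two regimes are the genuinely hard pair, and the
only confusions seen in calibration (5/100 under default noise) are
between them.

## Command-line pipeline

```sh
Rscript inst/exec/polyrepsim make-model --out model.tsv
Rscript inst/exec/polyrepsim simulate --config cfg.txt --out-dir out/
Rscript inst/exec/polyrepsim profile  --snapshots out/snapshots.tsv --out profiles.tsv
Rscript inst/exec/polyrepsim classify --profiles out/profiles.tsv --out report.tsv
```

All outputs are a pure function of the flat `key: value` config file and
its seed — two runs of the same config are byte-identical.

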