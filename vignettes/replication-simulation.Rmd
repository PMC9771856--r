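---
title: "Simulating early replication in a polytene band/interband fragment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating early replication in a polytene band/interband fragment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrepsim)
```

## The question the model addresses

Polytene chromosomes bundle ~1024 identical, precisely aligned DNA strands
(chromatids), so single-molecule stochastic events — such as which
replication origin fires, and when — become visible as population patterns
along one chromosome axis. Early in S phase, replication initiates inside
*INTs*: decondensed intervals between compact, late-replicating
ruby-chromatin bands (rb-bands), composed of alternating ~2-kbp interbands
(which carry promoters, ORC sites, and potential origins) and moderately
compacted gray bands. Different INTs show strikingly different early
labeling patterns: sharp paired bands flanking a point, or diffuse dots
that only gradually condense onto the rb-band edges.

`polyrepsim` asks whether **differences in initiation rate alone** —
synchronous firing versus firing spread uniformly over a 10-, 30-, or
60-minute window — are sufficient to generate these dissimilar patterns,
with everything else (origin placement law, fork speed, geometry) held
fixed. It simulates the fragment, renders microscope-style dot snapshots,
degrades them with a synthetic observation layer, and then tries to
*recover* the generating regime from the degraded patterns.

## The chromosome fragment

A `chromosome_model` is an ordered run of segments, each with a DNA
content (kbp) and an axial width (abstract width units). The ratio
`dna_kbp / axial_width` is the local compaction. Genomic and axial
coordinates are both 0-based with half-open segments `[start, end)`; a
point exactly on a boundary belongs to the right-hand segment, which makes
dot-to-segment classification unambiguous. `genomic_to_axial()` /
`axial_to_genomic()` form an exact piecewise-linear bijection.

The built-in fragment (`build_default_int()`) is a 52-kbp INT — six 2-kbp
interbands alternating with four 5-kbp gray bands and one 20-kbp middle
gray band, all drawn at equal axial width 1 — flanked by two black
rb-bands. Two quantities are not fixed by the biology we model and were
chosen once:

* **Black-flank DNA content, default 100 kbp per flank.** The largest
  intercalary-heterochromatin bands exceed 200 kbp, but 100 kbp keeps the
  late snapshots (60, 120 min) informative: forks are still in transit at
  60 min and have exactly left the fragment by 120 min.
* **Black-flank axial width, default `dna / 50`** (a 50-kbp-per-width
  compaction, consistent with the 1/50 relative axial speed used in
  `"stated"` mode). Bands are drawn wider than INT segments, but no
  specific width is canonical; it is configurable.

## Fork dynamics and the two speed modes

Each fired origin emits two divergent forks. Published descriptions of
this system state both (a) a constant *genomic* fork speed of 2 kbp/min —
ten times the ~0.24 kbp/min late-replicon rate, reflecting very early S
phase — and (b) relative *axial* dot speeds of V, V/5, V/20, V/50 in
interbands, gray, middle-gray and black segments. The two are mutually
inconsistent by about a factor of two for gray bands (a 5-kbp unit-width
band at constant 2 kbp/min yields V/2.5, not V/5). Rather than guess the
intent, both readings are implemented:

* `speed_mode = "dna"` (**default**): constant genomic speed (2 kbp/min);
  axial speed follows from local compaction. This is the only reading
  consistent with both "1 interband width per minute" and a worst-case
  INT completion of 52/2 = 26 min ≤ 30 min.
* `speed_mode = "stated"`: the printed axial speeds are imposed per
  segment kind, with V defined against the canonical 2-kbp unit-width
  interband (V = speed/2 widths/min).

In both modes fork motion is *event-driven*: per-segment speeds give a
piecewise-linear "traversal-time potential" over the fragment, and a
fork's position at any time is obtained by inverting it — no time
stepping, no accumulation of numerical error. Forks stop when they reach
the outer ends of the fragment; with one origin per chromatid and
divergent forks, no merging can occur.

An independent brute-force integrator, `fork_position_stepped()`, advances
a fork in explicit Δt = 10⁻³ min steps. A naive Euler step would overshoot
each segment boundary by up to |Δv|·Δt ≈ 10⁻³ kbp, and with ~10 boundary
crossings that alone would exceed the 2×10⁻³-kbp agreement tolerance the
tests demand; the stepper therefore splits a step exactly at segment
boundaries, which preserves its independence from the closed form (forward
integration versus potential inversion) while making the comparison sharp.
Closed form and stepper agree to ~10⁻¹⁰ kbp over 500 random cases in both
speed modes.

## Initiation scenarios

Each chromatid fires exactly one origin:

* **Position** — `dispersed` (default): uniform over the pooled interband
  DNA, i.e. each interband is hit in proportion to its DNA content and
  uniformly within; or `fixed_locus`: every chromatid fires at one given
  interband position, emulating a single highly efficient origin (the
  alternative explanation for paired signals).
* **Time** — `window_min = 0`: synchronous; otherwise i.i.d. uniform on
  `[0, window_min]`. A stated per-minute origin quota of ~10/min
  contradicts "1024 origins within 10 min" (≈102/min); the window endpoint
  is authoritative here, and uniform-over-window reproduces it exactly.

All draws come from one seeded stream in chromatid order, so results are
reproducible and independent of evaluation order.

## Snapshots, profiles and the edge-concentration index

`snapshot(records, t)` renders every active fork as a dot (a fork is
active from activation until it reaches a fragment end), giving the
invariant `dots(t) = 2·activated(t) − stopped(t)`. `density_profile()`
bins dots axially (default bin width 0.1 width units — fine enough to
resolve a unit-width band into 10 bins, coarse enough that a 1024-
chromatid snapshot still averages ~14 dots per occupied bin).

`edge_concentration_index()` operationalizes "signals concentrate at the
rb-band edges": the fraction of dots inside the flanking black bands
within `margin_kbp` of the black/INT boundary. No canonical margin
exists; the default is **30 kbp**, chosen so the index is meaningful at
the 30-minute snapshot: at 2 kbp/min, synchronous forks sit 8–60 kbp deep
in the blacks at t = 30, so any margin below ~8 kbp is already empty
again by then, while 30 kbp gives the analytic values 1/3 at 5 min and
1/2 at 30 min for the default geometry — a clean, testable rise followed
by the expected collapse to 0 once every fork passes the margin
(t ≳ 41 min).

## Synthetic observations

The generator emulates a super-resolution dot readout, not an image:

* **Detection dropout** — each dot is kept with probability `p_detect`
  (default 0.8: bright-point detection is good but not complete).
* **Axial localization jitter** — Gaussian error with SD
  `jitter_sd_axial` (default 0.05 width units, i.e. ~5% of a band width,
  on the order of the ~140-nm lateral resolution relative to band
  spacing), applied in *axial* space — where optical error physically
  arises — then clamped to the fragment.

It does **not** model fluorescence intensity, replication-factory
clustering, chromosome bending or stretching, or detection of anything
but fork positions. A green recovery test therefore establishes that the
initiation regimes are statistically distinguishable from dot densities
under dropout and jitter — not that a real micrograph could be classified.

## Scenario recovery

`classify_scenario()` scores an observed pattern against each candidate
regime by simulating reference replicates (default 5), averaging their
normalized axial profiles per time point, and summing Euclidean distances
across the default snapshot set {1, 5, 20, 30} min — the window where the
regimes differ most. Two design points matter:

* **Normalization is counts/(2·N), not counts/total dots.** The chromatid
  count still cancels between observed and reference patterns, but the
  *fraction of chromatids already fired* is retained. This is essential,
  not cosmetic: conditional on having fired, fork ages are identically
  distributed under any uniform window that has not closed by the
  snapshot time, so dividing by the dot total makes the 30- and 60-min
  windows theoretically indistinguishable at snapshots up to 30 min. A
  calibration run confirmed the failure mode (60-min patterns were
  systematically classified as 30-min, pulled by the lower reference
  noise of the better-populated candidate) and its disappearance under
  per-capacity normalization.
* **Distance is plain Euclidean** on the normalized profiles — monotone,
  simple, and sufficient for qualitatively distinct patterns; no metric
  learning is warranted by the problem.

Calibration (frozen before the acceptance thresholds were written): over
10 noiseless patterns per regime, recovery was 40/40; over 25 patterns
per regime under default noise, 95/100 with all five confusions between
the adjacent 30- and 60-min windows. The acceptance suite asserts the
frozen thresholds: ≥90% noiseless accuracy with only adjacent confusions,
and a diagonal-dominant confusion matrix under default noise.

## Numerical choices and degenerate inputs

* Coordinates are doubles in kbp/width units; round-trip mapping error is
  < 10⁻⁹ kbp over the whole fragment.
* A dot exactly on a bin or segment boundary goes right (half-open
  convention); the final bin closes at the fragment end.
* Empty snapshots profile to all-zero counts; the edge index of an empty
  snapshot is 0.
* `completion_time()` refuses regions that exclude the chromatid's
  origin: with a single origin, such a region can never be replicated
  from inside, and silently returning `Inf` would hide user error.
* Config files are flat `key: value` text with all times in minutes
  (4 s is entered as 0.0667) and all genomic lengths in kbp, so the
  seconds/minutes mixing of the source material cannot leak into code.

## Known limitations

* The ~10× fork slowdown in late-replicating bands is deliberately not
  modeled (constant speed per mode is itself a simplification of the
  system described); black-band transit times are therefore optimistic.
* One origin per chromatid: no licensing, interference, dormant origins,
  or inter-INT fork interactions.
* ORC-density-weighted placement (the observed left-biased origin
  distribution in some INTs) is out of scope; placement is uniform per
  kbp of interband DNA.
* The `stated` speed mode reproduces printed axial speeds but is not
  self-consistent with the stated genomic speed; it exists for fidelity,
  and the package never asserts which reading was intended.
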