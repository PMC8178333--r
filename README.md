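# crownmap

Spatial statistics and persistent homology for the hook-like sclerites
preserved inside scaphitid ammonite body chambers.

Some exceptionally preserved Late Cretaceous scaphitids contain 40–168
small hooks, each assignable to one of nine morphotypes (five major
bicuspid classes `G1`–`G5`, very small bicuspids `VSB`, and rare
tricuspid/unicuspid/rounded classes). Whether these are brachial-crown
(arm/tentacle) armature rather than taphonomic debris is a question about
their *arrangement in space*. `crownmap` implements the quantitative side
of that argument on 3D opening-landmark data:

* **Nearest-neighbour morphotype composition** against an analytic
  random-labelling null. For morphotype *i* with `Nm_i` of `N_tot` hooks,
  the expected same-morphotype nearest-neighbour count is
  `Em_ii = (Nm_i − 1)/(N_tot − 1) × Nm_i`, and after outlier exclusion the
  expected cross count is `Em_ij = N'm_j/(N'_tot − N'm_i) × N'm_i`.
  Observed/expected ratios (percent) measure clustering (same-morphotype)
  and pairing (cross-morphotype, e.g. the mirror pairs G1–G4 and G2–G5).
* **Tukey 1.5×IQR outlier exclusion** on each hook's mean distance to the
  rest of its morphotype.
* **Vietoris–Rips persistent homology** (dimensions 0–1, from first
  principles with a compiled GF(2) reduction) and the per-morphotype
  "links": the component-merge edges (= Euclidean MST), filtered to the
  strongest, best-integrated links by a Tukey fence on merge strengths.
* **Axis reconstruction**: per-morphotype diameter paths of the retained
  link graphs, merged across a morphotype pair into ordered candidate
  axes, with coverage, straightness and a basal-position score for the
  small morphotypes.
* **A synthetic-specimen generator** (clustered world and matched uniform
  null) so the whole pipeline is testable without the original CT data,
  which is not publicly deposited.

## Worked example

```r
library(crownmap)

cfg <- syntheticConfig(seed = 1)      # two straight paired axes, 120 hooks
sp  <- generateClustered(cfg)

dir <- tempfile(); runAnalyze(sp, dir)
runReport(dir)
```

```
crownmap analysis summary
specimens: synthetic_seed1
same-morphotype nearest-neighbour ratios (obs/exp %):
  G1: 24/5.04 (476%)
  G2: 24/5.04 (476%)
  G3: 4/0.35 (1133.3%)
  G4: 23/5.04 (456.2%)
  G5: 23/5.04 (456.2%)
  ...
top cross-morphotype association per morphotype:
  G1 -> G4 (380%)
  G2 -> G5 (364.8%)
  G3 -> VSB (1614.3%)
  ...
axes:
  synthetic_seed1 axis 1 [G1-G4]: 50 hooks, length 99.4 mm, straightness 0.374, coverage 1.00
  synthetic_seed1 axis 2 [G2-G5]: 50 hooks, length 107.7 mm, straightness 0.347, coverage 1.00
```

Reading the output: 24 of the 25 `G1` hooks have another `G1` as nearest
neighbour where 5.04 would be expected at random (ratio 476% — strong
clustering by morphotype); the top cross-morphotype partner of `G1` is
`G4` and of `G2` is `G5` (the mirror pairs); and two axes are recovered,
each containing 100% of its pair's hooks. On a matched random specimen
(`generateNull(cfg)`) the aggregate same-morphotype ratio sits at ≈ 100%.

A thin command-line wrapper is installed with the package:

```sh
CM=$(Rscript -e 'cat(system.file("scripts","crownmap",package="crownmap"))')
Rscript $CM simulate -o out/
Rscript $CM analyze -i out/landmarks.csv -o out/results
Rscript $CM report -i out/results
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline's headline quantities from scratch — it simulates
a seven-specimen clustered suite plus matched uniform nulls, runs the
nearest-neighbour, link and axis analyses, logs the aggregate ratios and
axis counts, and writes the JSON result file.

See `vignettes/crownmap-methods.Rmd` for the model, parameter rationale,
numerical choices and known limitations.
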