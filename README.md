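# calyxcycle

Joint kinetic analysis of presynaptic **membrane retrieval** (capacitance)
and **vesicle-protein retrieval** (pH-sensitive reporter fluorescence) at
large synaptic terminals such as the calyx of Held.

## The problem

After synaptic vesicles fuse, the terminal must take the membrane *and* the
vesicular proteins back. Capacitance measurements see the membrane:
exocytosis is an upward jump, endocytosis a recovery decay

    C_norm(t) = p + (1 - p) · Σᵢ aᵢ e^(−t/τᵢ),   Σ aᵢ = 1,

with a non-retrieved plateau `p` and fast/slow components. A cypHer-class
reporter (fluorescent at vesicular pH ≈ 5.5, quenched at extracellular
pH ≈ 7.4) sees the protein: its signal recovers only after the retrieved
organelle **re-acidifies**. Modelling each organelle as neutral for a delay
`d` and then acidifying exponentially with time constant `τ_acid`, mapped
through the Henderson–Hasselbalch curve φ(pH) = 1/(1 + 10^(pH − pKa))
(pKa 7.05, Hill 1), the population quench trace is the convolution of the
endocytic flux `e(t) = −dC_norm/dt` with the organelle de-quench kernel
`g`:

    Q(t) = 1 − ∫₀ᵗ e(t′) · g(t − t′) dt′.

`calyxcycle` provides, for anyone analysing (or teaching, or power-testing)
such paired recordings:

* a fully seeded **synthetic generator** of paired capacitance/fluorescence
  traces with noise, photobleaching, neighbour-ROI references,
  extracellular acid puffs and scenario presets (control rat/mouse,
  endocytosis block, re-acidification block, reporter stranding, bulk
  endocytosis, depression series);
* the **fitting stack**: per-pulse jump measurement, bi-exponential
  endocytosis fit, bleach correction, quench-trace normalisation, the
  convolution fit recovering `(d, τ_acid)` by grid search + refinement, a
  delayed single-exponential fit for long recordings, acid-puff
  surface-pool metrics and mean ± SEM / Student-t summaries;
* an **event-based Monte-Carlo oracle** (discrete organelles) that bounds
  the convolution model in the test suite.

## Worked example

```r
library(calyxcycle)

scn <- scenario_preset("rat_control", seed = 1, noise_sd = 0)
cm  <- simulate_capacitance(scn)          # pF trace, 10×50 ms train
rep <- simulate_reporter(scn, cm)         # raw fluorescence + state log

measure_jumps(cm, scn$protocol)$total_dCm_pF
#> [1] 1.517312

cmn <- normalize_cm(cm)
fit_endocytosis(cmn)
#> <cap_fit> bi-exponential, plateau 0.12, sse 2.77e-25 (n = 6001)
#>   tau = 5.2 s (37.0% of recoverable)
#>   tau = 66.5 s (63.0% of recoverable)

q <- normalize_invert(rep$fluor)          # inverted: 1 = fully quenched
round(c(cm_60s = endpoint_metric(cmn, 60),
        quench_60s = endpoint_metric(q, 60)), 3)
#>     cm_60s quench_60s
#>      0.345      0.540

fit_reacidification(cmn, q)
#> <reacid_fit> delay 14.00 s, tau_acid 38.64 s (sse 1.68e-08, per_organelle mode)
```

The summed per-pulse increments read back the 1.52 pF the generator
exocytosed (the last pulse's measurement window already contains ~0.2% of
recovery); the bi-exponential fit recovers the generating decay exactly;
the membrane is back to 0.345 of the jump 60 s after the train while the
reporter is still 0.54 quenched — and the convolution fit explains that lag
as a 14-s onset delay followed by a 38.6-s re-acidification. The quench
trace lags because organelle de-quenching, not membrane retrieval, is
rate-limiting at late times.

`run_replica(out_dir = "replica")` runs the same pipeline over every preset
and writes traces, ground truth, fit results (`results.json`) and overlay
plots.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the headline quantities from scratch against the installed
package: it simulates the noise-free rat and mouse presets, measures the
summed capacitance jumps, fits the bi-exponential recovery (fast/slow time
constants and fast fraction) and runs the convolution re-acidification fit
on both presets, writing one JSON object of recovered values.
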