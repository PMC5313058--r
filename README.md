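# ranvier

Node of Ranvier geometry and myelinated-axon conduction speed.

## What this is for

Conduction speed along myelinated CNS axons is usually attributed to
myelin thickness and internode length, but the node of Ranvier is a third
geometric determinant: a longer node has more membrane capacitance and a
higher axial resistance into the internode (slower), while — at fixed
channel density — it also carries more voltage-gated Na⁺ channels
(faster). Measured node lengths vary several-fold between CNS axons yet
are tightly conserved along each axon, so per-axon node-length adjustment
is a candidate mechanism for tuning spike arrival times at a membrane
cost hundreds of times smaller than remodelling the myelin sheath.

`ranvier` is for computational neuroscientists and neuroanatomists who
want to quantify that idea. It provides:

- a **double-cable compartmental model** of a myelinated axon — the
  axolemma and the periaxonal space under the myelin as two coupled
  cables, Hodgkin–Huxley-type nodal channels (fast Na⁺ m³h, persistent
  Na⁺ p³, slow K⁺ s), and the paranodal spiral pathway represented by its
  effective periaxonal width `w = A·L/[(π·d)²·N_wraps]` — with presets
  for rat optic-nerve and layer-V cortical axons (Table-1-style YAML
  files mirrored field-for-field);
- **in-silico experiments**: conduction speed between mid-axon nodes,
  sweeps of node length, internode length and myelin wrap count under
  constant-channel-density or constant-channel-number assumptions,
  alternating-node-length axons, and speed-matched equivalence solving;
- **morphometry**: node length from confocal line profiles as the
  distance between per-paranode half-maximum crossings, summed
  nodal-marker intensity, and the along-axon vs between-axon coefficient
  of variation analysis;
- a **synthetic-data generator** for axon populations and confocal-like
  line profiles with realistic statistics, so the full pipeline runs and
  is tested without any microscopy data.

The integrator is a backward-Euler 2×2-block tridiagonal solve in C++
(0.25 µs default step) with exponential-integrator gating updates; a full
51-node axon simulates in a few seconds.

## Worked example

```r
library(ranvier)

p <- cable_params("optic_nerve")
p
#> Myelinated axon parameters (optic_nerve)
#>   node:      d 0.73 um, L 1.02 um, gNa 3000 / gKs 80 / gNap 5 mS/cm2
#>   internode: d 0.82 um, L 139.26 um, 7 wraps (g-ratio 0.78)
#>   paranode:  L 2.11 um, effective periaxonal width 0.0077 nm
#>   potentials: Er -82, ELk -83.38, ENa 50, EK -84 mV

# derived geometry: the paranodal spiral pathway acts like a periaxonal
# space of sub-atomic effective width, sealing the internode
paranodal_effective_width(170, p$L_paranode, p$d_axon_internode, p$N_wraps)
#> [1] 0.007721575

# membrane-area cost of a speed change: myelin wrap vs node shortening
membrane_area_ledger(p, 1.02, 0.625)$ratio
#> [1] 1015.443

# simulate a reduced axon and sweep node length at constant channel number
sweep_node_length(p, c(0.5, 1.02, 2.2), "constant_number",
                  n_nodes = 11, first_node = 3, last_node = 8, dt = 5e-4)
#> Sweep of node_length (constant_number), preset 'optic_nerve': baseline 3.228 m/s at 1.02
#>   value speed_mps pct_change
#> 1  0.50     3.331      3.186
#> 2  1.02     3.228      0.000
#> 3  2.20     3.019     -6.474
```

Shortening nodes below the mean length speeds conduction (+3.2 % at
0.5 µm) and lengthening them slows it (−6.5 % at 2.2 µm) when the nodal
channel complement is held fixed; under constant channel density the
curve instead peaks near 1.7 µm. The full-protocol numbers (51 nodes,
speed between nodes 20 and 30) are what the acceptance script reports.

The morphometry/synthetic-data side closes on itself:

```r
dir <- tempfile()
end_to_end_fixture(population_model(), render_model(noise_sd = 20),
                   n_axons = 18, seed = 1, dir = dir)
res <- measure_fixture(dir)
r <- along_vs_between_reduction(
  data.frame(axon = res$axon, node_length = res$measured_length))
r$mean_reduction_pct   # node-length CoV along axons ~half the pooled CoV
```

See `vignettes/node-length-conduction.Rmd` for the model equations,
parameter meanings, numerical choices and known limitations.

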