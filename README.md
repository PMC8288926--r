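# hdperc — history-dependent percolation on multiplex networks

`hdperc` implements generational (history-dependent) percolation: an
iterative cluster-refinement process on multiplex networks — several layers
of links over one shared node set — in which each generation keeps a layer's
link only when both endpoints already belong to the same cluster of the
previous generation's configuration. Generation 1 is ordinary percolation of
layer A; generation 2 re-percolates those clusters through layer B; the
layers alternate until no cluster changes (the steady state, or "infinite
generation"). The package is for network scientists studying how iterated,
state-dependent processes change the nature of a percolation transition, and
for practitioners (e.g. in connectomics) who want the intermediate
generations as structural probes of a bilayer network.

## What it computes

**Engine** (`percolate_generations`, `apply_layer`, `components`, `dilute`):
deterministic generation-by-generation traces — largest-cluster fraction
ψⁿ, second-largest cluster size N₂, cluster counts and size histograms, and
the steady-state generation n_c — backed by a C++ union-find pass per
generation. Partitions can only refine, so ψⁿ is non-increasing and the
steady state always exists.

**Mean-field theory** (`er_F`, `configmodel_F`, `recursion_trace`,
`finite_generation_threshold`, `infinite_fixed_point`,
`discontinuous_critical_point`, `er_critical_point`): with 𝔉(x) the
giant-cluster fraction of a layer restricted to a random usable fraction x
(for ER layers the largest root of u = 1 − e^{−zxu}), the recursion

    ψⁿ = Sⁿ⁻¹ 𝔉(Sⁿ⁻¹),   Sⁿ = S⁰ 𝔉(Sⁿ⁻¹)

alternates layers A and B. Every finite generation has a continuous
transition (for ER layers z_c¹ = 1, z_c² = 1/(1−e⁻¹) ≈ 1.582, …), while the
steady state S = 𝔉(S) turns on tangentially: for two ER layers the
transition is discontinuous at z_c^∞ ≈ 2.455 with S_c ≈ 0.715 and a jump
ψ_c^∞ = S_c² ≈ 0.512. Occupation control (random link removal) replaces
𝔉(x) by 𝔉(px).

**Generators** (`er_layer`, `sf_layer`, `threshold_top_weights`,
`synthetic_weighted_pair`, `layer_overlap`): fixed-edge-count ER layers,
truncated power-law configuration-model layers (p_k ∝ k^(−γ) on m..K,
default K = √N), top-weight thresholding of symmetric weight matrices to a
target average degree (the standard weighted-connectome binarization), and a
synthetic correlated weighted bilayer emulating functional/morphological
brain matrices.

**Monte Carlo protocols** (`ensemble_sweep`, `order_parameter_samples`,
`classify_percolating`, `pseudo_critical_point`, `fit_power_scaling`,
`fit_offset_scaling`, `cluster_size_distribution`): coupled-marks occupation
sweeps, bimodal order-parameter classification into percolating and
non-percolating realizations, N₂-peak pseudo-critical detection, and the
finite-size scaling fits ψ_c ∝ N^(−ε) and ψ_c(N) = ψ_c0 + a·N^(−ϵ) that
diagnose continuous versus discontinuous transitions.

## Worked example

The 4-node multiplex with layer A a path 0–1–2–3 and layer B = {(0,2), (1,3)}:

```r
library(hdperc)
net <- multiplex_network(list(cbind(0:2, 1:3),
                              cbind(c(0, 1), c(2, 3))), n_nodes = 4)
percolate_generations(net)
#> Generation trace: 4 generations recorded (steady at n_c = 3)
#>   generation  psi second_largest n_clusters
#> 1          1 1.00              0          1
#> 2          2 0.50              2          2
#> 3          3 0.25              1          4
#> 4          4 0.25              1          4
```

Generation 1 connects everything through the path; generation 2 keeps B's
links inside that single cluster, splitting it into {0,2} and {1,3}
(ψ² = 0.5); generation 3 finds no A-link inside either pair, so everything
shatters (ψ³ = 0.25) and the steady state is reached at n_c = 3.

The analytic critical point of the infinite generation for two ER layers:

```r
er_critical_point()
#> Discontinuous critical point: control = 2.4554, S_c = 0.7153, psi_c = 0.5117
```

And the same transition seen from simulation — at z = 2.455 the steady-state
order parameter of a finite system is bimodal, and the percolating
realizations carry the jump:

```r
s <- order_parameter_samples(function(z, seed) er_multiplex(2^14, z, seed),
                             2.455, n = Inf, R = 100, seed = 1)
cl <- classify_percolating(s, 2^14)
round(c(fraction = cl$fraction, jump = mean(s[cl$mask])), 3)
#> fraction     jump
#>    0.610    0.554
```

A command-line front end wrapping these functions is installed at
`inst/cli/hdperc.R` (subcommands `generate-er`, `generate-sf`, `threshold`,
`percolate`, `overlap`, `theory-er`; every run writes a reproducibility
manifest).

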