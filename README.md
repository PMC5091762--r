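# biofilmshear

Mesoscale simulation of the shear mechanics of bacterial biofilms.

Biofilms are soft two-phase composites: comparatively rigid bacterial
cells embedded in a compliant extracellular polymeric substance (EPS)
matrix.  Under shear they strain-stiffen — protein chains in the EPS
uncoil and straighten — and under sustained loading the matrix tears,
softening the film and potentially isolating cells from the load-bearing
network.  `biofilmshear` reproduces this behaviour with a lattice-spring
model: a digitized binary cross-section (bacteria vs EPS) is mapped onto a
triangular network of axial springs with coordination number six, where

- bacterial springs are stiff and linear (100× modulus contrast),
- each EPS spring holds eight folded sub-springs with quenched random
  uncoiling energy thresholds ψ<sub>t,1</sub> < … < ψ<sub>t,8</sub>; when
  its strain energy crosses the next threshold one sub-spring uncoils and
  the spring stiffness rises along the series law
  k<sub>eff</sub>(m) = 8k / ((8 − m) + m/β), up to βk at m = 8,
- a fully uncoiled spring whose stored energy exceeds its rupture
  threshold ψ<sub>t,u</sub> is removed irreversibly,
- loading is quasi-static confined shear (bottom plate fixed, top plate
  displaced by γH with vertical motion suppressed), with full
  re-equilibration and event sweeps at every strain increment.

The package bundles a synthetic microstructure generator (rod-shaped cells
at a target area fraction, uniformly dispersed or clustered centrally or
at the corners), two published parameter presets, and analysis tools:
tangent stiffness, Hashin–Shtrikman bounds on the effective shear modulus,

    G_l = G1 + c2 [ 1/(G2−G1) + 6(K1+2G1)c1 / (5G1(3K1+4G1)) ]⁻¹ ,

force/unfolding localization maps, and detection of bacteria detached from
the load-bearing network.

## Worked example

Simulate tearing of a centrally clustered biofilm on the rupture preset
(EPS modulus 8000 N/m², uncoiling thresholds 1.05·10⁻³ ± 0.05·10⁻³ J,
rupture threshold 4·10⁻³ J):

```r
library(biofilmshear)

sim <- preset_study("korstgens2001", "central_cluster", 0.42, seed = 7)
attr(sim, "microstructure")
#> microstructure: 128 x 256 pixels, loading 0.412 (35 bacteria), 0.09 x 0.045 m
sim$network
#> lattice_network: 1612 nodes (31 x 52), 4671 springs (1211 bacterial, 25.9%), a = 0.00173077 m
summary(sim)
#> confined shear to gamma = 0.35 over 140 steps
#>   secant stiffness tau/gamma at gamma_max: 5252 N/m^2
#>   peak tangent stiffness: 1.357e+04 N/m^2 at gamma = 0.297
#>   first rupture at gamma = 0.173 (tau = 1179 N/m^2); 101 springs ruptured
#>   detached bacteria: 0
```

The summary shows the two regimes: stiffness climbs while sub-springs
uncoil, cracks start at a stress of about 1.2 kN/m² (clustered specimens
tear earlier and at lower stress than uniformly seeded ones), and rupture
then erodes the stiffness.  `plot(sim)` draws the stress–strain curve,
`plot(sim, "stiffness")` the tangent stiffness, and
`localization_map(sim, 0.35)` tabulates per-spring forces and categories
for contour plots.

Checking an effective stiffness against the composite bounds:

```r
p <- preset_parameters("stoodley2002")
hashin_shtrikman_bounds(p$props_eps, p$props_bact, 0.26)
#> Hashin-Shtrikman shear bounds at c2 = 0.26: [0.5743, 5.617] N/m^2
```

Configuration files (YAML/JSON, see `?load_config`) drive the same
pipeline from the command line via `inst/scripts/biofilm-shear.R`
(`generate`, `run`, `bounds`, `analyze` subcommands).

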