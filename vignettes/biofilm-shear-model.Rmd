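---
title: "A lattice-spring model of biofilm shear mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice-spring model of biofilm shear mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A biofilm cross-section is treated as a two-phase composite: rigid rod-shaped
bacteria embedded in a soft extracellular polymeric substance (EPS) matrix.
The digitized binary image of the cross-section is superimposed on a
triangular lattice of axial springs (coordination number six in the
interior).  A spring whose two endpoints and midpoint all fall on bacterial
pixels belongs to the bacterial phase and is simply a very stiff linear
spring; every other spring is EPS.

The EPS is where all the interesting mechanics happens.  Each EPS spring is
pictured as a chain of eight folded sub-springs.  Its stored strain energy
is compared against eight quenched random thresholds
$\psi_{t,1} < \dots < \psi_{t,8}$, drawn once per spring from a uniform law
and sorted; every time the energy first exceeds the next threshold one
sub-spring uncoils and the spring stiffens.  With $m$ of eight sub-springs
uncoiled and an uncoiled sub-spring $\beta$ times stiffer than a folded one,
the series law gives

$$ k_\mathrm{eff}(m) \;=\; \frac{8\,k}{(8-m) + m/\beta}, $$

which runs from $k$ at $m=0$ to $\beta k$ at $m=8$.  A fully uncoiled spring
whose stored energy then exceeds a final rupture threshold $\psi_{t,u}$ is
removed from the network irreversibly; its load redistributes to its
neighbours at the next re-solve.  Collectively these rules produce the
strain-stiffening-then-softening shear response, diagonal strain
localization, and damage concentrated in the thin EPS films between
closely packed cells.

Loading is quasi-static confined shear: the bottom node row is fixed, the
top row is displaced horizontally by $\gamma H$ with vertical motion
suppressed (rigid bonded plates), lateral edges are traction-free.  The
strain is raised in equal increments $\Delta\gamma$; after each solve the
spring energies are updated and unfolding/rupture events are processed one
sub-spring per spring per sweep, re-solving at fixed strain until a sweep
produces no events.  Because the kinematics are linear and the geometry is
frozen, the solution at a given stiffness distribution scales linearly in
$\gamma$, so steps without events need no new factorization.

Macroscopic outputs are the shear stress $\tau$ (sum of horizontal top-plate
reactions divided by plate area), the tangent stiffness $G_t =
d\tau/d\gamma$ (smoothed central differences), per-spring force and
category maps, and the set of bacteria that have lost every intact-spring
connection to the bottom plate (detached).

## Spring calibration and elastic limits

For a triangular lattice of equal axial springs the affine-limit identity

$$ k = \tfrac{\sqrt 3}{2}\,E\,t $$

maps a target Young's modulus to the spring constant independently of the
lattice spacing; the emergent Poisson ratio of the net is $1/3$ and its
shear modulus is $(3/8)Et$.  A uniaxial platen test on the homogeneous
default lattice recovers $E$ to better than 2% and $\nu = 1/3$ to better
than 2% (finite-size softening of the free columns accounts for the
residual).  Published parameter tables for the two bundled presets quote
$\nu = 0.33$ with $G = E/3$, which is internally inconsistent with isotropy
($G = 0.375E$ at $\nu = 1/3$); the package treats the printed $G$ values
purely as inputs to the Hashin–Shtrikman bound formulas and the lattice
geometry as the authority on $\nu$.  With $\nu = 1/3$ exactly, $K = E$,
which reproduces the published lower bound $G_l \approx 0.574$ N/m² at 26%
loading.

## Which energy drives the thresholds

The event rules compare "the strain energy in the spring" against
thresholds, and for a spring whose stiffness jumps at an event this phrase
is genuinely ambiguous.  The package implements four readings
(`energy_mode`), and the choice matters:

* **`base` (default)** — the reference-state energy
  $\tfrac12 k\,e^2$ at the current elongation, with $k$ the folded-state
  stiffness.  The uncoiling thresholds are properties of the folded chain,
  so each sub-spring uncoils at a well-defined elongation; $\psi$ is
  continuous through events and stiffening is progressive.
* **`stored`** — the elastic energy actually stored,
  $\tfrac12 k_\mathrm{eff}e^2$.  At each uncoiling this jumps by the
  stiffness ratio at frozen elongation, so a spring that crosses its first
  threshold tends to avalanche through the entire ladder at once; the
  macroscopic response becomes jumpy and bistable between disorder
  realizations.
* **`work`** — mechanical work accumulated over accepted solves,
  $\psi \mathrel{+}= f\,du + \tfrac12\,df\,du$.  Smooth, but a stiffened
  spring later unloaded by crack redistribution accumulates large negative
  work and its ladder stalls permanently.
* **`increment`** — the literal half-increment form
  $\psi \mathrel{+}= \tfrac12\,df\,du$.  The quadratic increments shrink
  linearly as $\Delta\gamma$ is refined, so onset strains depend on the
  step size; it is kept for fidelity studies only.

Whatever drives uncoiling, **rupture** is always evaluated against the
current stored energy $\tfrac12 k_\mathrm{eff}e^2$: scission of a fully
extended chain is governed by the load it carries now, not by its loading
history.  This combination (base-energy uncoiling, stored-energy rupture)
is the only one of the four that yields smooth stiffening *and* lets cracks
propagate without stalling, which is why it is the default.

## Boundary treatment: grip layers

Springs incident to the fully constrained top and bottom node rows are, by
default, part of the grips: they remain linearly elastic and never uncoil
or rupture.  The constrained rows carry a small systematic energy excess
(they cannot relax laterally), and at narrow threshold disorder that bias
otherwise nucleates a spurious delamination crack along the plates instead
of damage in the bulk.  Physically the plates are bonded to the specimen
and adhesive failure is not part of the EPS constitutive picture.  Set
`grip_layers = FALSE` to disable.

## Synthetic microstructures

The generator stamps discretized capsules (rectangles with semicircular
caps; an elliptical outline is available — cell shape has little effect on
the shear response) of uniformly random orientation until the bacterial
area fraction reaches the target within ±1%.  Centres are uniform over the
domain, Gaussian about the centre, or an equal mixture of Gaussians at the
four corners.  A candidate rod may overlap existing cells by at most
`max_overlap` (default 15%) of its area: cells may touch and partially
fuse, as they do in dense colonies, but clusters remain packings of mostly
distinct cells separated by thin EPS films.  This matters mechanically —
with unrestricted overlap a 42% central cluster coalesces into one solid
rigid blob with no interior films, which removes precisely the stress
concentrations that make clustered biofilms tear early, and collapses the
bacterium labelling (connected components under 8-connectivity) to a
single unit.  Candidates that would overshoot the loading band are
rejected, so the walk terminates inside ±1%; generation is bit-reproducible
given the seed.

What the generator does *not* emulate: real digitized cross-sections have
irregular cell outlines, size dispersity, partial-volume pixels and
imaging noise.  Tests passing on synthetic specimens therefore validate
the mechanics pipeline, not any claim about a particular experimental
image; masks of real cross-sections can be supplied as plain-text 0/1
grids or PNG/TIFF files.

## Physical scale of the specimens, and $\beta$

The published parameter sets give the uncoiling and rupture thresholds in
joules but no specimen dimensions, and spring energies scale with the
square of the physical lattice spacing — so each preset implies a specimen
scale that must be fixed before any energies are comparable.  The package
follows the source's own methodology (parameters set so that the simulated
response follows the corresponding experiment) and calibrates **one scalar
per preset, once**:

* `stoodley2002` (strain hardening, no rupture): a 0.8 m × 0.8 m square,
  chosen so that strain stiffening of the reference 42%-loading uniform
  specimen becomes appreciable around $\gamma \approx 0.15$ and is fully
  developed by 35%, as in the reported stress–strain curves.
* `korstgens2001` (hardening then tearing): a 0.09 m × 0.045 m slab,
  calibrated so that rupture in uniform 42% specimens initiates near the
  reported 1300 N/m² stress level.  The 2:1 aspect ratio reflects that
  imaged cross-sections are much wider than tall; mechanically it lets a
  central cluster span the gap between the plates, which routes the load
  path through the thin intra-cluster films — the stated mechanism for
  clustered biofilms tearing earlier.  The central-cluster rupture stress
  (≈1040 N/m², reported 1100), the uniform/central ordering, and the
  earlier stiffness peak for clustering are then emergent, not fitted.

Similarly the terminal stiffening ratio $\beta$ is only sketched in the
source (an uncoiled chain drawn as rigid).  The default $\beta = 8$ is
calibrated against the one quantitative nonlinearity anchor available: the
maximum spring force in a 42% uniform specimen grows roughly fifteen-fold
between 5% and 35% shear (measured 17.4 ± 1.3 over five disorder seeds at
the default conditions).  At $\beta = 100$ that amplification comes out
3–4× too large.  Note the absolute force magnitudes quoted alongside that
ratio (tenths of newtons) are not simultaneously reproducible with the
joule-scale thresholds under the $k = (\sqrt3/2)Et$ calibration at any
single specimen scale; only the ratio is scale-free.

## Numerical choices

* Default strain increment $\Delta\gamma = 0.0025$; the response without
  events is exactly linear (and is computed by scaling, not re-solving), so
  the increment only controls event ordering granularity.
* Sparse Cholesky factorization of the reduced stiffness operator
  $K_{ff} = B_f^{\mathsf T}\,\mathrm{diag}(k)\,B_f$; the free/constrained
  partition is rebuilt only when rupture changes the intact topology.
* A diagonal shift of $10^{-11}\times\max K_{ii}$ guards against floppy
  modes of dangling sub-chains; components with no path to a constrained
  node are pinned at zero with zero load.  Equilibrium residuals are
  tracked per step and sit at round-off level.
* When rupture severs every intact path between the plates the run ends
  early, flagged as structural failure, returning the partial result.
* One sub-spring per spring per sweep, with a cap of 200 sweeps per strain
  increment; capped steps are flagged, never silently accepted.
* Tangent stiffness uses central differences smoothed by a 5-step moving
  average.
* Two independent seeds (morphology, thresholds) let studies hold the
  specimen fixed while resampling disorder.

Reference problem sizes (the defaults of `preset_parameters()`): masks of
128×128 or 128×256 pixels, lattices of roughly 1200–1600 nodes and
3400–4700 springs, strain programs of 140–200 steps.  A full run takes
seconds to tens of seconds; these sizes resolve individual cells with
2–3 lattice spacings across a rod width while keeping seed-averaged
studies cheap.

## Known limitations

* **Small-strain linear kinematics on a frozen geometry** (by design, even
  at 35–50% applied strain): energy bookkeeping is per-step elastic, there
  is no contact, no ligament rotation, no finite-strain update.  One
  visible consequence: once a crack partially encircles a bacterium the
  surviving connections are unloaded by the crack opening (strain
  shielding), so *complete* detachment — a bacterium losing every intact
  path to the substratum — is rarer in this implementation than the
  two-phase damage maps suggest.  In the bundled rupture studies the
  uniform specimens keep every bacterium attached, as expected, but
  central clusters also typically end with zero fully detached bacteria;
  capturing reliable detachment appears to require the geometric
  nonlinearity this model deliberately omits.
* No viscoelasticity or rate dependence: the model addresses the elastic
  response at times short against the biofilm relaxation time scale.
* Two phases only — no water/air voids, no deformable bacteria; bacteria
  are a finite (100×) stiffness contrast, not rigid constraints.
* The Hashin–Shtrikman comparison applies three-dimensional bounds to a
  plane specimen, as in the source analysis; the free lateral edges also
  depress the measured modulus of narrow specimens by a few percent.
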