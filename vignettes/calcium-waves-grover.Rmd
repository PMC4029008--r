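---
title: "Calcium wave regimes and quantum-search correspondence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium wave regimes and quantum-search correspondence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calwave)
```

## The model

Intracellular calcium-induced calcium release (CICR) couples discrete
IP~3~-receptor release sites along the endoplasmic reticulum: when the local
cytosolic Ca^2+^ concentration at a site first reaches a threshold
$[\mathrm{Ca}^{2+}]_T$, the site releases a fixed quantity $\sigma$ of
Ca^2+^ over a duration $\tau$, and the released ions diffuse (coefficient
$D$) toward neighbouring sites a distance $d$ away. `calwave` implements
this fire-diffuse-fire (FDF) model in one dimension:

$$\frac{\partial c}{\partial t} = D\frac{\partial^2 c}{\partial x^2}
  + \frac{\sigma}{d^2\tau}\sum_i \delta(x - x_i)\,
    H(t - t_i)\,H(t_i + \tau - t),$$

with $t_i$ the first threshold-crossing time of site $i$. Sites fire exactly
once (deterministic refractoriness) and the equation carries no re-uptake or
extrusion terms; buffering is treated as instantaneous and absorbed into the
effective $\sigma$. Units are fixed package-wide: µm, s, µM.

Two dimensionless groups control the dynamics:

* $\Gamma = (\sigma/d^3) / ([\mathrm{Ca}^{2+}]_T - [\mathrm{Ca}^{2+}]_b)$,
  the released concentration relative to the threshold excess — how easily a
  wave ignites and how fast it travels;
* $\beta$, which decides the propagation mode: saltatory (site-to-site hops
  limited by inter-site diffusion, $v \propto D/d$) for $\beta$ well below
  1, continuous (release-kinetics limited, Luther scaling
  $v \approx \sqrt{\Gamma}\sqrt{D/\tau}$) for $\beta \gg 1$.

### The two beta conventions

The source literature prints $\beta = (D/\tau)/d^2$ once, but every worked
numerical value it reports is reproduced by $\beta = D\tau/d^2$ and none by
the literal form (e.g. $190 \times 0.04 / 2^2 = 1.9$, whereas
$(190/0.04)/2^2 = 1187.5$). `compute_beta()` therefore defaults to
`convention = "worked_example"` ($D\tau/d^2$) and keeps the literal form
available behind `convention = "as_printed"`. We deliberately do not
reconcile the two: the discrepancy is documented, both are computable, and
all shipped defaults and tests use the worked-example convention.

A related convention interaction appears in the inverse maps. With the
worked-example $\beta$, $\Gamma_S = \tau v g/(\beta d)$ recovers the
$\Gamma$ used to generate a saltatory velocity exactly; the continuous
inverse $\Gamma_C = v f/(\sqrt{\beta}\, d)$ recovers $\sqrt{\Gamma}$ under
the as-printed convention (and $\sqrt{\Gamma}/\tau$ under the
worked-example one). Both identities are frozen into the test suite as
stated rather than silently adjusted.

The unspecified inverse functions $g^{-1}$ and $f^{-1}$ in the velocity laws
are collapsed into a single configurable `geometry_factor` defaulting to 1,
the value implied by the worked usage $v \approx \sqrt{D/\tau}$ and
$v \approx D/d$.

## Numerical scheme

`simulate_fdf()` integrates the evolution equation with an explicit
forward-Euler / central-difference scheme.

* **Resolution.** Default `dx = d/20` (resolving inter-site gradients) and
  `dt = 0.4 dx^2/(2D)`, safely inside the stability bound
  `dt <= dx^2/(2D)`, which is enforced with a diagnostic error.
* **Source deposition.** Each $\delta$ source is deposited at the grid node
  nearest the site as a flux $(\sigma/d^2\tau)/dx$; the release duration is
  quantized to `round(tau/dt)` steps with the per-step deposit scaled so
  that each event adds exactly $\sigma/d^2$ (concentration × length). With
  reflecting (mirror) boundaries the update stencil conserves the discrete
  integral exactly, so total calcium equals the initial mass plus
  $\sigma/d^2$ per completed event to floating-point accuracy — the basis
  of the mass-conservation test at $10^{-6}$ relative tolerance.
* **Initiation and boundaries.** The source equation does not itself fix
  boundary conditions or an initiation protocol; reflecting boundaries and a
  single triggered site (site 1, firing at $t = 0$) are package choices, with
  absorbing boundaries and any trigger index available. The default domain
  adds a margin of $2d$ on each side of the lattice.
* **Threshold detection.** A site fires when the concentration at its
  nearest grid node first reaches $[\mathrm{Ca}^{2+}]_T$ after the update;
  simultaneous crossings are recorded in increasing site order. Each site
  fires once.
* **Duration.** Integration stops when every site has fired and all releases
  have completed, or at `t_max` (by default a generous multiple of the
  slower of the two velocity-law crossing-time estimates).

`estimate_velocity()` fits the least-squares slope of distance-from-trigger
versus firing time over the trailing half of fired sites, discarding the
initiation transient; it requires at least three firings and otherwise
returns an explicit failure flag rather than a number.

### What the simulated conditions do and do not show

The default parameter set used throughout the tests is the worked-example
condition set — $\tau = 0.04$ s, $d = 2$ µm, with a released concentration
of 5 µM against a 0.5 µM threshold excess ($\Gamma = 10$; threshold 0.6 µM
over a 0.1 µM basal level, resting-cytosol magnitudes). Against this
generator:

* A continuous-regime run at $D = 190$ µm²/s reaches 90% of the Luther
  asymptote $\sqrt{\Gamma D/\tau}$; across $\Gamma \in \{10, 25\}$ the
  measured ratio stays in $[0.75, 1.00]$, the band frozen after the oracle
  runs (the asymptote is a large-$\Gamma$ upper bound, so ratios a little
  below 1 are expected).
* The velocity–$D$ log–log slope is measured over decades chosen to lie
  cleanly inside one regime: $D \in \{120, \ldots, 1200\}$ µm²/s
  ($\beta \ge 1.2$) for the continuous slope ($\approx 0.55$, band
  $0.5 \pm 0.1$) and $D \in \{0.3, \ldots, 3\}$ µm²/s ($\beta \le 0.06$)
  for the saltatory slope ($\approx 0.96$, band $1.0 \pm 0.15$). The deep
  decade matters for the saltatory law: it is the $\beta \to 0$ asymptote,
  and at larger $D$ the hop delay approaches $\tau$ and the measured slope
  drifts down. For these scans the classifier's small-$D$
  conduction-failure overlay is disabled (`D_fail = 0`) because it encodes
  an empirical failure band for modest $\Gamma$, not a property of the
  idealized lattice being measured.
* Simulations use 10–14 sites; firing intervals are constant along the
  lattice at these sizes, so wake accumulation (the model has no re-uptake)
  does not bias the velocity fit.

What passing these tests does **not** show: behaviour under stochastic
channel gating, explicit mobile buffers, ER re-uptake, 2-D/3-D geometry, or
irregular cluster spacing — none of which are part of this evolution
equation. The model is an idealization whose value here is that its two
regimes realize the $v \propto D$ versus $v \propto \sqrt{D}$ contrast.

## Regime classification

`classify_regime()` labels a parameter point continuous when
$\beta \ge$ `beta_hi` (default 1.0, operationalizing "$\beta \gg 1$"),
saltatory when $\beta \le$ `beta_lo` (default 0.5), and mixed between.
Conduction failure overrides all three when $D < 10$ µm²/s with a
saltatory-side $\beta$, when $d > 3$ µm, or when $\Gamma$ leaves a
configurable admissible band (default $[0.1, 100]$: below ~0.1 a release
cannot plausibly ignite a neighbour; far above 100 the instantaneous-buffer
idealization has no support). Only the $D$, $d$ failure cut-offs are given
by the source material; the $\beta$ thresholds and $\Gamma$ band are
package defaults and are configurable everywhere they are used.

## IP3R gating

`open_probability()` implements the steady-state tetrameric open
probability: the cube of a per-monomer factor combining IP~3~ binding,
Ca^2+^ activation and Ca^2+^ inhibition. It is bell-shaped in Ca^2+^ at
fixed IP~3~ — low Ca^2+^ activates, high Ca^2+^ inhibits — with its peak
near 0.28 µM at saturating IP~3~ under the default constants.
`phi_terms()` and `extended_gamma()` extend $\Gamma$ to a net flux balance
(release + leak down the ER gradient, Hill-type re-uptake, buffer capture)
divided by the threshold excess; a negative value means waves cannot
initiate and is mapped to regime `failure` downstream rather than raised as
an error. The denominator's kinetic weighting, written ambiguously in the
source notation, is taken to equal the plain threshold difference
$[\mathrm{Ca}^{2+}]_T - [\mathrm{Ca}^{2+}]_b$; this is an assumption and is
documented as such.

No dissociation constants or flux magnitudes are given in the source
material. The shipped defaults (`gating_constants()`, `flux_params()`) are
repo defaults with DeYoung–Keizer-style magnitudes, labelled as such in the
documentation; scientific use requires explicit measured values.

## Quantum search module

`quantum_state()` is a dense complex statevector over $2^n$ basis states
(unit norm enforced at $10^{-12}$); this desk-scale representation is exact
for the register sizes used here ($n \le 20$) and deliberately avoids gate
decompositions or hardware backends.

* The oracle is implemented as a direct conditional phase flip
  $a_x \mapsto (-1)^{\theta(x)} a_x$. The ancilla formulation — an extra
  qubit in $(|0\rangle - |1\rangle)/\sqrt{2}$ flipped conditionally — is
  mathematically equivalent by phase kickback; the equivalence is verified
  against an explicit ancilla construction for $n \le 4$ in the tests.
* `grover_diffusion()` applies
  $H^{\otimes n}(2|0\rangle\langle 0| - I)H^{\otimes n}$, the inversion
  about the mean amplitude, checked against the dense matrix
  $2|\psi\rangle\langle\psi| - I$ for $n \le 6$.
* **Iteration counts.** Two conventions coexist and are kept separate on
  purpose. The measurement-optimal count
  $k = \mathrm{round}(\pi/(4\arcsin\sqrt{M/N}) - 1/2)$ (round half up,
  floored at 0) maximizes the closed-form success probability
  $\sin^2((2k+1)\arcsin\sqrt{M/N})$ and is what `grover_search()` runs; it
  gives $k = 1$, success 1 at $N = 4, M = 1$. The query-complexity count
  $\lceil (\pi/4)\sqrt{N/M} \rceil$ is the standard bound quoted for
  scaling statements; `query_count_comparison()` reports it as
  `grover_queries` because the $-1/2$ offset in the optimal count, while
  irrelevant asymptotically, biases the log–log slope of
  classical/quantum query ratios measurably at small $N$ (0.42 instead of
  the asymptotic 0.5 over $N = 4 \ldots 1024$). Both columns are returned,
  so either convention can be read off.
* The classical baseline is the exact expected number of sequential probes
  to the first of $M$ uniformly hidden targets, accumulated over the
  hitting-time distribution (equal to $(N+1)/(M+1)$, which the tests verify
  independently); exact enumeration removes Monte-Carlo noise from the
  speed-up comparison.
* Measurement sampling is the only stochastic element in the package; it is
  seeded explicitly and bit-reproducible.

`bell_state()`, `superdense_encode()`/`superdense_decode()` implement the
four Bell states and the two-classical-bits-per-qubit round trip (decode by
projection onto the Bell basis; non-Bell inputs yield the argmax outcome
flagged non-deterministic). `theta_conformation()` marks the conducting
IP~3~R monomer configuration $|110\rangle$ (IP~3~ bound, high-affinity
Ca^2+^ bound, low-affinity site free) among the eight 3-bit conformations,
and `count_primed_configurations()` evaluates the falling factorial
$M_n!/(M_n-1)! = M_n$ (4 for the tetramer).

## The Gamma-indexed register

`register_grid()` builds an `n_grid`-point grid with $\Gamma$ spaced
linearly (geometric optional) over `[gamma_min, gamma_max]` and $D$ spaced
over `[D_min, D_max]`, co-indexed: the one-to-one, order-preserving mapping
between the $\Gamma$ index and $D$ is the discrete register that the search
runs over. `build_search_register()` classifies every point, sorts by
$\Gamma$, assigns indices $0 \ldots N-1$, and pads up to the next power of
two with failure entries — padding can never add solutions. Points
classified continuous form the solution subset $i_M$; saltatory, mixed and
failed points form $i_F$. An empty $i_M$ is allowed and flagged, and
propagates to a distinct no-solution report (and CLI exit code) rather than
an error.

The spatial scale $d$ is a free configuration parameter: the same machinery
describes intercluster ($d \sim 2$ µm) and intracluster ($d \sim 0.02$ µm)
lattices, and the package makes no ruling on where the local/global
boundary lies.

`run_end_to_end()` chains grid → classification → register → Grover search
→ exact classical baseline → the $\lceil\sqrt{D_{max}/D_C}\rceil$
search-time bound → the quadratic-relation checks, and reproduces the
worked-example table. With the shipped default configuration the register
is $N = 16$ with $M = 4$ continuous solutions, for which a single Grover
iteration reaches success probability 1.

Two conventions here deserve note. First, the realized-register Grover
count in `algorithmic_search_time()` is the success-probability-peak count
$\lfloor \pi/(4\arcsin\sqrt{M/N}) \rfloor$ (3 for $N = 64, M = 4$),
cross-checked in the tests against the statevector peak. Second, the
velocity relation $v_C = v_S^2$ is dimensionally inconsistent as printed
(µm/s versus µm²/s²); `verify_quadratic_relations()` evaluates it as a
numeric comparison in fixed µm/s units only, reports a boolean, and never
enforces it.

## Problem sizes and runtime

The shipped test-suite and pipeline sizes are chosen for desk-scale
verification: FDF lattices of 10–14 sites at $dx = d/20$ (one refinement
level at $d/40$), exhaustive Grover checks for $n \le 5$, dense-matrix
operator checks for $n \le 6$, query-count series up to $N = 1024$, and a
16-point default register. The full suite runs in well under a minute on
one CPU.

## Known limitations

* The FDF runs omit re-uptake, extrusion, explicit buffers and stochastic
  gating; the extended-$\Gamma$ machinery quantifies those fluxes
  point-wise but is not coupled back into the PDE.
* The saltatory velocity law is recovered only in the deep-saltatory
  asymptote; near the regime boundary the measured exponent falls between
  the two laws, which is a property of the model, not of the integrator.
* The quantum module is a mathematical statevector simulator; nothing in
  the package asserts that a receptor physically realizes these operators,
  and decoherence, noise channels, counting and teleportation are out of
  scope.
* Default gating constants are order-of-magnitude placeholders.
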