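---
title: "Methods: ALPB surface potentials and hierarchical charge partitioning"
author: "hcpesp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ALPB surface potentials and hierarchical charge partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpesp)
```

## The physical model

`hcpesp` evaluates the electrostatic potential at surface vertices of a
biomolecule under the analytic linearized Poisson–Boltzmann (ALPB) model.
The potential outside the solute due to a single point charge $q$ is

$$
\phi \;=\; u \,\frac{q}{\epsilon_{in}}\,
\frac{1}{1+\alpha\beta}
\left[\frac{1+\alpha}{d} \;-\; \frac{\alpha\,(1-\beta)}{r}\right],
\qquad \beta = \frac{\epsilon_{in}}{\epsilon_{out}},
$$

with $d$ the charge-to-vertex distance, $r$ the distance from the vertex to
a fixed reference center of the structure, $\alpha$ the dimensionless ALPB
constant, and $u$ an output unit factor. The model assumes a single
low-dielectric solute region in a high-dielectric solvent, linear response,
and no ionic screening beyond what the ALPB form captures; the inside-
the-solute branch of the model and the estimation of the effective
electrostatic size are out of scope. Two limits anchor the implementation
and are enforced by tests: $\epsilon_{in}=\epsilon_{out}$ collapses the
expression *exactly* to the Coulomb potential $u\,q/(\epsilon d)$, and
$\alpha \to 0$ gives $u\,q/(\epsilon_{in} d)$.

The reference center for $r$ is the unweighted mean atom position. A vertex
set may carry its own designated center (e.g. when vertices were generated
for a structure whose center is known); the engines use it when present and
fall back to the structure center otherwise. $r$ is computed once per
vertex and shared by all kernel evaluations for that vertex.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `eps_in` | solute relative permittivity | 1 | typical protein interior values are 1–4 |
| `eps_out` | solvent relative permittivity | 80 | water at room temperature |
| `alpha` | ALPB constant | 0.580127 | exact-sphere value; configurable |
| `unit_factor` | output units | 1 | 332.0636 yields kcal/(mol·e); the default keeps analytic tests exact |
| `h_residue` | residue threshold, Å | 10 | first approximation level above atoms |
| `h_strand` | strand threshold, Å | 70 | second approximation level |
| `h_complex` | complex threshold, Å | ∞ | a single-complex structure is never approximated whole |
| `order` | approximate-charge order | 2 | see below |

## Hierarchical charge partitioning

A structure is partitioned along its natural organization: one complex,
strands keyed by chain id, residues keyed by (chain id, residue number),
atoms as leaves; strands and residues are ordered by first appearance so a
file round-trip preserves the hierarchy. Each component above the atom
level is summarized by:

* its geometric center (unweighted mean of member atom positions),
* its bounding radius (largest member-atom distance from that center),
* its total charge, and
* approximate point charges at both supported orders.

**Order 1** places the total (signed) charge at the $|q|$-weighted
centroid, falling back to the geometric center when all member charges are
zero. **Order 2** splits the members by charge sign and places each side's
total at that side's charge-weighted centroid; a side with zero total is
omitted. Order 2 therefore reduces to order 1 when all charges share one
sign, represents any one- or two-point charge set exactly, conserves total
charge exactly (as order 1 does), and preserves the leading dipole — which
matters because a neutral residue's order-1 summary carries no information
at all. Order 2 is the default for exactly that reason.

The per-vertex evaluation is a top-down traversal. At a component of level
$L$, if the vertex lies farther from the component's center than the
threshold $h_L$, the component contributes through its approximate charges
(each with its own $d$, sharing the vertex's $r$); otherwise the traversal
descends into its children, and atoms are always evaluated exactly. The
comparison is strictly `distance > threshold`, so a tie descends — the
conservative direction. The distance test uses the component center only;
the bounding radius is exposed on every component so users can check that
their thresholds comfortably exceed typical component extents (for the
default 10 Å residue threshold, residue bounding radii of ~2 Å leave a wide
margin). Comparing against center distance minus extent would be the more
conservative alternative; the plain center test is the simpler rule and the
one implemented.

Work is accounted as the number of single-charge kernel evaluations
(`kernel_calls`), the platform-neutral measure of cost, and a per-level
usage histogram: each time a component's approximate set serves one vertex
its level gains one count, and each exact atom evaluation counts one at the
atom level. The exact engine therefore reports `kernel_calls = N * P` and
all usage at the atom level.

## Numerical choices

* **Accumulation** is in double precision by default. The single-precision
  mode casts every kernel operand and the accumulator to 32-bit floats but
  keeps all threshold decisions in double, so both precision modes of the
  same traversal visit identical charge sets; the precision study thus
  isolates rounding error from approximation-path divergence.
* **Traversal order is fixed** — strands and residues in first-appearance
  order, atoms in file order — making results bit-reproducible per platform
  and precision. When atoms arrive already grouped by residue (as generator
  output and typical PQR files are), the HCP traversal at infinite
  thresholds performs the identical arithmetic as the exact engine and the
  two agree bit-for-bit.
* **Degenerate inputs**: a vertex coinciding with an atom, an approximate
  charge, or the reference center is a domain error naming the offending
  indices, not a silent Inf. Zero charges are evaluated like any other
  (they contribute 0); an all-zero-charge component at order 2 has an empty
  approximate set and contributes nothing.
* **Relative RMSE** is defined as
  $\mathrm{RMS}(\mathrm{test}-\mathrm{ref})/\mathrm{RMS}(\mathrm{ref})$ —
  scale-invariant and zero iff the arrays agree. The definition matters
  when comparing error tables across structures of very different potential
  magnitudes.

## The synthetic generator

Tests and characterization use synthetic structures so that every claim is
checkable without downloads. A spec fixes strand count, residues per
strand, atoms per residue, backbone step (default 3.8 Å, the Cα–Cα
spacing), residue extent (default 1.8 Å), and a charge law: `uniform`
(uniform(−0.5, 0.5) per atom, the generic partial-charge regime),
`neutral_residues` (per-residue totals shifted to exactly zero — the
hardest case for order-1 approximation), or `unit_dipole` (two atoms at
±0.5 e). Strand backbones are independent 3-D random walks; strand origins
are spread uniformly in a ball of radius
$1.5\,\cdot\,\text{spacing}\,\sqrt{\text{residues/strand}}\;n_{strands}^{1/3}$
(zero for a single strand) — the first factor is the walk's radius of
gyration scale, the second keeps per-strand spatial density roughly
constant as strands are added, which is how real multi-chain assemblies
grow. Vertices are placed by a Fibonacci spiral lattice on the sphere of
radius $R_{max} + \text{offset}$ about the structure center (offset 2 Å),
guaranteeing every kernel distance is at least the offset.

What the generator does *not* emulate: realistic secondary structure,
force-field charges and radii, excluded-volume packing, or true
solvent-excluded surfaces (the vertex sphere is a shell, not a molecular
surface). Passing tests therefore demonstrate the correctness and
scaling behaviour of the algorithms, and the qualitative accuracy/work
trade-off — not force-field-accurate potentials for any particular
protein.

## Fixture sizes and experiment design

The standard ensemble is 20 structures spanning 2–4 strands, 20–35
residues per strand, 3–5 atoms per residue, and both the `uniform` and
`neutral_residues` laws, with 80 vertices each — small enough that the full
ensemble evaluates in seconds, varied enough that distributional claims
(error controllability, work reduction) do not hinge on one geometry.

The scaling experiment uses 5 atoms per residue and 25 residues per strand
and grows the *strand count* with N (8 strands at N = 1,000, 16 at
N = 2,000). This choice is deliberate: sub-linear growth of HCP kernel
calls is an asymptotic far-field property, visible only when the structure
grows in spatial extent as well as atom count so that ever more components
fall beyond the 70 Å strand threshold. A structure that doubles its atom
count inside a fixed volume doubles its near field, and no correct
implementation shows sub-linear call growth there.

## Known limitations

* One complex per structure; multi-complex assemblies would need a forest
  above the current root.
* The approximation orders stop at the dipole split; quadrupole-accurate
  summaries would reduce the error further at the same thresholds.
* Potentials only — no forces, no gradients, no molecular dynamics.
* No wall-clock benchmarking: `kernel_calls` is the cost measure, since
  timing claims are hardware statements, not algorithm statements.
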