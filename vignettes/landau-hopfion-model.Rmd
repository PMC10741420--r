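---
title: "A Landau free-energy model of nucleosomal DNA on torus knots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Landau free-energy model of nucleosomal DNA on torus knots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfionDNA)
```

## The physical picture

Nucleosomal DNA — the ~147 bp wrapped ~1.75 left-handed turns around the
histone octamer — is treated here as *closed* circular DNA, because histone
H1 clamps the entry and exit points. Its conformation is then constrained by
White's formula, `Lk = Wr + Tw`. For a relaxed B-form double helix the
linking number is the number of helical turns, `Lk = N / n_i` with
`n_i = 10.5` bp per turn, so the canonical particle has `Lk = 147/10.5 = 14`,
writhe `Wr = -1.75` (left-handed wraps count negative), twist
`Tw = 14 - (-1.75) = 15.75`, and an average bending angle per superhelical
pitch of `|Wr| * 360° / Tw = 40°`.

```{r topology}
tidy(topology_state(lk = linking_number(147), wr = writhe_from_wrap(1.75, "left")))
```

The elastic cost of a conformation is written as a quadratic Landau
free-energy density in a normalised two-component complex order parameter
`Ψ` built from the Euler angles (φ, θ, χ) of the helix axis. Substituting
the Euler-angle parametrisation gives

$$F = \frac{B}{2}\left[\left(\frac{d\theta}{ds}\right)^2 +
\left(\frac{d\phi}{ds}\right)^2\sin^2\theta\right] +
\frac{C}{2}\left[\frac{d\phi}{ds}\cos\theta + \frac{d\chi}{ds}\right]^2,$$

where the first bracket is the squared curvature of the axis and the second
the squared torsion, `τ = (dφ/ds)cosθ + dχ/ds`; integrating `τ/2π` along the
molecule recovers the twist. The displayed grouping of the bending term is
the standard curvature expansion; it is also the only grouping under which
the torus-knot closed form below is an exact algebraic consequence, an
identity the test suite checks on random configurations.

## Parameters and units

| parameter | meaning | default | why |
|---|---|---|---|
| `lp_nm` | bending persistence length | 50 nm | canonical B-DNA value |
| `lt_nm` | torsional persistence length | 95 nm | canonical B-DNA value |
| `temperature_K` | temperature | 300 K | room temperature |
| `kB` | Boltzmann constant | 1.38e-23 J/K | fixed two-digit convention so B, C print as 2.07e-19 and 3.933e-19 J·nm |
| `bp_per_turn` | helical repeat | 10.5 bp | B-DNA |
| `r_deg` | mapped bending angle R | scenario-specific, 20° canonical | half the 40° bend per pitch |
| `m`, `n` | toroidal/poloidal angle rates | 1 | no physical estimate exists for them; unity is the symmetric choice, and both remain free parameters |

Two unit systems are carried side by side. In *reduced* units, arc length is
measured in the model's implicit unit and energies in $k_BT$, under which
the rigidities are numerically the persistence lengths, `B = 50`, `C = 95`.
All energy outputs default to reduced units because the model's reference
minima (938 and 1071 $k_BT$ per unit length) only take those values there;
`energy_to_si()` and the `units = "si"` argument convert back to joules.

## The torus-knot (Hopfion) reduction

A closed wrapped molecule is mapped onto a torus knot with toroidal winding
`P`, poloidal winding `Q`, and Hopf charge `W = P·Q` identified with the
linking number. The mapping pins the Euler angles to

$$\theta = 2R,\qquad \phi = P\varphi + Q\Theta,\qquad \chi = P\varphi - Q\Theta,$$

with `R` the bending angle after the mapping, constrained to (0°, 90°). With
constant coordinate rates `dφ/ds = m`, `dΘ/ds = n` and `dR/ds = 0`, the
general density collapses to the closed form

$$F(P) = \frac{B}{2}\left(Pm + \frac{W}{P}n\right)^2\sin^2(2R) +
2C\left(Pm\cos^2 R - \frac{W}{P}n\sin^2 R\right)^2 .$$

Two numerical conventions deserve a note:

* **Sign of the torsion factor.** The cross term of the expanded density is
  negative, which forces the minus sign inside the second bracket. The
  package treats the composition identity — closed form equals the general
  Euler density evaluated on the mapped rates — as the central correctness
  property and tests it to 1e-9 relative on 1000 random configurations.
* **Magnitudes.** `P` is identified with the magnitude of the wrap number
  (1.75 for the nucleosome); handedness signs live on the topology side
  (`Wr = -1.75`), and the conversion happens in exactly one place,
  `writhe_from_wrap()`.

Since `F` is independent of arc length under these assumptions, the total
energy of a molecule of reduced length `b` is just `F·b`
(`total_energy()`).

## Scans, minima, and the integer constraint

`energy_profile()` scans `F(P)` on a grid with `Q = W/P` held continuous.
The default grid is `[0.5, W]` in steps of 0.1 — the resolution at which the
reference argmins (1.9, 2.1) are stated; the profile range itself is a
package choice, as no canonical range exists. The best grid point is then
refined by bounded scalar minimisation (`stats::optimize`, tolerance 1e-8 in
`P`, bracketed by the neighbouring grid points), and both grid and refined
results are reported; the refined minimum is clamped never to exceed the
grid minimum, so degenerate one-point brackets stay safe.

Non-integer `P` values are scanned deliberately: the physically admissible
states have integer windings (`hopf_factorizations()` enumerates them and
`integer_minimum()` minimises over them, ties broken toward smaller `P`),
but the continuous profile is what reveals where the minimum sits relative
to the real nucleosome's `P = 1.75`.

```{r scan}
glance(energy_profile(14, r_deg = 20))
tidy(integer_minimum(14, r_deg = 20))
```

For the canonical charge `W = 14` the integer minimum is at `P = 2`, and the
continuous minimum lies nearby — the behaviour that motivates reading the
nucleosome's geometry as an energy-minimising design. The refined minimum
value grows monotonically with both `R` (over 18°–22°) and `W` (over
6–18), and the differences between neighbouring minima are small, which is
the model's account of conformational redundancy: small perturbations of
the wrap cost little energy.

## The effective B–Z potential

Torque-driven interconversion between right- and left-handed helices is
modelled by a tilted quartic double well in the chiral gauge variable ρ (the
rotation angle between successive base pairs, rad/bp):

$$V_{\mathrm{eff}}(\rho) = V_0\left[\left(\frac{\rho}{\omega_0}\right)^2 - 1\right]^2 -
(\tau - \tau_c)\,\rho,$$

with `V0 = 6e-21` J, `ω0 = 2π/10.5` rad/bp and critical torque
`τc = -7.9e-21` J. Stationary points solve a depressed cubic, handled in
closed form — the trigonometric method when the discriminant is positive
(three real roots), Cardano otherwise, and the `τ = τc` case short-circuited
so the symmetric roots `{-ω0, 0, +ω0}` are exact — with classification by
the sign of the second derivative. Tests cross-check the roots against a
dense-scan-plus-bisection oracle. The units of ρ are taken as rad/bp,
matching ω0, since no other convention is self-consistent.

```{r veff}
veff_stationary_points(effective_potential(tau = -5e-21))
```

## Degenerate inputs and numerical edges

* `theta` (and `2R`) are kept strictly inside their open intervals with a
  1e-9 guard band; the exact poles are reachable only through the closed-form
  limits (`F(R→0) = 2C(Pm)²`, `F(R→90°) = 2C(Qn)²`), which the tests verify.
* White's formula is enforced to 1e-12 on every constructed topology state;
  linking numbers are kept exact and rounded to integers only on request
  (`lk_integer()`, residual tolerance 1e-9).
* Twist integration uses trapezoidal quadrature on the caller's own grid —
  no hidden resampling — so its second-order convergence is directly
  testable.
* The trigonometric cubic branch clamps its `acos` argument to [-1, 1] to
  absorb rounding at the discriminant boundary.

## What the presets emulate — and what they do not

The preset scenarios (`list_scenarios()`) encode idealised wrap geometries:
147 bp/1.75 turns (with bending-angle variants at 5°–30°), 63 bp/0.75
turns, 168 bp/2 turns, 189 bp/2.25 turns. They assume a perfectly uniform,
sequence-independent elastic rod, exact closure of the wrapped segment,
commensurate lengths (integer `Lk`), constant `R`, `m = n = 1`, and no
histone–DNA binding energetics, electrostatics or salt dependence. Passing
tests therefore demonstrate the internal consistency of the elastic model
and the reproduction of its reference values — not agreement with any
particular crystal structure or single-molecule measurement. Problem sizes
are small throughout (grids of ~10²–10³ points; 10²–10³ random draws in the
property tests), so the whole suite runs in seconds.

## Known limitations

* `Wr` and `Tw` are taken as inputs (wrap turns, handedness); the package
  does not compute them from 3-D space curves via Gauss integrals.
* The Euler–Lagrange problem for the general density is out of scope: the
  functional is evaluated on given paths, never minimised over paths.
* The relation between general DNA knots and torus knots is only a mapping
  assumption; `m` and `n` have no independent physical estimate.
* The magnetic-tweezer experiment behind the effective potential is not
  modelled — only the potential itself.
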