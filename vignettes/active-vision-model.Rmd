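---
title: "The generative model behind activevision: scenes, saccades, and salience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The generative model behind activevision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

activevision is a desk-scale simulator of active vision: it generates
binocular retinal images from an explicit hierarchical scene model and a
gaze state, simulates the saccadic dynamics that move the eyes between
fixations, and scores candidate fixations by how much they are expected to
tell the observer about the world. This vignette documents the model itself:
the assumptions baked into each stage, the parameters that matter, the
numerical choices, and what the simulator can and cannot show.

## The scene hierarchy

Everything visible is a triangulated surface mesh, and every mesh is built
from one primitive: the unit sphere (`make_sphere_mesh()`), triangulated by
latitude-longitude subdivision with a deterministic vertex ordering. Objects
are recursive compositions: a spec is either a sphere or a list of child
specs, each carried into its parent's frame by an affine transform. The
transform order within each node is fixed as scale, then rotate, then
translate, mirroring the order in which the corresponding generative factors
condition one another.

Three conventions are worth stating because nothing else pins them down:

* **Coordinates** are right-handed, z up, in meters; angles are radians.
  Heading is measured counterclockwise from +x, so positive heading (and
  positive azimuth in the visual field) is egocentric *left*.
* **Scaling** parameters are log-scale: vertex coordinates are multiplied by
  `exp(scale)` componentwise. This makes scales positive by construction --
  a Gaussian prior over the parameters can never produce a reflection -- at
  the cost of excluding reflections and shears, which we do not implement.
* **Rotation** uses intrinsic rotations composed as
  `R = Rz(varphi) %*% Ry(phi) %*% Rx(theta)`. The axis order here is a
  package decision: it is documented, tested against the explicit
  composition of single-axis matrices, and used consistently everywhere,
  but other orders would serve equally well. Nothing downstream depends on
  the choice beyond its consistency.

The transforms are deterministic maps (no noise is injected at geometry
level; uncertainty lives in the priors over parameters, not in the geometry
itself). They deliberately do not commute -- rotating an anisotropically
scaled object is not the same as scaling a rotated one -- which is why the
recursion applies them in a fixed order and why `assemble_object()` is
tested against an oracle that flattens each leaf's transform chain into a
single matrix.

A *room* is a list of placed objects plus optional walls; a *room library*
adds a categorical prior over rooms. The prior is the top of the hierarchy:
conditioned on the room, every surface is determined. `lesion_object_hypothesis()`
implements object agnosia at this level by deleting every placement of a
named object from the model, so the lesioned model can never generate that
object's surfaces.

## The demonstration world

`build_demo_library()` constructs the fixture used throughout the tests and
the worked examples: three 4 x 4 x 3 m rooms under a uniform prior, viewed
from the room centre at eye height 1.5 m. Object 1 (a two-sphere snowman,
radii 0.28 m and 0.20 m) occupies the southeast corner in rooms 2 and 3 and
is absent from room 1; the northeast corner is empty everywhere; rooms 2 and
3 differ only in whether object 2 (a prolate ellipsoid, semi-axes 0.35 /
0.15 / 0.15 m) sits southwest or northwest (room 1 has it in both west
corners). Object centres sit at 1.1 m so that a gaze elevation of -0.2 rad
from eye height brings them comfortably inside a 40 degree field of view.

Two construction details are deliberate:

* **Walls are floor plus four sides, with no ceiling**, and the default
  light is a nearly vertical directional source. A closed box would put
  every interior surface in shadow of the ceiling, flattening all views to
  the ambient level and erasing the contrast the scenario depends on.
  Normals face the interior, since the viewer is inside.
* **The shared object-1 placement is bit-identical across rooms 2 and 3**,
  and the distinguishing objects sit well outside a southeast- or
  northeast-directed 40 degree cone. Renders of those views are therefore
  *exactly* equal across the rooms that should be indistinguishable, so
  outcome clustering at a tight tolerance behaves like the idealized
  discrete outcome space of the scenario.

## From gaze state to field of view

The allocentric gaze is the componentwise sum of head direction and
egocentric eye direction, heading wrapped into `(-pi, pi]`. The retina is a
uniformly spaced pinhole array -- a small foveal patch; log-polar retinal
topography is out of scope -- whose cells are tuples of a position in front
of the lens and a unit preferred-incidence direction. The outermost cells
sit at exactly half the angular extent, so the grid endpoints are exact and
the step refines as `extent / (n - 1)`.

The two eyes sit at the head position offset by half the interocular
baseline (default 0.06 m, a standard adult value; configurable, and set to 0
in tests that require exact left/right symmetry) along the head-left axis.
Convergence splits the two gaze headings symmetrically by `omega`. The
proprioceptive read-out (below) uses left `= theta - omega/2`; the field of
view splits as left `= p + omega/2`. Both satisfy the defining property --
the headings differ by exactly `omega` -- and the two signs are each applied
consistently within their module.

## Rendering

Rendering is single-bounce ray casting: for each retinal cell, trace the
line of sight, find the nearest surface (Moller-Trumbore intersection,
nearest hit, ties broken toward the lowest face index), and shade it as

```
intensity = ambient + lit * (c1 * max(0, v_n . z) + c2 * max(0, v_n . h)^c3)
```

where `z` is the unit direction toward the (infinitely distant) light,
`v_n` the surface normal, `h` the Blinn half-vector between the viewing
direction and `z`, and `lit` a shadow indicator obtained by casting a ray
from the hit point toward the light. Multi-bounce inter-surface reflection
is out of scope: light reaches a surface directly from the source or not at
all, and a shadowed point receives exactly the ambient level. We clamp the
specular dot product at zero before exponentiation (standard Blinn
practice), treat the source intensity inside the reflected term as a unit
constant, and take the shading constants `ambient = 0.1`, `c1 = 0.6`,
`c2 = 0.3`, `c3 = 8` as configurable defaults chosen to give visibly
distinct ambient, diffuse and specular regimes on the demo objects; no
canonical values exist for them.

Numerical guards: ray-triangle intersections require `t > 1e-9` to avoid
self-intersection; shadow rays start `1e-6` along the surface normal;
zero-area faces are skipped with a warning.

The image is written at the retinally *inverted* grid location -- flipped
across both axes -- so surfaces up and to the egocentric left activate
cells down and to the right, as pinhole optics dictate. This is what makes
the two lesion modes anatomically meaningful: zeroing one eye's image
reproduces monocular blindness (pre-chiasmatic), while deleting all
surfaces on one egocentric side of the head darkens the *same* side of both
retinal images -- the homonymous hemianopia pattern of a post-chiasmatic
lesion. Scene-side lesions act on the generative model before rendering;
monocular lesions are applied to the finished images.

Finally, the shaded image passes through a low-pass blur implemented in the
DCT domain: take the orthonormal 2-D type-II DCT, multiply coefficient
`(p, q)` by `exp(-(p^2 + q^2) / (2 sigma^2))`, invert. The DC coefficient is
multiplied by exactly 1, so the mean is preserved; the default
`sigma = min(n_rows, n_cols) / 6` attenuates the top of the spectrum to
near zero while leaving low frequencies essentially intact. The DCT is
computed by explicit orthonormal matrices (images here are at most a few
thousand pixels, so there is nothing to gain from an FFT factorization), and
the inverse transform's tiny negative excursions are clamped at zero with
the pre-clamp minimum reported as an attribute. Blurring follows rendering
and precedes the monocular zeroing; since the blur is linear and the zeroed
image is identically zero, the order relative to the monocular lesion is
immaterial.

## Saccadic dynamics and proprioception

Both eyes are driven by one conjugate state `theta = (heading, elevation)`
obeying a damped second-order plant,

```
J * theta'' = phi - theta - kappa * theta'
```

with `phi` the equilibrium point (the saccade target, in the
equilibrium-point reading of motor control), `J` the moment of inertia and
`kappa` the damping. The defaults `J = 1`, `kappa = 2` place the plant
exactly at critical damping -- the fastest approach to the target with no
overshoot or oscillation. No canonical numeric values exist for these
constants; both are configurable, and the behaviour of interest (relaxation
to `phi`, energy dissipation) holds for any `J > 0`, `kappa > 0`.

The simulator integrates this plant with fixed-step RK4 and, because the
plant is linear, carries its own exact solution: `closed_form_state()`
solves the characteristic equation per axis in the under-, over- and
critically damped regimes, and the test suite holds the integrator to within
1e-6 of it over a 2 s trajectory at `dt = 1e-3`. A Lyapunov function
(kinetic plus spring energy) is checked to be non-increasing at every step.

The proprioceptive read-out maps the state to II (position) and Ia
(velocity) afferents per eye. The convergence angle offsets the *heading*
II channels only -- left eye `theta - omega/2`, right eye
`theta + omega/2` -- while the elevation channels are identical across
eyes, because conjugate eye movements differ only in heading. With a seed,
Gaussian process noise of covariance `Pi_f^-1 * dt` enters the velocity
rows after each step (noise on the position rows would model slippage of
the kinematic constraint itself, which we do not intend), and sensory noise
of covariance `Pi_g^-1` corrupts every afferent channel. The default
precisions of `1e4` give noise of a few milliradians -- visible on a plot
but small against a 0.3 rad saccade. Without a seed the simulation is
noiseless and bit-reproducible.

## Salience: predictive entropy, ambiguity, information gain

A policy is a candidate gaze. Its epistemic value is the mutual information
between the room (the latent cause) and the predicted retinal observation
under that policy, which the package computes as predictive entropy minus
expected ambiguity and reports in bits (the log base is a package choice;
no canonical base exists).

Because the renderer is deterministic, the outcome space is discretized by
clustering: the policy's view is rendered in every room of non-zero belief,
and renders whose maximum absolute pixel difference is within `tol`
(default 1e-6) are one outcome, with probability equal to the summed belief
of their rooms. In the demo world this recovers the idealized discrete
outcomes exactly, because indistinguishable views are bit-identical by
construction. The conditional `P(y | room)` is then a point mass, so the
expected ambiguity is exactly zero and the information gain equals the
predictive entropy. The opposite extreme -- eyes closed, every retinal cell
equally likely to report any of `K` intensity bins regardless of the room
-- is exposed as `noise_uniform_bins()`, contributing `n_cells * log2(K)`
bits of ambiguity. Neither variant is asserted to be the "true" noise model
of rendered images; they bracket the two readings.

`mutual_information_oracle()` evaluates, by direct summation on a discrete
joint table, the three algebraically equal faces of the mutual information
(joint-versus-marginals KL, expected prior-to-posterior KL, entropy minus
ambiguity); the suite verifies their agreement to 1e-10 on random tables
and verifies that the planner's gain matches all three on the joint implied
by its own outcome clustering. `rank_policies()` orders policies by gain,
ties broken lexicographically by label; the report is a ranking only -- the
package deliberately asserts no softmax policy-selection distribution,
since none is canonical.

Belief updating is exact Bayes with the deterministic renderer as
likelihood: posterior proportional to prior times an indicator of whether
the room's render matches the observation within `tol`. Zero-prior rooms
can never be resurrected, and an observation inconsistent with every
credible room raises an error rather than silently returning an all-zero
belief.

## Problem sizes and reproducibility

The package's working resolution for the salience scenario is a 32 x 32
retinal array per eye over a 40 degree field, with sphere resolution 6
(about 370 faces for the richest demo room): fine enough to resolve the
demo objects cleanly, and small enough that a full binocular render takes
well under a second and the complete two-view scenario runs in seconds.
Unit tests use 9-16 pixel grids where the property under test does not
depend on resolution. `scripts/acceptance.R` re-runs the whole pipeline --
scenario entropies and ranking, the sequential belief update, the
mutual-information residual, and the saccade-versus-closed-form error --
from scratch and writes the numbers as JSON.

## What the demo world does and does not show

The fixture emulates the structure of the motivating scenario: categorical
uncertainty over a small set of rooms, objects whose presence or absence at
known locations is the only thing that varies, a deterministic renderer,
and exact repetition of views. Real scenes differ in ways that matter:
observations are noisy, so likelihoods are not indicators and outcome
clustering at a fixed tolerance is a modelling choice rather than exact;
object locations and identities vary continuously; photoreceptor sampling
is strongly non-uniform; and illumination is neither directional nor
single-bounce. Passing tests therefore certify the internal consistency of
the generative model and its information-theoretic planner -- not
quantitative fidelity to biological retinas or natural scenes.

Other known limitations: no color or texture (shading constants are global
rather than surface-varying), no head dynamics or vestibular signals, no
inhibition of return (beliefs change only through `update_belief()`), no
generalized coordinates of motion in the plant, and no approximate
inference -- the posterior over rooms is exact enumeration, which is the
point at this scale but does not extend to large scene spaces.
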