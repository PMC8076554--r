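# activevision

A desk-scale simulator of **active vision** built around an explicit
generative model, for computational neuroscientists and active-inference
researchers who want a transparent, fully inspectable alternative to learned
scene renderers. The package answers three questions in code:

1. **Seeing** — how does a hierarchical scene model (rooms → objects →
   parts → surfaces) plus a gaze state generate a pair of retinal images?
2. **Looking** — what dynamics move the eyes to a new fixation, and what
   proprioceptive signals do those movements produce?
3. **Where to look** — which candidate fixation is most informative about
   the world, and how do beliefs change once we have looked?

## The model in brief

**Scenes.** Every surface is a triangle mesh built from one primitive, the
unit sphere, by recursive affine transformation: vertices are scaled by
`exp(α, β, γ)` (log-scale parameters, so scales are positive by
construction), rotated by `R = R_z(φ″) R_y(φ) R_x(θ)`, and translated.
Objects compose recursively; a room is a set of placed objects plus walls;
a room library adds a categorical prior `P(room)`.

**Rendering.** For each retinal cell of a uniformly spaced pinhole array,
the renderer casts the line of sight, finds the nearest surface, and shades
it with a single-bounce Blinn–Phong model with cast shadows:

```
I = α_amb + η · ( c₁ · max(0, v_n·z) + c₂ · max(0, v_n·h)^c₃ )
```

where `z` is the light direction, `v_n` the surface normal, `h` the half
vector, and `η ∈ {0,1}` a shadow indicator. The image is retinally inverted
across both axes, then low-pass filtered in the DCT domain (Gaussian
attenuation of high-frequency coefficients; the mean is preserved exactly).
Lesion modes reproduce monocular blindness (one eye zeroed), homonymous
hemianopia (all surfaces on one egocentric side deleted, darkening the same
side of *both* retinas), and object agnosia (an object hypothesis removed
from the model).

**Saccades.** Both eyes follow one conjugate state `θ` of a damped
second-order plant, `J θ̈ = φ − θ − κ θ̇`, relaxing to the equilibrium
point `φ` (critical damping by default). II/Ia proprioceptive afferents
report position and velocity per eye; convergence `ω` offsets the heading
channels by `±ω/2`. The linear plant's exact closed-form solution ships
alongside the RK4 integrator as its oracle.

**Salience.** A candidate fixation is scored by expected information gain —
the mutual information between rooms and predicted observations:

```
I[room; y | π] = H[P(y|π)]  −  E_room H[P(y|room,π)]
               = predictive entropy − expected ambiguity   (bits)
```

With the deterministic renderer the ambiguity is zero and the gain is the
entropy of the clustered outcome distribution. Beliefs update by exact
Bayes against rendered observations.

## Worked example: the two-view salience scenario

Three rooms under a uniform prior; object 1 sits in the southeast corner in
rooms 2 and 3 only, and the northeast corner is empty everywhere.

```r
library(activevision)

lib <- build_demo_library()                       # three rooms, prior (⅓,⅓,⅓)
ctx <- render_context(build_retinal_array(32, 32))
pols <- list(policy("southeast", head_dir = c(-pi/4, -0.2)),
             policy("northeast", head_dir = c( pi/4, -0.2)))

rank_policies(rep(1/3, 3), pols, lib, ctx)
#>      policy predictive_entropy_bits expected_ambiguity_bits info_gain_bits rank
#> 1 southeast               0.9182958                       0      0.9182958    1
#> 2 northeast               0.0000000                       0      0.0000000    2
```

The southeast view can show either an empty corner (room 1, probability ⅓)
or object 1 (rooms 2–3, probability ⅔), so its predictive entropy is
`H(⅓, ⅔) = 0.918` bits; the northeast view looks the same in every room and
is worth exactly 0 bits. Now look southeast and see object 1:

```r
o   <- predictive_outcomes(rep(1/3, 3), pols[[1]], lib, ctx)
obs <- Filter(function(cl) 2 %in% cl$members, o$clusters)[[1]]$images
update_belief(rep(1/3, 3), obs, pols[[1]], lib, ctx)
#> [1] 0.0 0.5 0.5
```

Room 1 is ruled out; rooms 2 and 3 remain equally likely. Under this
posterior both original views score 0 bits, and the southwest/northwest
corners — where the two remaining rooms differ — become the salient
fixations (1 bit each).

A saccade toward `φ = (0.3, 0.2)` rad with the default critically damped
plant:

```r
tr <- integrate_saccade(oculo_state(), motor_command(c(0.3, 0.2)),
                        plant_params(omega = 0.1), dt = 1e-3, T = 2)
tail(tr[, 1:5], 1)
#>      time theta_h theta_e dtheta_h dtheta_e
#> 2001    2  0.1782  0.1188   0.0812  0.05413
```

(Still mid-flight at 2 s: critical damping at rate 1/s closes the remaining
error as `(a + bt)e^{-t}`.) The II heading afferents of the two eyes differ
by exactly `ω = 0.1` rad at every sample; the elevation afferents are
identical — eye movements are conjugate.

## Command line

A thin dispatcher lives at `inst/cli/activevision`:

```sh
Rscript inst/cli/activevision render  config.json   # PGM images + manifest
Rscript inst/cli/activevision saccade config.json   # trajectory CSV (+ plot)
Rscript inst/cli/activevision plan    config.json   # salience report CSV
Rscript inst/cli/activevision lesion-demo out/      # lesion gallery
```

Configs are JSON (see `?read_run_config`); exit code 2 signals a
configuration error.

## Package layout

- `R/mesh.R`, `R/scene.R` — sphere primitive, affine transforms, recursive
  object/room assembly, demo world, agnosia lesion, JSON scene configs
- `R/viewpoint.R` — allocentric gaze, retinal arrays, binocular field of view
- `R/render.R` — ray casting, Blinn–Phong shading, DCT blur, lesion modes
- `R/oculomotor.R` — saccadic plant, closed-form oracle, RK4, II/Ia afferents
- `R/planner.R` — outcome clustering, entropies, information gain, Bayes
- `R/cli.R`, `inst/cli/activevision` — run configs and shell entry point
- `vignettes/active-vision-model.Rmd` — the model, its assumptions, and
  every numerical choice, in detail
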